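## Plain-text table dialect.
##
## UTF-8; a sequence-length header "#L <float>" followed by four sections
## introduced by "#nodes", "#edges", "#sites", "#mutations".  Each section
## starts with a tab-separated column-header line and holds one row per
## line, columns tab-separated.  Floats are written with the shortest
## representation that round-trips exactly, so load(dump(x)) is the
## identity.  Metadata strings are escaped (\t, \n, \\) so arbitrary bytes
## survive the round trip.

fmt_float <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- sprintf("%.15g", x[i])
    if (as.numeric(s) != x[i]) {
      s <- sprintf("%.16g", x[i])
      if (as.numeric(s) != x[i]) {
        s <- sprintf("%.17g", x[i])
      }
    }
    out[i] <- s
  }
  out
}

escape_meta <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  gsub("\n", "\\n", x, fixed = TRUE)
}

unescape_meta <- function(x) {
  vapply(x, function(s) {
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    out <- character(0)
    i <- 1L
    while (i <= length(chars)) {
      ch <- chars[i]
      if (ch == "\\" && i < length(chars)) {
        nxt <- chars[i + 1L]
        out <- c(out, switch(nxt, t = "\t", n = "\n", "\\" = "\\", nxt))
        i <- i + 2L
      } else {
        out <- c(out, ch)
        i <- i + 1L
      }
    }
    paste0(out, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Write tables in the text dialect
#'
#' Serializes a collection to a plain-text, tab-separated format with one
#' section per table.  The format is lossless: all floating point columns use
#' shortest round-trip representations and [load_text()] recovers the
#' collection exactly.
#'
#' @param tables A [table_collection()].
#' @param destination A file path or connection.
#' @return `destination`, invisibly.
#' @seealso [load_text()]
#' @export
dump_text <- function(tables, destination) {
  check_tables_arg(tables)
  lines <- c(
    paste0("#L ", fmt_float(tables$sequence_length)),
    "#nodes",
    "time\tis_sample\tmetadata"
  )
  if (num_nodes(tables)) {
    lines <- c(lines, paste(
      fmt_float(tables$node_time),
      as.integer(tables$node_is_sample),
      escape_meta(tables$node_metadata),
      sep = "\t"
    ))
  }
  lines <- c(lines, "#edges", "left\tright\tparent\tchild")
  if (num_edges(tables)) {
    lines <- c(lines, paste(
      fmt_float(tables$edge_left), fmt_float(tables$edge_right),
      tables$edge_parent, tables$edge_child,
      sep = "\t"
    ))
  }
  lines <- c(lines, "#sites", "position\tancestral_state")
  if (num_sites(tables)) {
    lines <- c(lines, paste(
      fmt_float(tables$site_position), tables$site_ancestral,
      sep = "\t"
    ))
  }
  lines <- c(lines, "#mutations", "site\tnode\tderived_state")
  if (num_mutations(tables)) {
    lines <- c(lines, paste(
      tables$mut_site, tables$mut_node, tables$mut_derived,
      sep = "\t"
    ))
  }
  writeLines(lines, destination, useBytes = TRUE)
  invisible(destination)
}

parse_error <- function(lineno, msg) {
  stop(sprintf("text tables parse error at line %d: %s", lineno, msg),
       call. = FALSE)
}

#' Read tables from the text dialect
#'
#' Parses the format written by [dump_text()].  Malformed headers,
#' non-numeric fields, wrong column counts and dangling node/site references
#' raise errors naming the offending line.
#'
#' @param source A file path or connection.
#' @return A [table_collection()].
#' @export
load_text <- function(source) {
  lines <- readLines(source, warn = FALSE)
  if (length(lines) == 0L || !startsWith(lines[1], "#L ")) {
    parse_error(1L, "expected sequence-length header '#L <float>'")
  }
  L <- suppressWarnings(as.numeric(sub("^#L ", "", lines[1])))
  if (is.na(L) || L <= 0) {
    parse_error(1L, "sequence length must be a float > 0")
  }
  section_names <- c("#nodes", "#edges", "#sites", "#mutations")
  headers <- list(
    "#nodes" = "time\tis_sample\tmetadata",
    "#edges" = "left\tright\tparent\tchild",
    "#sites" = "position\tancestral_state",
    "#mutations" = "site\tnode\tderived_state"
  )
  starts <- match(section_names, lines)
  if (anyNA(starts)) {
    parse_error(length(lines),
                paste("missing section:", section_names[which(is.na(starts))[1]]))
  }
  if (is.unsorted(starts, strictly = TRUE) || starts[1] != 2L) {
    parse_error(starts[1], "sections must appear in order nodes, edges, sites, mutations")
  }
  bounds <- c(starts, length(lines) + 1L)

  section_rows <- function(k) {
    hdr_line <- starts[k] + 1L
    if (hdr_line >= bounds[k + 1L]) {
      parse_error(starts[k], paste("section", section_names[k], "missing column header"))
    }
    if (lines[hdr_line] != headers[[section_names[k]]]) {
      parse_error(hdr_line, sprintf(
        "bad column header for %s: expected '%s'", section_names[k],
        gsub("\t", ", ", headers[[section_names[k]]])
      ))
    }
    rng <- seq.int(hdr_line + 1L, length.out = bounds[k + 1L] - hdr_line - 1L)
    rng[nzchar(lines[rng])]
  }
  num_field <- function(x, lineno, what) {
    out <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(out) | !nzchar(x))
    if (length(bad)) {
      parse_error(lineno[bad[1]], sprintf("non-numeric %s field '%s'", what, x[bad[1]]))
    }
    out
  }
  int_field <- function(x, lineno, what) {
    out <- num_field(x, lineno, what)
    bad <- which(out != floor(out))
    if (length(bad)) {
      parse_error(lineno[bad[1]], sprintf("%s field '%s' is not an integer", what, x[bad[1]]))
    }
    as.integer(out)
  }
  split_cols <- function(rows, ncol, what) {
    parts <- strsplit(lines[rows], "\t", fixed = TRUE)
    # a trailing empty field (e.g. empty metadata) is dropped by strsplit
    parts <- lapply(parts, function(p) c(p, rep("", max(0L, ncol - length(p)))))
    bad <- which(vapply(parts, length, 1L) != ncol)
    if (length(bad)) {
      parse_error(rows[bad[1]], sprintf("expected %d tab-separated %s columns", ncol, what))
    }
    lapply(seq_len(ncol), function(j) vapply(parts, `[[`, "", j))
  }

  rows <- section_rows(1L)
  if (length(rows)) {
    cols <- split_cols(rows, 3L, "node")
    is_samp <- int_field(cols[[2]], rows, "is_sample")
    if (any(!is_samp %in% c(0L, 1L))) {
      parse_error(rows[which(!is_samp %in% c(0L, 1L))[1]], "is_sample must be 0 or 1")
    }
    node_time <- num_field(cols[[1]], rows, "time")
    node_is_sample <- is_samp == 1L
    node_metadata <- unescape_meta(cols[[3]])
  } else {
    node_time <- numeric(0); node_is_sample <- logical(0); node_metadata <- character(0)
  }

  rows <- section_rows(2L)
  if (length(rows)) {
    cols <- split_cols(rows, 4L, "edge")
    edge_left <- num_field(cols[[1]], rows, "left")
    edge_right <- num_field(cols[[2]], rows, "right")
    edge_parent <- int_field(cols[[3]], rows, "parent")
    edge_child <- int_field(cols[[4]], rows, "child")
    bad <- which(edge_parent < 0L | edge_parent >= length(node_time) |
                   edge_child < 0L | edge_child >= length(node_time))
    if (length(bad)) {
      parse_error(rows[bad[1]], sprintf(
        "edge references node %d but the node table has %d rows",
        max(edge_parent[bad[1]], edge_child[bad[1]]), length(node_time)
      ))
    }
  } else {
    edge_left <- edge_right <- numeric(0); edge_parent <- edge_child <- integer(0)
  }

  rows <- section_rows(3L)
  if (length(rows)) {
    cols <- split_cols(rows, 2L, "site")
    site_position <- num_field(cols[[1]], rows, "position")
    site_ancestral <- cols[[2]]
  } else {
    site_position <- numeric(0); site_ancestral <- character(0)
  }

  rows <- section_rows(4L)
  if (length(rows)) {
    cols <- split_cols(rows, 3L, "mutation")
    mut_site <- int_field(cols[[1]], rows, "site")
    mut_node <- int_field(cols[[2]], rows, "node")
    mut_derived <- cols[[3]]
    bad <- which(mut_site < 0L | mut_site >= length(site_position) |
                   mut_node < 0L | mut_node >= length(node_time))
    if (length(bad)) {
      parse_error(rows[bad[1]], "mutation references a site or node out of range")
    }
  } else {
    mut_site <- mut_node <- integer(0); mut_derived <- character(0)
  }

  new_table_collection(
    L,
    node_time = node_time, node_is_sample = node_is_sample,
    node_metadata = node_metadata,
    edge_left = edge_left, edge_right = edge_right,
    edge_parent = edge_parent, edge_child = edge_child,
    site_position = site_position, site_ancestral = site_ancestral,
    mut_site = mut_site, mut_node = mut_node, mut_derived = mut_derived
  )
}
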