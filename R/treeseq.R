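#' Construct a tree sequence from tables
#'
#' A tree sequence is a validated, canonically sorted snapshot of a table
#' collection, ready for marginal-tree traversal.  The constructor copies the
#' tables (so later in-place edits of `tables` do not leak in), sorts the
#' copy, validates it, and precomputes the edge insertion and removal orders
#' used by the sweep.
#'
#' @param tables A [table_collection()] passing [validate_tables()].
#' @return An object of class `"tree_sequence"`.
#' @seealso [trees()], [tree_at()], [variants()], [diversity()]
#' @export
tree_sequence <- function(tables) {
  check_tables_arg(tables)
  tc <- copy_tables(tables)
  sort_tables(tc)
  val <- validate_tables(tc)
  if (!val$ok) {
    stop(sprintf("tables do not form a valid tree sequence (%d violations; see validate_tables())",
                 nrow(val$violations)))
  }
  ts <- list(
    sequence_length = tc$sequence_length,
    node_time = tc$node_time,
    node_is_sample = tc$node_is_sample,
    node_metadata = tc$node_metadata,
    samples = which(tc$node_is_sample) - 1L,
    edge_left = tc$edge_left,
    edge_right = tc$edge_right,
    edge_parent = tc$edge_parent,
    edge_child = tc$edge_child,
    site_position = tc$site_position,
    site_ancestral = tc$site_ancestral,
    mut_site = tc$mut_site,
    mut_node = tc$mut_node,
    mut_derived = tc$mut_derived,
    # sweep indexes: insertion by left, removal by right
    in_order = order(tc$edge_left, tc$node_time[tc$edge_parent + 1L], tc$edge_parent),
    out_order = order(tc$edge_right, -tc$node_time[tc$edge_parent + 1L], tc$edge_parent)
  )
  class(ts) <- "tree_sequence"
  ts
}

#' @export
print.tree_sequence <- function(x, ...) {
  cat(sprintf(
    "<tree_sequence> L = %g: %d samples, %d nodes, %d edges, %d sites, %d trees\n",
    x$sequence_length, length(x$samples), length(x$node_time),
    length(x$edge_left), length(x$site_position), length(trees(x))
  ))
  invisible(x)
}

#' Tables of a tree sequence
#'
#' Recover the (sorted) table collection underlying a tree sequence.
#'
#' @param ts A [tree_sequence()].
#' @return A new [table_collection()].
#' @export
ts_tables <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  new_table_collection(
    ts$sequence_length,
    node_time = ts$node_time, node_is_sample = ts$node_is_sample,
    node_metadata = ts$node_metadata,
    edge_left = ts$edge_left, edge_right = ts$edge_right,
    edge_parent = ts$edge_parent, edge_child = ts$edge_child,
    site_position = ts$site_position, site_ancestral = ts$site_ancestral,
    mut_site = ts$mut_site, mut_node = ts$mut_node,
    mut_derived = ts$mut_derived
  )
}

new_marginal_tree <- function(left, right, parent, ts) {
  structure(
    list(left = left, right = right, parent = parent,
         time = ts$node_time, samples = ts$samples),
    class = "marginal_tree"
  )
}

#' @export
print.marginal_tree <- function(x, ...) {
  cat(sprintf("<marginal_tree> interval [%g, %g), %d roots\n",
              x$left, x$right, num_roots(x)))
  invisible(x)
}

#' Marginal trees of a tree sequence
#'
#' Sweeps along the genome, maintaining the current tree as a parent-pointer
#' vector: at each breakpoint the edges whose intervals end there are
#' removed and those that begin there are inserted, so the cost of moving
#' between adjacent trees is proportional to the number of edges that
#' change, not to the tree size.  Consecutive intervals whose trees are
#' identical (possible when the edge table is not squashed) are merged, so
#' the returned intervals tile `[0, L)` and each tree differs from its
#' neighbours.
#'
#' @param ts A [tree_sequence()].
#' @return A list of `marginal_tree` objects, each with fields `left`,
#'   `right` and `parent` -- an integer vector over all nodes giving each
#'   node's parent id at this position, `NA` where the node has none.
#' @export
trees <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  sweep_trees(ts)$trees
}

# Shared sweep: builds the tree list and per-breakpoint edge turnover.
sweep_trees <- function(ts) {
  E <- length(ts$edge_left)
  nn <- length(ts$node_time)
  L <- ts$sequence_length
  I <- ts$in_order
  O <- ts$out_order
  parent <- rep(NA_integer_, nn)
  out <- list()
  diffs <- list()
  j <- 1L
  k <- 1L
  x <- 0
  repeat {
    n_out <- 0L
    n_in <- 0L
    while (k <= E && ts$edge_right[O[k]] == x) {
      parent[ts$edge_child[O[k]] + 1L] <- NA_integer_
      k <- k + 1L
      n_out <- n_out + 1L
    }
    while (j <= E && ts$edge_left[I[j]] == x) {
      parent[ts$edge_child[I[j]] + 1L] <- ts$edge_parent[I[j]]
      j <- j + 1L
      n_in <- n_in + 1L
    }
    right <- L
    if (j <= E) right <- min(right, ts$edge_left[I[j]])
    if (k <= E) right <- min(right, ts$edge_right[O[k]])
    if (x > 0) {
      diffs[[length(diffs) + 1L]] <- c(x, n_out, n_in)
    }
    m <- length(out)
    if (m > 0L && identical(out[[m]]$parent, parent)) {
      out[[m]]$right <- right       # unchanged topology: extend the interval
    } else {
      out[[m + 1L]] <- new_marginal_tree(x, right, parent, ts)
    }
    if (right >= L) break
    x <- right
  }
  d <- if (length(diffs)) do.call(rbind, diffs) else matrix(numeric(0), ncol = 3)
  list(trees = out,
       diffs = data.frame(position = d[, 1], edges_out = as.integer(d[, 2]),
                          edges_in = as.integer(d[, 3])))
}

#' Per-breakpoint edge turnover
#'
#' For each interior breakpoint, the number of edges whose interval ends
#' there and the number that begin there.
#'
#' @param ts A [tree_sequence()].
#' @return A data frame with columns `position`, `edges_out`, `edges_in`.
#' @export
edge_diffs <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  sweep_trees(ts)$diffs
}

#' The marginal tree at a single position
#'
#' Built directly from the edge table -- the parent mapping is
#' `child -> parent` over all edges with `left <= x < right` -- with no
#' incremental state, so it also serves as a point oracle for the sweep.
#'
#' @param ts A [tree_sequence()].
#' @param x Genome position, `0 <= x < L`.
#' @return A `marginal_tree`.
#' @export
tree_at <- function(ts, x) {
  stopifnot(inherits(ts, "tree_sequence"))
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 ||
      x >= ts$sequence_length) {
    stop(sprintf("position must lie in [0, %g)", ts$sequence_length))
  }
  keep <- ts$edge_left <= x & x < ts$edge_right
  parent <- rep(NA_integer_, length(ts$node_time))
  parent[ts$edge_child[keep] + 1L] <- ts$edge_parent[keep]
  new_marginal_tree(x, x, parent, ts)
}

#' Breakpoint positions of a tree sequence
#'
#' @param ts A [tree_sequence()].
#' @return Numeric vector of tree interval boundaries, starting at 0 and
#'   ending at `L`.
#' @export
breakpoints <- function(ts) {
  tr <- trees(ts)
  c(vapply(tr, function(t) t$left, 0), ts$sequence_length)
}

# Logical vector over nodes: ancestral to (i.e. on a path from) some sample
# in this tree, samples included.
sample_ancestral <- function(tree, samples = tree$samples) {
  mark <- logical(length(tree$parent))
  for (s in samples) {
    v <- s + 1L
    while (!mark[v]) {
      mark[v] <- TRUE
      p <- tree$parent[v]
      if (is.na(p)) break
      v <- p + 1L
    }
  }
  mark
}

#' Total branch length and root count of a marginal tree
#'
#' `total_branch_length` sums `time[parent] - time[child]` over every branch
#' on a path from a sample to its root; material not ancestral to any sample
#' does not count.  `num_roots` counts the distinct root ancestors of the
#' samples (isolated samples count as their own root; components without
#' samples are ignored).
#'
#' @param tree A `marginal_tree`.
#' @param samples Node ids; defaults to the tree's samples.
#' @return A single number.
#' @export
total_branch_length <- function(tree, samples = tree$samples) {
  stopifnot(inherits(tree, "marginal_tree"))
  mark <- sample_ancestral(tree, samples)
  v <- which(mark)
  p <- tree$parent[v]
  ok <- !is.na(p)
  sum(tree$time[p[ok] + 1L] - tree$time[v[ok]])
}

#' @rdname total_branch_length
#' @export
num_roots <- function(tree, samples = tree$samples) {
  stopifnot(inherits(tree, "marginal_tree"))
  roots <- integer(0)
  for (s in samples) {
    v <- s + 1L
    while (!is.na(tree$parent[v])) {
      v <- tree$parent[v] + 1L
    }
    roots <- c(roots, v)
  }
  length(unique(roots))
}

# Mutations grouped by site: list over sites of integer row indices into the
# mutation columns (sorted order preserved: ancestral-most first).
site_mutations <- function(ts) {
  split(seq_along(ts$mut_site), factor(ts$mut_site, levels = seq_along(ts$site_position) - 1L))
}

# State of each sample at one site, by walking rootwards from each sample to
# the nearest node carrying a mutation at the site.  `rows` indexes the
# site's mutations; if one node carries several, the last (most derived in
# sort order) wins.
site_states <- function(ts, tree, rows, ancestral) {
  state_of_node <- new.env(parent = emptyenv())
  for (i in rows) {
    assign(as.character(ts$mut_node[i]), ts$mut_derived[i],
           envir = state_of_node)   # later rows overwrite earlier
  }
  vapply(ts$samples, function(s) {
    v <- s + 1L
    repeat {
      key <- as.character(v - 1L)
      if (!is.null(st <- get0(key, envir = state_of_node))) {
        return(st)
      }
      p <- tree$parent[v]
      if (is.na(p)) {
        return(ancestral)
      }
      v <- p + 1L
    }
  }, "")
}

#' Variants: per-sample states at every site
#'
#' Walks the marginal trees in genome order; at each site every sample's
#' state is the derived state of the nearest mutation on its rootward path,
#' or the site's ancestral state if there is none.
#'
#' @param ts A [tree_sequence()].
#' @return A list with one element per site: `list(id, position,
#'   ancestral_state, states)` where `states` is a character vector over the
#'   samples, in sample order.
#' @export
variants <- function(ts) {
  stopifnot(inherits(ts, "tree_sequence"))
  ns <- length(ts$site_position)
  if (ns == 0L) {
    return(list())
  }
  by_site <- site_mutations(ts)
  tr <- trees(ts)
  ti <- 1L
  out <- vector("list", ns)
  for (s in seq_len(ns)) {
    pos <- ts$site_position[s]
    while (tr[[ti]]$right <= pos) ti <- ti + 1L
    out[[s]] <- list(
      id = s - 1L,
      position = pos,
      ancestral_state = ts$site_ancestral[s],
      states = site_states(ts, tr[[ti]], by_site[[s]], ts$site_ancestral[s])
    )
  }
  out
}

# TRUE if node a (0-based) lies weakly below node b in the tree.
is_below <- function(tree, a, b) {
  v <- a + 1L
  repeat {
    if (v == b + 1L) return(TRUE)
    p <- tree$parent[v]
    if (is.na(p)) return(FALSE)
    v <- p + 1L
  }
}

#' Pairwise nucleotide diversity
#'
#' The average density of differences between pairs of sampled sequences,
#' \deqn{\pi = \frac{1}{\binom{n}{2} L} \sum_{\mathrm{sites}}
#'   \frac{1}{2} \sum_{\mathrm{states}\ a} c_a (n - c_a),}
#' where \eqn{c_a} is the number of samples carrying state \eqn{a}.  The
#' allele counts are obtained from the marginal trees: within each tree the
#' number of samples below every mutation's node is counted once, and nested
#' or back mutations are resolved by exclusion, so the full genotype matrix
#' is never formed.
#'
#' @param ts A [tree_sequence()].
#' @param sample_set Node ids over which to compute diversity; defaults to
#'   all samples.  At least two.
#' @return Diversity per unit of sequence length.
#' @export
diversity <- function(ts, sample_set = NULL) {
  stopifnot(inherits(ts, "tree_sequence"))
  if (is.null(sample_set)) {
    sample_set <- ts$samples
  }
  sample_set <- as.integer(sample_set)
  n <- length(sample_set)
  if (n < 2L) {
    stop("diversity requires at least two samples")
  }
  ns <- length(ts$site_position)
  if (ns == 0L) {
    return(0)
  }
  by_site <- site_mutations(ts)
  tr <- trees(ts)
  ti <- 1L
  total <- 0
  counts_below <- NULL
  for (s in seq_len(ns)) {
    pos <- ts$site_position[s]
    advanced <- FALSE
    while (tr[[ti]]$right <= pos) {
      ti <- ti + 1L
      advanced <- TRUE
    }
    if (is.null(counts_below) || advanced) {
      counts_below <- integer(length(ts$node_time))
      for (sm in sample_set) {
        v <- sm + 1L
        repeat {
          counts_below[v] <- counts_below[v] + 1L
          p <- tr[[ti]]$parent[v]
          if (is.na(p)) break
          v <- p + 1L
        }
      }
    }
    rows <- by_site[[s]]
    k <- length(rows)
    if (k == 0L) next
    tree <- tr[[ti]]
    # youngest-first exclusion: each mutation's count minus the counts
    # already claimed by mutations at or below its node
    rows_rev <- rev(rows)
    excl <- numeric(k)
    for (a in seq_len(k)) {
      ca <- counts_below[ts$mut_node[rows_rev[a]] + 1L]
      if (a > 1L) {
        for (b in seq_len(a - 1L)) {
          if (is_below(tree, ts$mut_node[rows_rev[b]], ts$mut_node[rows_rev[a]])) {
            ca <- ca - excl[b]
          }
        }
      }
      excl[a] <- ca
    }
    state <- c(ts$mut_derived[rows_rev], ts$site_ancestral[s])
    cnt <- c(excl, n - sum(excl))
    c_a <- vapply(split(cnt, state), sum, 0)
    total <- total + sum(c_a * (n - c_a)) / 2
  }
  total / (choose(n, 2) * ts$sequence_length)
}

#' Export marginal trees in Newick format
#'
#' One Newick string per marginal tree, preceded by a comment line
#' `#interval <left> <right>`.  Leaf labels are node ids; branch lengths are
#' parent-child time differences.  Every tree must have a single root.
#'
#' @param ts A [tree_sequence()].
#' @param destination File path or connection, or `NULL` to return the lines.
#' @return Character vector of output lines, invisibly when written.
#' @export
export_newick <- function(ts, destination = NULL) {
  stopifnot(inherits(ts, "tree_sequence"))
  lines <- character(0)
  for (tree in trees(ts)) {
    if (num_roots(tree) != 1L) {
      stop(sprintf("tree on [%g, %g) has %d roots; Newick requires one",
                   tree$left, tree$right, num_roots(tree)))
    }
    mark <- sample_ancestral(tree)
    kids <- vector("list", length(tree$parent))
    root <- NA_integer_
    for (v in which(mark)) {
      p <- tree$parent[v]
      if (is.na(p)) {
        root <- v
      } else {
        kids[[p + 1L]] <- c(kids[[p + 1L]], v)
      }
    }
    rec <- function(v) {
      ch <- kids[[v]]
      if (length(ch) == 0L) {
        return(as.character(v - 1L))
      }
      sub <- vapply(ch, function(c_) {
        paste0(rec(c_), ":", fmt_float(tree$time[tree$parent[c_] + 1L] - tree$time[c_]))
      }, "")
      paste0("(", paste(sub, collapse = ","), ")")
    }
    lines <- c(lines,
               sprintf("#interval %s %s", fmt_float(tree$left), fmt_float(tree$right)),
               paste0(rec(root), ";"))
  }
  if (is.null(destination)) {
    return(lines)
  }
  writeLines(lines, destination)
  invisible(lines)
}

#' Export genotypes as VCF
#'
#' Writes a VCF v4.2 with one record per site and one haploid genotype
#' column per sample.  The ancestral state is REF; derived states are ALT
#' alleles (several for multiallelic sites).  Continuous positions are
#' reported as `floor(position) + 1` (VCF positions are 1-based integers);
#' collisions are resolved by incrementing, so this export is lossy on
#' positions -- the text dialect keeps exact floats.
#'
#' @param ts A [tree_sequence()].
#' @param destination File path or connection, or `NULL` to return the lines.
#' @param chrom Chromosome name for the CHROM column.
#' @return Character vector of VCF lines, invisibly when written.
#' @export
export_vcf <- function(ts, destination = NULL, chrom = "1") {
  stopifnot(inherits(ts, "tree_sequence"))
  vs <- variants(ts)
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=treeseq",
    sprintf("##contig=<ID=%s,length=%d>", chrom,
            max(1L, as.integer(ceiling(ts$sequence_length)))),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", paste0("n", ts$samples)), collapse = "\t")
  )
  records <- character(0)
  last_pos <- 0L
  for (v in vs) {
    pos <- max(as.integer(floor(v$position)) + 1L, last_pos + 1L)
    last_pos <- pos
    alts <- setdiff(unique(v$states), v$ancestral_state)
    alleles <- c(v$ancestral_state, alts)
    gt <- match(v$states, alleles) - 1L
    records <- c(records, paste(
      c(chrom, pos, ".", v$ancestral_state,
        if (length(alts)) paste(alts, collapse = ",") else ".",
        ".", "PASS", ".", "GT", gt),
      collapse = "\t"
    ))
  }
  lines <- c(header, records)
  if (is.null(destination)) {
    return(lines)
  }
  writeLines(lines, destination)
  invisible(lines)
}
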