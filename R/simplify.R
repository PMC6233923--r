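#' Simplify a tree sequence to the history of a sample set
#'
#' Reduces a valid, sorted table collection to the minimal tree sequence
#' describing the given samples:
#'
#' 1. every marginal tree of the output equals the subtree of the
#'    corresponding input tree induced by the samples;
#' 2. non-sample vertices with fewer than two children in a marginal tree
#'    are removed (unary ancestry is elided; samples are kept everywhere);
#' 3. nodes and edges not ancestral to any sample are removed;
#' 4. adjacent redundant edges are merged ([squash_edges()] finds nothing to
#'    do on the output).
#'
#' The algorithm propagates ancestral segments backwards in time, processing
#' input parents youngest first, and runs in time linear in the number of
#' input edges.  In the output the samples are nodes `0 .. n-1` in the order
#' given; subsequent nodes are ordered by time since birth (ties broken by
#' input id).  Mutations whose (position, node) fall on retained ancestral
#' material are re-assigned to the output node carrying that material; all
#' others are dropped, and by default so are sites left without mutations.
#'
#' @param tables A valid [table_collection()] with edges in canonical sorted
#'   order (see [sort_tables()]).  Not modified.
#' @param samples Ordered vector of distinct node ids to become the new
#'   samples.
#' @param keep_sites Keep sites whose mutations were all dropped
#'   (default `FALSE`).
#' @return A list with components `tables` (the simplified collection,
#'   sorted, with sample flags set on nodes `0 .. n-1`) and `node_map`
#'   (integer vector over input node ids: the output id, or `NA` where the
#'   input node was not retained).  The attribute `ops` on `tables` records
#'   the number of basic segment operations performed.
#' @seealso [map_node()], [induced_subtree()]
#' @examples
#' ped <- toy_pedigree_tables()
#' sort_tables(ped)
#' res <- simplify_tables(ped, samples = sample_ids(ped))
#' edges(res$tables)
#' @export
simplify_tables <- function(tables, samples, keep_sites = FALSE) {
  check_tables_arg(tables)
  val <- validate_tables(tables)
  if (!val$ok) {
    stop(sprintf("cannot simplify invalid tables (%d violations; see validate_tables())",
                 nrow(val$violations)))
  }
  if (!edges_sorted(tables)) {
    stop("edge table is not in canonical sorted order; call sort_tables() first")
  }
  samples <- check_samples_arg(samples, num_nodes(tables))
  res <- simplify_core(tables, samples, keep_sites = keep_sites)
  res
}

check_samples_arg <- function(samples, n) {
  if (length(samples) == 0L) {
    stop("samples must be non-empty")
  }
  if (!is.numeric(samples) || anyNA(samples) || any(samples != floor(samples))) {
    stop("samples must be a vector of node ids")
  }
  samples <- as.integer(samples)
  if (any(samples < 0L | samples >= n)) {
    stop(sprintf("sample id out of range [0, %d)", n))
  }
  if (anyDuplicated(samples)) {
    stop("duplicate sample ids")
  }
  samples
}

# Core shared by the user-facing wrapper and the simulator checkpoints
# (which skip re-validation of tables they constructed).
simplify_core <- function(tables, samples, keep_sites = FALSE) {
  raw <- .simplify_cpp(
    tables$node_time,
    tables$edge_left, tables$edge_right,
    tables$edge_parent, tables$edge_child,
    tables$site_position[tables$mut_site + 1L],
    tables$mut_node,
    samples,
    tables$sequence_length
  )
  n <- length(samples)
  inp <- raw$out_node_input + 1L
  out_n <- length(inp)

  keep0 <- raw$mut_keep            # 0-based indices into the input mutations
  old_site <- tables$mut_site[keep0 + 1L]
  if (keep_sites) {
    site_keep <- seq_len(num_sites(tables))
  } else {
    site_keep <- sort(unique(old_site)) + 1L
  }
  # renumber surviving sites by position (canonical emission order)
  site_keep <- site_keep[order(tables$site_position[site_keep], site_keep)]
  site_map <- rep(NA_integer_, num_sites(tables))
  site_map[site_keep] <- seq_along(site_keep) - 1L

  mut_site <- site_map[old_site + 1L]
  mut_node <- raw$mut_out_node
  mut_derived <- tables$mut_derived[keep0 + 1L]
  out_time <- tables$node_time[inp]
  if (length(mut_site)) {
    o <- order(mut_site, -out_time[mut_node + 1L], mut_node, keep0)
    mut_site <- mut_site[o]
    mut_node <- mut_node[o]
    mut_derived <- mut_derived[o]
  }

  out <- new_table_collection(
    tables$sequence_length,
    node_time = out_time,
    node_is_sample = seq_len(out_n) <= n,
    node_metadata = tables$node_metadata[inp],
    edge_left = raw$edge_left, edge_right = raw$edge_right,
    edge_parent = raw$edge_parent, edge_child = raw$edge_child,
    site_position = tables$site_position[site_keep],
    site_ancestral = tables$site_ancestral[site_keep],
    mut_site = mut_site, mut_node = mut_node, mut_derived = mut_derived
  )
  attr(out, "ops") <- raw$ops
  node_map <- raw$node_map
  node_map[node_map < 0L] <- NA_integer_
  list(tables = out, node_map = node_map)
}

#' Look up input nodes in a simplification node map
#'
#' @param map The `node_map` component returned by [simplify_tables()].
#' @param ids Input node ids (zero-based), vectorized.
#' @return Output node ids, `NA` where an input node left no trace in the
#'   simplified tree sequence.
#' @export
map_node <- function(map, ids) {
  stopifnot(is.numeric(ids), all(is.na(ids) | (ids >= 0 & ids < length(map))))
  map[as.integer(ids) + 1L]
}

#' Induced subtree of a marginal tree (brute-force test oracle)
#'
#' Computes, directly from parent pointers, the forest obtained by
#' restricting a marginal tree to a sample set: sample-free subtrees are
#' dropped and every non-sample vertex with fewer than two sample-bearing
#' children is contracted away.  The result is returned in a canonical,
#' implementation-independent form: each retained vertex is labelled by the
#' sorted set of sample *indices* (positions in `samples`, zero-based) below
#' it plus its node time, and the forest is the sorted set of
#' `"child -> parent"` strings plus `"root: <label>"` entries.
#'
#' This is deliberately independent of [simplify_tables()] -- it contracts
#' vertices by exhaustive marking rather than segment propagation -- and
#' serves as the correctness oracle for it: simplifying and then reading a
#' marginal tree must give the same canonical forest as inducing the
#' corresponding input tree.
#'
#' @param tree A [marginal_tree][tree_at()].
#' @param samples Node ids to restrict to; defaults to the tree's samples.
#' @return Character vector: the canonical forest, sorted.
#' @export
induced_subtree <- function(tree, samples = tree$samples) {
  stopifnot(inherits(tree, "marginal_tree"))
  samples <- as.integer(samples)
  nn <- length(tree$parent)
  parent <- tree$parent                   # 0-based ids, NA at roots
  sample_index <- rep(NA_integer_, nn)
  sample_index[samples + 1L] <- seq_along(samples) - 1L

  below <- vector("list", nn)             # sample indices below each node
  o <- order(tree$time)                   # children strictly younger: safe order
  kids_with <- integer(nn)                # sample-bearing child count
  for (v in o) {
    s <- below[[v]]
    if (!is.na(sample_index[v])) {
      s <- c(s, sample_index[v])
      below[[v]] <- s       # nb: assigning NULL would delete the element
    }
    p <- parent[v]
    if (!is.na(p) && length(s)) {
      below[[p + 1L]] <- c(below[[p + 1L]], s)
      kids_with[p + 1L] <- kids_with[p + 1L] + 1L
    }
  }
  retained <- which(!is.na(sample_index) | kids_with >= 2L)
  lab <- function(v) {
    sprintf("{%s}@%s", paste(sort(below[[v]]), collapse = ","),
            fmt_float(tree$time[v]))
  }
  out <- character(0)
  for (v in retained) {
    p <- parent[v]
    while (!is.na(p) && !((p + 1L) %in% retained)) {
      p <- parent[p + 1L]
    }
    out <- c(out, if (is.na(p)) {
      paste0("root: ", lab(v))
    } else {
      paste0(lab(v), " -> ", lab(p + 1L))
    })
  }
  sort(out)
}
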