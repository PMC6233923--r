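#' Create an empty table collection
#'
#' A table collection holds the four columnar tables that define a succinct
#' tree sequence -- nodes, edges, sites and mutations -- together with the
#' sequence length `L`.  Node, edge, site and mutation ids are implicit: the
#' id of a row is its (zero-based) position in its table, and the `add_*`
#' functions are strictly append-only, so ids are stable once assigned.
#'
#' The collection has reference semantics: `add_node()` and friends grow the
#' tables in place and return the new row's id, mirroring the builder pattern
#' used when a simulator streams rows into the tables.  Use [copy_tables()]
#' to take an independent snapshot.
#'
#' @param sequence_length Total length of the genome, `L > 0`.  All edge
#'   intervals lie in `[0, L]` and all site positions in `[0, L)`.
#' @return An object of class `"table_collection"`.
#' @seealso [add_node()], [validate_tables()], [sort_tables()],
#'   [dump_text()], [tree_sequence()]
#' @examples
#' tc <- table_collection(10)
#' add_node(tc, time = 0, is_sample = TRUE)
#' add_node(tc, time = 1)
#' add_edge(tc, 0, 10, parent = 1, child = 0)
#' tc
#' @export
table_collection <- function(sequence_length) {
  if (!is.numeric(sequence_length) || length(sequence_length) != 1 ||
      !is.finite(sequence_length) || sequence_length <= 0) {
    stop("sequence_length must be a single finite value > 0")
  }
  tc <- new.env(parent = emptyenv())
  tc$sequence_length <- as.numeric(sequence_length)
  tc$node_time <- numeric(0)
  tc$node_is_sample <- logical(0)
  tc$node_metadata <- character(0)
  tc$edge_left <- numeric(0)
  tc$edge_right <- numeric(0)
  tc$edge_parent <- integer(0)
  tc$edge_child <- integer(0)
  tc$site_position <- numeric(0)
  tc$site_ancestral <- character(0)
  tc$mut_site <- integer(0)
  tc$mut_node <- integer(0)
  tc$mut_derived <- character(0)
  class(tc) <- "table_collection"
  tc
}

is_table_collection <- function(x) inherits(x, "table_collection")

check_tables_arg <- function(tables) {
  if (!is_table_collection(tables)) {
    stop("`tables` must be a table_collection")
  }
  invisible(tables)
}

#' @export
print.table_collection <- function(x, ...) {
  cat(sprintf(
    "<table_collection> L = %g: %d nodes, %d edges, %d sites, %d mutations\n",
    x$sequence_length, num_nodes(x), num_edges(x), num_sites(x),
    num_mutations(x)
  ))
  invisible(x)
}

#' Table sizes
#'
#' Row counts of the four tables of a collection.  Because ids are implicit
#' row positions, `num_nodes(tc)` is also the id that the next
#' [add_node()] call will return.
#'
#' @param tables A [table_collection()].
#' @return A single integer.
#' @export
num_nodes <- function(tables) length(tables$node_time)

#' @rdname num_nodes
#' @export
num_edges <- function(tables) length(tables$edge_left)

#' @rdname num_nodes
#' @export
num_sites <- function(tables) length(tables$site_position)

#' @rdname num_nodes
#' @export
num_mutations <- function(tables) length(tables$mut_site)

#' Extract tables as data frames
#'
#' Copy one of the four tables out of a collection as an ordinary data frame,
#' with the implicit row id in column `id` (zero-based, matching the ids used
#' in the edge/mutation columns and in the text dialect).
#'
#' @param tables A [table_collection()].
#' @return A data frame with one row per table row.
#' @export
nodes <- function(tables) {
  check_tables_arg(tables)
  data.frame(
    id = seq_along(tables$node_time) - 1L,
    time = tables$node_time,
    is_sample = tables$node_is_sample,
    metadata = tables$node_metadata,
    stringsAsFactors = FALSE
  )
}

#' @rdname nodes
#' @export
edges <- function(tables) {
  check_tables_arg(tables)
  data.frame(
    id = seq_along(tables$edge_left) - 1L,
    left = tables$edge_left,
    right = tables$edge_right,
    parent = tables$edge_parent,
    child = tables$edge_child
  )
}

#' @rdname nodes
#' @export
sites <- function(tables) {
  check_tables_arg(tables)
  data.frame(
    id = seq_along(tables$site_position) - 1L,
    position = tables$site_position,
    ancestral_state = tables$site_ancestral,
    stringsAsFactors = FALSE
  )
}

#' @rdname nodes
#' @export
mutations <- function(tables) {
  check_tables_arg(tables)
  data.frame(
    id = seq_along(tables$mut_site) - 1L,
    site = tables$mut_site,
    node = tables$mut_node,
    derived_state = tables$mut_derived,
    stringsAsFactors = FALSE
  )
}

#' Append a node row
#'
#' Nodes represent distinct (haploid) ancestral genomes.  `time` is measured
#' backwards from the end of history ("time ago"): larger values are older.
#' Rows are append-only; the returned id equals the previous node count and
#' existing rows are never reordered.
#'
#' @param tables A [table_collection()], modified in place.
#' @param time Birth time of the node, a finite value `>= 0`.
#' @param is_sample Whether the node is one of the focal samples whose
#'   history the tree sequence describes.
#' @param metadata Opaque string carried through sorting, simplification and
#'   text round trips without interpretation.
#' @return The zero-based id of the new row (equal to the node count before
#'   the call).
#' @export
add_node <- function(tables, time, is_sample = FALSE, metadata = "") {
  check_tables_arg(tables)
  if (!is.numeric(time) || length(time) != 1 || !is.finite(time) || time < 0) {
    stop("node time must be a single finite value >= 0")
  }
  if (!is.logical(is_sample) || length(is_sample) != 1 || is.na(is_sample)) {
    stop("is_sample must be TRUE or FALSE")
  }
  id <- num_nodes(tables)
  tables$node_time <- c(tables$node_time, as.numeric(time))
  tables$node_is_sample <- c(tables$node_is_sample, is_sample)
  tables$node_metadata <- c(tables$node_metadata, as.character(metadata))
  id
}

#' Append an edge row
#'
#' An edge `(left, right, parent, child)` asserts that `child` inherits from
#' `parent` over the half-open genomic interval `[left, right)`, in every
#' marginal tree on that interval.
#'
#' @inheritParams add_node
#' @param left,right Interval endpoints, `0 <= left < right <= L`.
#' @param parent,child Zero-based node ids already present in the node table;
#'   `parent != child`.
#' @return The zero-based id of the new edge.
#' @export
add_edge <- function(tables, left, right, parent, child) {
  check_tables_arg(tables)
  L <- tables$sequence_length
  if (!is.numeric(left) || !is.numeric(right) ||
      length(left) != 1 || length(right) != 1 ||
      !is.finite(left) || !is.finite(right)) {
    stop("edge endpoints must be single finite values")
  }
  if (left < 0 || right > L) {
    stop(sprintf("edge interval [%g, %g) out of bounds [0, %g]", left, right, L))
  }
  if (left >= right) {
    stop(sprintf("edge interval [%g, %g) is empty: need left < right", left, right))
  }
  n <- num_nodes(tables)
  parent <- check_node_id(parent, n, "parent")
  child <- check_node_id(child, n, "child")
  if (parent == child) {
    stop("edge parent and child must differ")
  }
  id <- num_edges(tables)
  tables$edge_left <- c(tables$edge_left, as.numeric(left))
  tables$edge_right <- c(tables$edge_right, as.numeric(right))
  tables$edge_parent <- c(tables$edge_parent, parent)
  tables$edge_child <- c(tables$edge_child, child)
  id
}

check_node_id <- function(id, n, what) {
  if (!is.numeric(id) || length(id) != 1 || is.na(id) || id != floor(id)) {
    stop(sprintf("%s must be a single integer node id", what))
  }
  id <- as.integer(id)
  if (id < 0L || id >= n) {
    stop(sprintf("unknown %s node id %d (node table has %d rows)", what, id, n))
  }
  id
}

#' Append a site row
#'
#' A site is a genomic position with an ancestral state; mutations refer to
#' sites by id.
#'
#' @inheritParams add_node
#' @param position Genome coordinate in `[0, L)`.
#' @param ancestral_state State carried by samples with no mutation above
#'   them at this site.
#' @return The zero-based id of the new site.
#' @export
add_site <- function(tables, position, ancestral_state) {
  check_tables_arg(tables)
  if (!is.numeric(position) || length(position) != 1 || !is.finite(position) ||
      position < 0 || position >= tables$sequence_length) {
    stop(sprintf("site position must lie in [0, %g)", tables$sequence_length))
  }
  id <- num_sites(tables)
  tables$site_position <- c(tables$site_position, as.numeric(position))
  tables$site_ancestral <- c(tables$site_ancestral, as.character(ancestral_state))
  id
}

#' Append a mutation row
#'
#' A mutation records a state change at a site: `node` is the first node to
#' inherit `derived_state`; every sample below `node` in the marginal tree at
#' the site's position carries the derived state unless a further mutation
#' intervenes.  A derived state equal to some other allele (a back mutation)
#' is legal.
#'
#' @inheritParams add_node
#' @param site Zero-based site id.
#' @param node Zero-based node id.
#' @param derived_state New state below `node`.
#' @return The zero-based id of the new mutation.
#' @export
add_mutation <- function(tables, site, node, derived_state) {
  check_tables_arg(tables)
  if (!is.numeric(site) || length(site) != 1 || is.na(site) ||
      site != floor(site) || site < 0 || site >= num_sites(tables)) {
    stop(sprintf("unknown site id (site table has %d rows)", num_sites(tables)))
  }
  node <- check_node_id(node, num_nodes(tables), "mutation")
  id <- num_mutations(tables)
  tables$mut_site <- c(tables$mut_site, as.integer(site))
  tables$mut_node <- c(tables$mut_node, node)
  tables$mut_derived <- c(tables$mut_derived, as.character(derived_state))
  id
}

#' Copy a table collection
#'
#' Because collections have reference semantics, use this to snapshot state
#' before an in-place operation such as [sort_tables()].
#'
#' @param tables A [table_collection()].
#' @return A new, independent `table_collection` with identical contents.
#' @export
copy_tables <- function(tables) {
  check_tables_arg(tables)
  out <- table_collection(tables$sequence_length)
  for (f in TABLE_FIELDS) {
    assign(f, get(f, envir = tables), envir = out)
  }
  out
}

TABLE_FIELDS <- c(
  "node_time", "node_is_sample", "node_metadata",
  "edge_left", "edge_right", "edge_parent", "edge_child",
  "site_position", "site_ancestral",
  "mut_site", "mut_node", "mut_derived"
)

#' Exact equality of two table collections
#'
#' Compares sequence length and every column of every table for exact
#' equality (floats bit-for-bit, metadata byte-for-byte).
#'
#' @param a,b [table_collection()] objects.
#' @return `TRUE` or `FALSE`.
#' @export
tables_equal <- function(a, b) {
  check_tables_arg(a)
  check_tables_arg(b)
  if (!identical(a$sequence_length, b$sequence_length)) {
    return(FALSE)
  }
  for (f in TABLE_FIELDS) {
    if (!identical(get(f, envir = a), get(f, envir = b))) {
      return(FALSE)
    }
  }
  TRUE
}

# Bulk constructor used internally by the simulator, simplify and the text
# loader; columns are taken as given with only light length checks.
new_table_collection <- function(sequence_length,
                                 node_time = numeric(0),
                                 node_is_sample = logical(0),
                                 node_metadata = NULL,
                                 edge_left = numeric(0),
                                 edge_right = numeric(0),
                                 edge_parent = integer(0),
                                 edge_child = integer(0),
                                 site_position = numeric(0),
                                 site_ancestral = NULL,
                                 mut_site = integer(0),
                                 mut_node = integer(0),
                                 mut_derived = NULL) {
  tc <- table_collection(sequence_length)
  n <- length(node_time)
  tc$node_time <- as.numeric(node_time)
  tc$node_is_sample <- if (length(node_is_sample)) as.logical(node_is_sample) else rep(FALSE, n)
  tc$node_metadata <- if (is.null(node_metadata)) rep("", n) else as.character(node_metadata)
  stopifnot(
    length(tc$node_is_sample) == n, length(tc$node_metadata) == n,
    length(edge_right) == length(edge_left),
    length(edge_parent) == length(edge_left),
    length(edge_child) == length(edge_left)
  )
  tc$edge_left <- as.numeric(edge_left)
  tc$edge_right <- as.numeric(edge_right)
  tc$edge_parent <- as.integer(edge_parent)
  tc$edge_child <- as.integer(edge_child)
  tc$site_position <- as.numeric(site_position)
  tc$site_ancestral <- if (is.null(site_ancestral)) {
    rep("0", length(site_position))
  } else {
    as.character(site_ancestral)
  }
  tc$mut_site <- as.integer(mut_site)
  tc$mut_node <- as.integer(mut_node)
  tc$mut_derived <- if (is.null(mut_derived)) {
    rep("1", length(mut_site))
  } else {
    as.character(mut_derived)
  }
  stopifnot(
    length(tc$site_ancestral) == length(tc$site_position),
    length(tc$mut_node) == length(tc$mut_site),
    length(tc$mut_derived) == length(tc$mut_site)
  )
  tc
}

#' Sample ids of a table collection
#'
#' Zero-based ids of nodes flagged as samples, in id order.
#'
#' @param tables A [table_collection()] or [tree_sequence()].
#' @return Integer vector of node ids.
#' @export
sample_ids <- function(tables) {
  if (inherits(tables, "tree_sequence")) {
    return(tables$samples)
  }
  check_tables_arg(tables)
  which(tables$node_is_sample) - 1L
}
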