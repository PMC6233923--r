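#' Sort tables into canonical order
#'
#' Sorting establishes the order the sweep and simplification algorithms
#' rely on.  The node table is never reordered (ids are stable); the other
#' tables are permuted in place:
#'
#' * edges by `(time[parent], parent, child, left)`, all ascending, so that
#'   all edges sharing a parent are contiguous and parents appear youngest
#'   first -- the processing order of [simplify_tables()];
#' * sites by position, with exact-duplicate positions collapsed (first
#'   occurrence kept) and mutation `site` ids remapped accordingly;
#' * mutations by `(site, time[node] descending)` so that at each site the
#'   ancestral-most state change comes first.
#'
#' Sorting never repairs validity: run [validate_tables()] first if in doubt.
#'
#' @param tables A [table_collection()], sorted in place.
#' @return The collection, invisibly.
#' @export
sort_tables <- function(tables) {
  check_tables_arg(tables)
  o <- order(tables$node_time[tables$edge_parent + 1L], tables$edge_parent,
             tables$edge_child, tables$edge_left)
  tables$edge_left <- tables$edge_left[o]
  tables$edge_right <- tables$edge_right[o]
  tables$edge_parent <- tables$edge_parent[o]
  tables$edge_child <- tables$edge_child[o]
  deduplicate_sites(tables)
  invisible(tables)
}

#' Sort sites by position, dropping duplicates, and order mutations
#'
#' Keeps the first site row at each exact position, remaps mutation site ids
#' onto the surviving rows, and sorts mutations by `(site, node time
#' descending)`.  Called by [sort_tables()]; exported for use on tables whose
#' edges are already in order.
#'
#' @inheritParams sort_tables
#' @return The collection, invisibly.
#' @export
deduplicate_sites <- function(tables) {
  check_tables_arg(tables)
  pos <- tables$site_position
  if (length(pos)) {
    o <- order(pos)                       # stable: first-added wins ties
    keep <- o[!duplicated(pos[o])]
    new_id <- integer(length(pos))        # old id -> new id
    new_id[keep] <- seq_along(keep)
    dup <- setdiff(seq_along(pos), keep)
    if (length(dup)) {
      new_id[dup] <- match(pos[dup], pos[keep])   # position in keep = new id
    }
    tables$site_position <- pos[keep]
    tables$site_ancestral <- tables$site_ancestral[keep]
    tables$mut_site <- new_id[tables$mut_site + 1L] - 1L
  }
  if (length(tables$mut_site)) {
    o <- order(tables$mut_site, -tables$node_time[tables$mut_node + 1L],
               tables$mut_node)
    tables$mut_site <- tables$mut_site[o]
    tables$mut_node <- tables$mut_node[o]
    tables$mut_derived <- tables$mut_derived[o]
  }
  invisible(tables)
}

#' Merge genomically adjacent edges
#'
#' Replaces each run of edges `(l, x, p, c)`, `(x, r, p, c)` sharing a parent
#' and child and abutting exactly with the single edge `(l, r, p, c)`.  The
#' union of intervals per `(parent, child)` pair is unchanged; only the
#' representation shrinks.
#'
#' @param edges A data frame with columns `left`, `right`, `parent`, `child`
#'   (as returned by [edges()]; an `id` column is ignored).
#' @return A data frame of squashed edges, sorted by `(parent, child, left)`.
#' @export
squash_edges <- function(edges) {
  stopifnot(is.data.frame(edges),
            all(c("left", "right", "parent", "child") %in% names(edges)))
  n <- nrow(edges)
  if (n == 0L) {
    return(data.frame(left = numeric(0), right = numeric(0),
                      parent = integer(0), child = integer(0)))
  }
  o <- order(edges$parent, edges$child, edges$left)
  l <- edges$left[o]
  r <- edges$right[o]
  p <- edges$parent[o]
  c_ <- edges$child[o]
  # start of a run: different (parent, child) than predecessor, or a gap
  new_run <- c(TRUE, p[-1] != p[-n] | c_[-1] != c_[-n] | l[-1] != r[-n])
  grp <- cumsum(new_run)
  starts <- which(new_run)
  ends <- c(starts[-1] - 1L, n)
  data.frame(
    left = l[starts],
    right = r[ends],
    parent = as.integer(p[starts]),
    child = as.integer(c_[starts])
  )
}

# In-place variant used at simplification boundaries: squashes the edge
# table of a collection and restores canonical sort order.
squash_tables <- function(tables) {
  sq <- squash_edges(edges(tables))
  o <- order(tables$node_time[sq$parent + 1L], sq$parent, sq$child, sq$left)
  tables$edge_left <- sq$left[o]
  tables$edge_right <- sq$right[o]
  tables$edge_parent <- sq$parent[o]
  tables$edge_child <- sq$child[o]
  invisible(tables)
}

# TRUE if the edge table is in canonical sorted order.
edges_sorted <- function(tables) {
  n <- num_edges(tables)
  if (n < 2L) {
    return(TRUE)
  }
  k1 <- tables$node_time[tables$edge_parent + 1L]
  k2 <- tables$edge_parent
  k3 <- tables$edge_child
  k4 <- tables$edge_left
  lt <- k1[-n] < k1[-1]
  eq <- k1[-n] == k1[-1]
  lt2 <- eq & (k2[-n] < k2[-1])
  eq2 <- eq & (k2[-n] == k2[-1])
  lt3 <- eq2 & (k3[-n] < k3[-1])
  eq3 <- eq2 & (k3[-n] == k3[-1])
  le4 <- eq3 & (k4[-n] <= k4[-1])
  all(lt | lt2 | lt3 | le4)
}
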