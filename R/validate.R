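#' Validate a table collection
#'
#' Checks the two structural requirements that guarantee a pair of node and
#' edge tables describes, at every genomic position, a forest of trees:
#'
#' * **R1** -- offspring are born after their parents: for every edge,
#'   `time[parent] > time[child]` strictly (times are "time ago", so parents
#'   have larger values).  This also rules out cycles.
#' * **R2** -- the set of intervals on which each node is a child is
#'   disjoint: no node inherits from two parents at the same position.
#'
#' Bounds checks from the data model are reported as well: node times finite
#' and non-negative, edge intervals non-empty and inside `[0, L]`, site
#' positions inside `[0, L)`, and all node/site references in range.
#' Violations are data, not errors: the function always returns a report.
#'
#' @param tables A [table_collection()].
#' @return A list with elements `ok` (logical) and `violations`, a data frame
#'   with columns `table`, `row` (zero-based id of the offending row), `rule`
#'   and `message`, one row per violation.
#' @examples
#' tc <- table_collection(10)
#' n0 <- add_node(tc, 0, is_sample = TRUE)
#' n1 <- add_node(tc, 0)   # same time as its child: violates R1
#' add_edge(tc, 0, 10, parent = n1, child = n0)
#' validate_tables(tc)$violations
#' @export
validate_tables <- function(tables) {
  check_tables_arg(tables)
  v <- list()
  note <- function(table, row, rule, message) {
    v[[length(v) + 1L]] <<- data.frame(
      table = table, row = as.integer(row), rule = rule, message = message,
      stringsAsFactors = FALSE
    )
  }
  L <- tables$sequence_length
  n <- num_nodes(tables)

  bad <- which(!is.finite(tables$node_time) | tables$node_time < 0)
  for (i in bad) {
    note("nodes", i - 1L, "node_time",
         sprintf("node %d has time %g; need finite time >= 0", i - 1L,
                 tables$node_time[i]))
  }

  el <- tables$edge_left
  er <- tables$edge_right
  ep <- tables$edge_parent
  ec <- tables$edge_child
  bad <- which(!is.finite(el) | !is.finite(er) | el < 0 | er > L | el >= er)
  for (i in bad) {
    note("edges", i - 1L, "edge_interval",
         sprintf("edge %d has interval [%g, %g); need 0 <= left < right <= %g",
                 i - 1L, el[i], er[i], L))
  }
  bad_ref <- which(ep < 0L | ep >= n | ec < 0L | ec >= n | ep == ec)
  for (i in bad_ref) {
    note("edges", i - 1L, "edge_nodes",
         sprintf("edge %d has parent %d, child %d; need distinct valid node ids",
                 i - 1L, ep[i], ec[i]))
  }
  ok_ref <- setdiff(seq_along(el), bad_ref)
  r1 <- ok_ref[tables$node_time[ep[ok_ref] + 1L] <= tables$node_time[ec[ok_ref] + 1L]]
  for (i in r1) {
    note("edges", i - 1L, "R1",
         sprintf("edge %d: parent %d (time %g) not strictly older than child %d (time %g)",
                 i - 1L, ep[i], tables$node_time[ep[i] + 1L], ec[i],
                 tables$node_time[ec[i] + 1L]))
  }
  for (i in r2_violations(el, er, ec)) {
    note("edges", i - 1L, "R2",
         sprintf("edge %d: child %d has overlapping parent intervals", i - 1L, ec[i]))
  }

  bad <- which(!is.finite(tables$site_position) | tables$site_position < 0 |
                 tables$site_position >= L)
  for (i in bad) {
    note("sites", i - 1L, "site_position",
         sprintf("site %d at position %g outside [0, %g)", i - 1L,
                 tables$site_position[i], L))
  }

  ns <- num_sites(tables)
  bad <- which(tables$mut_site < 0L | tables$mut_site >= ns |
                 tables$mut_node < 0L | tables$mut_node >= n)
  for (i in bad) {
    note("mutations", i - 1L, "mutation_refs",
         sprintf("mutation %d references site %d / node %d out of range",
                 i - 1L, tables$mut_site[i], tables$mut_node[i]))
  }

  violations <- if (length(v)) {
    do.call(rbind, v)
  } else {
    data.frame(table = character(0), row = integer(0), rule = character(0),
               message = character(0), stringsAsFactors = FALSE)
  }
  list(ok = nrow(violations) == 0L, violations = violations)
}

# Row indices (1-based) of edges whose child-interval overlaps that of
# another edge with the same child.  An edge is flagged if it overlaps *any*
# other edge, matching the brute-force pairwise definition.
r2_violations <- function(left, right, child) {
  out <- logical(length(left))
  for (ch in unique(child)) {
    idx <- which(child == ch)
    if (length(idx) < 2L) next
    o <- idx[order(left[idx], right[idx])]
    l <- left[o]
    r <- right[o]
    k <- length(o)
    # overlaps an earlier (by left) interval
    cummax_r <- cummax(c(-Inf, r[-k]))
    first <- l < cummax_r
    # overlaps a later interval: next left starts before own right
    second <- c(l[-1] < r[-k], FALSE)
    out[o[first | second]] <- TRUE
  }
  which(out)
}

#' Is a tree sequence fully coalesced?
#'
#' A valid table collection guarantees a *forest* at every position; many
#' applications additionally need a single tree everywhere.  This sweeps the
#' marginal trees and checks that every one has exactly one root over the
#' sample set.
#'
#' @param x A [table_collection()] (sorted or not; a sorted copy is taken) or
#'   a [tree_sequence()].
#' @return `TRUE` if every marginal tree has exactly one sample-bearing root.
#' @export
check_fully_coalesced <- function(x) {
  ts <- if (inherits(x, "tree_sequence")) x else tree_sequence(x)
  if (length(ts$samples) == 0L) {
    stop("no sample nodes are flagged; cannot assess coalescence")
  }
  for (tree in trees(ts)) {
    if (num_roots(tree) != 1L) {
      return(FALSE)
    }
  }
  TRUE
}
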