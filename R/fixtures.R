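#' A small worked example: three samples, two trees, a back mutation
#'
#' A tree sequence over a chromosome of length 10 with five nodes: samples
#' 0, 1 and 2 at time 0, and ancestors 3 and 4 born one and two units of
#' time ago.  The first tree, on `[0, 5)`, is `((0,1)3,2)4`; the second, on
#' `[5, 10)`, is `((1,2)3,0)4`.  The branch joining node 1 to node 3 spans
#' the whole chromosome and is stored as a single edge; the edge from node 2
#' to node 4 exists only on `[0, 5)`.  Two sites carry three mutations: at
#' position 2.5 (ancestral "A") a single mutation gives node 2 the state
#' "T"; at position 7.5 (ancestral "G") a mutation above node 3 changes the
#' state to "C" and a back mutation above node 1 restores "G".
#'
#' @return A [tree_sequence()].
#' @examples
#' ts <- toy_tree_sequence()
#' length(trees(ts))
#' vapply(variants(ts), function(v) paste(v$states, collapse = ""), "")
#' @export
toy_tree_sequence <- function() {
  tc <- table_collection(10)
  for (i in 0:2) add_node(tc, 0, is_sample = TRUE)
  add_node(tc, 1)                        # node 3
  add_node(tc, 2)                        # node 4
  add_edge(tc, 0, 5, 3, 0)
  add_edge(tc, 0, 10, 3, 1)
  add_edge(tc, 5, 10, 3, 2)
  add_edge(tc, 0, 5, 4, 2)
  add_edge(tc, 0, 10, 4, 3)
  add_edge(tc, 5, 10, 4, 0)
  s0 <- add_site(tc, 2.5, "A")
  s1 <- add_site(tc, 7.5, "G")
  add_mutation(tc, s0, 2, "T")
  add_mutation(tc, s1, 3, "C")
  add_mutation(tc, s1, 1, "G")           # back mutation
  tree_sequence(tc)
}

#' A diploid pedigree with recorded meioses
#'
#' The embellished pedigree relating the ten homologous chromosomes of five
#' diploid individuals (BC, DE, FG, HI and JK) to a common ancestral
#' chromosome A, on a genome normalised to `[0, 1)`: 11 node rows (one per
#' chromosome, labelled in the metadata column) and 15 edge rows (one per
#' distinctly inherited segment).  B, C, D and E inherit clonally from A.
#' G inherited the left 70% of the chromosome from E and the remainder from
#' D.  H is a meiotic product of F and G (breakpoint 0.5), I of D and E
#' (breakpoint 0.2), and J and K of H and I: J inherits all of its
#' chromosome from H, while K carries I's material outside `[0.5, 0.9)` and
#' H's inside it.  J and K are flagged as samples: simplifying to them
#' coalesces at H exactly on `[0.5, 0.9)`, at E on `[0.2, 0.5)` (along the
#' paths J-H-G-E and K-I-E), and at A elsewhere.
#'
#' Edges are emitted in simulation order (youngest chromosomes first), so
#' the collection needs [sort_tables()] before building trees or
#' simplifying.
#'
#' @return A [table_collection()].
#' @examples
#' ped <- toy_pedigree_tables()
#' sort_tables(ped)
#' res <- simplify_tables(ped, samples = sample_ids(ped))
#' head(edges(res$tables), 4)
#' @export
toy_pedigree_tables <- function() {
  tc <- table_collection(1)
  lab <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K")
  tim <- c(4, 3, 3, 3, 3, 2, 2, 1, 1, 0, 0)
  for (i in seq_along(lab)) {
    add_node(tc, tim[i], is_sample = lab[i] %in% c("J", "K"),
             metadata = lab[i])
  }
  id <- function(x) match(x, lab) - 1L
  # youngest first, as a forwards simulator would emit them
  add_edge(tc, 0.0, 0.5, id("I"), id("K"))
  add_edge(tc, 0.5, 0.9, id("H"), id("K"))
  add_edge(tc, 0.9, 1.0, id("I"), id("K"))
  add_edge(tc, 0.0, 1.0, id("H"), id("J"))
  add_edge(tc, 0.0, 0.2, id("D"), id("I"))
  add_edge(tc, 0.2, 1.0, id("E"), id("I"))
  add_edge(tc, 0.0, 0.5, id("G"), id("H"))
  add_edge(tc, 0.5, 1.0, id("F"), id("H"))
  add_edge(tc, 0.0, 0.7, id("E"), id("G"))
  add_edge(tc, 0.7, 1.0, id("D"), id("G"))
  add_edge(tc, 0.0, 1.0, id("B"), id("F"))
  add_edge(tc, 0.0, 1.0, id("A"), id("E"))
  add_edge(tc, 0.0, 1.0, id("A"), id("D"))
  add_edge(tc, 0.0, 1.0, id("A"), id("C"))
  add_edge(tc, 0.0, 1.0, id("A"), id("B"))
  tc
}

#' Random simulated fixtures for property tests
#'
#' `random_wf_fixture()` runs a small seeded Wright-Fisher simulation and
#' returns its simplified tables (always valid).  `random_tables()`
#' produces small random collections for validator fuzzing, optionally with
#' an injected violation of one of the validity rules; the returned list
#' names which rule (if any) is broken.
#'
#' @param N,T Population size and generations for the simulation.
#' @param seed Integer seed; output is deterministic per seed.
#' @return For `random_wf_fixture`, a [table_collection()].  For
#'   `random_tables`, `list(tables, violation)` with `violation` one of
#'   `"none"`, `"R1"`, `"R2"`.
#' @export
random_wf_fixture <- function(N, T, seed) {
  simulate_wf(N = N, T = T, seed = seed)$tables
}

#' @rdname random_wf_fixture
#' @param violation Which validity rule to break.
#' @export
random_tables <- function(seed, violation = c("none", "R1", "R2")) {
  violation <- match.arg(violation)
  tc <- with_seed(seed, {
    N <- 2L + as.integer(floor(runif(1) * 6))
    T <- 2L + as.integer(floor(runif(1) * 10))
    run_wf(N, T, 1, Inf, "single", 1, 0, NULL, TRUE)$tables
  })
  if (violation == "R1") {
    # a parent not strictly older than its child: tie the two oldest nodes
    o <- order(-tc$node_time)
    add_edge(tc, 0, tc$sequence_length, o[2] - 1L, o[1] - 1L)
  } else if (violation == "R2") {
    # re-issue an existing edge shifted to overlap the child's intervals
    l <- tc$edge_left[1]
    r <- tc$edge_right[1]
    mid <- (l + r) / 2
    add_edge(tc, l, mid, tc$edge_parent[1], tc$edge_child[1])
  }
  list(tables = tc, violation = violation)
}
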