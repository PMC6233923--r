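## Closed-form coalescent predictions for the size of simplified tree
## sequences from a haploid Wright-Fisher population of size N observed for
## T generations.  All logarithms are natural (the harmonic-sum identity
## H_x ~ log(x) + gamma underlying the approximations requires it).  These
## are expectations and bounds, meant to be compared against replicate
## averages, never asserted per replicate.

#' Upper bound on simplified edge count
#'
#' The expected number of edges needed to store the last `T` generations of
#' history of a haploid Wright-Fisher population of size `N` is bounded by
#' \deqn{2N\left(1 + 4\log\left(\min\left(N, \frac{T+2}{2}\right)\right)\right),}
#' floored below at `2N`: at most `2N - 2` edges describe the leftmost tree,
#' and each topology change along the genome turns over at most four edges,
#' at a rate governed by the total tree length up to time `T`.  Grows as
#' `O(N log T)`, saturating once `(T+2)/2 >= N`.
#'
#' @param N Haploid population size, `>= 1`.
#' @param T Number of generations of recorded history, `>= 0`.
#' @return The bound (a float; not an integer).
#' @examples
#' edge_bound(100, 1000)
#' @export
edge_bound <- function(N, T) {
  check_positive(N, "N")
  stopifnot(all(T >= 0))
  pmax(2 * N, 2 * N * (1 + 4 * log(pmin(N, (T + 2) / 2))))
}

#' Expected number of roots after T generations
#'
#' A marginal tree cut `T` generations ago is expected to have around
#' `r(T) = 2N / (T + 2)` roots: the `N` tips descend from about `n`
#' lineages `2(N/n - 1)` generations ago, and `r(T)` inverts that
#' relationship.  A crude estimate; clamped to `[1, N]`.
#'
#' @inheritParams edge_bound
#' @return Expected root count.
#' @export
expected_roots <- function(N, T) {
  check_positive(N, "N")
  stopifnot(all(T >= 0))
  pmin(pmax(2 * N / (T + 2), 1), N)
}

#' Expected total length of a coalescent tree
#'
#' While a coalescent tree has `k` lineages it persists for `2N/(k(k-1))`
#' generations in expectation, contributing `2N/(k-1)` to the total branch
#' length.  Summing over `n_lower < k <= N` gives the exact harmonic form
#' \deqn{2N \sum_{k=n_lower+1}^{N} \frac{1}{k-1} = 2N\,(H_{N-1} - H_{n_lower-1}),}
#' approximately `2N log N` for `n_lower = 1` and large `N`.
#'
#' @param N Number of tips (= haploid population size here).
#' @param n_lower Count only epochs with more than `n_lower` lineages
#'   (default 1: the whole tree down to the MRCA).
#' @return Expected tree length in generations.
#' @export
expected_tree_length <- function(N, n_lower = 1) {
  check_positive(N, "N")
  stopifnot(n_lower >= 1, n_lower < N)
  ks <- seq.int(n_lower + 1, N)
  2 * N * sum(1 / (ks - 1))
}

#' Generations back to n ancestral lineages
#'
#' The `N` tips of a coalescent tree are expected to descend from only `n`
#' lineages around `2(N/n - 1)` generations ago.  Exact algebraic inverse of
#' [expected_roots()].
#'
#' @inheritParams edge_bound
#' @param n Target number of lineages, `1 <= n <= N`.
#' @return Expected number of generations.
#' @export
generations_to_n_lineages <- function(N, n) {
  check_positive(N, "N")
  stopifnot(all(n >= 1), all(n <= N))
  2 * (N / n - 1)
}

#' Mutation-count reduction from retrospective placement
#'
#' Forwards-time generation of infinite-sites mutations at total rate `mu`
#' per generation produces around `mu * N * T` mutations, one batch per
#' meiosis, most of them destined to be lost.  Placing mutations on the
#' simplified tree sequence instead produces around `mu * 2N log N`
#' (proportional to the total area).  The ratio,
#' \deqn{\frac{NT}{2N \log N} = \frac{T}{2 \log N},}
#' is how many times fewer mutations need to be generated.
#'
#' @param N Haploid population size, `>= 2`.
#' @param T Number of generations simulated, `>= 1`.
#' @return The reduction factor.
#' @examples
#' mutation_reduction_factor(2e4, 2e5)   # about ten thousand
#' @export
mutation_reduction_factor <- function(N, T) {
  stopifnot(all(N >= 2), all(T >= 1))
  T / (2 * log(N))
}

#' Expected edges to store a fully coalesced population history
#'
#' With `T` large relative to `N`, the expected marginal tree length is
#' about `2N log N`, and the tree sequence describing the entire population
#' needs no more than `2N + 8N log(N)` edges.  Note this constant differs
#' from [edge_bound()]'s saturation value `2N(1 + 4 log N)`: the additive
#' `2N` term enters differently in the two derivations, so neither
#' dominates the other for all `N`; both are exposed as stated.
#'
#' @param N Haploid population size, `>= 2`.
#' @return Expected maximum edge count, `O(N log N)`.
#' @export
max_edges_full_population <- function(N) {
  stopifnot(all(N >= 2))
  2 * N + 8 * N * log(N)
}

check_positive <- function(x, what) {
  if (!is.numeric(x) || any(is.na(x)) || any(x < 1)) {
    stop(sprintf("%s must be >= 1", what))
  }
  invisible(x)
}
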