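#' Place neutral mutations on a recorded genealogy
#'
#' Because neutral alleles do not affect the population process, generating
#' them afterwards on the recorded genealogy is equivalent to generating
#' them during the simulation.  For each edge, the number of mutations is
#' drawn Poisson with mean `mu * (right - left) * (time[parent] -
#' time[child])`; positions are uniform on the edge's interval and all
#' distinct (continuum / infinite-sites model).  Each mutation creates a new
#' site and a single mutation record on the edge's *child* node -- the first
#' node to inherit the new state.  Mutations are only ever placed on edges,
#' never above local roots.
#'
#' @param ts A [tree_sequence()].
#' @param mu Mutation rate per unit of sequence length per generation,
#'   `>= 0`.
#' @param model `"binary"` (ancestral `"0"`, derived `"1"`; the default,
#'   matching infinite-sites summaries) or `"nucleotide"` (uniform random
#'   ancestral base, uniform random different derived base).
#' @param seed Optional integer; with a seed the output is reproducible and
#'   the caller's RNG state is left untouched.
#' @return A new [tree_sequence()] carrying the input tables plus the new
#'   sites and mutations, sorted.
#' @examples
#' sim <- simulate_wf(N = 10, T = 50, seed = 1)
#' ts <- tree_sequence(sim$tables)
#' mts <- throw_mutations(ts, mu = 0.5, seed = 2)
#' diversity(mts)
#' @export
throw_mutations <- function(ts, mu, model = c("binary", "nucleotide"),
                            seed = NULL) {
  stopifnot(inherits(ts, "tree_sequence"))
  model <- match.arg(model)
  if (!is.numeric(mu) || length(mu) != 1 || is.na(mu) || mu < 0) {
    stop("mutation rate mu must be a single value >= 0")
  }
  with_seed(seed, {
    span <- ts$edge_right - ts$edge_left
    branch <- ts$node_time[ts$edge_parent + 1L] - ts$node_time[ts$edge_child + 1L]
    k <- rpois(length(span), mu * span * branch)
    total <- sum(k)
    edge_of <- rep(seq_along(k), k)
    pos <- runif(total, ts$edge_left[edge_of], ts$edge_right[edge_of])
    while (anyDuplicated(pos) || any(pos %in% ts$site_position)) {
      redo <- duplicated(pos) | pos %in% ts$site_position
      pos[redo] <- runif(sum(redo), ts$edge_left[edge_of[redo]],
                         ts$edge_right[edge_of[redo]])
    }
    if (model == "binary") {
      anc <- rep("0", total)
      der <- rep("1", total)
    } else {
      bases <- c("A", "C", "G", "T")
      anc <- bases[1L + floor(runif(total) * 4)]
      der <- vapply(anc, function(a) {
        others <- bases[bases != a]
        others[1L + floor(runif(1) * 3)]
      }, "", USE.NAMES = FALSE)
    }
    tc <- ts_tables(ts)
    ns0 <- num_sites(tc)
    tc$site_position <- c(tc$site_position, pos)
    tc$site_ancestral <- c(tc$site_ancestral, anc)
    tc$mut_site <- c(tc$mut_site, ns0 + seq_len(total) - 1L)
    tc$mut_node <- c(tc$mut_node, ts$edge_child[edge_of])
    tc$mut_derived <- c(tc$mut_derived, der)
    sort_tables(tc)
    tree_sequence(tc)
  })
}

# Evaluate `expr` under a temporary RNG seed, restoring the caller's state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Total area of a tree sequence
#'
#' The sum over edges of segment length times branch duration,
#' \eqn{\sum_e (r_e - \ell_e)(t_{p_e} - t_{c_e})}.  This equals the integral
#' over the genome of the marginal tree length, and governs both the
#' expected number of retained mutations (`mu * total_area`) and the rate of
#' edge turnover along the genome.  Both computations are available; they
#' agree whenever every recorded branch is part of some marginal tree (the
#' `"trees"` method sums all branches of each tree, sample-ancestral or
#' not, weighted by the tree's interval).
#'
#' @param ts A [tree_sequence()].
#' @param method `"edges"` (direct sum; the default) or `"trees"`
#'   (genome integral of tree length).
#' @return A single number in units of generations times sequence length.
#' @export
total_area <- function(ts, method = c("edges", "trees")) {
  stopifnot(inherits(ts, "tree_sequence"))
  method <- match.arg(method)
  if (method == "edges") {
    sum((ts$edge_right - ts$edge_left) *
          (ts$node_time[ts$edge_parent + 1L] - ts$node_time[ts$edge_child + 1L]))
  } else {
    total <- 0
    for (tree in trees(ts)) {
      v <- which(!is.na(tree$parent))
      len <- sum(tree$time[tree$parent[v] + 1L] - tree$time[v])
      total <- total + len * (tree$right - tree$left)
    }
    total
  }
}
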