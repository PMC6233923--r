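#' Forwards-time Wright-Fisher simulation with genealogy recording
#'
#' Simulates a randomly mating population of `N` haploid individuals, each
#' carrying one chromosome of length `L`, for `T` discrete generations,
#' recording the genealogy as it goes: every birth appends one node (the
#' newborn's birth time) and one edge per distinctly inherited segment.  By
#' default each meiosis has exactly one crossover at a uniform position `x`,
#' so a newborn `u` with parents `a` and `b` contributes edges
#' `(0, x, a, u)` and `(x, L, b, u)`; parents are drawn uniformly with
#' replacement (self-parenting allowed).  Every `simplify_interval`
#' generations the tables are simplified down to the history of the current
#' population, which keeps the resident table size bounded; the final tables
#' are simplified to the final population unless `final_simplify = FALSE`.
#'
#' Node times count down from `T` (founders) to `0` (final generation), so
#' they are already "time ago" from the end of the run; simplification only
#' uses the ordering of times, so checkpoints need no clock translation.
#' Per birth, the random draws `(a, b, x)` are consumed in a fixed order
#' from one generator stream and simplification consumes no randomness, so
#' the final simplified tables are independent of `simplify_interval` for a
#' fixed seed.
#'
#' @param N Haploid population size, `>= 1`.
#' @param T Number of generations, `>= 0`.
#' @param L Chromosome length, `> 0`.
#' @param simplify_interval Simplify every this many generations (`Inf` to
#'   never simplify mid-run).
#' @param seed Optional integer seed; the caller's RNG state is restored.
#' @param crossovers `"single"` -- exactly one crossover per meiosis (the
#'   default) -- or `"poisson"`, with `Poisson(crossover_rate)` crossovers
#'   at uniform positions (zero crossovers give a single clonal edge from
#'   parent `a`).
#' @param crossover_rate Mean crossovers per meiosis for `"poisson"` mode.
#' @param forward_mutation_rate Optional per-unit-length, per-generation
#'   neutral mutation rate: each newborn receives `Poisson(rate * L)`
#'   mutations at uniform positions, recorded in the site/mutation tables as
#'   they happen (binary states).  This forwards-generation mode exists to
#'   validate that retrospective placement with [throw_mutations()] is
#'   statistically identical; retrospective placement is the efficient path.
#' @param init Optional prior history from [initialize_from()]: the founder
#'   generation takes its node ids from the supplied tables, whose times are
#'   shifted `T` generations into the past, so lineages that fail to
#'   coalesce within the simulated epoch coalesce inside the prior.
#' @param final_simplify Simplify to the final population before returning
#'   (default `TRUE`).  With `FALSE` the raw recorded tables are returned in
#'   emission order (unsorted), with the final population flagged as
#'   samples: a run of `T` generations has `N(T+1)` node rows (founders
#'   included) and `2NT` edge rows in `"single"` mode.
#' @return A list with components `tables` (a [table_collection()]),
#'   `samples` (node ids of the final population, `0..N-1` after a final
#'   simplify) and `max_edge_rows` (the largest resident edge count seen,
#'   a measure of the memory the simplification interval trades against).
#' @examples
#' sim <- simulate_wf(N = 8, T = 20, seed = 1)
#' ts <- tree_sequence(sim$tables)
#' length(trees(ts))
#' @export
simulate_wf <- function(N, T, L = 1, simplify_interval = 10, seed = NULL,
                        crossovers = c("single", "poisson"),
                        crossover_rate = 1,
                        forward_mutation_rate = 0,
                        init = NULL, final_simplify = TRUE) {
  crossovers <- match.arg(crossovers)
  stopifnot(
    is.numeric(N), length(N) == 1, N >= 1, N == floor(N),
    is.numeric(T), length(T) == 1, T >= 0, T == floor(T),
    is.numeric(L), length(L) == 1, L > 0,
    is.numeric(simplify_interval), length(simplify_interval) == 1,
    simplify_interval >= 1,
    is.numeric(crossover_rate), crossover_rate >= 0,
    is.numeric(forward_mutation_rate), forward_mutation_rate >= 0
  )
  N <- as.integer(N)
  T <- as.integer(T)
  with_seed(seed, run_wf(N, T, L, simplify_interval, crossovers,
                         crossover_rate, forward_mutation_rate, init,
                         final_simplify))
}

run_wf <- function(N, T, L, s, crossovers, crossover_rate, fmu, init,
                   final_simplify) {
  # base columns (simplified prefix of history) + per-generation buffers
  if (is.null(init)) {
    base <- list(
      node_time = rep(as.numeric(T), N),
      node_metadata = rep("", N),
      edge_left = numeric(0), edge_right = numeric(0),
      edge_parent = integer(0), edge_child = integer(0),
      site_position = numeric(0), site_ancestral = character(0),
      mut_site = integer(0), mut_node = integer(0), mut_derived = character(0)
    )
    P <- seq_len(N) - 1L
  } else {
    if (!inherits(init, "wf_init")) {
      stop("init must come from initialize_from()")
    }
    if (length(init$samples) != N) {
      stop(sprintf("init has %d samples but N = %d", length(init$samples), N))
    }
    tc <- init$tables
    base <- list(
      node_time = tc$node_time + T,   # prior times shifted into the past
      node_metadata = tc$node_metadata,
      edge_left = tc$edge_left, edge_right = tc$edge_right,
      edge_parent = tc$edge_parent, edge_child = tc$edge_child,
      site_position = tc$site_position, site_ancestral = tc$site_ancestral,
      mut_site = tc$mut_site, mut_node = tc$mut_node,
      mut_derived = tc$mut_derived
    )
    P <- init$samples
  }
  n_nodes <- length(base$node_time)
  buf <- new_buffers()
  max_edge_rows <- length(base$edge_left)

  flush_tables <- function(sample_ids) {
    nt <- c(base$node_time, unlist(buf$node_time))
    nm <- c(base$node_metadata, rep("", length(nt) - length(base$node_metadata)))
    flags <- logical(length(nt))
    flags[sample_ids + 1L] <- TRUE
    new_table_collection(
      L,
      node_time = nt, node_is_sample = flags, node_metadata = nm,
      edge_left = c(base$edge_left, unlist(buf$edge_left)),
      edge_right = c(base$edge_right, unlist(buf$edge_right)),
      edge_parent = c(base$edge_parent, unlist(buf$edge_parent)),
      edge_child = c(base$edge_child, unlist(buf$edge_child)),
      site_position = c(base$site_position, unlist(buf$site_position)),
      site_ancestral = c(base$site_ancestral,
                         rep("0", length(unlist(buf$site_position)))),
      mut_site = c(base$mut_site, unlist(buf$mut_site)),
      mut_node = c(base$mut_node, unlist(buf$mut_node)),
      mut_derived = c(base$mut_derived,
                      rep("1", length(unlist(buf$mut_site))))
    )
  }

  checkpoint <- function() {
    tc <- flush_tables(P)
    sort_tables(tc)
    res <- simplify_core(tc, P)
    out <- res$tables
    base <<- list(
      node_time = out$node_time, node_metadata = out$node_metadata,
      edge_left = out$edge_left, edge_right = out$edge_right,
      edge_parent = out$edge_parent, edge_child = out$edge_child,
      site_position = out$site_position, site_ancestral = out$site_ancestral,
      mut_site = out$mut_site, mut_node = out$mut_node,
      mut_derived = out$mut_derived
    )
    buf <<- new_buffers()
    n_nodes <<- length(out$node_time)
    P <<- seq_len(N) - 1L
    res$tables
  }

  for (g in seq_len(T)) {
    t_now <- T - g
    u3 <- runif(3L * N)
    ia <- seq.int(1L, 3L * N, by = 3L)
    a <- pmin(as.integer(floor(u3[ia] * N)), N - 1L)
    b <- pmin(as.integer(floor(u3[ia + 1L] * N)), N - 1L)
    x <- u3[ia + 2L] * L
    x[x <= 0 | x >= L] <- L / 2       # guard the open interval (0, L)
    newborn <- n_nodes + seq_len(N) - 1L
    buf$node_time[[length(buf$node_time) + 1L]] <- rep(as.numeric(t_now), N)

    if (crossovers == "single") {
      buf$edge_left[[length(buf$edge_left) + 1L]] <- as.vector(rbind(0, x))
      buf$edge_right[[length(buf$edge_right) + 1L]] <- as.vector(rbind(x, L))
      buf$edge_parent[[length(buf$edge_parent) + 1L]] <-
        as.vector(rbind(P[a + 1L], P[b + 1L]))
      buf$edge_child[[length(buf$edge_child) + 1L]] <- rep(newborn, each = 2L)
    } else {
      k <- rpois(N, crossover_rate)
      el <- er <- numeric(0)
      ep <- ec <- integer(0)
      for (i in seq_len(N)) {
        bp <- if (k[i] > 0) sort(runif(k[i], 0, L)) else numeric(0)
        bounds <- c(0, bp, L)
        nseg <- length(bounds) - 1L
        pars <- rep_len(c(P[a[i] + 1L], P[b[i] + 1L]), nseg)
        el <- c(el, bounds[-length(bounds)])
        er <- c(er, bounds[-1])
        ep <- c(ep, pars)
        ec <- c(ec, rep(newborn[i], nseg))
      }
      buf$edge_left[[length(buf$edge_left) + 1L]] <- el
      buf$edge_right[[length(buf$edge_right) + 1L]] <- er
      buf$edge_parent[[length(buf$edge_parent) + 1L]] <- ep
      buf$edge_child[[length(buf$edge_child) + 1L]] <- ec
    }

    if (fmu > 0) {
      km <- rpois(N, fmu * L)
      total <- sum(km)
      if (total > 0) {
        ns_now <- length(base$site_position) + sum(lengths(buf$site_position))
        buf$site_position[[length(buf$site_position) + 1L]] <- runif(total, 0, L)
        buf$mut_site[[length(buf$mut_site) + 1L]] <- ns_now + seq_len(total) - 1L
        buf$mut_node[[length(buf$mut_node) + 1L]] <- rep(newborn, km)
      }
    }

    n_nodes <- n_nodes + N
    P <- newborn
    max_edge_rows <- max(max_edge_rows,
                         length(base$edge_left) + sum(lengths(buf$edge_left)))
    if (g < T && is.finite(s) && (T - g) %% s == 0) {
      checkpoint()
    }
  }

  if (final_simplify) {
    tables <- checkpoint()
    samples <- seq_len(N) - 1L
  } else {
    tables <- flush_tables(P)
    samples <- P
  }
  list(tables = tables, samples = samples, max_edge_rows = max_edge_rows)
}

new_buffers <- function() {
  list(node_time = list(),
       edge_left = list(), edge_right = list(),
       edge_parent = list(), edge_child = list(),
       site_position = list(), mut_site = list(), mut_node = list())
}

#' Record one birth in a table collection
#'
#' Appends the newborn's node row and one edge per distinctly inherited
#' segment, alternating between the two parents starting from `parent_a` at
#' the left end of the chromosome.  This is the single bookkeeping step a
#' forwards-time simulator of any breeding model needs to perform per new
#' genome.
#'
#' @param tables A [table_collection()], modified in place.
#' @param time Birth time of the newborn ("time ago" convention).
#' @param parent_a,parent_b Node ids of the two parental chromosomes.
#' @param breakpoints Crossover positions, strictly increasing, inside
#'   `(0, L)`.  Empty means clonal inheritance of `[0, L)` from `parent_a`.
#' @return The newborn's node id.
#' @export
record_birth <- function(tables, time, parent_a, parent_b,
                         breakpoints = numeric(0)) {
  check_tables_arg(tables)
  L <- tables$sequence_length
  breakpoints <- as.numeric(breakpoints)
  if (length(breakpoints)) {
    if (is.unsorted(breakpoints, strictly = TRUE) ||
        breakpoints[1] <= 0 || breakpoints[length(breakpoints)] >= L) {
      stop(sprintf("breakpoints must be strictly increasing inside (0, %g)", L))
    }
  }
  u <- add_node(tables, time)
  bounds <- c(0, breakpoints, L)
  parents <- rep_len(c(parent_a, parent_b), length(bounds) - 1L)
  for (i in seq_len(length(bounds) - 1L)) {
    add_edge(tables, bounds[i], bounds[i + 1L], parents[i], u)
  }
  u
}

#' Simplify at a generation boundary
#'
#' Sorts a copy of the tables and simplifies to the given current
#' population, relabelling it `0..N-1`: the bookkeeping that keeps the
#' simulator's individual ids in sync with the node ids in the tables.
#'
#' @param tables A valid [table_collection()]; not modified.
#' @param samples Node ids of the current population.
#' @return A list with `tables` (simplified), `samples` (now `0..N-1`) and
#'   `node_map` (input id to output id, `NA` where dropped).
#' @export
simplify_checkpoint <- function(tables, samples) {
  tc <- copy_tables(tables)
  sort_tables(tc)
  res <- simplify_tables(tc, samples)
  list(tables = res$tables, samples = seq_along(samples) - 1L,
       node_map = res$node_map)
}

#' Start a simulation from prior history
#'
#' Packages an existing tree sequence (for example the output of a
#' coalescent simulation, or an earlier [simulate_wf()] run) as the founder
#' state of a new simulation: the founder population takes its node ids
#' from `samples`, and history recorded by the new run is appended on top.
#' Lineages that fail to coalesce during the simulated epoch then coalesce
#' within the prior instead of being left as multiple roots.
#'
#' @param tables A valid [table_collection()] whose youngest generation is
#'   at time 0.
#' @param samples Node ids to use as the founder population; its length
#'   must equal the `N` passed to [simulate_wf()].
#' @return An object of class `"wf_init"` for the `init` argument of
#'   [simulate_wf()].
#' @export
initialize_from <- function(tables, samples) {
  check_tables_arg(tables)
  val <- validate_tables(tables)
  if (!val$ok) {
    stop("prior tables are not valid")
  }
  samples <- check_samples_arg(samples, num_nodes(tables))
  tc <- copy_tables(tables)
  sort_tables(tc)
  structure(list(tables = tc, samples = samples), class = "wf_init")
}
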