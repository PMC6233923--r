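# Brute-force and closed-form oracles, kept deliberately independent of the
# implementation paths they check.

# O(E^2) pairwise interval-overlap check of rule R2: returns the sorted
# 0-based ids of edges overlapping another edge with the same child.
brute_r2_rows <- function(ed) {
  bad <- logical(nrow(ed))
  if (nrow(ed) >= 2) {
    for (i in seq_len(nrow(ed) - 1)) {
      for (j in seq.int(i + 1, nrow(ed))) {
        if (ed$child[i] == ed$child[j] &&
            ed$left[i] < ed$right[j] && ed$left[j] < ed$right[i]) {
          bad[i] <- TRUE
          bad[j] <- TRUE
        }
      }
    }
  }
  sort(which(bad) - 1L)
}

# Genotype matrix from variants(): samples in rows, sites in columns.
genotype_matrix <- function(ts) {
  vs <- variants(ts)
  if (length(vs) == 0) {
    return(matrix(character(0), nrow = length(ts$samples), ncol = 0))
  }
  do.call(cbind, lapply(vs, `[[`, "states"))
}

# Literal pairwise-difference diversity from the genotype matrix.
pi_matrix <- function(ts) {
  g <- genotype_matrix(ts)
  n <- nrow(g)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in seq.int(i + 1, n)) {
      diffs <- diffs + sum(g[i, ] != g[j, ])
    }
  }
  diffs / (choose(n, 2) * ts$sequence_length)
}

# Number of polymorphic sites (>= 2 distinct states among the samples).
count_segregating <- function(ts) {
  sum(vapply(variants(ts), function(v) length(unique(v$states)) > 1, TRUE))
}

# Exact expected total length of the genealogy of all N individuals at a
# single position of a discrete Wright-Fisher population, truncated at T
# generations: the ancestor-count chain is an occupancy process (k lineages
# choose among N parents; the transition to j distinct parents involves the
# Stirling subset numbers, computed in log space), and each generation
# contributes one unit of branch per lineage, branches above the MRCA
# excluded.
wf_exact_tree_length <- function(N, T) {
  lS <- matrix(-Inf, N + 1, N + 1)
  lS[1, 1] <- 0
  for (k in 1:N) {
    for (j in 1:k) {
      a <- if (j <= k - 1) log(j) + lS[k, j + 1] else -Inf
      b <- lS[k, j]
      m <- max(a, b)
      lS[k + 1, j + 1] <- if (is.finite(m)) m + log(exp(a - m) + exp(b - m)) else -Inf
    }
  }
  M <- matrix(0, N, N)
  for (k in 1:N) {
    for (j in 1:k) {
      M[k, j] <- exp(lchoose(N, j) + lS[k + 1, j + 1] + lgamma(j + 1) -
                       k * log(N))
    }
  }
  p <- c(rep(0, N - 1), 1)
  len <- 0
  for (t in seq_len(T)) {
    len <- len + sum(p * seq_len(N)) - p[1]
    p <- as.vector(p %*% M)
  }
  len
}

# Truncate the edge table of a collection to its first k rows (prefix in
# canonical sorted order), keeping everything else.
edge_prefix <- function(tc, k) {
  out <- copy_tables(tc)
  out$edge_left <- tc$edge_left[seq_len(k)]
  out$edge_right <- tc$edge_right[seq_len(k)]
  out$edge_parent <- tc$edge_parent[seq_len(k)]
  out$edge_child <- tc$edge_child[seq_len(k)]
  out
}

# Compare every marginal tree of a simplified output against the
# brute-force induced subtree of the unsimplified input; TRUE if all match.
oracle_trees_match <- function(in_ts, out_ts, samples) {
  in_trees <- trees(in_ts)
  out_trees <- trees(out_ts)
  oi <- 1L
  for (tree in in_trees) {
    mid <- (tree$left + tree$right) / 2
    while (out_trees[[oi]]$right <= mid) oi <- oi + 1L
    a <- induced_subtree(tree, samples = samples)
    b <- induced_subtree(out_trees[[oi]], samples = out_ts$samples)
    if (!identical(a, b)) {
      return(FALSE)
    }
  }
  TRUE
}

# Structural checks on a simplified collection: within every marginal tree,
# non-sample nodes that appear as a parent have >= 2 children and non-sample
# nodes never dangle as childless leaves; every node and edge is reachable
# from a sample.  Returns NULL if clean, else a message.
simplified_structure_problem <- function(tc) {
  ts <- tree_sequence(tc)
  nn <- length(ts$node_time)
  reached <- logical(nn)
  for (tree in trees(ts)) {
    present_child <- which(!is.na(tree$parent))
    nkids <- tabulate(tree$parent[present_child] + 1L, nbins = nn)
    parents <- which(nkids > 0L)
    bad <- parents[!ts$node_is_sample[parents] & nkids[parents] < 2L]
    if (length(bad)) {
      return(sprintf("unary non-sample node %d in tree at %g", bad[1] - 1L, tree$left))
    }
    leaf <- present_child[nkids[present_child] == 0L]
    if (any(!ts$node_is_sample[leaf])) {
      return(sprintf("non-sample leaf in tree at %g", tree$left))
    }
    reached <- reached | sample_ancestral_mark(tree, ts$samples)
  }
  if (!all(reached)) {
    return(sprintf("node %d unreachable from any sample", which(!reached)[1] - 1L))
  }
  # every edge is live at its own midpoint
  for (i in seq_along(ts$edge_left)) {
    mid <- (ts$edge_left[i] + ts$edge_right[i]) / 2
    tree <- tree_at(ts, mid)
    if (is.na(tree$parent[ts$edge_child[i] + 1L]) ||
        tree$parent[ts$edge_child[i] + 1L] != ts$edge_parent[i]) {
      return(sprintf("edge %d not expressed at its midpoint", i - 1L))
    }
  }
  NULL
}

sample_ancestral_mark <- function(tree, samples) {
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

# Mean pairwise TMRCA over all sample pairs in one marginal tree: the pairs
# whose MRCA is node u number C(n_u, 2) minus the pairs already joined in
# u's children.
pair_tmrca_mean <- function(tree, ts) {
  nn <- length(tree$parent)
  cnt <- integer(nn)
  for (s in ts$samples) {
    v <- s + 1L
    repeat {
      cnt[v] <- cnt[v] + 1L
      p <- tree$parent[v]
      if (is.na(p)) break
      v <- p + 1L
    }
  }
  kids_sum <- numeric(nn)
  for (v in seq_len(nn)) {
    p <- tree$parent[v]
    if (!is.na(p)) kids_sum[p + 1L] <- kids_sum[p + 1L] + choose(cnt[v], 2)
  }
  acc <- 0
  for (v in seq_len(nn)) {
    if (cnt[v] >= 2L) {
      acc <- acc + (choose(cnt[v], 2) - kids_sum[v]) * ts$node_time[v]
    }
  }
  acc / choose(length(ts$samples), 2)
}
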