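test_that("the toy tree sequence sweeps into its two known trees", {
  ts <- toy_tree_sequence()
  tr <- trees(ts)
  expect_length(tr, 2L)
  expect_equal(breakpoints(ts), c(0, 5, 10))

  t1 <- tree_at(ts, 2.5)
  expect_equal(t1$parent[2 + 1], 4L)     # branch 2 -> 4 on the left tree only
  expect_equal(tree_at(ts, 7.5)$parent[2 + 1], 3L)
  expect_equal(t1$parent[1 + 1], 3L)     # branch 1 -> 3 in both trees
  expect_equal(tree_at(ts, 7.5)$parent[1 + 1], 3L)

  # branch lengths read off the node times: |T| = 1 + 1 + 2 + 1 = 5
  expect_equal(total_branch_length(tr[[1]]), 5)
  expect_equal(num_roots(tr[[1]]), 1L)
  expect_true(check_fully_coalesced(ts))
})

test_that("degenerate tree sequences behave sensibly", {
  # empty edge table: every node is an isolated root
  tc <- table_collection(1)
  add_node(tc, 0, is_sample = TRUE)
  add_node(tc, 0, is_sample = TRUE)
  ts <- tree_sequence(tc)
  tr <- trees(ts)
  expect_length(tr, 1L)
  expect_true(all(is.na(tr[[1]]$parent)))
  expect_equal(num_roots(tr[[1]]), 2L)
  expect_false(check_fully_coalesced(ts))

  # a single sample: zero branch length, one root
  tc1 <- table_collection(1)
  add_node(tc1, 0, is_sample = TRUE)
  tr1 <- trees(tree_sequence(tc1))[[1]]
  expect_equal(total_branch_length(tr1), 0)
  expect_equal(num_roots(tr1), 1L)
})

test_that("tree intervals tile the genome and match the point oracle", {
  for (seed in 1:6) {
    tc <- random_wf_fixture(8, 30, seed = 40 + seed)
    ts <- tree_sequence(tc)
    tr <- trees(ts)
    expect_equal(tr[[1]]$left, 0)
    expect_equal(tr[[length(tr)]]$right, ts$sequence_length)
    for (i in seq_len(length(tr) - 1)) {
      expect_equal(tr[[i]]$right, tr[[i + 1]]$left)
    }
    for (tree in tr) {
      mid <- (tree$left + tree$right) / 2
      expect_equal(tree$parent, tree_at(ts, mid)$parent)
    }
  }
})

test_that("edge turnover per interior breakpoint is at most four each way", {
  for (seed in 1:5) {
    sim <- simulate_wf(N = 20, T = 200, simplify_interval = 10,
                       seed = 60 + seed)
    ts <- tree_sequence(sim$tables)
    tr <- trees(ts)
    n <- length(ts$samples)
    # the leftmost tree needs at most 2n - 2 edges
    expect_lte(sum(ts$edge_left == 0), 2 * n - 2)

    d <- edge_diffs(ts)
    root_of <- vapply(tr, function(t) paste(sort(unique(vapply(
      ts$samples, function(s) {
        v <- s + 1L
        while (!is.na(t$parent[v])) v <- t$parent[v] + 1L
        v
      }, 1L))), collapse = ","), "")
    bpos <- vapply(tr, function(t) t$left, 0)[-1]
    for (i in seq_len(nrow(d))) {
      ti <- match(d$position[i], bpos)
      if (is.na(ti)) next             # boundary merged into an equal tree
      if (root_of[ti] != root_of[ti + 1]) next   # root changes are exempt
      expect_lte(d$edges_out[i], 4L)
      expect_lte(d$edges_in[i], 4L)
    }
  }
})

test_that("variants resolve mutation inheritance including back mutations", {
  ts <- toy_tree_sequence()
  vs <- variants(ts)
  expect_length(vs, 2L)
  expect_equal(vs[[1]]$states, c("A", "A", "T"))   # node 2 inherits "T"
  # older mutation to "C" above, back mutation restores "G" for sample 1
  expect_equal(vs[[2]]$states, c("G", "G", "C"))

  # a site with no mutations is ancestral everywhere
  tc <- ts_tables(ts)
  add_site(tc, 9, "Z")
  vs2 <- variants(tree_sequence(tc))
  expect_equal(vs2[[3]]$states, c("Z", "Z", "Z"))
})

test_that("diversity matches hand-computed and matrix values", {
  # one biallelic site, n = 4, derived count 2, L = 1: pi = 4/6
  tc <- table_collection(1)
  for (i in 1:4) add_node(tc, 0, is_sample = TRUE)
  p <- add_node(tc, 1)
  r <- add_node(tc, 2)
  for (s in 0:1) add_edge(tc, 0, 1, p, s)
  for (s in 2:3) add_edge(tc, 0, 1, r, s)
  add_edge(tc, 0, 1, r, p)
  s0 <- add_site(tc, 0.5, "0")
  add_mutation(tc, s0, p, "1")
  ts <- tree_sequence(tc)
  expect_equal(diversity(ts), (2 * 2) / 6)
  expect_equal(diversity(ts), pi_matrix(ts))

  # with no mutations diversity is zero
  tc2 <- ts_tables(toy_tree_sequence())
  tc2$mut_site <- integer(0); tc2$mut_node <- integer(0)
  tc2$mut_derived <- character(0)
  tc2$site_position <- numeric(0); tc2$site_ancestral <- character(0)
  expect_equal(diversity(tree_sequence(tc2)), 0)
  expect_error(diversity(ts, sample_set = 0L), "two samples")
})

test_that("newick export is well-formed and ape reads it back", {
  ts <- toy_tree_sequence()
  lines <- export_newick(ts)
  expect_length(lines, 4L)
  expect_match(lines[1], "^#interval 0 5$")
  expect_match(lines[3], "^#interval 5 10$")
  ph <- ape::read.tree(text = lines[4])   # right tree: 3 leaves
  expect_equal(sort(ph$tip.label), c("0", "1", "2"))
  expect_equal(ape::Ntip(ph), 3L)
  # leaf-to-root depths equal the node times (root at time 2)
  depths <- ape::node.depth.edgelength(ph)[1:3]
  expect_equal(depths, rep(2, 3))

  # multi-root trees are refused
  tc <- table_collection(1)
  add_node(tc, 0, is_sample = TRUE)
  add_node(tc, 0, is_sample = TRUE)
  expect_error(export_newick(tree_sequence(tc)), "roots")
})

test_that("VCF export writes one haploid record per site", {
  ts <- toy_tree_sequence()
  lines <- export_vcf(ts)
  expect_match(lines[1], "VCFv4.2")
  rec <- lines[grep("^[^#]", lines)]
  expect_length(rec, 2L)
  f1 <- strsplit(rec[1], "\t")[[1]]
  f2 <- strsplit(rec[2], "\t")[[1]]
  expect_equal(as.integer(c(f1[2], f2[2])), c(3L, 8L))  # floor(pos) + 1
  expect_equal(f1[4], "A")
  expect_equal(f1[5], "T")
  expect_equal(f1[10:12], c("0", "0", "1"))
  expect_equal(f2[10:12], c("0", "0", "1"))              # C is the only ALT

  # no sites: header only
  tc <- ts_tables(ts)
  tc$mut_site <- integer(0); tc$mut_node <- integer(0)
  tc$mut_derived <- character(0)
  tc$site_position <- numeric(0); tc$site_ancestral <- character(0)
  expect_length(grep("^[^#]", export_vcf(tree_sequence(tc))), 0L)

  # position collisions bump to the next integer
  tcc <- table_collection(10)
  add_node(tcc, 0, is_sample = TRUE)
  add_node(tcc, 1)
  add_edge(tcc, 0, 10, 1, 0)
  add_site(tcc, 1.2, "A"); add_site(tcc, 1.7, "G")
  rec2 <- grep("^[^#]", export_vcf(tree_sequence(tcc)), value = TRUE)
  pos <- as.integer(vapply(strsplit(rec2, "\t"), `[[`, "", 2))
  expect_equal(pos, c(2L, 3L))
})
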