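test_that("row insertion is append-only with dense implicit ids", {
  tc <- table_collection(10)
  expect_equal(add_node(tc, 0, is_sample = TRUE), 0L)
  expect_equal(add_node(tc, 0, is_sample = TRUE), 1L)
  expect_equal(add_node(tc, 0, is_sample = TRUE), 2L)
  expect_equal(add_node(tc, 1), 3L)
  expect_equal(add_node(tc, 2), 4L)
  expect_equal(num_nodes(tc), 5L)
  expect_equal(nodes(tc)$id, 0:4)
  expect_equal(nodes(tc)$time, c(0, 0, 0, 1, 2))

  expect_equal(add_edge(tc, 0, 10, 3, 1), 0L)
  expect_equal(add_edge(tc, 0, 5, 4, 2), 1L)
  expect_equal(add_site(tc, 2.5, "A"), 0L)
  expect_equal(add_mutation(tc, 0, 2, "T"), 0L)
  # a derived state equal to another site's ancestral state is legal
  expect_equal(add_site(tc, 7.5, "G"), 1L)
  expect_equal(add_mutation(tc, 1, 1, "G"), 1L)
  expect_equal(num_mutations(tc), 2L)
})

test_that("malformed rows are rejected with diagnostics", {
  tc <- table_collection(10)
  expect_error(add_node(tc, -1), "time")
  expect_error(add_node(tc, NaN), "time")
  add_node(tc, 0)
  add_node(tc, 1)
  expect_error(add_edge(tc, 5, 5, 1, 0), "empty")
  expect_error(add_edge(tc, 7, 3, 1, 0), "empty")
  expect_error(add_edge(tc, -1, 5, 1, 0), "out of bounds")
  expect_error(add_edge(tc, 0, 11, 1, 0), "out of bounds")
  expect_error(add_edge(tc, 0, 5, 1, 1), "differ")
  expect_error(add_edge(tc, 0, 5, 99, 0), "unknown")
  expect_error(add_site(tc, 10, "A"), "position")
  expect_error(add_site(tc, -0.1, "A"), "position")
  add_site(tc, 1, "A")
  expect_error(add_mutation(tc, 5, 0, "T"), "site")
  expect_error(add_mutation(tc, 0, 99, "T"), "unknown")
})

test_that("validation enforces R1 strictly and R2 disjointness", {
  ped <- toy_pedigree_tables()
  expect_true(validate_tables(ped)$ok)

  tc <- table_collection(10)
  n0 <- add_node(tc, 1, is_sample = TRUE)
  n1 <- add_node(tc, 1)
  add_edge(tc, 0, 10, n1, n0)       # equal times: R1 is strict
  rep <- validate_tables(tc)
  expect_false(rep$ok)
  expect_equal(rep$violations$rule, "R1")
  expect_equal(rep$violations$row, 0L)

  tc <- table_collection(10)
  add_node(tc, 0, is_sample = TRUE)
  add_node(tc, 1)
  add_node(tc, 2)
  add_edge(tc, 0, 6, 1, 0)
  add_edge(tc, 4, 10, 2, 0)         # child 0 has two parents on [4, 6)
  rep <- validate_tables(tc)
  expect_false(rep$ok)
  expect_equal(rep$violations$rule, c("R2", "R2"))
  expect_equal(sort(rep$violations$row), c(0L, 1L))
})

test_that("R2 detection agrees with the brute-force pairwise check", {
  for (seed in 1:60) {
    fz <- random_tables(seed, violation = sample(c("none", "R1", "R2"), 1))
    rep <- validate_tables(fz$tables)
    got <- sort(rep$violations$row[rep$violations$rule == "R2"])
    expect_identical(got, brute_r2_rows(edges(fz$tables)),
                     info = paste("seed", seed))
    if (fz$violation == "none") {
      expect_true(rep$ok, info = paste("seed", seed))
    } else {
      expect_true(fz$violation %in% rep$violations$rule,
                  info = paste("seed", seed))
    }
  }
})

test_that("sorting is canonical, idempotent and permutation-invariant", {
  ped <- toy_pedigree_tables()          # emitted youngest-first: not sorted
  sort_tables(ped)
  once <- copy_tables(ped)
  sort_tables(ped)
  expect_true(tables_equal(once, ped))  # idempotent

  # random permutation of a valid edge table sorts back to the same order
  tc <- random_wf_fixture(8, 20, seed = 4)
  sort_tables(tc)
  ref <- copy_tables(tc)
  perm <- sample(num_edges(tc))
  tc$edge_left <- tc$edge_left[perm]
  tc$edge_right <- tc$edge_right[perm]
  tc$edge_parent <- tc$edge_parent[perm]
  tc$edge_child <- tc$edge_child[perm]
  sort_tables(tc)
  expect_true(tables_equal(ref, tc))

  # edges sharing a parent are contiguous, parents youngest first
  tp <- ped$node_time[ped$edge_parent + 1L]
  expect_true(!is.unsorted(tp))
})

test_that("mutations sort ancestral-most first and duplicate sites collapse", {
  tc <- table_collection(10)
  for (i in 0:2) add_node(tc, i, is_sample = i == 0)
  add_edge(tc, 0, 10, 1, 0)
  add_edge(tc, 0, 10, 2, 1)
  s0 <- add_site(tc, 7.5, "G")
  s1 <- add_site(tc, 2.5, "A")
  add_site(tc, 2.5, "X")               # exact duplicate position: dropped
  add_mutation(tc, s0, 0, "C")         # younger node: must sort after
  add_mutation(tc, s0, 2, "T")
  add_mutation(tc, 2, 0, "Z")          # refers to the duplicate site
  sort_tables(tc)
  expect_equal(sites(tc)$position, c(2.5, 7.5))
  expect_equal(sites(tc)$ancestral_state, c("A", "G"))
  mu <- mutations(tc)
  expect_equal(mu$site, c(0L, 1L, 1L))
  expect_equal(mu$derived_state, c("Z", "T", "C"))  # time-ago descending
})

test_that("squashing merges abutting edges and recovers fragmented tables", {
  ed <- data.frame(left = c(0, 0.5), right = c(0.5, 1),
                   parent = c(3L, 3L), child = c(0L, 0L))
  sq <- squash_edges(ed)
  expect_equal(nrow(sq), 1L)
  expect_equal(sq$left, 0)
  expect_equal(sq$right, 1)

  ed2 <- data.frame(left = c(0, 0.5), right = c(0.5, 1),
                    parent = c(3L, 4L), child = c(0L, 0L))
  expect_equal(nrow(squash_edges(ed2)), 2L)   # different parents: untouched

  # fragment every edge of a valid table at interior points; squash recovers
  set.seed(99)
  tc <- random_wf_fixture(6, 15, seed = 2)
  sort_tables(tc)
  ref <- edges(tc)[, c("left", "right", "parent", "child")]
  frag <- do.call(rbind, lapply(seq_len(nrow(ref)), function(i) {
    k <- sample(0:3, 1)
    cuts <- sort(runif(k, ref$left[i], ref$right[i]))
    b <- unique(c(ref$left[i], cuts, ref$right[i]))
    data.frame(left = b[-length(b)], right = b[-1],
               parent = ref$parent[i], child = ref$child[i])
  }))
  frag <- frag[sample(nrow(frag)), ]
  got <- squash_edges(frag)
  ord <- order(ref$parent, ref$child, ref$left)
  expect_equal(got, ref[ord, ], ignore_attr = TRUE)
})

test_that("text dialect round-trips exactly", {
  f <- withr::local_tempfile()
  ts <- toy_tree_sequence()
  tc <- ts_tables(ts)
  dump_text(tc, f)
  expect_true(tables_equal(load_text(f), tc))

  # empty collection: headers only
  empty <- table_collection(1)
  dump_text(empty, f)
  expect_true(tables_equal(load_text(f), empty))

  # metadata and awkward floats survive byte-for-byte
  tc2 <- table_collection(1)
  add_node(tc2, 1 / 3, is_sample = TRUE, metadata = "tab\there\nand\\slash")
  add_node(tc2, 0.1 + 0.2)
  add_edge(tc2, 0, 2 / 3, 1, 0)
  dump_text(tc2, f)
  expect_true(tables_equal(load_text(f), tc2))

  # simulated tables with many floats
  tc3 <- random_wf_fixture(10, 30, seed = 11)
  dump_text(tc3, f)
  expect_true(tables_equal(load_text(f), tc3))
})

test_that("text dialect parse errors name the offending line", {
  f <- withr::local_tempfile()
  writeLines(c("#L 5", "#nodes", "time\tis_sample\tmetadata",
               "0\t1\t", "#edges", "left\tright\tparent\tchild",
               "0\t5\t99\t0", "#sites", "position\tancestral_state",
               "#mutations", "site\tnode\tderived_state"), f)
  expect_error(load_text(f), "line 7.*node 99")

  writeLines(c("#L 5", "#nodes", "time\tis_sample\tmetadata",
               "zero\t1\t", "#edges", "left\tright\tparent\tchild",
               "#sites", "position\tancestral_state",
               "#mutations", "site\tnode\tderived_state"), f)
  expect_error(load_text(f), "line 4")

  writeLines(c("#L 5", "#nodes", "wrong\theader"), f)
  expect_error(load_text(f), "missing section|column header")

  writeLines("nonsense", f)
  expect_error(load_text(f), "line 1")
})

test_that("metadata is preserved through sort and simplify", {
  ped <- toy_pedigree_tables()
  sort_tables(ped)
  expect_equal(nodes(ped)$metadata,
               c("A", "B", "C", "D", "E", "F", "G", "H", "I", "J", "K"))
  res <- simplify_tables(ped, samples = c(9L, 10L))
  expect_equal(nodes(res$tables)$metadata, c("J", "K", "H", "E", "A"))
})
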