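test_that("protein_distance: closed forms, saturation, errors", {
  expect_equal(protein_distance("MKVA", "MKVA"), 0)
  expect_equal(protein_distance("MKVA", "MKLS"), log(2))  # p = 0.5
  # gaps excluded from the shared denominator
  expect_equal(protein_distance("MK-A", "MKV-"), 0)
  expect_error(protein_distance("--A", "A--"), "incomparable")
  d <- protein_distance(paste(rep("A", 20), collapse = ""),
                        paste(rep("K", 20), collapse = ""))
  expect_equal(as.numeric(d), 3.0)
  expect_true(isTRUE(attr(d, "saturated")))
  # correction is monotone in p and >= p
  p <- seq(0.05, 0.9, by = 0.05)
  dd <- -log(1 - p)
  expect_true(all(diff(dd) > 0) && all(dd >= p))
})

test_that("nj_tree recovers the hand-worked 4-taxon additive case", {
  # tree ((A:1,B:2):1,(C:3,D:4)) with internal edge 1 between the pairs
  d <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(d)
  expect_identical(ape::Ntip(tr), 4L)
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_true(is_monophyletic(tr, c("C", "D")))
  expect_equal(ape::cophenetic.phylo(tr)[rownames(d), colnames(d)], d,
               tolerance = 1e-12)
  # pendant branch lengths recovered exactly
  bl <- setNames(tr$edge.length[match(seq_len(4), tr$edge[, 2])],
                 tr$tip.label)
  expect_equal(bl[c("A", "B", "C", "D")], c(A = 1, B = 2, C = 3, D = 4))
})

test_that("nj_tree resolves three equidistant taxa as a unit star", {
  d <- matrix(2, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  tr <- nj_tree(d)
  expect_equal(sort(tr$edge.length), rep(1, 3))
  expect_error(nj_tree(d[1:2, 1:2]), "size error")
})

test_that("nj_tree recovers random additive matrices exactly (n <= 12)", {
  for (seed in 1:8) {
    n <- sample(4:12, 1)
    fx <- random_additive_matrix(n, seed)
    out <- nj_tree(fx$d)
    path <- ape::cophenetic.phylo(out)[rownames(fx$d), colnames(fx$d)]
    expect_lt(max(abs(path - fx$d)), 1e-9)
    # independent oracle: ape's own NJ yields the same bipartitions
    oracle <- ape::nj(as.dist(fx$d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(out),
                                           ape::unroot(oracle))), 0)
  }
})

test_that("nj_tree is invariant to taxon input order", {
  fx <- random_additive_matrix(8, 77)
  perm <- sample(8)
  t1 <- nj_tree(fx$d)
  t2 <- nj_tree(fx$d[perm, perm])
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
})

test_that("distance matrix validation catches shape errors", {
  d <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_silent(validate_distance_matrix(d))
  d2 <- d; d2[1, 2] <- 2
  expect_error(validate_distance_matrix(d2), "not symmetric")
  d3 <- d; diag(d3) <- 1
  expect_error(validate_distance_matrix(d3), "diagonal")
})

test_that("bootstrap supports: separation, determinism, replicate granularity", {
  fx <- make_two_clade_alignment(n_per_clade = 4, length = 200, seed = 3)
  tr <- bootstrap_support(fx$alignment, replicates = 100, seed = 10)
  expect_true(is_monophyletic(tr, fx$clade1))
  # the separating edge carries 100% support: every nontrivial split that
  # equals clade A gets full support
  ets_labels <- tr$node.label[tr$node.label != ""]
  expect_true("100" %in% ets_labels)

  tr2 <- bootstrap_support(fx$alignment, replicates = 100, seed = 10)
  expect_identical(tr$node.label, tr2$node.label)

  tr3 <- bootstrap_support(fx$alignment, replicates = 1, seed = 4)
  sup <- as.integer(tr3$node.label[tr3$node.label != ""])
  expect_true(all(sup %in% c(0L, 100L)))
})

test_that("is_monophyletic agrees with examples and the split oracle", {
  tr <- newick_read("((A:1,B:1):1,(C:1,D:1):1);")
  expect_true(is_monophyletic(tr, c("A", "B")))
  expect_false(is_monophyletic(tr, c("A", "C")))
  expect_error(is_monophyletic(tr, c("A", "Z")), "unknown taxa")
  expect_error(is_monophyletic(tr, tr$tip.label), "proper subset")

  skip_if_not_installed("phangorn")
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(5:20, 1)
    tree <- ape::unroot(ape::rtree(n))
    taxa <- sample(tree$tip.label, sample(2:(n - 2), 1))
    expect_identical(is_monophyletic(tree, taxa),
                     oracle_monophyletic(tree, taxa))
  }
})

test_that("fitch_changes matches exhaustive minima and the monophyly link", {
  tr <- newick_read("((A:1,B:1):1,(C:1,D:1):1);")
  expect_identical(fitch_changes(tr, c(A = "in", B = "in",
                                       C = "out", D = "out")), 1L)

  # 6-leaf caterpillar with alternating labels needs 3 changes
  cat6 <- newick_read("(((((t1:1,t2:1):1,t3:1):1,t4:1):1,t5:1):1,t6:1);")
  lab <- setNames(rep(c("in", "out"), 3), paste0("t", 1:6))
  expect_identical(fitch_changes(ape::unroot(cat6), lab), 3L)
  expect_identical(oracle_fitch(ape::unroot(cat6), lab), 3L)

  expect_error(fitch_changes(tr, c(A = "in", B = "in", C = "out")),
               "unlabeled leaf")
  expect_identical(fitch_changes(tr, c(A = "in", B = "in",
                                       C = "in", D = "in")), 0L)
})

test_that("fitch equals the brute-force minimum and iff-1 monophyly (n <= 10)", {
  set.seed(47)
  for (rep in 1:20) {
    n <- sample(4:10, 1)
    tree <- ape::unroot(ape::rtree(n))
    k <- sample(1:(n - 1), 1)
    ingroup <- sample(tree$tip.label, k)
    labels <- setNames(ifelse(tree$tip.label %in% ingroup, "in", "out"),
                       tree$tip.label)
    fc <- fitch_changes(tree, labels)
    expect_identical(fc, oracle_fitch(tree, labels))
    expect_identical(fc == 1L, is_monophyletic(tree, ingroup))
  }
})

test_that("the interspersion fixture behaves like the LGT scenario", {
  fx <- make_interspersion_fixture()
  expect_false(is_monophyletic(fx$tree, fx$ingroup))
  expect_identical(fitch_changes(fx$tree, fx$labels), 3L)
  expect_identical(oracle_fitch(fx$tree, fx$labels), 3L)
})
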