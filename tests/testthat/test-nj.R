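test_that("three taxa give the closed-form star solution", {
  d <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  t <- nj_build(d)
  expect_equal(length(t$tip.label), 3L)
  expect_equal(nrow(t$edge), 3L)            # 2n - 3
  len <- setNames(t$edge.length, t$tip.label[t$edge[, 2]])
  expect_equal(len[c("A", "B", "C")], c(A = 0.5, B = 1.5, C = 2.5))
})

test_that("a four-taxon additive matrix is recovered exactly", {
  tru <- ape::read.tree(text = "((A:1,B:2):1,(C:3,D:4):0);")
  ids <- c("A", "B", "C", "D")
  d <- cophenetic(tru)[ids, ids]
  expect_equal(d["A", "B"], 3)              # the intended matrix
  expect_equal(d["A", "C"], 5)
  expect_equal(d["B", "D"], 7)
  t <- nj_build(d)
  expect_equal(robinson_foulds(t, ape::unroot(tru)), 0)   # split AB|CD
  expect_equal(max(abs(cophenetic(t)[ids, ids] - d)), 0, tolerance = 1e-12)
})

test_that("equidistant taxa resolve deterministically by the tie-break", {
  ids <- c("A", "B", "C", "D")
  d <- matrix(1, 4, 4, dimnames = list(ids, ids))
  diag(d) <- 0
  t1 <- nj_build(d)
  t2 <- nj_build(d)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(nrow(t1$edge), 5L)
  # first Q minimum in row-major order joins A and B
  expect_equal(robinson_foulds(
    t1, ape::read.tree(text = "((A:1,B:1),C:1,D:1);")), 0)
})

test_that("NJ is consistent on additive matrices and agrees with ape", {
  for (s in 1:30) {
    n <- 4 + (s %% 7)
    tru <- random_additive_case(n, s)
    ids <- tru$tip.label
    d <- cophenetic(tru)[ids, ids]
    t <- nj_build(d)
    expect_equal(nrow(t$edge), 2 * n - 3)
    expect_equal(robinson_foulds(t, tru), 0)
    expect_lt(max(abs(cophenetic(t)[ids, ids] - d)), 1e-9)
    # independent implementation cross-check
    expect_equal(robinson_foulds(t, ape::nj(as.dist(d))), 0)
  }
})

test_that("degenerate or invalid matrices are rejected", {
  d2 <- matrix(c(0, 1, 1, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_build(d2), "at least 3")
  d3 <- matrix(c(0, 1, 2, 3, 0, 1, 2, 1, 0), 3,
               dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  expect_error(nj_build(d3), "symmetric")
})

test_that("Robinson-Foulds matches an independent implementation", {
  q1 <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  q2 <- ape::read.tree(text = "((A:1,C:1):1,(B:1,D:1):1);")
  expect_equal(robinson_foulds(q1, q1), 0)
  expect_equal(robinson_foulds(q1, q2), 2)
  expect_equal(robinson_foulds(q2, q1), 2)
  for (s in 1:10) {
    t1 <- random_additive_case(8, s)
    t2 <- random_additive_case(8, s + 100)
    t2$tip.label <- t1$tip.label
    expect_equal(robinson_foulds(t1, t2),
                 as.integer(phangorn::RF.dist(t1, t2)))
  }
  t3 <- random_additive_case(5, 1)
  t4 <- random_additive_case(6, 2)
  expect_error(robinson_foulds(t3, t4), "leaf set")
})

test_that("midpoint rooting halves the diameter and preserves paths", {
  t2 <- ape::read.tree(text = "(A:1,B:3);")
  r2 <- midpoint_root(t2)
  expect_equal(sort(r2$edge.length), c(2, 2))

  # one long terminal branch: the root must sit on it
  cat5 <- ape::read.tree(text = "((((A:0.1,B:0.1):0.1,C:0.1):0.1,D:0.1):0.1,Z:10);")
  r <- midpoint_root(ape::unroot(cat5))
  root <- length(r$tip.label) + 1L
  kids <- r$edge[r$edge[, 1] == root, 2]
  expect_true(match("Z", r$tip.label) %in% kids)
  # diameter found by brute force over all leaf pairs
  ids <- cat5$tip.label
  dm <- cophenetic(cat5)[ids, ids]
  depth <- cophenetic(r)[ids, ids]
  expect_equal(max(dm), max(depth))

  for (s in 1:5) {
    t <- random_additive_case(7, s + 50)
    r <- midpoint_root(t)
    expect_true(ape::is.rooted(r))
    expect_equal(cophenetic(r)[t$tip.label, t$tip.label],
                 cophenetic(t)[t$tip.label, t$tip.label],
                 tolerance = 1e-12)
  }
})

test_that("zero-length trees root deterministically with a note", {
  t <- ape::read.tree(text = "(B:0,A:0,C:0);")
  t$edge.length <- rep(0, length(t$edge.length))
  expect_message(r <- midpoint_root(t), "leaf 'A'")
  expect_true(ape::is.rooted(r))
})

test_that("Newick round-trips preserve topology, lengths and supports", {
  f <- tempfile(fileext = ".nwk")
  writeLines("(A:1,B:2);", f)
  t <- read_newick(f)
  f2 <- tempfile(fileext = ".nwk")
  write_newick(t, f2)
  expect_identical(readLines(f2), "(A:1,B:2);")

  writeLines("((A:1,B:2)87:1,C:3);", f)
  t2 <- read_newick(f)
  expect_true("87" %in% t2$node.label)
  write_newick(t2, f2)
  expect_identical(readLines(f2), "((A:1,B:2)87:1,C:3);")

  writeLines("((A:1,B:2;", f)
  expect_error(read_newick(f), "unclosed")
  writeLines("(A:1,B:2));", f)
  expect_error(read_newick(f), "character 10")
})

test_that("bootstrap supports are percentages attached to the point tree", {
  a <- two_group_alignment()
  t1 <- bootstrap_supports(a, replicates = 1, seed = 5)
  s1 <- attr(t1, "supports")
  expect_true(all(s1 %in% c(0, 100)))

  t50 <- bootstrap_supports(a, replicates = 50, seed = 5)
  t50b <- bootstrap_supports(a, replicates = 50, seed = 5)
  expect_identical(t50$node.label, t50b$node.label)
  s <- attr(t50, "supports")
  expect_true(all(s >= 0 & s <= 100))
  # display filter blanks sub-threshold labels only
  filt <- filter_supports(t50, 50)
  v <- suppressWarnings(as.numeric(filt$node.label))
  expect_true(all(is.na(v) | v >= 50))
})
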