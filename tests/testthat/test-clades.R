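test_that("reference-anchored assignment recovers generating labels", {
  ts <- make_clade_testset(5, 0.5, 0.1, seed = 2)
  tr <- nj_build(distance_matrix(ts$alignment))
  asg <- assign_clades(midpoint_root(tr), ts$refs)
  expect_true(all(asg$method == "monophyly"))
  got <- asg$clade[match(ts$truth$leaf, asg$leaf)]
  expect_equal(got, ts$truth$clade)
  # reference leaves keep their catalog clade
  ref_rows <- asg[match(ts$refs$name, asg$leaf), ]
  expect_equal(ref_rows$clade, ts$refs$clade)
  # census matches generator composition
  expect_equal(clade_census(asg),
               c(A = 5L, B = 5L, C = 5L, D = 5L, unassigned = 0L))
})

test_that("a leaf branching outside all reference subtrees is unassigned", {
  txt <- paste0("(((((A1:.1,A2:.1):1,(B1:.1,B2:.1):1):.5,",
                "(C1:.1,C2:.1):1):.5,(D1:.1,D2:.1):1):.5,Q:3);")
  t <- ape::read.tree(text = txt)
  refs <- mini_catalog(c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
                       rep(c("A", "B", "C", "D"), each = 2))
  asg <- assign_clades(t, refs)
  expect_equal(asg$clade[asg$leaf == "Q"], "unassigned")
  expect_equal(asg$clade[asg$leaf == "A2"], "A")
  expect_true(all(asg$method == "monophyly"))
})

test_that("deeply diverged members of one reference group share its clade", {
  # stand-ins for the two most divergent characterized UndPP-GlcNAc
  # epimerases, placed in the D reference group at p-distance 0.5
  txt <- paste0("(((A1:.1,A2:.1):1,(B1:.1,B2:.1):1):.5,",
                "((D1:.05,EcO157:.15):.1,(D2:.05,YptbO10:.15):.1):.5,",
                "(C1:.1,C2:.1):1.5);")
  t <- midpoint_root(ape::read.tree(text = txt))
  refs <- mini_catalog(c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
                       rep(c("A", "B", "C", "D"), each = 2))
  asg <- assign_clades(t, refs)
  expect_equal(asg$clade[asg$leaf == "EcO157"], "D")
  expect_equal(asg$clade[asg$leaf == "YptbO10"], "D")
  expect_equal(cophenetic(ape::read.tree(text = txt))["EcO157", "YptbO10"],
               0.5)
})

test_that("non-monophyletic references fall back to nearest reference", {
  # A references straddle the B pair, so no disjoint MRCA subtrees exist
  txt <- "((A1:.1,(B1:.1,B2:.1):.3):.2,A2:.1,((C1:.1,C2:.1):.5,(D1:.1,D2:.1):.5):.4);"
  t <- midpoint_root(ape::read.tree(text = txt))
  refs <- mini_catalog(c("A1", "A2", "B1", "B2", "C1", "C2", "D1", "D2"),
                       rep(c("A", "B", "C", "D"), each = 2))
  asg <- assign_clades(t, refs)
  expect_true(all(asg$method == "nearest-reference"))
  # references remain self-consistent at distance zero
  ref_rows <- asg[match(refs$name, asg$leaf), ]
  expect_equal(ref_rows$clade, refs$clade)
  expect_true(all(ref_rows$value == 0))
})

test_that("missing reference leaves are reported by name", {
  ts <- make_clade_testset(3, 0.5, 0.1, seed = 4)
  tr <- midpoint_root(nj_build(distance_matrix(ts$alignment)))
  refs <- ts$refs
  refs$name[1] <- "NOT_IN_TREE"
  expect_error(assign_clades(tr, refs), "NOT_IN_TREE")
})

test_that("nearest reference uses patristic distance with catalog-order ties", {
  refs <- mini_catalog(c("R1", "R2", "R3", "R4"), c("A", "B", "C", "D"))
  t <- ape::read.tree(
    text = "(((R1:1,R2:1):1,(X:1,R3:3):1):1,R4:9);")
  pat <- cophenetic(t)
  # a reference is its own nearest reference at distance 0
  self <- nearest_reference(t, "R1", refs)
  expect_equal(self$clade, "A")
  expect_equal(self$distance, 0)
  # X is equidistant from the A and B references: earlier catalog entry wins
  expect_equal(pat["X", "R1"], pat["X", "R2"])
  x <- nearest_reference(t, "X", refs)
  expect_equal(x$clade, "A")
  expect_equal(x$distance, pat["X", "R1"])
  # max_dist caps assignment
  far <- nearest_reference(t, "X", refs, max_dist = 0.5)
  expect_equal(far$clade, "unassigned")
})

test_that("patristic distances equal brute-force path sums", {
  for (s in 1:5) {
    t <- random_additive_case(7, s + 200)
    pat <- cophenetic(t)
    pairs <- combn(t$tip.label, 2)
    for (k in seq_len(ncol(pairs))) {
      expect_equal(pat[pairs[1, k], pairs[2, k]],
                   patristic_bf(t, pairs[1, k], pairs[2, k]),
                   tolerance = 1e-12)
    }
  }
})

test_that("clade census counts all labels and sums to the leaf count", {
  asg <- data.frame(
    leaf = sprintf("L%d", 1:10),
    clade = c(rep("A", 4), rep("B", 3), rep("D", 2), "unassigned"),
    method = "monophyly", value = NA_real_)
  cen <- clade_census(asg)
  expect_equal(cen, c(A = 4L, B = 3L, C = 0L, D = 2L, unassigned = 1L))
  expect_equal(sum(cen), nrow(asg))
})

test_that("the shipped reference catalog anchors all four clades", {
  path <- system.file("extdata", "reference_catalog.tsv",
                      package = "epiclades")
  cat <- read_reference_catalog(path)
  expect_setequal(unique(cat$clade), c("A", "B", "C", "D"))
  funs <- cat$`function`[cat$clade == "A"]
  expect_true(any(grepl("UDP-GlcNAc", funs)))   # a gne exemplar
  expect_true(any(grepl("UDP-Glc ", funs)))     # a galE exemplar
})
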