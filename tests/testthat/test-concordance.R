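test_that("per-record verdicts follow the expectation contract", {
  # group 1: both genes required and both present
  v <- assess_record(ounit_structure(1, 1, 0, 0), TRUE, TRUE)
  expect_equal(v[c("gnu", "gne")], list(gnu = "match", gne = "match"))
  # O157-like: gnu required and present, gne not required and absent
  v <- assess_record(ounit_structure(1, 0, 0, 0), TRUE, FALSE)
  expect_equal(v[c("gnu", "gne")], list(gnu = "match", gne = "match"))
  # GalNAc-free structure carrying an unpredicted gne
  v <- assess_record(ounit_structure(0, 0, 1, 0), FALSE, TRUE)
  expect_equal(v$gne, "present_when_not_predicted")
  expect_equal(v$gnu, "match")
  # required gene absent
  v <- assess_record(ounit_structure(1, 0, 0, 0), FALSE, FALSE)
  expect_equal(v$gnu, "missing_when_expected")
})

test_that("coupled conditional pairs count one event, never two", {
  s2 <- ounit_structure(1, 0, 1, 0)   # either gnu or gne needed
  both_verdicts <- function(v) unlist(v[c("gnu", "gne")], use.names = FALSE)
  # exactly one gene present satisfies the pair either way round
  expect_equal(both_verdicts(assess_record(s2, TRUE, FALSE)),
               c("match", "match"))
  expect_equal(both_verdicts(assess_record(s2, FALSE, TRUE)),
               c("match", "match"))
  # neither present: one missing event, attributed to gnu by default
  v <- assess_record(s2, FALSE, FALSE)
  expect_equal(both_verdicts(v), c("missing_when_expected", "match"))
  v <- assess_record(s2, FALSE, FALSE, attribute_to = "gne")
  expect_equal(both_verdicts(v), c("match", "missing_when_expected"))
  # both present: requirement met plus one surplus event
  v <- assess_record(s2, TRUE, TRUE)
  expect_equal(both_verdicts(v), c("present_when_not_predicted", "match"))
})

test_that("an uncoupled conditional gene matches either observed state", {
  s3 <- ounit_structure(1, 1, 1, 0)   # gne always needed, gnu conditional
  e <- expected_genes(s3)
  expect_equal(e$gnu, "CONDITIONAL")
  expect_equal(e$gne, "REQUIRED")
  expect_false(e$coupled)
  expect_equal(assess_record(s3, TRUE, TRUE)$gnu, "match")
  expect_equal(assess_record(s3, FALSE, TRUE)$gnu, "match")
  expect_equal(assess_record(s3, FALSE, FALSE)$gne, "missing_when_expected")
})

test_that("a fully concordant table reports no discordances", {
  g <- generate_serogroup_table(n = 20, inject_missing = 0,
                                inject_surplus = 0, seed = 9)
  r <- concordance_report(g$table)
  expect_equal(r$n, 20L)
  expect_equal(r$gnu_matches, 20L)
  expect_equal(r$gne_matches, 20L)
  expect_equal(r$missing_when_expected, 0L)
  expect_equal(r$present_when_not_predicted, 0L)
})

test_that("injected discordances are recovered exactly", {
  g <- generate_serogroup_table(n = 115, inject_missing = 7,
                                inject_surplus = 10, seed = 5)
  r <- concordance_report(g$table)
  expect_equal(r$missing_when_expected, 7L)
  expect_equal(r$present_when_not_predicted, 10L)
  expect_equal(r$gnu_matches + sum(r$per_record$gnu_verdict != "match"),
               r$n)
  expect_equal(r$gne_matches + sum(r$per_record$gne_verdict != "match"),
               r$n)
  # ledger rows name exactly the discordant serogroup-gene slots
  per <- r$per_record
  discordant <- c(per$serogroup[per$gnu_verdict != "match"],
                  per$serogroup[per$gne_verdict != "match"])
  expect_setequal(g$ledger$serogroup, discordant)
})

test_that("aggregates reconcile with per-record verdicts and record order", {
  g <- generate_serogroup_table(n = 40, inject_missing = 3,
                                inject_surplus = 4, seed = 17)
  r <- concordance_report(g$table)
  verdicts <- c(r$per_record$gnu_verdict, r$per_record$gne_verdict)
  expect_equal(sum(verdicts == "match"), r$gnu_matches + r$gne_matches)
  expect_equal(sum(verdicts == "missing_when_expected"),
               r$missing_when_expected)
  expect_equal(sum(verdicts == "present_when_not_predicted"),
               r$present_when_not_predicted)
  # permutation invariance of the aggregates
  shuf <- g$table[withr::with_seed(1, sample(nrow(g$table))), ]
  r2 <- concordance_report(shuf)
  expect_equal(r2[c("n", "gnu_matches", "gne_matches",
                    "missing_when_expected",
                    "present_when_not_predicted")],
               r[c("n", "gnu_matches", "gne_matches",
                   "missing_when_expected",
                   "present_when_not_predicted")])
})

test_that("duplicate serogroup labels are rejected", {
  g <- generate_serogroup_table(n = 5, seed = 1)
  tbl <- g$table
  tbl$serogroup[2] <- tbl$serogroup[1]
  expect_error(concordance_report(tbl), "duplicate serogroup")
})

test_that("odds ratio is the cross-product with optional Haldane correction", {
  # the printed PCR screen: 14/22 GalNAc-positive, 4/40 GalNAc-negative
  expect_equal(odds_ratio(c(14, 8, 4, 36)), 15.75)
  expect_equal(odds_ratio(c(14, 8, 4, 36)), (14 * 36) / (8 * 4))
  expect_equal(odds_ratio(c(1, 1, 1, 1)), 1)
  expect_error(odds_ratio(c(5, 0, 2, 10)), "haldane")
  h <- odds_ratio(c(5, 0, 2, 10), correction = "haldane")
  expect_true(is.finite(h) && h > 1)
  # invariance under transposition
  for (s in 1:5) {
    t <- withr::with_seed(s, sample(1:20, 4, replace = TRUE))
    expect_equal(odds_ratio(t), odds_ratio(t[c(1, 3, 2, 4)]))
  }
})

test_that("Fisher exact p equals exhaustive hypergeometric enumeration", {
  expect_equal(fisher_exact(c(1, 1, 1, 1)), 1)
  for (s in 1:20) {
    t <- withr::with_seed(s, sample(0:8, 4, replace = TRUE))
    if (sum(t) == 0) next
    expect_equal(fisher_exact(t), fisher_enum(t[1], t[2], t[3], t[4]),
                 tolerance = 1e-10)
  }
  # the printed screen supports the GalNAc association
  expect_lt(fisher_exact(c(14, 8, 4, 36)), 0.05)
})
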