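#' Assess one serogroup's observed genes against expectation
#'
#' Per-gene verdicts comparing expected (from structure, via
#' [expected_genes()]) and observed gnu/gne presence. For non-conditional
#' genes: REQUIRED+present and NOT_REQUIRED+absent are `match`,
#' REQUIRED+absent is `missing_when_expected`, NOT_REQUIRED+present is
#' `present_when_not_predicted`. For a coupled CONDITIONAL pair (exactly
#' one gene needed): one gene present means both match; neither present
#' counts one missing event; both present counts the requirement as
#' satisfied plus one surplus event. Missing and surplus events of a
#' coupled pair are attributed to `gnu` by convention (configurable). An
#' uncoupled CONDITIONAL gene (its partner REQUIRED) matches either
#' observed state, since its requirement is not decidable from structure
#' alone.
#'
#' @param s An [ounit_structure()].
#' @param gnu_observed,gne_observed Observed gene presence flags.
#' @param attribute_to Gene carrying a coupled pair's single
#'   missing/surplus event (`"gnu"` default, or `"gne"`).
#' @return List with `gnu` and `gne` verdicts (each `"match"`,
#'   `"missing_when_expected"` or `"present_when_not_predicted"`) plus
#'   the `expectation`.
#' @export
assess_record <- function(s, gnu_observed, gne_observed,
                          attribute_to = c("gnu", "gne")) {
  attribute_to <- match.arg(attribute_to)
  exp <- expected_genes(s)
  verdict_one <- function(status, present) {
    if (status == "REQUIRED") {
      if (present) "match" else "missing_when_expected"
    } else if (status == "NOT_REQUIRED") {
      if (present) "present_when_not_predicted" else "match"
    } else {
      "match"   # uncoupled CONDITIONAL: either state admissible
    }
  }
  if (exp$coupled) {
    npresent <- sum(gnu_observed, gne_observed)
    v <- c(gnu = "match", gne = "match")
    if (npresent == 0L) v[attribute_to] <- "missing_when_expected"
    if (npresent == 2L) v[attribute_to] <- "present_when_not_predicted"
    out <- list(gnu = unname(v["gnu"]), gne = unname(v["gne"]))
  } else {
    out <- list(gnu = verdict_one(exp$gnu, gnu_observed),
                gne = verdict_one(exp$gne, gne_observed))
  }
  out$expectation <- exp
  out
}

#' Genotype-structure concordance accounting over a serogroup table
#'
#' Aggregates [assess_record()] over every serogroup: how often the
#' gnu and gne genes are present or absent as expected from the O-unit
#' structure, how many genes are missing when expected, and how many are
#' present when not predicted.
#'
#' @param tbl Data frame with columns `serogroup`, `main_galnac`,
#'   `side_galnac`, `main_glcnac`, `side_glcnac`, `gnu_observed`,
#'   `gne_observed` (see [read_serogroup_table()]).
#' @inheritParams assess_record
#' @return A `concordance_report` list: `n`, `gnu_matches`,
#'   `gne_matches`, `missing_when_expected`,
#'   `present_when_not_predicted`, and `per_record` (data frame of
#'   per-serogroup verdicts, group labels and expectations).
#' @export
concordance_report <- function(tbl, attribute_to = c("gnu", "gne")) {
  attribute_to <- match.arg(attribute_to)
  tbl <- validate_serogroup_table(tbl)
  n <- nrow(tbl)
  rows <- vector("list", n)
  for (k in seq_len(n)) {
    s <- ounit_structure(tbl$main_galnac[k], tbl$side_galnac[k],
                         tbl$main_glcnac[k], tbl$side_glcnac[k])
    v <- assess_record(s, tbl$gnu_observed[k], tbl$gne_observed[k],
                       attribute_to)
    rows[[k]] <- data.frame(
      serogroup = tbl$serogroup[k],
      group = v$expectation$group,
      gnu_expected = v$expectation$gnu,
      gne_expected = v$expectation$gne,
      gnu_observed = tbl$gnu_observed[k],
      gne_observed = tbl$gne_observed[k],
      gnu_verdict = v$gnu,
      gne_verdict = v$gne,
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  verdicts <- c(per$gnu_verdict, per$gne_verdict)
  structure(list(
    n = n,
    gnu_matches = sum(per$gnu_verdict == "match"),
    gne_matches = sum(per$gne_verdict == "match"),
    missing_when_expected = sum(verdicts == "missing_when_expected"),
    present_when_not_predicted =
      sum(verdicts == "present_when_not_predicted"),
    per_record = per), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Concordance over", x$n, "serogroups\n")
  cat("  gnu as expected:", x$gnu_matches, "/", x$n, "\n")
  cat("  gne as expected:", x$gne_matches, "/", x$n, "\n")
  cat("  missing when expected:   ", x$missing_when_expected, "\n")
  cat("  present when not predicted:", x$present_when_not_predicted, "\n")
  invisible(x)
}

.as_2x2 <- function(t) {
  if (is.matrix(t)) t <- as.vector(t(t))
  if (length(t) != 4L || any(t < 0) || any(t != round(t)))
    stop("need four non-negative integer cell counts a, b, c, d")
  t
}

#' Odds ratio of a 2x2 table
#'
#' Cross-product ratio `(a d) / (b c)` of cells `(a, b, c, d)` read
#' row-wise (outcome+ / outcome- by exposure+ / exposure-). The Haldane
#' correction adds 0.5 to every cell first, allowing zero cells.
#'
#' @param t Vector `c(a, b, c, d)` or a 2x2 matrix (row-wise).
#' @param correction `"none"` (default) or `"haldane"`.
#' @return Positive odds ratio.
#' @export
odds_ratio <- function(t, correction = c("none", "haldane")) {
  correction <- match.arg(correction)
  t <- .as_2x2(t)
  if (correction == "haldane") t <- t + 0.5
  if (any(t == 0))
    stop("zero cell; use correction = \"haldane\"")
  (t[1] * t[4]) / (t[2] * t[3])
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Exact hypergeometric two-sided p-value (sum of the probabilities of
#' all tables with the observed margins that are no more probable than
#' the observed one).
#'
#' @inheritParams odds_ratio
#' @return p-value in `(0, 1]`.
#' @export
fisher_exact <- function(t) {
  t <- .as_2x2(t)
  stats::fisher.test(matrix(t, 2L, 2L, byrow = TRUE))$p.value
}
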