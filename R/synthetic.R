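#' Expected proportion of differing sites for a path length
#'
#' Closed form of the 20-state equal-rates substitution model: two
#' sequences separated by total branch length `b` (expected substitutions
#' per site) differ at a site with probability
#' `(19/20) (1 - exp(-20 b / 19))`, saturating at 0.95.
#'
#' @param b Branch length(s) `>= 0`.
#' @return Expected p-distance(s) in `[0, 0.95)`.
#' @export
brlen_to_pdist <- function(b) {
  stopifnot(all(b >= 0))
  (19 / 20) * (1 - exp(-20 * b / 19))
}

#' Branch length giving a target expected p-distance
#'
#' Inverse of [brlen_to_pdist()]; defined for `p < 0.95`.
#'
#' @param p Target expected proportion(s) of differing sites.
#' @return Branch length(s) in substitutions per site.
#' @export
pdist_to_brlen <- function(p) {
  stopifnot(all(p >= 0), all(p < 0.95))
  -(19 / 20) * log(1 - (20 / 19) * p)
}

#' Simulate a protein alignment along a tree
#'
#' Equal-rates 20-state substitution process: the root sequence is drawn
#' uniformly, each site evolves independently down the tree, and along a
#' branch of length `b` a site changes with probability
#' [brlen_to_pdist()]`(b)`, moving uniformly to one of the 19 other
#' residues. No indels are generated (gap-free output); the result is
#' fully determined by `seed`.
#'
#' @param tree `phylo` tree with branch lengths (substitutions per site).
#' @param length Number of alignment columns.
#' @param seed Integer seed.
#' @return An [aligned_proteins] object with one row per tree leaf.
#' @export
simulate_alignment <- function(tree, length, seed = 1) {
  stopifnot(inherits(tree, "phylo"), length >= 1)
  if (is.null(tree$edge.length)) stop("tree must have branch lengths")
  tr <- ape::reorder.phylo(tree, "cladewise")  # parents precede children
  ntip <- length(tr$tip.label)
  nnode <- ntip + tr$Nnode
  withr::with_seed(seed, {
    states <- matrix(NA_integer_, nnode, length)
    states[ntip + 1L, ] <- sample.int(20L, length, replace = TRUE)
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]
      ch <- tr$edge[e, 2L]
      p <- brlen_to_pdist(tr$edge.length[e])
      s <- states[par, ]
      hit <- runif(length) < p
      k <- sum(hit)
      if (k > 0L)
        s[hit] <- ((s[hit] - 1L + sample.int(19L, k, replace = TRUE)) %% 20L) + 1L
      states[ch, ] <- s
    }
    mat <- matrix(AA_LETTERS[states[seq_len(ntip), ]], ntip, length)
    rownames(mat) <- tr$tip.label
    aligned_proteins(mat)
  })
}

#' Synthetic four-clade protein family with reference stand-ins
#'
#' Emulates the study design of a reference-anchored clade
#' classification: four ancestral sequences at mutual expected divergence
#' `between_div` (on the p-distance scale), each radiating into
#' `n_per_clade` leaves at within-clade divergence `within_div`. The
#' default between-clade divergence of 0.5 mirrors the deepest observed
#' within-clade divergence of the real protein set (50% amino-acid
#' differences). Each clade splits basally into two sub-lineages and the
#' first leaf of each sub-lineage is flagged as a characterized-reference
#' stand-in, so the two references of a clade straddle the clade's root
#' and their most recent common ancestor subtends the whole clade.
#'
#' @param n_per_clade Leaves per clade (`>= 2`).
#' @param between_div Expected p-distance between ancestors
#'   (`> within_div`, `< 0.95`).
#' @param within_div Expected p-distance between leaves of the two
#'   sub-lineages of a clade.
#' @param seed Integer seed.
#' @param length Alignment columns (default 400).
#' @return List with `alignment` ([aligned_proteins]), `tree` (the true
#'   generating `phylo`), `truth` (data frame `leaf`, `clade`) and
#'   `refs` (a synthetic reference-catalog data frame).
#' @export
make_clade_testset <- function(n_per_clade = 5, between_div = 0.5,
                               within_div = 0.1, seed = 1, length = 400) {
  stopifnot(between_div > within_div, n_per_clade >= 2)
  t_anc <- pdist_to_brlen(between_div) / 2
  tw <- pdist_to_brlen(within_div)
  h1 <- tw / 4   # clade root -> sub-lineage ancestor
  h2 <- tw / 4   # sub-lineage ancestor -> tip
  clades <- c("A", "B", "C", "D")
  sub <- vapply(clades, function(cl) {
    tips <- sprintf("%s%d", cl, seq_len(n_per_clade))
    half <- split(tips, rep(1:2, length.out = length(tips)))
    lineage <- vapply(half, function(tt) {
      if (length(tt) == 1L)
        sprintf("%s:%.15g", tt, h1 + h2)
      else
        sprintf("(%s):%.15g",
                paste(sprintf("%s:%.15g", tt, h2), collapse = ","), h1)
    }, "")
    sprintf("(%s):%.15g", paste(lineage, collapse = ","), t_anc)
  }, "")
  tree <- ape::read.tree(text = paste0("(", paste(sub, collapse = ","), ");"))
  aln <- simulate_alignment(tree, length, seed)
  truth <- data.frame(
    leaf = aln$ids,
    clade = substr(aln$ids, 1L, 1L),
    stringsAsFactors = FALSE)
  refs <- data.frame(
    name = as.vector(rbind(sprintf("%s1", clades), sprintf("%s2", clades))),
    organism = "synthetic",
    clade = rep(clades, each = 2L),
    `function` = rep(c("gne/galE stand-in", "gnaB stand-in",
                       "unknown-function stand-in", "gnu stand-in"),
                     each = 2L),
    accession = NA_character_,
    check.names = FALSE,
    stringsAsFactors = FALSE)
  list(alignment = aln, tree = tree, truth = truth, refs = refs)
}

# structure templates per pattern group: (main_galnac, side_galnac,
# main_glcnac, side_glcnac)
GROUP_TEMPLATES <- list(
  `1` = list(c(1, 1, 0, 0), c(2, 0, 0, 0), c(1, 2, 0, 0)),
  `2` = list(c(1, 0, 1, 0), c(1, 0, 1, 1), c(1, 0, 2, 0)),
  `3` = list(c(1, 1, 1, 0), c(2, 0, 1, 0), c(1, 1, 2, 0)),
  `4` = list(c(0, 0, 1, 0), c(0, 0, 2, 0), c(0, 0, 1, 1)),
  `5` = list(c(1, 0, 0, 0), c(1, 0, 0, 1)),
  `6` = list(c(0, 1, 1, 0), c(0, 2, 1, 0), c(0, 1, 2, 0))
)

# default mix emulating the described composition of the 115-serogroup
# catalog: 101 of 115 in groups 3-6
DEFAULT_PATTERN_MIX <- c(`1` = 6, `2` = 8, `3` = 9, `4` = 52,
                         `5` = 25, `6` = 15) / 115

# largest-remainder apportionment of n among proportions
.apportion <- function(n, prop) {
  raw <- n * prop
  base <- floor(raw)
  left <- n - sum(base)
  if (left > 0) {
    extra <- order(raw - base, decreasing = TRUE)[seq_len(left)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Simulate a serogroup table with controlled discordances
#'
#' Draws O-unit structures according to `pattern_mix` over the six
#' structural groups, sets gnu/gne presence to the axiom-implied
#' expectation (coupled CONDITIONAL pairs resolved to exactly one gene by
#' a seeded fair coin; an uncoupled CONDITIONAL gene by a coin), then
#' injects exactly `inject_missing` missing-when-expected events (a
#' REQUIRED, present gene flipped absent) and `inject_surplus`
#' present-when-not-predicted events (a NOT_REQUIRED, absent gene flipped
#' present), each at a distinct (serogroup, gene) slot so the concordance
#' report recovers the injected counts exactly.
#'
#' @param n Number of serogroup records.
#' @param pattern_mix Proportions over groups 1-6 (default emulates the
#'   101-of-115-in-groups-3-6 composition).
#' @param inject_missing,inject_surplus Numbers of injected discordances.
#' @param seed Integer seed.
#' @return List with `table` (serogroup data frame) and `ledger` (data
#'   frame of injected events: `serogroup`, `gene`, `event`).
#' @export
generate_serogroup_table <- function(n = 115,
                                     pattern_mix = DEFAULT_PATTERN_MIX,
                                     inject_missing = 0,
                                     inject_surplus = 0,
                                     seed = 1) {
  stopifnot(n >= 1, inject_missing >= 0, inject_surplus >= 0)
  if (inject_missing + inject_surplus > n)
    stop("inject_missing + inject_surplus must not exceed n")
  if (length(pattern_mix) != 6L || any(pattern_mix < 0))
    stop("pattern_mix must give 6 non-negative proportions")
  if (abs(sum(pattern_mix) - 1) > 1e-6)
    stop("pattern_mix proportions must sum to 1")
  counts <- .apportion(n, pattern_mix)

  withr::with_seed(seed, {
    groups <- rep(1:6, counts)
    groups <- sample(groups)          # shuffle group order across records
    rows <- vector("list", n)
    for (k in seq_len(n)) {
      tpl <- GROUP_TEMPLATES[[groups[k]]]
      cnt <- tpl[[sample.int(length(tpl), 1L)]]
      s <- ounit_structure(cnt[1], cnt[2], cnt[3], cnt[4])
      exp <- expected_genes(s)
      presence <- function(status) switch(status,
        REQUIRED = TRUE, NOT_REQUIRED = FALSE,
        CONDITIONAL = NA)            # resolved below
      gnu <- presence(exp$gnu)
      gne <- presence(exp$gne)
      if (exp$coupled) {
        pick_gnu <- runif(1) < 0.5
        gnu <- pick_gnu
        gne <- !pick_gnu
      } else {
        if (is.na(gnu)) gnu <- runif(1) < 0.5
        if (is.na(gne)) gne <- runif(1) < 0.5
      }
      rows[[k]] <- data.frame(
        serogroup = sprintf("S%03d", k),
        main_galnac = cnt[1], side_galnac = cnt[2],
        main_glcnac = cnt[3], side_glcnac = cnt[4],
        gnu_observed = gnu, gne_observed = gne,
        gnu_status = exp$gnu, gne_status = exp$gne,
        stringsAsFactors = FALSE)
    }
    tbl <- do.call(rbind, rows)

    # injection slots: only unambiguous (REQUIRED / NOT_REQUIRED) genes
    # produce exactly one discordance per flip
    slots <- rbind(
      data.frame(row = seq_len(n), gene = "gnu",
                 status = tbl$gnu_status, present = tbl$gnu_observed,
                 stringsAsFactors = FALSE),
      data.frame(row = seq_len(n), gene = "gne",
                 status = tbl$gne_status, present = tbl$gne_observed,
                 stringsAsFactors = FALSE))
    miss_pool <- which(slots$status == "REQUIRED" & slots$present)
    surp_pool <- which(slots$status == "NOT_REQUIRED" & !slots$present)
    if (length(miss_pool) < inject_missing)
      stop("only ", length(miss_pool),
           " eligible slots for missing-gene injections")
    if (length(surp_pool) < inject_surplus)
      stop("only ", length(surp_pool),
           " eligible slots for surplus-gene injections")
    miss_sel <- if (inject_missing > 0)
      sample(miss_pool, inject_missing) else integer(0)
    surp_sel <- if (inject_surplus > 0)
      sample(surp_pool, inject_surplus) else integer(0)

    ledger <- data.frame(serogroup = character(0), gene = character(0),
                         event = character(0), stringsAsFactors = FALSE)
    flip <- function(sel, event) {
      for (idx in sel) {
        r <- slots$row[idx]
        g <- slots$gene[idx]
        col <- paste0(g, "_observed")
        tbl[r, col] <<- !tbl[r, col]
        ledger <<- rbind(ledger, data.frame(
          serogroup = tbl$serogroup[r], gene = g, event = event,
          stringsAsFactors = FALSE))
      }
    }
    flip(miss_sel, "missing")
    flip(surp_sel, "surplus")

    tbl$gnu_status <- NULL
    tbl$gne_status <- NULL
    list(table = tbl, ledger = ledger)
  })
}
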