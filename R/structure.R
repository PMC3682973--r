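#' O-antigen repeat-unit residue pattern
#'
#' Counts of main-chain and side-branch GalNAc and GlcNAc residues in one
#' O-unit structure. For Wzx/Wzy-pathway O units lacking an initial
#' transferase gene, synthesis starts from UndPP-GlcNAc made by WecA, so
#' the first sugar must be a main-chain GlcNAc or GalNAc residue.
#'
#' @param main_galnac,side_galnac,main_glcnac,side_glcnac Non-negative
#'   integer residue counts.
#' @return An `ounit_structure` list.
#' @export
ounit_structure <- function(main_galnac = 0, side_galnac = 0,
                            main_glcnac = 0, side_glcnac = 0) {
  counts <- c(main_galnac = main_galnac, side_galnac = side_galnac,
              main_glcnac = main_glcnac, side_glcnac = side_glcnac)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("residue counts must be non-negative integers")
  structure(as.list(counts), class = "ounit_structure")
}

# admissible first sugars: one main-chain GlcNAc or GalNAc residue
.first_choices <- function(s) {
  c(if (s$main_glcnac >= 1) "GlcNAc", if (s$main_galnac >= 1) "GalNAc")
}

# the two axioms: gnu is needed iff the first sugar is GalNAc (UndPP-level
# epimerisation); gne is needed iff any GalNAc residue is not the first
# sugar (UDP-GalNAc donor required)
.needs_given_first <- function(s, first) {
  total_galnac <- s$main_galnac + s$side_galnac
  list(gnu = first == "GalNAc",
       gne = (total_galnac - (first == "GalNAc")) > 0)
}

#' Structural pattern group of an O-unit
#'
#' Labels the GlcNAc/GalNAc pattern with one of six groups used in the
#' expectation accounting: 1 = GalNAc first plus further GalNAc, no
#' main-chain GlcNAc; 2 = single GalNAc with ambiguous first sugar
#' (main-chain GalNAc + GlcNAc, no other GalNAc); 3 = ambiguous first
#' sugar with additional GalNAc; 4 = no GalNAc at all; 5 = a single
#' main-chain GalNAc that must be first; 6 = main-chain GlcNAc with
#' side-branch GalNAc only. Group ids are labels; gene expectations are
#' always derived from the axioms in [expected_genes()].
#'
#' @param s An [ounit_structure()].
#' @return Integer group label 1-6.
#' @export
structure_group <- function(s) {
  stopifnot(inherits(s, "ounit_structure"))
  if (length(.first_choices(s)) == 0L)
    stop("no admissible first sugar: structure has no main-chain ",
         "GlcNAc or GalNAc residue")
  total_galnac <- s$main_galnac + s$side_galnac
  if (total_galnac == 0L) return(4L)
  if (s$main_galnac == 0L) return(6L)
  if (s$main_glcnac == 0L) {
    if (total_galnac == 1L) return(5L)
    return(1L)
  }
  if (total_galnac == 1L) return(2L)
  3L
}

#' Expected gnu/gne gene presence from O-unit structure
#'
#' Evaluates the first-sugar axioms over every admissible first-sugar
#' choice: a gene needed under every choice is `REQUIRED`, under no
#' choice `NOT_REQUIRED`, otherwise `CONDITIONAL`. When both genes are
#' CONDITIONAL they are coupled: exactly one of the pair is needed,
#' depending on which main-chain residue is the first sugar.
#'
#' @param s An [ounit_structure()] satisfying the main-chain invariant.
#' @return A `gene_expectation` list with elements `gnu`, `gne` (each
#'   `"REQUIRED"`, `"NOT_REQUIRED"` or `"CONDITIONAL"`), `group`,
#'   `coupled` and `note`.
#' @export
expected_genes <- function(s) {
  stopifnot(inherits(s, "ounit_structure"))
  choices <- .first_choices(s)
  if (length(choices) == 0L)
    stop("no admissible first sugar: structure has no main-chain ",
         "GlcNAc or GalNAc residue")
  needs <- lapply(choices, .needs_given_first, s = s)
  status <- function(gene) {
    v <- vapply(needs, `[[`, logical(1), gene)
    if (all(v)) "REQUIRED" else if (!any(v)) "NOT_REQUIRED" else "CONDITIONAL"
  }
  gnu <- status("gnu")
  gne <- status("gne")
  coupled <- gnu == "CONDITIONAL" && gne == "CONDITIONAL"
  note <- if (coupled) {
    "exactly one of gnu/gne needed, depending on the first sugar"
  } else if (gnu == "CONDITIONAL") {
    "gnu needed only if the single main-chain GalNAc is the first sugar"
  } else {
    ""
  }
  structure(list(gnu = gnu, gne = gne, group = structure_group(s),
                 coupled = coupled, note = note),
            class = "gene_expectation")
}

#' Predict the first sugar of an O-unit from structure and gene content
#'
#' Applies the prediction rules: absence of a `gnu` gene (in the cluster
#' or at the galF-linked locus) makes GlcNAc the very likely first sugar;
#' presence of `gnu` with an admissible GalNAc makes GalNAc the likely
#' first sugar (the converse rule, not absolute because the galF-linked
#' locus can segregate independently of the cluster); a structure with
#' only one admissible main-chain residue forces the choice. A `gnu`-free
#' cluster whose structure admits no GlcNAc first sugar is a conflict and
#' yields `ambiguous`.
#'
#' @param s An [ounit_structure()].
#' @param gnu_present Is a gnu gene present (cluster or galF-linked locus)?
#' @param gne_present Is a gne gene present in the cluster?
#' @return List with `sugar` (`"GlcNAc"`, `"GalNAc"` or `"ambiguous"`),
#'   `strength` (`"very-likely"`, `"likely"` or `"ambiguous"`) and
#'   `rationale`.
#' @export
predict_first_sugar <- function(s, gnu_present, gne_present = FALSE) {
  stopifnot(inherits(s, "ounit_structure"),
            is.logical(gnu_present), is.logical(gne_present))
  choices <- .first_choices(s)
  pred <- function(sugar, strength, rationale)
    list(sugar = sugar, strength = strength, rationale = rationale)

  if (length(choices) == 0L)
    return(pred("ambiguous", "ambiguous", "no-main-chain-hexnac"))

  if (!gnu_present) {
    if ("GlcNAc" %in% choices)
      return(pred("GlcNAc", "very-likely", "gnu-absent-rule"))
    # structure forces a GalNAc first sugar but the required gnu is absent
    return(pred("ambiguous", "ambiguous",
                "conflict: gnu absent but no main-chain GlcNAc"))
  }
  if ("GalNAc" %in% choices) {
    why <- "gnu-present-converse"
    if (gne_present)
      why <- paste0(why, "; gne present implies a non-first GalNAc")
    return(pred("GalNAc", "likely", why))
  }
  # gnu present but no admissible GalNAc: gnu unexplained by this structure
  pred("GlcNAc", "very-likely", "structure-forced; gnu not required")
}
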