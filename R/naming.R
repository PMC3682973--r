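#' Genomic context of a candidate 4-epimerase gene
#'
#' Context flags used by the annotation rules. All flags default to
#' absent/unknown, which yields the clade's default name.
#'
#' @param in_gal_operon Gene is adjacent to a `galK` or `galT` homolog
#'   (galactose-utilisation operon).
#' @param in_ops_cluster Gene lies within an O-antigen (OPS) gene cluster.
#' @param at_galF_locus Gene sits upstream of the OPS cluster at the
#'   galF-linked locus.
#' @param gnaA_adjacent Number of coding sequences between this gene and a
#'   `gnaA`/`wbpO` homolog, or `NA` if none was found.
#' @param galE_elsewhere A separate `galE` gene exists in the genome.
#' @return A `genomic_context` list.
#' @export
genomic_context <- function(in_gal_operon = FALSE, in_ops_cluster = FALSE,
                            at_galF_locus = FALSE, gnaA_adjacent = NA,
                            galE_elsewhere = FALSE) {
  for (f in list(in_gal_operon, in_ops_cluster, at_galF_locus,
                 galE_elsewhere))
    if (!is.logical(f) || length(f) != 1L || is.na(f))
      stop("context flags must be single TRUE/FALSE values")
  if (!is.na(gnaA_adjacent) &&
      (!is.numeric(gnaA_adjacent) || gnaA_adjacent < 0))
    stop("gnaA_adjacent must be NA or a non-negative integer")
  structure(list(in_gal_operon = in_gal_operon,
                 in_ops_cluster = in_ops_cluster,
                 at_galF_locus = at_galF_locus,
                 gnaA_adjacent = gnaA_adjacent,
                 galE_elsewhere = galE_elsewhere),
            class = "genomic_context")
}

#' Recommend a gene name from clade and genomic context
#'
#' Encodes the annotation recommendations: clade B genes are named `gnaB`
#' (the clade of UDP-GlcNAcA 4-epimerases, always partnered with a
#' gnaA/wbpO oxidase; confidence is strong when the partner lies within
#' `gnaA_threshold` coding sequences), clade D genes are named `gnu`
#' (UndPP-GlcNAc 4-epimerases), clade C has no known function, and clade A
#' genes default to `galE` unless OPS-cluster context indicates `gne`
#' (strong when a separate `galE` exists elsewhere in the genome).
#' Contradictory context (gal-operon and OPS-cluster flags both set)
#' warns and resolves by gal-operon precedence at weak confidence.
#'
#' @param clade One of `"A"`, `"B"`, `"C"`, `"D"`, `"unassigned"`.
#' @param ctx A [genomic_context()] object.
#' @param gnaA_threshold Maximum intervening coding sequences for a strong
#'   clade-B call (default 2, the most separated documented gene pair).
#' @return List with `name` (one of galE, gne, gnaB, gnu, unknown),
#'   `confidence` (strong/default/weak) and `rationale` (rule id).
#' @export
recommend_name <- function(clade, ctx = genomic_context(),
                           gnaA_threshold = 2) {
  if (!clade %in% ASSIGN_LEVELS)
    stop("clade must be one of ", paste(ASSIGN_LEVELS, collapse = ", "))
  stopifnot(inherits(ctx, "genomic_context"))
  rec <- function(name, confidence, rationale)
    list(name = name, confidence = confidence, rationale = rationale)

  switch(clade,
    B = {
      if (is.na(ctx$gnaA_adjacent)) {
        message("clade B gene with no gnaA/wbpO homolog recorded; ",
                "clade B epimerases are normally paired with one")
        rec("gnaB", "default", "cladeB-no-gnaA-context")
      } else if (ctx$gnaA_adjacent <= gnaA_threshold) {
        rec("gnaB", "strong", "cladeB-gnaA-adjacent")
      } else {
        rec("gnaB", "default", "cladeB-gnaA-distant")
      }
    },
    D = rec("gnu", "strong", "cladeD-gnu"),
    C = rec("unknown", "default", "cladeC-function-unknown"),
    A = {
      if (ctx$in_gal_operon && ctx$in_ops_cluster) {
        warning("contradictory context: gal-operon and OPS-cluster both ",
                "set; resolving by gal-operon precedence", call. = FALSE)
        rec("galE", "weak", "cladeA-contradictory-context")
      } else if (ctx$in_gal_operon) {
        rec("galE", "strong", "cladeA-gal-operon")
      } else if (ctx$in_ops_cluster) {
        if (ctx$galE_elsewhere)
          rec("gne", "strong", "cladeA-ops-cluster-galE-elsewhere")
        else
          rec("gne", "default", "cladeA-ops-cluster")
      } else {
        rec("galE", "default", "cladeA-default")
      }
    },
    unassigned = rec("unknown", "default", "unassigned")
  )
}

#' Apply naming rules across a table of clade assignments
#'
#' @param asg Assignment data frame from [assign_clades()].
#' @param contexts Optional data frame keyed by `leaf` with the
#'   [genomic_context()] fields as columns; leaves without a row get the
#'   default (all-absent) context.
#' @inheritParams recommend_name
#' @return `asg` with added columns `gene_name`, `confidence`,
#'   `rationale`.
#' @export
annotate_assignments <- function(asg, contexts = NULL, gnaA_threshold = 2) {
  ctx_for <- function(leaf) {
    if (is.null(contexts) || !leaf %in% contexts$leaf)
      return(genomic_context())
    row <- contexts[contexts$leaf == leaf, , drop = FALSE][1L, ]
    genomic_context(
      in_gal_operon = isTRUE(as.logical(row$in_gal_operon)),
      in_ops_cluster = isTRUE(as.logical(row$in_ops_cluster)),
      at_galF_locus = isTRUE(as.logical(row$at_galF_locus)),
      gnaA_adjacent = if ("gnaA_adjacent" %in% names(row))
        row$gnaA_adjacent else NA,
      galE_elsewhere = isTRUE(as.logical(row$galE_elsewhere)))
  }
  recs <- lapply(seq_len(nrow(asg)), function(k)
    recommend_name(asg$clade[k], ctx_for(asg$leaf[k]), gnaA_threshold))
  asg$gene_name <- vapply(recs, `[[`, "", "name")
  asg$confidence <- vapply(recs, `[[`, "", "confidence")
  asg$rationale <- vapply(recs, `[[`, "", "rationale")
  asg
}
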