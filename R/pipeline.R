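SEROGROUP_COLS <- c("serogroup", "main_galnac", "side_galnac",
                    "main_glcnac", "side_glcnac",
                    "gnu_observed", "gne_observed")

.as_flag <- function(x) {
  if (is.logical(x)) return(x)
  v <- tolower(as.character(x))
  out <- rep(NA, length(v))
  out[v %in% c("true", "t", "1", "yes", "y")] <- TRUE
  out[v %in% c("false", "f", "0", "no", "n")] <- FALSE
  out
}

#' Validate a serogroup table
#'
#' Checks column presence, unique serogroup labels, non-negative integer
#' residue counts, parseable presence flags, and the main-chain invariant
#' (every Wzx/Wzy O unit must carry at least one main-chain GlcNAc or
#' GalNAc). Errors name the offending row.
#'
#' @param tbl Data frame with the columns listed in
#'   [read_serogroup_table()].
#' @return The validated (type-normalized) data frame.
#' @export
validate_serogroup_table <- function(tbl) {
  if (nrow(tbl) < 1L) stop("serogroup table is empty")
  missing <- setdiff(SEROGROUP_COLS, names(tbl))
  if (length(missing))
    stop("serogroup table lacks column(s): ",
         paste(missing, collapse = ", "))
  if (anyDuplicated(tbl$serogroup))
    stop("duplicate serogroup label: ",
         tbl$serogroup[duplicated(tbl$serogroup)][1L])
  for (col in c("main_galnac", "side_galnac", "main_glcnac",
                "side_glcnac")) {
    v <- suppressWarnings(as.numeric(tbl[[col]]))
    bad <- which(is.na(v) | v < 0 | v != round(v))
    if (length(bad))
      stop("row ", bad[1L], ": column '", col,
           "' must be a non-negative integer")
    tbl[[col]] <- as.integer(v)
  }
  for (col in c("gnu_observed", "gne_observed")) {
    v <- .as_flag(tbl[[col]])
    bad <- which(is.na(v))
    if (length(bad))
      stop("row ", bad[1L], ": column '", col,
           "' must be TRUE/FALSE (or 1/0, yes/no)")
    tbl[[col]] <- v
  }
  bad <- which(tbl$main_galnac + tbl$main_glcnac < 1L)
  if (length(bad))
    stop("row ", bad[1L], " ('", tbl$serogroup[bad[1L]],
         "'): no main-chain GlcNAc or GalNAc residue")
  tbl
}

#' Read a serogroup structure/genotype table
#'
#' Tab-separated file with columns `serogroup`, `main_galnac`,
#' `side_galnac`, `main_glcnac`, `side_glcnac`, `gnu_observed`,
#' `gne_observed` (the layout of a structural-and-genetic serogroup
#' catalog). Lines starting with `#` are comments.
#'
#' @param path Path to the TSV file.
#' @return A validated data frame.
#' @export
read_serogroup_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tbl <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  validate_serogroup_table(tbl)
}

#' Write a serogroup table as TSV
#'
#' @param tbl Serogroup data frame.
#' @param path Output path.
#' @param header Optional comment line(s) written before the table.
#' @export
write_serogroup_table <- function(tbl, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(tbl, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Summary statistics of a serogroup catalog
#'
#' Row count, per-group membership, membership of groups 3-6 (the
#' structures whose gnu/gne needs are determined independently of the
#' first-sugar choice for at least one gene), and the concordance
#' aggregates.
#'
#' @param tbl Serogroup data frame.
#' @return List of counts plus the full [concordance_report()].
#' @export
serogroup_summary <- function(tbl) {
  rep <- concordance_report(tbl)
  gtab <- table(factor(rep$per_record$group, levels = 1:6))
  list(n_rows = rep$n,
       group_counts = setNames(as.integer(gtab), names(gtab)),
       groups_3_to_6 = sum(rep$per_record$group >= 3),
       gnu_matches = rep$gnu_matches,
       gne_matches = rep$gne_matches,
       missing_when_expected = rep$missing_when_expected,
       present_when_not_predicted = rep$present_when_not_predicted,
       report = rep)
}

# small deterministic polynomial hash for config provenance lines
config_hash <- function(cfg) {
  txt <- paste(deparse(cfg), collapse = "")
  h <- 0
  for (b in utf8ToInt(txt)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

.write_tsv_with_header <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config_hash=", hash), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the phylogenetic pipeline end to end
#'
#' Alignment to distances to neighbour-joining tree with bootstrap
#' supports, midpoint rooting, reference-anchored clade assignment and
#' gene-name recommendation. Identical inputs, config and seed give
#' identical outputs.
#'
#' @param alignment Path to an aligned FASTA file or an
#'   [aligned_proteins] object.
#' @param refs Path to a reference-catalog TSV or a data frame.
#' @param out_dir Output directory (created if needed).
#' @param contexts Optional genomic-context data frame (see
#'   [annotate_assignments()]).
#' @inheritParams bootstrap_supports
#' @param support_threshold Display threshold for supports in the written
#'   tree (default 50).
#' @param max_dist Optional nearest-reference distance cap.
#' @return Invisible list with `tree`, `assignments`, `annotations` and
#'   the written file paths.
#' @export
run_phylo_pipeline <- function(alignment, refs, out_dir,
                               model = "pdist",
                               gap_policy = "pairwise-deletion",
                               replicates = 1000, seed = 1,
                               support_threshold = 50,
                               max_dist = NULL, contexts = NULL) {
  cfg <- list(model = model, gap_policy = gap_policy,
              replicates = replicates, seed = seed,
              support_threshold = support_threshold,
              max_dist = max_dist)
  hash <- config_hash(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_con <- file(log_path, "w")
  on.exit(close(log_con))
  logline <- function(...) {
    msg <- paste0(...)
    writeLines(msg, log_con)
    message(msg)
  }
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    logline(sprintf("stage %-12s %6.2fs", name,
                    proc.time()[["elapsed"]] - t0))
    out
  }

  logline("epiclades phylo pipeline, config_hash=", hash)
  logline("R ", as.character(getRversion()), "; seed=", seed,
          "; model=", model, "; gaps=", gap_policy,
          "; replicates=", replicates)

  a <- stage("read", {
    if (inherits(alignment, "aligned_proteins")) alignment
    else read_aligned_fasta(alignment)
  })
  logline("alignment: ", length(a$ids), " sequences x ", a$length,
          " columns")
  catalog <- stage("catalog", {
    if (is.data.frame(refs)) validate_reference_catalog(refs)
    else read_reference_catalog(refs)
  })
  tree <- stage("tree", withr::with_preserve_seed(
    bootstrap_supports(a, replicates = replicates, seed = seed,
                       model = model, gap_policy = gap_policy)))
  rooted <- stage("root", midpoint_root(tree))
  attr(rooted, "supports") <- attr(tree, "supports")
  asg <- stage("assign", assign_clades(rooted, catalog,
                                       max_dist = max_dist))
  ann <- stage("annotate", annotate_assignments(asg, contexts))
  logline("clade census: ",
          paste(names(clade_census(asg)), clade_census(asg),
                sep = "=", collapse = " "))

  tree_path <- file.path(out_dir, "tree.nwk")
  write_newick(filter_supports(tree, support_threshold), tree_path)
  asg_path <- file.path(out_dir, "assignments.tsv")
  .write_tsv_with_header(asg, asg_path, hash)
  ann_path <- file.path(out_dir, "annotations.tsv")
  .write_tsv_with_header(ann, ann_path, hash)
  logline("wrote ", tree_path, ", ", asg_path, ", ", ann_path)

  invisible(list(tree = tree, rooted = rooted, assignments = asg,
                 annotations = ann,
                 files = c(tree = tree_path, assignments = asg_path,
                           annotations = ann_path, log = log_path)))
}

#' Run the structure-to-concordance pipeline
#'
#' Serogroup table to per-record gene expectations and first-sugar
#' predictions, plus the aggregate concordance report (JSON) and
#' per-record verdicts (TSV).
#'
#' @param table Path to a serogroup TSV or a data frame.
#' @param out_dir Output directory.
#' @inheritParams assess_record
#' @return Invisible list with `expectations`, `report` and file paths.
#' @export
run_structure_pipeline <- function(table, out_dir,
                                   attribute_to = c("gnu", "gne")) {
  attribute_to <- match.arg(attribute_to)
  tbl <- if (is.data.frame(table)) validate_serogroup_table(table)
         else read_serogroup_table(table)
  cfg <- list(attribute_to = attribute_to, n = nrow(tbl))
  hash <- config_hash(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  expectations <- do.call(rbind, lapply(seq_len(nrow(tbl)), function(k) {
    s <- ounit_structure(tbl$main_galnac[k], tbl$side_galnac[k],
                         tbl$main_glcnac[k], tbl$side_glcnac[k])
    e <- expected_genes(s)
    fs <- predict_first_sugar(s, tbl$gnu_observed[k], tbl$gne_observed[k])
    data.frame(serogroup = tbl$serogroup[k], group = e$group,
               gnu_expected = e$gnu, gne_expected = e$gne,
               first_sugar = fs$sugar, first_sugar_strength = fs$strength,
               stringsAsFactors = FALSE)
  }))
  report <- concordance_report(tbl, attribute_to)

  exp_path <- file.path(out_dir, "expectations.tsv")
  .write_tsv_with_header(expectations, exp_path, hash)
  per_path <- file.path(out_dir, "concordance_per_record.tsv")
  .write_tsv_with_header(report$per_record, per_path, hash)
  json_path <- file.path(out_dir, "concordance.json")
  jsonlite::write_json(
    list(config_hash = hash, n = report$n,
         gnu_matches = report$gnu_matches,
         gne_matches = report$gne_matches,
         missing_when_expected = report$missing_when_expected,
         present_when_not_predicted = report$present_when_not_predicted),
    json_path, auto_unbox = TRUE, pretty = TRUE)

  invisible(list(expectations = expectations, report = report,
                 files = c(expectations = exp_path,
                           per_record = per_path, json = json_path)))
}
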