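CLADE_LEVELS <- c("A", "B", "C", "D")
ASSIGN_LEVELS <- c(CLADE_LEVELS, "unassigned")

#' Read a reference catalog of characterized epimerases
#'
#' Tab-separated file with columns `name`, `organism`, `clade`,
#' `function`, `accession`. Names must be unique; clade labels must be in
#' A-D and every clade must have at least one entry.
#'
#' @param path Path to the TSV file.
#' @return A data frame, one row per characterized reference protein.
#' @export
read_reference_catalog <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   comment.char = "#")
  validate_reference_catalog(df)
}

#' Validate a reference catalog data frame
#'
#' @param df Data frame with at least columns `name` and `clade`.
#' @return The validated data frame (invisibly the same object).
#' @export
validate_reference_catalog <- function(df) {
  for (col in c("name", "clade"))
    if (!col %in% names(df)) stop("reference catalog lacks column '", col, "'")
  if (anyDuplicated(df$name))
    stop("duplicate reference name: ", df$name[duplicated(df$name)][1L])
  bad <- setdiff(unique(df$clade), CLADE_LEVELS)
  if (length(bad))
    stop("invalid clade label(s): ", paste(bad, collapse = ", "))
  missing <- setdiff(CLADE_LEVELS, unique(df$clade))
  if (length(missing))
    stop("reference catalog has no entry for clade(s): ",
         paste(missing, collapse = ", "))
  df
}

# tip label sets spanned by each clade's references (MRCA subtree)
.clade_tipsets <- function(t, refs) {
  out <- list()
  for (cl in CLADE_LEVELS) {
    rn <- refs$name[refs$clade == cl]
    if (length(rn) == 1L) {
      out[[cl]] <- rn
    } else {
      mrca <- ape::getMRCA(t, rn)
      tips <- phangorn::Descendants(t, mrca, type = "tips")[[1]]
      out[[cl]] <- t$tip.label[tips]
    }
  }
  out
}

#' Assign clades A-D to tree leaves using reference anchors
#'
#' For each clade the most recent common ancestor of its reference leaves
#' is found on the rooted tree. If the four reference subtrees are
#' mutually disjoint, every leaf inside exactly one subtree receives that
#' clade (method `"monophyly"`) and leaves outside all four are
#' `"unassigned"`; if the subtrees overlap (references non-monophyletic)
#' every leaf falls back to nearest-reference assignment by patristic
#' distance (method `"nearest-reference"`). The supporting value is the
#' MRCA node's bootstrap support (if present) for monophyly calls, or the
#' patristic distance for nearest-reference calls, so boundary
#' assignments can be audited.
#'
#' @param t Rooted `phylo` tree containing every reference leaf.
#' @param refs Reference catalog data frame (see
#'   [read_reference_catalog()]).
#' @param max_dist Optional cap on patristic distance for
#'   nearest-reference calls; beyond it a leaf is `"unassigned"`.
#' @return Data frame with columns `leaf`, `clade`, `method`, `value`.
#' @export
assign_clades <- function(t, refs, max_dist = NULL) {
  stopifnot(inherits(t, "phylo"))
  refs <- validate_reference_catalog(refs)
  if (!ape::is.rooted(t)) stop("tree must be rooted (see midpoint_root)")
  absent <- setdiff(refs$name, t$tip.label)
  if (length(absent))
    stop("reference leaf missing from tree: ", absent[1L])

  tipsets <- .clade_tipsets(t, refs)
  pairs <- utils::combn(CLADE_LEVELS, 2L)
  disjoint <- all(apply(pairs, 2L, function(p)
    length(intersect(tipsets[[p[1]]], tipsets[[p[2]]])) == 0L))

  leaves <- t$tip.label
  if (disjoint) {
    supp <- attr(t, "supports")
    node_support <- function(cl) {
      rn <- refs$name[refs$clade == cl]
      if (length(rn) < 2L || is.null(t$node.label)) return(NA_real_)
      mrca <- ape::getMRCA(t, rn)
      suppressWarnings(as.numeric(t$node.label[mrca - length(t$tip.label)]))
    }
    clade <- rep("unassigned", length(leaves))
    value <- rep(NA_real_, length(leaves))
    for (cl in CLADE_LEVELS) {
      inside <- leaves %in% tipsets[[cl]]
      clade[inside] <- cl
      value[inside] <- node_support(cl)
    }
    out <- data.frame(leaf = leaves, clade = clade, method = "monophyly",
                      value = value, stringsAsFactors = FALSE)
  } else {
    pat <- stats::cophenetic(t)
    calls <- lapply(leaves, function(lf)
      .nearest_reference_calc(pat, lf, refs, max_dist))
    out <- data.frame(leaf = leaves,
                      clade = vapply(calls, `[[`, "", "clade"),
                      method = "nearest-reference",
                      value = vapply(calls, `[[`, 0, "distance"),
                      stringsAsFactors = FALSE)
  }
  out
}

.nearest_reference_calc <- function(pat, leaf, refs, max_dist) {
  d <- pat[leaf, refs$name]
  k <- which.min(d)          # first minimum = earliest catalog entry
  if (!is.null(max_dist) && d[k] > max_dist)
    return(list(clade = "unassigned", distance = unname(d[k])))
  list(clade = refs$clade[k], distance = unname(d[k]))
}

#' Nearest characterized reference for one leaf
#'
#' Clade of the reference leaf at minimal patristic (path-length)
#' distance; ties are broken by catalog order. If `max_dist` is given and
#' exceeded the leaf is `"unassigned"`.
#'
#' @param t `phylo` tree.
#' @param leaf Leaf identifier.
#' @inheritParams assign_clades
#' @return List with `clade` and `distance`.
#' @export
nearest_reference <- function(t, leaf, refs, max_dist = NULL) {
  refs <- validate_reference_catalog(refs)
  if (!leaf %in% t$tip.label) stop("no such leaf: ", leaf)
  pat <- stats::cophenetic(t)
  .nearest_reference_calc(pat, leaf, refs, max_dist)
}

#' Count leaves per assigned clade
#'
#' @param asg Assignment data frame from [assign_clades()].
#' @return Named integer vector over A, B, C, D, unassigned; sums to the
#'   leaf count.
#' @export
clade_census <- function(asg) {
  tab <- table(factor(asg$clade, levels = ASSIGN_LEVELS))
  setNames(as.integer(tab), names(tab))
}
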