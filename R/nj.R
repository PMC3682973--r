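#' Neighbour-joining tree from a distance matrix
#'
#' Classic neighbour-joining agglomeration: iteratively joins the pair
#' `(i, j)` minimizing `Q(i,j) = (n-2) d(i,j) - sum_k d(i,k) - sum_k d(j,k)`,
#' with branch lengths by the standard NJ formulas. Ties on the Q criterion
#' are broken by the lowest (row, column) position in the current matrix,
#' making the output deterministic; negative branch lengths are clamped to
#' zero. On an additive (tree-metric) input the true topology and branch
#' lengths are recovered exactly.
#'
#' @param d Symmetric numeric matrix with zero diagonal and row/column
#'   names; at least 3 taxa.
#' @return An unrooted binary `phylo` tree (class from \pkg{ape}) with
#'   `2n - 3` edges.
#' @export
nj_build <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa")
  if (is.null(rownames(d))) stop("distance matrix must carry taxon names")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(d < 0)) stop("distances must be non-negative")

  ids <- rownames(d)
  if (any(grepl("[,:;()\\[\\]]", ids)))
    stop("taxon names must not contain Newick metacharacters")

  frags <- ids          # growing Newick fragment per active cluster
  D <- unname(d)
  m <- n
  clamp <- function(x) pmax(x, 0)

  while (m > 3L) {
    rs <- rowSums(D)
    Q <- (m - 2) * D - outer(rs, rs, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]

    li <- D[i, j] / 2 + (rs[i] - rs[j]) / (2 * (m - 2))
    lj <- D[i, j] - li
    newfrag <- sprintf("(%s:%.15g,%s:%.15g)",
                       frags[i], clamp(li), frags[j], clamp(lj))

    keep <- setdiff(seq_len(m), c(i, j))
    dnew <- (D[i, keep] + D[j, keep] - D[i, j]) / 2
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew),
               c(dnew, 0))
    frags <- c(frags[keep], newfrag)
    m <- m - 1L
  }

  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c_ <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  txt <- sprintf("(%s:%.15g,%s:%.15g,%s:%.15g);",
                 frags[1L], clamp(a), frags[2L], clamp(b),
                 frags[3L], clamp(c_))
  ape::read.tree(text = txt)
}

# Non-trivial bipartitions of a tree as canonical keys: each split is
# represented by the side NOT containing the lexicographically smallest
# tip label, tips sorted and pasted. Trivial splits (side of size 1 or
# n-1) are excluded.
tree_splits <- function(t) {
  ntip <- length(t$tip.label)
  if (ntip < 4L) return(character(0))
  ref <- sort(t$tip.label)[1L]
  parts <- ape::prop.part(t)
  keys <- character(0)
  for (p in parts) {
    tips <- t$tip.label[p]
    if (ref %in% tips) tips <- setdiff(t$tip.label, tips)
    sz <- length(tips)
    if (sz >= 2L && sz <= ntip - 2L)
      keys <- c(keys, paste(sort(tips), collapse = "|"))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Number of non-trivial bipartitions present in exactly one of the two
#' trees (symmetric difference). Rootings are ignored; both trees must
#' share the same leaf set.
#'
#' @param t1,t2 `phylo` trees over identical leaf sets.
#' @return Non-negative integer.
#' @export
robinson_foulds <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label))
    stop("trees must share the same leaf set")
  s1 <- tree_splits(t1)
  s2 <- tree_splits(t2)
  length(setdiff(s1, s2)) + length(setdiff(s2, s1))
}

#' Root a tree at the midpoint of its longest leaf-to-leaf path
#'
#' Path lengths between every pair of leaves are conserved. If every
#' branch length is zero the midpoint is undefined and the root is placed
#' deterministically on the terminal edge of the lexicographically
#' smallest leaf (with a message).
#'
#' @param t Unrooted `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(t) {
  stopifnot(inherits(t, "phylo"))
  if (is.null(t$edge.length)) stop("tree must have branch lengths")
  if (!all(is.finite(t$edge.length))) stop("branch lengths must be finite")
  ntip <- length(t$tip.label)
  if (ntip < 2L) stop("need at least 2 leaves")
  if (all(t$edge.length == 0)) {
    message("all branch lengths zero; rooting on the edge of leaf '",
            sort(t$tip.label)[1L], "'")
    return(ape::root(t, outgroup = sort(t$tip.label)[1L],
                     resolve.root = TRUE))
  }
  if (ntip == 2L) {
    tot <- sum(t$edge.length)
    out <- t
    out$edge.length <- rep(tot / 2, length(out$edge.length))
    return(out)
  }
  phangorn::midpoint(t)
}

#' Neighbour-joining tree with bootstrap supports
#'
#' Builds the point-estimate tree from the full alignment, then
#' `replicates` NJ trees from column-resampled alignments; each internal
#' bipartition of the point tree receives support equal to 100 times the
#' fraction of replicate trees containing it. Supports are stored as
#' internal node labels. Replicates whose distance matrix is undefined are
#' skipped with a warning; more than 10% skipped is an error.
#'
#' @param a An [aligned_proteins] object.
#' @param replicates Number of bootstrap replicates (default 1000).
#' @param seed Integer master seed governing all replicate resampling.
#' @inheritParams distance_matrix
#' @return Unrooted `phylo` with `node.label` supports and a numeric
#'   attribute `supports` (percent, one value per internal node; the root
#'   entry is the trivial full split).
#' @export
bootstrap_supports <- function(a, replicates = 1000, seed = 1,
                               model = c("pdist", "poisson"),
                               gap_policy = c("pairwise-deletion",
                                              "complete-deletion")) {
  stopifnot(inherits(a, "aligned_proteins"))
  if (replicates < 1L) stop("replicates must be >= 1")
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)

  point <- nj_build(distance_matrix(a, model, gap_policy))
  rep_seeds <- withr::with_seed(seed,
                                sample.int(.Machine$integer.max, replicates))
  trees <- vector("list", replicates)
  skipped <- 0L
  for (k in seq_len(replicates)) {
    trees[[k]] <- tryCatch(
      nj_build(distance_matrix(bootstrap_resample(a, rep_seeds[k]),
                               model, gap_policy)),
      error = function(e) {
        warning("bootstrap replicate ", k, " skipped: ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
    if (is.null(trees[[k]])) skipped <- skipped + 1L
  }
  if (skipped > 0.1 * replicates)
    stop(skipped, " of ", replicates, " bootstrap replicates failed")
  trees <- Filter(Negate(is.null), trees)
  class(trees) <- "multiPhylo"

  counts <- ape::prop.clades(point, trees, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  supp <- 100 * counts / length(trees)
  point$node.label <- sprintf("%g", supp)
  attr(point, "supports") <- supp
  attr(point, "replicates_used") <- length(trees)
  point
}

#' Blank node-support labels below a display threshold
#'
#' Bootstrap convention: only supports at or above the threshold
#' (default 50) are shown.
#'
#' @param t `phylo` with numeric-like `node.label`.
#' @param threshold Percentage in `[0, 100]`.
#' @return The tree with sub-threshold labels blanked.
#' @export
filter_supports <- function(t, threshold = 50) {
  stopifnot(threshold >= 0, threshold <= 100)
  if (is.null(t$node.label)) return(t)
  v <- suppressWarnings(as.numeric(t$node.label))
  t$node.label[!is.na(v) & v < threshold] <- ""
  t
}

#' Read a Newick tree file
#'
#' Internal node labels (e.g. bootstrap supports) are preserved. A basic
#' parenthesis-balance check reports the character offset of the first
#' imbalance before handing the text to the parser.
#'
#' @param path Path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  depth <- 0L
  chars <- strsplit(txt, "")[[1]]
  for (k in seq_along(chars)) {
    if (chars[k] == "(") depth <- depth + 1L
    if (chars[k] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("malformed Newick: unbalanced ')' at character ", k)
  }
  if (depth != 0L)
    stop("malformed Newick: ", depth, " unclosed '(' at end of input")
  t <- tryCatch(ape::read.tree(text = txt), error = function(e)
    stop("malformed Newick: ", conditionMessage(e)))
  if (is.null(t)) stop("malformed Newick: parser returned no tree")
  t
}

#' Write a tree to a Newick file
#'
#' Branch lengths are written with 10 significant digits; internal node
#' labels (supports) are included.
#'
#' @param t A `phylo` tree.
#' @param path Output path.
#' @export
write_newick <- function(t, path) {
  ape::write.tree(t, file = path, digits = 10)
  invisible(path)
}
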