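#' @importFrom stats setNames runif
#' @importFrom utils read.delim write.table
NULL

#' The 20 standard amino-acid letters
#'
#' One-letter codes in alphabetical order. Gap is `"-"`; `"X"` marks an
#' unknown residue. Both are excluded from distance comparisons.
#' @export
AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ALLOWED_CHARS <- c(AA_LETTERS, "-", "X")

#' Construct an aligned protein set
#'
#' A rectangular, gapped protein alignment held as a character matrix with
#' one row per sequence (rownames are the sequence identifiers) and one
#' column per alignment column.
#'
#' @param mat Character matrix of single residues, rownames = unique ids.
#' @return An object of class `aligned_proteins` with elements `ids`,
#'   `mat` and `length` (the column count).
#' @export
aligned_proteins <- function(mat) {
  if (!is.matrix(mat) || !is.character(mat))
    stop("alignment must be a character matrix")
  ids <- rownames(mat)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("all sequences must carry non-empty identifiers")
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1L])
  if (ncol(mat) < 1L)
    stop("alignment must have at least one column")
  bad <- !(mat %in% ALLOWED_CHARS)
  if (any(bad)) {
    off <- which(bad, arr.ind = TRUE)[1L, ]
    stop("invalid residue '", mat[bad][1L], "' in sequence '",
         ids[off[1L]], "'")
  }
  structure(list(ids = ids, mat = mat, length = ncol(mat)),
            class = "aligned_proteins")
}

#' @export
print.aligned_proteins <- function(x, ...) {
  cat("Aligned protein set:", length(x$ids), "sequences x",
      x$length, "columns\n")
  invisible(x)
}

#' Read an aligned protein FASTA file
#'
#' Reads aligned (gapped) protein FASTA. Residues are upper-cased and the
#' `.` gap alias is normalized to `-`. Identifiers are the first
#' whitespace-delimited token of each header and must be unique; all
#' sequences must have equal length.
#'
#' @param path Path to a FASTA file with at least one record.
#' @return An [aligned_proteins] object.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                             set.attributes = FALSE)
  if (length(recs) == 0L) stop("no FASTA records in ", path)
  ids <- sub("\\s.*$", "", names(recs))
  if (anyDuplicated(ids))
    stop("duplicate sequence identifier: ", ids[duplicated(ids)][1L])
  seqs <- gsub(".", "-", toupper(unlist(recs)), fixed = TRUE)
  lens <- nchar(seqs)
  if (length(unique(lens)) > 1L) {
    ref <- lens[1L]
    off <- ids[which(lens != ref)[1L]]
    stop("ragged alignment: sequence '", off, "' has length ",
         lens[lens != ref][1L], ", expected ", ref)
  }
  mat <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(mat) <- ids
  aligned_proteins(mat)
}

#' Write an aligned protein set to FASTA
#'
#' @param a An [aligned_proteins] object.
#' @param path Output path.
#' @export
write_aligned_fasta <- function(a, path) {
  stopifnot(inherits(a, "aligned_proteins"))
  seqs <- apply(a$mat, 1L, paste, collapse = "")
  seqinr::write.fasta(as.list(seqs), names = a$ids, file.out = path,
                      nbchar = 80)
  invisible(path)
}

# columns usable for comparison: gap and X carry no signal
.comparable <- function(a, gap_policy) {
  ok <- !(a$mat == "-" | a$mat == "X")
  if (gap_policy == "complete-deletion") {
    keep <- apply(ok, 2L, all)
    ok[] <- rep(keep, each = nrow(ok))
  }
  ok
}

#' Pairwise p-distance between two aligned sequences
#'
#' Proportion of compared alignment columns at which the two residues
#' differ. Gap (`-`) and unknown (`X`) positions are excluded; under
#' `"pairwise-deletion"` a column is compared when both members of the pair
#' are informative, under `"complete-deletion"` only columns informative in
#' every sequence of the alignment are used.
#'
#' @param a An [aligned_proteins] object.
#' @param i,j Sequence identifiers.
#' @param gap_policy `"pairwise-deletion"` (default) or
#'   `"complete-deletion"`.
#' @return A value in `[0, 1]`.
#' @export
p_distance <- function(a, i, j,
                       gap_policy = c("pairwise-deletion",
                                      "complete-deletion")) {
  stopifnot(inherits(a, "aligned_proteins"))
  gap_policy <- match.arg(gap_policy)
  for (id in c(i, j))
    if (!id %in% a$ids) stop("no such sequence: ", id)
  ok <- .comparable(a, gap_policy)
  comp <- ok[i, ] & ok[j, ]
  if (!any(comp))
    stop("undefined distance: no comparable columns between '",
         i, "' and '", j, "'")
  mean(a$mat[i, comp] != a$mat[j, comp])
}

#' Poisson correction of a proportion of differing sites
#'
#' Maps an observed proportion of differences `p` to the expected number of
#' substitutions per site under a Poisson model, `-ln(1 - p)`. Equals `p`
#' to first order as `p -> 0` and is monotone increasing.
#'
#' @param p Proportion(s) in `[0, 1)`.
#' @return Corrected distance(s), `>= p`.
#' @export
poisson_correct <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 1)) stop("Poisson correction saturates at p >= 1")
  -log1p(-p)
}

#' Pairwise distance matrix over an alignment
#'
#' Applies [p_distance()] (optionally Poisson-corrected) to every pair of
#' sequences.
#'
#' @param a An [aligned_proteins] object with at least two sequences.
#' @param model `"pdist"` (default) or `"poisson"`.
#' @inheritParams p_distance
#' @return Symmetric numeric matrix with zero diagonal, dimnames = ids,
#'   attribute `model`.
#' @export
distance_matrix <- function(a, model = c("pdist", "poisson"),
                            gap_policy = c("pairwise-deletion",
                                           "complete-deletion")) {
  stopifnot(inherits(a, "aligned_proteins"))
  model <- match.arg(model)
  gap_policy <- match.arg(gap_policy)
  n <- length(a$ids)
  if (n < 2L) stop("need at least 2 sequences")
  ok <- .comparable(a, gap_policy)
  d <- matrix(0, n, n, dimnames = list(a$ids, a$ids))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      comp <- ok[i, ] & ok[j, ]
      if (!any(comp))
        stop("undefined distance for pair ('", a$ids[i], "', '",
             a$ids[j], "'): no comparable columns")
      p <- mean(a$mat[i, comp] != a$mat[j, comp])
      if (model == "poisson") {
        if (p >= 1)
          stop("Poisson correction saturates for pair ('", a$ids[i],
               "', '", a$ids[j], "')")
        p <- -log1p(-p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  attr(d, "model") <- model
  d
}

#' Bootstrap-resample alignment columns
#'
#' Draws alignment columns uniformly with replacement (Felsenstein
#' bootstrap), preserving sequence ids and alignment length. Fully
#' determined by `seed`; the caller's RNG state is untouched.
#'
#' @param a An [aligned_proteins] object.
#' @param seed Integer seed.
#' @return An [aligned_proteins] object of identical dimensions.
#' @export
bootstrap_resample <- function(a, seed) {
  stopifnot(inherits(a, "aligned_proteins"))
  idx <- withr::with_seed(seed,
                          sample.int(a$length, a$length, replace = TRUE))
  m <- a$mat[, idx, drop = FALSE]
  rownames(m) <- a$ids
  out <- aligned_proteins(m)
  attr(out, "column_index") <- idx
  out
}

#' Write a distance matrix as a square TSV table
#'
#' Header row of ids, row labels in the first column.
#' @param d Distance matrix from [distance_matrix()].
#' @param path Output path.
#' @export
write_distance_tsv <- function(d, path) {
  df <- data.frame(id = rownames(d), d, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a distance matrix in square PHYLIP format
#'
#' @inheritParams write_distance_tsv
#' @export
write_distance_phylip <- function(d, path) {
  n <- nrow(d)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    writeLines(paste0(formatC(rownames(d)[i], width = -10),
                      paste(sprintf("%.6f", d[i, ]), collapse = "  ")),
               con)
  }
  invisible(path)
}
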