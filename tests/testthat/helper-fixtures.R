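# fixtures are built in code; no binary data

# alignment from named equal-length strings
make_aln <- function(seqs) {
  mat <- do.call(rbind, strsplit(unname(seqs), "", fixed = TRUE))
  rownames(mat) <- names(seqs)
  aligned_proteins(mat)
}

write_fasta_text <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

# unrooted tree with random positive branch lengths; its cophenetic
# matrix is additive by construction
random_additive_case <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n)
    tr$edge.length <- runif(nrow(tr$edge), 0.1, 1)
    ape::unroot(tr)
  })
}

# two groups of identical sequences differing at n_diag diagnostic
# columns, plus one private variant column per group
two_group_alignment <- function(n_per_group = 5, ncols = 100,
                                n_diag = 40, seed = 42) {
  withr::with_seed(seed, {
    base <- sample(AA_LETTERS, ncols, replace = TRUE)
    alt <- vapply(base, function(x)
      sample(setdiff(AA_LETTERS, x), 1), "")
    g1 <- matrix(rep(base, n_per_group), n_per_group, ncols, byrow = TRUE)
    g2 <- g1
    g2[, seq_len(n_diag)] <- matrix(rep(alt[seq_len(n_diag)], n_per_group),
                                    n_per_group, n_diag, byrow = TRUE)
    g1[1, ncols - 1] <- alt[ncols - 1]
    g2[1, ncols] <- alt[ncols]
    m <- rbind(g1, g2)
    rownames(m) <- c(paste0("x", seq_len(n_per_group)),
                     paste0("y", seq_len(n_per_group)))
    aligned_proteins(m)
  })
}

# independent expectation oracle: enumerate every individual main-chain
# residue as the candidate first sugar and apply the two axioms
axiom_oracle <- function(mg, sg, mc, sc) {
  firsts <- c(rep("GalNAc", mg), rep("GlcNAc", mc))
  if (length(firsts) == 0L) return(NULL)
  gnu_v <- firsts == "GalNAc"
  gne_v <- (mg + sg - (firsts == "GalNAc")) > 0
  st <- function(v) {
    if (all(v)) "REQUIRED" else if (!any(v)) "NOT_REQUIRED"
    else "CONDITIONAL"
  }
  list(gnu = st(gnu_v), gne = st(gne_v))
}

# brute-force two-sided Fisher p: enumerate all tables with the observed
# margins, sum hypergeometric probabilities <= observed
fisher_enum <- function(a, b, c, d) {
  m <- a + b
  n_ <- c + d
  k <- a + c
  x <- max(0, k - n_):min(k, m)
  probs <- dhyper(x, m, n_, k)
  pobs <- dhyper(a, m, n_, k)
  sum(probs[probs <= pobs * (1 + 1e-7)])
}

# brute-force patristic distance: sum branch lengths along the node path
patristic_bf <- function(t, i, j) {
  ii <- match(i, t$tip.label)
  jj <- match(j, t$tip.label)
  np <- ape::nodepath(t, ii, jj)
  tot <- 0
  for (k in seq_len(length(np) - 1L)) {
    e <- which((t$edge[, 1] == np[k] & t$edge[, 2] == np[k + 1]) |
               (t$edge[, 1] == np[k + 1] & t$edge[, 2] == np[k]))
    tot <- tot + t$edge.length[e]
  }
  tot
}

# small reference catalog stand-in over given names
mini_catalog <- function(names, clades) {
  data.frame(name = names, organism = "synthetic", clade = clades,
             `function` = "stand-in", accession = NA_character_,
             check.names = FALSE, stringsAsFactors = FALSE)
}
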