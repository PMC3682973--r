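# epiclades

Functional classification of bacterial N-acetylhexosamine 4-epimerases
and rule-based prediction of O-antigen gene content.

## What this is for

Enzymes of the NAD-dependent epimerase/dehydratase family that
interconvert gluco/galacto configurations at C4 were long annotated
indiscriminately as *gne* (UDP-GlcNAc 4-epimerase) or *galE* (UDP-Glc
4-epimerase). They in fact fall into well-separated clades with three
distinct substrates:

| Clade | Gene name | Substrate | Role |
|---|---|---|---|
| A | *gne* / *galE* | UDP-GlcNAc / UDP-Glc | UDP-GalNAc donor; galactose utilisation |
| B | *gnaB* | UDP-GlcNAcA | UDP-GalNAcA pathway (paired with *gnaA*) |
| C | — | unknown | only characterized member is a 4-keto-sugar reductase |
| D | *gnu* | UndPP-GlcNAc | epimerizes the lipid-linked **first sugar** of the O unit |

`epiclades` rebuilds this classification as a tested R pipeline for
people annotating polysaccharide gene clusters:

* **Trees** — p-distances over aligned protein FASTA (pairwise or
  complete deletion, optional Poisson correction `-ln(1-p)`),
  deterministic neighbour joining on the Q criterion
  `Q(i,j) = (n-2) d_ij - Σ_k d_ik - Σ_k d_jk`, Felsenstein bootstrap
  supports (percentage of replicate trees containing each bipartition
  of the point tree), midpoint rooting, Robinson–Foulds comparison,
  Newick I/O.
* **Clades** — reference-anchored assignment: monophyly of the
  characterized references per clade, with an audited
  nearest-reference (patristic) fallback.
* **Names** — annotation rules mapping (clade, genomic context) to
  *galE* / *gne* / *gnaB* / *gnu* / unknown with a confidence tier.
* **Structure logic** — from O-unit GlcNAc/GalNAc counts, expected
  *gnu*/*gne* presence via two axioms (the first sugar is a main-chain
  GlcNAc or GalNAc; *gnu* ⇔ GalNAc first, *gne* ⇔ some GalNAc not
  first), first-sugar prediction from gene content, and a
  genotype–structure concordance report with odds-ratio / Fisher
  support statistics.
* **Simulators** — seeded generators for alignments evolved along
  known trees (equal-rates 20-state model) and serogroup catalogs with
  exactly controlled discordances, closing the loop on every stage.

## Worked example

The shipped workflow (`analysis/01_simulate_data.R` →
`02_tree_and_clades.R` → `03_structure_concordance.R`) simulates both
study inputs and runs both branches. In an R session:

```r
library(epiclades)

# four clades, 5 leaves each, between-clade divergence 0.5
ts <- make_clade_testset(n_per_clade = 5, between_div = 0.5,
                         within_div = 0.1, seed = 1)
tree <- bootstrap_supports(ts$alignment, replicates = 200, seed = 1)
asg <- assign_clades(midpoint_root(tree), ts$refs)
clade_census(asg)
#>          A          B          C          D unassigned
#>          5          5          5          5          0

# 115-serogroup catalog with 7 missing + 10 surplus genes injected
g <- generate_serogroup_table(n = 115, inject_missing = 7,
                              inject_surplus = 10, seed = 1)
concordance_report(g$table)
#> Concordance over 115 serogroups
#>   gnu as expected: 104 / 115
#>   gne as expected: 109 / 115
#>   missing when expected:    7
#>   present when not predicted: 10

# association of the clade D gene with GalNAc in the PCR screen
odds_ratio(c(14, 8, 4, 36))   # 14/22 GalNAc+ vs 4/40 GalNAc-
#> [1] 15.75
fisher_exact(c(14, 8, 4, 36))
#> [1] 1.674778e-05
```

The census shows every simulated protein recovered into its generating
clade; the concordance report recovers exactly the injected
discordance load (7 genes missing when expected, 10 present when not
predicted); the 2×2 statistics quantify the association between
GalNAc-containing O units and presence of the clade D (*gnu*) gene.

See `vignettes/epimerase-clades.Rmd` for the model, the axioms, the
accounting conventions and the simulators' scope.

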