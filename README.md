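# tcrcompare

Comparative analysis of antigen-specific T-cell receptor (TCR)
repertoires between donor cohorts — built for the question of what
separates **auto-reactive** repertoires (donors carrying the presenting
HLA allele) from **allo-reactive** ones (donors lacking it), and usable
for any two-cohort clonotype contrast.

Given annotated paired-chain clonotype tables (donor, cohort, V/D/J gene
calls, CDR3α/β amino-acid strings, copy counts), the package computes
the full set of repertoire-architecture readouts that distinguish such
cohorts:

* **Repertoire views** — *abundance* weighting (clones count by copy
  number) and *appearance* weighting (every unique receptor decreased
  to one count, seeded random order), with receptor-identity
  deduplication and pooling.
* **Gene usage** — percent usage per TRBV/TRBJ/TRBD/TRAV/TRAJ gene,
  deployment against a fixed 30-gene TRBV catalogue ("k of 30 genes
  used"), V–J pairing matrices exported as chord-diagram records, and
  CDR3 length spectra with "fraction under L residues" readouts.
* **CDR3 physiochemistry** — hydrophobic-residue fraction, Kyte–
  Doolittle GRAVY, average and monoisotopic molecular weight, and
  theoretical pI from the Henderson–Hasselbalch net charge
  `Z(pH) = Σ_basic n_g/(1+10^(pH−pKa_g)) − Σ_acidic n_g/(1+10^(pKa_g−pH))`
  solved by bisection (EMBOSS or Expasy-style pKa sets).
* **Twelve diversity indices** per donor from clone counts `n_i`
  (`p_i = n_i/N`): richness S, dominance λ = Σp², Simpson 1−λ, 1/λ,
  Shannon H = −Σp ln p, Menhinick S/√N, Margalef (S−1)/ln N,
  Buzas–Gibson e^H/S, equitability H/ln S, Berger–Parker max(n)/N and
  its inverse, and the Gini coefficient — plus cohort log2 fold changes
  (allo over auto) with exact Mann–Whitney p values.
* **Comparison statistics** — exact small-sample Mann–Whitney U by full
  enumeration of labelings, and a replicate-free two-way sum-of-squares
  variance partition ("% of total variation") for cohort × category
  grids.
* **CDR3 motifs** — exact interior k-mer enumeration (GLIPH-style trims,
  presence semantics), cohort enrichment by Fisher's exact test with BH
  correction, and cohort-exclusivity flags.
* **A seeded V(D)J repertoire simulator** with `auto_like` / `allo_like`
  presets encoding the designed contrasts (gene-usage breadth, length
  left-shift, clonal expansion, acidic interior bias) and ground truth
  for recovery testing.

## Worked example

```r
library(tcrcompare)

study  <- simulate_study(seed = 1)   # 3 auto-like + 3 allo-like donors
donors <- donor_diversity(study$clonotypes)
donors[, c("label", "cohort", "S", "N", "shannon", "gini", "berger_parker")]
#>   label  cohort     S     N shannon   gini berger_parker
#> 1 auto_1 auto      60   141    3.58 0.482         0.121
#> 2 auto_2 auto      60   182    3.49 0.543         0.121
#> 3 auto_3 auto      60   139    3.64 0.467         0.101
#> 4 allo_1 allo      80    84    4.36 0.0452        0.0238
#> 5 allo_2 allo      80    84    4.35 0.0464        0.0357
#> 6 allo_3 allo      80    95    4.25 0.150         0.0632

fc <- cohort_log2fc(donors[donors$cohort == "allo", ],
                    donors[donors$cohort == "auto", ])
fc[fc$metric %in% c("menhinick", "margalef", "gini", "berger_parker"), ]
#>   metric        mean_allo mean_auto log2fc     p
#> 1 menhinick        8.56       4.86   0.815   0.1
#> 2 berger_parker    0.0409     0.114 -1.48    0.1
#> 3 margalef        17.7       11.7    0.590   0.1
#> 4 gini             0.0806     0.497 -2.62    0.1
```

The allo-like cohort recovers the designed architecture: more unique
clonotypes per donor (positive Menhinick and Margalef fold changes) and
far weaker clonal dominance (negative Gini and Berger–Parker). The p
values sit at 0.10 — the smallest value an exact rank test can produce
at 3 donors per arm, which is why fold-change *sign patterns*, not
univariate significance, are the readout at this cohort size.

The one-call pipeline runs every stage and (optionally) writes a CSV +
JSON bundle:

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "results"))
res$physchem_means[, c("cohort", "n_sequences", "gravy", "pi")]
#>   cohort n_sequences   gravy    pi
#> 1 auto           180  0.285   6.82
#> 2 allo           240 -0.0638  5.51

res$fraction_below
#>   cohort basis      threshold percent_below
#> 1 auto   abundance         13          11.0
#> 2 auto   appearance        13          14.4
#> 3 allo   abundance         13          47.1
#> 4 allo   appearance        13          48.3
```

Allo-like CDR3β loops are shorter (48% vs 14% under 13 residues on the
appearance basis) and more acidic (mean pI 5.51 vs 6.82), with lower
GRAVY — the designed physiochemical contrast, measured end to end from
simulated sequences. A thin command-line wrapper is installed at
`inst/scripts/tcr_pipeline.R`.

## Documentation

The methods vignette
(`vignettes/tcr-repertoire-comparison.Rmd`) describes the models and
assumptions behind each readout, the simulator's design and its limits,
the numerical choices (pKa sets, log bases, tie handling, exact-test
enumeration bounds), and known limitations.
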