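---
title: "Comparing antigen-specific TCR repertoires: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing antigen-specific TCR repertoires: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`tcrcompare` quantifies how two cohorts of antigen-specific T-cell
receptor (TCR) repertoires differ — the canonical use case being
auto-reactive donors (who carry the presenting HLA allele) versus
allo-reactive donors (who lack it). This vignette is the package's own
account of the models and numerical choices behind each readout, and of
what the bundled simulator does and does not emulate.

```{r setup}
library(tcrcompare)
```

## Clonotypes, receptor identity, and the two repertoire weightings

The unit of observation is a paired-chain clonotype: TRAV/TRAJ and
TRBV/TRBD/TRBJ gene calls, the CDR3 amino-acid strings of both chains, and
a copy number (cells observed with that exact receptor). Two conventions
matter throughout:

* **Receptor identity** is the tuple (TRAV, TRAJ, TRBV, TRBJ, CDR3α,
  CDR3β) at the allele-free gene level. TRBD is excluded because calls on
  that very short segment are frequently ambiguous; alleles are stripped
  because usage is reported at the gene level. This is the standard
  clonotype definition in repertoire analysis.
* **CDR3 strings are full IMGT junctions**, including the conserved
  C104 and F/W118 anchors, and "CDR3 length" means the length of that
  string. V-QUEST-style annotation emits junctions with anchors, so this
  is the convention ingested data will most often carry;
  `fraction_below()` exposes an inclusive/exclusive flag so either
  reading of "under 13 residues" is available (the default is strict
  `<`).

Every analysis runs on a `repertoire_view`, which deduplicates receptors
and attaches weights under one of two bases:

* **abundance** — weights are summed copy numbers; dominant clones count
  in proportion to their expansion;
* **appearance** — every unique receptor is decreased to one count, and
  the rows are put in a seeded random order. The shuffle is the
  "randomly selected" step of appearance normalisation; because no
  subsample size is standard, the default keeps all receptors and an
  optional `subsample` argument enables seeded downsampling.

All randomness in the package — this shuffle and the simulator — flows
through explicit integer seeds that are recorded in output metadata, so
any bundle can be regenerated byte-for-byte.

## The simulator: designed contrasts with ground truth

`simulate_study()` generates per-donor clonotype tables from two
`cohort_config` objects and returns the realised per-donor richness and
totals alongside, so recovery tests can compare what the pipeline
measures against what was injected. Each clone draws:

* V/D/J genes from per-cohort usage distributions over the bundled
  30-gene TRBV catalogue (and TRBJ/TRAV/TRAJ/TRBD catalogues);
* a CDR3 built as `C` + two anchor-proximal residues (biased to A/S,
  emulating germline-encoded `CASS...` prefixes) + interior residues
  from a biased residue distribution + `F`, with total length from a
  one- or two-component Gaussian rounded and clamped to [8, 25] aa;
* a copy number: 1 with probability `1 - p_expanded`, otherwise `1 + G`
  with `G` geometric on {1, 2, ...} with mean `1/copy_law`. One
  parameter reproduces the "few dominant multi-copy clones" pie
  structure of real sorted repertoires.

The shipped presets are the package's fixed study conditions, chosen to
mirror the qualitative contrasts reported for auto- versus allo-reactive
repertoires at realistic single-cell sorting scale:

| parameter | `auto_like` | `allo_like` | emulates |
|---|---|---|---|
| donors | 3 | 3 | small sorted cohorts (n = 3 per arm) |
| clones/donor | 60 | 80 | a few hundred receptors per study |
| TRBV usage | decay over 19/30 genes | flatter decay over 30/30 | narrow vs broad gene deployment |
| CDR3 length | Gaussian 15 ± 2 aa (5% at 11 ± 1.5) | 50% component at 11 ± 1.5 aa | Gaussian peak at 15 vs left-shifted spectratype |
| expansion | p = 0.3, copy law 0.15 | p = 0.05, copy law 0.6 | heavy clonal dominance vs mostly singletons |
| interior bias | I/L/V/F ×1.3, D/E ×0.8 | D/E ×2 | hydrophobic vs acidic CDR3 chemistry |

What the simulator does **not** emulate: nucleotide-level recombination
(no TdT insertions, no codon structure), thymic selection, α/β
correlation (chains are drawn independently), sequencing error, or
convergent recombination of public clones. Passing recovery tests
therefore show the *analysis chain* is faithful to designed
distributional contrasts — not that real repertoires satisfy those
contrasts.

## Gene usage, deployment, pairing, spectratype

Usage profiles are percentages of view weight per allele-free gene, so
every profile exists in abundance and appearance form and records its
basis. Deployment counts the distinct genes observed against the fixed
catalogue denominator (observed genes missing from the catalogue are
warned about and counted as used, without inflating the denominator).
Pairing matrices accumulate weight per (V gene, J gene) pair and export
as flat records for chord plotting; their marginals reproduce the usage
profiles exactly, which the test suite asserts. Length spectra are
percentages per junction length.

## Physiochemical calculators

These replace point-and-click tools with versioned constants
(`scale_registry()`):

* **GRAVY** — mean Kyte–Doolittle hydropathy; **hydrophobic fraction**
  is a separate membership readout over a configurable set (default
  A, C, F, I, L, M, V, W), because published repertoire work reports
  "hydrophobicity" and GRAVY as distinct quantities while the defining
  set behind the former is usually undocumented.
* **Molecular weight** — residue-mass sums plus one water (average
  18.01528 Da, monoisotopic 18.010565 Da).
* **Net charge and pI** — Henderson–Hasselbalch occupancies of the
  basic groups (N-terminus, H, K, R) minus the acidic groups
  (C-terminus, D, E, C, Y). The charge is strictly decreasing in pH and
  every peptide carries both termini, so the pI is the unique root in
  (0, 14); it is found by bisection to |charge| < 1e-6 (at most 200
  halvings of a 14-unit interval, far more than needed). The pKa set
  defaults to the EMBOSS constants with a Bjellqvist/Expasy-style set
  behind a flag; the chosen set is recorded in every output. Because
  the web tools used in published work do not publish their pKa tables,
  absolute pI values are comparable only within one constant set —
  cohort *differences* are the supported readout.

Ambiguous residues (`X`, `*`, lowercase) are rejected at ingest rather
than silently kept, since every one of these quantities is undefined for
them.

```{r}
theoretical_pi("GG")        # symmetric two-group case: (8.6 + 3.6) / 2
gravy("IVL")                # (4.5 + 4.2 + 3.8) / 3
molecular_weight("G")       # 57.0519 + water
```

## The twelve diversity indices

`diversity_report()` computes, from clone copy counts `n_i` (with
`N = sum(n_i)`, `p_i = n_i/N`, `S` clonotypes): richness ("biodiversity"
= S), dominance λ = Σp², Simpson 1 − λ, reciprocal Simpson 1/λ, Shannon
H = −Σ p ln p, Menhinick S/√N, Margalef (S−1)/ln N, Buzas–Gibson e^H/S,
equitability H/ln S, Berger–Parker max(n)/N and its inverse, and the
Gini coefficient from the ascending-sorted covariance form
Σ(2i−S−1)x₍ᵢ₎/(S·Σx). Conventions follow the PAST software family:
natural logarithms throughout, "dominance" is λ (so Simpson and
dominance move in opposite directions), equitability is defined as 1 for
a single-clone repertoire, and the Gini uses the uncorrected form with
the S/(S−1) small-sample factor behind a flag. "Biodiversity" is
implemented as richness — it is the only conventional metric not
otherwise covered by the list. The whole set is verified against an
independent literal-formula oracle (with Gini re-derived via the
mean-absolute-difference definition) to 1e-9.

`cohort_log2fc()` reports `log2(mean_allo / mean_auto)` per metric with
an exact Mann–Whitney p on the per-donor values; a zero cohort mean
yields an explicit `undefined` marker rather than a propagating `NaN`,
with an optional pseudocount.

## Comparison statistics

**Exact Mann–Whitney.** At donor-level sample sizes, asymptotic rank
tests are meaningless, so the p value is computed by full enumeration of
all `choose(n_a + n_b, n_a)` labelings (midranks for ties; two-sided p =
twice the smaller tail, capped at 1), with a tie-corrected normal
fallback past 12 total observations. One consequence worth stating
plainly: with 3 donors per arm the smallest achievable two-sided p is
2/20 = 0.10, so *no* univariate donor-level comparison at n = 3 can
reach 0.05 — matching the observation that individual diversity metrics
in small cohorts show consistent fold-change signs without univariate
significance. For the same reason the suite's type-I calibration of the
test runs at 6 donors per arm (924 labelings, exact rejection rate at
the 0.05 level ≈ 0.039), the smallest balanced design whose exact test
can reject at all.

**Variance partition.** `variance_partition()` decomposes a cohort ×
category grid with one value per cell into row, column and residual sums
of squares; without replicates the interaction is inseparable from the
residual, so it is reported as residual. For grids of *percentages* —
usage profiles, length spectra, where each cohort's row sums to 100 —
the cohort main effect is structurally zero (all row means equal
100/n_categories). The between-cohort divergence of such grids lives
entirely in the interaction term, so the pipeline's
"percent of variation" readout for usage and spectratype grids is
`percent_residual`, labelled as such in the outputs. This mirrors what
grouped two-way ANOVA readouts of normalised profiles actually measure.

## Motifs

Motif analysis is a deliberately transparent stand-in for
database-driven motif finders (GLIPH-style tools): exact contiguous
k-mers (defaults k ∈ {2, 3, 4}) of CDR3β interiors (defaults: trim 3
residues from each end), counted by per-sequence presence on appearance
views. Motifs supported by at least `min_sequences` (default 2)
sequences are "identified"; all observed motifs stay in the table so
pairwise comparisons can form full 2 × 2 presence tables
(Fisher's exact test, BH-corrected across motifs). A motif is flagged
cohort-exclusive when it is identified in exactly one cohort — the
analogue of a motif reported "only in" one repertoire. Because
"contained more motifs at 93% and 84%" readings are ambiguous between
motif-set size and sequence coverage, `motif_breadth()` emits both
(retained-motif count and the fraction of sequences containing at least
one retained motif) and asserts neither as the published definition.
No reference database, clustering or HLA scoring is attempted, and
published absolute motif counts are not reproduction targets — they are
tool- and database-version-dependent.

## Problem sizes and determinism

The package's own verification runs at sizes a laptop handles in
minutes, chosen to keep Monte-Carlo assertions sharp: 200 random count
vectors for the diversity oracle, 500 random CDR3-like peptides for the
pI grid oracle, 100 random small samples for Mann–Whitney enumeration,
200 simulated null studies (6 + 6 donors × 50 clones) for type-I
calibration, and 100 simulated contrast studies (3 + 3 donors at the
preset sizes) for directional recovery, which demand each designed sign
to be recovered in at least 95 of 100 seeds. Identical configs and seeds
produce byte-identical output bundles, which the suite also asserts.

## Known limitations

* Appearance normalisation keeps all unique receptors by default; if a
  published workflow subsampled, use `subsample` with a recorded seed.
* The physiochemical magnitudes depend on the constant set; only
  within-set comparisons are meaningful.
* The simulator's independence assumptions (between chains, between
  donors) make it unsuitable for studying receptor sharing or public
  clones.
* AIRR ingestion is β-chain-centric (one rearrangement row per
  receptor); fully paired AIRR schemas should be mapped to the
  `simple_csv` dialect.
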