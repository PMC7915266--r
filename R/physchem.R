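# Per-CDR3 physiochemical calculators: hydrophobic-residue fraction,
# Kyte-Doolittle GRAVY, average and monoisotopic molecular weight, and
# Henderson-Hasselbalch net charge / theoretical pI. All scale constants are
# exposed through scale_registry() and echoed into pipeline metadata so any
# number can be traced to its constant set.

# Kyte & Doolittle (1982) hydropathy scale.
.kd_hydropathy <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, E = -3.5, Q = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# Residue (monomer minus water) masses in Da.
.aa_mass_average <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
.aa_mass_mono <- c(
  A = 71.03711, R = 156.10111, N = 114.04293, D = 115.02694, C = 103.00919,
  E = 129.04259, Q = 128.05858, G = 57.02146, H = 137.05891, I = 113.08406,
  L = 113.08406, K = 128.09496, M = 131.04049, F = 147.06841, P = 97.05276,
  S = 87.03203, T = 101.04768, W = 186.07931, Y = 163.06333, V = 99.06841
)
.water_average <- 18.01528
.water_mono <- 18.010565

# pKa sets: EMBOSS iep defaults, and Bjellqvist-style constants as used by
# the Expasy family of tools.
.pka_sets <- list(
  emboss = list(nterm = 8.6, cterm = 3.6,
                side = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5,
                         K = 10.8, R = 12.5, Y = 10.1)),
  expasy = list(nterm = 7.5, cterm = 3.55,
                side = c(C = 9.0, D = 4.05, E = 4.45, H = 5.98,
                         K = 10.0, R = 12.0, Y = 10.0))
)

.default_hydrophobic <- c("A", "C", "F", "I", "L", "M", "V", "W")

#' Physiochemical constant registry
#'
#' All residue-level constants used by the calculators, named so outputs can
#' record exactly which tables produced them.
#'
#' @param pka_set `"emboss"` (default) or `"expasy"` (Bjellqvist-style).
#' @return A list with `hydropathy` (Kyte-Doolittle), `mass_average`,
#'   `mass_monoisotopic`, `water_average`, `water_monoisotopic`, `pka`
#'   (N-/C-terminus and side-chain pKa values), `pka_set` and
#'   `hydrophobic_set`.
#' @export
scale_registry <- function(pka_set = c("emboss", "expasy")) {
  pka_set <- match.arg(pka_set)
  list(hydropathy = .kd_hydropathy,
       mass_average = .aa_mass_average,
       mass_monoisotopic = .aa_mass_mono,
       water_average = .water_average,
       water_monoisotopic = .water_mono,
       pka = .pka_sets[[pka_set]],
       pka_set = pka_set,
       hydrophobic_set = .default_hydrophobic)
}

.check_seq <- function(seq) {
  if (!is.character(seq) || length(seq) == 0L || any(is.na(seq))) {
    abort("sequences must be a character vector without NA",
          class = "tcrcompare_error_domain")
  }
  pat <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$")
  bad <- !grepl(pat, seq)
  if (any(bad)) {
    abort(paste0("sequence '", seq[bad][1], "' contains a residue outside ",
                 "the 20 standard upper-case one-letter codes"),
          class = "tcrcompare_error_domain")
  }
  invisible(seq)
}

.aa_counts <- function(seqs) {
  m <- vapply(strsplit(seqs, "", fixed = TRUE),
              function(ch) tabulate(match(ch, AA_ALPHABET), nbins = 20L),
              numeric(20))
  m <- t(matrix(m, nrow = 20L))
  colnames(m) <- AA_ALPHABET
  m
}

#' Grand average of hydropathy (GRAVY)
#'
#' Mean Kyte-Doolittle hydropathy over the residues of each sequence.
#'
#' @param seq Character vector of amino-acid sequences.
#' @return Numeric vector of GRAVY scores.
#' @examples
#' gravy("IVL") # (4.5 + 4.2 + 3.8) / 3
#' @export
gravy <- function(seq) {
  .check_seq(seq)
  counts <- .aa_counts(seq)
  as.vector(counts %*% .kd_hydropathy[AA_ALPHABET]) / nchar(seq)
}

#' Hydrophobic residue fraction
#'
#' Fraction of residues belonging to the hydrophobic set. This is a distinct
#' readout from GRAVY: it counts membership rather than averaging a scale.
#'
#' @param seq Character vector of amino-acid sequences.
#' @param hydrophobic_set Residues counted as hydrophobic; defaults to
#'   A, C, F, I, L, M, V, W.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
hydrophobic_fraction <- function(seq, hydrophobic_set = .default_hydrophobic) {
  .check_seq(seq)
  if (any(!hydrophobic_set %in% AA_ALPHABET)) {
    abort("`hydrophobic_set` must contain standard residues only",
          class = "tcrcompare_error_domain")
  }
  counts <- .aa_counts(seq)
  rowSums(counts[, hydrophobic_set, drop = FALSE]) / nchar(seq)
}

#' Peptide molecular weight
#'
#' Sum of residue masses plus one water mass.
#'
#' @param seq Character vector of amino-acid sequences.
#' @param mode `"average"` or `"monoisotopic"`.
#' @return Numeric vector of masses in Da.
#' @examples
#' molecular_weight("G") # 57.0519 + 18.01528
#' @export
molecular_weight <- function(seq, mode = c("average", "monoisotopic")) {
  mode <- match.arg(mode)
  .check_seq(seq)
  counts <- .aa_counts(seq)
  if (mode == "average") {
    as.vector(counts %*% .aa_mass_average[AA_ALPHABET]) + .water_average
  } else {
    as.vector(counts %*% .aa_mass_mono[AA_ALPHABET]) + .water_mono
  }
}

# Ionisable-group counts and pKa values for a set of sequences.
.charge_groups <- function(seq, pka) {
  counts <- .aa_counts(seq)
  n <- length(seq)
  basic <- cbind(nterm = rep(1, n),
                 H = counts[, "H"], K = counts[, "K"], R = counts[, "R"])
  acidic <- cbind(cterm = rep(1, n),
                  D = counts[, "D"], E = counts[, "E"],
                  C = counts[, "C"], Y = counts[, "Y"])
  list(basic = basic,
       pk_basic = c(pka$nterm, pka$side[c("H", "K", "R")]),
       acidic = acidic,
       pk_acidic = c(pka$cterm, pka$side[c("D", "E", "C", "Y")]))
}

# Henderson-Hasselbalch net charge; `pH` is a scalar or one value per row.
.charge_at <- function(groups, pH) {
  ch <- numeric(nrow(groups$basic))
  for (g in seq_along(groups$pk_basic)) {
    ch <- ch + groups$basic[, g] / (1 + 10^(pH - groups$pk_basic[g]))
  }
  for (g in seq_along(groups$pk_acidic)) {
    ch <- ch - groups$acidic[, g] / (1 + 10^(groups$pk_acidic[g] - pH))
  }
  ch
}

#' Henderson-Hasselbalch net charge
#'
#' Sum of basic-group protonation occupancies (N-terminus, H, K, R) minus
#' acidic-group deprotonation occupancies (C-terminus, D, E, C, Y) at a
#' given pH. Strictly decreasing in pH for every sequence.
#'
#' @param seq Character vector of amino-acid sequences.
#' @param pH pH value(s) in (0, 14); a scalar or one value per sequence.
#' @param pka_set `"emboss"` or `"expasy"`.
#' @return Numeric vector of net charges.
#' @export
net_charge <- function(seq, pH, pka_set = c("emboss", "expasy")) {
  pka_set <- match.arg(pka_set)
  .check_seq(seq)
  if (!is.numeric(pH) || any(pH <= 0) || any(pH >= 14)) {
    abort("`pH` must lie in (0, 14)", class = "tcrcompare_error_domain")
  }
  n <- max(length(seq), length(pH))
  if (length(seq) == 1L) seq <- rep(seq, n)
  if (!length(pH) %in% c(1L, n) || length(seq) != n) {
    abort("`seq` and `pH` lengths are incompatible",
          class = "tcrcompare_error_domain")
  }
  groups <- .charge_groups(seq, .pka_sets[[pka_set]])
  .charge_at(groups, pH)
}

#' Theoretical isoelectric point
#'
#' The unique pH in (0, 14) at which the Henderson-Hasselbalch net charge is
#' zero, found by bisection (net charge is strictly decreasing in pH, so the
#' root exists and is unique: every peptide carries at least the N- and
#' C-terminal groups).
#'
#' @param seq Character vector of amino-acid sequences.
#' @param pka_set `"emboss"` or `"expasy"`.
#' @param tol Convergence tolerance on |net charge| (default 1e-6).
#' @param max_iter Maximum bisection iterations.
#' @return Numeric vector of pI values (pH units).
#' @examples
#' theoretical_pi("GG") # (8.6 + 3.6) / 2 under the EMBOSS set
#' @export
theoretical_pi <- function(seq, pka_set = c("emboss", "expasy"),
                           tol = 1e-6, max_iter = 200L) {
  pka_set <- match.arg(pka_set)
  .check_seq(seq)
  groups <- .charge_groups(seq, .pka_sets[[pka_set]])
  lo <- rep(0, length(seq))
  hi <- rep(14, length(seq))
  mid <- (lo + hi) / 2
  ch <- .charge_at(groups, mid)
  iter <- 0L
  while (any(abs(ch) >= tol) && iter < max_iter) {
    pos <- ch > 0
    lo[pos] <- mid[pos]
    hi[!pos] <- mid[!pos]
    mid <- (lo + hi) / 2
    ch <- .charge_at(groups, mid)
    iter <- iter + 1L
  }
  if (any(abs(ch) >= tol)) {
    abort("pI bisection failed to converge",
          class = "tcrcompare_error_numerical")
  }
  mid
}

#' Physiochemical profile of an appearance repertoire
#'
#' One record per unique CDR3-beta sequence of an appearance view, plus the
#' mean of every property over records. Appearance weighting means each
#' unique receptor contributes once, matching how pooled repertoires are
#' profiled.
#'
#' @param view An appearance-mode `repertoire_view`.
#' @param pka_set `"emboss"` or `"expasy"`.
#' @param hydrophobic_set See [hydrophobic_fraction()].
#' @return A list with `records` (tibble: `sequence`, `length`,
#'   `hydrophobic_fraction`, `gravy`, `mw_average`, `mw_monoisotopic`,
#'   `pi`), `means` (one-row tibble with `n_sequences`), and the constant
#'   identifiers `pka_set`, `hydrophobic_set`.
#' @export
physchem_profile <- function(view, pka_set = c("emboss", "expasy"),
                             hydrophobic_set = .default_hydrophobic) {
  stopifnot(inherits(view, "repertoire_view"))
  pka_set <- match.arg(pka_set)
  if (view$mode != "appearance") {
    abort("physchem_profile expects an appearance view (one count per receptor)",
          class = "tcrcompare_error_mode_mismatch")
  }
  seqs <- unique(view$clonotypes$cdr3b)
  records <- tibble(
    sequence = seqs,
    length = nchar(seqs),
    hydrophobic_fraction = hydrophobic_fraction(seqs, hydrophobic_set),
    gravy = gravy(seqs),
    mw_average = molecular_weight(seqs, "average"),
    mw_monoisotopic = molecular_weight(seqs, "monoisotopic"),
    pi = theoretical_pi(seqs, pka_set)
  )
  means <- tibble(
    n_sequences = nrow(records),
    hydrophobic_fraction = mean(records$hydrophobic_fraction),
    gravy = mean(records$gravy),
    mw_average = mean(records$mw_average),
    mw_monoisotopic = mean(records$mw_monoisotopic),
    pi = mean(records$pi)
  )
  list(records = records, means = means,
       pka_set = pka_set, hydrophobic_set = hydrophobic_set)
}
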