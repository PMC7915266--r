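# Twelve clonotype diversity indices computed from clone copy counts
# n_i (i = 1..S, N = sum n_i, p_i = n_i / N):
#   biodiversity            S (richness)
#   dominance               lambda = sum p_i^2
#   simpson                 1 - lambda
#   reciprocal_simpson      1 / lambda
#   shannon                 H = -sum p_i ln p_i (natural log)
#   menhinick               S / sqrt(N)
#   margalef                (S - 1) / ln N (0 when N = 1)
#   buzas_gibson            e^H / S
#   equitability            H / ln S (1 when S = 1)
#   berger_parker           d = max n_i / N
#   inverted_berger_parker  1 / d
#   gini                    sum_i (2i - S - 1) x_(i) / (S sum x), ascending
# Conventions follow the PAST software family; "biodiversity" is richness.

DIVERSITY_METRICS <- c("biodiversity", "simpson", "dominance",
                       "reciprocal_simpson", "shannon", "menhinick",
                       "buzas_gibson", "equitability", "berger_parker",
                       "inverted_berger_parker", "margalef", "gini")

#' Diversity report for one repertoire
#'
#' Computes the twelve diversity indices from clone copy counts (the
#' abundance weights of a donor repertoire).
#'
#' @param counts Positive integer clone sizes, one per unique clonotype.
#' @param label Repertoire label.
#' @param gini_correction If `TRUE`, multiplies the Gini coefficient by the
#'   small-sample factor `S / (S - 1)`.
#' @return A one-row tibble: `label`, `S`, `N` and the twelve metrics.
#' @examples
#' diversity_report(c(4, 3, 2, 1))
#' @export
diversity_report <- function(counts, label = "repertoire",
                             gini_correction = FALSE) {
  if (!is.numeric(counts) || length(counts) == 0L || any(is.na(counts)) ||
      any(counts <= 0) || any(counts != round(counts))) {
    abort("`counts` must be positive integer clone sizes",
          class = "tcrcompare_error_domain")
  }
  x <- as.numeric(counts)
  S <- length(x)
  N <- sum(x)
  p <- x / N
  lambda <- sum(p^2)
  H <- -sum(p * log(p))
  d <- max(x) / N
  xs <- sort(x)
  gini <- sum((2 * seq_len(S) - S - 1) * xs) / (S * sum(xs))
  if (gini_correction && S > 1L) gini <- gini * S / (S - 1)
  tibble(
    label = label, S = S, N = N,
    biodiversity = S,
    simpson = 1 - lambda,
    dominance = lambda,
    reciprocal_simpson = 1 / lambda,
    shannon = H,
    menhinick = S / sqrt(N),
    buzas_gibson = exp(H) / S,
    equitability = if (S == 1L) 1 else H / log(S),
    berger_parker = d,
    inverted_berger_parker = 1 / d,
    margalef = if (N == 1) 0 else (S - 1) / log(N),
    gini = gini
  )
}

#' Per-donor diversity reports
#'
#' Builds an abundance view per donor and reports the twelve indices from
#' its clone copy counts.
#'
#' @param clonotypes Clonotype tibble for one or more donors.
#' @return A tibble with one row per donor (plus a `cohort` column).
#' @export
donor_diversity <- function(clonotypes) {
  df <- as_clonotypes(clonotypes)
  donors <- unique(df$donor_id)
  out <- lapply(donors, function(d) {
    sub <- df[df$donor_id == d, , drop = FALSE]
    v <- make_view(sub, "abundance", label = d)
    rep_ <- diversity_report(v$clonotypes$weight, label = d)
    rep_$cohort <- sub$cohort[1]
    rep_
  })
  dplyr::bind_rows(out)
}

#' Cohort log2 fold changes in diversity
#'
#' For each metric, `log2fc = log2(mean_allo / mean_auto)` (direction:
#' allo over auto) with an optional pseudocount for zero means, and an exact
#' Mann-Whitney two-sided p value comparing the per-donor values.
#'
#' @param reports_allo,reports_auto Tibbles of per-donor reports (rows) as
#'   returned by [diversity_report()] / [donor_diversity()].
#' @param pseudocount Added to both means before the ratio; with the default
#'   0, a zero mean yields an explicit `undefined = TRUE` marker instead of
#'   a NaN.
#' @return A tibble (`metric`, `mean_allo`, `mean_auto`, `log2fc`, `p`,
#'   `undefined`) with attribute `direction = "allo_over_auto"`.
#' @export
cohort_log2fc <- function(reports_allo, reports_auto, pseudocount = 0) {
  if (nrow(reports_allo) == 0L || nrow(reports_auto) == 0L) {
    abort("both cohorts need at least one report",
          class = "tcrcompare_error_empty_input")
  }
  rows <- lapply(DIVERSITY_METRICS, function(m) {
    va <- reports_allo[[m]]
    vu <- reports_auto[[m]]
    ma <- mean(va) + pseudocount
    mu <- mean(vu) + pseudocount
    undefined <- (ma <= 0 || mu <= 0)
    tibble(
      metric = m,
      mean_allo = mean(va), mean_auto = mean(vu),
      log2fc = if (undefined) NA_real_ else log2(ma / mu),
      p = mann_whitney_exact(va, vu)$p,
      undefined = undefined
    )
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "direction") <- "allo_over_auto"
  out
}
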