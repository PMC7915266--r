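# Comparison statistics: a replicate-free two-way sum-of-squares variance
# partition ("% of total variation" between cohorts and between categories)
# and an exact small-sample Mann-Whitney test by full enumeration of
# labelings.

#' Two-way sum-of-squares variance partition
#'
#' Fixed-effects decomposition of a cohort x category grid with one value
#' per cell: `SS_total = sum((x - grand mean)^2)`, `SS_cohort` from row
#' means, `SS_category` from column means, and the remainder (which absorbs
#' the interaction, inseparable without replicates) reported as residual.
#' Percentages are `100 * SS / SS_total` and sum to 100.
#'
#' @param table Numeric matrix; rows are cohorts, columns are categories
#'   (e.g. genes or CDR3 lengths), at least 2 x 2.
#' @return A list of class `variance_partition` with `ss_total`,
#'   `ss_cohort`, `ss_category`, `ss_residual`, `percent_cohort`,
#'   `percent_category`, `percent_residual` and `undefined` (`TRUE` for a
#'   constant table, where the partition does not exist).
#' @export
variance_partition <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m) || nrow(m) < 2L || ncol(m) < 2L || anyNA(m)) {
    abort("`table` must be a numeric matrix with >= 2 rows and >= 2 columns",
          class = "tcrcompare_error_domain")
  }
  grand <- mean(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total == 0) {
    return(structure(list(ss_total = 0, ss_cohort = 0, ss_category = 0,
                          ss_residual = 0, percent_cohort = NA_real_,
                          percent_category = NA_real_,
                          percent_residual = NA_real_, undefined = TRUE),
                     class = "variance_partition"))
  }
  ss_cohort <- ncol(m) * sum((rowMeans(m) - grand)^2)
  ss_category <- nrow(m) * sum((colMeans(m) - grand)^2)
  ss_residual <- max(ss_total - ss_cohort - ss_category, 0)
  structure(list(
    ss_total = ss_total, ss_cohort = ss_cohort,
    ss_category = ss_category, ss_residual = ss_residual,
    percent_cohort = 100 * ss_cohort / ss_total,
    percent_category = 100 * ss_category / ss_total,
    percent_residual = 100 * ss_residual / ss_total,
    undefined = FALSE
  ), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  if (x$undefined) {
    cat("<variance_partition> undefined (constant table)\n")
  } else {
    cat(sprintf(
      "<variance_partition> cohort %.2f%% | category %.2f%% | residual %.2f%%\n",
      x$percent_cohort, x$percent_category, x$percent_residual))
  }
  invisible(x)
}

#' Exact Mann-Whitney U test
#'
#' U from rank sums with midranks for ties; the p value is exact, from full
#' enumeration of all `choose(n_a + n_b, n_a)` labelings of the pooled
#' sample (two-sided p = min(1, 2 * one-sided), where the one-sided p is the
#' smaller tail of the permutation distribution of U). Designed for the
#' small cohort sizes of donor-level comparisons; beyond `exact_limit`
#' total observations it falls back to the tie-corrected normal
#' approximation with a logged note.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param exact_limit Largest `n_a + n_b` for exact enumeration.
#' @return A list with `U` (statistic of sample `a`), `p` (two-sided) and
#'   `method` (`"exact"` or `"normal_approximation"`).
#' @examples
#' mann_whitney_exact(c(1, 2, 3), c(4, 5, 6)) # U = 0, p = 0.10
#' @export
mann_whitney_exact <- function(a, b, exact_limit = 12L) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) == 0L ||
      length(b) == 0L || anyNA(a) || anyNA(b)) {
    abort("`a` and `b` must be non-empty numeric vectors",
          class = "tcrcompare_error_domain")
  }
  na <- length(a)
  nb <- length(b)
  n <- na + nb
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (n <= exact_limit) {
    idx <- combn(n, na)
    u_all <- colSums(matrix(r[idx], nrow = na)) - na * (na + 1) / 2
    eps <- 1e-9
    p_lo <- mean(u_all <= u_obs + eps)
    p_hi <- mean(u_all >= u_obs - eps)
    p <- min(1, 2 * min(p_lo, p_hi))
    method <- "exact"
  } else {
    inform(paste0("n = ", n, " exceeds exact_limit = ", exact_limit,
                  "; using the normal approximation"))
    mu <- na * nb / 2
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(na * nb / 12 * (n + 1 - tie_term))
    if (sigma == 0) {
      p <- 1
    } else {
      z <- (abs(u_obs - mu) - 0.5) / sigma
      p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    }
    method <- "normal_approximation"
  }
  list(U = u_obs, p = p, method = method)
}
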