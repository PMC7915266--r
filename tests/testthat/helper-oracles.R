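# Independent oracles: literal-formula diversity, grid-search pI,
# permutation Mann-Whitney, and hypergeometric Fisher enumeration. These
# deliberately re-derive each quantity along a different route from the
# package implementation.

# Literal formulas over unsorted counts; Gini via the mean-absolute-
# difference definition rather than the sorted-covariance form.
oracle_diversity <- function(x) {
  x <- as.numeric(x)
  N <- sum(x)
  S <- length(x)
  p <- x / N
  H <- -sum(p * log(p))
  gini <- sum(abs(outer(x, x, "-"))) / (2 * S^2 * mean(x))
  list(
    biodiversity = S,
    simpson = 1 - sum(p * p),
    dominance = sum(p * p),
    reciprocal_simpson = 1 / sum(p * p),
    shannon = H,
    menhinick = S / sqrt(N),
    buzas_gibson = exp(H) / S,
    equitability = if (S == 1) 1 else H / log(S),
    berger_parker = max(x) / N,
    inverted_berger_parker = N / max(x),
    margalef = if (N == 1) 0 else (S - 1) / log(N),
    gini = gini
  )
}

# Grid-search pI with its own Henderson-Hasselbalch implementation and its
# own copy of the EMBOSS pKa constants: coarse 0.01 scan refined to a 1e-4
# grid around the minimum-|charge| point.
oracle_pi_grid <- function(seq) {
  pk_side <- c(C = 8.5, D = 3.9, E = 4.1, H = 6.5,
               K = 10.8, R = 12.5, Y = 10.1)
  chars <- strsplit(seq, "")[[1]]
  nb <- c(sum(chars == "H"), sum(chars == "K"), sum(chars == "R"))
  pkb <- c(pk_side[["H"]], pk_side[["K"]], pk_side[["R"]])
  na_ <- c(sum(chars == "D"), sum(chars == "E"),
           sum(chars == "C"), sum(chars == "Y"))
  pka <- c(pk_side[["D"]], pk_side[["E"]], pk_side[["C"]], pk_side[["Y"]])
  charge <- function(ph) {
    pos <- 1 / (1 + 10^(ph - 8.6)) +
      sum(nb / (1 + 10^(ph - pkb)))
    neg <- 1 / (1 + 10^(3.6 - ph)) +
      sum(na_ / (1 + 10^(pka - ph)))
    pos - neg
  }
  coarse <- seq(0.01, 13.99, by = 0.01)
  ch <- vapply(coarse, charge, numeric(1))
  centre <- coarse[which.min(abs(ch))]
  fine <- seq(max(centre - 0.02, 1e-4), min(centre + 0.02, 14 - 1e-4),
              by = 1e-4)
  chf <- vapply(fine, charge, numeric(1))
  fine[which.min(abs(chf))]
}

# Full enumeration of the permutation distribution of the rank sum of
# sample `a`; two-sided p as twice the smaller tail, capped at 1.
oracle_rank_perm_p <- function(a, b) {
  n <- length(a) + length(b)
  r <- rank(c(a, b))
  sets <- utils::combn(n, length(a))
  w_obs <- sum(r[seq_along(a)])
  w_all <- apply(sets, 2, function(i) sum(r[i]))
  p1 <- min(mean(w_all <= w_obs + 1e-9), mean(w_all >= w_obs - 1e-9))
  min(1, 2 * p1)
}

# Two-sided Fisher p by direct hypergeometric enumeration: sum of all table
# probabilities no larger than the observed one.
oracle_fisher_p <- function(x11, x12, x21, x22) {
  m <- x11 + x21
  n_ <- x12 + x22
  k <- x11 + x12
  supp <- max(0, k - n_):min(k, m)
  probs <- stats::dhyper(supp, m, n_, k)
  p_obs <- stats::dhyper(x11, m, n_, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
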