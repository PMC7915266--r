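# Interior k-mer CDR3 motif enumeration with cohort enrichment and
# exclusivity flags. Motifs are exact contiguous k-mers of CDR3 interiors
# (conserved ends trimmed), counted by per-sequence presence: a sequence
# contributes at most once to each motif regardless of how often the motif
# occurs inside it. A motif table keeps every observed motif with a
# `retained` flag (>= min_sequences supporting sequences) so that pairwise
# comparisons have the full contingency counts available.

#' CDR3 interior
#'
#' Removes `trim_n` leading and `trim_c` trailing residues (the conserved
#' anchor-proximal ends). Sequences too short to trim return `NA` so batch
#' callers can skip them with a logged count rather than fail.
#'
#' @param seq Character vector of CDR3 sequences.
#' @param trim_n,trim_c Non-negative trim lengths.
#' @return Character vector of interiors (`NA` where
#'   `nchar(seq) <= trim_n + trim_c`).
#' @examples
#' interior("CASSYGQGAYEQYF", 3, 3) # "SYGQGAYE"
#' @export
interior <- function(seq, trim_n = 3L, trim_c = 3L) {
  if (trim_n < 0 || trim_c < 0) {
    abort("trim lengths must be non-negative",
          class = "tcrcompare_error_domain")
  }
  len <- nchar(seq)
  out <- rep(NA_character_, length(seq))
  ok <- !is.na(seq) & len > trim_n + trim_c
  out[ok] <- substr(seq[ok], trim_n + 1L, len[ok] - trim_c)
  out
}

.kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, seq_len(n - k + 1L), seq(k, n)))
}

#' Interior k-mer motif table
#'
#' Enumerates contiguous k-mers of the CDR3-beta interiors of an appearance
#' view and counts, for each motif, the number of distinct sequences
#' containing it. Motifs supported by at least `min_sequences` sequences
#' are flagged `retained`; all observed motifs are kept in the table so
#' comparisons can build full contingency counts.
#'
#' @param view An appearance-mode `repertoire_view`.
#' @param k_values Integer k-mer lengths (default 2, 3, 4).
#' @param trim_n,trim_c Interior trims (default 3 and 3).
#' @param min_sequences Retention threshold (default 2).
#' @return A tibble (`motif`, `k`, `sequences_containing`, `fraction`,
#'   `retained`) of class `motif_table`, with attributes `k_values`,
#'   `trim_n`, `trim_c`, `min_sequences`, `n_sequences`, `coverage`
#'   (fraction of sequences containing >= 1 retained motif) and `label`.
#' @export
motif_counts <- function(view, k_values = c(2L, 3L, 4L),
                         trim_n = 3L, trim_c = 3L, min_sequences = 2L) {
  stopifnot(inherits(view, "repertoire_view"))
  if (view$mode != "appearance") {
    abort("motif_counts expects an appearance view (presence semantics)",
          class = "tcrcompare_error_mode_mismatch")
  }
  k_values <- sort(unique(as.integer(k_values)))
  if (length(k_values) == 0L || any(k_values < 1L)) {
    abort("`k_values` must be positive integers",
          class = "tcrcompare_error_config")
  }
  seqs <- unique(view$clonotypes$cdr3b)
  ints <- interior(seqs, trim_n, trim_c)
  skipped <- sum(is.na(ints))
  if (skipped > 0L) {
    inform(paste0("skipped ", skipped,
                  " sequence(s) too short for trimming"))
  }
  ints <- ints[!is.na(ints)]
  if (length(ints) == 0L) {
    abort("no sequences survive interior trimming",
          class = "tcrcompare_error_empty_input")
  }
  per_seq <- lapply(ints, function(s) {
    unlist(lapply(k_values, function(k) .kmers(s, k)), use.names = FALSE)
  })
  kmer_pool <- unlist(per_seq, use.names = FALSE)
  if (length(kmer_pool) == 0L) {
    abort("no k-mers: every interior is shorter than the smallest k",
          class = "tcrcompare_error_empty_input")
  }
  counts <- table(kmer_pool)
  n_seq <- length(ints)
  out <- tibble(
    motif = names(counts),
    k = nchar(names(counts)),
    sequences_containing = as.integer(counts),
    fraction = as.integer(counts) / n_seq,
    retained = as.integer(counts) >= min_sequences
  )
  out <- out[order(-out$sequences_containing, out$motif), ]
  retained_set <- out$motif[out$retained]
  coverage <- if (length(retained_set) == 0L) 0 else {
    mean(vapply(per_seq, function(km) any(km %in% retained_set), logical(1)))
  }
  structure(out, k_values = k_values, trim_n = trim_n, trim_c = trim_c,
            min_sequences = min_sequences, n_sequences = n_seq,
            coverage = coverage, label = view$label,
            class = c("motif_table", class(out)))
}

#' Motif breadth of a repertoire
#'
#' @param table A `motif_table`.
#' @return A list with `n_motifs` (retained motifs) and `coverage`
#'   (fraction of sequences containing at least one retained motif).
#' @export
motif_breadth <- function(table) {
  stopifnot(inherits(table, "motif_table"))
  list(n_motifs = sum(table$retained),
       coverage = attr(table, "coverage"))
}

#' Compare motif tables between two cohorts
#'
#' For every motif retained in at least one table: per-cohort fractions, a
#' pseudocount-stabilised fold change, Fisher's exact two-sided p on the
#' 2 x 2 presence table, Benjamini-Hochberg q values across motifs, and an
#' exclusivity flag (`"a"`/`"b"` when the motif passes the retention
#' threshold in exactly one cohort — i.e. is "identified" only there —
#' `"none"` otherwise).
#'
#' @param table_a,table_b `motif_table` objects built with identical
#'   `k_values`, trims and threshold.
#' @param epsilon Pseudo-fraction added to numerator and denominator of the
#'   fold change (default 1e-6).
#' @return A tibble (`motif`, `k`, `count_a`, `count_b`, `fraction_a`,
#'   `fraction_b`, `fold`, `p`, `q`, `exclusive`).
#' @export
motif_compare <- function(table_a, table_b, epsilon = 1e-6) {
  stopifnot(inherits(table_a, "motif_table"), inherits(table_b, "motif_table"))
  for (at in c("k_values", "trim_n", "trim_c", "min_sequences")) {
    if (!identical(attr(table_a, at), attr(table_b, at))) {
      abort(paste0("motif tables were built with different `", at, "`"),
            class = "tcrcompare_error_config")
    }
  }
  n_a <- attr(table_a, "n_sequences")
  n_b <- attr(table_b, "n_sequences")
  motifs <- union(table_a$motif[table_a$retained],
                  table_b$motif[table_b$retained])
  ca <- setNames(table_a$sequences_containing, table_a$motif)[motifs]
  cb <- setNames(table_b$sequences_containing, table_b$motif)[motifs]
  ca[is.na(ca)] <- 0L
  cb[is.na(cb)] <- 0L
  ra <- motifs %in% table_a$motif[table_a$retained]
  rb <- motifs %in% table_b$motif[table_b$retained]
  fa <- ca / n_a
  fb <- cb / n_b
  p <- vapply(seq_along(motifs), function(i) {
    fisher.test(matrix(c(ca[i], n_a - ca[i], cb[i], n_b - cb[i]),
                       nrow = 2))$p.value
  }, numeric(1))
  exclusive <- rep("none", length(motifs))
  exclusive[ra & !rb] <- "a"
  exclusive[rb & !ra] <- "b"
  out <- tibble(
    motif = motifs, k = nchar(motifs),
    count_a = as.integer(ca), count_b = as.integer(cb),
    fraction_a = fa, fraction_b = fb,
    fold = (fa + epsilon) / (fb + epsilon),
    p = p, q = p.adjust(p, method = "BH"),
    exclusive = exclusive
  )
  out[order(out$p, out$motif), ]
}
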