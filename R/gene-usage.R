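# Gene-usage profiles, deployment counts, V-J pairing matrices (chord
# data) and CDR3 length spectra. All frequencies are computed on the weights
# of the chosen repertoire view, so every readout exists in both an
# abundance-normalised and an appearance-normalised form; the basis is
# recorded on every output.

#' Gene-usage profile of a repertoire view
#'
#' Percent usage per gene (allele-free) for one segment kind, weighted by
#' the view's basis. Clonotypes lacking a call for the segment are excluded
#' with a logged count.
#'
#' @param view A `repertoire_view`.
#' @param segment_kind One of `"TRBV"`, `"TRBJ"`, `"TRBD"`, `"TRAV"`,
#'   `"TRAJ"`.
#' @return A tibble (`gene`, `weight`, `percent`) with attributes
#'   `segment_kind`, `basis` and `total_observations`; class
#'   `usage_profile`.
#' @export
usage_profile <- function(view, segment_kind = c("TRBV", "TRBJ", "TRBD",
                                                 "TRAV", "TRAJ")) {
  stopifnot(inherits(view, "repertoire_view"))
  segment_kind <- match.arg(segment_kind)
  genes <- strip_allele(view$clonotypes[[tolower(segment_kind)]])
  w <- view$clonotypes$weight
  keep <- !is.na(genes)
  if (!any(keep)) {
    abort(paste0("no ", segment_kind, " calls in view '", view$label, "'"),
          class = "tcrcompare_error_empty_segment")
  }
  if (any(!keep)) {
    inform(paste0("excluded ", sum(!keep), " clonotype(s) without a ",
                  segment_kind, " call"))
  }
  agg <- rowsum(w[keep], genes[keep], reorder = TRUE)
  out <- tibble(gene = rownames(agg), weight = unname(agg[, 1]),
                percent = 100 * unname(agg[, 1]) / sum(agg[, 1]))
  structure(out, segment_kind = segment_kind, basis = view$mode,
            total_observations = sum(w[keep]),
            class = c("usage_profile", class(out)))
}

#' Gene deployment against a reference catalogue
#'
#' Counts how many distinct genes carry nonzero weight in the view.
#' Observed genes absent from the catalogue raise a logged warning and are
#' counted in `genes_used` but not in `catalogue_size`.
#'
#' @param view A `repertoire_view`.
#' @param segment_kind Segment kind (see [usage_profile()]).
#' @param catalogue Reference gene list; defaults to the bundled catalogue.
#' @return A list with `genes_used`, `catalogue_size`, `percent`.
#' @export
deployment <- function(view, segment_kind = c("TRBV", "TRBJ", "TRBD",
                                              "TRAV", "TRAJ"),
                       catalogue = NULL) {
  stopifnot(inherits(view, "repertoire_view"))
  segment_kind <- match.arg(segment_kind)
  catalogue <- catalogue %||% gene_catalogue(segment_kind)
  if (length(catalogue) == 0L) {
    abort("`catalogue` must be non-empty", class = "tcrcompare_error_config")
  }
  genes <- strip_allele(view$clonotypes[[tolower(segment_kind)]])
  observed <- unique(genes[!is.na(genes) & view$clonotypes$weight > 0])
  extra <- setdiff(observed, catalogue)
  if (length(extra) > 0L) {
    warn(paste0("observed gene(s) not in catalogue: ",
                paste(extra, collapse = ", ")))
  }
  list(genes_used = length(observed),
       catalogue_size = length(catalogue),
       percent = 100 * length(observed) / length(catalogue))
}

#' V-J pairing matrix (chord data)
#'
#' Accumulates view weight per (row gene, column gene) pair, e.g.
#' TRBV x TRBJ or TRAV x TRAJ. Clonotypes missing either call are excluded
#' with a logged count. Marginals reproduce the corresponding usage
#' profiles.
#'
#' @param view A `repertoire_view`.
#' @param row_kind,col_kind Segment kinds for rows and columns.
#' @return A long-format tibble (`row_gene`, `col_gene`, `weight`) with
#'   attributes `row_kind`, `col_kind`, `basis`; class `pairing_matrix`.
#' @export
pairing_matrix <- function(view, row_kind = "TRBV", col_kind = "TRBJ") {
  stopifnot(inherits(view, "repertoire_view"))
  row_kind <- match.arg(row_kind, SEGMENT_KINDS)
  col_kind <- match.arg(col_kind, SEGMENT_KINDS)
  rg <- strip_allele(view$clonotypes[[tolower(row_kind)]])
  cg <- strip_allele(view$clonotypes[[tolower(col_kind)]])
  keep <- !is.na(rg) & !is.na(cg)
  if (!any(keep)) {
    abort(paste0("no clonotypes carry both ", row_kind, " and ", col_kind,
                 " calls"),
          class = "tcrcompare_error_empty_segment")
  }
  if (any(!keep)) {
    inform(paste0("excluded ", sum(!keep), " clonotype(s) missing a ",
                  row_kind, " or ", col_kind, " call"))
  }
  key <- paste(rg[keep], cg[keep], sep = "\t")
  agg <- rowsum(view$clonotypes$weight[keep], key, reorder = TRUE)
  parts <- strsplit(rownames(agg), "\t", fixed = TRUE)
  out <- tibble(row_gene = vapply(parts, `[`, character(1), 1L),
                col_gene = vapply(parts, `[`, character(1), 2L),
                weight = unname(agg[, 1]))
  structure(out, row_kind = row_kind, col_kind = col_kind,
            basis = view$mode,
            class = c("pairing_matrix", class(out)))
}

#' Flat pairing records for chord-diagram export
#'
#' @param pm A `pairing_matrix`.
#' @return A plain tibble of (`row_gene`, `col_gene`, `weight`, `basis`).
#' @export
pairing_records <- function(pm) {
  stopifnot(inherits(pm, "pairing_matrix"))
  tibble(row_gene = pm$row_gene, col_gene = pm$col_gene,
         weight = pm$weight, basis = attr(pm, "basis"))
}

#' CDR3 length spectrum
#'
#' Percentage of view weight per CDR3 length (amino acids, anchors
#' included).
#'
#' @param view A `repertoire_view`.
#' @param chain `"cdr3b"` (default) or `"cdr3a"`.
#' @return A tibble (`length`, `weight`, `percent`) with attributes `basis`
#'   and `chain`; class `length_spectrum`.
#' @export
length_spectrum <- function(view, chain = c("cdr3b", "cdr3a")) {
  stopifnot(inherits(view, "repertoire_view"))
  chain <- match.arg(chain)
  seqs <- view$clonotypes[[chain]]
  keep <- !is.na(seqs)
  if (!any(keep)) {
    abort(paste0("no ", chain, " sequences in view"),
          class = "tcrcompare_error_empty_input")
  }
  if (any(!keep)) {
    inform(paste0("excluded ", sum(!keep), " clonotype(s) without ", chain))
  }
  len <- nchar(seqs[keep])
  agg <- rowsum(view$clonotypes$weight[keep], len, reorder = TRUE)
  out <- tibble(length = as.integer(rownames(agg)), weight = unname(agg[, 1]),
                percent = 100 * unname(agg[, 1]) / sum(agg[, 1]))
  structure(out, basis = view$mode, chain = chain,
            class = c("length_spectrum", class(out)))
}

#' Percentage of the spectrum below a length threshold
#'
#' @param spectrum A `length_spectrum`.
#' @param threshold Length threshold in amino acids (> 0).
#' @param inclusive If `TRUE`, lengths equal to `threshold` are included;
#'   the default is the strict reading of "under" (`length < threshold`).
#' @return Percentage in \[0, 100\].
#' @export
fraction_below <- function(spectrum, threshold, inclusive = FALSE) {
  stopifnot(inherits(spectrum, "length_spectrum"))
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    abort("`threshold` must be a positive length in amino acids",
          class = "tcrcompare_error_domain")
  }
  sel <- if (inclusive) spectrum$length <= threshold
         else spectrum$length < threshold
  sum(spectrum$percent[sel])
}
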