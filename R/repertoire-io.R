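# Clonotype tables, readers/writers, and abundance/appearance repertoire
# views. A clonotype table is a tibble with one row per observed paired-chain
# receptor; a repertoire view wraps a deduplicated table plus a weighting
# mode ("abundance" keeps copy numbers, "appearance" flattens every receptor
# to weight one).

.clonotype_columns <- c("donor_id", "cohort", "antigen",
                        "trav", "traj", "trbv", "trbd", "trbj",
                        "cdr3a", "cdr3b", "copies")

#' Parse an IMGT-style gene label
#'
#' Splits an allele suffix on `"*"`, normalises case and whitespace, and
#' infers the segment kind from the label prefix. Canonicalisation is
#' idempotent.
#'
#' @param label A single gene-call string, e.g. `"TRBV7-9"` or `"TRBD1*01"`.
#' @return A list with `segment_kind`, `gene_label` (allele-free) and
#'   `allele` (two-digit string or `NA`).
#' @examples
#' parse_gene_name("TRBD1*01")
#' parse_gene_name(" trbj2-7 ")
#' @export
parse_gene_name <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(trimws(label))) {
    abort("`label` must be a single non-empty string",
          class = "tcrcompare_error_malformed_gene")
  }
  lab <- toupper(gsub("[[:space:]]+", "", label))
  parts <- strsplit(lab, "*", fixed = TRUE)[[1]]
  gene <- parts[[1]]
  allele <- if (length(parts) > 1L && nzchar(parts[[2]])) parts[[2]] else NA_character_
  kind <- substr(gene, 1L, 4L)
  if (!kind %in% SEGMENT_KINDS) {
    abort(paste0("malformed gene label: '", label,
                 "' (expected a TRAV/TRAJ/TRBV/TRBD/TRBJ prefix)"),
          class = "tcrcompare_error_malformed_gene")
  }
  list(segment_kind = kind, gene_label = gene, allele = allele)
}

#' Strip allele suffixes from gene calls
#'
#' Vectorised canonicalisation to the gene level: uppercases, removes
#' whitespace and drops any `*NN` allele suffix. `NA` is preserved.
#'
#' @param x Character vector of gene calls.
#' @return Character vector of allele-free labels.
#' @examples
#' strip_allele(c("TRBV7-9*01", "trbd1"))
#' @export
strip_allele <- function(x) {
  out <- toupper(gsub("[[:space:]]+", "", x))
  sub("\\*.*$", "", out)
}

.canonical_call <- function(x, column) {
  out <- toupper(gsub("[[:space:]]+", "", x))
  out[!is.na(out) & out == ""] <- NA_character_
  ok <- is.na(out) | substr(out, 1L, 4L) %in% SEGMENT_KINDS
  if (!all(ok)) {
    abort(paste0("malformed gene label in column '", column, "': '",
                 x[!ok][1], "'"),
          class = "tcrcompare_error_malformed_gene")
  }
  out
}

.check_cdr3 <- function(x, column, allow_na = FALSE) {
  pat <- paste0("^[", paste(AA_ALPHABET, collapse = ""), "]+$")
  bad <- !grepl(pat, x)
  if (allow_na) bad <- bad & !is.na(x)
  if (any(bad)) {
    abort(paste0("column '", column, "' contains a non-standard amino-acid ",
                 "string: '", x[bad][1], "' (only the 20 one-letter codes, ",
                 "upper case, are accepted)"),
          class = "tcrcompare_error_domain")
  }
  invisible(x)
}

#' Validate and canonicalise a clonotype table
#'
#' Checks the full clonotype schema: cohort labels in `{auto, allo}` (or
#' `NA`), gene calls with recognised segment prefixes, CDR3 strings over the
#' 20 standard upper-case one-letter codes (ambiguity codes such as `X` or
#' `*` are rejected at ingest because downstream physiochemical math is
#' undefined for them), and positive integer copy numbers.
#'
#' @param df A data frame with columns `donor_id`, `cohort`, `antigen`,
#'   `trav`, `traj`, `trbv`, `trbd`, `trbj`, `cdr3a`, `cdr3b`, `copies`.
#' @return A validated tibble with canonicalised gene calls.
#' @export
as_clonotypes <- function(df) {
  df <- as_tibble(df)
  missing <- setdiff(.clonotype_columns, names(df))
  if (length(missing) > 0L) {
    abort(paste0("missing clonotype column(s): ",
                 paste(missing, collapse = ", ")),
          class = "tcrcompare_error_schema")
  }
  df <- df[.clonotype_columns]
  if (nrow(df) == 0L) {
    abort("empty clonotype table", class = "tcrcompare_error_empty_input")
  }
  bad_cohort <- !is.na(df$cohort) & !df$cohort %in% c("auto", "allo")
  if (any(bad_cohort)) {
    abort(paste0("cohort must be 'auto' or 'allo', got '",
                 df$cohort[bad_cohort][1], "'"),
          class = "tcrcompare_error_schema")
  }
  for (col in c("trav", "traj", "trbv", "trbd", "trbj")) {
    df[[col]] <- .canonical_call(df[[col]], col)
  }
  if (any(is.na(df$cdr3b))) {
    abort("cdr3b must be present for every clonotype",
          class = "tcrcompare_error_schema")
  }
  .check_cdr3(df$cdr3b, "cdr3b")
  .check_cdr3(df$cdr3a, "cdr3a", allow_na = TRUE)
  copies <- df$copies
  if (!is.numeric(copies) || any(is.na(copies)) ||
      any(copies != round(copies)) || any(copies < 1)) {
    abort("copies must be positive integers",
          class = "tcrcompare_error_domain")
  }
  df$copies <- as.integer(copies)
  df$donor_id <- as.character(df$donor_id)
  df
}

#' Read a clonotype table
#'
#' Reads annotated clonotypes from disk. The `simple_csv` dialect carries the
#' full paired-chain schema by name. The `airr_tsv` dialect reads an AIRR
#' Rearrangement-style TSV describing the beta chain (`v_call`, `d_call`,
#' `j_call`, `junction_aa`, `duplicate_count`, `repertoire_id`), with
#' optional `cohort` and `antigen` metadata columns; alpha-chain fields are
#' left `NA`. Rows with a missing CDR3-beta are dropped with a logged count.
#'
#' @param path Path to the file.
#' @param dialect `"simple_csv"` or `"airr_tsv"`.
#' @return A validated clonotype tibble in file order.
#' @export
read_clonotypes <- function(path, dialect = c("simple_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "tcrcompare_error_schema")
  }
  if (dialect == "simple_csv") {
    raw <- readr::read_csv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    missing <- setdiff(.clonotype_columns, names(raw))
    if (length(missing) > 0L) {
      abort(paste0("missing column(s) in ", path, ": ",
                   paste(missing, collapse = ", ")),
            class = "tcrcompare_error_schema")
    }
    df <- raw[.clonotype_columns]
    df$copies <- readr::parse_integer(df$copies)
  } else {
    raw <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(.default = "c"))
    req <- c("v_call", "d_call", "j_call", "junction_aa",
             "duplicate_count", "repertoire_id")
    missing <- setdiff(req, names(raw))
    if (length(missing) > 0L) {
      abort(paste0("missing AIRR column(s) in ", path, ": ",
                   paste(missing, collapse = ", ")),
            class = "tcrcompare_error_schema")
    }
    raw$duplicate_count <- readr::parse_integer(raw$duplicate_count)
    df <- tibble(
      donor_id = raw$repertoire_id,
      cohort   = if ("cohort" %in% names(raw)) raw$cohort else NA_character_,
      antigen  = if ("antigen" %in% names(raw)) raw$antigen else NA_character_,
      trav = NA_character_, traj = NA_character_,
      trbv = raw$v_call, trbd = raw$d_call, trbj = raw$j_call,
      cdr3a = NA_character_,
      cdr3b = raw$junction_aa,
      copies = raw$duplicate_count
    )
  }
  if (nrow(df) == 0L) {
    abort(paste0("no clonotype rows in ", path),
          class = "tcrcompare_error_empty_input")
  }
  drop <- is.na(df$cdr3b) | df$cdr3b == ""
  if (any(drop)) {
    inform(paste0("dropped ", sum(drop), " row(s) with missing cdr3b"))
    df <- df[!drop, ]
  }
  if (nrow(df) == 0L) {
    abort(paste0("no usable clonotype rows in ", path),
          class = "tcrcompare_error_empty_input")
  }
  as_clonotypes(df)
}

#' Write a clonotype table
#'
#' @param clonotypes A clonotype tibble (validated with [as_clonotypes()]).
#' @param path Output path.
#' @param dialect `"simple_csv"` (full paired-chain schema) or `"airr_tsv"`
#'   (beta-chain AIRR Rearrangement columns plus `cohort`/`antigen`).
#' @return `path`, invisibly.
#' @export
write_clonotypes <- function(clonotypes, path,
                             dialect = c("simple_csv", "airr_tsv")) {
  dialect <- match.arg(dialect)
  df <- as_clonotypes(clonotypes)
  if (dialect == "simple_csv") {
    readr::write_csv(df, path, na = "")
  } else {
    out <- tibble(
      repertoire_id = df$donor_id,
      cohort = df$cohort, antigen = df$antigen,
      v_call = df$trbv, d_call = df$trbd, j_call = df$trbj,
      junction_aa = df$cdr3b, duplicate_count = df$copies
    )
    readr::write_tsv(out, path, na = "")
  }
  invisible(path)
}

# Receptor identity: gene-level (allele-free) V/J calls of both chains plus
# both CDR3 strings; TRBD is excluded (short-segment calls are ambiguous).
.receptor_key <- function(df) {
  paste(
    ifelse(is.na(df$trav), "", strip_allele(df$trav)),
    ifelse(is.na(df$traj), "", strip_allele(df$traj)),
    ifelse(is.na(df$trbv), "", strip_allele(df$trbv)),
    ifelse(is.na(df$trbj), "", strip_allele(df$trbj)),
    ifelse(is.na(df$cdr3a), "", df$cdr3a),
    df$cdr3b,
    sep = "|"
  )
}

.collapse_receptors <- function(df) {
  key <- .receptor_key(df)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  out$copies <- as.integer(rowsum(as.numeric(df$copies), key,
                                  reorder = FALSE)[, 1])
  out
}

new_repertoire_view <- function(clonotypes, mode, label, seed = NULL) {
  structure(list(clonotypes = clonotypes, mode = mode,
                 label = label, seed = seed),
            class = "repertoire_view")
}

#' Build an abundance or appearance repertoire view
#'
#' Deduplicates identical receptors (same allele-free V/J calls of both
#' chains and both CDR3 strings; TRBD is ignored) and attaches a weight per
#' unique receptor. In abundance mode weights are summed copy numbers; in
#' appearance mode every receptor is decreased to weight one and the rows
#' are put in a seeded random order (the "randomly selected" step), with
#' optional seeded downsampling to `subsample` receptors.
#'
#' @param clonotypes Clonotype tibble.
#' @param mode `"abundance"` or `"appearance"`.
#' @param seed Integer seed; required in appearance mode.
#' @param label Free-text label; defaults to the donor ids present.
#' @param subsample Optional number of receptors to keep (appearance mode).
#' @return A `repertoire_view` object.
#' @export
make_view <- function(clonotypes, mode = c("abundance", "appearance"),
                      seed = NULL, label = NULL, subsample = NULL) {
  mode <- match.arg(mode)
  df <- as_clonotypes(clonotypes)
  coll <- .collapse_receptors(df)
  if (is.null(label)) {
    label <- paste(unique(coll$donor_id), collapse = "+")
  }
  if (mode == "abundance") {
    coll$weight <- as.numeric(coll$copies)
  } else {
    if (is.null(seed)) {
      abort("appearance views require an explicit `seed`",
            class = "tcrcompare_error_config")
    }
    seed <- .assert_scalar_int(seed, "seed")
    coll$weight <- 1
    perm <- .with_seed(seed, sample.int(nrow(coll)))
    coll <- coll[perm, , drop = FALSE]
    if (!is.null(subsample)) {
      subsample <- .assert_scalar_int(subsample, "subsample")
      if (subsample < 1L || subsample > nrow(coll)) {
        abort("`subsample` must be between 1 and the number of unique receptors",
              class = "tcrcompare_error_config")
      }
      coll <- coll[seq_len(subsample), , drop = FALSE]
    }
  }
  new_repertoire_view(coll, mode, label, seed)
}

#' Number of unique clonotypes in a view
#' @param view A `repertoire_view`.
#' @return Integer S.
#' @export
view_S <- function(view) {
  stopifnot(inherits(view, "repertoire_view"))
  nrow(view$clonotypes)
}

#' Total weight of a view
#'
#' Total copies in abundance mode; equals [view_S()] in appearance mode.
#' @param view A `repertoire_view`.
#' @return Numeric N.
#' @export
view_N <- function(view) {
  stopifnot(inherits(view, "repertoire_view"))
  sum(view$clonotypes$weight)
}

#' @export
print.repertoire_view <- function(x, ...) {
  cat("<repertoire_view> ", x$label, "\n",
      "  mode: ", x$mode,
      "  S = ", view_S(x), "  N = ", format(view_N(x)), "\n", sep = "")
  invisible(x)
}

#' Pool repertoire views
#'
#' Concatenates views of the same mode and re-deduplicates by receptor
#' identity: abundance weights are summed, appearance weights are re-set to
#' one. The pooled label records the source labels. Appearance pooling keeps
#' deterministic first-occurrence order (the seeded shuffle happens at view
#' construction).
#'
#' @param views A list of `repertoire_view` objects sharing one mode.
#' @return A pooled `repertoire_view`.
#' @export
pool_views <- function(views) {
  if (!is.list(views) || length(views) == 0L ||
      !all(vapply(views, inherits, logical(1), "repertoire_view"))) {
    abort("`views` must be a non-empty list of repertoire_view objects",
          class = "tcrcompare_error_config")
  }
  modes <- unique(vapply(views, function(v) v$mode, character(1)))
  if (length(modes) > 1L) {
    abort(paste0("cannot pool views with mixed modes: ",
                 paste(modes, collapse = ", ")),
          class = "tcrcompare_error_mode_mismatch")
  }
  df <- dplyr::bind_rows(lapply(views, function(v) v$clonotypes))
  key <- .receptor_key(df)
  first <- !duplicated(key)
  out <- df[first, , drop = FALSE]
  w <- rowsum(df$weight, key, reorder = FALSE)[, 1]
  cp <- as.integer(rowsum(as.numeric(df$copies), key, reorder = FALSE)[, 1])
  out$copies <- cp
  out$weight <- if (modes == "abundance") as.numeric(w) else 1
  label <- paste(vapply(views, function(v) v$label, character(1)),
                 collapse = "+")
  new_repertoire_view(out, modes, label, views[[1]]$seed)
}
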