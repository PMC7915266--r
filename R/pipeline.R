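# End-to-end orchestration: simulate or ingest clonotypes, build cohort
# views, and emit the full comparison bundle (usage, deployment, pairing,
# length spectra, physiochemistry, diversity with log2 fold changes,
# motifs, variance partitions) plus a JSON manifest recording every seed
# and constant-set identifier needed to regenerate the bundle. With a fixed
# config and seed the bundle is byte-identical across runs.

#' Pipeline configuration
#'
#' @param input Optional path to a clonotype file; when `NULL` the bundled
#'   simulator presets generate a paper-like study (3 auto + 3 allo donors).
#' @param dialect Input dialect, `"simple_csv"` or `"airr_tsv"`.
#' @param seed Integer seed (mandatory: appearance views and simulation are
#'   both seeded).
#' @param out_dir Optional output directory for the CSV/JSON bundle.
#' @param pka_set,hydrophobic_set Physiochemical constant choices.
#' @param k_values,trim_n,trim_c,min_sequences Motif parameters.
#' @param length_threshold CDR3 length threshold (aa) for the "fraction
#'   under" readout (default 13).
#' @param pseudocount Pseudocount for diversity log2 fold changes.
#' @param antigen Antigen label used when simulating.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(input = NULL, dialect = "simple_csv",
                            seed = NULL, out_dir = NULL,
                            pka_set = "emboss",
                            hydrophobic_set = .default_hydrophobic,
                            k_values = c(2L, 3L, 4L),
                            trim_n = 3L, trim_c = 3L, min_sequences = 2L,
                            length_threshold = 13L, pseudocount = 0,
                            antigen = "IMN") {
  if (is.null(seed)) {
    abort("`seed` is mandatory: appearance views and simulation are seeded",
          class = "tcrcompare_error_config")
  }
  seed <- .assert_scalar_int(seed, "seed")
  structure(list(input = input, dialect = dialect, seed = seed,
                 out_dir = out_dir, pka_set = pka_set,
                 hydrophobic_set = hydrophobic_set,
                 k_values = as.integer(k_values),
                 trim_n = as.integer(trim_n), trim_c = as.integer(trim_c),
                 min_sequences = as.integer(min_sequences),
                 length_threshold = as.integer(length_threshold),
                 pseudocount = pseudocount, antigen = antigen),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (or JSON, a YAML subset) document whose keys
#'   match the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0L) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "tcrcompare_error_config")
  }
  do.call(pipeline_config, cfg)
}

# Per-cohort pooled views in both bases. Donor-level appearance views get
# distinct sub-seeds derived from the master seed.
.cohort_views <- function(clonotypes, seed) {
  out <- list()
  for (co in c("auto", "allo")) {
    sub <- clonotypes[clonotypes$cohort == co, , drop = FALSE]
    if (nrow(sub) == 0L) {
      abort(paste0("no clonotypes for cohort '", co, "'"),
            class = "tcrcompare_error_empty_input")
    }
    donors <- unique(sub$donor_id)
    ab <- lapply(donors, function(d) {
      make_view(sub[sub$donor_id == d, , drop = FALSE], "abundance",
                label = d)
    })
    ap <- lapply(seq_along(donors), function(i) {
      make_view(sub[sub$donor_id == donors[i], , drop = FALSE], "appearance",
                seed = seed + 7919L * i + ifelse(co == "auto", 0L, 104729L),
                label = donors[i])
    })
    out[[co]] <- list(donors = donors,
                      abundance = ab, appearance = ap,
                      pooled_abundance = pool_views(ab),
                      pooled_appearance = pool_views(ap))
  }
  out
}

.usage_table <- function(views, segment_kind) {
  rows <- list()
  for (co in c("auto", "allo")) {
    for (basis in c("abundance", "appearance")) {
      v <- views[[co]][[paste0("pooled_", basis)]]
      up <- usage_profile(v, segment_kind)
      rows[[paste(co, basis)]] <- tibble(
        segment = segment_kind, cohort = co, basis = basis,
        gene = up$gene, weight = up$weight, percent = up$percent
      )
    }
  }
  dplyr::bind_rows(rows)
}

# cohort x category percent grid for the variance partition.
.usage_grid <- function(usage_tbl, basis) {
  sub <- usage_tbl[usage_tbl$basis == basis, , drop = FALSE]
  wide <- tidyr::pivot_wider(sub[c("cohort", "gene", "percent")],
                             names_from = "gene", values_from = "percent",
                             values_fill = 0)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$cohort
  m
}

#' Run the full comparison pipeline
#'
#' Executes every analysis stage on either a supplied clonotype file or a
#' simulated paper-like study, and (when `out_dir` is set) writes the table
#' bundle plus `manifest.json`. Stage failures abort with the stage name.
#'
#' @param config A `pipeline_config`.
#' @return Invisibly, a named list of all result tables and objects.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)),
            class = "tcrcompare_error_pipeline")
    })
  }

  clonotypes <- stage("input", {
    if (is.null(config$input)) {
      simulate_study(cohort_preset("auto_like"), cohort_preset("allo_like"),
                     seed = config$seed, antigen = config$antigen)$clonotypes
    } else {
      read_clonotypes(config$input, config$dialect)
    }
  })

  views <- stage("views", .cohort_views(clonotypes, config$seed))

  usage <- stage("usage", dplyr::bind_rows(
    .usage_table(views, "TRBV"),
    .usage_table(views, "TRBJ"),
    .usage_table(views, "TRBD")
  ))

  deployment_tbl <- stage("deployment", {
    rows <- list()
    for (co in c("auto", "allo")) {
      for (sk in c("TRBV", "TRBJ", "TRAV", "TRAJ")) {
        d <- deployment(views[[co]]$pooled_appearance, sk)
        rows[[paste(co, sk)]] <- tibble(
          cohort = co, segment = sk, genes_used = d$genes_used,
          catalogue_size = d$catalogue_size, percent = d$percent
        )
      }
    }
    dplyr::bind_rows(rows)
  })

  pairing <- stage("pairing", {
    rows <- list()
    for (co in c("auto", "allo")) {
      for (pair in list(c("TRBV", "TRBJ"), c("TRAV", "TRAJ"))) {
        pm <- pairing_matrix(views[[co]]$pooled_abundance,
                             pair[1], pair[2])
        rec <- pairing_records(pm)
        rec$cohort <- co
        rec$pairing <- paste(pair, collapse = "-")
        rows[[paste(co, pair[1])]] <- rec
      }
    }
    dplyr::bind_rows(rows)
  })

  spectra <- stage("length_spectrum", {
    rows <- list()
    frac <- list()
    for (co in c("auto", "allo")) {
      for (basis in c("abundance", "appearance")) {
        sp <- length_spectrum(views[[co]][[paste0("pooled_", basis)]])
        rows[[paste(co, basis)]] <- tibble(
          cohort = co, basis = basis,
          length = sp$length, weight = sp$weight, percent = sp$percent
        )
        frac[[paste(co, basis)]] <- tibble(
          cohort = co, basis = basis,
          threshold = config$length_threshold,
          percent_below = fraction_below(sp, config$length_threshold)
        )
      }
    }
    list(spectrum = dplyr::bind_rows(rows),
         fraction_below = dplyr::bind_rows(frac))
  })

  physchem <- stage("physchem", {
    recs <- list()
    means <- list()
    for (co in c("auto", "allo")) {
      pp <- physchem_profile(views[[co]]$pooled_appearance,
                             pka_set = config$pka_set,
                             hydrophobic_set = config$hydrophobic_set)
      r <- pp$records
      r$cohort <- co
      recs[[co]] <- r
      m <- pp$means
      m$cohort <- co
      means[[co]] <- m
    }
    list(records = dplyr::bind_rows(recs), means = dplyr::bind_rows(means))
  })

  diversity <- stage("diversity", {
    donors <- donor_diversity(clonotypes)
    cohort_tbl <- cohort_log2fc(donors[donors$cohort == "allo", ],
                                donors[donors$cohort == "auto", ],
                                pseudocount = config$pseudocount)
    list(per_donor = donors, cohort = cohort_tbl)
  })

  motifs <- stage("motifs", {
    ta <- motif_counts(views$auto$pooled_appearance,
                       k_values = config$k_values,
                       trim_n = config$trim_n, trim_c = config$trim_c,
                       min_sequences = config$min_sequences)
    tb <- motif_counts(views$allo$pooled_appearance,
                       k_values = config$k_values,
                       trim_n = config$trim_n, trim_c = config$trim_c,
                       min_sequences = config$min_sequences)
    cmp <- motif_compare(tb, ta)
    names(cmp)[names(cmp) == "count_a"] <- "count_allo"
    names(cmp)[names(cmp) == "count_b"] <- "count_auto"
    names(cmp)[names(cmp) == "fraction_a"] <- "fraction_allo"
    names(cmp)[names(cmp) == "fraction_b"] <- "fraction_auto"
    cmp$exclusive <- c(a = "allo", b = "auto",
                       none = "none")[cmp$exclusive]
    ba <- motif_breadth(ta)
    bb <- motif_breadth(tb)
    breadth <- tibble(cohort = c("auto", "allo"),
                      n_motifs = c(ba$n_motifs, bb$n_motifs),
                      coverage = c(ba$coverage, bb$coverage))
    list(auto = ta, allo = tb, compare = cmp, breadth = breadth)
  })

  variance <- stage("variance_partition", {
    rows <- list()
    grids <- list()
    for (basis in c("abundance", "appearance")) {
      for (sk in c("TRBV", "TRBJ")) {
        g <- .usage_grid(usage[usage$segment == sk, , drop = FALSE], basis)
        grids[[paste(sk, basis)]] <- g
        vp <- variance_partition(g)
        rows[[paste(sk, basis)]] <- tibble(
          analysis = paste0(sk, "_usage"), basis = basis,
          percent_cohort = vp$percent_cohort,
          percent_category = vp$percent_category,
          percent_residual = vp$percent_residual
        )
      }
      sp <- spectra$spectrum[spectra$spectrum$basis == basis, , drop = FALSE]
      wide <- tidyr::pivot_wider(sp[c("cohort", "length", "percent")],
                                 names_from = "length",
                                 values_from = "percent", values_fill = 0)
      g <- as.matrix(wide[, -1, drop = FALSE])
      rownames(g) <- wide$cohort
      vp <- variance_partition(g)
      rows[[paste("len", basis)]] <- tibble(
        analysis = "CDR3_length", basis = basis,
        percent_cohort = vp$percent_cohort,
        percent_category = vp$percent_category,
        percent_residual = vp$percent_residual
      )
    }
    dplyr::bind_rows(rows)
  })

  result <- list(
    clonotypes = clonotypes, views = views, usage = usage,
    deployment = deployment_tbl, pairing = pairing,
    spectrum = spectra$spectrum, fraction_below = spectra$fraction_below,
    physchem_records = physchem$records, physchem_means = physchem$means,
    diversity_per_donor = diversity$per_donor,
    diversity_cohort = diversity$cohort,
    motif_auto = motifs$auto, motif_allo = motifs$allo,
    motif_compare = motifs$compare, motif_breadth = motifs$breadth,
    variance_partition = variance,
    config = config
  )

  if (!is.null(config$out_dir)) {
    stage("write_bundle", .write_bundle(result, config))
  }
  invisible(result)
}

.write_bundle <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(config$out_dir, name)
  write_clonotypes(result$clonotypes, out("clonotypes.csv"))
  readr::write_csv(result$usage, out("usage.csv"))
  readr::write_csv(result$deployment, out("deployment.csv"))
  readr::write_csv(result$pairing, out("pairing.csv"))
  jsonlite::write_json(result$pairing, out("pairing_chord.json"),
                       dataframe = "rows", digits = NA)
  readr::write_csv(result$spectrum, out("length_spectrum.csv"))
  readr::write_csv(result$fraction_below, out("length_fraction_below.csv"))
  readr::write_csv(result$physchem_records, out("physchem_records.csv"))
  readr::write_csv(result$physchem_means, out("physchem_means.csv"))
  readr::write_csv(result$diversity_per_donor, out("diversity_per_donor.csv"))
  readr::write_csv(result$diversity_cohort, out("diversity_cohort.csv"))
  readr::write_csv(as_tibble(result$motif_auto), out("motifs_auto.csv"))
  readr::write_csv(as_tibble(result$motif_allo), out("motifs_allo.csv"))
  readr::write_csv(result$motif_compare, out("motif_compare.csv"))
  readr::write_csv(result$motif_breadth, out("motif_breadth.csv"))
  readr::write_csv(result$variance_partition, out("variance_partition.csv"))
  manifest <- list(
    package = "tcrcompare",
    version = as.character(utils::packageVersion("tcrcompare")),
    seed = config$seed,
    input = config$input %||% "simulated:paper_like",
    pka_set = config$pka_set,
    hydrophobic_set = paste(config$hydrophobic_set, collapse = ""),
    hydropathy_scale = "kyte_doolittle_1982",
    shannon_log_base = "e",
    k_values = config$k_values,
    trim_n = config$trim_n, trim_c = config$trim_c,
    min_sequences = config$min_sequences,
    length_threshold = config$length_threshold,
    pseudocount = config$pseudocount,
    direction = "allo_over_auto",
    files = c("clonotypes.csv", "usage.csv", "deployment.csv",
              "pairing.csv", "pairing_chord.json", "length_spectrum.csv",
              "length_fraction_below.csv", "physchem_records.csv",
              "physchem_means.csv", "diversity_per_donor.csv",
              "diversity_cohort.csv", "motifs_auto.csv", "motifs_allo.csv",
              "motif_compare.csv", "motif_breadth.csv",
              "variance_partition.csv")
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(config$out_dir)
}
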