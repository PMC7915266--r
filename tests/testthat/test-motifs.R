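test_that("interior trimming slices and skips as specified", {
  expect_equal(interior("CASSYGQGAYEQYF", 3, 3), "SYGQGAYE")
  expect_equal(interior("CASSYGQF", 0, 0), "CASSYGQF")
  expect_true(is.na(interior("CASF", 3, 3)))
  expect_error(interior("CASSYGQF", -1, 0),
               class = "tcrcompare_error_domain")
})

test_that("motif counting uses per-sequence presence semantics", {
  # interiors SYGQ and AYGQ share the 3-mer YGQ
  df <- clono_fixture(cdr3b = c("CASSYGQEQF", "CASAYGQEQF"))
  v <- make_view(df, "appearance", seed = 1)
  tab <- motif_counts(v, k_values = 3, trim_n = 3, trim_c = 3)
  expect_equal(tab$sequences_containing[tab$motif == "YGQ"], 2L)
  expect_true(tab$retained[tab$motif == "YGQ"])

  # "SS" occurs twice inside one interior but counts once
  df2 <- clono_fixture(cdr3b = c("CASSSSEQF", "CASSLGQEQF"))
  tab2 <- motif_counts(make_view(df2, "appearance", seed = 1),
                       k_values = 2, trim_n = 3, trim_c = 3,
                       min_sequences = 1)
  expect_equal(tab2$sequences_containing[tab2$motif == "SS"], 1L)

  # the default threshold drops singletons from the retained set
  expect_false(any(tab$retained & tab$sequences_containing < 2))

  expect_error(motif_counts(make_view(df, "abundance"), k_values = 3),
               class = "tcrcompare_error_mode_mismatch")
})

test_that("motif counts are order-invariant and additive over disjoint sets", {
  set.seed(41)
  df <- clono_fixture(cdr3b = random_cdr3(30, 12, 18))
  v1 <- make_view(df, "appearance", seed = 1)
  v2 <- make_view(df, "appearance", seed = 99) # different shuffle
  t1 <- motif_counts(v1, min_sequences = 1)
  t2 <- motif_counts(v2, min_sequences = 1)
  expect_equal(setNames(t1$sequences_containing, t1$motif),
               setNames(t2$sequences_containing, t2$motif))

  # union of disjoint repertoires sums per-motif counts
  dfa <- clono_fixture(cdr3b = random_cdr3(15, 12, 16), donor_id = "a")
  dfb <- clono_fixture(cdr3b = random_cdr3(15, 12, 16), donor_id = "b")
  stopifnot(length(intersect(dfa$cdr3b, dfb$cdr3b)) == 0)
  ta <- motif_counts(make_view(dfa, "appearance", seed = 1),
                     min_sequences = 1)
  tb <- motif_counts(make_view(dfb, "appearance", seed = 1),
                     min_sequences = 1)
  tu <- motif_counts(make_view(rbind(dfa, dfb), "appearance", seed = 1),
                     min_sequences = 1)
  ca <- setNames(ta$sequences_containing, ta$motif)
  cb <- setNames(tb$sequences_containing, tb$motif)
  for (m in tu$motif) {
    expect_equal(tu$sequences_containing[tu$motif == m],
                 sum(ca[m], cb[m], na.rm = TRUE),
                 label = paste("motif", m))
  }

  # k = interior length: exactly one motif per sequence
  df3 <- clono_fixture(cdr3b = random_cdr3(10, 14, 14))
  t3 <- motif_counts(make_view(df3, "appearance", seed = 1),
                     k_values = 8, min_sequences = 1)
  expect_equal(sum(t3$sequences_containing), 10L)
})

test_that("cohort comparison flags exclusivity and matches the Fisher oracle", {
  base_auto <- clono_fixture(cdr3b = paste0("CASS", c("LAPG", "MNHE", "WTRQ",
                                                      "KKEW", "PNHR"),
                                            "EQF"),
                             cohort = "auto")
  with_ygq <- clono_fixture(cdr3b = paste0("CAS", c("SYGQW", "AYGQK",
                                                    "TYGQL", "PMNDE",
                                                    "HWERT"), "EQF"),
                            cohort = "allo")
  ta <- motif_counts(make_view(with_ygq, "appearance", seed = 1),
                     k_values = 3)
  tb <- motif_counts(make_view(base_auto, "appearance", seed = 1),
                     k_values = 3)
  cmp <- motif_compare(ta, tb)
  ygq <- cmp[cmp$motif == "YGQ", ]
  expect_equal(ygq$count_a, 3L)
  expect_equal(ygq$count_b, 0L)
  expect_equal(ygq$exclusive, "a")

  # identical tables: folds exactly 1, nothing exclusive
  same <- motif_compare(ta, ta)
  expect_true(all(same$fold == 1))
  expect_true(all(same$exclusive == "none"))

  # Fisher p against hypergeometric enumeration for an 8/10 vs 1/10 table
  p_pkg <- stats::fisher.test(matrix(c(8, 2, 1, 9), nrow = 2))$p.value
  expect_equal(p_pkg, oracle_fisher_p(8, 2, 1, 9), tolerance = 1e-9)
  expect_lt(abs(p_pkg - 0.0055), 5e-4)

  mismatched <- motif_counts(make_view(base_auto, "appearance", seed = 1),
                             k_values = 2)
  expect_error(motif_compare(ta, mismatched),
               class = "tcrcompare_error_config")
})

test_that("motif breadth reports retained motifs and sequence coverage", {
  df <- clono_fixture(cdr3b = c("CASSYGQEQF", "CASAYGQEQF", "CASPMNDEQFF"))
  tab <- motif_counts(make_view(df, "appearance", seed = 1), k_values = 3)
  br <- motif_breadth(tab)
  expect_equal(br$n_motifs, sum(tab$retained))
  expect_equal(br$coverage, 2 / 3) # YGQ family covers 2 of 3 sequences

  # lowering the threshold can only increase coverage
  set.seed(43)
  dfr <- clono_fixture(cdr3b = random_cdr3(25, 12, 18))
  v <- make_view(dfr, "appearance", seed = 1)
  cov <- vapply(c(5, 3, 2, 1), function(th) {
    motif_breadth(motif_counts(v, min_sequences = th))$coverage
  }, numeric(1))
  expect_true(all(diff(cov) >= 0))
})
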