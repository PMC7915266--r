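test_that("gene labels are parsed, canonicalised and allele-split", {
  g <- parse_gene_name("TRBV7-9")
  expect_equal(g$segment_kind, "TRBV")
  expect_equal(g$gene_label, "TRBV7-9")
  expect_true(is.na(g$allele))

  g <- parse_gene_name("TRBD1*01")
  expect_equal(g[c("segment_kind", "gene_label", "allele")],
               list(segment_kind = "TRBD", gene_label = "TRBD1",
                    allele = "01"))

  g <- parse_gene_name(" trbj2-7 ")
  expect_equal(g$gene_label, "TRBJ2-7")

  # canonicalisation is idempotent
  again <- parse_gene_name(parse_gene_name("trbv5-4*02")$gene_label)
  expect_equal(again$gene_label, "TRBV5-4")

  expect_error(parse_gene_name("IGHV1-2"),
               class = "tcrcompare_error_malformed_gene")
  expect_error(parse_gene_name(""),
               class = "tcrcompare_error_malformed_gene")
})

test_that("simple_csv round-trips exactly and schema errors are explicit", {
  df <- clono_fixture(cdr3b = c("CASSYGQGAYEQYF", "CASSLAPGATNEKLFF",
                                "CSARDGGQETQYF"),
                      copies = c(5L, 2L, 1L),
                      donor_id = c("d1", "d1", "d2"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_clonotypes(df, path)
  back <- read_clonotypes(path)
  expect_equal(as.data.frame(back), as.data.frame(df))

  # missing mandatory column is named
  broken <- df[setdiff(names(df), "copies")]
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(broken, path2)
  expect_error(read_clonotypes(path2), "copies",
               class = "tcrcompare_error_schema")

  # header-only file
  path3 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(df[0, ], path3)
  expect_error(read_clonotypes(path3),
               class = "tcrcompare_error_empty_input")
})

test_that("AIRR TSV rows map onto beta-chain clonotypes", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "repertoire_id\tcohort\tv_call\td_call\tj_call\tjunction_aa\tduplicate_count",
    "d1\tauto\tTRBV7-9*01\tTRBD1*01\tTRBJ2-1*01\tCASSYGQGAYEQYF\t5",
    "d1\tauto\tTRBV5-4\tTRBD2\tTRBJ2-7\t\t1",
    "d2\tallo\tTRBV2\tTRBD1\tTRBJ1-1\tCASSLDRGEQFF\t1"
  ), path)
  expect_message(cl <- read_clonotypes(path, "airr_tsv"), "1 row")
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$cdr3b[1], "CASSYGQGAYEQYF")
  expect_equal(cl$copies[1], 5L)
  expect_equal(cl$trbv[1], "TRBV7-9*01")
  expect_true(all(is.na(cl$cdr3a)))
})

test_that("ambiguous residues and bad copies are rejected at ingest", {
  expect_error(as_clonotypes(clono_fixture("CASSXGQF")),
               class = "tcrcompare_error_domain")
  expect_error(as_clonotypes(clono_fixture("cassygqf")),
               class = "tcrcompare_error_domain")
  expect_error(as_clonotypes(clono_fixture("CASS*GQF")),
               class = "tcrcompare_error_domain")
  bad <- clono_fixture("CASSYGQF")
  bad$copies <- 0L
  expect_error(as_clonotypes(bad), class = "tcrcompare_error_domain")
})

test_that("views flatten, deduplicate and weight receptors correctly", {
  df <- clono_fixture(cdr3b = c("CASSYGQGAYEQYF", "CASSLAPGATNEKLFF",
                                "CSARDGGQETQYF"),
                      copies = c(5L, 2L, 1L))
  ap <- make_view(df, "appearance", seed = 1)
  expect_equal(ap$clonotypes$weight, c(1, 1, 1))
  expect_equal(view_S(ap), 3L)
  expect_equal(view_N(ap), 3)

  ab <- make_view(df, "abundance")
  expect_equal(view_S(ab), 3L)
  expect_equal(view_N(ab), 8)

  # identical receptors collapse, copies summed
  dup <- clono_fixture(cdr3b = c("CASSYGQF", "CASSYGQF"), copies = c(2L, 3L))
  abd <- make_view(dup, "abundance")
  expect_equal(view_S(abd), 1L)
  expect_equal(view_N(abd), 5)

  # TRBD and alleles are excluded from receptor identity
  dup2 <- clono_fixture(cdr3b = c("CASSYGQF", "CASSYGQF"),
                        trbd = c("TRBD1*01", "TRBD2*02"),
                        trbv = c("TRBV7-9*01", "TRBV7-9*02"),
                        copies = c(1L, 1L))
  expect_equal(view_S(make_view(dup2, "abundance")), 1L)
})

test_that("appearance shuffle is seed-stable and seeded subsampling works", {
  set.seed(42)
  df <- random_clonotypes(40)
  v1 <- make_view(df, "appearance", seed = 7)
  v2 <- make_view(df, "appearance", seed = 7)
  v3 <- make_view(df, "appearance", seed = 8)
  expect_identical(v1$clonotypes$cdr3b, v2$clonotypes$cdr3b)
  expect_false(identical(v1$clonotypes$cdr3b, v3$clonotypes$cdr3b))

  sub <- make_view(df, "appearance", seed = 7, subsample = 10)
  expect_equal(view_S(sub), 10L)
  expect_identical(sub$clonotypes$cdr3b, v1$clonotypes$cdr3b[1:10])

  expect_error(make_view(df, "appearance"),
               class = "tcrcompare_error_config")
})

test_that("N(abundance) >= N(appearance) = S, equal iff all copies are 1", {
  set.seed(11)
  for (i in 1:20) {
    df <- random_clonotypes(sample(5:30, 1), max_copies = sample(1:4, 1))
    ab <- make_view(df, "abundance")
    ap <- make_view(df, "appearance", seed = i)
    expect_equal(view_N(ap), view_S(ap))
    expect_equal(view_S(ab), view_S(ap))
    expect_gte(view_N(ab), view_N(ap))
    if (all(ab$clonotypes$copies == 1L)) {
      expect_equal(view_N(ab), view_N(ap))
    } else {
      expect_gt(view_N(ab), view_N(ap))
    }
    # identical receptor multisets across modes
    expect_setequal(tcrcompare:::.receptor_key(ab$clonotypes),
                    tcrcompare:::.receptor_key(ap$clonotypes))
  }
})

test_that("pooling concatenates, re-deduplicates and checks modes", {
  set.seed(3)
  mk <- function(n, donor) {
    make_view(random_clonotypes(n, donors = donor), "appearance", seed = 1)
  }
  vs <- list(mk(10, "a"), mk(12, "b"), mk(8, "c"))
  pooled <- pool_views(vs)
  expect_equal(view_S(pooled), 30L)
  expect_true(all(pooled$clonotypes$weight == 1))

  # shared receptor sums weights in abundance mode
  shared <- clono_fixture("CASSYGQF", copies = 2L, donor_id = "a")
  shared2 <- clono_fixture("CASSYGQF", copies = 3L, donor_id = "b")
  p2 <- pool_views(list(make_view(shared, "abundance"),
                        make_view(shared2, "abundance")))
  expect_equal(view_S(p2), 1L)
  expect_equal(view_N(p2), 5)

  # single-view pooling is the identity on content
  one <- make_view(clono_fixture("CASSYGQF"), "abundance")
  p1 <- pool_views(list(one))
  expect_equal(p1$clonotypes$cdr3b, one$clonotypes$cdr3b)
  expect_equal(view_N(p1), view_N(one))

  expect_error(pool_views(list(make_view(shared, "abundance"),
                               make_view(shared2, "appearance", seed = 1))),
               class = "tcrcompare_error_mode_mismatch")
})
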