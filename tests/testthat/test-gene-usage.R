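test_that("usage profiles are weight-based percentages on the view basis", {
  df <- clono_fixture(cdr3b = c("CASSYGQF", "CASSLGQF"),
                      trbv = c("TRBV2", "TRBV7-9"), copies = c(2L, 2L))
  up <- usage_profile(make_view(df, "abundance"), "TRBV")
  expect_equal(sort(up$percent), c(50, 50))
  expect_equal(attr(up, "basis"), "abundance")
  expect_equal(sum(up$percent), 100, tolerance = 1e-6)

  df2 <- clono_fixture(cdr3b = c("CASSYGQF", "CASSLGQF"),
                       trbv = c("TRBV2", "TRBV2*01"), copies = c(3L, 1L))
  df2$trbv[2] <- "TRBV7-9"
  df2$copies <- c(3L, 1L)
  up2 <- usage_profile(make_view(df2, "abundance"), "TRBV")
  expect_equal(up2$percent[up2$gene == "TRBV2"], 75)
  expect_equal(up2$percent[up2$gene == "TRBV7-9"], 25)

  # appearance flattening ignores copies
  up3 <- usage_profile(make_view(df2, "appearance", seed = 1), "TRBV")
  expect_equal(sort(up3$percent), c(50, 50))

  # allele-level calls collapse to gene level
  df3 <- clono_fixture(cdr3b = c("CASSYGQF", "CASSLGQF"),
                       trbv = c("TRBV2*01", "TRBV2*02"))
  up4 <- usage_profile(make_view(df3, "abundance"), "TRBV")
  expect_equal(up4$gene, "TRBV2")
  expect_equal(up4$percent, 100)
})

test_that("deployment counts catalogue genes with nonzero weight", {
  genes27 <- gene_catalogue("TRBV")[1:27]
  df <- clono_fixture(cdr3b = random_cdr3(27), trbv = genes27)
  d <- deployment(make_view(df, "abundance"), "TRBV")
  expect_equal(d$genes_used, 27L)
  expect_equal(d$catalogue_size, 30L)
  expect_equal(d$percent, 90)

  d19 <- deployment(make_view(df[1:19, ], "abundance"), "TRBV")
  expect_equal(d19$percent, 100 * 19 / 30, tolerance = 1e-9)

  # a non-catalogue gene warns, counts in genes_used, not in catalogue_size
  df2 <- clono_fixture(cdr3b = random_cdr3(2),
                       trbv = c("TRBV2", "TRBV6-6"))
  expect_warning(d2 <- deployment(make_view(df2, "abundance"), "TRBV"),
                 "TRBV6-6")
  expect_equal(d2$genes_used, 2L)
  expect_equal(d2$catalogue_size, 30L)

  # no calls at all
  df3 <- clono_fixture("CASSYGQF", trbv = NA_character_)
  d3 <- deployment(make_view(df3, "abundance"), "TRBV")
  expect_equal(d3$genes_used, 0L)
  expect_equal(d3$percent, 0)
})

test_that("pairing matrices accumulate weight and marginalise to usage", {
  df <- clono_fixture("CASSYGQF", trbv = "TRBV5-4", trav = "TRAV12-2",
                      copies = 4L)
  pm <- pairing_matrix(make_view(df, "abundance"), "TRBV", "TRAV")
  expect_equal(nrow(pm), 1L)
  expect_equal(pm$weight, 4)
  expect_equal(pm$row_gene, "TRBV5-4")
  expect_equal(pm$col_gene, "TRAV12-2")

  df2 <- clono_fixture(cdr3b = c("CASSYGQF", "CASSLGQF", "CASSMGQF"),
                       trbv = "TRBV2", trbj = "TRBJ2-7")
  pm2 <- pairing_matrix(make_view(df2, "abundance"), "TRBV", "TRBJ")
  expect_equal(pm2$weight, 3)

  set.seed(8)
  df3 <- random_clonotypes(60)
  v <- make_view(df3, "abundance")
  pm3 <- pairing_matrix(v, "TRBV", "TRBJ")
  up_row <- usage_profile(v, "TRBV")
  up_col <- usage_profile(v, "TRBJ")
  row_marg <- rowsum(pm3$weight, pm3$row_gene)[, 1]
  col_marg <- rowsum(pm3$weight, pm3$col_gene)[, 1]
  expect_equal(row_marg[up_row$gene], setNames(up_row$weight, up_row$gene))
  expect_equal(col_marg[up_col$gene], setNames(up_col$weight, up_col$gene))
  expect_equal(sum(pm3$weight), view_N(v))
})

test_that("length spectra and fraction_below follow the strict reading", {
  df <- clono_fixture(cdr3b = c("CASSYGQGAYEQ", "CASSLAPGATNE",
                                "CASSYGQGAYEQYNA", "CASSLAPGATNEKLF"))
  sp <- length_spectrum(make_view(df, "appearance", seed = 1))
  expect_equal(sp$percent[sp$length == 12], 50)
  expect_equal(sp$percent[sp$length == 15], 50)
  expect_equal(fraction_below(sp, 13), 50)
  expect_equal(fraction_below(sp, 12), 0)
  expect_equal(fraction_below(sp, 12, inclusive = TRUE), 50)

  all15 <- clono_fixture(cdr3b = c("CASSYGQGAYEQYNA", "CASSLAPGATNEKLF"))
  sp15 <- length_spectrum(make_view(all15, "abundance"))
  expect_equal(fraction_below(sp15, 13), 0)

  expect_error(fraction_below(sp, 0), class = "tcrcompare_error_domain")
})

test_that("profiles are permutation-invariant and pool consistently", {
  set.seed(13)
  df <- random_clonotypes(50)
  v1 <- make_view(df, "abundance")
  v2 <- make_view(df[sample(nrow(df)), ], "abundance")
  u1 <- usage_profile(v1, "TRBV")
  u2 <- usage_profile(v2, "TRBV")
  expect_equal(setNames(u1$percent, u1$gene), setNames(u2$percent, u2$gene))
  s1 <- length_spectrum(v1)
  s2 <- length_spectrum(v2)
  expect_equal(s1$percent, s2$percent)

  # pooled profile equals the weight-weighted average of donor profiles
  donors <- split(df, df$donor_id)
  views <- lapply(donors, function(d) make_view(d, "abundance"))
  pooled <- pool_views(views)
  up_pool <- usage_profile(pooled, "TRBV")
  combined <- do.call(rbind, lapply(views, function(v) {
    u <- usage_profile(v, "TRBV")
    data.frame(gene = u$gene, weight = u$weight)
  }))
  manual <- rowsum(combined$weight, combined$gene)[, 1]
  manual_pct <- 100 * manual / sum(manual)
  expect_equal(setNames(up_pool$percent, up_pool$gene),
               manual_pct[up_pool$gene],
               tolerance = 1e-9)
})
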