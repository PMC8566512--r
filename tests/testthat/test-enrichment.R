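test_that("prevalence filter keeps ASVs at the inclusive ceiling boundary", {
  set.seed(3)
  counts <- matrix(stats::rpois(66 * 4, 5), nrow = 66)
  counts[, 1] <- 0; counts[sample(66, 2), 1] <- 3   # 2 of 66 = 3.0% -> out
  counts[, 2] <- 0; counts[sample(66, 3), 2] <- 3   # 3 of 66 >= ceil(2.64) -> in
  counts[, 3] <- 5                                  # everywhere -> in
  tab <- tiny_table(counts, fraction = rep("PA", 66), layer = rep("epi", 66))
  kept <- prevalence_filter(tab, 0.04)
  expect_false("asv_001" %in% colnames(kept$counts))
  expect_true(all(c("asv_002", "asv_003") %in% colnames(kept$counts)))
  all_zero <- tiny_table(matrix(0L, 5, 3), rep("PA", 5), rep("epi", 5))
  expect_error(prevalence_filter(all_zero), "every ASV")
})

test_that("size factors recover scaling and ignore ASV order", {
  set.seed(4)
  base <- stats::rpois(40, 50) + 1
  counts <- rbind(base, base, base * 2)
  tab <- tiny_table(counts, rep("PA", 3), rep("epi", 3))
  sf <- size_factors(tab)
  expect_equal(unname(sf / sf[1]), c(1, 1, 2), tolerance = 1e-10)
  perm <- sample(ncol(counts))
  expect_equal(unname(size_factors(counts[, perm])), unname(sf))
  # identical samples: all factors 1
  expect_equal(unname(size_factors(rbind(base, base))), c(1, 1))
  # no all-positive reference ASV: library-size fallback with warning
  z <- rbind(c(0L, 5L), c(5L, 0L))
  expect_warning(sfz <- size_factors(z), "library-size")
  expect_true(all(sfz > 0))
})

test_that("the shifted-log VST is monotone with the expected anchors", {
  counts <- rbind(c(0L, 1L, 100L), c(2L, 10L, 7L))
  v <- vst(counts, factors = c(1, 2))
  expect_equal(v[1, 1], 0)              # zero count maps to 0
  expect_equal(v[1, 2], 1)              # count == factor maps to log2(2)
  expect_equal(v[2, 1], 1)
  norm <- sweep(counts, 1, c(1, 2), "/")
  expect_equal(order(v), order(norm))   # rank-preserving
})

test_that("identical layer distributions produce near-null contrasts", {
  suite <- make_community_suite(two_layer_cfg(seed = 51))
  res <- nb_contrast(suite$table, c("epi", "meso"),
                     enrichment_config(contrasts = list(c("epi", "meso"))))
  expect_lte(mean(res$enriched, na.rm = TRUE), 0.1)
  expect_lt(abs(stats::median(res$lfc, na.rm = TRUE)), 0.5)
  expect_true(all(res$padj >= res$p, na.rm = TRUE))
})

test_that("swapping the contrast order flips the fold-change sign only", {
  suite <- make_community_suite(two_layer_cfg(seed = 52, n_planted = 4))
  cfg <- enrichment_config(contrasts = list(c("epi", "meso")))
  fwd <- nb_contrast(suite$table, c("epi", "meso"), cfg)
  rev <- nb_contrast(suite$table, c("meso", "epi"), cfg)
  expect_equal(fwd$lfc, -rev$lfc, tolerance = 1e-6)
  expect_equal(fwd$p, rev$p, tolerance = 1e-9)
  expect_equal(fwd$enriched, rev$enriched)
})

test_that("the contrast pipeline is invariant to sample order", {
  suite <- make_community_suite(two_layer_cfg(seed = 53, n_planted = 3))
  tab <- suite$table
  cfg <- enrichment_config(contrasts = list(c("epi", "meso")))
  res1 <- nb_contrast(prevalence_filter(tab), c("epi", "meso"), cfg)
  perm <- rev(seq_len(nrow(tab$counts)))
  tab2 <- subset_asv_table(tab, samples = perm)
  res2 <- nb_contrast(prevalence_filter(tab2), c("epi", "meso"), cfg)
  expect_equal(res1$p, res2$p, tolerance = 1e-9)
  expect_equal(res1$lfc, res2$lfc, tolerance = 1e-6)
})

test_that("planted four-fold effects are detected and flagged deeper", {
  suite <- make_community_suite(two_layer_cfg(seed = 54, n_planted = 5))
  res <- nb_contrast(suite$table, c("epi", "meso"),
                     enrichment_config(contrasts = list(c("epi", "meso"))))
  pl <- suite$truth$planted$asv
  hits <- res[res$asv %in% pl, ]
  expect_gte(sum(hits$enriched), 4)
  expect_true(all(hits$direction[hits$enriched] == "deeper"))
  expect_equal(mean(hits$lfc), 2, tolerance = 0.5)
})

test_that("discoveries shrink monotonically as the padj threshold tightens", {
  suite <- make_community_suite(two_layer_cfg(seed = 55, n_planted = 5))
  base <- enrichment_config(contrasts = list(c("epi", "meso")))
  res <- nb_contrast(suite$table, c("epi", "meso"), base)
  n_disc <- vapply(c(0.2, 0.1, 0.05, 0.01), function(th) {
    sum(!is.na(res$padj) & res$padj < th & abs(res$lfc) > 1)
  }, numeric(1))
  expect_true(all(diff(n_disc) <= 0))
  # BH: padj monotone in p
  ord <- order(res$p)
  expect_true(all(diff(res$padj[ord][!is.na(res$padj[ord])]) >= -1e-12))
})

test_that("degenerate contrasts signal insufficient data", {
  suite <- make_community_suite(two_layer_cfg(seed = 56, n_per_group = 2))
  tab <- subset_asv_table(suite$table,
                          samples = which(suite$table$sample_data$layer == "epi"))
  expect_error(nb_contrast(tab, c("epi", "meso"), enrichment_config()),
               ">= 2 samples")
})

test_that("family summaries apply the strict more-than-3 rule and sign convention", {
  taxo <- data.frame(family = c(rep("famA", 4), rep("famB", 3), rep("famC", 5)),
                     row.names = sprintf("a%02d", 1:12))
  res <- data.frame(asv = sprintf("a%02d", 1:12), contrast = "epi-meso",
                    lfc = c(rep(2, 4), rep(2, 3), rep(c(2, -1.5), c(3, 2))),
                    se = 0.1, p = 0.001, padj = 0.01,
                    direction = "deeper", enriched = TRUE)
  fam <- family_summary(res, taxo, enrichment_config())
  expect_setequal(fam$family, c("famA", "famC"))  # famB has exactly 3 -> out
  expect_equal(fam$mean_lfc[fam$family == "famA"], 2)
  expect_equal(fam$se_lfc[fam$family == "famA"], 0)
  # mixed-sign family still reported with |mean| < 1
  expect_equal(fam$mean_lfc[fam$family == "famC"], mean(c(2, 2, 2, -1.5, -1.5)))
  expect_equal(nrow(family_summary(res[0, ], taxo, enrichment_config())), 0)
})

test_that("footprints run from zero to one and recover the seeded fraction", {
  counts <- rbind(c(10L, 10L, 0L, 0L), c(0L, 0L, 5L, 5L))
  tab <- tiny_table(counts, fraction = c("sediment", "sediment"),
                    layer = c("sediment", "sediment"))
  fp <- enriched_footprint(c("asv_001", "asv_002"), tab)
  expect_equal(fp$per_sample$fraction_of_reads, c(1, 0))
  fp0 <- enriched_footprint(character(0), tab)
  expect_equal(fp0$per_sample$fraction_of_reads, c(0, 0))

  cfg <- synthetic_config(seed = 61, community = list(
    n_asvs = 200, stations_per_region = 1, n_sediment = 6,
    reads_range = c(20000, 20000), sediment_seed_fraction = 0.15))
  suite <- make_community_suite(cfg)
  sed <- subset_asv_table(suite$table, samples = which(
    suite$table$sample_data$fraction == "sediment"))
  fp1 <- enriched_footprint(unique(suite$truth$planted$asv), sed,
                            group_by = "fraction")
  expect_lt(abs(fp1$summary$mean - 0.15), 0.02)
})
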