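# helpers: build source/sink count matrices over a shared taxon universe
.two_sources <- function(seed, n_taxa = 200, depth = 5000) {
  set.seed(seed)
  p1 <- c(stats::rexp(n_taxa / 2), rep(1e-3, n_taxa / 2)); p1 <- p1 / sum(p1)
  p2 <- c(rep(1e-3, n_taxa / 2), stats::rexp(n_taxa / 2)); p2 <- p2 / sum(p2)
  ids <- sprintf("t%03d", seq_len(n_taxa))
  src <- rbind(s1 = stats::rmultinom(1, depth, p1)[, 1],
               s2 = stats::rmultinom(1, depth, p2)[, 1])
  colnames(src) <- ids
  list(src = src, p1 = p1, p2 = p2, ids = ids)
}

test_that("rarefaction hits the target depth and drops shallow samples", {
  set.seed(5)
  counts <- rbind(stats::rmultinom(1, 5000, rep(1, 50))[, 1],
                  stats::rmultinom(1, 8000, rep(1, 50))[, 1],
                  stats::rmultinom(1, 4999, rep(1, 50))[, 1])
  tab <- tiny_table(counts, fraction = rep("FL", 3), layer = rep("epi", 3))
  expect_warning(r <- rarefy(tab, 5000, seed = 1), "dropping 1")
  expect_equal(unname(rowSums(r$counts)), c(5000, 5000))
  # a sample already at depth is passed through unchanged
  expect_equal(r$counts["smp_01", ], tab$counts["smp_01", ])
  expect_error(rarefy(tab, 10000), "below the rarefaction depth")
})

test_that("rarefaction is hypergeometric: expected counts scale with depth", {
  set.seed(6)
  counts <- matrix(stats::rmultinom(1, 12000, prop.table(stats::rexp(40)))[, 1],
                   nrow = 1)
  tab <- tiny_table(counts, "FL", "epi")
  depth <- 3000
  acc <- matrix(0, 200, ncol(counts))
  for (s in 1:200) acc[s, ] <- rarefy(tab, depth, seed = s)$counts[1, ]
  expected <- depth * counts[1, ] / sum(counts[1, ])
  expect_equal(colMeans(acc), expected, tolerance = 0.05)
})

test_that("a sink identical to one of two disjoint sources maps to it", {
  ts <- .two_sources(11)
  sink <- matrix(stats::rmultinom(1, 5000, ts$p1)[, 1], 1,
                 dimnames = list("sinkA", ts$ids))
  fit <- fit_sources(sink, ts$src, mst_config(seed = 7))
  expect_gt(fit$proportions["sinkA", "s1"], 0.95)
  expect_equal(sum(fit$proportions), 1)
})

test_that("a sink with taxa absent from every source goes to Unknown", {
  ts <- .two_sources(12)
  src <- ts$src
  src[, 181:200] <- 0L
  pz <- c(rep(0, 180), stats::rexp(20)); pz <- pz / sum(pz)
  sink <- matrix(stats::rmultinom(1, 5000, pz)[, 1], 1,
                 dimnames = list("sinkU", ts$ids))
  fit <- fit_sources(sink, src, mst_config(seed = 7))
  expect_gt(fit$proportions["sinkU", "Unknown"], 0.95)
})

test_that("posterior mixture estimates increase with the planted fraction", {
  ts <- .two_sources(13)
  est <- vapply(c(0.3, 0.5, 0.7), function(g) {
    sink <- matrix(stats::rmultinom(1, 5000, g * ts$p1 + (1 - g) * ts$p2)[, 1],
                   1, dimnames = list("s", ts$ids))
    fit_sources(sink, ts$src, mst_config(seed = 3))$proportions[1, "s1"]
  }, numeric(1))
  expect_true(all(diff(est) > 0))
})

test_that("fixed seeds reproduce the fit; proportions always sum to one", {
  ts <- .two_sources(14)
  sink <- matrix(stats::rmultinom(1, 5000, 0.5 * ts$p1 + 0.5 * ts$p2)[, 1],
                 1, dimnames = list("s", ts$ids))
  f1 <- fit_sources(sink, ts$src, mst_config(seed = 99))
  f2 <- fit_sources(sink, ts$src, mst_config(seed = 99))
  expect_identical(f1$proportions, f2$proportions)
  expect_equal(unname(rowSums(f1$proportions)), 1)
  f3 <- fit_sources(sink, ts$src, mst_config(seed = 100))
  expect_false(identical(f1$proportions, f3$proportions))
})

test_that("label permutation leaves the mixture estimates equivariant", {
  ts <- .two_sources(15)
  sink <- matrix(stats::rmultinom(1, 5000, 0.6 * ts$p1 + 0.4 * ts$p2)[, 1],
                 1, dimnames = list("s", ts$ids))
  f_ab <- fit_sources(sink, ts$src, mst_config(seed = 5))
  f_ba <- fit_sources(sink, ts$src[c("s2", "s1"), ], mst_config(seed = 5))
  expect_equal(f_ab$proportions[1, "s1"], f_ba$proportions[1, "s1"],
               tolerance = 0.03)
  expect_equal(f_ab$proportions[1, "s2"], f_ba$proportions[1, "s2"],
               tolerance = 0.03)
})

test_that("leave-one-out maps held-out samples to their own pool", {
  set.seed(16)
  n_taxa <- 120
  pa <- prop.table(c(stats::rexp(60), rep(1e-4, 60)))
  pb <- prop.table(c(rep(1e-4, 60), stats::rexp(60)))
  counts <- rbind(stats::rmultinom(2, 5000, pa) |> t(),
                  stats::rmultinom(2, 5000, pb) |> t())
  tab <- tiny_table(counts, fraction = rep("FL", 4),
                    layer = c("surface", "surface", "meso", "meso"))
  loo <- leave_one_out(tab, mst_config(seed = 8), group_by = "layer")
  expect_equal(unname(rowSums(loo)), rep(1, 4))
  expect_gt(loo["smp_01", "surface"], 0.9)  # predicted by its twin
  expect_gt(loo["smp_03", "meso"], 0.9)
  expect_lt(loo["smp_01", "meso"], 0.05)
  single <- tiny_table(counts[1, , drop = FALSE], "FL", "surface")
  expect_error(leave_one_out(single), ">= 2")
})

test_that("layer summaries aggregate and pool surface with epipelagic", {
  ts <- .two_sources(17)
  sinks <- rbind(stats::rmultinom(1, 5000, 0.6 * ts$p1 + 0.4 * ts$p2)[, 1],
                 stats::rmultinom(1, 5000, 0.6 * ts$p1 + 0.4 * ts$p2)[, 1])
  rownames(sinks) <- c("k1", "k2"); colnames(sinks) <- ts$ids
  src <- ts$src
  rownames(src) <- c("surface|ice-covered", "epi|ice-covered")
  fit <- fit_sources(sinks, src, mst_config(seed = 2))
  md <- data.frame(layer = c("bathy", "bathy"), region = "ice-covered",
                   row.names = c("k1", "k2"))
  su <- summarize_by_layer(fit, md)
  one <- su[su$source == "surface|ice-covered", ]
  expect_equal(one$mean, mean(fit$proportions[, "surface|ice-covered"]))
  pooled <- summarize_by_layer(fit, md, pool_surface_epi = TRUE)
  se_row <- pooled[pooled$source == "surface+epi", ]
  expect_equal(se_row$mean,
               mean(rowSums(fit$proportions[, c("surface|ice-covered",
                                                "epi|ice-covered")])))
  # single sink: summary equals its own proportions
  su1 <- summarize_by_layer(
    fit_sources(sinks[1, , drop = FALSE], src, mst_config(seed = 2)),
    md[1, , drop = FALSE])
  expect_equal(su1$mean[su1$source == "Unknown"],
               unname(fit_sources(sinks[1, , drop = FALSE], src,
                                  mst_config(seed = 2))$proportions[1, "Unknown"]))
})

test_that("mismatched taxon universes and empty sources are rejected", {
  ts <- .two_sources(18)
  sink <- ts$src[1, , drop = FALSE]
  colnames(sink) <- rev(colnames(sink))
  expect_error(fit_sources(sink, ts$src), "ASV universe")
  expect_error(fit_sources(ts$src[1, , drop = FALSE],
                           ts$src[0, , drop = FALSE]), "empty source")
})
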