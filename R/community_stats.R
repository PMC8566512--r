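# Alpha diversity, ordination, FL-PA distance contrasts and PERMANOVA.

#' Bias-corrected Chao1 richness
#'
#' `S_obs + f1 (f1 - 1) / (2 (f2 + 1))` with `f1`/`f2` the singleton and
#' doubleton counts. Always at least `S_obs`.
#'
#' @param counts Non-negative integer counts per ASV for one sample.
#' @return Chao1 estimate.
#' @export
#' @examples
#' chao1(c(rep(1, 4), rep(2, 2), 10, 20, 5, 7))  # S_obs 10 -> 12
chao1 <- function(counts) {
  if (length(counts) == 0 || sum(counts) == 0) {
    stop("empty sample: Chao1 undefined", call. = FALSE)
  }
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers", call. = FALSE)
  }
  s_obs <- sum(counts > 0)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Shannon diversity (natural log)
#'
#' `-sum(p_i log p_i)` over positive proportions; 0 for a single ASV,
#' maximal (`log k`) for a uniform community of `k` ASVs.
#'
#' @param counts Non-negative counts per ASV for one sample.
#' @return Shannon index in nats.
#' @export
shannon <- function(counts) {
  total <- sum(counts)
  if (length(counts) == 0 || total <= 0) {
    stop("empty sample: Shannon undefined", call. = FALSE)
  }
  p <- counts[counts > 0] / total
  -sum(p * log(p))
}

#' Asymptotic richness extrapolation to doubled sequencing depth
#'
#' A simple Chao1-anchored approximation: the expected richness at double
#' the current depth interpolates between the observed richness and the
#' Chao1 asymptote with the standard rarefaction-style saturation term
#' `S_obs + (S_chao - S_obs) * (1 - (1 - f1 / n)^n)` evaluated for the
#' additional reads. Intended as a quick saturation check, not a full
#' coverage-based rarefaction.
#'
#' @param counts Non-negative integer counts per ASV for one sample.
#' @return `list(observed, chao1, doubled_depth_estimate)`.
#' @export
extrapolate_richness_doubled <- function(counts) {
  s_obs <- sum(counts > 0)
  s_chao <- chao1(counts)
  n <- sum(counts)
  f1 <- sum(counts == 1)
  extra <- (s_chao - s_obs) * (1 - (1 - f1 / max(n, 1))^n)
  list(observed = s_obs, chao1 = s_chao,
       doubled_depth_estimate = s_obs + extra)
}

#' Per-sample alpha-diversity table
#'
#' @param x An `asv_table`.
#' @return `data.frame(sample, reads, observed, chao1, shannon)` plus the
#'   sample metadata columns.
#' @export
alpha_diversity <- function(x) {
  stopifnot(inherits(x, "asv_table"))
  out <- data.frame(
    sample = rownames(x$counts),
    reads = rowSums(x$counts),
    observed = rowSums(x$counts > 0),
    chao1 = apply(x$counts, 1, chao1),
    shannon = apply(x$counts, 1, shannon),
    row.names = NULL)
  cbind(out, x$sample_data[out$sample, , drop = FALSE], row.names = NULL)
}

#' Principal component analysis of community profiles
#'
#' Centred covariance PCA (via [stats::prcomp()]) of a variance-stabilised
#' matrix, with a deterministic sign convention: on each axis the loading of
#' largest magnitude is made positive.
#'
#' @param vst_matrix Samples x features real matrix (see [vst()]).
#' @return `list(scores, loadings, var_explained)`; `var_explained` in
#'   percent, summing to <= 100.
#' @export
pca_communities <- function(vst_matrix) {
  if (nrow(vst_matrix) < 2) stop("need >= 2 samples", call. = FALSE)
  keep <- apply(vst_matrix, 2, function(col) stats::var(col) > 0)
  if (!any(keep)) stop("constant matrix: PCA degenerate", call. = FALSE)
  pc <- stats::prcomp(vst_matrix[, keep, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  for (j in seq_len(ncol(pc$rotation))) {
    piv <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[piv, j] < 0) {
      pc$rotation[, j] <- -pc$rotation[, j]
      pc$x[, j] <- -pc$x[, j]
    }
  }
  list(scores = pc$x, loadings = pc$rotation,
       var_explained = 100 * pc$sdev^2 / sum(pc$sdev^2))
}

#' Paired FL-PA Euclidean distances with a regional rank test
#'
#' For each (station, layer) with both a free-living and a
#' particle-associated sample, computes the Euclidean distance between the
#' two variance-stabilised profiles; per layer, compares the distances of
#' the two regions with a Wilcoxon rank-sum test, BH-adjusted across layers.
#' Unmatched samples are skipped with a warning.
#'
#' @param vst_matrix Samples x features matrix (see [vst()]).
#' @param metadata `data.frame` with `fraction`, `layer`, `region`, `station`
#'   columns, rownames matching the matrix.
#' @return `list(pairs = data.frame(station, layer, region, distance),
#'   tests = data.frame(layer, p, padj))`.
#' @export
fl_pa_distance <- function(vst_matrix, metadata) {
  md <- metadata[rownames(vst_matrix), , drop = FALSE]
  keys <- unique(md[md$fraction %in% c("FL", "PA"), c("station", "layer")])
  pairs <- list()
  skipped <- 0
  for (r in seq_len(nrow(keys))) {
    st <- keys$station[r]; ly <- keys$layer[r]
    fl <- rownames(md)[md$station == st & md$layer == ly & md$fraction == "FL"]
    pa <- rownames(md)[md$station == st & md$layer == ly & md$fraction == "PA"]
    if (length(fl) != 1 || length(pa) != 1) { skipped <- skipped + 1; next }
    pairs[[length(pairs) + 1]] <- data.frame(
      station = st, layer = ly, region = md[fl, "region"],
      distance = sqrt(sum((vst_matrix[fl, ] - vst_matrix[pa, ])^2)))
  }
  if (skipped > 0) warning(sprintf("skipped %d unmatched station-layer combinations", skipped))
  pairs <- do.call(rbind, pairs)
  tests <- NULL
  if (!is.null(pairs)) {
    tests <- do.call(rbind, lapply(split(pairs, pairs$layer), function(d) {
      regions <- unique(d$region)
      p <- if (length(regions) == 2 && all(table(d$region) >= 1)) {
        suppressWarnings(stats::wilcox.test(distance ~ region, data = d)$p.value)
      } else NA_real_
      data.frame(layer = d$layer[1], p = p)
    }))
    tests$padj <- stats::p.adjust(tests$p, method = "BH")
    rownames(tests) <- NULL
  }
  list(pairs = pairs, tests = tests)
}

#' PERMANOVA on a distance matrix
#'
#' One-way permutational multivariate analysis of variance: the pseudo-F is
#' computed from the among/within sums of squared distances
#' (`SS_total = sum(d^2)/n`, `SS_within = sum over groups of within-group
#' d^2 / n_g`), `R^2 = SS_among / SS_total`, and the p value is
#' `(1 + #(F_perm >= F_obs)) / (1 + n_perm)` under free permutation of the
#' group labels.
#'
#' @param d A `dist` object or symmetric distance matrix over samples.
#' @param grouping Factor (or coercible) of group labels, >= 2 groups, no
#'   singleton groups.
#' @param n_perm Number of permutations, default 999.
#' @param seed Integer seed for the permutations.
#' @return `list(f = pseudo-F, r2, p, df = c(k - 1, n - k))`.
#' @export
permanova <- function(d, grouping, n_perm = 999, seed = 1) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  grouping <- as.factor(grouping)
  if (length(grouping) != n) stop("grouping length must match the distance matrix", call. = FALSE)
  k <- nlevels(droplevels(grouping))
  if (k < 2 || n < 3) stop("need >= 2 groups and >= 3 samples", call. = FALSE)
  if (any(table(grouping) < 2)) {
    stop("singleton group: within-group variance undefined", call. = FALSE)
  }
  d2 <- dm^2
  ss_total <- sum(d2[upper.tri(d2)]) / n
  stat <- function(g) {
    ss_within <- 0
    for (lv in levels(g)) {
      idx <- which(g == lv)
      ss_within <- ss_within +
        sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
    }
    ss_among <- ss_total - ss_within
    (ss_among / (k - 1)) / (ss_within / (n - k))
  }
  f_obs <- stat(grouping)
  r2 <- 1 - 1 / (1 + f_obs * (k - 1) / (n - k))
  .with_seed(seed, {
    f_perm <- vapply(seq_len(n_perm), function(i) {
      stat(factor(sample(as.character(grouping)), levels = levels(grouping)))
    }, numeric(1))
    list(f = f_obs, r2 = r2,
         p = (1 + sum(f_perm >= f_obs)) / (1 + n_perm),
         df = c(k - 1, n - k))
  })
}
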