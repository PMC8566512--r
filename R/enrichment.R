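# Depth-contrast enrichment of particle-associated ASVs: prevalence filter,
# median-of-ratios size factors, shifted-log VST, negative-binomial Wald
# contrasts with BH adjustment, family summaries, and the footprint of
# PA-enriched ASVs in other communities.

#' Enrichment-analysis configuration
#'
#' @param lfc_threshold Minimum absolute log2 fold change, default 1 (i.e.
#'   double the sequences).
#' @param padj_threshold Maximum BH-adjusted p value, default 0.1.
#' @param prevalence_min Minimum fraction of samples an ASV must appear in
#'   (count >= 1), default 0.04.
#' @param contrasts List of ordered layer pairs `c(shallow, deep)`; default
#'   the consecutive pelagic pairs surface-epi, epi-meso, meso-bathy.
#' @param min_asvs_per_family Families are reported only with strictly more
#'   than this many enriched ASVs, default 3.
#' @return An object of class `enrichment_config`.
#' @export
enrichment_config <- function(lfc_threshold = 1, padj_threshold = 0.1,
                              prevalence_min = 0.04,
                              contrasts = list(c("surface", "epi"),
                                               c("epi", "meso"),
                                               c("meso", "bathy")),
                              min_asvs_per_family = 3) {
  .stopifnot_scalar_pos(lfc_threshold, "lfc_threshold")
  .stopifnot_scalar_pos(padj_threshold, "padj_threshold")
  structure(list(lfc_threshold = lfc_threshold,
                 padj_threshold = padj_threshold,
                 prevalence_min = prevalence_min, contrasts = contrasts,
                 min_asvs_per_family = min_asvs_per_family),
            class = "enrichment_config")
}

#' Prevalence filter
#'
#' Keeps ASVs present (count >= 1) in at least `ceiling(min_frac * n)` of the
#' `n` samples (inclusive at the boundary).
#'
#' @param x An `asv_table`.
#' @param min_frac Minimum prevalence fraction, default 0.04.
#' @return The filtered `asv_table`.
#' @export
prevalence_filter <- function(x, min_frac = 0.04) {
  stopifnot(inherits(x, "asv_table"))
  need <- ceiling(min_frac * nrow(x$counts))
  keep <- colSums(x$counts >= 1) >= need
  if (!any(keep)) stop("prevalence filter removed every ASV", call. = FALSE)
  subset_asv_table(x, asvs = which(keep))
}

#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors relative to the per-ASV geometric mean
#' across samples; ASVs with any zero are excluded from the reference set.
#' When no reference ASV remains, falls back (with a warning) to library-size
#' scaling normalised to geometric mean 1.
#'
#' @param x An `asv_table` or counts matrix (samples x ASVs).
#' @return Named numeric vector of positive factors, one per sample.
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "asv_table")) x$counts else as.matrix(x)
  ref <- colSums(counts == 0) == 0
  if (!any(ref)) {
    warning("no ASV is positive in all samples; falling back to library-size scaling")
    libs <- rowSums(counts)
    sf <- libs / exp(mean(log(libs)))
    return(sf)
  }
  logc <- log(counts[, ref, drop = FALSE])
  log_gm <- colMeans(logc)
  apply(exp(sweep(logc, 2, log_gm)), 1, stats::median)
}

#' Shifted-log variance stabilisation
#'
#' `log2(count / size_factor + 1)`: monotone in the normalised counts, maps
#' zeros to zero. Intended for ordination and distance computation, not for
#' testing.
#'
#' @param x An `asv_table` or counts matrix (samples x ASVs).
#' @param factors Size factors from [size_factors()] (computed if missing).
#' @return Real-valued matrix of the same shape.
#' @export
vst <- function(x, factors = NULL) {
  counts <- if (inherits(x, "asv_table")) x$counts else as.matrix(x)
  if (is.null(factors)) factors <- size_factors(counts)
  log2(sweep(counts, 1, factors, "/") + 1)
}

# raw method-of-moments NB dispersion with size factors (can be negative):
# Var(K/sf) = mu * mean(1/sf) + phi * mu^2, pooled across the two groups
.mom_dispersion_raw <- function(k, sf, group) {
  z <- k / sf
  mus <- tapply(z, group, mean)
  resid2 <- (z - mus[group])^2
  df <- length(z) - length(mus)
  if (df <= 0) return(NA_real_)
  s2 <- sum(resid2) / df
  mu <- mean(z)
  if (mu <= 0) return(NA_real_)
  (s2 - mu * mean(1 / sf)) / mu^2
}

# robust mean-dispersion trend phi(mu) = a + b / mu fitted over all ASVs:
# b is the median of phi * mu (the extra-Poisson mass per read), a the
# median residual asymptotic dispersion, both clamped at 0
.dispersion_trend <- function(phis, mus) {
  ok <- is.finite(phis) & mus > 0
  if (sum(ok) < 3) return(c(a = 0, b = 0))
  b <- max(stats::median(pmax(phis[ok], 0) * mus[ok]), 0)
  a <- max(stats::median(phis[ok] - b / mus[ok]), 0)
  c(a = a, b = b)
}

# exact conditional NB test (DESeq-2010 style): given the ASV's total count,
# the probability that group A received a split as or less likely than the
# observed one, under a common mean and the working dispersion. Group sums
# of NB variables with unequal size factors are approximated by matching
# mean and variance.
.exact_nb_p <- function(k, grp, sf, phi) {
  a_idx <- grp == levels(grp)[1]
  kA <- sum(k[a_idx]); total <- sum(k)
  if (total == 0) return(NA_real_)
  sA <- sum(sf[a_idx]); sB <- sum(sf[!a_idx])
  mu <- total / (sA + sB)
  sizeA <- sA^2 / (phi * sum(sf[a_idx]^2))
  sizeB <- sB^2 / (phi * sum(sf[!a_idx]^2))
  ka <- 0:total
  lp <- stats::dnbinom(ka, mu = mu * sA, size = sizeA, log = TRUE) +
    stats::dnbinom(total - ka, mu = mu * sB, size = sizeB, log = TRUE)
  lp <- lp - max(lp)
  pr <- exp(lp)
  pr <- pr / sum(pr)
  min(1, sum(pr[pr <= pr[kA + 1] * (1 + 1e-8)]))
}

#' Negative-binomial depth contrast
#'
#' Tests, per ASV, the abundance difference of particle-associated samples
#' between two water layers under a negative-binomial model with
#' size-factor normalisation. The per-ASV dispersion is estimated by method
#' of moments, moderated by the conservative maximum of the per-ASV
#' estimate and a robust mean-dispersion trend `a + b / mu` fitted across
#' ASVs, and floored at 1e-8. Significance comes from an exact conditional
#' two-group negative-binomial test (the probability, given the ASV's total
#' count, of a group split as or less likely than the observed one); the
#' log2 fold change and its standard error come from a negative-binomial
#' log-linear fit with size-factor offsets. p values are Benjamini-Hochberg
#' adjusted across ASVs within the contrast. An ASV is flagged enriched
#' when `|lfc| > lfc_threshold` and `padj < padj_threshold`. Positive `lfc`
#' means enrichment in the deeper layer.
#'
#' @param x An `asv_table` (typically PA samples of one region, prevalence
#'   filtered).
#' @param contrast Ordered layer pair `c(shallow, deep)`; both layers need
#'   >= 2 samples.
#' @param cfg An [enrichment_config()].
#' @return `data.frame(asv, contrast, lfc, se, p, padj, direction, enriched)`.
#' @export
nb_contrast <- function(x, contrast, cfg = enrichment_config()) {
  stopifnot(inherits(x, "asv_table"), length(contrast) == 2)
  sel <- x$sample_data$layer %in% contrast
  sub <- subset_asv_table(x, samples = which(sel))
  grp <- factor(sub$sample_data$layer, levels = contrast)
  if (any(table(grp) < 2)) {
    stop(sprintf("need >= 2 samples in each of '%s' and '%s'",
                 contrast[1], contrast[2]), call. = FALSE)
  }
  sf <- size_factors(sub)
  counts <- sub$counts
  n_asv <- ncol(counts)
  lfc <- se <- p <- rep(NA_real_, n_asv)
  log_sf <- log(sf)
  norm <- sweep(counts, 1, sf, "/")
  mus <- colMeans(norm)
  phis_raw <- vapply(seq_len(n_asv),
                     function(j) .mom_dispersion_raw(counts[, j], sf, grp),
                     numeric(1))
  trend <- .dispersion_trend(phis_raw, mus)
  for (j in seq_len(n_asv)) {
    k <- counts[, j]
    if (all(k == 0)) next
    phi <- max(phis_raw[j], trend["a"] + trend["b"] / mus[j], 1e-8, na.rm = TRUE)
    p[j] <- .exact_nb_p(k, grp, sf, phi)
    fit <- tryCatch(
      suppressWarnings(stats::glm(
        k ~ grp + offset(log_sf),
        family = MASS::negative.binomial(theta = 1 / phi))),
      error = function(e) NULL)
    cf <- if (is.null(fit)) NULL else
      tryCatch(summary(fit)$coefficients, error = function(e) NULL)
    if (!is.null(cf) && nrow(cf) >= 2) {
      lfc[j] <- cf[2, 1] / log(2)
      se[j] <- cf[2, 2] / log(2)
    } else {
      # moment fallback when the GLM degenerates (e.g. one group all zero)
      m <- tapply(norm[, j], grp, mean)
      lfc[j] <- log2((m[2] + 0.5) / (m[1] + 0.5))
    }
  }
  padj <- stats::p.adjust(p, method = "BH")
  enriched <- !is.na(padj) & abs(lfc) > cfg$lfc_threshold &
    padj < cfg$padj_threshold
  data.frame(asv = colnames(counts),
             contrast = paste(contrast, collapse = "-"),
             lfc = lfc, se = se, p = p, padj = padj,
             direction = ifelse(is.na(lfc), NA_character_,
                                ifelse(lfc > 0, "deeper", "shallower")),
             enriched = enriched, row.names = NULL)
}

#' Run all configured depth contrasts
#'
#' Convenience wrapper applying [nb_contrast()] to every layer pair in the
#' configuration and row-binding the results.
#'
#' @inheritParams nb_contrast
#' @return Combined results `data.frame`.
#' @export
run_contrasts <- function(x, cfg = enrichment_config()) {
  do.call(rbind, lapply(cfg$contrasts, function(ct) nb_contrast(x, ct, cfg)))
}

#' Family-level summary of enriched ASVs
#'
#' Aggregates enriched ASVs per (family, contrast): count, mean log2 fold
#' change and its standard error. Only families with strictly more than
#' `min_asvs_per_family` enriched ASVs in a contrast are reported. Positive
#' means indicate enrichment in the deeper layer.
#'
#' @param results Output of [nb_contrast()] / [run_contrasts()].
#' @param taxonomy `data.frame` with a `family` column, rownames = ASV ids.
#' @param cfg An [enrichment_config()].
#' @return `data.frame(family, contrast, n_enriched, mean_lfc, se_lfc)`.
#' @export
family_summary <- function(results, taxonomy, cfg = enrichment_config()) {
  enr <- results[results$enriched & !is.na(results$lfc), , drop = FALSE]
  if (nrow(enr) == 0) {
    return(data.frame(family = character(), contrast = character(),
                      n_enriched = integer(), mean_lfc = numeric(),
                      se_lfc = numeric()))
  }
  enr$family <- taxonomy[enr$asv, "family"]
  out <- do.call(rbind, lapply(
    split(enr, list(enr$family, enr$contrast), drop = TRUE),
    function(d) data.frame(family = d$family[1], contrast = d$contrast[1],
                           n_enriched = nrow(d), mean_lfc = mean(d$lfc),
                           se_lfc = stats::sd(d$lfc) / sqrt(nrow(d)))))
  out <- out[out$n_enriched > cfg$min_asvs_per_family, , drop = FALSE]
  rownames(out) <- NULL
  out[order(out$contrast, out$family), , drop = FALSE]
}

#' Sequence footprint of an ASV set in target communities
#'
#' Per target sample, the fraction of sequences belonging to the given
#' (e.g. PA-enriched) ASV set; grouped mean and standard error by the
#' requested metadata columns. An empty ASV set yields all-zero fractions.
#'
#' @param enriched_asvs Character vector of ASV ids.
#' @param target An `asv_table` (e.g. deep FL or sediment samples) sharing
#'   the ASV universe.
#' @param group_by Metadata columns for the grouped summary, default
#'   `c("region", "fraction", "layer")`.
#' @return `list(per_sample = data.frame(sample, fraction_of_reads), summary
#'   = data.frame(group columns, mean, se, n))`.
#' @export
enriched_footprint <- function(enriched_asvs, target,
                               group_by = c("region", "fraction", "layer")) {
  stopifnot(inherits(target, "asv_table"))
  hit <- colnames(target$counts) %in% enriched_asvs
  frac <- rowSums(target$counts[, hit, drop = FALSE]) / rowSums(target$counts)
  per_sample <- data.frame(sample = rownames(target$counts),
                           fraction_of_reads = unname(frac))
  md <- target$sample_data
  grp <- do.call(paste, c(md[group_by], sep = "|"))
  summ <- do.call(rbind, lapply(split(frac, grp), function(f) {
    data.frame(mean = mean(f),
               se = if (length(f) > 1) stats::sd(f) / sqrt(length(f)) else NA_real_,
               n = length(f))
  }))
  keys <- do.call(rbind, strsplit(rownames(summ), "|", fixed = TRUE))
  colnames(keys) <- group_by
  summ <- cbind(as.data.frame(keys), summ)
  rownames(summ) <- NULL
  list(per_sample = per_sample, summary = summ)
}
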