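# Bayesian microbial source tracking: rarefaction, collapsed-Gibbs mixture
# estimation with an Unknown component, leave-one-out validation, summaries.

#' Source-tracking configuration
#'
#' Defaults follow the standard SourceTracker-style configuration: Dirichlet
#' hyperparameters `alpha` (source taxon distributions) and `beta` (mixing
#' proportions) of 0.001, 100 burn-in sweeps, 10 restarts, and rarefaction
#' to 5000 reads.
#'
#' @param alpha,beta Dirichlet hyperparameters, > 0.
#' @param burn_in Gibbs sweeps before the recorded draw, >= 1.
#' @param restarts Independent restarts (one draw recorded per restart), >= 1.
#' @param rarefaction_depth Reads per sample after rarefaction.
#' @param seed Integer seed.
#' @return An object of class `mst_config`.
#' @export
mst_config <- function(alpha = 0.001, beta = 0.001, burn_in = 100,
                       restarts = 10, rarefaction_depth = 5000, seed = 1) {
  .stopifnot_scalar_pos(alpha, "alpha")
  .stopifnot_scalar_pos(beta, "beta")
  if (burn_in < 1 || restarts < 1) {
    stop("burn_in and restarts must be >= 1", call. = FALSE)
  }
  structure(list(alpha = alpha, beta = beta, burn_in = as.integer(burn_in),
                 restarts = as.integer(restarts),
                 rarefaction_depth = as.integer(rarefaction_depth),
                 seed = as.integer(seed)),
            class = "mst_config")
}

#' Rarefy an ASV table to even depth
#'
#' Sub-samples each sample's reads without replacement to exactly `depth`
#' reads. Samples with fewer reads than `depth` are dropped with a warning.
#'
#' @param x An `asv_table`.
#' @param depth Target depth (reads), >= 1.
#' @param seed Integer seed.
#' @return The rarefied `asv_table`.
#' @export
rarefy <- function(x, depth = 5000, seed = 1) {
  stopifnot(inherits(x, "asv_table"))
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  totals <- rowSums(x$counts)
  keep <- totals >= depth
  if (!any(keep)) stop("all samples are below the rarefaction depth", call. = FALSE)
  if (any(!keep)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(!keep), depth,
                    paste(rownames(x$counts)[!keep], collapse = ", ")))
  }
  counts <- x$counts[keep, , drop = FALSE]
  .with_seed(seed, {
    for (i in seq_len(nrow(counts))) {
      if (totals[keep][i] == depth) next
      reads <- rep.int(seq_len(ncol(counts)), counts[i, ])
      picked <- sample(reads, depth)
      counts[i, ] <- tabulate(picked, nbins = ncol(counts))
    }
  })
  asv_table(counts, x$sample_data[rownames(counts), , drop = FALSE], x$taxonomy)
}

.pool_sources <- function(sources, group_by) {
  md <- sources$sample_data
  grp <- do.call(paste, c(md[group_by], sep = "|"))
  pooled <- rowsum(sources$counts, grp)
  pooled[order(rownames(pooled)), , drop = FALSE]
}

#' Estimate source mixtures of sink communities
#'
#' For each sink sample, every read is assigned a latent source (one of the
#' pooled known sources or an Unknown source whose distribution is learned
#' from the current assignments) and updated by a collapsed Gibbs sampler;
#' after the burn-in one draw is recorded per restart and the reported
#' proportions are the mean over restarts. Known-source distributions are
#' the fixed training counts smoothed by `alpha` and augmented by the
#' current assignments.
#'
#' @param sinks `asv_table` of sink (e.g. particle-associated) samples, or a
#'   counts matrix sharing the ASV universe of `sources`. Tables should be
#'   rarefied to even depth first (see [rarefy()]).
#' @param sources `asv_table` of source (e.g. free-living) samples, or a
#'   pre-pooled source-by-ASV counts matrix.
#' @param cfg An [mst_config()].
#' @param group_by Metadata columns used to pool source samples into named
#'   sources; default `c("layer", "region")`.
#' @return An object of class `mst_fit`: `proportions` (sinks x sources +
#'   `"Unknown"`, rows summing to 1), `sd` (over restarts), `cfg`.
#' @export
fit_sources <- function(sinks, sources, cfg = mst_config(),
                        group_by = c("layer", "region")) {
  stopifnot(inherits(cfg, "mst_config"))
  sink_counts <- if (inherits(sinks, "asv_table")) sinks$counts else as.matrix(sinks)
  src_counts <- if (inherits(sources, "asv_table")) {
    .pool_sources(sources, group_by)
  } else as.matrix(sources)
  if (nrow(src_counts) == 0) stop("empty source set", call. = FALSE)
  if (!identical(colnames(sink_counts), colnames(src_counts))) {
    stop("sinks and sources must share the same ASV universe", call. = FALSE)
  }
  src_names <- c(rownames(src_counts), "Unknown")
  props <- matrix(NA_real_, nrow(sink_counts), length(src_names),
                  dimnames = list(rownames(sink_counts), src_names))
  sds <- props
  m_tv <- t(src_counts)  # taxa x sources
  storage.mode(m_tv) <- "integer"
  .with_seed(cfg$seed, {
    for (s in seq_len(nrow(sink_counts))) {
      taxa <- rep.int(seq_len(ncol(sink_counts)), sink_counts[s, ]) - 1L
      draws <- mst_gibbs(as.integer(taxa), m_tv, cfg$alpha, cfg$beta,
                         cfg$burn_in, cfg$restarts)
      props[s, ] <- colMeans(draws)
      sds[s, ] <- apply(draws, 2, stats::sd)
    }
  })
  structure(list(proportions = props, sd = sds, cfg = cfg,
                 sources = rownames(src_counts)),
            class = "mst_fit")
}

#' @export
print.mst_fit <- function(x, ...) {
  cat(sprintf("mst_fit: %d sink(s) x %d source(s) + Unknown (%d restarts, %d burn-in sweeps)\n",
              nrow(x$proportions), length(x$sources),
              x$cfg$restarts, x$cfg$burn_in))
  print(round(x$proportions, 3))
  invisible(x)
}

#' @export
summary.mst_fit <- function(object, ...) {
  data.frame(sink = rep(rownames(object$proportions),
                        each = ncol(object$proportions)),
             source = rep(colnames(object$proportions),
                          nrow(object$proportions)),
             proportion = as.vector(t(object$proportions)),
             sd = as.vector(t(object$sd)),
             row.names = NULL)
}

#' Leave-one-out validation of the source set
#'
#' Each source sample is hidden in turn, treated as a sink, and fit against
#' the remaining source samples; a well-resolved source set predicts each
#' held-out sample mostly from its own group.
#'
#' @param sources `asv_table` of source samples (>= 2 samples).
#' @param cfg An [mst_config()].
#' @param group_by Metadata columns defining the pooled sources.
#' @return Matrix of proportions, one row per held-out sample.
#' @export
leave_one_out <- function(sources, cfg = mst_config(),
                          group_by = c("layer", "region")) {
  stopifnot(inherits(sources, "asv_table"))
  n <- nrow(sources$counts)
  if (n < 2) stop("need >= 2 source samples", call. = FALSE)
  out <- NULL
  for (i in seq_len(n)) {
    rest <- subset_asv_table(sources, samples = setdiff(seq_len(n), i))
    fit <- fit_sources(sources$counts[i, , drop = FALSE], rest, cfg, group_by)
    row <- fit$proportions
    if (is.null(out)) {
      out <- matrix(NA_real_, n, ncol(row),
                    dimnames = list(rownames(sources$counts), colnames(row)))
    }
    out[i, colnames(row)] <- row
  }
  out
}

#' Summarise mixing proportions by sink group
#'
#' Groups sink samples by metadata columns (default layer and region) and
#' reports each source's mean and standard deviation; optionally pools the
#' surface and epipelagic source columns into a single `surface+epi` column.
#'
#' @param fit An [fit_sources()] result.
#' @param metadata `data.frame` with rows matching the sinks in `fit` and
#'   the grouping columns.
#' @param group_by Grouping columns, default `c("layer", "region")`.
#' @param pool_surface_epi Pool sources whose name starts with `surface` or
#'   `epi` into one column, default `FALSE`.
#' @return `data.frame` in long format: group columns, `source`, `mean`, `sd`,
#'   `n`.
#' @export
summarize_by_layer <- function(fit, metadata, group_by = c("layer", "region"),
                               pool_surface_epi = FALSE) {
  stopifnot(inherits(fit, "mst_fit"))
  props <- fit$proportions
  md <- metadata[rownames(props), , drop = FALSE]
  if (pool_surface_epi) {
    se_cols <- grep("^(surface|epi)", colnames(props), value = TRUE)
    if (length(se_cols) > 1) {
      pooled <- rowSums(props[, se_cols, drop = FALSE])
      props <- cbind(props[, setdiff(colnames(props), se_cols), drop = FALSE],
                     `surface+epi` = pooled)
    }
  }
  grp <- do.call(paste, c(md[group_by], sep = "|"))
  out <- list()
  for (g in sort(unique(grp))) {
    sub <- props[grp == g, , drop = FALSE]
    parts <- strsplit(g, "|", fixed = TRUE)[[1]]
    block <- data.frame(source = colnames(sub),
                        mean = colMeans(sub),
                        sd = apply(sub, 2, stats::sd),
                        n = nrow(sub), row.names = NULL)
    for (k in seq_along(group_by)) block[[group_by[k]]] <- parts[k]
    out[[g]] <- block[, c(group_by, "source", "mean", "sd", "n")]
  }
  do.call(rbind, c(out, make.row.names = FALSE))
}
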