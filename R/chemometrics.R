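# Normalization and unsupervised structure discovery for feature tables:
# quantile + log2 normalization, PCA on centered data, Ward clustering on
# Pearson correlation distance, and per-feature regression trees ranking
# the design factors by their contribution to intensity variance.

#' Quantile-normalize sample columns, then log2-transform
#'
#' Each sample column is mapped onto the mean order-statistic profile
#' (after which all columns share the same multiset of values), then
#' log2(x + pseudocount) is applied. The transform provenance is recorded
#' in the `transform` attribute.
#'
#' @param table Feature table tibble with >= 2 samples.
#' @param pseudocount Non-negative value added before the log.
#' @return A tibble of the same shape with normalized sample columns.
#' @export
normalize_quantile_log <- function(table, pseudocount = 1) {
  smp <- sample_columns(table)
  if (length(smp) < 2) {
    abort("quantile normalization needs at least 2 sample columns")
  }
  if (pseudocount < 0) abort("pseudocount must be non-negative")
  m <- as.matrix(table[smp])
  qn <- limma::normalizeQuantiles(m)
  out <- table
  out[smp] <- as.data.frame(log2(qn + pseudocount))
  attr(out, "transform") <- list(steps = c("quantile", "log2"),
                                 pseudocount = pseudocount)
  out
}

#' Principal component analysis of samples
#'
#' Column-centered (no unit-variance scaling) singular value
#' decomposition of the samples x features matrix; reports scores,
#' loadings and the percentage of variance per component.
#'
#' @param table Normalized feature table (or any feature table tibble).
#' @param n_components Number of components to keep.
#' @return An object of class `pca_result`: list with `scores` (tibble,
#'   sample_id + PCs), `loadings` (tibble, feature_id + PCs),
#'   `var_explained` (percent, descending), `sdev`.
#' @export
pca_2d <- function(table, n_components = 2) {
  smp <- sample_columns(table)
  x <- t(as.matrix(table[smp]))           # samples x features
  max_comp <- min(nrow(x) - 1, ncol(x))
  if (n_components > max_comp) {
    abort(sprintf("n_components must be <= min(samples - 1, features) = %d",
                  max_comp))
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_all <- pc$sdev^2
  var_explained <- 100 * var_all / sum(var_all)
  keep <- seq_len(n_components)
  scores <- as_tibble(pc$x[, keep, drop = FALSE])
  scores <- mutate(scores, sample_id = smp, .before = 1)
  loadings <- as_tibble(pc$rotation[, keep, drop = FALSE])
  loadings <- mutate(loadings, feature_id = table$feature_id, .before = 1)
  out <- list(scores = scores, loadings = loadings,
              var_explained = var_explained[keep],
              sdev = pc$sdev)
  class(out) <- "pca_result"
  out
}

#' Ward hierarchical clustering on Pearson correlation distance
#'
#' Pairwise sample distance d_ij = 1 - Pearson(sample_i, sample_j),
#' clustered with Ward's minimum-variance criterion applied directly to
#' the correlation distance (Ward.D, the usual choice for metabolomics
#' heatmaps, despite Ward's Euclidean derivation).
#'
#' @param table Feature table tibble (normally normalized first).
#' @return An object of class `linkage_tree`: list with `tree` (hclust),
#'   `distance` (matrix), `samples`.
#' @export
hierarchical_cluster <- function(table) {
  smp <- sample_columns(table)
  if (length(smp) < 2) abort("clustering needs at least 2 samples")
  m <- as.matrix(table[smp])
  const <- smp[apply(m, 2, stats::sd) == 0]
  if (length(const)) {
    abort(sprintf("correlation undefined for constant sample(s): %s",
                  paste(const, collapse = ", ")))
  }
  d <- 1 - stats::cor(m)
  tree <- stats::hclust(stats::as.dist(d), method = "ward.D")
  out <- list(tree = tree, distance = d, samples = smp)
  class(out) <- "linkage_tree"
  out
}

#' Cut a linkage tree into k groups
#'
#' @param linkage A `linkage_tree`.
#' @param k Number of groups.
#' @return Tibble with `sample_id`, `cluster`.
#' @export
cut_linkage <- function(linkage, k) {
  cl <- stats::cutree(linkage$tree, k = k)
  tibble(sample_id = names(cl), cluster = unname(cl))
}

#' Rank design factors by contribution to intensity variance
#'
#' Fits, for every feature, a small regression tree (depth <= `max_depth`)
#' predicting the feature's per-sample intensity from the design factors,
#' and aggregates each factor's total variance reduction (rpart variable
#' importance) across features. Scores are normalized to percentages and
#' ranked; ties broken by factor name for determinism.
#'
#' @param table Feature table tibble.
#' @param meta Sample metadata tibble.
#' @param factors Design factor columns to rank.
#' @param max_depth Maximum tree depth.
#' @param seed Integer seed (rpart surrogate handling is deterministic,
#'   but the seed also covers any future stochastic options).
#' @return A tibble of class `factor_importance` with columns `factor`,
#'   `importance`, `importance_pct`, `rank`.
#' @export
rank_factor_importance <- function(table, meta,
                                   factors = c("genotype", "n_conc_mM",
                                               "time_dag", "organ"),
                                   max_depth = 3, seed = NULL) {
  validate_sample_metadata(meta)
  for (f in factors) {
    if (!f %in% names(meta)) abort(sprintf("factor '%s' not in metadata", f))
    if (length(unique(meta[[f]])) < 2) {
      abort(sprintf("factor '%s' has a single level", f))
    }
  }
  smp <- sample_columns(table)
  meta <- meta[match(smp, meta$sample_id), ]
  design <- as.data.frame(lapply(meta[factors], factor))
  m <- as.matrix(table[smp])
  totals <- stats::setNames(numeric(length(factors)), factors)
  with_seed(seed, {
    for (i in seq_len(nrow(m))) {
      dat <- cbind(y = m[i, ], design)
      fit <- rpart::rpart(y ~ ., data = dat, method = "anova",
                          control = rpart::rpart.control(
                            maxdepth = max_depth, cp = 0.001,
                            minsplit = 4, minbucket = 2, xval = 0))
      imp <- fit$variable.importance
      if (!is.null(imp)) {
        common <- intersect(names(imp), factors)
        totals[common] <- totals[common] + imp[common]
      }
    }
  })
  total_sum <- sum(totals)
  pct <- if (total_sum > 0) 100 * totals / total_sum else totals * 0
  ord <- order(-totals, names(totals))
  out <- tibble(factor = names(totals), importance = unname(totals),
                importance_pct = unname(pct))
  out$rank <- match(out$factor, out$factor[ord])
  out <- arrange(out, .data$rank)
  class(out) <- c("factor_importance", class(out))
  out
}
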