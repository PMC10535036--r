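# Community-ecology analysis of spectral features: each m/z_rt feature is
# treated as a species, its ion abundance as the species abundance, and a
# sample as a sampling unit, so richness estimators, diversity indices and
# accumulation curves apply unchanged.

#' Shannon diversity index
#'
#' H' = -sum(p_i log p_i) in natural-log units, where p_i is the abundance
#' share of feature i. Zero abundances are dropped before normalization.
#'
#' @param abundances Non-negative numeric vector with at least one
#'   positive entry.
#' @return Shannon H' (0 for a single feature).
#' @export
shannon <- function(abundances) {
  if (any(abundances < 0)) abort("abundances must be non-negative")
  x <- abundances[abundances > 0]
  if (!length(x)) abort("all abundances are zero: H' is undefined")
  p <- x / sum(x)
  -sum(p * log(p))
}

#' Pielou evenness
#'
#' J' = H' / log(S), the observed Shannon diversity relative to its
#' maximum at richness S. Undefined (NA, with a warning) when S = 1.
#'
#' @param H_prime Shannon diversity in natural-log units.
#' @param S Richness (number of features), >= 1.
#' @return J' in `[0, 1]`, or NA when S = 1.
#' @export
pielou <- function(H_prime, S) {
  if (S < 1) abort("richness S must be at least 1")
  if (S == 1) {
    warn("J' is undefined for a single-feature community (log S = 0)")
    return(NA_real_)
  }
  H_prime / log(S)
}

#' Incidence counts for richness estimation
#'
#' Summarizes a presence/absence matrix into the quantities the
#' nonparametric richness estimators need: observed richness S_obs, the
#' number of features found in exactly one sample (uniques, Q1) and in
#' exactly two samples (duplicates, Q2), and the number of samples m.
#'
#' @param presence Logical matrix features x samples, or the output of
#'   [binarize()].
#' @return A list with `S_obs`, `Q1`, `Q2`, `m` of class
#'   `incidence_counts`.
#' @export
incidence_counts <- function(presence) {
  if (is.data.frame(presence)) presence <- presence_matrix(presence)
  freq <- rowSums(presence)
  out <- list(S_obs = sum(freq > 0), Q1 = sum(freq == 1),
              Q2 = sum(freq == 2), m = ncol(presence))
  class(out) <- "incidence_counts"
  out
}

as_incidence <- function(counts) {
  if (inherits(counts, "incidence_counts")) return(counts)
  if (is.list(counts) && all(c("S_obs", "Q1", "Q2", "m") %in% names(counts)))
    return(counts)
  abort("expected an incidence_counts object (see incidence_counts())")
}

#' Chao1 richness estimator
#'
#' Classic form S_obs + Q1^2 / (2 Q2) when doubletons exist; the
#' bias-corrected form S_obs + Q1 (Q1 - 1) / 2 when Q2 = 0. Always at
#' least S_obs.
#'
#' @param counts An [incidence_counts()] object (Q1 = uniques,
#'   Q2 = duplicates).
#' @return Estimated richness.
#' @export
chao1 <- function(counts) {
  counts <- as_incidence(counts)
  with(counts, {
    if (Q2 > 0) S_obs + Q1^2 / (2 * Q2)
    else S_obs + Q1 * (Q1 - 1) / 2
  })
}

#' First- and second-order jackknife richness estimators
#'
#' Order 1: S_obs + Q1 (m - 1) / m. Order 2:
#' S_obs + Q1 (2m - 3) / m - Q2 (m - 2)^2 / (m (m - 1)).
#'
#' @param counts An [incidence_counts()] object.
#' @param order 1 or 2.
#' @return Estimated richness.
#' @export
jackknife <- function(counts, order = 1) {
  counts <- as_incidence(counts)
  if (!order %in% c(1, 2)) abort("jackknife order must be 1 or 2")
  if (counts$m < 2) abort("jackknife requires at least 2 samples")
  with(counts, {
    if (order == 1) S_obs + Q1 * (m - 1) / m
    else S_obs + Q1 * (2 * m - 3) / m - Q2 * (m - 2)^2 / (m * (m - 1))
  })
}

#' Species accumulation curve over samples
#'
#' Expected feature richness as samples are accumulated, either by
#' averaging over random sample orderings (`method = "permutation"`, with
#' the SD of richness at each accumulation step) or by the exact
#' sample-based rarefaction formula
#' E`[`S_k`]` = sum_i (1 - choose(m - m_i, k) / choose(m, k)), where m_i is
#' the number of samples containing feature i. Both reach S_obs at k = m.
#' Chao1 and jackknife asymptote estimates are attached.
#'
#' @param presence Logical matrix or [binarize()] output.
#' @param n_permutations Number of random orderings (permutation method).
#' @param seed Integer seed for the permutation method.
#' @param method `"permutation"` or `"exact"`.
#' @return A tibble of class `sac_curve` with columns `k`,
#'   `mean_richness`, `sd`, and attributes `asymptote_estimates`,
#'   `S_obs`, `method`, `n_permutations`, `seed`.
#' @export
species_accumulation <- function(presence, n_permutations = 100, seed = NULL,
                                 method = c("permutation", "exact")) {
  method <- match.arg(method)
  if (is.data.frame(presence)) presence <- presence_matrix(presence)
  if (!length(presence) || ncol(presence) < 1) {
    abort("presence matrix is empty")
  }
  m <- ncol(presence)
  freq <- rowSums(presence)
  present <- presence[freq > 0, , drop = FALSE]
  freq <- freq[freq > 0]
  S_obs <- nrow(present)

  if (method == "exact") {
    mean_richness <- vapply(seq_len(m), function(k) {
      sum(1 - exp(lchoose(m - freq, k) - lchoose(m, k)))
    }, 0)
    sd_k <- rep(NA_real_, m)
  } else {
    if (n_permutations < 1) abort("n_permutations must be at least 1")
    rich <- with_seed(seed, {
      vapply(seq_len(n_permutations), function(i) {
        ord <- sample(m)
        seen <- matrixStats_cummax(present[, ord, drop = FALSE])
        colSums(seen)
      }, numeric(m))
    })
    rich <- matrix(rich, nrow = m)
    mean_richness <- rowMeans(rich)
    sd_k <- apply(rich, 1, stats::sd)
  }
  est <- incidence_counts(present)
  curve <- tibble(k = seq_len(m), mean_richness = mean_richness, sd = sd_k)
  attr(curve, "asymptote_estimates") <- c(
    chao1 = chao1(est),
    jack1 = if (m >= 2) jackknife(est, 1) else NA_real_,
    jack2 = if (m >= 2) jackknife(est, 2) else NA_real_)
  attr(curve, "S_obs") <- S_obs
  attr(curve, "method") <- method
  attr(curve, "n_permutations") <- if (method == "permutation") n_permutations else NA_integer_
  attr(curve, "seed") <- seed
  class(curve) <- c("sac_curve", class(curve))
  curve
}

# cumulative "seen so far" along accumulated samples (logical OR scan)
matrixStats_cummax <- function(x) {
  out <- x
  if (ncol(x) > 1) {
    for (j in 2:ncol(x)) out[, j] <- out[, j] | out[, j - 1]
  }
  out
}

#' Asymptote summary of an accumulation curve
#'
#' Reports the richness at the accumulation asymptote and the share of the
#' full spectral library it represents, as a percentage truncated to two
#' decimals (matching the reporting convention used throughout the
#' package).
#'
#' @param curve A `sac_curve`, or a single asymptote richness value.
#' @param library_total Total number of features in the library.
#' @return A tibble with `asymptote`, `library_total`, `common_pct`.
#' @export
asymptote_summary <- function(curve, library_total) {
  if (length(library_total) != 1 || library_total <= 0) {
    abort("library_total must be a single positive count")
  }
  asym <- if (inherits(curve, "sac_curve")) {
    curve$mean_richness[nrow(curve)]
  } else {
    as.numeric(curve)
  }
  if (library_total < asym) {
    abort("library_total cannot be smaller than the asymptote richness")
  }
  tibble(asymptote = asym, library_total = library_total,
         common_pct = percent_trunc(asym, library_total))
}

# percentage truncated (not rounded) to `digits` decimals
percent_trunc <- function(part, whole, digits = 2) {
  floor(100 * part / whole * 10^digits + 1e-9) / 10^digits
}

#' Fit a rank-abundance curve model
#'
#' Sorts abundances in decreasing order and fits the expected relative
#' abundance at each rank under the chosen model. The ecological null is
#' the broken-stick model, whose expected proportion at rank i of S is
#' (1/S) sum_(k=i..S) 1/k (no free parameters). Also available:
#' geometric-series preemption (one parameter, fitted by golden-section
#' search) and the log-normal rank model (two parameters). Deviance is the
#' residual sum of squares on proportions; AIC is computed from the
#' Gaussian log-likelihood of the proportion residuals.
#'
#' @param abundances Non-negative vector with at least one positive entry.
#' @param model `"broken_stick"`, `"preemption"` or `"lognormal"`.
#' @return A tibble of class `rac_fit` with columns `rank`, `abundance`,
#'   `proportion`, `fitted_proportion` and attributes `model`, `deviance`,
#'   `aic`, `n_parameters`.
#' @export
rank_abundance_fit <- function(abundances,
                               model = c("broken_stick", "preemption",
                                         "lognormal")) {
  model <- tryCatch(match.arg(model), error = function(e)
    abort(sprintf("unsupported model '%s'; available: broken_stick, preemption, lognormal",
                  model[1])))
  x <- sort(abundances[abundances > 0], decreasing = TRUE)
  if (!length(x)) abort("all abundances are zero")
  S <- length(x)
  p_obs <- x / sum(x)
  ranks <- seq_len(S)
  fit <- switch(model,
    broken_stick = {
      p_exp <- vapply(ranks, function(i) sum(1 / (i:S)) / S, 0)
      list(p = p_exp, k = 0L)
    },
    preemption = {
      f <- function(alpha) {
        p <- alpha * (1 - alpha)^(ranks - 1)
        p <- p / sum(p)
        sum((p_obs - p)^2)
      }
      alpha <- stats::optimize(f, c(1e-6, 1 - 1e-6))$minimum
      p <- alpha * (1 - alpha)^(ranks - 1)
      list(p = p / sum(p), k = 1L)
    },
    lognormal = {
      # expected proportion from normal quantiles of log abundance
      q <- stats::qnorm((ranks - 0.5) / S)
      f <- function(par) {
        p <- exp(par[1] + par[2] * rev(q))
        p <- p / sum(p)
        sum((p_obs - p)^2)
      }
      par <- stats::optim(c(log(1 / S), 1), f)$par
      p <- exp(par[1] + par[2] * rev(q))
      list(p = p / sum(p), k = 2L)
    })
  rss <- sum((p_obs - fit$p)^2)
  # Gaussian AIC on proportion residuals; +1 parameter for the variance
  aic <- if (rss < .Machine$double.eps) -Inf else
    S * log(rss / S) + 2 * (fit$k + 1)
  out <- tibble(rank = ranks, abundance = x, proportion = p_obs,
                fitted_proportion = fit$p)
  attr(out, "model") <- model
  attr(out, "deviance") <- rss
  attr(out, "aic") <- aic
  attr(out, "n_parameters") <- fit$k
  class(out) <- c("rac_fit", class(out))
  out
}

#' Pearson correlation between richness and diversity
#'
#' Reports Pearson's r, the coefficient of determination as a percentage
#' (R2 = 100 r^2), and the two-sided p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3 with nonzero variance.
#' @return A tibble with `r`, `R2`, `p_value`, `n`.
#' @export
correlate_richness_diversity <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("correlation requires at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("correlation is undefined for a constant vector")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), R2 = 100 * unname(ct$estimate)^2,
         p_value = ct$p.value, n = length(x))
}

#' One-way ANOVA with Tukey HSD letter display
#'
#' Fits a one-way ANOVA of `values` on `groups`, runs Tukey's honest
#' significant difference test, and summarizes the pairwise results as a
#' compact letter display (groups sharing no letter differ at `alpha`).
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor).
#' @param alpha Significance level for the letter display.
#' @return A list of class `anova_tukey` with elements `F`, `p_value`,
#'   `group_means` (tibble), `tukey` (tibble of pairwise comparisons),
#'   `tukey_letters` (named character), `alpha`.
#' @export
anova_tukey <- function(values, groups, alpha = 0.05) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) abort("need at least 2 groups")
  sizes <- table(groups)
  if (any(sizes < 2)) {
    abort(sprintf("Tukey's test needs >= 2 observations per group (too small: %s)",
                  paste(names(sizes)[sizes < 2], collapse = ", ")))
  }
  dat <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = dat)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  pair_names <- rownames(tk)
  pairs <- do.call(rbind, strsplit(pair_names, "-", fixed = TRUE))
  tukey <- tibble(group_a = pairs[, 1], group_b = pairs[, 2],
                  diff = tk[, "diff"], p_adj = tk[, "p adj"])
  means <- dat |>
    group_by(g) |>
    summarise(mean = mean(.data$y), n = dplyr::n(), .groups = "drop") |>
    rename(group = "g")
  out <- list(F = an[1, "F value"], p_value = an[1, "Pr(>F)"],
              group_means = means, tukey = tukey,
              tukey_letters = letter_display(tukey, levels(groups), alpha),
              alpha = alpha)
  class(out) <- "anova_tukey"
  out
}

# insert-and-absorb compact letter display from pairwise adjusted p-values
letter_display <- function(tukey, groups, alpha) {
  k <- length(groups)
  differ <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  for (i in seq_len(nrow(tukey))) {
    a <- tukey$group_a[i]; b <- tukey$group_b[i]
    if (!is.na(tukey$p_adj[i]) && tukey$p_adj[i] <= alpha) {
      differ[a, b] <- differ[b, a] <- TRUE
    }
  }
  # each letter = a maximal set of mutually non-different groups
  sets <- list()
  for (g in groups) {
    placed <- FALSE
    for (s in seq_along(sets)) {
      if (!any(differ[g, sets[[s]]])) {
        sets[[s]] <- c(sets[[s]], g)
        placed <- TRUE
      }
    }
    if (!placed) sets[[length(sets) + 1]] <- g
  }
  # absorb subsets
  keep <- rep(TRUE, length(sets))
  for (i in seq_along(sets)) {
    for (j in seq_along(sets)) {
      if (i != j && keep[i] && keep[j] && all(sets[[i]] %in% sets[[j]])) {
        keep[i] <- FALSE
      }
    }
  }
  sets <- sets[keep]
  letters_out <- stats::setNames(rep("", k), groups)
  for (s in seq_along(sets)) {
    for (g in sets[[s]]) {
      letters_out[g] <- paste0(letters_out[g], letters[s])
    }
  }
  letters_out
}

#' Per-group diversity profiles of a feature table
#'
#' Splits samples by the requested design factors and computes, per
#' group: observed richness S, Shannon H', Pielou J', and the Chao1 and
#' jackknife richness estimates from presence/absence across the group's
#' samples. Abundance-based indices use replicate-summed intensities by
#' default (`aggregate = "sum"`), or the per-sample mean of the index
#' (`aggregate = "mean_per_sample"`).
#'
#' @param table Feature table tibble.
#' @param meta Sample metadata tibble.
#' @param group_by Character vector of metadata columns defining groups.
#' @param detection_threshold Intensity threshold for presence.
#' @param aggregate `"sum"` or `"mean_per_sample"`.
#' @return A tibble with one row per group.
#' @export
diversity_profile <- function(table, meta,
                              group_by = c("genotype", "n_conc_mM",
                                           "time_dag", "organ"),
                              detection_threshold = 0,
                              aggregate = c("sum", "mean_per_sample")) {
  aggregate <- match.arg(aggregate)
  validate_sample_metadata(meta)
  miss <- setdiff(group_by, names(meta))
  if (length(miss)) {
    abort(sprintf("group_by column(s) not in metadata: %s",
                  paste(miss, collapse = ", ")))
  }
  groups <- meta |>
    group_by(across(all_of(group_by))) |>
    summarise(sample_ids = list(.data$sample_id), .groups = "drop")
  rows <- pmap(groups, function(...) {
    row <- list(...)
    ids <- row$sample_ids
    sub <- as.matrix(table[ids])
    rownames(sub) <- table$feature_id
    pres <- sub > detection_threshold
    counts <- incidence_counts(pres)
    abund <- if (aggregate == "sum") rowSums(sub) else NULL
    if (aggregate == "sum") {
      H <- shannon(abund)
      S <- sum(abund > 0)
    } else {
      per <- apply(sub, 2, function(col) {
        if (any(col > 0)) shannon(col) else NA_real_
      })
      H <- mean(per, na.rm = TRUE)
      S <- counts$S_obs
    }
    J <- if (S > 1) H / log(S) else NA_real_
    tibble(!!!row[group_by], S = S, H_prime = H, J_prime = J,
           S_obs = counts$S_obs, Q1 = counts$Q1, Q2 = counts$Q2,
           m = counts$m,
           chao1 = chao1(counts),
           jack1 = if (counts$m >= 2) jackknife(counts, 1) else NA_real_,
           jack2 = if (counts$m >= 2) jackknife(counts, 2) else NA_real_)
  })
  list_rbind(rows)
}
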