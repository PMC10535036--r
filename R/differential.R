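# Differential chemical-marker calling: pairwise 4 mM vs 0.2 mM nitrate
# contrasts, group-mean fold changes with a two-sided FC >= 2 rule,
# per-ESI-mode calling followed by cross-mode set union (avoiding the
# mutual suppression bias of pooling ionization modes first), and
# unique/shared partitioning of differential features across contrasts.

#' Build the study's pairwise nitrate contrasts
#'
#' Each contrast compares optimal (4 mM) against depleted (0.2 mM)
#' nitrate within one genotype-by-organ cell; both sampling times are
#' included on both sides, so time is matched across the contrast.
#' `per_mode_4` yields the four contrasts to be applied within each ESI
#' mode; `merged_4` yields the same four labels scoped for cross-mode
#' merged differential sets.
#'
#' @param meta Sample metadata tibble.
#' @param scheme `"per_mode_4"` or `"merged_4"`.
#' @return A tibble of class `contrast_spec` with columns `label`,
#'   `genotype`, `organ`, `n_conc_A`, `n_conc_B`, `mode_scope`.
#' @export
build_contrasts <- function(meta, scheme = c("per_mode_4", "merged_4")) {
  scheme <- match.arg(scheme)
  validate_sample_metadata(meta)
  cells <- tidyr::expand_grid(genotype = c("WT", "nia1_nia2"),
                              organ = c("rosette", "root"))
  for (i in seq_len(nrow(cells))) {
    for (conc in c(4, 0.2)) {
      hit <- meta$genotype == cells$genotype[i] &
        meta$organ == cells$organ[i] & meta$n_conc_mM == conc
      if (!any(hit)) {
        abort(sprintf("no samples for design cell %s/%s at %g mM",
                      cells$genotype[i], cells$organ[i], conc))
      }
    }
  }
  out <- mutate(cells,
                label = sprintf("%s_%s_4mM_vs_0.2mM", .data$genotype,
                                .data$organ),
                n_conc_A = 4, n_conc_B = 0.2,
                mode_scope = if (scheme == "merged_4") "merged" else "per_mode",
                .before = 1)
  out <- relocate(out, "label")
  class(out) <- c("contrast_spec", class(out))
  out
}

select_contrast_samples <- function(meta, spec_row, side = c("A", "B")) {
  side <- match.arg(side)
  conc <- if (side == "A") spec_row$n_conc_A else spec_row$n_conc_B
  meta$sample_id[meta$genotype == spec_row$genotype &
                   meta$organ == spec_row$organ &
                   meta$n_conc_mM == conc]
}

#' Fold change of one contrast over a feature table
#'
#' FC = (mean_A + pseudocount) / (mean_B + pseudocount) on raw group-mean
#' intensities, with log2FC, and a Welch two-sample t-test on
#' log2(x + pseudocount) when both sides have >= 2 samples.
#'
#' @param table Feature table tibble.
#' @param meta Sample metadata tibble.
#' @param spec One row of a [build_contrasts()] tibble (or the tibble
#'   itself with `contrast` selecting a row by label).
#' @param pseudocount Positive value stabilizing zero means.
#' @param contrast Label selecting a row when `spec` has several.
#' @return A tibble of class `contrast_result` with per-feature columns
#'   `feature_id`, `esi_mode`, `mean_A`, `mean_B`, `FC`, `log2FC`,
#'   `p_value`, and attribute `contrast`.
#' @export
fold_change_contrast <- function(table, meta, spec, pseudocount = 1,
                                 contrast = NULL) {
  if (nrow(spec) > 1) {
    if (is.null(contrast)) abort("spec has several contrasts: pick one via `contrast`")
    spec <- spec[spec$label == contrast, ]
    if (!nrow(spec)) abort(sprintf("no contrast labelled '%s'", contrast))
  }
  if (pseudocount <= 0) abort("pseudocount must be positive")
  ids_A <- select_contrast_samples(meta, spec, "A")
  ids_B <- select_contrast_samples(meta, spec, "B")
  ids_A <- intersect(ids_A, sample_columns(table))
  ids_B <- intersect(ids_B, sample_columns(table))
  if (!length(ids_A) || !length(ids_B)) {
    abort(sprintf("contrast '%s': a selector matches no samples in the table",
                  spec$label))
  }
  fold_change_groups(table, ids_A, ids_B, pseudocount = pseudocount,
                     label = spec$label)
}

#' Fold change between two explicit sample groups
#'
#' The workhorse behind [fold_change_contrast()], usable with any sample
#' split (e.g. genotype groups in recovery studies).
#'
#' @param table Feature table tibble.
#' @param ids_A,ids_B Sample-id character vectors (columns of `table`).
#' @param pseudocount Positive value stabilizing zero means.
#' @param label Contrast label recorded on the result.
#' @return A `contrast_result` tibble (see [fold_change_contrast()]).
#' @export
fold_change_groups <- function(table, ids_A, ids_B, pseudocount = 1,
                               label = "custom") {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (!length(ids_A) || !length(ids_B)) abort("both groups need samples")
  mA <- rowMeans(as.matrix(table[ids_A]))
  mB <- rowMeans(as.matrix(table[ids_B]))
  fc <- (mA + pseudocount) / (mB + pseudocount)
  p <- rep(NA_real_, nrow(table))
  if (length(ids_A) >= 2 && length(ids_B) >= 2) {
    lA <- log2(as.matrix(table[ids_A]) + pseudocount)
    lB <- log2(as.matrix(table[ids_B]) + pseudocount)
    p <- vapply(seq_len(nrow(table)), function(i) {
      a <- lA[i, ]; b <- lB[i, ]
      if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        if (mean(a) == mean(b)) 1 else 0
      } else {
        tryCatch(stats::t.test(a, b)$p.value, error = function(e) NA_real_)
      }
    }, 0)
  }
  out <- tibble(feature_id = table$feature_id, esi_mode = table$esi_mode,
                mean_A = mA, mean_B = mB, FC = fc, log2FC = log2(fc),
                p_value = p)
  attr(out, "contrast") <- label
  attr(out, "pseudocount") <- pseudocount
  class(out) <- c("contrast_result", class(out))
  out
}

#' Flag differential features in a contrast result
#'
#' The fold-change rule is two-sided: a feature is differential when
#' max(FC, 1/FC) >= `fc_min` (and, if `p_max` is given, p <= `p_max`).
#' Direction records which side of the contrast the feature is higher in.
#'
#' @param result A `contrast_result` from [fold_change_contrast()].
#' @param fc_min Fold-change threshold, >= 1 (inclusive).
#' @param p_max Optional p-value ceiling; default none.
#' @return The result tibble with added `is_differential`, `direction`
#'   and `neg_log10_p` (volcano ordinate) columns.
#' @export
call_differential <- function(result, fc_min = 2, p_max = NULL) {
  if (fc_min < 1) abort("fc_min must be >= 1")
  two_sided <- pmax(result$FC, 1 / result$FC)
  flag <- two_sided >= fc_min
  if (!is.null(p_max)) {
    flag <- flag & !is.na(result$p_value) & result$p_value <= p_max
  }
  out <- mutate(result,
                is_differential = flag,
                direction = ifelse(.data$FC >= 1, "up_in_A", "up_in_B"),
                neg_log10_p = -log10(.data$p_value))
  attr(out, "fc_min") <- fc_min
  attr(out, "p_max") <- p_max
  attr(out, "contrast") <- attr(result, "contrast")
  class(out) <- unique(c("contrast_result", class(out)))
  out
}

#' Run all contrasts of one mode and return differential sets
#'
#' Convenience wrapper: applies [fold_change_contrast()] and
#' [call_differential()] for every contrast over one mode's feature
#' table.
#'
#' @param table One mode's feature table.
#' @param meta Sample metadata.
#' @param specs [build_contrasts()] output.
#' @param fc_min,p_max,pseudocount Passed through.
#' @return Named list (by contrast label) of character vectors of
#'   differential feature ids.
#' @export
differential_sets <- function(table, meta, specs, fc_min = 2, p_max = NULL,
                              pseudocount = 1) {
  sets <- map(seq_len(nrow(specs)), function(i) {
    res <- fold_change_contrast(table, meta, specs[i, ],
                                pseudocount = pseudocount)
    res <- call_differential(res, fc_min = fc_min, p_max = p_max)
    res$feature_id[res$is_differential]
  })
  stats::setNames(sets, specs$label)
}

#' Merge per-mode differential sets into merged contrasts
#'
#' For each contrast label, the merged differential set is the union of
#' the mode-specific differential sets; features keep their mode tags, so
#' the union never collapses features across polarities. Differential
#' calling must happen per mode *before* merging — pooling the raw
#' libraries first would let ionization differences between modes mask
#' real signals (the mutual suppression effect), so passing feature
#' tables here is an error.
#'
#' @param per_mode_results Named list (one element per ESI mode) of named
#'   lists (one element per contrast label) of differential feature-id
#'   character vectors.
#' @return Named list of merged differential sets, one per contrast.
#' @export
merge_contrasts_across_modes <- function(per_mode_results) {
  if (is.data.frame(per_mode_results) ||
      any(map_lgl(per_mode_results, is.data.frame))) {
    abort(paste("merge_contrasts_across_modes takes per-mode differential",
                "feature-id sets, not feature tables: call differential",
                "features per ESI mode first (merging raw libraries before",
                "calling invites the mutual suppression effect)"))
  }
  labels <- unique(unlist(map(per_mode_results, names)))
  merged <- map(labels, function(lab) {
    sort(unique(unlist(map(per_mode_results, ~ .x[[lab]]))))
  })
  stats::setNames(merged, labels)
}

#' Partition differential features into unique vs shared
#'
#' Across a list of per-contrast differential sets, a feature is "unique"
#' when it appears in exactly one contrast and "shared" when it appears
#' in two or more. Fractions are percentages of the total, truncated to
#' two decimals.
#'
#' @param sets Named list of character vectors (one per contrast).
#' @return A one-row tibble with `total`, `unique_count`, `shared_count`,
#'   `unique_fraction`, `shared_fraction`, `n_contrasts`.
#' @export
partition_unique_shared <- function(sets) {
  if (!length(sets)) abort("need at least one differential set")
  counts <- table(unlist(map(sets, unique)))
  total <- length(counts)
  uniq <- sum(counts == 1)
  shared <- sum(counts >= 2)
  if (total == 0) {
    warn("empty union: fractions undefined")
    return(tibble(total = 0L, unique_count = 0L, shared_count = 0L,
                  unique_fraction = NA_real_, shared_fraction = NA_real_,
                  n_contrasts = length(sets)))
  }
  tibble(total = total, unique_count = uniq, shared_count = shared,
         unique_fraction = percent_trunc(uniq, total),
         shared_fraction = percent_trunc(shared, total),
         n_contrasts = length(sets))
}
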