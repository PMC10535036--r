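# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_point
#'   geom_col geom_hline geom_vline labs theme_minimal scale_y_log10
#'   coord_flip facet_wrap
#' @export
ggplot2::autoplot

#' @export
tidy.sac_curve <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.sac_curve <- function(x, ...) {
  est <- attr(x, "asymptote_estimates")
  tibble(S_obs = attr(x, "S_obs"), chao1 = est[["chao1"]],
         jack1 = est[["jack1"]], jack2 = est[["jack2"]],
         method = attr(x, "method"),
         n_permutations = attr(x, "n_permutations"))
}

#' @export
tidy.rac_fit <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.rac_fit <- function(x, ...) {
  tibble(model = attr(x, "model"), deviance = attr(x, "deviance"),
         aic = attr(x, "aic"), n_parameters = attr(x, "n_parameters"),
         n_ranks = nrow(x))
}

#' @export
tidy.pca_result <- function(x, ...) {
  x$scores
}

#' @export
glance.pca_result <- function(x, ...) {
  tibble(component = paste0("PC", seq_along(x$var_explained)),
         var_explained = x$var_explained)
}

#' @export
tidy.anova_tukey <- function(x, ...) {
  x$tukey
}

#' @export
glance.anova_tukey <- function(x, ...) {
  tibble(F = x$F, p_value = x$p_value, n_groups = nrow(x$group_means),
         alpha = x$alpha)
}

#' @export
tidy.contrast_result <- function(x, ...) {
  as_tibble(x)
}

#' @export
glance.contrast_result <- function(x, ...) {
  tibble(contrast = attr(x, "contrast") %||% NA_character_,
         n_features = nrow(x),
         n_differential = if ("is_differential" %in% names(x))
           sum(x$is_differential) else NA_integer_,
         fc_min = attr(x, "fc_min") %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Accumulation-curve plot
#'
#' @param object A `sac_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sac_curve <- function(object, ...) {
  df <- as_tibble(object)
  p <- ggplot(df, aes(x = .data$k, y = .data$mean_richness))
  if (!all(is.na(df$sd))) {
    p <- p + geom_ribbon(aes(ymin = .data$mean_richness - .data$sd,
                             ymax = .data$mean_richness + .data$sd),
                         alpha = 0.2)
  }
  p + geom_line() + geom_point() +
    labs(x = "samples accumulated", y = "expected feature richness",
         title = "Species accumulation curve") +
    theme_minimal()
}

#' Rank-abundance plot with fitted model
#'
#' @param object A `rac_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rac_fit <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$rank)) +
    geom_point(aes(y = .data$proportion)) +
    geom_line(aes(y = .data$fitted_proportion), colour = "steelblue") +
    scale_y_log10() +
    labs(x = "abundance rank", y = "relative abundance",
         title = sprintf("Rank-abundance curve (%s fit)",
                         attr(object, "model"))) +
    theme_minimal()
}

#' PCA score plot
#'
#' @param object A `pca_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pca_result <- function(object, ...) {
  sc <- object$scores
  ggplot(sc, aes(x = .data$PC1, y = .data$PC2)) +
    geom_point() +
    labs(x = sprintf("PC1 (%.1f%%)", object$var_explained[1]),
         y = sprintf("PC2 (%.1f%%)", object$var_explained[2]),
         title = "PCA of samples") +
    theme_minimal()
}

#' Volcano plot of a flagged contrast result
#'
#' @param result A `contrast_result` after [call_differential()].
#' @param fc_min Fold-change threshold drawn as guides.
#' @return A ggplot.
#' @export
plot_volcano <- function(result, fc_min = attr(result, "fc_min") %||% 2) {
  df <- as_tibble(result)
  ggplot(df, aes(x = .data$log2FC, y = .data$neg_log10_p,
                 colour = .data$is_differential)) +
    geom_point(alpha = 0.6) +
    geom_vline(xintercept = c(-log2(fc_min), log2(fc_min)),
               linetype = "dashed") +
    labs(x = "log2 fold change", y = "-log10 p",
         colour = "differential",
         title = attr(result, "contrast") %||% "contrast") +
    theme_minimal()
}

#' Population-pyramid plot of paired fold changes
#'
#' @param pyramid A `pyramid_table`.
#' @return A ggplot with side-A magnitudes to the left and side-B to the
#'   right.
#' @export
plot_pyramid <- function(pyramid) {
  pair <- attr(pyramid, "pair")
  df <- as_tibble(pyramid) |>
    mutate(label = ifelse(is.na(.data$name), .data$compound_id, .data$name)) |>
    tidyr::pivot_longer(c("fc_A", "fc_B"), names_to = "side",
                        values_to = "FC") |>
    mutate(signed = ifelse(.data$side == "fc_A", -.data$FC, .data$FC))
  ggplot(df, aes(x = stats::reorder(.data$label, abs(.data$signed)),
                 y = .data$signed, fill = .data$side)) +
    geom_col() +
    coord_flip() +
    labs(x = NULL, y = sprintf("fold change (left: %s, right: %s)",
                               pair[1], pair[2])) +
    theme_minimal()
}
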