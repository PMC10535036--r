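# Pipeline bookkeeping: a validated summary report of the per-mode and
# merged counts, population-pyramid fold-change comparison tables, and
# metabolite-to-pathway link tables for circular-plot input.

#' Assemble and validate the pipeline summary report
#'
#' Collects the headline bookkeeping of a full run — per-mode library
#' totals, differential unique/shared partitions, accumulation-curve
#' asymptote summaries, the annotated-feature split by genotype, and the
#' pathway unique-contrast/multi-contrast partition — and checks every
#' partition identity (unique + shared = total; splits sum to their
#' totals). Any violation is an error: an inconsistent report never
#' leaves this function.
#'
#' @param library_totals Named numeric, features per ESI mode, e.g.
#'   `c(positive = 3407, negative = 4521)`.
#' @param partitions Named list (by mode) of [partition_unique_shared()]
#'   rows.
#' @param sac_summaries Optional named list (by mode) of
#'   [asymptote_summary()] rows.
#' @param annotation_split Optional named numeric of annotated feature
#'   counts per genotype.
#' @param pathway_partition Optional named numeric
#'   `c(unique_contrast = ..., multi_contrast = ...)`.
#' @return A list of class `summary_report`.
#' @export
build_summary <- function(library_totals, partitions,
                          sac_summaries = NULL, annotation_split = NULL,
                          pathway_partition = NULL) {
  report <- list(
    library_totals = library_totals,
    total_signals = sum(library_totals),
    partitions = partitions,
    sac_summaries = sac_summaries,
    annotation_split = annotation_split,
    annotated_total = if (!is.null(annotation_split)) sum(annotation_split),
    pathway_partition = pathway_partition,
    pathway_total = if (!is.null(pathway_partition)) sum(pathway_partition)
  )
  for (mode in names(partitions)) {
    p <- partitions[[mode]]
    if (p$unique_count + p$shared_count != p$total) {
      abort(sprintf(
        "summary integrity: %s partition violates unique + shared = total (%d + %d != %d)",
        mode, p$unique_count, p$shared_count, p$total))
    }
    if (!is.na(p$unique_fraction) && !is.na(p$shared_fraction)) {
      if (abs(p$unique_fraction + p$shared_fraction - 100) > 0.02) {
        abort(sprintf("summary integrity: %s fractions do not sum to 100%%", mode))
      }
    }
  }
  if (!is.null(sac_summaries)) {
    for (mode in names(sac_summaries)) {
      s <- sac_summaries[[mode]]
      if (s$asymptote > s$library_total) {
        abort(sprintf("summary integrity: %s asymptote exceeds library total", mode))
      }
    }
  }
  if (!is.null(annotation_split) && any(annotation_split < 0)) {
    abort("summary integrity: negative annotation count")
  }
  if (!is.null(pathway_partition)) {
    need <- c("unique_contrast", "multi_contrast")
    if (!all(need %in% names(pathway_partition))) {
      abort("pathway_partition needs 'unique_contrast' and 'multi_contrast'")
    }
  }
  flagged <- all(map_dbl(partitions, ~ .x$total) == 0)
  report$empty <- flagged
  if (flagged) warn("summary report has no differential features")
  class(report) <- "summary_report"
  report
}

#' @export
print.summary_report <- function(x, ...) {
  cat("Pipeline summary report\n")
  cat(sprintf("  spectral signals: %s (total %d)\n",
              paste(sprintf("%s=%d", names(x$library_totals),
                            x$library_totals), collapse = ", "),
              x$total_signals))
  for (mode in names(x$partitions)) {
    p <- x$partitions[[mode]]
    cat(sprintf("  %s differential: %d (%d unique [%.2f%%], %d shared [%.2f%%])\n",
                mode, p$total, p$unique_count, p$unique_fraction,
                p$shared_count, p$shared_fraction))
  }
  if (!is.null(x$sac_summaries)) {
    for (mode in names(x$sac_summaries)) {
      s <- x$sac_summaries[[mode]]
      cat(sprintf("  %s SAC asymptote: %g of %d (%.2f%% common)\n",
                  mode, s$asymptote, s$library_total, s$common_pct))
    }
  }
  if (!is.null(x$annotation_split)) {
    cat(sprintf("  annotated: %d (%s)\n", x$annotated_total,
                paste(sprintf("%s=%d", names(x$annotation_split),
                              x$annotation_split), collapse = ", ")))
  }
  if (!is.null(x$pathway_partition)) {
    cat(sprintf("  pathways: %d (%d unique-contrast, %d multi-contrast)\n",
                x$pathway_total, x$pathway_partition[["unique_contrast"]],
                x$pathway_partition[["multi_contrast"]]))
  }
  invisible(x)
}

#' Write a summary report as JSON
#'
#' @param report A `summary_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_summary <- function(report, path) {
  out <- unclass(report)
  out$schema_version <- "1.0"
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Population-pyramid fold-change comparison table
#'
#' Puts the fold changes of annotated metabolites in two contrasts
#' back-to-back (side A vs side B), one row per metabolite, sorted by the
#' larger of the two magnitudes; a metabolite missing from one side keeps
#' an NA magnitude and is flagged in `missing_side`.
#'
#' @param annotated_fc Tibble with columns `compound_id` (optionally
#'   `name`), `contrast`, `FC`.
#' @param pair Character vector of the two contrast labels to compare.
#' @return Tibble of class `pyramid_table` with `compound_id`, `name`,
#'   `fc_A`, `fc_B`, `missing_side`, sorted descending by
#'   max(fc_A, fc_B).
#' @export
population_pyramid_table <- function(annotated_fc, pair) {
  if (length(pair) != 2) abort("pair must name exactly two contrasts")
  if (!all(pair %in% annotated_fc$contrast)) {
    abort(sprintf("contrast(s) absent from the table: %s",
                  paste(setdiff(pair, annotated_fc$contrast), collapse = ", ")))
  }
  if (!"name" %in% names(annotated_fc)) annotated_fc$name <- NA_character_
  wide <- annotated_fc |>
    dplyr::filter(.data$contrast %in% pair) |>
    select("compound_id", "name", "contrast", "FC") |>
    distinct(.data$compound_id, .data$contrast, .keep_all = TRUE) |>
    tidyr::pivot_wider(names_from = "contrast", values_from = "FC")
  fc_A <- wide[[pair[1]]]
  fc_B <- wide[[pair[2]]]
  out <- tibble(compound_id = wide$compound_id, name = wide$name,
                fc_A = fc_A, fc_B = fc_B,
                missing_side = dplyr::case_when(
                  is.na(fc_A) & is.na(fc_B) ~ "both",
                  is.na(fc_A) ~ "A",
                  is.na(fc_B) ~ "B",
                  TRUE ~ "none"))
  out <- arrange(out, dplyr::desc(pmax(.data$fc_A, .data$fc_B, na.rm = TRUE)))
  attr(out, "pair") <- pair
  class(out) <- c("pyramid_table", class(out))
  out
}

#' Metabolite-pathway link table for circular plots
#'
#' One link per (annotated differential compound, pathway containing it),
#' weighted by |log2FC|; ready for circos-style rendering.
#'
#' @param annotation Annotation hits tibble (from [annotate_features()]),
#'   restricted to differential features; NA compound rows are ignored.
#' @param enrichment [pathway_overrepresentation()] tibble for the
#'   contrast (only pathways with k >= 1 contribute links).
#' @param fc Tibble with `feature_id` and `log2FC` for the contrast.
#' @param pathways Pathway tibble or database list.
#' @return Tibble with `compound_id`, `pathway_id`, `weight`.
#' @export
circos_link_table <- function(annotation, enrichment, fc, pathways) {
  if (!is.data.frame(pathways)) pathways <- pathways$pathways
  ann <- dplyr::filter(annotation, !is.na(.data$compound_id))
  ann <- left_join(ann, select(fc, "feature_id", "log2FC"),
                   by = "feature_id")
  active <- enrichment$pathway_id[enrichment$k >= 1]
  rows <- map(active, function(pid) {
    members <- pathway_members(pathways, pid)
    linked <- dplyr::filter(ann, .data$compound_id %in% members)
    if (!nrow(linked)) return(NULL)
    linked |>
      group_by(.data$compound_id) |>
      summarise(weight = max(abs(.data$log2FC)), .groups = "drop") |>
      mutate(pathway_id = pid, .after = "compound_id")
  })
  out <- list_rbind(keep(rows, ~ !is.null(.x)))
  if (is.null(out) || !nrow(out)) {
    return(tibble(compound_id = character(), pathway_id = character(),
                  weight = numeric()))
  }
  out
}
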