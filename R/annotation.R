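# Presumptive (MSI level 3-like) annotation of m/z features against a
# compound database via adduct arithmetic within a ppm tolerance, and
# pathway over-representation of the annotated differential compounds
# with hypergeometric and permutation nulls.

#' Default electrospray adduct rules
#'
#' The common singly charged adducts: positive mode `[M+H]+`, `[M+Na]+`,
#' `[M+K]+`, `[M+NH4]+`; negative mode `[M-H]-`, `[M+Cl]-`, `[M+HCOO]-`.
#' An observed m/z relates to the neutral monoisotopic mass M by
#' m/z = (M + shift) / |z|.
#'
#' @return Tibble with `name`, `esi_mode`, `charge`, `mass_shift_da`.
#' @export
default_adduct_rules <- function() {
  tibble(
    name = c("[M+H]+", "[M+Na]+", "[M+K]+", "[M+NH4]+",
             "[M-H]-", "[M+Cl]-", "[M+HCOO]-"),
    esi_mode = c(rep("positive", 4), rep("negative", 3)),
    charge = c(1L, 1L, 1L, 1L, -1L, -1L, -1L),
    mass_shift_da = c(1.007276, 22.989218, 38.963158, 18.033823,
                      -1.007276, 34.969402, 44.998201)
  )
}

#' Candidate neutral masses for an observed m/z
#'
#' Inverts every mode-matching adduct rule: M = |z| * mz - shift.
#' Non-positive candidates are dropped.
#'
#' @param mz Observed mass-to-charge ratio (> 0).
#' @param esi_mode `"positive"` or `"negative"`.
#' @param rules Adduct rule tibble (see [default_adduct_rules()]).
#' @return Tibble with `adduct`, `neutral_mass`.
#' @export
candidate_neutral_masses <- function(mz, esi_mode,
                                     rules = default_adduct_rules()) {
  if (mz <= 0) abort("mz must be positive")
  esi_mode <- check_esi_mode(esi_mode)
  r <- dplyr::filter(rules, .data$esi_mode == .env$esi_mode)
  if (!nrow(r)) abort(sprintf("no adduct rule for mode '%s'", esi_mode))
  out <- tibble(adduct = r$name,
                neutral_mass = abs(r$charge) * mz - r$mass_shift_da)
  dplyr::filter(out, .data$neutral_mass > 0)
}

#' Annotate features against a compound database
#'
#' For every feature, each mode-matching adduct rule proposes a neutral
#' mass; every database compound within `ppm_tolerance` of a proposal
#' becomes a hit, with its signed ppm error. Features may hit several
#' compounds (all reported, ordered by |ppm error| within feature);
#' features without any hit are retained with NA compound columns.
#'
#' @param features Tibble with `feature_id`, `mz`, `esi_mode` (a feature
#'   table works directly).
#' @param db Compound database: list with a `compounds` tibble, or the
#'   tibble itself (`compound_id`, `name`, `monoisotopic_mass`).
#' @param rules Adduct rule tibble.
#' @param ppm_tolerance Tolerance in parts per million (> 0).
#' @return Tibble with `feature_id`, `mz`, `esi_mode`, `compound_id`,
#'   `compound_name`, `adduct`, `neutral_mass`, `ppm_error`.
#' @export
annotate_features <- function(features, db, rules = default_adduct_rules(),
                              ppm_tolerance = 10) {
  if (ppm_tolerance <= 0) abort("ppm_tolerance must be positive")
  compounds <- if (is.data.frame(db)) db else db$compounds
  if (is.null(compounds) || !nrow(compounds)) abort("compound database is empty")
  rows <- map(seq_len(nrow(features)), function(i) {
    fmz <- features$mz[i]
    mode <- features$esi_mode[i]
    cand <- candidate_neutral_masses(fmz, mode, rules)
    hits <- NULL
    if (nrow(cand)) {
      grid <- tidyr::expand_grid(cand, compounds)
      grid <- mutate(grid, ppm_error = 1e6 * (.data$neutral_mass -
                       .data$monoisotopic_mass) / .data$monoisotopic_mass)
      hits <- dplyr::filter(grid, abs(.data$ppm_error) <= ppm_tolerance)
    }
    if (is.null(hits) || !nrow(hits)) {
      tibble(feature_id = features$feature_id[i], mz = fmz, esi_mode = mode,
             compound_id = NA_character_, compound_name = NA_character_,
             adduct = NA_character_, neutral_mass = NA_real_,
             ppm_error = NA_real_)
    } else {
      hits <- arrange(hits, abs(.data$ppm_error))
      tibble(feature_id = features$feature_id[i], mz = fmz, esi_mode = mode,
             compound_id = hits$compound_id, compound_name = hits$name,
             adduct = hits$adduct, neutral_mass = hits$neutral_mass,
             ppm_error = hits$ppm_error)
    }
  })
  list_rbind(rows)
}

pathway_members <- function(pathways, pathway_id) {
  pathways$compound_ids[[match(pathway_id, pathways$pathway_id)]]
}

#' Hypergeometric pathway over-representation
#'
#' For each pathway, k = |hits in pathway|, K = |pathway in universe|;
#' the Fisher p-value is the upper-tail hypergeometric probability of
#' drawing >= k pathway members when |hits| compounds are drawn from the
#' universe without replacement.
#'
#' @param hit_compounds Character set of differential compound ids
#'   (deduplicated internally).
#' @param pathways Pathway tibble (`pathway_id`, `name`, list-column
#'   `compound_ids`), or a [generate_compound_db()] result.
#' @param universe Character set of all annotatable compound ids.
#' @param contrast Optional contrast label carried into the output.
#' @return Tibble with `pathway_id`, `name`, `k`, `K`, `n_hits`,
#'   `universe_size`, `p_fisher` (and `contrast` when given).
#' @export
pathway_overrepresentation <- function(hit_compounds, pathways, universe,
                                       contrast = NULL) {
  if (!is.data.frame(pathways)) pathways <- pathways$pathways
  hit_compounds <- unique(hit_compounds)
  universe <- unique(universe)
  if (!all(hit_compounds %in% universe)) {
    abort("hit_compounds must be a subset of the universe")
  }
  n_hits <- length(hit_compounds)
  U <- length(universe)
  out <- map(seq_len(nrow(pathways)), function(i) {
    members <- intersect(pathways$compound_ids[[i]], universe)
    K <- length(members)
    k <- length(intersect(hit_compounds, members))
    p <- if (K == 0) 1 else
      stats::phyper(k - 1, K, U - K, n_hits, lower.tail = FALSE)
    tibble(pathway_id = pathways$pathway_id[i], name = pathways$name[i],
           k = k, K = K, n_hits = n_hits, universe_size = U, p_fisher = p)
  })
  out <- list_rbind(out)
  if (!is.null(contrast)) out$contrast <- contrast
  out
}

#' Permutation null for pathway over-representation
#'
#' Repeatedly draws |hits| compounds uniformly without replacement from
#' the universe and records each pathway's overlap, giving the empirical
#' p-value p_perm = (1 + #(null >= observed)) / (1 + n_permutations)
#' (add-one estimator, never exactly zero). Deterministic under `seed`.
#'
#' @param hit_compounds Observed differential compound set.
#' @param pathways Pathway tibble or database list.
#' @param universe All annotatable compound ids.
#' @param n_permutations Number of null draws (>= 100).
#' @param seed Integer seed.
#' @return The [pathway_overrepresentation()] tibble with added `p_perm`
#'   and `null_mean_k` columns.
#' @export
permutation_pathway_null <- function(hit_compounds, pathways, universe,
                                     n_permutations = 1000, seed = NULL) {
  if (!is.data.frame(pathways)) pathways <- pathways$pathways
  hit_compounds <- unique(hit_compounds)
  universe <- unique(universe)
  n_hits <- length(hit_compounds)
  if (n_hits > length(universe)) {
    abort("more hits than compounds in the universe")
  }
  if (n_permutations < 100) abort("n_permutations must be >= 100")
  obs <- pathway_overrepresentation(hit_compounds, pathways, universe)
  member_sets <- map(pathways$compound_ids, ~ intersect(.x, universe))
  exceed <- numeric(nrow(pathways))
  null_sum <- numeric(nrow(pathways))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      draw <- sample(universe, n_hits)
      ov <- map_dbl(member_sets, ~ length(intersect(draw, .x)))
      exceed <- exceed + (ov >= obs$k)
      null_sum <- null_sum + ov
    }
  })
  obs$p_perm <- (1 + exceed) / (1 + n_permutations)
  obs$null_mean_k <- null_sum / n_permutations
  obs
}

#' Prevalent pathways across contrasts
#'
#' A pathway counts as enriched in a contrast when it has at least one
#' hit and passes the significance rule (p_fisher <= `p_max`); it is
#' prevalent when it is enriched in strictly more than `min_fraction` of
#' the contrasts.
#'
#' @param enrichments Row-bound [pathway_overrepresentation()] tibbles
#'   with a `contrast` column.
#' @param min_fraction Prevalence threshold (default 0.5, strict).
#' @param p_max Fisher p ceiling for "enriched" (default 0.05; set to 1
#'   to count any pathway with a hit).
#' @return Tibble with `pathway_id`, `n_enriched`, `n_contrasts`,
#'   `fraction`, `prevalent`.
#' @export
pathway_prevalence <- function(enrichments, min_fraction = 0.5, p_max = 0.05) {
  if (!"contrast" %in% names(enrichments)) {
    abort("enrichments must carry a 'contrast' column")
  }
  n_contrasts <- length(unique(enrichments$contrast))
  enrichments |>
    group_by(.data$pathway_id) |>
    summarise(n_enriched = sum(.data$k >= 1 & .data$p_fisher <= p_max),
              .groups = "drop") |>
    mutate(n_contrasts = n_contrasts,
           fraction = .data$n_enriched / n_contrasts,
           prevalent = .data$fraction > min_fraction)
}

#' "k of K" pathway activity counts
#'
#' Per contrast and pathway, reports how many of the pathway's K database
#' members are among the contrast's differential compounds, formatted as
#' the field's customary "k of K" string. Pathways with no hit in any
#' contrast are dropped.
#'
#' @param hits_per_contrast Named list (by contrast) of differential
#'   compound-id sets.
#' @param pathways Pathway tibble or database list.
#' @return Tibble with `contrast`, `pathway_id`, `name`, `k`, `K`,
#'   `activity`.
#' @export
pathway_activity_counts <- function(hits_per_contrast, pathways) {
  if (!is.data.frame(pathways)) pathways <- pathways$pathways
  rows <- imap(hits_per_contrast, function(hits, lab) {
    tibble(contrast = lab,
           pathway_id = pathways$pathway_id,
           name = pathways$name,
           k = map_dbl(pathways$compound_ids,
                       ~ length(intersect(unique(hits), .x))),
           K = map_dbl(pathways$compound_ids, length))
  })
  out <- list_rbind(rows)
  active <- out |>
    group_by(.data$pathway_id) |>
    summarise(any_hit = any(.data$k >= 1), .groups = "drop")
  out <- dplyr::semi_join(out, dplyr::filter(active, .data$any_hit),
                          by = "pathway_id")
  mutate(out, activity = sprintf("%d of %d", as.integer(.data$k),
                                 as.integer(.data$K)))
}

#' Read a compound database from TSV
#'
#' Expects columns `compound_id`, `name`, `monoisotopic_mass`.
#'
#' @param path File path.
#' @return Compound tibble.
#' @export
read_compound_db <- function(path) {
  tab <- read_delim_auto(path)
  need <- c("compound_id", "name", "monoisotopic_mass")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    abort(sprintf("compound database missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(tab$compound_id)) abort("duplicate compound_id")
  if (any(tab$monoisotopic_mass <= 0)) abort("non-positive monoisotopic mass")
  tab
}

#' Read a pathway database from a GMT-style TSV
#'
#' Each line: pathway_id, name, then tab-separated member compound ids.
#'
#' @param path File path.
#' @param compounds Optional compound tibble; when given, membership is
#'   checked against it.
#' @return Pathway tibble with list-column `compound_ids`.
#' @export
read_pathway_db <- function(path, compounds = NULL) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad)) {
    abort(sprintf("pathway line(s) without members: %s",
                  paste(bad, collapse = ", ")))
  }
  out <- tibble(pathway_id = map_chr(parts, 1),
                name = map_chr(parts, 2),
                compound_ids = map(parts, ~ .x[-(1:2)]))
  if (!is.null(compounds)) {
    unknown <- setdiff(unlist(out$compound_ids), compounds$compound_id)
    if (length(unknown)) {
      abort(sprintf("pathway members absent from compound database: %s",
                    paste(utils::head(unknown, 5), collapse = ", ")))
    }
  }
  out
}

#' Write compound and pathway databases as flat text
#'
#' @param db A [generate_compound_db()] result.
#' @param compound_path,pathway_path Output paths (TSV and GMT-style TSV).
#' @return Invisibly, the two paths.
#' @export
write_compound_db <- function(db, compound_path, pathway_path) {
  utils::write.table(db$compounds, compound_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  lines <- map_chr(seq_len(nrow(db$pathways)), function(i) {
    paste(c(db$pathways$pathway_id[i], db$pathways$name[i],
            db$pathways$compound_ids[[i]]), collapse = "\t")
  })
  writeLines(lines, pathway_path, useBytes = TRUE)
  invisible(c(compound_path, pathway_path))
}
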