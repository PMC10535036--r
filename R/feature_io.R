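#' @importFrom rlang .data abort warn .env
#' @importFrom dplyr mutate filter select arrange bind_rows distinct across
#'   group_by summarise ungroup left_join n relocate all_of any_of pull rename
#' @importFrom tibble tibble as_tibble is_tibble
#' @importFrom purrr map map_dbl map_chr map_lgl map2 imap keep pmap list_rbind
NULL

#' Construct canonical feature identifiers
#'
#' A spectral feature is identified by the triple (m/z, retention time,
#' ESI mode). Identity uses m/z and rt rounded to a configured precision;
#' features that differ only in ionization mode are distinct, so the mode
#' tag is part of the id.
#'
#' @param mz Numeric vector of mass-to-charge ratios (Da, > 0).
#' @param rt Numeric vector of retention times (minutes, >= 0).
#' @param esi_mode Character vector, `"positive"` or `"negative"`.
#' @param mz_digits,rt_digits Rounding precision defining feature identity.
#' @return Character vector of ids such as `"pos_180.0634_5.21"`.
#' @export
feature_id <- function(mz, rt, esi_mode, mz_digits = 4, rt_digits = 2) {
  esi_mode <- check_esi_mode(esi_mode)
  tag <- ifelse(esi_mode == "positive", "pos", "neg")
  sprintf(paste0("%s_%.", mz_digits, "f_%.", rt_digits, "f"),
          tag, round(mz, mz_digits), round(rt, rt_digits))
}

check_esi_mode <- function(esi_mode) {
  esi_mode <- as.character(esi_mode)
  bad <- !esi_mode %in% c("positive", "negative")
  if (any(bad)) {
    abort(sprintf("esi_mode must be 'positive' or 'negative', got: %s",
                  paste(unique(esi_mode[bad]), collapse = ", ")))
  }
  esi_mode
}

#' Names of the sample (intensity) columns of a feature table
#'
#' @param table A feature table tibble.
#' @return Character vector of sample column names.
#' @export
sample_columns <- function(table) {
  setdiff(names(table), c("feature_id", "mz", "rt", "esi_mode"))
}

#' Validate a feature table
#'
#' Checks the structural invariants of a feature table: mandatory columns,
#' positive m/z, non-negative rt and intensities, no duplicate feature
#' identity, and (optionally) no all-zero sample column. Called by the
#' readers; exported so externally built tibbles can be checked too.
#'
#' @param table Tibble with columns `mz`, `rt`, `esi_mode`, `feature_id`
#'   and one numeric column per sample.
#' @param sample_meta Optional sample metadata tibble; when given, sample
#'   columns must match its `sample_id` set exactly.
#' @param allow_zero_samples Permit all-zero sample columns (default FALSE).
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_feature_table <- function(table, sample_meta = NULL,
                                   allow_zero_samples = FALSE) {
  for (col in c("mz", "rt", "esi_mode", "feature_id")) {
    if (!col %in% names(table)) {
      abort(sprintf("feature table is missing mandatory column '%s'", col))
    }
  }
  check_esi_mode(table$esi_mode)
  if (any(table$mz <= 0)) {
    abort(sprintf("non-positive m/z at row(s): %s",
                  paste(which(table$mz <= 0), collapse = ", ")))
  }
  if (any(table$rt < 0)) {
    abort(sprintf("negative retention time at row(s): %s",
                  paste(which(table$rt < 0), collapse = ", ")))
  }
  smp <- sample_columns(table)
  if (length(smp) == 0) abort("feature table has no sample columns")
  for (s in smp) {
    v <- table[[s]]
    if (!is.numeric(v)) abort(sprintf("sample column '%s' is not numeric", s))
    if (anyNA(v)) abort(sprintf("missing intensity in sample '%s'", s))
    if (any(v < 0)) {
      abort(sprintf("negative intensity in sample '%s' at row(s): %s",
                    s, paste(which(v < 0), collapse = ", ")))
    }
    if (!allow_zero_samples && all(v == 0)) {
      abort(sprintf("sample column '%s' is all zero (set allow_zero_samples = TRUE to permit)", s))
    }
  }
  dup <- duplicated(table$feature_id)
  if (any(dup)) {
    abort(sprintf("duplicate feature identity: %s",
                  paste(unique(table$feature_id[dup]), collapse = ", ")))
  }
  if (!is.null(sample_meta)) {
    validate_sample_metadata(sample_meta)
    missing <- setdiff(smp, sample_meta$sample_id)
    extra <- setdiff(sample_meta$sample_id, smp)
    if (length(missing) || length(extra)) {
      abort(sprintf(
        "sample columns and metadata disagree (columns without metadata: %s; metadata without columns: %s)",
        paste(missing, collapse = ", "), paste(extra, collapse = ", ")))
    }
  }
  invisible(table)
}

#' Validate sample metadata
#'
#' @param meta Tibble with columns `sample_id`, `genotype`, `n_conc_mM`,
#'   `time_dag`, `organ`, `replicate`.
#' @return The metadata, invisibly, if valid.
#' @export
validate_sample_metadata <- function(meta) {
  need <- c("sample_id", "genotype", "n_conc_mM", "time_dag", "organ", "replicate")
  miss <- setdiff(need, names(meta))
  if (length(miss)) {
    abort(sprintf("sample metadata is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("duplicate sample_id in metadata")
  }
  checks <- list(
    genotype = c("WT", "nia1_nia2"),
    organ    = c("rosette", "root")
  )
  for (col in names(checks)) {
    bad <- !meta[[col]] %in% checks[[col]]
    if (any(bad)) {
      abort(sprintf("invalid %s value(s): %s", col,
                    paste(unique(meta[[col]][bad]), collapse = ", ")))
    }
  }
  if (any(is.na(meta$n_conc_mM)) || any(is.na(meta$time_dag))) {
    abort("n_conc_mM and time_dag must be populated for every sample")
  }
  invisible(meta)
}

#' Read a feature table from a wide TSV/CSV file
#'
#' The canonical wide format has columns `mz`, `rt`, optionally `esi_mode`,
#' then one intensity column per sample. Lines starting with `#` are
#' comments. The delimiter is inferred from the file extension
#' (`.csv` = comma, anything else = tab).
#'
#' @param path File path.
#' @param esi_mode Ionization mode to tag features with; required when the
#'   file has no `esi_mode` column.
#' @param mz_digits,rt_digits Feature-identity rounding precision.
#' @return A validated feature table tibble; row and column order are
#'   preserved from the file.
#' @export
read_feature_table <- function(path, esi_mode = NULL,
                               mz_digits = 4, rt_digits = 2) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  tab <- read_delim_auto(path)
  for (col in c("mz", "rt")) {
    if (!col %in% names(tab)) {
      abort(sprintf("'%s': missing mandatory column '%s'", path, col))
    }
  }
  if (!"esi_mode" %in% names(tab)) {
    if (is.null(esi_mode)) {
      abort("file has no esi_mode column and no esi_mode was supplied")
    }
    tab$esi_mode <- check_esi_mode(esi_mode)
  } else if (!is.null(esi_mode)) {
    tab$esi_mode <- check_esi_mode(esi_mode)
  }
  tab$feature_id <- feature_id(tab$mz, tab$rt, tab$esi_mode,
                               mz_digits, rt_digits)
  tab <- relocate(tab, "feature_id", "mz", "rt", "esi_mode")
  validate_feature_table(tab, allow_zero_samples = TRUE)
  tab
}

read_delim_auto <- function(path) {
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  readr::read_delim(path, delim = delim, comment = "#",
                    show_col_types = FALSE, progress = FALSE)
}

#' Read sample metadata from a TSV/CSV file
#'
#' @param path File path; expects columns `sample_id`, `genotype`,
#'   `n_conc_mM`, `time_dag`, `organ`, `replicate`.
#' @return A validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  meta <- read_delim_auto(path)
  validate_sample_metadata(meta)
  meta
}

#' Write a feature table (or any tibble) as tab-delimited UTF-8
#'
#' Prepends `#`-prefixed comment lines recording the package version and
#' any parameters supplied, so outputs carry their provenance.
#'
#' @param table Tibble to write.
#' @param path Output path.
#' @param params Optional named list recorded in the comment header.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path, params = list()) {
  ver <- tryCatch(as.character(utils::packageVersion("metabolodiv")),
                  error = function(e) "dev")
  header <- c(
    sprintf("# metabolodiv %s", ver),
    sprintf("# written: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
  )
  if (length(params)) {
    header <- c(header, sprintf("# %s: %s", names(params),
                                vapply(params, function(x)
                                  paste(format(x), collapse = ","), "")))
  }
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Binarize a feature table into a presence/absence matrix
#'
#' A feature is present in a sample when its intensity strictly exceeds
#' the detection threshold. The default threshold 0 treats any nonzero
#' ion abundance as a detection.
#'
#' @param table Feature table tibble.
#' @param detection_threshold Non-negative intensity threshold.
#' @return A tibble with the same feature columns and logical sample
#'   columns, with the threshold recorded in attribute
#'   `detection_threshold`.
#' @export
binarize <- function(table, detection_threshold = 0) {
  if (!is.numeric(detection_threshold) || length(detection_threshold) != 1 ||
      detection_threshold < 0) {
    abort("detection_threshold must be a single non-negative number")
  }
  smp <- sample_columns(table)
  out <- mutate(table, across(all_of(smp), ~ .x > detection_threshold))
  if (!any(as.matrix(out[smp]))) {
    warn("detection threshold exceeds every intensity: presence matrix is all FALSE")
  }
  attr(out, "detection_threshold") <- detection_threshold
  out
}

#' Extract the logical presence matrix from a binarized table
#'
#' @param presence Output of [binarize()] (or a feature table, binarized
#'   at threshold 0 on the fly).
#' @return Logical matrix, features x samples, rownames = feature ids.
#' @export
presence_matrix <- function(presence) {
  smp <- sample_columns(presence)
  m <- as.matrix(presence[smp])
  if (!is.logical(m)) m <- m > 0
  rownames(m) <- presence$feature_id
  m
}

#' Merge per-mode spectral libraries into one feature table
#'
#' The merged feature set is the disjoint, mode-tagged union: features are
#' never collapsed across ESI modes (an identical (m/z, rt) seen in both
#' polarities remains two features), and identical keys within a mode are
#' kept once. All tables must cover the same samples; columns are aligned
#' by `sample_id`.
#'
#' @param tables List of feature table tibbles.
#' @return A single merged feature table.
#' @export
merge_mode_libraries <- function(tables) {
  if (!length(tables)) abort("no tables to merge")
  ref <- sort(sample_columns(tables[[1]]))
  for (i in seq_along(tables)) {
    smp <- sort(sample_columns(tables[[i]]))
    if (!identical(smp, ref)) {
      abort(sprintf("sample sets differ between tables (unmatched: %s)",
                    paste(union(setdiff(smp, ref), setdiff(ref, smp)),
                          collapse = ", ")))
    }
  }
  cols <- c("feature_id", "mz", "rt", "esi_mode", sample_columns(tables[[1]]))
  merged <- bind_rows(map(tables, ~ select(.x, all_of(cols))))
  distinct(merged, .data$feature_id, .keep_all = TRUE)
}
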