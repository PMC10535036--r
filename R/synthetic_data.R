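# Ground-truthed synthetic dual-mode metabolomics data.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: log-normal baseline abundances across features with a
# rare-feature tail (high per-sample dropout), multiplicative planted
# fold-change effects on design factors, and feature m/z values derived
# from known compound neutral masses via adduct arithmetic plus Gaussian
# ppm noise, alongside decoy m/z kept well away from every compound.

# run code under a seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Community parameters for the synthetic feature generator
#'
#' Baseline feature abundances are log-normal across features
#' (`abundance_lognormal_mu`, `abundance_lognormal_sigma` on the log-e
#' scale), giving a few dominant ions and a long tail, with an extra
#' replicate-level log-normal noise term (`replicate_sigma`). A fraction
#' of features is "rare": their per-sample non-detection (dropout)
#' probability is high, which is what bends species-accumulation curves.
#'
#' @param n_features_per_mode Features simulated in each ESI mode.
#' @param abundance_lognormal_mu,abundance_lognormal_sigma Meanlog and
#'   sdlog of the across-feature baseline abundance distribution.
#' @param replicate_sigma Sdlog of within-group replicate noise.
#' @param rare_fraction Fraction of features given the rare dropout rate.
#' @param dropout_prob_rare,dropout_prob_common Per-sample non-detection
#'   probabilities for rare and common features.
#' @return A list of validated parameters.
#' @export
community_params <- function(n_features_per_mode = 400,
                             abundance_lognormal_mu = 8,
                             abundance_lognormal_sigma = 1.5,
                             replicate_sigma = 0.3,
                             rare_fraction = 0.3,
                             dropout_prob_rare = 0.6,
                             dropout_prob_common = 0.02) {
  stopifnot(n_features_per_mode >= 1,
            abundance_lognormal_sigma > 0, replicate_sigma >= 0)
  for (p in c(rare_fraction, dropout_prob_rare, dropout_prob_common)) {
    if (p < 0 || p > 1) abort("fractions and probabilities must lie in [0, 1]")
  }
  list(n_features_per_mode = as.integer(n_features_per_mode),
       abundance_lognormal_mu = abundance_lognormal_mu,
       abundance_lognormal_sigma = abundance_lognormal_sigma,
       replicate_sigma = replicate_sigma,
       rare_fraction = rare_fraction,
       dropout_prob_rare = dropout_prob_rare,
       dropout_prob_common = dropout_prob_common)
}

#' A planted multiplicative effect on one design factor
#'
#' The effect multiplies the mean abundance of the affected features in
#' the factor's treatment level (genotype: `nia1_nia2`; n_conc: 0.2 mM;
#' time: 30 dag; organ: root) by `fold_change` (up) or `1/fold_change`
#' (down); `direction_mix` is the fraction of affected features going up.
#'
#' @param factor One of `"genotype"`, `"n_conc"`, `"time"`, `"organ"`.
#' @param affected_fraction Fraction of features carrying the effect.
#' @param fold_change True fold change, >= 1.
#' @param direction_mix Fraction of affected features regulated upward.
#' @return A list describing the effect.
#' @export
planted_effect <- function(factor, affected_fraction, fold_change,
                           direction_mix = 0.5) {
  factor <- match.arg(factor, c("genotype", "n_conc", "time", "organ"))
  stopifnot(affected_fraction >= 0, affected_fraction <= 1,
            fold_change >= 1, direction_mix >= 0, direction_mix <= 1)
  list(factor = factor, affected_fraction = affected_fraction,
       fold_change = fold_change, direction_mix = direction_mix)
}

#' Full-factorial hydroponic study design
#'
#' Two genotypes (WT, nia1/nia2) x two nitrate concentrations (4, 0.2 mM)
#' x two sampling ages (15, 30 dag) x two organs (rosette, root), with
#' `n_replicates` samples per cell.
#'
#' @param n_replicates Replicates per design cell.
#' @return A sample metadata tibble.
#' @export
default_design <- function(n_replicates = 3) {
  grid <- tidyr::expand_grid(
    genotype = c("WT", "nia1_nia2"),
    n_conc_mM = c(4, 0.2),
    time_dag = c(15L, 30L),
    organ = c("rosette", "root"),
    replicate = seq_len(n_replicates)
  )
  mutate(grid,
         sample_id = sprintf("%s_%gmM_%ddag_%s_r%d",
                             .data$genotype, .data$n_conc_mM, .data$time_dag,
                             .data$organ, .data$replicate),
         .before = 1)
}

# treatment level per factor, for applying planted effects
treatment_level <- function(factor) {
  switch(factor,
         genotype = "nia1_nia2", n_conc = 0.2, time = 30L, organ = "root")
}

factor_column <- function(factor) {
  switch(factor,
         genotype = "genotype", n_conc = "n_conc_mM",
         time = "time_dag", organ = "organ")
}

#' Generate a synthetic compound and pathway database
#'
#' Compounds receive unique KEGG-style ids and monoisotopic neutral masses
#' whose pairwise separation exceeds twice the default 10 ppm annotation
#' tolerance at the mass-range midpoint, so annotation against the
#' generating database is unambiguous. Pathways are random (possibly
#' overlapping) compound subsets.
#'
#' @param n_compounds,n_pathways Counts of compounds and pathways.
#' @param pathway_size_range Integer interval of pathway sizes.
#' @param mass_range Neutral-mass interval in Da.
#' @param seed Integer seed; identical seeds give identical databases.
#' @return A list with tibbles `compounds` (`compound_id`, `name`,
#'   `monoisotopic_mass`) and `pathways` (`pathway_id`, `name`,
#'   list-column `compound_ids`).
#' @export
generate_compound_db <- function(n_compounds, n_pathways,
                                 pathway_size_range = c(5, 15),
                                 mass_range = c(100, 900), seed = 1) {
  stopifnot(n_compounds >= 1, n_pathways >= 0,
            length(mass_range) == 2, mass_range[1] > 0,
            mass_range[2] > mass_range[1],
            max(pathway_size_range) <= n_compounds)
  mid <- mean(mass_range)
  gap_req <- 2 * 10e-6 * mid      # 2 x 10 ppm at the midpoint
  step <- 3 * gap_req
  grid <- seq(mass_range[1], mass_range[2], by = step)
  if (length(grid) < n_compounds) {
    abort(sprintf(
      "cannot place %d compounds with >%.4f Da separation in [%g, %g]: widen the mass range",
      n_compounds, gap_req, mass_range[1], mass_range[2]))
  }
  with_seed(seed, {
    masses <- sort(sample(grid, n_compounds)) +
      stats::runif(n_compounds, -0.2, 0.2) * gap_req
    compounds <- tibble(
      compound_id = sprintf("C%05d", seq_len(n_compounds)),
      name = sprintf("compound_%d", seq_len(n_compounds)),
      monoisotopic_mass = masses
    )
    pathways <- tibble(
      pathway_id = sprintf("map%05d", seq_len(n_pathways)),
      name = sprintf("pathway_%d", seq_len(n_pathways)),
      compound_ids = map(seq_len(max(n_pathways, 0)), function(i) {
        k <- if (pathway_size_range[1] == pathway_size_range[2])
          pathway_size_range[1]
        else sample(seq(pathway_size_range[1], pathway_size_range[2]), 1)
        sort(sample(compounds$compound_id, k))
      })
    )
    list(compounds = compounds, pathways = pathways)
  })
}

# m/z values implied by a compound database under a set of adduct rules
adducted_mz <- function(masses, rules) {
  unlist(map2(rules$mass_shift_da, abs(rules$charge),
              function(d, z) (masses + d) / z))
}

#' Simulate dual-mode feature tables with complete ground truth
#'
#' Baseline abundances are drawn log-normal per feature; planted effects
#' multiply the mean in the factor's treatment level before dropout is
#' applied; a chosen fraction of features take their m/z from
#' adduct-transformed compound masses plus Gaussian ppm noise, while the
#' rest get decoy m/z at least three ppm tolerances away from every
#' adduct-transformed compound mass.
#'
#' @param design Sample metadata tibble (see [default_design()]).
#' @param community Output of [community_params()].
#' @param effects List of [planted_effect()]s; affected feature sets are
#'   disjoint across effects.
#' @param compound_db Output of [generate_compound_db()], or NULL for a
#'   purely decoy metabolome.
#' @param adduct_rules Adduct rule tibble (see [default_adduct_rules()]).
#' @param annotatable_fraction Fraction of features derived from compound
#'   masses (requires `compound_db`).
#' @param ppm_noise_sd Gaussian m/z noise, in ppm, on annotatable features.
#' @param ppm_tolerance Annotation tolerance used to place decoys.
#' @param seed Integer seed.
#' @return A list with `tables` (named list of per-mode feature tables),
#'   `design`, and `ground_truth` (tibbles `differential_features`,
#'   `feature_to_compound`, and character vector `enriched_pathways`).
#' @export
simulate_feature_table <- function(design,
                                   community = community_params(),
                                   effects = list(),
                                   compound_db = NULL,
                                   adduct_rules = default_adduct_rules(),
                                   annotatable_fraction = 0,
                                   ppm_noise_sd = 2,
                                   ppm_tolerance = 10,
                                   seed = 1) {
  validate_sample_metadata(design)
  for (eff in effects) {
    col <- factor_column(eff$factor)
    if (length(unique(design[[col]])) < 2) {
      abort(sprintf("design does not vary factor '%s' used by a planted effect",
                    eff$factor))
    }
  }
  if (annotatable_fraction > 0 && is.null(compound_db)) {
    abort("annotatable_fraction > 0 requires a compound_db")
  }
  with_seed(seed, {
    tables <- list()
    gt_diff <- list()
    gt_map <- list()
    for (mode in c("positive", "negative")) {
      sim <- simulate_one_mode(design, community, effects, compound_db,
                               adduct_rules, annotatable_fraction,
                               ppm_noise_sd, ppm_tolerance, mode)
      tables[[mode]] <- sim$table
      gt_diff[[mode]] <- sim$differential
      gt_map[[mode]] <- sim$mapping
    }
    mapping <- bind_rows(gt_map)
    enriched <- character(0)
    if (!is.null(compound_db) && nrow(mapping) && length(effects)) {
      diff_ids <- bind_rows(gt_diff)$feature_id
      hit_cpds <- unique(mapping$compound_id[mapping$feature_id %in% diff_ids])
      enriched <- compound_db$pathways$pathway_id[
        map_lgl(compound_db$pathways$compound_ids,
                ~ length(intersect(.x, hit_cpds)) > 0)]
    }
    list(tables = tables, design = design,
         ground_truth = list(differential_features = bind_rows(gt_diff),
                             feature_to_compound = mapping,
                             enriched_pathways = enriched))
  })
}

simulate_one_mode <- function(design, community, effects, compound_db,
                              adduct_rules, annotatable_fraction,
                              ppm_noise_sd, ppm_tolerance, mode) {
  n <- community$n_features_per_mode
  m <- nrow(design)

  # m/z assignment: compound-derived or decoy
  n_annot <- if (is.null(compound_db)) 0L else round(annotatable_fraction * n)
  rules <- dplyr::filter(adduct_rules, .data$esi_mode == mode)
  mz <- numeric(n)
  mapping <- NULL
  if (n_annot > 0) {
    cpd_idx <- sample(nrow(compound_db$compounds), n_annot, replace = TRUE)
    rule_idx <- sample(nrow(rules), n_annot, replace = TRUE)
    M <- compound_db$compounds$monoisotopic_mass[cpd_idx]
    base_mz <- (M + rules$mass_shift_da[rule_idx]) / abs(rules$charge[rule_idx])
    mz[seq_len(n_annot)] <- base_mz *
      (1 + stats::rnorm(n_annot, 0, ppm_noise_sd) / 1e6)
    mapping <- tibble(esi_mode = mode,
                      compound_id = compound_db$compounds$compound_id[cpd_idx],
                      adduct = rules$name[rule_idx])
  }
  n_decoy <- n - n_annot
  if (n_decoy > 0) {
    lo <- 80
    hi <- 1000
    forbidden <- if (is.null(compound_db)) numeric(0) else
      sort(adducted_mz(compound_db$compounds$monoisotopic_mass, rules))
    decoys <- numeric(0)
    while (length(decoys) < n_decoy) {
      cand <- stats::runif(2 * (n_decoy - length(decoys)), lo, hi)
      if (length(forbidden)) {
        ok <- vapply(cand, function(x) {
          all(abs(x - forbidden) / forbidden * 1e6 > 3 * ppm_tolerance)
        }, TRUE)
        cand <- cand[ok]
      }
      decoys <- c(decoys, cand)
    }
    mz[n_annot + seq_len(n_decoy)] <- decoys[seq_len(n_decoy)]
  }
  rt <- stats::runif(n, 0.5, 15)
  ids <- feature_id(mz, rt, mode)
  while (anyDuplicated(ids)) {   # rounded-identity collisions: jitter rt
    dup <- duplicated(ids)
    rt[dup] <- stats::runif(sum(dup), 0.5, 15)
    ids <- feature_id(mz, rt, mode)
  }

  # baseline abundances and planted effects
  baseline <- stats::rlnorm(n, community$abundance_lognormal_mu,
                            community$abundance_lognormal_sigma)
  log_mult <- matrix(0, n, m)   # log fold multipliers per feature x sample
  unassigned <- seq_len(n)
  differential <- list()
  for (eff in effects) {
    k <- round(eff$affected_fraction * n)
    if (k > length(unassigned)) {
      abort("planted effects exceed the feature pool: lower affected_fraction")
    }
    idx <- sort(sample(unassigned, k))
    unassigned <- setdiff(unassigned, idx)
    n_up <- round(eff$direction_mix * k)
    up <- rep(c(TRUE, FALSE), c(n_up, k - n_up))
    col <- factor_column(eff$factor)
    in_trt <- design[[col]] == treatment_level(eff$factor)
    lfc <- ifelse(up, log(eff$fold_change), -log(eff$fold_change))
    log_mult[idx, in_trt] <- log_mult[idx, in_trt] + lfc
    differential[[length(differential) + 1]] <- tibble(
      esi_mode = mode, factor = eff$factor, feature_id = ids[idx],
      true_fc = eff$fold_change,
      direction = ifelse(up, "up_in_treatment", "down_in_treatment"))
  }

  # rare-feature dropout
  rare <- stats::runif(n) < community$rare_fraction
  p_drop <- ifelse(rare, community$dropout_prob_rare,
                   community$dropout_prob_common)
  noise <- matrix(stats::rnorm(n * m, 0, community$replicate_sigma), n, m)
  intens <- baseline * exp(log_mult + noise)
  drop <- matrix(stats::runif(n * m), n, m) < p_drop
  intens[drop] <- 0
  intens <- round(intens, 2)

  tab <- tibble(feature_id = ids, mz = mz, rt = rt, esi_mode = mode)
  tab[design$sample_id] <- as.data.frame(intens)
  if (!is.null(mapping)) {
    mapping <- mutate(mapping, feature_id = ids[seq_len(nrow(mapping))],
                      .after = "esi_mode")
  }
  list(table = tab,
       differential = bind_rows(differential),
       mapping = mapping)
}

#' Fixture reproducing the study's printed bookkeeping structure
#'
#' Builds synthetic per-contrast differential feature-id sets, an
#' annotation table and a pathway partition whose unique/shared structure
#' matches the published counts: 1818 ESI+ differential features (998 in
#' exactly one of the four contrasts, 820 in two or more), 3214 ESI-
#' features (1408 unique, 1806 shared), 735 annotated metabolites split
#' 315 (WT) / 420 (nia1/nia2), and 79 pathways of which 16 are enriched
#' in a single contrast and 63 in several. The membership layout is
#' synthetic; only the set structure is meaningful.
#'
#' @param seed Integer seed controlling the (irrelevant) arrangement of
#'   shared features across contrast pairs.
#' @return A list with `esi_positive` and `esi_negative` (each a named
#'   list of four character-vector differential sets), `annotation`
#'   (tibble `feature_id`, `genotype`), and `pathway_partition` (tibble
#'   `pathway_id`, `n_contrasts`).
#' @export
paper_scale_fixture <- function(seed = 1) {
  contrasts <- c("WT_rosette", "WT_root", "nia1_nia2_rosette", "nia1_nia2_root")
  build_sets <- function(prefix, n_unique, n_shared) {
    ids_u <- sprintf("%s_u%04d", prefix, seq_len(n_unique))
    ids_s <- sprintf("%s_s%04d", prefix, seq_len(n_shared))
    sets <- stats::setNames(vector("list", 4), contrasts)
    # unique features: spread round-robin over the four contrasts
    u_assign <- rep(seq_len(4), length.out = n_unique)
    # shared features: each placed in exactly one of the six contrast pairs
    pairs <- utils::combn(4, 2)
    s_assign <- rep(seq_len(ncol(pairs)), length.out = n_shared)
    for (i in seq_len(4)) {
      in_pair <- apply(pairs[, s_assign, drop = FALSE] == i, 2, any)
      sets[[i]] <- c(ids_u[u_assign == i], ids_s[in_pair])
    }
    sets
  }
  with_seed(seed, {
    esi_pos <- build_sets("pos", 998, 820)
    esi_neg <- build_sets("neg", 1408, 1806)
    annotation <- tibble(
      feature_id = sprintf("ann_%04d", seq_len(735)),
      genotype = rep(c("WT", "nia1_nia2"), c(315, 420)))
    pathway_partition <- tibble(
      pathway_id = sprintf("map%05d", seq_len(79)),
      n_contrasts = c(rep(1L, 16), sample(2:8, 63, replace = TRUE)))
    list(esi_positive = esi_pos, esi_negative = esi_neg,
         annotation = annotation, pathway_partition = pathway_partition)
  })
}

#' Write simulation ground truth as a JSON sidecar
#'
#' @param ground_truth The `ground_truth` element of
#'   [simulate_feature_table()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
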