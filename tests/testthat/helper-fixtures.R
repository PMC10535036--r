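# Small in-code fixtures shared across the test files.

tiny_meta <- function(n_replicates = 1) {
  default_design(n_replicates)
}

# 3-feature, 4-sample positive-mode table with simple integer intensities
tiny_table <- function() {
  tab <- tibble::tibble(
    mz = c(101.1234, 250.5, 399.9999),
    rt = c(1.5, 5.25, 12.0),
    esi_mode = "positive",
    s1 = c(0, 5, 10),
    s2 = c(1, 0, 20),
    s3 = c(2, 3, 0),
    s4 = c(4, 6, 8)
  )
  tab$feature_id <- feature_id(tab$mz, tab$rt, tab$esi_mode)
  dplyr::relocate(tab, feature_id, mz, rt, esi_mode)
}

# presence matrix used by accumulation-curve tests
toy_presence <- function() {
  m <- matrix(c(TRUE, TRUE, FALSE,
                TRUE, FALSE, FALSE,
                FALSE, TRUE, TRUE,
                FALSE, FALSE, TRUE,
                TRUE, TRUE, TRUE), ncol = 3, byrow = TRUE)
  rownames(m) <- paste0("f", 1:5)
  colnames(m) <- paste0("s", 1:3)
  m
}

# brute-force mean richness at each accumulation step over ALL sample
# orderings (the independent oracle for species_accumulation)
enumerate_sac <- function(presence) {
  m <- ncol(presence)
  perms <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  all_ord <- perms(seq_len(m))
  rich <- sapply(all_ord, function(ord) {
    seen <- rep(FALSE, nrow(presence))
    vapply(ord, function(j) {
      seen <<- seen | presence[, j]
      sum(seen)
    }, 0)
  })
  rowMeans(rich)
}

# simulation used by several recovery tests: one genotype effect at
# fold change 4, 6 replicates per group, modest replicate noise and no
# dropout (the conditions the recovery checks are defined under)
recovery_sim <- function(seed = 42, fold_change = 4, affected_fraction = 0.2,
                         n_features = 300, n_replicates = 6) {
  design <- default_design(n_replicates)
  simulate_feature_table(
    design,
    community = community_params(n_features_per_mode = n_features,
                                 replicate_sigma = 0.25,
                                 rare_fraction = 0,
                                 dropout_prob_rare = 0,
                                 dropout_prob_common = 0),
    effects = list(planted_effect("genotype", affected_fraction, fold_change,
                                  direction_mix = 0.5)),
    seed = seed)
}

# genotype fold change within a single design cell, so each side has
# exactly the design's replicate count
genotype_fc <- function(sim, mode = "positive") {
  tab <- sim$tables[[mode]]
  meta <- sim$design
  cell <- meta$organ == "rosette" & meta$n_conc_mM == 4 & meta$time_dag == 15
  ids_mut <- meta$sample_id[cell & meta$genotype == "nia1_nia2"]
  ids_wt <- meta$sample_id[cell & meta$genotype == "WT"]
  fold_change_groups(tab, ids_mut, ids_wt, label = "nia1_nia2_vs_WT")
}
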