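test_that("Shannon diversity matches hand-computed values", {
  expect_equal(shannon(c(1, 1, 1, 1)), log(4))
  expect_equal(shannon(5), 0)
  # p = (0.5, 0.25, 0.25): -sum(p log p) = 1.039721
  expect_equal(shannon(c(2, 1, 1)), 1.039721, tolerance = 1e-6)
  expect_equal(shannon(c(0, 2, 0, 1, 1)), shannon(c(2, 1, 1)))
  expect_error(shannon(c(0, 0)), "undefined")
  expect_error(shannon(c(-1, 2)), "non-negative")
})

test_that("Pielou evenness normalizes H' by log richness", {
  expect_equal(pielou(log(4), 4), 1)
  expect_equal(pielou(1.039721, 3), 0.946395, tolerance = 1e-6)
  expect_warning(J <- pielou(0, 1), "undefined")
  expect_true(is.na(J))
  expect_error(pielou(1, 0), "at least 1")
})

test_that("Chao1 uses the classic and bias-corrected forms", {
  ic <- function(S, Q1, Q2, m = 5) {
    structure(list(S_obs = S, Q1 = Q1, Q2 = Q2, m = m),
              class = "incidence_counts")
  }
  expect_equal(chao1(ic(10, 3, 1)), 14.5)        # 10 + 9/2
  expect_equal(chao1(ic(10, 0, 4)), 10)          # no singletons, no correction
  expect_equal(chao1(ic(8, 2, 0)), 9)            # bias-corrected 8 + 2*1/2
  expect_gte(chao1(ic(10, 3, 1)), 10)
})

test_that("jackknife estimators follow the order-1 and order-2 formulas", {
  ic <- function(S, Q1, Q2, m) {
    structure(list(S_obs = S, Q1 = Q1, Q2 = Q2, m = m),
              class = "incidence_counts")
  }
  expect_equal(jackknife(ic(10, 3, 1, 5), 1), 12.4)    # 10 + 3*4/5
  expect_equal(jackknife(ic(10, 3, 1, 5), 2), 13.75)   # 10 + 3*7/5 - 9/20
  expect_equal(jackknife(ic(10, 0, 0, 5), 1), 10)
  expect_error(jackknife(ic(10, 3, 1, 1), 1), "at least 2")
  expect_error(jackknife(ic(10, 3, 1, 5), 3), "order")
})

test_that("richness estimators never fall below observed richness", {
  set.seed(11)
  for (i in 1:25) {
    pres <- matrix(runif(60) < 0.4, nrow = 12)
    pres <- pres[rowSums(pres) > 0, , drop = FALSE]
    if (!nrow(pres)) next
    counts <- incidence_counts(pres)
    expect_gte(chao1(counts), counts$S_obs)
    expect_gte(jackknife(counts, 1), counts$S_obs)
    # the order-2 jackknife subtracts a doubleton term and is only
    # guaranteed to sit above S_obs when no doubletons dominate
    if (counts$Q2 == 0) expect_gte(jackknife(counts, 2), counts$S_obs)
  }
})

test_that("incidence counts agree with vegan on random matrices", {
  skip_if_not_installed("vegan")
  set.seed(21)
  pres <- matrix(runif(200) < 0.35, nrow = 20)
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  counts <- incidence_counts(pres)
  pool <- vegan::specpool(t(pres) * 1)
  # vegan applies an (m-1)/m small-sample factor to the classic Chao1
  # correction term; undo it to compare the shared arithmetic
  classic_from_vegan <- counts$S_obs +
    (pool$chao - counts$S_obs) * counts$m / (counts$m - 1)
  expect_equal(chao1(counts), classic_from_vegan, tolerance = 1e-9)
  expect_equal(jackknife(counts, 1), pool$jack1, tolerance = 1e-9)
  expect_equal(jackknife(counts, 2), pool$jack2, tolerance = 1e-9)
})

test_that("exact accumulation equals brute-force ordering enumeration", {
  pres <- toy_presence()
  oracle <- enumerate_sac(pres)
  exact <- species_accumulation(pres, method = "exact")
  expect_equal(exact$mean_richness, oracle, tolerance = 1e-12)
  expect_equal(exact$mean_richness[3], 5)   # full accumulation = S_obs
})

test_that("permutation accumulation converges to the exact expectation", {
  pres <- toy_presence()
  exact <- species_accumulation(pres, method = "exact")
  perm <- species_accumulation(pres, n_permutations = 4000, seed = 9)
  expect_equal(perm$mean_richness, exact$mean_richness, tolerance = 0.05)
  expect_equal(perm$mean_richness[3], attr(perm, "S_obs"))
  # saturated community: curve flat at S_obs
  sat <- species_accumulation(matrix(TRUE, 4, 3), n_permutations = 5, seed = 1)
  expect_equal(sat$mean_richness, rep(4, 3))
  expect_error(species_accumulation(matrix(TRUE, 0, 0)), "empty")
})

test_that("exact accumulation matches vegan's rarefaction expectation", {
  skip_if_not_installed("vegan")
  set.seed(31)
  pres <- matrix(runif(120) < 0.4, nrow = 15)
  pres <- pres[rowSums(pres) > 0, , drop = FALSE]
  ours <- species_accumulation(pres, method = "exact")
  veg <- vegan::specaccum(t(pres) * 1, method = "exact")
  expect_equal(ours$mean_richness, as.numeric(veg$richness), tolerance = 1e-8)
})

test_that("asymptote summaries report truncated two-decimal percentages", {
  s <- asymptote_summary(1172, 3407)
  expect_equal(s$common_pct, 34.39)
  expect_equal(asymptote_summary(848, 4521)$common_pct, 18.75)
  expect_equal(asymptote_summary(500, 500)$common_pct, 100)
  expect_error(asymptote_summary(10, 0), "positive")
  expect_error(asymptote_summary(100, 50), "smaller")
})

test_that("broken-stick expectations and fit diagnostics are correct", {
  # S = 2: expected proportions (0.75, 0.25)
  fit2 <- rank_abundance_fit(c(7, 3), model = "broken_stick")
  expect_equal(fit2$fitted_proportion, c(0.75, 0.25))
  expect_equal(rank_abundance_fit(5)$fitted_proportion, 1)
  expect_true(sum(fit2$fitted_proportion) == 1)

  # observed exactly at the null expectation: deviance 0
  S <- 6
  p_exp <- vapply(1:S, function(i) sum(1 / (i:S)) / S, 0)
  perfect <- rank_abundance_fit(p_exp * 1000, model = "broken_stick")
  expect_lt(attr(perfect, "deviance"), 1e-20)

  expect_error(rank_abundance_fit(c(3, 1), model = "zipf"), "broken_stick")
})

test_that("preemption and lognormal models fit their own data closely", {
  ranks <- 1:12
  geo <- 0.4 * 0.6^(ranks - 1)
  fit <- rank_abundance_fit(geo * 500, model = "preemption")
  expect_lt(attr(fit, "deviance"), 1e-6)
  expect_equal(attr(fit, "n_parameters"), 1L)
  logn <- rank_abundance_fit(sort(rlnorm(30, 3, 1), decreasing = TRUE),
                             model = "lognormal")
  expect_equal(attr(logn, "n_parameters"), 2L)
  expect_true(is.finite(attr(logn, "deviance")))
})

test_that("Pearson correlation summaries satisfy R2 = 100 r^2", {
  x <- c(1, 2, 3, 4)
  lin <- correlate_richness_diversity(x, 2 * x + 1)
  expect_equal(lin$r, 1)
  expect_equal(lin$R2, 100)
  expect_equal(correlate_richness_diversity(x, -x)$r, -1)
  hand <- correlate_richness_diversity(x, c(2, 1, 4, 3))
  expect_equal(hand$r, 0.6)
  expect_equal(hand$R2, 36)
  set.seed(5)
  for (i in 1:10) {
    a <- rnorm(8); b <- rnorm(8)
    cs <- correlate_richness_diversity(a, b)
    expect_equal(cs$R2, 100 * cs$r^2)
  }
  expect_error(correlate_richness_diversity(x, rep(1, 4)), "constant")
  expect_error(correlate_richness_diversity(1:2, 1:2), "at least 3")
})

test_that("one-way ANOVA with Tukey letters matches hand-worked cases", {
  same <- anova_tukey(c(1, 2, 3, 1, 2, 3), rep(c("a", "b"), each = 3))
  expect_equal(same$F, 0)
  expect_equal(unname(unique(same$tukey_letters)), "a")

  # SSB = 4 (df 1), SSW = 1 (df 2) => F = 8
  f8 <- anova_tukey(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(f8$F, 8)

  far <- anova_tukey(c(0, 0.1, 0, 0.1, 10, 10.1),
                     rep(c("g1", "g2", "g3"), each = 2))
  letters_far <- far$tukey_letters
  expect_equal(letters_far[["g1"]], letters_far[["g2"]])
  expect_false(letters_far[["g3"]] %in% letters_far[c("g1", "g2")])

  expect_error(anova_tukey(c(1, 2, 3), c("a", "a", "b")), ">= 2 observations")
})

test_that("diversity profiles respect the H' <= log S bound and rank planted groups", {
  sim <- recovery_sim(seed = 4)
  prof <- diversity_profile(sim$tables$positive, sim$design,
                            group_by = c("genotype", "n_conc_mM"))
  expect_true(all(prof$H_prime >= 0))
  expect_true(all(prof$H_prime <= log(prof$S) + 1e-9))
  expect_true(all(prof$J_prime >= 0 & prof$J_prime <= 1, na.rm = TRUE))
  expect_true(all(prof$chao1 >= prof$S_obs))

  # planting extra features in one condition raises its richness
  design <- default_design(4)
  base <- simulate_feature_table(
    design, community_params(n_features_per_mode = 150, rare_fraction = 0,
                             dropout_prob_common = 0),
    seed = 8)
  tab <- base$tables$positive
  wt_ids <- design$sample_id[design$genotype == "WT"]
  tab[1:50, wt_ids] <- 0                        # these features absent in WT
  prof2 <- diversity_profile(tab, design, group_by = "genotype",
                             aggregate = "sum")
  s_wt <- prof2$S[prof2$genotype == "WT"]
  s_mut <- prof2$S[prof2$genotype == "nia1_nia2"]
  expect_gt(s_mut, s_wt)
})
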