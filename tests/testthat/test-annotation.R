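test_that("candidate neutral masses invert the adduct arithmetic", {
  pos <- candidate_neutral_masses(181.070664, "positive")
  glucose_pos <- pos$neutral_mass[pos$adduct == "[M+H]+"]
  expect_equal(glucose_pos, 180.063388, tolerance = 1e-6)

  neg <- candidate_neutral_masses(179.056112, "negative")
  glucose_neg <- neg$neutral_mass[neg$adduct == "[M-H]-"]
  expect_equal(glucose_neg, 180.063388, tolerance = 1e-6)

  # rules whose shift exceeds the observed m/z are dropped
  tiny <- candidate_neutral_masses(10, "positive")
  expect_false("[M+Na]+" %in% tiny$adduct)

  expect_error(candidate_neutral_masses(-1, "positive"), "positive")
  only_pos <- default_adduct_rules()[default_adduct_rules()$esi_mode ==
                                       "positive", ]
  expect_error(candidate_neutral_masses(100, "negative", only_pos),
               "no adduct rule")
})

test_that("adduct inversion reproduces the observed m/z to machine precision", {
  rules <- default_adduct_rules()
  for (i in seq_len(nrow(rules))) {
    mz <- 387.1234
    M <- abs(rules$charge[i]) * mz - rules$mass_shift_da[i]
    back <- (M + rules$mass_shift_da[i]) / abs(rules$charge[i])
    expect_equal(back, mz, tolerance = 1e-12)
  }
})

test_that("annotation respects the ppm tolerance and multiplicity policy", {
  compounds <- tibble::tibble(
    compound_id = c("C00001", "C00002", "C00003"),
    name = c("a", "b", "c"),
    monoisotopic_mass = c(180.063388, 180.063388 * (1 + 5e-6), 300))
  feats <- tibble::tibble(
    feature_id = c("pos_1", "pos_2"),
    # midway between the two compounds 5 ppm apart; and 25 ppm off C00003
    mz = c((180.063388 * (1 + 2.5e-6)) + 1.007276, (300 * (1 + 25e-6)) + 1.007276),
    esi_mode = "positive")
  ann <- annotate_features(feats, compounds, ppm_tolerance = 10)
  hits1 <- ann[ann$feature_id == "pos_1" & !is.na(ann$compound_id), ]
  expect_setequal(hits1$compound_id, c("C00001", "C00002"))
  expect_true(all(diff(abs(hits1$ppm_error)) >= 0))   # ordered by |ppm|

  # 25 ppm away at 10 ppm tolerance: unannotated but reported
  hits2 <- ann[ann$feature_id == "pos_2", ]
  expect_equal(nrow(hits2), 1)
  expect_true(is.na(hits2$compound_id))

  expect_error(annotate_features(feats, compounds[0, ]), "empty")
})

test_that("hypergeometric enrichment equals brute-force subset enumeration", {
  # universe 20, pathway 5, hits 5, overlap 3
  universe <- paste0("c", 1:20)
  pathway <- tibble::tibble(pathway_id = "p1", name = "p1",
                            compound_ids = list(universe[1:5]))
  hits <- c(universe[1:3], universe[11:12])
  row <- pathway_overrepresentation(hits, pathway, universe)
  expect_equal(row$k, 3)
  expect_equal(row$K, 5)

  # enumerate every 5-subset of the universe, count those with >= 3
  combos <- utils::combn(20, 5)
  overlap <- colSums(combos <= 5)
  p_brute <- mean(overlap >= 3)
  expect_equal(row$p_fisher, p_brute, tolerance = 1e-12)

  # degenerate cases
  none <- pathway_overrepresentation(universe[11:12], pathway, universe)
  expect_equal(none$k, 0)
  expect_equal(none$p_fisher, 1)
  whole <- tibble::tibble(pathway_id = "all", name = "all",
                          compound_ids = list(universe))
  certain <- pathway_overrepresentation(hits, whole, universe)
  expect_equal(certain$k, length(hits))
  expect_equal(certain$p_fisher, 1)

  expect_error(pathway_overrepresentation(c("zz"), pathway, universe),
               "subset")
})

test_that("brute-force enumeration matches phyper on random small instances", {
  set.seed(41)
  for (i in 1:8) {
    U <- sample(8:25, 1)
    universe <- paste0("c", 1:U)
    K <- sample(2:(U - 2), 1)
    n <- sample(2:(U - 2), 1)
    pathway <- tibble::tibble(pathway_id = "p", name = "p",
                              compound_ids = list(universe[1:K]))
    hits <- sample(universe, n)
    row <- pathway_overrepresentation(hits, pathway, universe)
    combos <- utils::combn(U, n)
    p_brute <- mean(colSums(combos <= K) >= row$k)
    expect_equal(row$p_fisher, p_brute, tolerance = 1e-10)
  }
})

test_that("the permutation null is calibrated, minimal when planted, and seeded", {
  universe <- paste0("c", 1:40)
  pathways <- tibble::tibble(
    pathway_id = c("p1", "p2"), name = c("p1", "p2"),
    compound_ids = list(universe[1:8], universe[9:30]))

  # fully planted pathway: every hit inside p1 -> minimal attainable p
  planted <- permutation_pathway_null(universe[1:6], pathways, universe,
                                      n_permutations = 200, seed = 7)
  expect_equal(planted$p_perm[planted$pathway_id == "p1"], 1 / 201)

  # determinism
  again <- permutation_pathway_null(universe[1:6], pathways, universe,
                                    n_permutations = 200, seed = 7)
  expect_identical(planted$p_perm, again$p_perm)

  # p_perm tracks p_fisher for a random draw as permutations grow
  set.seed(13)
  hits <- sample(universe, 10)
  res <- permutation_pathway_null(hits, pathways, universe,
                                  n_permutations = 4000, seed = 3)
  expect_equal(res$p_perm, res$p_fisher, tolerance = 0.05)

  expect_error(permutation_pathway_null(universe, pathways, universe[1:5],
                                        seed = 1), "more hits")
  expect_error(permutation_pathway_null(universe[1:2], pathways, universe,
                                        n_permutations = 10, seed = 1),
               ">= 100")
})

test_that("permutation p-values are roughly uniform under the null", {
  # a wide overlap support keeps the p-value distribution close to
  # continuous, which is what the KS sanity check needs
  universe <- paste0("c", 1:200)
  pathways <- tibble::tibble(pathway_id = "p1", name = "p1",
                             compound_ids = list(universe[1:100]))
  set.seed(29)
  pvals <- vapply(1:60, function(i) {
    hits <- sample(universe, 50)
    permutation_pathway_null(hits, pathways, universe,
                             n_permutations = 200, seed = i)$p_perm
  }, 0)
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
  # add-one estimator: valid p-values, never zero
  expect_true(all(pvals > 0 & pvals <= 1))
})

test_that("prevalence uses a strict majority of contrasts", {
  enr <- tibble::tibble(
    pathway_id = rep(c("p1", "p2", "p3"), each = 8),
    k = c(rep(1, 5), 0, 0, 0,   rep(1, 4), rep(0, 4),   rep(0, 8)),
    p_fisher = 0.01,
    contrast = rep(paste0("ct", 1:8), 3))
  prev <- pathway_prevalence(enr, min_fraction = 0.5)
  expect_true(prev$prevalent[prev$pathway_id == "p1"])    # 5/8 > 0.5
  expect_false(prev$prevalent[prev$pathway_id == "p2"])   # 4/8 not strict
  expect_false(prev$prevalent[prev$pathway_id == "p3"])
  expect_error(pathway_prevalence(dplyr::select(enr, -contrast)), "contrast")
})

test_that("activity counts report k of K and drop never-hit pathways", {
  pathways <- tibble::tibble(
    pathway_id = c("p1", "p2"), name = c("p1", "p2"),
    compound_ids = list(paste0("c", 1:5), paste0("c", 6:11)))
  act <- pathway_activity_counts(
    list(ctA = c("c1", "c2"), ctB = character(0)), pathways)
  expect_equal(act$activity[act$contrast == "ctA" & act$pathway_id == "p1"],
               "2 of 5")
  # p1 retained in both contrasts (hit somewhere); p2 dropped entirely
  expect_setequal(unique(act$pathway_id), "p1")
  expect_equal(act$activity[act$contrast == "ctB"], "0 of 5")

  # planted full pathway: all 6 members hit
  act2 <- pathway_activity_counts(list(ct = paste0("c", 6:11)), pathways)
  expect_equal(act2$activity[act2$pathway_id == "p2"], "6 of 6")
})

test_that("databases round-trip through their flat-text formats", {
  db <- generate_compound_db(20, 3, c(4, 8), c(100, 600), seed = 2)
  cp <- withr::local_tempfile(fileext = ".tsv")
  pp <- withr::local_tempfile(fileext = ".gmt")
  write_compound_db(db, cp, pp)
  cps <- read_compound_db(cp)
  expect_equal(cps$compound_id, db$compounds$compound_id)
  expect_equal(cps$monoisotopic_mass, db$compounds$monoisotopic_mass,
               tolerance = 1e-9)
  pws <- read_pathway_db(pp, cps)
  expect_equal(pws$pathway_id, db$pathways$pathway_id)
  expect_identical(pws$compound_ids, db$pathways$compound_ids)
})
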