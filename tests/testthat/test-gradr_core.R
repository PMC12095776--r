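test_that("row-Z-scoring standardises profiles and flags constants", {
  z <- zscore_profile(c(1, 2, 3))
  expect_equal(mean(z), 0)
  expect_equal(sd(z), 1)

  expect_true(all(is.na(zscore_profile(rep(5, 22)))))

  m <- rbind(a = c(1, 2, 3, 4), b = rep(5, 4))
  zm <- zscore_profile(m)
  expect_equal(attr(zm, "degenerate"), "b")
})

test_that("profile Pearson matches the covariance-formula oracle on random pairs", {
  set.seed(123)
  for (i in 1:1000) {
    a <- runif(22, 0, 100)
    b <- runif(22, 0, 100)
    expect_equal(profile_pearson(a, b), oracle_pearson(a, b),
                 tolerance = 1e-12)
  }
})

test_that("Pearson r is invariant under z-scoring and exact on affine pairs", {
  set.seed(321)
  for (i in 1:200) {
    a <- runif(22, 0, 100)
    b <- runif(22, 0, 100)
    expect_equal(profile_pearson(a, b),
                 profile_pearson(zscore_profile(a), zscore_profile(b)),
                 tolerance = 1e-10)
  }
  a <- runif(22)
  expect_equal(profile_pearson(a, a), 1)
  expect_equal(profile_pearson(a, -2 * a + 7), -1)
  expect_equal(profile_pearson(c(0, 1, 4, 2), c(1, 3, 7, 5)),
               oracle_pearson(c(0, 1, 4, 2), c(1, 3, 7, 5)),
               tolerance = 1e-12)
  expect_error(profile_pearson(rep(1, 5), 1:5), "constant")
  expect_error(profile_pearson(1:4, 1:5), "length")
})

test_that("per-RNA prediction applies every filter of the method", {
  fx <- make_filter_fixture()
  cyt_pred <- predict_interactors("RNA_CYT", fx$ds, fx$cfg)
  passed_cyt <- cyt_pred$protein_id[cyt_pred$passed]
  expect_setequal(passed_cyt, c("P_good_cyt", "P_border"))

  # boundary: fold-change 1.99 and p 0.06 both excluded even at r ~ 1
  expect_false("P_lowfc" %in% cyt_pred$protein_id)
  expect_false("P_highp" %in% cyt_pred$protein_id)
  # compartment filters remove proteins before correlation
  expect_false("P_wrongcomp" %in% cyt_pred$protein_id)
  expect_false("P_undetected" %in% cyt_pred$protein_id)
  # RBP + eligible protein below the r threshold is scored but not passed
  expect_true("P_lowr" %in% cyt_pred$protein_id)
  expect_false(cyt_pred$passed[cyt_pred$protein_id == "P_lowr"])
  expect_lt(cyt_pred$pearson_r[cyt_pred$protein_id == "P_lowr"], 0.5)

  # nuclear query: mitochondrial protein absent despite near-perfect r
  nuc_pred <- predict_interactors("RNA_NUC", fx$ds, fx$cfg)
  expect_false("P_mito" %in% nuc_pred$protein_id)
  expect_setequal(nuc_pred$protein_id[nuc_pred$passed], "P_good_nuc")

  # ordering and ranks: descending r, dense ranks over passing rows
  expect_true(!is.unsorted(rev(cyt_pred$pearson_r)))
  expect_equal(cyt_pred$rank[cyt_pred$passed],
               seq_len(sum(cyt_pred$passed)))
  expect_error(predict_interactors("nope", fx$ds, fx$cfg), "unknown")
})

test_that("prediction agrees with a brute-force re-evaluation of the rules", {
  fx <- make_filter_fixture()
  for (rna in c("RNA_CYT", "RNA_NUC")) {
    pred <- predict_interactors(rna, fx$ds, fx$cfg)
    oracle <- oracle_interactors(
      rna, fx$rna, fx$prot, fx$oops,
      fx$ds$rna_compartment, fx$prot_cyt, fx$prot_nuc,
      mito_ids = "P_mito", cfg = fx$cfg)
    expect_setequal(pred$protein_id[pred$passed], oracle)
  }
})

test_that("prediction is invariant to input row order and profile z-scoring", {
  fx <- make_filter_fixture()
  cfg <- fx$cfg
  pred <- predict_interactors("RNA_CYT", fx$ds, cfg)

  set.seed(8)
  perm_p <- sample(nrow(fx$prot))
  perm_o <- sample(nrow(fx$oops))
  ds2 <- combined_dataset(
    rna_profiles = gradient_matrix(fx$rna[2:1, ], "rna"),
    protein_profiles = gradient_matrix(fx$prot[perm_p, ], "protein"),
    oops = fx$oops[perm_o, ],
    rna_compartment = fx$ds$rna_compartment,
    protein_elig_cyt = fx$ds$protein_elig_cyt,
    protein_elig_nuc = fx$ds$protein_elig_nuc,
    mito_list = "P_mito")
  pred2 <- predict_interactors("RNA_CYT", ds2, cfg)
  expect_equal(pred2, pred)

  # z-scored profiles give identical r and identical decisions
  zr <- zscore_profile(unclass(fx$rna))
  zp <- zscore_profile(unclass(fx$prot))
  ds3 <- combined_dataset(
    rna_profiles = gradient_matrix(zr - min(zr), "rna"),
    protein_profiles = gradient_matrix(zp - min(zp), "protein"),
    oops = fx$oops,
    rna_compartment = fx$ds$rna_compartment,
    protein_elig_cyt = fx$ds$protein_elig_cyt,
    protein_elig_nuc = fx$ds$protein_elig_nuc,
    mito_list = "P_mito")
  pred3 <- predict_interactors("RNA_CYT", ds3, cfg)
  expect_equal(pred3$protein_id, pred$protein_id)
  expect_equal(pred3$pearson_r, pred$pearson_r, tolerance = 1e-10)
})

test_that("tightening any threshold never enlarges the passed set", {
  fx <- make_filter_fixture()
  base <- predict_interactors("RNA_CYT", fx$ds, fx$cfg)
  base_passed <- base$protein_id[base$passed]
  tighter <- list(gradr_config(oops_fc_min = 3),
                  gradr_config(oops_p_max = 0.02),
                  gradr_config(r_min = 0.8))
  for (cfg in tighter) {
    p <- predict_interactors("RNA_CYT", fx$ds, cfg)
    expect_true(all(p$protein_id[p$passed] %in% base_passed))
  }
})

test_that("whole-interactome table is consistent with per-RNA predictions", {
  fx <- make_filter_fixture()
  all_tab <- interactome_all(fx$ds, fx$cfg)
  expect_true(all(c("rna_id", "protein_id", "pearson_r", "passed")
                  %in% names(all_tab)))
  per_rna <- do.call(rbind, lapply(c("RNA_CYT", "RNA_NUC"), function(r) {
    predict_interactors(r, fx$ds, fx$cfg)
  }))
  passed_union <- paste(per_rna$rna_id[per_rna$passed],
                        per_rna$protein_id[per_rna$passed])
  got <- interactome_all(fx$ds, fx$cfg, passed_only = TRUE)
  expect_setequal(paste(got$rna_id, got$protein_id), passed_union)
})

test_that("correlation matrix is symmetric with unit diagonal and clusters complexes", {
  sim <- simulate_cosedimentome(simulation_spec(noise_sd = 0.05,
                                                rng_seed = 33))
  prots <- c(sprintf("PROT_C1_%02d", 1:8), sprintf("PROT_C2_%02d", 1:8))
  icm <- interactor_correlation_matrix(prots, sim$protein_profiles)
  expect_equal(unname(diag(icm$r)), rep(1, 16))
  expect_equal(icm$r, t(icm$r), tolerance = 1e-12)
  expect_true(all(icm$r >= -1 - 1e-12 & icm$r <= 1 + 1e-12))

  # two planted complexes form two contiguous leaf blocks
  comp <- sub("_..$", "", icm$leaf_order)
  expect_equal(length(rle(comp)$lengths), 2)

  expect_error(interactor_correlation_matrix("PROT_C1_01",
                                             sim$protein_profiles), ">= 2")
})
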