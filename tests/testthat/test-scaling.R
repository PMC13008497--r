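test_that("identity and shifted pairs recover exact factors", {
  pd <- make_linear_pairs(n = 10, p = 5, slope = 1, intercept = 0)
  fac <- fit_scaling_factors(pd)
  expect_equal(fac$slope, rep(1, 5), tolerance = 1e-12)
  expect_equal(fac$intercept, rep(0, 5), tolerance = 1e-10)
  expect_equal(fac$pearson_r, rep(1, 5), tolerance = 1e-12)

  pd2 <- make_linear_pairs(n = 10, p = 5, slope = 1, intercept = 2)
  fac2 <- fit_scaling_factors(pd2)
  expect_equal(fac2$slope, rep(1, 5), tolerance = 1e-12)
  expect_equal(fac2$intercept, rep(2, 5), tolerance = 1e-10)
})

test_that("per-protein OLS matches the lm oracle to 1e-10", {
  set.seed(51)
  pd <- make_linear_pairs(n = 23, p = 40, slope = runif(40, 0.5, 1.5),
                          intercept = rnorm(40), noise_sd = 0.4)
  fac <- fit_scaling_factors(pd)
  for (j in seq_len(40)) {
    fit <- lm(pd$plasma$values[, j] ~ pd$serum$values[, j])
    expect_equal(fac$slope[j], unname(coef(fit)[2]), tolerance = 1e-10)
    expect_equal(fac$intercept[j], unname(coef(fit)[1]), tolerance = 1e-10)
    expect_equal(fac$residual_sd[j], summary(fit)$sigma, tolerance = 1e-10)
  }
})

test_that("the fitted line minimizes the residual sum of squares", {
  set.seed(52)
  pd <- make_linear_pairs(n = 15, p = 6, slope = 1.1, intercept = 0.5,
                          noise_sd = 0.3)
  fac <- fit_scaling_factors(pd)
  rss <- function(slope, intercept, j)
    sum((pd$plasma$values[, j] - slope * pd$serum$values[, j] - intercept)^2)
  for (j in 1:6) {
    base <- rss(fac$slope[j], fac$intercept[j], j)
    for (k in 1:10) {
      expect_gte(rss(fac$slope[j] + rnorm(1, 0, 0.05),
                     fac$intercept[j] + rnorm(1, 0, 0.05), j), base)
    }
  }
})

test_that("zero serum variance skips the protein with a warning, never zero-fills", {
  pd <- make_linear_pairs(n = 8, p = 3)
  pd$serum$values[, 2] <- 5
  expect_warning(fac <- fit_scaling_factors(pd), "zero serum variance")
  expect_false("prot002" %in% fac$protein_id)
  expect_equal(attr(fac, "skipped"), "prot002")
})

test_that("apply_scaling implements the affine map and its policies", {
  pd <- make_linear_pairs(n = 8, p = 4)
  fac <- fit_scaling_factors(pd)

  # slope 1 / intercept 0 is the identity
  id <- fac; id$slope[] <- 1; id$intercept[] <- 0
  expect_identical(apply_scaling(pd$serum, id)$values, pd$serum$values)

  # direct substitution: 10 * 0.9 + 1 = 10
  one <- make_pm(matrix(10, 1, 1, dimnames = list("s1", "prot001")))
  f1 <- data.frame(protein_id = "prot001", slope = 0.9, intercept = 1)
  expect_equal(apply_scaling(one, f1)$values[1, 1], 10)

  # noiseless round trip reconstructs plasma
  pd3 <- make_linear_pairs(n = 12, p = 6, slope = runif(6, 0.7, 1.3),
                           intercept = rnorm(6), noise_sd = 0)
  fac3 <- fit_scaling_factors(pd3)
  sc <- apply_scaling(pd3$serum, fac3)
  expect_equal(unname(sc$values), unname(pd3$plasma$values), tolerance = 1e-10)

  # missing-factor policies
  fmiss <- fac[fac$protein_id != "prot003", ]
  expect_error(apply_scaling(pd$serum, fmiss), "prot003")
  dropped <- apply_scaling(pd$serum, fmiss, policy = "drop")
  expect_false("prot003" %in% protein_ids(dropped))
  pass <- apply_scaling(pd$serum, fmiss, policy = "passthrough")
  expect_equal(pass$values[, "prot003"], pd$serum$values[, "prot003"])

  raw <- make_pm(matrix(2^8, 2, 1, dimnames = list(c("a", "b"), "prot001")),
                 scale = "raw_rfu")
  expect_error(apply_scaling(raw, f1), "log2")
})

test_that("cross-validation partitions by patient and covers every pair once", {
  x <- small_synth(seed = 23, contaminated_cohort = NA,
                   contamination_panel_size = 0)
  pd <- synth_paired(x)
  cv <- fit_scaling_factors_cv(pd, k = 4, seed = 3)
  fa <- cv$fold_assignment
  expect_setequal(fa$pair, seq_len(n_pairs(pd)))
  # no patient spans folds
  expect_true(all(tapply(fa$fold, fa$patient_id,
                         function(f) length(unique(f))) == 1))
  # every serum sample scaled exactly once
  expect_setequal(rownames(cv$scaled_serum$values), pd$pairs$serum_sample_id)
  expect_error(fit_scaling_factors_cv(pd, k = n_pairs(pd) + 1), "exceeds")
})

test_that("noiseless CV reproduces plasma out of fold; noisy CV is never optimistic", {
  pd <- make_linear_pairs(n = 20, p = 8, slope = runif(8, 0.8, 1.2),
                          intercept = rnorm(8), noise_sd = 0, seed = 9)
  cv <- fit_scaling_factors_cv(pd, k = 5, seed = 2)
  sc <- cv$scaled_serum$values[pd$pairs$serum_sample_id, ]
  expect_equal(unname(sc), unname(pd$plasma$values), tolerance = 1e-8)
  # all folds learn the same (noiseless) truth
  s1 <- cv$fold_factors[[1]]$slope
  for (f in 2:5) expect_equal(cv$fold_factors[[f]]$slope, s1, tolerance = 1e-8)

  # optimism: out-of-fold residual sd >= in-sample residual sd on average
  set.seed(53)
  pdn <- make_linear_pairs(n = 40, p = 60, slope = 1, intercept = 0,
                           noise_sd = 0.4, seed = 10)
  full <- fit_scaling_factors(pdn)
  cvn <- fit_scaling_factors_cv(pdn, k = 5, seed = 4)
  oof <- cvn$scaled_serum$values[pdn$pairs$serum_sample_id, full$protein_id]
  oof_sd <- sqrt(colMeans((pdn$plasma$values[, full$protein_id] - oof)^2))
  in_sd <- full$residual_sd * sqrt((40 - 2) / 40)  # same normalization
  expect_gt(mean(oof_sd), mean(in_sd))
})

test_that("mismatched control is a seeded derangement preserving the sample multiset", {
  pd <- make_linear_pairs(n = 12, p = 4)
  mm1 <- mismatched_control(pd, seed = 5)
  mm2 <- mismatched_control(pd, seed = 5)
  mm3 <- mismatched_control(pd, seed = 6)
  perm <- attr(mm1, "permutation")
  expect_true(all(perm != seq_len(12)))
  expect_identical(attr(mm2, "permutation"), perm)
  expect_false(identical(attr(mm3, "permutation"), perm))
  expect_setequal(mm1$pairs$plasma_sample_id, pd$pairs$plasma_sample_id)
  expect_identical(mm1$pairs$serum_sample_id, pd$pairs$serum_sample_id)
  expect_equal(rownames(mm1$plasma$values), mm1$pairs$plasma_sample_id)

  one <- subset_pairs(pd, keep = 1)
  expect_error(mismatched_control(one), "derangement")
})

test_that("factor-set comparison reports agreement and the attenuation law", {
  pd <- make_linear_pairs(n = 15, p = 30, slope = runif(30, 0.6, 1.4),
                          intercept = rnorm(30), noise_sd = 0.2, seed = 13)
  fac <- fit_scaling_factors(pd)
  self <- compare_factor_sets(fac, fac)
  expect_equal(self$slope_r, 1)
  expect_equal(self$intercept_r, 1)
  expect_equal(self$n_shared, 30L)

  a <- fac[1:8, ]; b <- fac[25:30, ]
  expect_error(compare_factor_sets(a, b), ">= 10")

  # two independent noisy estimates of a common truth: attenuation
  set.seed(54)
  sigma <- 0.25; tau <- 0.15
  truth <- rnorm(800, 1, sigma)
  mk <- function() data.frame(protein_id = sprintf("p%03d", 1:800),
                              slope = truth + rnorm(800, 0, tau),
                              intercept = truth + rnorm(800, 0, tau))
  cmpr <- compare_factor_sets(mk(), mk())
  expected_r <- sigma^2 / (sigma^2 + tau^2)
  expect_equal(cmpr$slope_r, expected_r, tolerance = 0.1)
})
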