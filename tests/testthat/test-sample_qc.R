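test_that("scale-factor filter is inclusive at the bounds and pair-propagating", {
  md <- data.frame(
    sample_id = c("s1", "s2", "s3", "s4", "s5", "s6"),
    norm_scale_factor = c(0.39, 0.4, 1.0, 2.5, 2.51, NA))
  frag <- scale_factor_filter(md)
  expect_setequal(frag$excluded_samples$sample_id, c("s1", "s5"))
  expect_true(all(frag$excluded_samples$reason == "scale_factor_out_of_range"))
  expect_match(frag$flags, "s6")  # missing factor flags, never excludes

  pairs <- data.frame(serum_sample_id = c("s2", "s3", "s5"),
                      plasma_sample_id = c("s1", "s4", "s6"))
  frag2 <- scale_factor_filter(md, pairs = pairs)
  # pair 1: plasma fails; pair 3: serum fails; pair 2: both pass
  expect_equal(frag2$excluded_pairs, c(1L, 3L))
})

test_that("pairing QC keeps perfectly duplicated pairs and excludes planted mismatches", {
  set.seed(21)
  v <- matrix(rnorm(25 * 40, 8, 1.5), 25, 40)
  serum <- make_pm(v, "serum")
  plasma <- make_pm(v, "plasma")
  rownames(plasma$values) <- sub("se_", "pl_", rownames(plasma$values))
  plasma$metadata$sample_id <- rownames(plasma$values)
  pd <- build_pairs(serum, plasma)
  pq <- pairing_qc(pd)
  expect_true(all(abs(pq$pair_stats$correlation - 1) < 1e-12))
  expect_length(pq$excluded_pairs, 0L)
  expect_false(pq$halt)

  # planted truth recovery: 5 shuffled pairs among 50 low-noise pairs
  for (s in 1:3) {
    cfg <- synth_config(seed = s, n_cohorts = 1, pairs_per_cohort = 50,
                        n_proteins = 300, noise_sd = 0.2, fraction_lod = 0,
                        fraction_coag = 0, contaminated_cohort = NA,
                        contamination_panel_size = 0, fraction_t1 = 0,
                        cohort_shift_sd = 0, value_scale = "log2")
    pd2 <- synth_paired(generate_cohorts(cfg))
    inj <- inject_pair_mismatches(pd2, k = 5, seed = s + 100)
    pq2 <- pairing_qc(inj$pd, multiplier = 3)
    expect_setequal(unname(pq2$excluded_pairs), which(inj$mismatched))
  }
})

test_that("pairing QC halts when pairs are generally uncorrelated", {
  cfg <- synth_config(seed = 4, n_cohorts = 1, pairs_per_cohort = 30,
                      n_proteins = 150, fraction_lod = 0, fraction_coag = 0,
                      contaminated_cohort = NA, contamination_panel_size = 0,
                      fraction_t1 = 0, value_scale = "log2")
  pd <- synth_paired(generate_cohorts(cfg))
  shuffled <- mismatched_control(pd, seed = 9)  # destroy all true pairings
  pq <- pairing_qc(shuffled)
  expect_true(pq$halt)
  expect_match(pq$flags, "uncorrelated")
  expect_lt(median(pq$pair_stats$correlation), 0.2)
})

test_that("pairing QC decisions are invariant to protein-wise affine rescaling", {
  cfg <- synth_config(seed = 6, n_cohorts = 1, pairs_per_cohort = 30,
                      n_proteins = 100, noise_sd = 0.4, fraction_lod = 0,
                      fraction_coag = 0, contaminated_cohort = NA,
                      contamination_panel_size = 0, fraction_t1 = 0,
                      value_scale = "log2")
  pd <- synth_paired(generate_cohorts(cfg))
  pq1 <- pairing_qc(pd)
  set.seed(61)
  a <- runif(100, 0.5, 3); b <- rnorm(100, 0, 5)
  pd2 <- pd
  pd2$plasma <- proteomic_matrix(
    sweep(sweep(pd$plasma$values, 2, a, "*"), 2, b, "+"),
    pd$plasma$metadata, scale = "log2")
  pq2 <- pairing_qc(pd2)
  expect_equal(pq2$pair_stats$correlation, pq1$pair_stats$correlation,
               tolerance = 1e-10)
})

test_that("contamination scores are calibrated in reference sd units", {
  cfg <- synth_config(seed = 14, n_cohorts = 1, pairs_per_cohort = 60,
                      n_proteins = 80, contamination_panel_size = 20,
                      contaminated_cohort = NA, fraction_lod = 0,
                      fraction_coag = 0, fraction_t1 = 0,
                      cohort_shift_sd = 0, value_scale = "log2")
  x <- generate_cohorts(cfg)
  ref <- x$plasma
  panel <- marker_panel("platelet", x$truth$contamination_panel)
  fit <- iterative_scale_fit(subset_matrix(ref, proteins = panel$protein_ids))

  # sample exactly at the reference means scores ~0; +2 ref sd scores ~2
  probe <- rbind(fit$center, fit$center + 2 * fit$scale)
  rownames(probe) <- c("at_mean", "plus2")
  pm <- proteomic_matrix(
    probe, data.frame(sample_id = rownames(probe), specimen = "plasma",
                      cohort_id = c("X", "Y")), scale = "log2")
  cr <- contamination_scores(pm, panel, ref)
  sc <- setNames(cr$sample_scores$score, cr$sample_scores$sample_id)
  expect_lt(abs(sc[["at_mean"]]), 0.05)
  expect_equal(sc[["plus2"]], 2, tolerance = 0.05)

  # translation calibration: +delta on every panel protein adds ~delta
  delta <- 0.7
  shifted <- ref$values[1:5, ]
  shifted[, panel$protein_ids] <- shifted[, panel$protein_ids] +
    delta * rep(fit$scale[panel$protein_ids], each = 5)
  base <- contamination_scores(
    subset_matrix(ref, samples = 1:5), panel, ref)$sample_scores$score
  moved <- contamination_scores(
    proteomic_matrix(shifted, ref$metadata[1:5, ], scale = "log2"),
    panel, ref)$sample_scores$score
  expect_equal(moved - base, rep(delta, 5), tolerance = 0.02)
})

test_that("a spiked cohort is flagged against a shared-truth reference; clean cohorts are not", {
  for (s in 1:3) {
    cfg <- synth_config(seed = s, n_cohorts = 4,
                        pairs_per_cohort = c(20, 20, 20, 60),
                        n_proteins = 150, contamination_panel_size = 25,
                        contaminated_cohort = 3, contamination_spike_sd = 1.5,
                        fraction_lod = 0, fraction_coag = 0, fraction_t1 = 0,
                        value_scale = "log2")
    x <- generate_cohorts(cfg)
    pl <- x$plasma
    study <- subset_matrix(pl, samples = pl$metadata$cohort_id %in% c("A", "B", "C"))
    ref <- subset_matrix(pl, samples = pl$metadata$cohort_id == "D")
    panel <- marker_panel("platelet", x$truth$contamination_panel)
    cr <- contamination_scores(study, panel, ref)
    expect_equal(unique(cr$flagged$cohort_id), "C")
  }
  expect_error(
    contamination_scores(study, marker_panel("ghost", "nonexistent"), ref),
    "ghost")
})

test_that("generalizability QC passes identity, notes global offsets, recovers planted shifts", {
  x <- small_synth(seed = 8, n_proteins = 150)
  coh <- subset_matrix(x$serum, samples = x$serum$metadata$cohort_id == "A")
  g <- generalizability_qc(coh, coh)
  expect_equal(g$verdict, "pass")
  expect_equal(g$pearson_r, 1)
  expect_length(g$outlier_proteins, 0L)

  # global +0.3 shift: correlation 1, no protein-level outliers, offset noted
  shifted <- proteomic_matrix(coh$values + 0.3, coh$metadata, scale = "log2")
  g2 <- generalizability_qc(shifted, coh)
  expect_equal(g2$verdict, "pass")
  expect_length(g2$outlier_proteins, 0L)
  expect_equal(g2$systematic_offset, 0.3, tolerance = 1e-12)
  expect_match(g2$notes, "offset")

  # planted 10% shift recovery at the strict fence
  cfg <- synth_config(seed = 18, n_cohorts = 2, pairs_per_cohort = c(100, 200),
                      n_proteins = 400, fraction_lod = 0, fraction_coag = 0,
                      contaminated_cohort = NA, contamination_panel_size = 0,
                      fraction_t1 = 0, cohort_shift_sd = 0,
                      value_scale = "log2")
  y <- generate_cohorts(cfg)
  se <- y$serum
  cohA <- subset_matrix(se, samples = se$metadata$cohort_id == "A")
  refB <- subset_matrix(se, samples = se$metadata$cohort_id == "B")
  set.seed(19)
  planted <- sample(protein_ids(cohA), 40)
  v <- cohA$values; v[, planted] <- v[, planted] + 2
  g3 <- generalizability_qc(proteomic_matrix(v, cohA$metadata, "log2"),
                            refB, multiplier = 3)
  expect_setequal(g3$outlier_proteins, planted)
  expect_equal(g3$verdict, "flag")
})

test_that("generalizability QC is symmetric up to sign", {
  x <- small_synth(seed = 9, n_proteins = 150)
  a <- subset_matrix(x$plasma, samples = x$plasma$metadata$cohort_id == "A")
  b <- subset_matrix(x$plasma, samples = x$plasma$metadata$cohort_id == "B")
  g_ab <- generalizability_qc(a, b)
  g_ba <- generalizability_qc(b, a)
  expect_equal(g_ab$median_diff$diff, -g_ba$median_diff$diff)
  expect_setequal(g_ab$outlier_proteins, g_ba$outlier_proteins)
})
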