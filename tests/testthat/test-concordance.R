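test_that("bh_adjust matches hand cases and validates input", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.1, 1.2)), "outside")
  expect_error(bh_adjust(c(-0.1, 0.2)), "outside")
})

test_that("bh_adjust equals the brute-force step-up oracle and preserves p-order", {
  set.seed(41)
  for (i in 1:1000) {
    m <- sample(1:50, 1)
    p <- runif(m)^sample(1:3, 1)
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("spearman is rank-invariant where pearson is not", {
  set.seed(42)
  s <- matrix(rnorm(30 * 3, 8, 1), 30, 3)
  serum <- make_pm(s, "serum")
  # plasma = cubed (monotone, nonlinear) / negated / linear copies of serum
  pl <- cbind((s[, 1] - 8)^3, -s[, 2], s[, 3])
  plasma <- make_pm(pl, "plasma")
  rownames(plasma$values) <- sub("se_", "pl_", rownames(plasma$values))
  plasma$metadata$sample_id <- rownames(plasma$values)
  tab <- protein_concordance(build_pairs(serum, plasma))
  expect_equal(tab$spearman_r[1], 1)
  expect_lt(tab$pearson_r[1], 1)
  expect_equal(tab$spearman_r[2], -1)
  expect_equal(tab$spearman_r[3], 1)
  expect_equal(tab$pearson_r[3], 1)
})

test_that("spearman p-values match cor.test across small and moderate n", {
  for (n in c(7, 9, 12, 40)) {
    set.seed(n)
    s <- matrix(rnorm(n * 8, 8), n, 8)
    pl <- 0.7 * s + matrix(rnorm(n * 8, 0, 1), n, 8)
    serum <- make_pm(s, "serum")
    plasma <- make_pm(pl, "plasma")
    rownames(plasma$values) <- sub("se_", "pl_", rownames(plasma$values))
    plasma$metadata$sample_id <- rownames(plasma$values)
    tab <- protein_concordance(build_pairs(serum, plasma))
    ref_p <- vapply(1:8, function(j) {
      suppressWarnings(cor.test(s[, j], pl[, j], method = "spearman",
                                exact = n <= 9)$p.value)
    }, numeric(1))
    expect_equal(tab$spearman_p, ref_p, tolerance = 1e-8)
  }
})

test_that("zero-variance proteins are flagged, not selected, and never error", {
  s <- matrix(c(rnorm(10, 8), rep(5, 10)), 10, 2)
  pl <- matrix(rnorm(20, 8), 10, 2)
  serum <- make_pm(s, "serum")
  plasma <- make_pm(pl, "plasma")
  rownames(plasma$values) <- sub("se_", "pl_", rownames(plasma$values))
  plasma$metadata$sample_id <- rownames(plasma$values)
  tab <- protein_concordance(build_pairs(serum, plasma))
  expect_true(tab$flagged[2])
  expect_true(is.na(tab$spearman_r[2]))
  expect_false("prot002" %in% select_proteins(tab, q_threshold = 1))
})

test_that("protein selection applies the q threshold and the correlation floor", {
  tab <- data.frame(protein_id = c("a", "b", "c", "d"),
                    spearman_r = c(0.9, 0.25, 0.5, 0.9),
                    spearman_q = c(0.01, 0.01, 0.2, 0.04),
                    flagged = FALSE)
  expect_setequal(select_proteins(tab), c("a", "b", "d"))
  expect_setequal(select_proteins(tab, r_floor = 0.3), c("a", "d"))
  expect_setequal(select_proteins(tab, q_threshold = 0.02), c("a", "b"))
  expect_setequal(select_proteins(tab, q_threshold = 0.02, r_floor = 0.3), "a")
})

test_that("ratio classification finds the coagulation tails and is scale-invariant", {
  # identical matrices: every ratio exactly 1, all central
  v <- matrix(2^rnorm(60, 8), 12, 5)
  serum <- make_pm(v, "serum", scale = "raw_rfu")
  plasma <- make_pm(v, "plasma", scale = "raw_rfu")
  rownames(plasma$values) <- sub("se_", "pl_", rownames(plasma$values))
  plasma$metadata$sample_id <- rownames(plasma$values)
  rc <- ratio_classification(build_pairs(serum, plasma))
  expect_true(all(rc$median_ratio == 1))
  expect_true(all(rc$ratio_class == "central"))

  # planted extreme-ratio proteins among ~ratio-1 proteins
  set.seed(43)
  n <- 30; p <- 500
  s <- matrix(2^rnorm(n * p, 8, 1), n, p)
  mult <- rep(1, p); mult[5] <- 100; mult[9] <- 0.01
  pl <- sweep(s, 2, mult, "*") * 2^matrix(rnorm(n * p, 0, 0.1), n, p)
  serum <- make_pm(s, "serum", scale = "raw_rfu")
  plasma <- make_pm(pl, "plasma", scale = "raw_rfu")
  rownames(plasma$values) <- sub("se_", "pl_", rownames(plasma$values))
  plasma$metadata$sample_id <- rownames(plasma$values)
  pd <- build_pairs(serum, plasma)
  rc2 <- ratio_classification(pd)
  expect_equal(rc2$ratio_class[5], "high_plasma")
  expect_equal(rc2$ratio_class[9], "high_serum")
  expect_equal(rc2$median_ratio[5], 100, tolerance = 0.15)

  # common positive rescaling of both matrices changes nothing
  pd2 <- pd
  pd2$serum$values <- pd$serum$values * 7.3
  pd2$plasma$values <- pd$plasma$values * 7.3
  rc3 <- ratio_classification(pd2)
  expect_equal(rc3$ratio_class, rc2$ratio_class)
  expect_equal(rc3$median_ratio, rc2$median_ratio, tolerance = 1e-12)
})

test_that("fisher enrichment matches the hypergeometric oracle and skips disjoint panels", {
  set.seed(44)
  universe <- sprintf("u%04d", 1:1000)
  panel <- marker_panel("plt", universe[1:20])
  res <- panel_enrichment(universe[1:20], universe, panel, fdr = 0.1)
  expect_lt(res$fisher_p, 1e-20)
  expect_true(res$enriched)

  # random 2x2 tables vs the hypergeometric sum oracle
  for (i in 1:50) {
    N <- sample(40:200, 1)
    K <- sample(5:20, 1)
    nsel <- sample(5:30, 1)
    univ <- sprintf("x%03d", seq_len(N))
    pan <- marker_panel("p", sample(univ, K))
    sel <- sample(univ, nsel)
    got <- panel_enrichment(sel, univ, pan, fdr = 0.1)$fisher_p
    a <- length(intersect(sel, pan$protein_ids))
    # two-sided fisher p: sum of hypergeometric probabilities <= P(observed)
    dens <- dhyper(0:min(K, nsel), K, N - K, nsel)
    oracle <- sum(dens[dens <= dens[a + 1] * (1 + 1e-7)])
    expect_equal(got, oracle, tolerance = 1e-10)
  }

  expect_warning(
    res2 <- panel_enrichment(universe[1:5], universe,
                             list(marker_panel("gone", "zzz"),
                                  marker_panel("plt", universe[1:20]))),
    "gone")
  expect_equal(res2$panel_id, "plt")
})

test_that("random selections are enriched at about the nominal FDR", {
  set.seed(45)
  universe <- sprintf("u%03d", 1:400)
  panels <- lapply(1:8, function(i)
    marker_panel(paste0("pan", i), sample(universe, 25)))
  hits <- replicate(150, {
    sel <- sample(universe, 40)
    mean(panel_enrichment(sel, universe, panels, fdr = 0.1)$enriched)
  })
  # BH at FDR 0.1 under the null: family-wise false-call rate ~<= 0.1
  expect_lt(mean(hits), 0.1)
})

test_that("the top PC tracks a planted specimen offset and rank tests behave", {
  x <- small_synth(seed = 20, n_proteins = 150, contaminated_cohort = NA,
                   contamination_panel_size = 0)
  comb <- proteomic_matrix(rbind(x$serum$values, x$plasma$values),
                           rbind(x$serum$metadata, x$plasma$metadata),
                           scale = "log2")
  pa <- pc_association(comb, comb$metadata$specimen, n_components = 10)
  expect_lt(pa$p[1], 0.05)
  expect_equal(which.max(pa$explained_variance), 1L)
  expect_error(pc_association(comb, rep("one", nrow(comb$values))), "levels")

  # >2 levels goes through Kruskal-Wallis without error
  pa3 <- pc_association(comb, interaction(comb$metadata$specimen,
                                          comb$metadata$cohort_id),
                        n_components = 5)
  expect_true(all(pa3$p >= 0 & pa3$p <= 1))
})
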