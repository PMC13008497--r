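# Fixture builders used across the suite. Everything is generated in code;
# nothing is read from disk except in the explicit I/O round-trip tests.

# minimal valid matrix with hand-set values
make_pm <- function(values, specimen = "serum", scale = "log2",
                    cohort = "A", patient = NULL, timepoint = "T0",
                    nsf = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("%s_s%02d", substr(specimen, 1, 2), seq_len(n))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("prot%03d", seq_len(ncol(values)))
  md <- data.frame(
    sample_id = rownames(values),
    patient_id = patient %||% sprintf("P%02d", seq_len(n)),
    cohort_id = cohort,
    specimen = specimen,
    timepoint = timepoint,
    stringsAsFactors = FALSE
  )
  if (!is.null(nsf)) md$norm_scale_factor <- nsf
  proteomic_matrix(values, md, scale = scale)
}

# small paired dataset with exact linear truth (no noise unless asked)
make_linear_pairs <- function(n = 10, p = 6, slope = 1, intercept = 0,
                              noise_sd = 0, seed = 1) {
  set.seed(seed)
  s <- matrix(rnorm(n * p, mean = 8, sd = 1.5), n, p)
  slope <- rep_len(slope, p)
  intercept <- rep_len(intercept, p)
  pl <- sweep(sweep(s, 2, slope, "*"), 2, intercept, "+") +
    matrix(rnorm(n * p, 0, noise_sd), n, p)
  rownames(s) <- sprintf("P%02d_T0_S", seq_len(n))
  rownames(pl) <- sprintf("P%02d_T0_P", seq_len(n))
  colnames(s) <- colnames(pl) <- sprintf("prot%03d", seq_len(p))
  serum <- make_pm(s, "serum", patient = sprintf("P%02d", seq_len(n)))
  plasma <- make_pm(pl, "plasma", patient = sprintf("P%02d", seq_len(n)))
  build_pairs(serum, plasma)
}

# default small synthetic cohort set on the log2 scale (fast)
small_synth <- function(seed = 1, ...) {
  args <- list(seed = seed, n_cohorts = 2, pairs_per_cohort = c(20, 15),
               n_proteins = 120, contamination_panel_size = 15,
               contaminated_cohort = 2, fraction_t1 = c(0, 0.3),
               value_scale = "log2")
  args[names(list(...))] <- list(...)
  generate_cohorts(do.call(synth_config, args))
}

# independent brute-force quantile (linear interpolation between order
# statistics, the type-7 convention) used as the IQR oracle
oracle_quartile <- function(x, prob) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * prob + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# independent brute-force BH step-up oracle
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# independent iterative z-scoring oracle: plain loop, re-derived from the
# procedure description, no shared code with the implementation
oracle_iterative <- function(x, bound = 4, max_iter = 50) {
  keep <- rep(TRUE, length(x))
  for (i in seq_len(max_iter)) {
    mu <- mean(x[keep]); s <- sd(x[keep])
    out <- keep & abs((x - mu) / s) > bound
    if (!any(out)) break
    keep[out] <- FALSE
  }
  mu <- mean(x[keep]); s <- sd(x[keep])
  z <- (x - mu) / s
  z[!keep] <- sign(x[!keep] - mu) * bound
  z
}
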