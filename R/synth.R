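# Seeded generator of paired serum/plasma cohorts with known ground truth.
# Every pipeline stage is testable against planted truth without access to
# patient data. The generative model (log2 scale):
#
#   serum  = baseline_j + cohort_shift_cj + patient_effect_ij + noise
#   plasma = slope_j * serum + intercept_j + independent noise
#
# with protein subpopulations layered on top: detection-limit (LOD)
# compressed proteins (hard floor + floor noise, breaking rank
# correlation), coagulation-affected proteins with extreme plasma/serum
# ratios (intercepts of +/- log2(100) magnitude), contamination-marker
# spikes confined to one cohort's plasma, longitudinal T1 re-samples
# sharing a damped patient effect, and optional planted pair mismatches.

#' Configuration for the synthetic paired-cohort generator
#'
#' Defaults mirror the study design the pipeline was built around: three
#' cohorts of 55 / 82 / 47 serum-plasma pairs (the second with ~48% T1
#' re-samples), 7289 proteins, and the third cohort's plasma carrying a
#' contamination-marker spike. All sizes and effect magnitudes are
#' configurable; `seed` is mandatory and the output is fully reproducible.
#'
#' @param seed Integer seed (mandatory).
#' @param n_cohorts Number of cohorts.
#' @param pairs_per_cohort Integer vector (recycled) of pairs per cohort.
#' @param n_proteins Number of protein analytes.
#' @param protein_baseline_mean,protein_baseline_sd Log2 baseline abundance
#'   distribution across proteins (typical multiplexed-assay dynamic range).
#' @param patient_sd Between-patient biological sd (log2).
#' @param noise_sd Residual measurement noise sd (log2), applied
#'   independently to serum and plasma.
#' @param slope_mean,slope_sd True scaling-slope distribution across
#'   proteins.
#' @param intercept_mean,intercept_sd True scaling-intercept distribution
#'   (log2 units).
#' @param fraction_lod Fraction of proteins compressed at the detection
#'   limit.
#' @param lod_floor Detection floor (log2 units).
#' @param lod_floor_noise_sd Sd of the independent noise replacing floored
#'   values (breaks serum-plasma rank correlation).
#' @param fraction_coag Fraction of coagulation-affected proteins (half
#'   plasma-retained, half serum-accumulated).
#' @param coag_magnitude Magnitude of coagulation intercepts (default
#'   log2(100), producing ~100x / ~0.01x ratios).
#' @param contaminated_cohort Index of the cohort whose plasma carries the
#'   contamination spike (`NA` for none).
#' @param contamination_panel_size Number of contamination-marker proteins.
#' @param contamination_spike_sd Spike size in units of the marker's plasma
#'   sd.
#' @param fraction_t1 Fraction (recycled per cohort) of pairs that are T1
#'   re-samples of existing patients.
#' @param t1_perturb_sd Sd of the damped perturbation added to the patient
#'   effect at T1.
#' @param cohort_shift_sd Sd of small per-protein cohort offsets (kept
#'   below the specimen effect so cohort separation is weaker than specimen
#'   separation).
#' @param mismatch_count Number of pairs whose plasma is regenerated from a
#'   different patient effect (planted pairing failures).
#' @param value_scale Scale of the emitted matrices (`"raw_rfu"` default,
#'   or `"log2"`).
#' @return A validated list of class `synth_config`.
#' @export
synth_config <- function(seed,
                         n_cohorts = 3,
                         pairs_per_cohort = c(55, 82, 47),
                         n_proteins = 7289,
                         protein_baseline_mean = 8,
                         protein_baseline_sd = 2,
                         patient_sd = 1,
                         noise_sd = 0.3,
                         slope_mean = 1,
                         slope_sd = 0.2,
                         intercept_mean = 0,
                         intercept_sd = 0.5,
                         fraction_lod = 0.05,
                         lod_floor = 4,
                         lod_floor_noise_sd = 0.1,
                         fraction_coag = 0.02,
                         coag_magnitude = log2(100),
                         contaminated_cohort = 3,
                         contamination_panel_size = 30,
                         contamination_spike_sd = 1.5,
                         fraction_t1 = c(0, 39 / 82, 0),
                         t1_perturb_sd = 0.5,
                         cohort_shift_sd = 0.2,
                         mismatch_count = 0,
                         value_scale = c("raw_rfu", "log2")) {
  abort_if(missing(seed), "synth_config requires a seed")
  value_scale <- match.arg(value_scale)
  # the default spiked cohort only exists in designs with >= 3 cohorts
  if (missing(contaminated_cohort) && n_cohorts < 3) {
    contaminated_cohort <- NA
  }
  cfg <- list(seed = as.integer(seed), n_cohorts = as.integer(n_cohorts),
              pairs_per_cohort = rep_len(as.integer(pairs_per_cohort),
                                         n_cohorts),
              n_proteins = as.integer(n_proteins),
              protein_baseline_mean = protein_baseline_mean,
              protein_baseline_sd = protein_baseline_sd,
              patient_sd = patient_sd, noise_sd = noise_sd,
              slope_mean = slope_mean, slope_sd = slope_sd,
              intercept_mean = intercept_mean, intercept_sd = intercept_sd,
              fraction_lod = fraction_lod, lod_floor = lod_floor,
              lod_floor_noise_sd = lod_floor_noise_sd,
              fraction_coag = fraction_coag, coag_magnitude = coag_magnitude,
              contaminated_cohort = contaminated_cohort,
              contamination_panel_size = as.integer(contamination_panel_size),
              contamination_spike_sd = contamination_spike_sd,
              fraction_t1 = rep_len(fraction_t1, n_cohorts),
              t1_perturb_sd = t1_perturb_sd,
              cohort_shift_sd = cohort_shift_sd,
              mismatch_count = as.integer(mismatch_count),
              value_scale = value_scale)
  abort_if(cfg$n_cohorts < 1 || any(cfg$pairs_per_cohort < 1),
           "need >= 1 cohort with >= 1 pair each")
  abort_if(cfg$n_proteins < 1, "need >= 1 protein")
  fr <- c(cfg$fraction_lod, cfg$fraction_coag, cfg$fraction_t1)
  abort_if(any(fr < 0 | fr > 1), "fractions must lie in [0, 1]")
  special <- cfg$fraction_lod + cfg$fraction_coag +
    cfg$contamination_panel_size / cfg$n_proteins
  abort_if(special > 1,
           "special protein classes exceed the protein universe (%.2f > 1)",
           special)
  abort_if(any(c(cfg$patient_sd, cfg$noise_sd, cfg$slope_sd,
                 cfg$intercept_sd, cfg$cohort_shift_sd, cfg$t1_perturb_sd,
                 cfg$lod_floor_noise_sd) < 0),
           "standard deviations must be >= 0")
  abort_if(!is.na(cfg$contaminated_cohort) &&
             (cfg$contaminated_cohort < 1 ||
                cfg$contaminated_cohort > cfg$n_cohorts),
           "contaminated_cohort out of range")
  abort_if(cfg$mismatch_count >= sum(cfg$pairs_per_cohort),
           "mismatch_count must be < total pairs")
  structure(cfg, class = "synth_config")
}

#' Generate paired serum/plasma cohorts with known ground truth
#'
#' See [synth_config()] for the generative model and its parameters. The
#' emitted matrices pool all cohorts (cohort membership lives in the
#' metadata) so that cohort-level analyses subset by `cohort_id`.
#'
#' @param cfg A [synth_config()].
#' @return A list of class `synth_cohorts`: `serum` and `plasma`
#'   (`proteomic_matrix` objects), `truth` (list of data.frames `proteins`
#'   with true slope/intercept/class, `samples` with contamination status,
#'   `pairs` with the genuinely-matched flag, plus `contamination_panel`),
#'   and `config`.
#' @export
generate_cohorts <- function(cfg) {
  abort_if(!inherits(cfg, "synth_config"), "cfg must be a synth_config")
  with_seed(cfg$seed, generate_cohorts_impl(cfg))
}

generate_cohorts_impl <- function(cfg) {
  P <- cfg$n_proteins
  prot <- sprintf("seq.%05d.12", seq_len(P))

  cls <- rep("normal", P)
  n_lod <- round(cfg$fraction_lod * P)
  n_coag <- round(cfg$fraction_coag * P)
  n_con <- min(cfg$contamination_panel_size, P - n_lod - n_coag)
  special <- sample.int(P, n_lod + n_coag + n_con)
  idx_lod <- special[seq_len(n_lod)]
  idx_coag <- special[n_lod + seq_len(n_coag)]
  idx_con <- special[n_lod + n_coag + seq_len(n_con)]
  cls[idx_lod] <- "lod"
  coag_hi <- idx_coag[seq_len(floor(n_coag / 2))]
  coag_lo <- setdiff(idx_coag, coag_hi)
  cls[coag_hi] <- "coag_high_plasma"
  cls[coag_lo] <- "coag_high_serum"
  cls[idx_con] <- "contamination_marker"

  baseline <- stats::rnorm(P, cfg$protein_baseline_mean,
                           cfg$protein_baseline_sd)
  # LOD proteins sit well below the floor so almost all mass is compressed
  baseline[idx_lod] <- stats::rnorm(n_lod, cfg$lod_floor - 2, 0.5)
  slope <- stats::rnorm(P, cfg$slope_mean, cfg$slope_sd)
  intercept <- stats::rnorm(P, cfg$intercept_mean, cfg$intercept_sd)
  # coagulation proteins are a pure specimen offset at the configured
  # magnitude; slope heterogeneity would smear the planted ratio
  slope[idx_coag] <- cfg$slope_mean
  intercept[coag_hi] <- cfg$coag_magnitude + stats::rnorm(length(coag_hi), 0, 0.2)
  intercept[coag_lo] <- -cfg$coag_magnitude + stats::rnorm(length(coag_lo), 0, 0.2)

  shift <- matrix(stats::rnorm(cfg$n_cohorts * P, 0, cfg$cohort_shift_sd),
                  cfg$n_cohorts, P)

  serum_rows <- list(); plasma_rows <- list(); md_rows <- list()
  for (co in seq_len(cfg$n_cohorts)) {
    coh <- LETTERS[co]
    n_pr <- cfg$pairs_per_cohort[co]
    n_t1 <- round(cfg$fraction_t1[co] * n_pr)
    n_pat <- n_pr - n_t1
    abort_if(n_pat < 1, "cohort %s has no T0 patients after T1 allocation", coh)
    u <- matrix(stats::rnorm(n_pat * P, 0, cfg$patient_sd), n_pat, P)
    pat_idx <- c(seq_len(n_pat), seq_len(n_t1))
    tp <- c(rep("T0", n_pat), rep("T1", n_t1))
    for (i in seq_along(pat_idx)) {
      pe <- u[pat_idx[i], ]
      if (tp[i] == "T1") {
        pe <- pe + stats::rnorm(P, 0, cfg$t1_perturb_sd)
      }
      sv <- baseline + shift[co, ] + pe + stats::rnorm(P, 0, cfg$noise_sd)
      pv <- slope * sv + intercept + stats::rnorm(P, 0, cfg$noise_sd)
      serum_rows[[length(serum_rows) + 1L]] <- sv
      plasma_rows[[length(plasma_rows) + 1L]] <- pv
      md_rows[[length(md_rows) + 1L]] <- data.frame(
        patient_id = sprintf("%s_P%03d", coh, pat_idx[i]),
        cohort_id = coh, timepoint = tp[i], stringsAsFactors = FALSE)
    }
  }
  md <- do.call(rbind, md_rows)
  S <- do.call(rbind, serum_rows)
  Pm <- do.call(rbind, plasma_rows)
  colnames(S) <- colnames(Pm) <- prot

  # planted pairing failures: plasma regenerated from a fresh patient effect
  matched <- rep(TRUE, nrow(md))
  if (cfg$mismatch_count > 0) {
    mm <- sample.int(nrow(md), cfg$mismatch_count)
    for (i in mm) {
      co <- match(md$cohort_id[i], LETTERS)
      sv_alien <- baseline + shift[co, ] + stats::rnorm(P, 0, cfg$patient_sd) +
        stats::rnorm(P, 0, cfg$noise_sd)
      Pm[i, ] <- slope * sv_alien + intercept + stats::rnorm(P, 0, cfg$noise_sd)
    }
    matched[mm] <- FALSE
  }

  # contamination spike: flagged cohort's plasma, marker proteins only,
  # expressed in units of each marker's plasma sd
  contaminated <- rep(FALSE, nrow(md))
  if (!is.na(cfg$contaminated_cohort) && n_con > 0) {
    rows <- md$cohort_id == LETTERS[cfg$contaminated_cohort]
    plasma_sd <- sqrt(slope[idx_con]^2 *
                        (cfg$patient_sd^2 + cfg$noise_sd^2) + cfg$noise_sd^2)
    Pm[rows, idx_con] <- Pm[rows, idx_con] +
      rep(cfg$contamination_spike_sd * plasma_sd, each = sum(rows))
    contaminated <- rows
  }

  # detection floor: hard floor plus independent floor noise
  if (n_lod > 0) {
    for (mat in c("S", "Pm")) {
      v <- get(mat)
      sub <- v[, idx_lod, drop = FALSE]
      low <- sub < cfg$lod_floor
      sub[low] <- cfg$lod_floor +
        stats::rnorm(sum(low), 0, cfg$lod_floor_noise_sd)
      v[, idx_lod] <- sub
      assign(mat, v)
    }
  }

  sid_s <- sprintf("%s_%s_S", md$patient_id, md$timepoint)
  sid_p <- sprintf("%s_%s_P", md$patient_id, md$timepoint)
  rownames(S) <- sid_s
  rownames(Pm) <- sid_p
  nsf <- stats::runif(2 * nrow(md), 0.6, 1.6)
  md_s <- data.frame(sample_id = sid_s, md, specimen = "serum",
                     norm_scale_factor = nsf[seq_len(nrow(md))],
                     stringsAsFactors = FALSE)
  md_p <- data.frame(sample_id = sid_p, md, specimen = "plasma",
                     norm_scale_factor = nsf[nrow(md) + seq_len(nrow(md))],
                     stringsAsFactors = FALSE)

  if (cfg$value_scale == "raw_rfu") {
    S <- 2^S
    Pm <- 2^Pm
  }

  truth <- list(
    proteins = data.frame(protein_id = prot, slope = slope,
                          intercept = intercept, class = cls,
                          stringsAsFactors = FALSE),
    samples = data.frame(sample_id = c(sid_s, sid_p),
                         contaminated = c(rep(FALSE, nrow(md)), contaminated),
                         stringsAsFactors = FALSE),
    pairs = data.frame(patient_id = md$patient_id, timepoint = md$timepoint,
                       matched = matched, stringsAsFactors = FALSE),
    contamination_panel = prot[idx_con]
  )
  structure(list(serum = proteomic_matrix(S, md_s, scale = cfg$value_scale),
                 plasma = proteomic_matrix(Pm, md_p, scale = cfg$value_scale),
                 truth = truth,
                 config = cfg),
            class = "synth_cohorts")
}

#' @export
print.synth_cohorts <- function(x, ...) {
  cat(sprintf("synth_cohorts: %d cohorts, %d pairs, %d proteins [%s]\n",
              x$config$n_cohorts, nrow(x$truth$pairs),
              x$config$n_proteins, x$config$value_scale))
  invisible(x)
}

#' Pair the two matrices of a synthetic cohort set
#'
#' Convenience wrapper around [build_pairs()].
#'
#' @param x A `synth_cohorts` object.
#' @param cohort Optional cohort id (e.g. `"A"`) to restrict to.
#' @return A `paired_dataset`.
#' @export
synth_paired <- function(x, cohort = NULL) {
  s <- x$serum; p <- x$plasma
  if (!is.null(cohort)) {
    s <- subset_matrix(s, samples = s$metadata$cohort_id %in% cohort)
    p <- subset_matrix(p, samples = p$metadata$cohort_id %in% cohort)
  }
  build_pairs(s, p)
}

#' Plant pairing failures by swapping plasma among k pairs
#'
#' Selects `k` pairs (seeded) and cyclically rotates their plasma
#' assignments, so each affected pair receives another affected pair's
#' plasma and the sample multiset is preserved. The planted truth is
#' returned alongside the perturbed dataset so pairing-QC recovery can be
#' checked exactly.
#'
#' @param pd A `paired_dataset`.
#' @param k Number of pairs to mismatch (0 is the identity; 1 is
#'   impossible; must be < number of pairs).
#' @param seed Integer seed.
#' @return List: `pd` (perturbed `paired_dataset`), `mismatched` (logical
#'   per pair).
#' @export
inject_pair_mismatches <- function(pd, k, seed = 1) {
  n <- n_pairs(pd)
  abort_if(k >= n, "k must be < number of pairs (%d)", n)
  abort_if(k == 1, "cannot mismatch a single pair (no swap partner)")
  abort_if(k < 0, "k must be >= 0")
  flags <- rep(FALSE, n)
  if (k == 0) return(list(pd = pd, mismatched = flags))
  idx <- with_seed(seed, sample.int(n, k))
  pairs <- pd$pairs
  pairs$plasma_sample_id[idx] <- pairs$plasma_sample_id[idx[c(seq_len(k)[-1], 1)]]
  flags[idx] <- TRUE
  out <- structure(
    list(serum = pd$serum,
         plasma = subset_matrix(pd$plasma, samples = pairs$plasma_sample_id),
         pairs = pairs,
         orphans = pd$orphans),
    class = "paired_dataset")
  list(pd = out, mismatched = flags)
}
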