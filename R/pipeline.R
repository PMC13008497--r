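# End-to-end orchestration of the bridging workflow with QC gates as hard
# decision points: log2 transform -> protein selection -> pairing QC ->
# contamination QC -> generalizability QC -> factor fitting -> scaling ->
# bridging QC.

#' Pipeline configuration
#'
#' Aggregates every tunable threshold of the workflow so that a run
#' manifest can record exactly what was used.
#'
#' @param iqr_multiplier IQR fence multiplier for all outlier screens
#'   (default 1.5).
#' @param sd_bound,max_iterations Iterative-scaling parameters (defaults 4
#'   and 50).
#' @param scale_factor_range Acceptance range for assay normalization scale
#'   factors (default `c(0.4, 2.5)`, inclusive).
#' @param q_threshold,r_floor Protein-selection thresholds (defaults 0.05
#'   and 0).
#' @param enrichment_fdr FDR for panel-enrichment calls (default 0.1).
#' @param cv_k Cross-validation folds when factors are applied to their own
#'   cohort (default 5).
#' @param seed Integer seed for all randomized steps.
#' @param quartile_type Quantile interpolation type (default 7, linear).
#' @param class_threshold Probability threshold for binary prediction
#'   agreement (default 0.5).
#' @param pairing_halt_floor Median pair correlation below which pairing QC
#'   halts the run (default 0.3).
#' @param generalizability_tail,generalizability_floor Flagging thresholds
#'   of the generalizability check (defaults 0.05 and 0.8).
#' @return A list of class `bridge_config`.
#' @export
bridge_config <- function(iqr_multiplier = 1.5,
                          sd_bound = 4,
                          max_iterations = 50,
                          scale_factor_range = c(0.4, 2.5),
                          q_threshold = 0.05,
                          r_floor = 0,
                          enrichment_fdr = 0.1,
                          cv_k = 5,
                          seed = 1,
                          quartile_type = 7,
                          class_threshold = 0.5,
                          pairing_halt_floor = 0.3,
                          generalizability_tail = 0.05,
                          generalizability_floor = 0.8) {
  cfg <- as.list(environment())
  abort_if(any(c(cfg$iqr_multiplier, cfg$sd_bound, cfg$q_threshold,
                 cfg$enrichment_fdr) <= 0),
           "thresholds must be positive")
  abort_if(length(cfg$scale_factor_range) != 2 ||
             diff(cfg$scale_factor_range) < 0,
           "scale_factor_range must be an ordered pair")
  structure(cfg, class = "bridge_config")
}

# exit codes per gate, distinguishable by caller and CLI
GATE_CODES <- c(ok = 0L, assay_qc = 1L, pairing_qc = 2L,
                contamination_qc = 3L, generalizability_qc = 4L,
                bridging_qc = 5L)

#' Run the serum-plasma bridging workflow end to end
#'
#' Executes, in order: log2 transformation (if needed), assay-QC
#' scale-factor filtering, per-protein concordance screening and selection,
#' pairing QC, contamination QC (when panels and a plasma reference are
#' supplied), generalizability QC (when reference matrices are supplied),
#' scaling-factor fitting on the surviving pairs and proteins, application
#' to the target serum matrix, and bridging QC (pair co-clustering, plus
#' prediction agreement when a predictor is supplied). A failed gate halts
#' the run with a machine-readable verdict and a nonzero status unless
#' `force = TRUE`, in which case the flag is carried into the final report
#' and the run continues — supporting deliberate, investigated overrides.
#'
#' @param pd A `paired_dataset` (raw RFU or log2).
#' @param config A [bridge_config()].
#' @param target_serum Serum matrix to scale (default: the paired serum).
#' @param reference_serum,reference_plasma Optional external reference
#'   matrices for generalizability QC (log2 or raw RFU).
#' @param contamination_panels Optional [marker_panel()] list for
#'   contamination QC (requires `reference_plasma`).
#' @param predictor Optional [surrogate_predictor()] (or object with a
#'   `predict` method) for prediction-agreement bridging QC.
#' @param out_dir Optional directory; when given, the factor table, scaled
#'   matrix, concordance table and a JSON run manifest are written there.
#' @param force Downgrade gate halts to warnings carried in the report.
#' @return A list of class `bridge_run`: `status` (0 = success, otherwise
#'   the failing gate's code), `halted_at` (gate name or `NA`), `gates`
#'   (per-gate verdicts), `qc`, `concordance`, `selected`, `factors`,
#'   `scaled_serum`, `bridging`, `manifest`.
#' @export
run_pipeline <- function(pd, config = bridge_config(),
                         target_serum = NULL,
                         reference_serum = NULL, reference_plasma = NULL,
                         contamination_panels = NULL,
                         predictor = NULL,
                         out_dir = NULL, force = FALSE) {
  abort_if(!inherits(pd, "paired_dataset"), "pd must be a paired_dataset")
  gates <- list()
  halted_at <- NA_character_
  status <- GATE_CODES[["ok"]]
  halt <- function(gate) {
    if (is.na(halted_at)) {
      halted_at <<- gate
      status <<- GATE_CODES[[gate]]
    }
  }

  to_log2 <- function(m) if (is.null(m) || m$scale == "log2") m
    else log2_transform(m)
  if (pd$serum$scale == "raw_rfu") {
    pd <- structure(list(serum = log2_transform(pd$serum),
                         plasma = log2_transform(pd$plasma),
                         pairs = pd$pairs, orphans = pd$orphans),
                    class = "paired_dataset")
  }
  target_serum <- to_log2(target_serum %||% pd$serum)
  reference_serum <- to_log2(reference_serum)
  reference_plasma <- to_log2(reference_plasma)

  # --- gate: assay QC (normalization scale factors) ---------------------
  assay <- NULL
  if ("norm_scale_factor" %in% names(pd$serum$metadata)) {
    md <- rbind(pd$serum$metadata, pd$plasma$metadata)
    assay <- scale_factor_filter(md, low = config$scale_factor_range[1],
                                 high = config$scale_factor_range[2],
                                 pairs = pd$pairs)
    gates$assay_qc <- list(pass = TRUE,
                           n_excluded_pairs = length(assay$excluded_pairs))
    if (length(assay$excluded_pairs) > 0) {
      pd <- subset_pairs(pd, keep = -assay$excluded_pairs)
    }
    if (n_pairs(pd) < 8) {
      gates$assay_qc$pass <- FALSE
      halt("assay_qc")
    }
  }

  # --- protein selection -------------------------------------------------
  conc <- protein_concordance(pd)
  selected <- select_proteins(conc, q_threshold = config$q_threshold,
                              r_floor = config$r_floor)

  # --- gate: pairing QC --------------------------------------------------
  # pairing is assessed over the selected biomarkers, but when the screen
  # retains almost nothing (itself a symptom of broken pairing) fall back
  # to all proteins so the gate can still render a verdict
  pairing_panel <- if (length(selected) >= 10) selected else NULL
  pq <- pairing_qc(pd, panel = pairing_panel,
                   multiplier = config$iqr_multiplier,
                   halt_floor = config$pairing_halt_floor)
  gates$pairing_qc <- list(pass = !pq$halt,
                           n_excluded = length(pq$excluded_pairs),
                           flags = pq$flags)
  if (pq$halt) halt("pairing_qc")
  if (!pq$halt && length(pq$excluded_pairs) > 0) {
    pd <- subset_pairs(pd, keep = -pq$excluded_pairs)
  }

  # --- gate: contamination QC -------------------------------------------
  contam <- NULL
  if (!is.null(contamination_panels) && !is.null(reference_plasma)) {
    contam <- contamination_scores(pd$plasma, contamination_panels,
                                   reference_plasma,
                                   multiplier = config$iqr_multiplier,
                                   sd_bound = config$sd_bound,
                                   max_iterations = config$max_iterations)
    source_cohorts <- unique(pd$plasma$metadata$cohort_id)
    hit <- intersect(contam$flagged$cohort_id, source_cohorts)
    gates$contamination_qc <- list(pass = length(hit) == 0,
                                   flagged_cohorts = unique(hit))
    if (length(hit) > 0) halt("contamination_qc")
  }

  # --- gate: generalizability QC ----------------------------------------
  gener <- list()
  if (!is.null(reference_plasma)) {
    gener$plasma <- generalizability_qc(
      pd$plasma, reference_plasma, multiplier = config$iqr_multiplier,
      tail_fraction = config$generalizability_tail,
      spearman_floor = config$generalizability_floor)
  }
  if (!is.null(reference_serum)) {
    gener$serum <- generalizability_qc(
      pd$serum, reference_serum, multiplier = config$iqr_multiplier,
      tail_fraction = config$generalizability_tail,
      spearman_floor = config$generalizability_floor)
  }
  if (length(gener) > 0) {
    verdicts <- vapply(gener, function(g) g$verdict, character(1))
    gates$generalizability_qc <- list(pass = !any(verdicts == "flag"),
                                      verdicts = verdicts)
    if (any(verdicts == "flag")) halt("generalizability_qc")
  }

  proceed <- is.na(halted_at) || force
  factors <- scaled <- bridging <- NULL
  if (proceed) {
    sel_pd <- subset_pairs(pd, proteins = intersect(selected,
                                                    protein_ids(pd$serum)))
    factors <- suppressWarnings(fit_scaling_factors(sel_pd))
    scaled <- apply_scaling(
      subset_matrix(target_serum,
                    proteins = intersect(factors$protein_id,
                                         protein_ids(target_serum))),
      factors)
    scaled_pd <- structure(
      list(serum = subset_matrix(scaled,
                                 samples = intersect(sample_ids(scaled),
                                                     sel_pd$pairs$serum_sample_id)),
           plasma = subset_matrix(sel_pd$plasma,
                                  proteins = protein_ids(scaled)),
           pairs = sel_pd$pairs, orphans = pd$orphans),
      class = "paired_dataset")
    bridging <- list(coclustering = pair_coclustering(scaled_pd))
    if (!is.null(predictor)) {
      p_plasma <- predict_probabilities(predictor, scaled_pd$plasma)
      p_serum <- predict_probabilities(predictor, scaled_pd$serum)
      bridging$agreement <- prediction_agreement(
        p_plasma, p_serum, threshold = config$class_threshold)
      pass <- bridging$agreement$r2_fitted >= 0.5
      gates$bridging_qc <- list(pass = pass,
                                r2_unity = bridging$agreement$r2_unity,
                                r2_fitted = bridging$agreement$r2_fitted)
      if (!pass) halt("bridging_qc")
    }
  }

  manifest <- list(
    config = unclass(config),
    n_pairs_in = nrow(pd$pairs) + length(assay$excluded_pairs %||% integer()),
    n_pairs_used = n_pairs(pd),
    n_proteins_selected = length(selected),
    gates = lapply(gates, function(g) g[setdiff(names(g), "flags")]),
    status = unname(status),
    halted_at = halted_at,
    forced = force
  )

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(factors)) {
      write_factor_table(factors, file.path(out_dir, "scaling_factors.tsv"))
    }
    if (!is.null(scaled)) {
      write_matrix(scaled, file.path(out_dir, "scaled_serum.tsv"),
                   file.path(out_dir, "scaled_serum_metadata.tsv"))
    }
    utils::write.table(conc, file.path(out_dir, "concordance.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }

  structure(list(status = unname(status), halted_at = halted_at,
                 gates = gates,
                 qc = list(assay = assay, pairing = pq,
                           contamination = contam,
                           generalizability = gener),
                 concordance = conc, selected = selected,
                 factors = factors, scaled_serum = scaled,
                 bridging = bridging, manifest = manifest),
            class = "bridge_run")
}

#' @export
print.bridge_run <- function(x, ...) {
  cat(sprintf("bridge_run: status %d%s\n", x$status,
              if (!is.na(x$halted_at)) paste0(" (halted at ", x$halted_at, ")")
              else ""))
  for (g in names(x$gates)) {
    cat(sprintf("  gate %-22s %s\n", g,
                if (isTRUE(x$gates[[g]]$pass)) "pass" else "FLAG"))
  }
  if (!is.null(x$factors)) {
    cat(sprintf("  factors: %d proteins; scaled: %s samples\n",
                nrow(x$factors),
                if (is.null(x$scaled_serum)) "0"
                else nrow(x$scaled_serum$values)))
  }
  invisible(x)
}
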