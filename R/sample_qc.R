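# Pre-scaling QC checkpoints: assay-QC (normalization scale factors),
# pairing QC, contamination QC and cross-cohort generalizability QC.
# Each returns a structured report fragment; run_pipeline() turns flagged
# fragments into hard gates.

#' Assay-QC filter on per-sample normalization scale factors
#'
#' Samples whose assay normalization scale factor lies outside
#' `[low, high]` (inclusive at both ends) are excluded; when a pair table is
#' supplied, a pair is excluded if either of its members fails, since a
#' single failing member invalidates the pair for factor fitting. A missing
#' factor yields a flag, not an exclusion.
#'
#' @param metadata data.frame with `sample_id` and `norm_scale_factor`.
#' @param low,high Acceptance bounds (defaults 0.4 and 2.5, the platform's
#'   standard acceptance range).
#' @param pairs Optional pair table (as in `paired_dataset$pairs`).
#' @return A list of class `qc_fragment`: `excluded_samples` (data.frame
#'   sample_id, reason, value), `excluded_pairs` (row indices into `pairs`),
#'   `flags` (character).
#' @export
scale_factor_filter <- function(metadata, low = 0.4, high = 2.5, pairs = NULL) {
  abort_if(!"norm_scale_factor" %in% names(metadata),
           "metadata lacks a norm_scale_factor column")
  abort_if(low > high, "scale-factor range is reversed")
  nsf <- metadata$norm_scale_factor
  flags <- character()
  miss <- is.na(nsf)
  if (any(miss)) {
    flags <- sprintf("missing norm_scale_factor for %s (not excluded)",
                     name_some(metadata$sample_id[miss]))
  }
  fail <- !miss & (nsf < low | nsf > high)
  excluded_samples <- data.frame(
    sample_id = as.character(metadata$sample_id[fail]),
    reason = rep("scale_factor_out_of_range", sum(fail)),
    value = nsf[fail],
    stringsAsFactors = FALSE
  )
  excluded_pairs <- integer()
  if (!is.null(pairs)) {
    bad_ids <- excluded_samples$sample_id
    excluded_pairs <- which(pairs$serum_sample_id %in% bad_ids |
                              pairs$plasma_sample_id %in% bad_ids)
  }
  structure(list(check = "assay_qc",
                 excluded_samples = excluded_samples,
                 excluded_pairs = excluded_pairs,
                 flags = flags),
            class = "qc_fragment")
}

#' Pairing QC: exclude pairs with outlying low serum-plasma correlation
#'
#' Protein levels are z-scored per protein within each specimen (pooled
#' across cohorts), the Pearson correlation between the serum and plasma
#' profile of each pair is computed over a biomarker panel (all shared
#' proteins when no panel is given), and pairs whose correlation falls below
#' the lower IQR fence of the correlation distribution are excluded.
#' Because profiles are z-scored first, the exclusion decision is invariant
#' to protein-wise affine rescaling of either matrix. If pairs are generally
#' uncorrelated (median pair correlation below `halt_floor`) the fragment
#' carries a halt flag: bridging is not valid on such data and the process
#' should stop.
#'
#' @param pd A `paired_dataset` on the log2 scale with >= 8 pairs.
#' @param panel Optional character vector (or [marker_panel()]) of proteins
#'   over which pair correlations are computed; >= 10 measured proteins
#'   required.
#' @param multiplier IQR fence multiplier (default 1.5).
#' @param halt_floor Median pair correlation below which the halt flag is
#'   raised (default 0.3).
#' @return A `qc_fragment` with `pair_stats` (pair key, correlation,
#'   excluded), `bounds`, `excluded_pairs` (indices), `halt` and `flags`.
#' @export
pairing_qc <- function(pd, panel = NULL, multiplier = 1.5, halt_floor = 0.3) {
  abort_if(n_pairs(pd) < 8, "pairing QC needs >= 8 pairs (got %d)", n_pairs(pd))
  if (inherits(panel, "marker_panel")) panel <- panel$protein_ids
  prot <- protein_ids(pd$serum)
  if (!is.null(panel)) {
    unmeasured <- setdiff(panel, prot)
    if (length(unmeasured) > 0) {
      warning(sprintf("panel members not measured: %s", name_some(unmeasured)),
              call. = FALSE)
    }
    prot <- intersect(panel, prot)
  }
  abort_if(length(prot) < 10,
           "pairing QC needs >= 10 panel proteins measured (got %d)",
           length(prot))

  zs <- zscore_per_protein(subset_matrix(pd$serum, proteins = prot))
  zp <- zscore_per_protein(subset_matrix(pd$plasma, proteins = prot))
  # correlation across proteins within each pair = column-wise on transposes
  r <- col_pearson(t(zs$values), t(zp$values))
  bounds <- iqr_bounds(r, multiplier = multiplier)
  excluded <- r < bounds$lower
  halt <- stats::median(r) < halt_floor
  flags <- if (halt) {
    sprintf(paste0("pairs generally uncorrelated (median r = %.3f < %.2f); ",
                   "serum-plasma bridging is not valid on this dataset"),
            stats::median(r), halt_floor)
  } else character()

  structure(list(check = "pairing_qc",
                 pair_stats = data.frame(pd$pairs, correlation = r,
                                         excluded = excluded,
                                         stringsAsFactors = FALSE),
                 bounds = bounds,
                 excluded_pairs = which(excluded),
                 n_proteins = length(prot),
                 halt = halt,
                 flags = flags),
            class = "qc_fragment")
}

#' Contamination scoring against a reference cohort
#'
#' Marker-panel measurements (e.g. platelet or erythrocyte contamination
#' panels) are standardized against the distribution of an external
#' reference cohort of the same specimen type: iterative-scaling parameters
#' are fitted on the reference and applied to the study matrix, so scores
#' are in reference sd units. The per-sample score for a panel is the mean
#' of its standardized panel-protein values; a sample matching the
#' reference means scores ~0 and a sample elevated by d reference sds on
#' every panel protein scores ~d. Cohorts whose median score exceeds the
#' upper IQR fence of the reference samples' own scores (the null
#' distribution defining "uncontaminated") are flagged.
#'
#' @param m A `proteomic_matrix` (log2) with a `cohort_id` metadata column.
#' @param panels A [marker_panel()] or list of them.
#' @param reference A `proteomic_matrix` (log2) of the same specimen type.
#' @param multiplier IQR fence multiplier for cohort flagging (default 1.5).
#' @param sd_bound,max_iterations Iterative-scaling parameters.
#' @return An object of class `contamination_report`: `sample_scores`
#'   (sample_id, cohort_id, panel_id, score), `cohort_medians`,
#'   `thresholds` (per panel), `flagged` (panel_id, cohort_id).
#' @export
contamination_scores <- function(m, panels, reference, multiplier = 1.5,
                                 sd_bound = 4, max_iterations = 50) {
  if (inherits(panels, "marker_panel")) panels <- list(panels)
  abort_if(length(panels) == 0, "no panels supplied")
  spec_m <- unique(m$metadata$specimen)
  spec_r <- unique(reference$metadata$specimen)
  abort_if(length(spec_m) == 1 && length(spec_r) == 1 && spec_m != spec_r,
           "matrix and reference specimen types differ (%s vs %s)",
           spec_m, spec_r)
  abort_if(!"cohort_id" %in% names(m$metadata),
           "metadata lacks a cohort_id column")

  scores <- list(); medians <- list(); flagged <- list(); thresholds <- list()
  for (panel in panels) {
    prot <- intersect(panel$protein_ids,
                      intersect(protein_ids(m), protein_ids(reference)))
    abort_if(length(prot) == 0,
             "panel '%s' has no proteins in common with the matrices",
             panel$panel_id)
    ref_sub <- subset_matrix(reference, proteins = prot)
    fit <- iterative_scale_fit(ref_sub, sd_bound = sd_bound,
                               max_iterations = max_iterations)
    z_m <- iterative_scale_apply(subset_matrix(m, proteins = prot), fit)
    z_ref <- iterative_scale_apply(ref_sub, fit)
    s_m <- rowMeans(z_m$values)
    s_ref <- rowMeans(z_ref$values)
    thr <- iqr_bounds(s_ref, multiplier = multiplier)$upper
    med <- tapply(s_m, m$metadata$cohort_id, stats::median)
    scores[[panel$panel_id]] <- data.frame(
      sample_id = sample_ids(m),
      cohort_id = as.character(m$metadata$cohort_id),
      panel_id = panel$panel_id, score = s_m,
      stringsAsFactors = FALSE)
    medians[[panel$panel_id]] <- data.frame(
      panel_id = panel$panel_id, cohort_id = names(med),
      median_score = as.numeric(med), stringsAsFactors = FALSE)
    thresholds[[panel$panel_id]] <- thr
    hit <- names(med)[med > thr]
    if (length(hit) > 0) {
      flagged[[panel$panel_id]] <- data.frame(
        panel_id = panel$panel_id, cohort_id = hit, stringsAsFactors = FALSE)
    }
  }
  structure(list(sample_scores = do.call(rbind, unname(scores)),
                 cohort_medians = do.call(rbind, unname(medians)),
                 thresholds = unlist(thresholds),
                 flagged = if (length(flagged) > 0)
                   do.call(rbind, unname(flagged))
                 else data.frame(panel_id = character(),
                                 cohort_id = character())),
            class = "contamination_report")
}

#' @export
print.contamination_report <- function(x, ...) {
  cat("contamination_report\n")
  print(x$cohort_medians)
  if (nrow(x$flagged) > 0) {
    cat("flagged:\n"); print(x$flagged)
  } else cat("no cohort flagged\n")
  invisible(x)
}

#' Generalizability QC: per-protein median concordance with a reference set
#'
#' Scaling factors fitted on a paired cohort transfer to other measurements
#' only if that cohort is representative of them. This check compares
#' per-protein medians (log2) between a study cohort and an external
#' reference of the same specimen type: the distribution of median
#' differences is screened with the IQR fence (proteins outside the fences
#' form the outlier set), and Pearson / Spearman correlations of the two
#' median vectors are reported. The verdict is `"flag"` when the outlier
#' tail is large (fraction above `tail_fraction`) or the median vectors
#' correlate poorly (Spearman below `spearman_floor`); a pure global offset
#' shifts all differences equally, flags no individual protein, and is
#' reported as a systematic-offset note instead.
#'
#' @param cohort,reference `proteomic_matrix` objects (log2) sharing >= 50
#'   proteins.
#' @param multiplier IQR fence multiplier (default 1.5; use a stricter fence
#'   such as 3 when the goal is to identify individual incompatible proteins
#'   rather than conservative screening).
#' @param tail_fraction Outlier-fraction threshold for flagging (default 0.05).
#' @param spearman_floor Minimum acceptable Spearman correlation of the
#'   median vectors (default 0.8).
#' @return An object of class `concordance_check`: `median_diff` (data.frame
#'   protein_id, cohort_median, reference_median, diff, outlier), `bounds`,
#'   `pearson_r`, `spearman_r`, `outlier_proteins`, `systematic_offset`,
#'   `verdict` (`"pass"` or `"flag"`), `notes`.
#' @export
generalizability_qc <- function(cohort, reference, multiplier = 1.5,
                                tail_fraction = 0.05, spearman_floor = 0.8) {
  abort_if(cohort$scale != "log2" || reference$scale != "log2",
           "generalizability QC expects log2-scale matrices")
  prot <- intersect(protein_ids(cohort), protein_ids(reference))
  abort_if(length(prot) == 0, "no shared proteins")
  abort_if(length(prot) < 50,
           "generalizability QC needs >= 50 shared proteins (got %d)",
           length(prot))
  med_c <- apply(cohort$values[, prot, drop = FALSE], 2L, stats::median)
  med_r <- apply(reference$values[, prot, drop = FALSE], 2L, stats::median)
  diff <- med_c - med_r
  bounds <- iqr_bounds(diff, multiplier = multiplier)
  out <- is_outlier(bounds, diff)
  pearson_r <- stats::cor(med_c, med_r)
  spearman_r <- stats::cor(med_c, med_r, method = "spearman")
  offset <- stats::median(diff)
  notes <- character()
  if (abs(offset) > 0.1) {
    notes <- c(notes, sprintf("systematic offset of %+.3f log2 units", offset))
  }
  verdict <- if (mean(out) > tail_fraction || spearman_r < spearman_floor)
    "flag" else "pass"
  structure(list(median_diff = data.frame(protein_id = prot,
                                          cohort_median = med_c,
                                          reference_median = med_r,
                                          diff = diff, outlier = out,
                                          row.names = NULL,
                                          stringsAsFactors = FALSE),
                 bounds = bounds,
                 pearson_r = pearson_r, spearman_r = spearman_r,
                 outlier_proteins = prot[out],
                 outlier_fraction = mean(out),
                 systematic_offset = offset,
                 verdict = verdict, notes = notes),
            class = "concordance_check")
}

#' @export
print.concordance_check <- function(x, ...) {
  cat(sprintf(paste0("concordance_check: %s (pearson %.3f, spearman %.3f, ",
                     "outliers %d/%d)\n"),
              x$verdict, x$pearson_r, x$spearman_r,
              length(x$outlier_proteins), nrow(x$median_diff)))
  for (n in x$notes) cat(" note:", n, "\n")
  invisible(x)
}
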