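# Per-protein serum-to-plasma linear scaling factors: ordinary least
# squares of plasma on serum in log2 space, one (slope, intercept) per
# protein, with cross-validated and negative-control variants, the scaling
# transform itself, and cross-cohort factor-set comparison.

#' Fit per-protein serum-to-plasma scaling factors
#'
#' For each protein, ordinary least squares of plasma log2(RFU) (response)
#' on serum log2(RFU) (predictor) across pairs, minimizing the residual sum
#' of squares with no regularization. The closed-form solution is used:
#' slope = cov(serum, plasma) / var(serum), intercept = mean(plasma) -
#' slope * mean(serum). Alongside the fit, the per-protein Spearman
#' concordance screen (r, two-sided p, BH q) is computed so the factor
#' table matches the published supplementary-table shape. Proteins with
#' zero serum variance cannot be fitted and are skipped with a flag, never
#' silently zero-filled.
#'
#' @param pd A `paired_dataset` on the log2 scale with >= 3 pairs.
#' @param provenance Optional string recorded on the result (e.g. cohort id
#'   and fit mode).
#' @return An object of class `scaling_factor_set` (a data.frame): columns
#'   protein_id, slope, intercept, n_pairs, pearson_r, spearman_r, p, q,
#'   residual_sd. Skipped proteins are listed in attribute `"skipped"`;
#'   `provenance` is stored as an attribute.
#' @export
fit_scaling_factors <- function(pd, provenance = "full") {
  abort_if(pd$serum$scale != "log2" || pd$plasma$scale != "log2",
           "factor fitting expects log2-scale data (log2_transform first)")
  n <- n_pairs(pd)
  abort_if(n < 3, "factor fitting needs >= 3 pairs (got %d)", n)
  s <- pd$serum$values
  p <- pd$plasma$values

  sbar <- colMeans(s)
  pbar <- colMeans(p)
  cs <- sweep(s, 2L, sbar, "-")
  cp <- sweep(p, 2L, pbar, "-")
  sxx <- colSums(cs^2)
  sxy <- colSums(cs * cp)
  syy <- colSums(cp^2)

  skipped <- sxx == 0
  slope <- sxy / sxx
  intercept <- pbar - slope * sbar
  rss <- pmax(syy - slope * sxy, 0)
  residual_sd <- sqrt(rss / (n - 2))
  pearson_r <- sxy / sqrt(sxx * syy)
  pearson_r[syy == 0 & !skipped] <- NA_real_

  spearman_r <- col_spearman(s, p)
  spearman_p <- spearman_pvalue(spearman_r, s, p, n = n)

  keep <- !skipped
  tab <- data.frame(
    protein_id = colnames(s)[keep],
    slope = slope[keep],
    intercept = intercept[keep],
    n_pairs = n,
    pearson_r = pearson_r[keep],
    spearman_r = spearman_r[keep],
    p = spearman_p[keep],
    q = NA_real_,
    residual_sd = residual_sd[keep],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  ok <- !is.na(tab$p)
  tab$q[ok] <- bh_adjust(tab$p[ok])
  if (any(skipped)) {
    warning(sprintf("%d protein(s) with zero serum variance skipped: %s",
                    sum(skipped), name_some(colnames(s)[skipped])),
            call. = FALSE)
  }
  attr(tab, "skipped") <- colnames(s)[skipped]
  attr(tab, "provenance") <- provenance
  class(tab) <- c("scaling_factor_set", "data.frame")
  tab
}

#' Apply scaling factors to a serum matrix
#'
#' Transforms serum log2 measurements to their plasma equivalents protein
#' by protein: `scaled = raw * slope + intercept`. Proteins without a
#' fitted factor are handled per `policy`: `"error"` (default) stops naming
#' them, `"drop"` removes them from the output, `"passthrough"` leaves them
#' unscaled.
#'
#' @param serum A `proteomic_matrix` on the log2 scale.
#' @param factors A `scaling_factor_set`.
#' @param policy One of `"error"`, `"drop"`, `"passthrough"`.
#' @return A `proteomic_matrix` of scaled log2 values.
#' @export
apply_scaling <- function(serum, factors,
                          policy = c("error", "drop", "passthrough")) {
  policy <- match.arg(policy)
  abort_if(serum$scale != "log2",
           "apply_scaling expects log2-scale input (log2_transform first)")
  prot <- protein_ids(serum)
  idx <- match(prot, factors$protein_id)
  missing <- prot[is.na(idx)]
  if (length(missing) > 0) {
    if (policy == "error") {
      stop(sprintf("no scaling factor for protein(s): %s",
                   name_some(missing)), call. = FALSE)
    }
    if (policy == "drop") {
      serum <- subset_matrix(serum, proteins = setdiff(prot, missing))
      prot <- protein_ids(serum)
      idx <- match(prot, factors$protein_id)
    }
  }
  slope <- ifelse(is.na(idx), 1, factors$slope[idx])
  intercept <- ifelse(is.na(idx), 0, factors$intercept[idx])
  v <- sweep(sweep(serum$values, 2L, slope, "*"), 2L, intercept, "+")
  proteomic_matrix(v, serum$metadata, scale = "log2",
                   flagged_proteins = serum$flagged_proteins)
}

#' Cross-validated scaling factors with out-of-fold scaled serum
#'
#' When factors must be applied to the same cohort they were fitted on,
#' in-sample application would be optimistic; instead pairs are partitioned
#' into k folds at the patient level (all pairs of one patient fall in the
#' same fold, preventing leakage through repeated-timepoint samples),
#' factors are fitted on k-1 folds and applied to the held-out serum
#' samples, and the out-of-fold scaled rows are assembled so every pair is
#' scaled exactly once. Only proteins fitted in every fold appear in the
#' scaled matrix.
#'
#' @param pd A `paired_dataset` on the log2 scale.
#' @param k Number of folds (default 5); must satisfy 2 <= k <= number of
#'   patients.
#' @param seed Integer seed for the fold assignment.
#' @return List: `scaled_serum` (a `proteomic_matrix`, rows in pair order),
#'   `fold_factors` (list of `scaling_factor_set`), `fold_assignment`
#'   (data.frame pair index, patient_id, fold).
#' @export
fit_scaling_factors_cv <- function(pd, k = 5, seed = 1) {
  n <- n_pairs(pd)
  abort_if(k < 2, "k must be >= 2")
  abort_if(k > n, "k = %d exceeds the number of pairs (%d)", k, n)
  patients <- unique(pd$pairs$patient_id)
  abort_if(k > length(patients),
           "k = %d exceeds the number of patients (%d); folds are patient-grouped",
           k, length(patients))
  fold_of_patient <- with_seed(seed, {
    shuffled <- sample(patients)
    stats::setNames(rep_len(seq_len(k), length(shuffled)), shuffled)[patients]
  })
  fold <- unname(fold_of_patient[pd$pairs$patient_id])

  fold_factors <- vector("list", k)
  fitted_everywhere <- NULL
  scaled_rows <- vector("list", k)
  for (f in seq_len(k)) {
    train <- subset_pairs(pd, keep = fold != f)
    test_serum <- subset_matrix(pd$serum,
                                samples = pd$pairs$serum_sample_id[fold == f])
    fac <- suppressWarnings(
      fit_scaling_factors(train, provenance = sprintf("cv_fold %d", f)))
    fold_factors[[f]] <- fac
    fitted_everywhere <- if (is.null(fitted_everywhere)) fac$protein_id
      else intersect(fitted_everywhere, fac$protein_id)
    scaled_rows[[f]] <- apply_scaling(
      subset_matrix(test_serum, proteins = fac$protein_id), fac)
  }
  prot <- fitted_everywhere
  mats <- lapply(scaled_rows, function(m) m$values[, prot, drop = FALSE])
  all_vals <- do.call(rbind, mats)
  all_vals <- all_vals[match(pd$pairs$serum_sample_id, rownames(all_vals)), ,
                       drop = FALSE]
  scaled <- proteomic_matrix(all_vals, pd$serum$metadata, scale = "log2")
  list(scaled_serum = scaled,
       fold_factors = fold_factors,
       fold_assignment = data.frame(pair = seq_len(n),
                                    patient_id = pd$pairs$patient_id,
                                    fold = fold))
}

#' Mismatched-pair negative control
#'
#' Reassigns plasma samples to serum samples by a seeded derangement (a
#' permutation with no fixed point, so no original pairing survives by
#' chance), leaving the serum side and the sample multiset untouched.
#' Factors fitted on the mismatched set form the null expectation: slopes
#' centered near zero and intercepts near the per-protein plasma mean.
#'
#' @param pd A `paired_dataset` with >= 2 pairs.
#' @param seed Integer seed.
#' @return A `paired_dataset` with permuted plasma assignments; the
#'   permutation is stored in attribute `"permutation"`.
#' @export
mismatched_control <- function(pd, seed = 1) {
  n <- n_pairs(pd)
  abort_if(n < 2, "no derangement exists for %d pair(s)", n)
  perm <- with_seed(seed, {
    repeat {
      cand <- sample.int(n)
      if (!any(cand == seq_len(n))) break
    }
    cand
  })
  pairs <- pd$pairs
  pairs$plasma_sample_id <- pairs$plasma_sample_id[perm]
  out <- structure(
    list(serum = pd$serum,
         plasma = subset_matrix(pd$plasma, samples = pairs$plasma_sample_id),
         pairs = pairs,
         orphans = pd$orphans),
    class = "paired_dataset")
  attr(out, "permutation") <- perm
  out
}

#' Compare two scaling-factor sets
#'
#' Pearson correlations of slopes and of intercepts over the shared
#' proteins, plus (when present) the Spearman correlation of the two sets'
#' per-protein serum-plasma Spearman coefficients. High agreement across
#' independently fitted cohorts indicates the scaling relationships are
#' reproducible and the factors generalizable.
#'
#' @param a,b `scaling_factor_set` objects sharing >= 10 proteins.
#' @return An object of class `factor_set_comparison`: `n_shared`,
#'   `slope_r`, `intercept_r`, `concordance_spearman_r`.
#' @export
compare_factor_sets <- function(a, b) {
  shared <- intersect(a$protein_id, b$protein_id)
  abort_if(length(shared) < 10,
           "factor sets share %d protein(s); >= 10 required", length(shared))
  ia <- match(shared, a$protein_id)
  ib <- match(shared, b$protein_id)
  conc <- if (all(c("spearman_r") %in% names(a)) &&
              all(c("spearman_r") %in% names(b))) {
    stats::cor(a$spearman_r[ia], b$spearman_r[ib], method = "spearman",
               use = "complete.obs")
  } else NA_real_
  structure(list(n_shared = length(shared),
                 slope_r = stats::cor(a$slope[ia], b$slope[ib]),
                 intercept_r = stats::cor(a$intercept[ia], b$intercept[ib]),
                 concordance_spearman_r = conc),
            class = "factor_set_comparison")
}

#' @export
print.factor_set_comparison <- function(x, ...) {
  cat(sprintf(paste0("factor_set_comparison: %d shared proteins; slope r = ",
                     "%.3f, intercept r = %.3f\n"),
              x$n_shared, x$slope_r, x$intercept_r))
  invisible(x)
}
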