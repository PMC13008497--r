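# Bridging QC: does downstream biological signal survive the serum-to-
# plasma scaling? Quantified as agreement between predictions computed
# from plasma versus scaled serum, and as pair-level co-clustering.

#' Build a surrogate linear-logistic predictor
#'
#' A deterministic stand-in for a proprietary plasma-trained classifier,
#' used to exercise the bridging-validation machinery: a fixed-weight
#' standardized linear score passed through a logistic link. Positive
#' weights are drawn once from the seed (uniform on \[0.5, 1.5\], an
#' abundance-weighted risk score) and frozen; per-protein centers and
#' scales are frozen at construction, either from a reference (training)
#' matrix or supplied directly, so that systematic shifts in later input
#' — such as a biased scaling intercept — propagate into the predictions
#' instead of being silently re-normalized away.
#'
#' @param panel Character vector of required protein ids (non-empty).
#' @param weights_seed Integer seed for the weight draw.
#' @param reference Optional `proteomic_matrix` (log2) from which
#'   per-protein centers (means) and scales (sds) are frozen.
#' @param center,scale Optional named numeric vectors overriding the
#'   reference-derived (or unit) standardization.
#' @param gain Logistic steepness applied to the weighted mean score
#'   (default 2, giving probabilities spread over roughly 0.2-0.8 for
#'   typical standardized panels).
#' @return An object of class `surrogate_predictor`; apply it with
#'   [predict_probabilities()] or `predict()`.
#' @export
surrogate_predictor <- function(panel, weights_seed = 1, reference = NULL,
                                center = NULL, scale = NULL, gain = 2) {
  panel <- unique(as.character(panel))
  abort_if(length(panel) == 0, "predictor panel is empty")
  w <- with_seed(weights_seed, stats::runif(length(panel), 0.5, 1.5))
  names(w) <- panel
  if (!is.null(reference)) {
    miss <- setdiff(panel, protein_ids(reference))
    abort_if(length(miss) > 0,
             "reference lacks panel protein(s): %s", name_some(miss))
    ctr <- colMeans(reference$values[, panel, drop = FALSE])
    scl <- apply(reference$values[, panel, drop = FALSE], 2L, stats::sd)
    scl[scl == 0] <- 1
  } else {
    ctr <- stats::setNames(rep(0, length(panel)), panel)
    scl <- stats::setNames(rep(1, length(panel)), panel)
  }
  if (!is.null(center)) ctr[names(center)] <- center
  if (!is.null(scale)) scl[names(scale)] <- scale
  structure(list(panel = panel, weights = w, center = ctr, scale = scl,
                 gain = gain, weights_seed = weights_seed),
            class = "surrogate_predictor")
}

#' Probabilities from a surrogate predictor
#'
#' Deterministic given its input: standardizes the panel proteins with the
#' frozen center/scale, forms the weighted mean score, and maps it through
#' the logistic link. A sample equal to the frozen centers scores exactly
#' 0.5. Fails loudly on missing required proteins.
#'
#' @param predictor A [surrogate_predictor()].
#' @param m A `proteomic_matrix` on the log2 scale containing the panel.
#' @return Named numeric vector of probabilities in (0, 1), one per sample.
#' @export
predict_probabilities <- function(predictor, m) {
  abort_if(!inherits(predictor, "surrogate_predictor"),
           "predictor must be a surrogate_predictor")
  miss <- setdiff(predictor$panel, protein_ids(m))
  abort_if(length(miss) > 0,
           "input lacks required protein(s): %s", name_some(miss))
  x <- m$values[, predictor$panel, drop = FALSE]
  z <- sweep(sweep(x, 2L, predictor$center, "-"), 2L, predictor$scale, "/")
  score <- as.numeric(z %*% predictor$weights) / sum(predictor$weights)
  stats::setNames(stats::plogis(predictor$gain * score), sample_ids(m))
}

#' @export
predict.surrogate_predictor <- function(object, newdata, ...) {
  predict_probabilities(object, newdata)
}

#' Agreement between two prediction vectors
#'
#' The bridging-validation verdict for predictive modeling. Two complementary
#' coefficients are reported: agreement with the unity line,
#' `R2_unity = 1 - sum((y - x)^2) / sum((y - mean(y))^2)` with the plasma
#' predictions `y` as reference (penalizes any systematic bias; can be
#' negative), and agreement with the best-fit line, `r2_fitted` = squared
#' Pearson correlation (blind to affine bias; always in \[0, 1\] and never
#' below `R2_unity`, by least-squares optimality). A constant-bias shift
#' therefore leaves `r2_fitted` at 1 while dragging `R2_unity` down — the
#' signature of a contaminated factor-source cohort. Both vectors are also
#' dichotomized at `threshold` and the binary agreement is reported with a
#' two-sided Fisher exact p-value on the 2x2 concordance table.
#'
#' @param p_plasma Plasma-based probabilities in \[0, 1\] (the reference).
#' @param p_serum_scaled Scaled-serum-based probabilities, same length >= 5.
#' @param threshold Classification threshold (default 0.5).
#' @return An object of class `prediction_agreement`: `r2_unity`,
#'   `r2_fitted`, `class_agreement_pct`, `agreement_p`, `threshold`, `n`.
#' @export
prediction_agreement <- function(p_plasma, p_serum_scaled, threshold = 0.5) {
  abort_if(length(p_plasma) != length(p_serum_scaled),
           "prediction vectors differ in length")
  n <- length(p_plasma)
  abort_if(n < 5, "agreement needs >= 5 subjects (got %d)", n)
  abort_if(any(!is.finite(p_plasma)) || any(!is.finite(p_serum_scaled)),
           "predictions must be finite")
  abort_if(any(p_plasma < 0 | p_plasma > 1) ||
             any(p_serum_scaled < 0 | p_serum_scaled > 1),
           "predictions must lie in [0, 1]")
  ssy <- sum((p_plasma - mean(p_plasma))^2)
  abort_if(ssy == 0,
           "plasma predictions are constant; unity-line R2 is undefined")
  r2_unity <- 1 - sum((p_plasma - p_serum_scaled)^2) / ssy
  r <- stats::cor(p_plasma, p_serum_scaled)
  r2_fitted <- if (is.na(r)) NA_real_ else r^2
  cls_p <- p_plasma >= threshold
  cls_s <- p_serum_scaled >= threshold
  agree <- 100 * mean(cls_p == cls_s)
  tab <- table(factor(cls_p, c(FALSE, TRUE)), factor(cls_s, c(FALSE, TRUE)))
  pval <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(r2_unity = r2_unity, r2_fitted = r2_fitted,
                 class_agreement_pct = agree, agreement_p = pval,
                 threshold = threshold, n = n),
            class = "prediction_agreement")
}

#' @export
print.prediction_agreement <- function(x, ...) {
  cat(sprintf(paste0("prediction_agreement (n = %d): R2_unity = %.3f, ",
                     "r2_fitted = %.3f, class agreement = %.1f%% (p = %.3g)\n"),
              x$n, x$r2_unity, x$r2_fitted, x$class_agreement_pct,
              x$agreement_p))
  invisible(x)
}

#' Pair co-clustering after scaling
#'
#' The bridging-validation verdict for descriptive analyses: on the
#' combined serum+plasma set (z-scored per protein across the combination,
#' so residual specimen offsets remain visible), computes (i) the fraction
#' of pairs that are mutual cross-specimen nearest neighbors by Euclidean
#' distance, and (ii) a chance-corrected specimen-split score for the
#' 2-cluster Ward cut (`hclust` ward.D2): 1 when the cut reproduces the
#' specimen labels exactly, ~0 when the cut is unrelated to specimen.
#' Before scaling, specimen differences dominate and the split score is
#' high; after successful scaling pairs should co-cluster (high MNN
#' fraction, low split score).
#'
#' @param pd A `paired_dataset` (log2 or scaled log2) with >= 4 pairs.
#' @return An object of class `coclustering`: `mnn_fraction`,
#'   `specimen_split`, `cluster` (2-cluster assignment).
#' @export
pair_coclustering <- function(pd) {
  n <- n_pairs(pd)
  abort_if(n < 4, "co-clustering needs >= 4 pairs (got %d)", n)
  combined <- rbind(pd$serum$values, pd$plasma$values)
  rownames(combined) <- c(paste0("S:", pd$pairs$serum_sample_id),
                          paste0("P:", pd$pairs$plasma_sample_id))
  mu <- colMeans(combined)
  s <- apply(combined, 2L, stats::sd)
  s[s == 0] <- 1
  z <- sweep(sweep(combined, 2L, mu, "-"), 2L, s, "/")

  zs <- z[seq_len(n), , drop = FALSE]
  zp <- z[n + seq_len(n), , drop = FALSE]
  # cross-specimen squared distances, pairs x pairs
  d2 <- outer(rowSums(zs^2), rowSums(zp^2), "+") - 2 * tcrossprod(zs, zp)
  nn_sp <- apply(d2, 1L, which.min)   # for each serum, nearest plasma
  nn_ps <- apply(d2, 2L, which.min)   # for each plasma, nearest serum
  mutual <- vapply(seq_len(n), function(i)
    nn_sp[i] == i && nn_ps[i] == i, logical(1))

  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = 2)
  specimen <- rep(c("serum", "plasma"), each = n)
  acc <- mean((cl == 1) == (specimen == "serum"))
  split_score <- 2 * abs(acc - 0.5)

  structure(list(mnn_fraction = mean(mutual),
                 specimen_split = split_score,
                 cluster = cl),
            class = "coclustering")
}

#' @export
print.coclustering <- function(x, ...) {
  cat(sprintf("coclustering: MNN fraction = %.3f, specimen split = %.3f\n",
              x$mnn_fraction, x$specimen_split))
  invisible(x)
}
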