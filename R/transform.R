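# Scale conversions and the two normalization schemes, plus the shared
# IQR outlier machinery used by every QC step.

#' Log2-transform a raw RFU matrix
#'
#' RFU distributions are roughly log-normal, so all parametric steps of the
#' pipeline (regression, z-scores, PCA) operate on log2 values. No
#' pseudocount is added: RFUs are positive by construction and a
#' non-positive value indicates corrupt input.
#'
#' @param m A `proteomic_matrix` on the `raw_rfu` scale.
#' @return A `proteomic_matrix` on the `log2` scale.
#' @export
log2_transform <- function(m) {
  abort_if(m$scale != "raw_rfu", "matrix is already on the log2 scale")
  abort_if(any(m$values <= 0), "non-positive value present; cannot log2-transform")
  proteomic_matrix(log2(m$values), m$metadata, scale = "log2",
                   flagged_proteins = m$flagged_proteins)
}

#' Per-protein z-score standardization
#'
#' Centers and scales each protein column to mean 0 and unit standard
#' deviation (sample sd, n-1, by default). Zero-variance proteins are set to
#' zero and recorded in `flagged_proteins` rather than erroring: multiplexed
#' panels routinely contain saturated or dead analytes and the pipeline must
#' proceed past them.
#'
#' @param m A `proteomic_matrix` on the log2 scale with >= 2 samples.
#' @param sd_type `"sample"` (divisor n-1, default) or `"population"` (n).
#' @return A `proteomic_matrix` of z-scores (scale flag stays `log2`).
#' @export
zscore_per_protein <- function(m, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  abort_if(m$scale != "log2", "z-scoring expects log2-scale input")
  n <- nrow(m$values)
  abort_if(n < 2, "z-scoring needs >= 2 samples")
  mu <- colMeans(m$values)
  centered <- sweep(m$values, 2L, mu, "-")
  ss <- colSums(centered^2)
  s <- sqrt(ss / if (sd_type == "sample") (n - 1) else n)
  flat <- s == 0 | !is.finite(s)
  s[flat] <- 1
  z <- sweep(centered, 2L, s, "/")
  z[, flat] <- 0
  proteomic_matrix(z, m$metadata, scale = "log2",
                   flagged_proteins = union(m$flagged_proteins,
                                            colnames(z)[flat]))
}

#' Tukey-fence outlier bounds from quartiles
#'
#' Computes the first and third quartiles (linear interpolation between
#' order statistics, `stats::quantile` type 7 by default) and the lower /
#' upper outlier thresholds `Q1 - multiplier*(Q3-Q1)` and
#' `Q3 + multiplier*(Q3-Q1)`. The same rule is reused for pair-correlation
#' screening, plasma/serum ratio classification, cross-cohort median
#' concordance and contamination flagging.
#'
#' @param values Numeric vector of finite values.
#' @param multiplier Fence multiplier (default 1.5).
#' @param type Quantile interpolation type passed to [stats::quantile()].
#' @param min_n Minimum number of values required (default 4; a quartile
#'   from fewer points is not meaningful for screening).
#' @return An object of class `outlier_bounds`: list with `q1`, `q3`,
#'   `lower`, `upper`, `multiplier`.
#' @export
iqr_bounds <- function(values, multiplier = 1.5, type = 7, min_n = 4) {
  values <- as.numeric(values)
  abort_if(any(!is.finite(values)), "iqr_bounds requires finite values")
  abort_if(length(values) < min_n,
           "iqr_bounds needs >= %d values (got %d)", min_n, length(values))
  abort_if(multiplier < 0, "multiplier must be >= 0")
  q <- stats::quantile(values, c(0.25, 0.75), type = type, names = FALSE)
  iqr <- q[2] - q[1]
  structure(list(q1 = q[1], q3 = q[2],
                 lower = q[1] - multiplier * iqr,
                 upper = q[2] + multiplier * iqr,
                 multiplier = multiplier),
            class = "outlier_bounds")
}

#' @export
print.outlier_bounds <- function(x, ...) {
  cat(sprintf("outlier_bounds: Q1=%.4g Q3=%.4g -> [%.4g, %.4g] (multiplier %.2g)\n",
              x$q1, x$q3, x$lower, x$upper, x$multiplier))
  invisible(x)
}

#' Which values fall outside the fences?
#' @param bounds An `outlier_bounds` object.
#' @param x Numeric vector.
#' @return Logical vector, `TRUE` for values below `lower` or above `upper`.
#' @export
is_outlier <- function(bounds, x) x < bounds$lower | x > bounds$upper

# One column of the iterative-scaling loop. Returns center/scale of the
# final outlier-excluded distribution plus the excluded index set.
its_fit_col <- function(x, sd_bound, max_iterations) {
  inc <- rep(TRUE, length(x))
  mu <- s <- NA_real_
  for (it in seq_len(max_iterations)) {
    mu <- mean(x[inc])
    s <- stats::sd(x[inc])
    if (!is.finite(s) || s == 0) {
      return(list(center = mu, scale = NA_real_, excluded = !inc,
                  degenerate = TRUE))
    }
    z <- (x - mu) / s
    new_out <- inc & abs(z) > sd_bound
    if (!any(new_out)) break
    inc[new_out] <- FALSE
    if (!any(inc)) {
      return(list(center = NA_real_, scale = NA_real_, excluded = !inc,
                  degenerate = TRUE))
    }
  }
  list(center = mu, scale = s, excluded = !inc, degenerate = FALSE)
}

#' Fit iterative-scaling parameters per protein
#'
#' The fitting half of [iterative_scale()]: per protein, alternate z-score
#' standardization with exclusion of values beyond `sd_bound` standard
#' deviations until no new outliers appear (the excluded set grows
#' monotonically, so the loop terminates). Returns the center and scale of
#' the final, outlier-excluded ("modified") distribution, which can then be
#' applied to the same matrix (with imputation) or to new data such as
#' samples standardized against a reference cohort.
#'
#' @param m A `proteomic_matrix` on the log2 scale with >= 3 samples.
#' @param sd_bound Outlier threshold in sd units (default 4).
#' @param max_iterations Iteration cap guaranteeing termination under
#'   adversarial input (default 50).
#' @return List with numeric vectors `center` and `scale` (per protein),
#'   logical matrix `excluded`, and character vector `flagged` (proteins with
#'   a degenerate, zero-spread distribution).
#' @export
iterative_scale_fit <- function(m, sd_bound = 4, max_iterations = 50) {
  abort_if(m$scale != "log2", "iterative scaling expects log2-scale input")
  abort_if(nrow(m$values) < 3, "iterative scaling needs >= 3 samples")
  abort_if(sd_bound <= 0, "sd_bound must be positive")
  p <- ncol(m$values)
  center <- scale <- numeric(p)
  excluded <- matrix(FALSE, nrow(m$values), p, dimnames = dimnames(m$values))
  flagged <- logical(p)
  for (j in seq_len(p)) {
    fit <- its_fit_col(m$values[, j], sd_bound, max_iterations)
    center[j] <- fit$center
    scale[j] <- fit$scale
    excluded[, j] <- fit$excluded
    flagged[j] <- fit$degenerate
  }
  names(center) <- names(scale) <- colnames(m$values)
  list(center = center, scale = scale, excluded = excluded,
       flagged = colnames(m$values)[flagged],
       sd_bound = sd_bound)
}

#' Standardize a matrix against previously fitted iterative-scale parameters
#'
#' Applies `(x - center) / scale` per protein with no outlier imputation;
#' used to express new samples (e.g. a study cohort) in sd units of a
#' reference distribution. Proteins flagged degenerate in the fit are set to
#' zero and flagged.
#'
#' @param m A `proteomic_matrix` on the log2 scale.
#' @param fit Result of [iterative_scale_fit()] covering `m`'s proteins.
#' @return A `proteomic_matrix` of standardized values.
#' @export
iterative_scale_apply <- function(m, fit) {
  abort_if(m$scale != "log2", "expects log2-scale input")
  miss <- setdiff(protein_ids(m), names(fit$center))
  abort_if(length(miss) > 0,
           "fit lacks parameters for protein(s): %s", name_some(miss))
  ctr <- fit$center[protein_ids(m)]
  scl <- fit$scale[protein_ids(m)]
  bad <- !is.finite(scl) | scl == 0
  scl[bad] <- 1
  z <- sweep(sweep(m$values, 2L, ctr, "-"), 2L, scl, "/")
  z[, bad] <- 0
  proteomic_matrix(z, m$metadata, scale = "log2",
                   flagged_proteins = union(m$flagged_proteins,
                                            protein_ids(m)[bad]))
}

#' Iterative scaling: z-scores with outlier exclusion and imputation
#'
#' The pipeline's main normalization for skewed assay distributions. Per
#' protein: (i) z-score standardize; (ii) flag values beyond `sd_bound`
#' standard deviations; (iii) exclude flagged values and repeat until no new
#' outliers; (iv) report all values as z-scores of the final
#' outlier-excluded distribution, with excluded values imputed to exactly
#' `+sd_bound` (above the final mean) or `-sd_bound` (below it). Columns
#' whose values are all excluded or have zero spread are returned as zeros
#' and flagged.
#'
#' @inheritParams iterative_scale_fit
#' @return A `proteomic_matrix` of standardized values.
#' @export
iterative_scale <- function(m, sd_bound = 4, max_iterations = 50) {
  fit <- iterative_scale_fit(m, sd_bound = sd_bound,
                             max_iterations = max_iterations)
  out <- iterative_scale_apply(m, fit)
  z <- out$values
  imput <- fit$excluded & !(colnames(z)[col(z)] %in% fit$flagged)
  if (any(imput)) {
    z[imput] <- sign(z[imput]) * sd_bound
  }
  proteomic_matrix(z, m$metadata, scale = "log2",
                   flagged_proteins = out$flagged_proteins)
}

#' Robust scaling: center by median, scale by IQR
#'
#' The companion normalization used to check that findings do not depend on
#' outlier handling: per protein `(x - median) / IQR`, preserving extreme
#' values instead of imputing them. Zero-IQR proteins are zeroed and
#' flagged.
#'
#' @param m A `proteomic_matrix` on the log2 scale with >= 4 samples.
#' @param type Quantile interpolation type (see [iqr_bounds()]).
#' @return A `proteomic_matrix` of robust-scaled values.
#' @export
robust_scale <- function(m, type = 7) {
  abort_if(m$scale != "log2", "robust scaling expects log2-scale input")
  abort_if(nrow(m$values) < 4, "robust scaling needs >= 4 samples")
  med <- apply(m$values, 2L, stats::median)
  q <- apply(m$values, 2L, stats::quantile, probs = c(0.25, 0.75), type = type)
  iqr <- q[2, ] - q[1, ]
  flat <- iqr == 0
  iqr[flat] <- 1
  z <- sweep(sweep(m$values, 2L, med, "-"), 2L, iqr, "/")
  z[, flat] <- 0
  proteomic_matrix(z, m$metadata, scale = "log2",
                   flagged_proteins = union(m$flagged_proteins,
                                            colnames(z)[flat]))
}
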