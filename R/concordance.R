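# Per-protein serum-plasma agreement statistics, protein selection, ratio
# classification, marker-panel enrichment, and the PC-association
# diagnostic.

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (monotone-enforced, capped at 1) via
#' [stats::p.adjust()], with input validation: the pipeline treats p-values
#' outside \[0, 1\] as corrupt input rather than clamping them.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  abort_if(!is.numeric(p), "p must be numeric")
  bad <- !is.na(p) & (p < 0 | p > 1)
  abort_if(any(bad), "p-values outside [0, 1] at position(s): %s",
           name_some(which(bad)))
  stats::p.adjust(p, method = "BH")
}

#' Per-protein serum-plasma concordance screen
#'
#' For every protein, Pearson and Spearman correlations between serum and
#' plasma values across pairs, a two-sided Spearman p-value (exact
#' permutation null for n <= 9 pairs, t approximation otherwise), and a
#' Benjamini-Hochberg q-value across all proteins. Spearman is the primary
#' screen because rare concordant values far from the assay detection limit
#' inflate Pearson correlations for proteins that are otherwise compressed
#' near the floor; the difference `pearson_r - spearman_r` is reported per
#' protein together with a floor-distance statistic (median log2 value minus
#' the protein's 1st-percentile value) as a diagnostic of that pattern.
#' Zero-variance proteins get NA correlations and a flag.
#'
#' @param pd A `paired_dataset` on the log2 scale with >= 5 pairs.
#' @return An object of class `concordance_table` (a data.frame): columns
#'   protein_id, pearson_r, spearman_r, spearman_p, spearman_q, n_pairs,
#'   r_inflation, floor_distance, flagged.
#' @export
protein_concordance <- function(pd) {
  abort_if(pd$serum$scale != "log2", "concordance expects log2-scale data")
  n <- n_pairs(pd)
  abort_if(n < 5, "concordance needs >= 5 pairs (got %d)", n)
  s <- pd$serum$values
  p <- pd$plasma$values
  pearson_r <- col_pearson(s, p)
  spearman_r <- col_spearman(s, p)
  spearman_p <- spearman_pvalue(spearman_r, s, p, n = n)
  spearman_q <- rep(NA_real_, length(spearman_p))
  ok <- !is.na(spearman_p)
  spearman_q[ok] <- bh_adjust(spearman_p[ok])
  # distance of the bulk of the distribution from the observed floor, a
  # proxy for detection-limit compression (pooled over both specimens)
  pooled <- rbind(s, p)
  floor_distance <- apply(pooled, 2L, function(x)
    stats::median(x) - stats::quantile(x, 0.01, names = FALSE))
  tab <- data.frame(
    protein_id = colnames(s),
    pearson_r = pearson_r,
    spearman_r = spearman_r,
    spearman_p = spearman_p,
    spearman_q = spearman_q,
    n_pairs = n,
    r_inflation = pearson_r - spearman_r,
    floor_distance = floor_distance,
    flagged = is.na(pearson_r) | is.na(spearman_r),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  class(tab) <- c("concordance_table", "data.frame")
  tab
}

#' Select proteins eligible for cross-specimen bridging
#'
#' The minimum requirement is a significant Spearman correlation after
#' Benjamini-Hochberg adjustment (`q < q_threshold`); because at typical
#' pair counts the significance threshold corresponds to a weak correlation
#' (Spearman r around 0.3 at ~50 pairs), an optional correlation floor
#' raises the bar when downstream modeling demands stronger agreement.
#' Flagged (zero-variance) proteins are never selected.
#'
#' @param table A `concordance_table`.
#' @param q_threshold BH q cutoff (default 0.05).
#' @param r_floor Minimum Spearman correlation (default 0).
#' @return Character vector of selected protein ids.
#' @export
select_proteins <- function(table, q_threshold = 0.05, r_floor = 0) {
  keep <- !table$flagged &
    !is.na(table$spearman_q) & table$spearman_q < q_threshold &
    table$spearman_r >= r_floor
  table$protein_id[keep]
}

#' Plasma-to-serum ratio classification
#'
#' Per protein, the median over pairs of the raw-RFU ratio plasma/serum
#' (computed as `2^(plasma - serum)` when the dataset is on the log2 scale,
#' which is equivalent). The IQR fence is applied to the log2 of the median
#' ratios across proteins, so the two tails are treated symmetrically:
#' proteins above the upper fence are classified `high_plasma`
#' (clot-retained factors such as fibrinogen, with ratios up to ~100),
#' proteins below the lower fence `high_serum` (clot-released factors such
#' as thrombin, ratios down to ~0.01), and the remainder `central`. The
#' classification is invariant to multiplying both matrices by a common
#' positive constant.
#'
#' @param pd A `paired_dataset` (raw RFU or log2 scale).
#' @param multiplier IQR fence multiplier (default 1.5).
#' @return data.frame: protein_id, median_ratio, log2_ratio, ratio_class.
#' @export
ratio_classification <- function(pd, multiplier = 1.5) {
  if (pd$serum$scale == "log2") {
    lr <- pd$plasma$values - pd$serum$values
  } else {
    lr <- log2(pd$plasma$values) - log2(pd$serum$values)
  }
  log2_ratio <- apply(lr, 2L, stats::median)
  bounds <- iqr_bounds(log2_ratio, multiplier = multiplier)
  cls <- rep("central", length(log2_ratio))
  cls[log2_ratio > bounds$upper] <- "high_plasma"
  cls[log2_ratio < bounds$lower] <- "high_serum"
  out <- data.frame(protein_id = colnames(lr),
                    median_ratio = 2^log2_ratio,
                    log2_ratio = log2_ratio,
                    ratio_class = cls,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(out, "bounds") <- bounds
  out
}

#' Marker-panel enrichment of a protein selection
#'
#' Two-sided Fisher exact test on the 2x2 table (in/out selection x in/out
#' panel) for each user-supplied panel, with Benjamini-Hochberg adjustment
#' across panels; a panel is called enriched at `q < fdr`. Panels with no
#' member in the universe are skipped with a warning.
#'
#' @param selected Character vector of selected protein ids (subset of
#'   `universe`).
#' @param universe Character vector of all measured protein ids.
#' @param panels A [marker_panel()] or list of them.
#' @param fdr FDR threshold for the enriched call (default 0.1).
#' @return data.frame: panel_id, overlap, panel_size, selection_size,
#'   universe_size, odds_ratio, fisher_p, fisher_q, enriched.
#' @export
panel_enrichment <- function(selected, universe, panels, fdr = 0.1) {
  if (inherits(panels, "marker_panel")) panels <- list(panels)
  stray <- setdiff(selected, universe)
  abort_if(length(stray) > 0,
           "selected ids outside the universe: %s", name_some(stray))
  rows <- list()
  for (panel in panels) {
    in_univ <- intersect(panel$protein_ids, universe)
    if (length(in_univ) == 0) {
      warning(sprintf("panel '%s' has no members in the universe; skipped",
                      panel$panel_id), call. = FALSE)
      next
    }
    a <- length(intersect(selected, in_univ))
    b <- length(selected) - a
    c_ <- length(in_univ) - a
    d <- length(universe) - a - b - c_
    ft <- stats::fisher.test(matrix(c(a, b, c_, d), nrow = 2),
                             alternative = "two.sided")
    rows[[panel$panel_id]] <- data.frame(
      panel_id = panel$panel_id, overlap = a, panel_size = length(in_univ),
      selection_size = length(selected), universe_size = length(universe),
      odds_ratio = unname(ft$estimate), fisher_p = ft$p.value,
      stringsAsFactors = FALSE)
  }
  abort_if(length(rows) == 0, "no panel overlaps the universe")
  out <- do.call(rbind, unname(rows))
  out$fisher_q <- bh_adjust(out$fisher_p)
  out$enriched <- out$fisher_q < fdr
  rownames(out) <- NULL
  out
}

#' Association of principal components with a sample covariate
#'
#' Diagnoses which sources of variation dominate a dataset: principal
#' components of the (optionally per-protein z-scored) matrix are computed,
#' and each component's scores are tested for association with a categorical
#' covariate by a rank test (Mann-Whitney for 2 levels, Kruskal-Wallis for
#' more). On combined serum+plasma data the top component is expected to be
#' specimen-associated before normalization; after per-specimen iterative
#' scaling no top component should be.
#'
#' @param m A `proteomic_matrix` (log2).
#' @param labels Factor or character vector, one label per sample, >= 2
#'   levels.
#' @param n_components Number of leading PCs to test (default 20, capped at
#'   `min(n_samples - 1, n_proteins)`).
#' @param normalize `"zscore"` (default) or `"none"` (centering only).
#' @return data.frame: component, explained_variance, p; PC scores in
#'   attribute `"scores"`.
#' @export
pc_association <- function(m, labels, n_components = 20,
                           normalize = c("zscore", "none")) {
  normalize <- match.arg(normalize)
  labels <- factor(labels)
  abort_if(length(labels) != nrow(m$values),
           "one label per sample required")
  abort_if(nlevels(labels) < 2, "labels must have >= 2 levels")
  x <- if (normalize == "zscore") zscore_per_protein(m)$values else m$values
  n_components <- min(n_components, nrow(x) - 1L, ncol(x))
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = n_components)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  pvals <- vapply(seq_len(n_components), function(k) {
    sc <- pc$x[, k]
    if (nlevels(labels) == 2) {
      split_sc <- split(sc, labels)
      suppressWarnings(
        stats::wilcox.test(split_sc[[1]], split_sc[[2]])$p.value)
    } else {
      stats::kruskal.test(sc, labels)$p.value
    }
  }, numeric(1))
  out <- data.frame(component = seq_len(n_components),
                    explained_variance = ev[seq_len(n_components)],
                    p = pvals)
  attr(out, "scores") <- pc$x
  out
}
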