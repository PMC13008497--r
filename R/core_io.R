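# Domain containers and delimited-text I/O.
#
# A proteomic_matrix is the object every transform acts on: a complete
# (no missing cells) samples x proteins numeric matrix in either raw RFU
# (relative fluorescence units, strictly positive) or log2(RFU), plus a
# per-sample metadata table. A paired_dataset aligns a serum and a plasma
# matrix row-by-row on (patient_id, timepoint) keys.

METADATA_REQUIRED <- c("sample_id", "patient_id", "cohort_id", "specimen",
                       "timepoint")

#' Construct a proteomic measurement matrix
#'
#' Bundles a samples-by-proteins numeric matrix with per-sample metadata and
#' a scale flag. All downstream operations (transforms, QC, concordance,
#' scaling) take and return this container. Construction validates the
#' invariants of the assay data model: no missing cells, unique sample and
#' protein identifiers, strictly positive values on the raw RFU scale, and a
#' metadata row for every sample.
#'
#' @param values Numeric matrix, samples as rows (rownames = sample ids),
#'   proteins as columns (colnames = analyte ids).
#' @param metadata data.frame with at least columns `sample_id` and
#'   `specimen` (`"serum"` or `"plasma"`); rows are matched to `values` by
#'   `sample_id`. Optional columns used elsewhere: `patient_id`, `cohort_id`,
#'   `timepoint`, `norm_scale_factor`, `prep_protocol`.
#' @param scale `"raw_rfu"` or `"log2"`.
#' @param flagged_proteins Character vector of protein ids flagged by a
#'   transform (e.g. zero variance); carried along, never silently dropped.
#' @return An object of class `proteomic_matrix`: a list with elements
#'   `values`, `metadata`, `scale`, `flagged_proteins`.
#' @export
proteomic_matrix <- function(values, metadata,
                             scale = c("raw_rfu", "log2"),
                             flagged_proteins = character()) {
  scale <- match.arg(scale)
  abort_if(!is.matrix(values) || !is.numeric(values),
           "`values` must be a numeric matrix (samples x proteins)")
  abort_if(is.null(rownames(values)) || is.null(colnames(values)),
           "`values` must carry sample ids as rownames and protein ids as colnames")
  sample_ids <- rownames(values)
  protein_ids <- colnames(values)
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  abort_if(length(dup_s) > 0, "duplicate sample ids: %s", name_some(dup_s))
  dup_p <- unique(protein_ids[duplicated(protein_ids)])
  abort_if(length(dup_p) > 0, "duplicate protein ids: %s", name_some(dup_p))

  bad <- which(!is.finite(values), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    offenders <- sprintf("(%s, %s)", sample_ids[bad[, 1]], protein_ids[bad[, 2]])
    stop(sprintf("matrix has %d missing/non-finite cell(s): %s",
                 nrow(bad), name_some(offenders)), call. = FALSE)
  }
  if (scale == "raw_rfu" && any(values <= 0)) {
    bad <- which(values <= 0, arr.ind = TRUE)
    offenders <- sprintf("(%s, %s)", sample_ids[bad[, 1]], protein_ids[bad[, 2]])
    stop(sprintf("raw RFU values must be strictly positive; offending cell(s): %s",
                 name_some(offenders)), call. = FALSE)
  }

  abort_if(!is.data.frame(metadata) || !"sample_id" %in% names(metadata),
           "`metadata` must be a data.frame with a `sample_id` column")
  abort_if(!"specimen" %in% names(metadata),
           "`metadata` must carry a `specimen` column (serum|plasma)")
  metadata$sample_id <- as.character(metadata$sample_id)
  missing_md <- setdiff(sample_ids, metadata$sample_id)
  abort_if(length(missing_md) > 0,
           "samples without metadata: %s", name_some(missing_md))
  abort_if(anyDuplicated(metadata$sample_id) > 0,
           "duplicate sample_id rows in metadata")
  metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  rownames(metadata) <- NULL
  bad_spec <- setdiff(unique(metadata$specimen), c("serum", "plasma"))
  abort_if(length(bad_spec) > 0,
           "specimen must be 'serum' or 'plasma'; found: %s", name_some(bad_spec))
  if ("norm_scale_factor" %in% names(metadata)) {
    nsf <- metadata$norm_scale_factor
    abort_if(any(!is.na(nsf) & nsf <= 0),
             "norm_scale_factor must be positive where present")
  }

  structure(
    list(values = values, metadata = metadata, scale = scale,
         flagged_proteins = as.character(flagged_proteins)),
    class = "proteomic_matrix"
  )
}

#' @export
print.proteomic_matrix <- function(x, ...) {
  cat(sprintf("proteomic_matrix: %d samples x %d proteins [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  spec <- table(x$metadata$specimen)
  cat("  specimen:", paste(sprintf("%s=%d", names(spec), spec), collapse = ", "),
      "\n")
  if (length(x$flagged_proteins) > 0)
    cat(sprintf("  flagged proteins: %d\n", length(x$flagged_proteins)))
  invisible(x)
}

#' @export
dim.proteomic_matrix <- function(x) dim(x$values)

#' Sample and protein identifiers of a proteomic matrix
#' @param m A `proteomic_matrix`.
#' @return Character vector of identifiers.
#' @export
sample_ids <- function(m) rownames(m$values)

#' @rdname sample_ids
#' @export
protein_ids <- function(m) colnames(m$values)

#' Subset a proteomic matrix by samples or proteins
#'
#' @param m A `proteomic_matrix`.
#' @param samples,proteins Character ids or logical/integer index; `NULL`
#'   keeps all.
#' @return A `proteomic_matrix`.
#' @export
subset_matrix <- function(m, samples = NULL, proteins = NULL) {
  v <- m$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(proteins)) v <- v[, proteins, drop = FALSE]
  proteomic_matrix(v, m$metadata, scale = m$scale,
                   flagged_proteins = intersect(m$flagged_proteins, colnames(v)))
}

#' Read a wide proteomic matrix and its sample metadata
#'
#' Reads a delimited text file whose first column is `sample_id` and whose
#' remaining columns are protein analyte ids, plus a metadata table keyed by
#' `sample_id`. Any missing cell, duplicate identifier, non-positive raw RFU
#' value or sample without a metadata row is a hard error naming the
#' offenders: the data model assumes complete matrices, so silent repair is
#' never attempted.
#'
#' @param path Path to the matrix file (TSV by default).
#' @param metadata_path Path to the metadata table; must contain columns
#'   `r paste(METADATA_REQUIRED, collapse = ", ")`.
#' @param value_scale `"raw_rfu"` or `"log2"`.
#' @param sep Field separator (default tab; use `","` for CSV).
#' @return A validated [proteomic_matrix()].
#' @export
read_matrix <- function(path, metadata_path,
                        value_scale = c("raw_rfu", "log2"), sep = "\t") {
  value_scale <- match.arg(value_scale)
  raw <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                           colClasses = "character", na.strings = c("NA", ""))
  abort_if(ncol(raw) < 2, "matrix file must have sample_id plus >=1 protein column")
  ids <- raw[[1]]
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    offenders <- sprintf("(%s, %s)", ids[bad[, 1]], colnames(num)[bad[, 2]])
    stop(sprintf("missing or non-numeric cell(s) in %s: %s",
                 path, name_some(offenders)), call. = FALSE)
  }

  md <- utils::read.table(metadata_path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  miss_cols <- setdiff(METADATA_REQUIRED, names(md))
  abort_if(length(miss_cols) > 0,
           "metadata is missing required column(s): %s", name_some(miss_cols))
  proteomic_matrix(num, md, scale = value_scale)
}

#' Write a proteomic matrix (and optionally its metadata) to delimited text
#'
#' @param m A `proteomic_matrix`.
#' @param path Output path for the wide matrix.
#' @param metadata_path Optional output path for the metadata table.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, metadata_path = NULL, sep = "\t") {
  df <- data.frame(sample_id = sample_ids(m), m$values, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  if (!is.null(metadata_path)) {
    utils::write.table(m$metadata, metadata_path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Align serum and plasma matrices into a paired dataset
#'
#' Pairs are formed on the exact `(patient_id, timepoint)` key; a patient may
#' contribute several timepoints, each its own pair. Proteins are intersected
#' and placed in identical order in both matrices, and the rows of both
#' matrices are reordered so that row i of serum and row i of plasma belong
#' to pair i. Samples with no mate are reported in the `orphans` element,
#' never silently dropped.
#'
#' @param serum,plasma `proteomic_matrix` objects on the same scale, with
#'   metadata columns `patient_id` and `timepoint`.
#' @return An object of class `paired_dataset`: list with `serum`, `plasma`
#'   (row-aligned), `pairs` (data.frame with patient_id, timepoint,
#'   serum_sample_id, plasma_sample_id) and `orphans`.
#' @export
build_pairs <- function(serum, plasma) {
  for (m in list(serum, plasma)) {
    abort_if(!inherits(m, "proteomic_matrix"), "inputs must be proteomic_matrix")
    abort_if(!all(c("patient_id", "timepoint") %in% names(m$metadata)),
             "metadata must carry patient_id and timepoint for pairing")
  }
  abort_if(!identical(serum$scale, plasma$scale),
           "serum and plasma matrices must be on the same scale (%s vs %s)",
           serum$scale, plasma$scale)

  key <- function(md) paste(md$patient_id, md$timepoint, sep = "\r")
  ks <- key(serum$metadata); kp <- key(plasma$metadata)
  dup_s <- unique(ks[duplicated(ks)]); dup_p <- unique(kp[duplicated(kp)])
  abort_if(length(dup_s) > 0 || length(dup_p) > 0,
           "ambiguous pairing key (duplicate patient/timepoint): %s",
           name_some(gsub("\r", "/", c(dup_s, dup_p))))

  shared_key <- intersect(ks, kp)
  abort_if(length(shared_key) == 0, "no (patient_id, timepoint) keys in common")
  is_ <- match(shared_key, ks); ip <- match(shared_key, kp)
  pairs <- data.frame(
    patient_id = as.character(serum$metadata$patient_id[is_]),
    timepoint = as.character(serum$metadata$timepoint[is_]),
    serum_sample_id = sample_ids(serum)[is_],
    plasma_sample_id = sample_ids(plasma)[ip],
    stringsAsFactors = FALSE
  )
  orphans <- data.frame(
    sample_id = c(sample_ids(serum)[!ks %in% shared_key],
                  sample_ids(plasma)[!kp %in% shared_key]),
    specimen = c(rep("serum", sum(!ks %in% shared_key)),
                 rep("plasma", sum(!kp %in% shared_key))),
    stringsAsFactors = FALSE
  )
  if (nrow(orphans) > 0) {
    warning(sprintf("%d unpaired sample(s) reported in $orphans: %s",
                    nrow(orphans), name_some(orphans$sample_id)), call. = FALSE)
  }

  prot <- intersect(protein_ids(serum), protein_ids(plasma))
  abort_if(length(prot) == 0, "serum and plasma share no proteins")

  structure(
    list(
      serum = subset_matrix(serum, samples = pairs$serum_sample_id,
                            proteins = prot),
      plasma = subset_matrix(plasma, samples = pairs$plasma_sample_id,
                             proteins = prot),
      pairs = pairs,
      orphans = orphans
    ),
    class = "paired_dataset"
  )
}

#' @export
print.paired_dataset <- function(x, ...) {
  cat(sprintf("paired_dataset: %d pairs x %d proteins [%s]\n",
              nrow(x$pairs), ncol(x$serum$values), x$serum$scale))
  if (nrow(x$orphans) > 0)
    cat(sprintf("  orphans: %d\n", nrow(x$orphans)))
  invisible(x)
}

#' Number of pairs in a paired dataset
#' @param pd A `paired_dataset`.
#' @return Integer.
#' @export
n_pairs <- function(pd) nrow(pd$pairs)

#' Subset a paired dataset by pairs or proteins
#' @param pd A `paired_dataset`.
#' @param keep Logical or integer index over pairs; `NULL` keeps all.
#' @param proteins Protein ids or index; `NULL` keeps all.
#' @return A `paired_dataset`.
#' @export
subset_pairs <- function(pd, keep = NULL, proteins = NULL) {
  if (is.null(keep)) keep <- seq_len(n_pairs(pd))
  pairs <- pd$pairs[keep, , drop = FALSE]
  rownames(pairs) <- NULL
  structure(
    list(
      serum = subset_matrix(pd$serum, samples = pairs$serum_sample_id,
                            proteins = proteins),
      plasma = subset_matrix(pd$plasma, samples = pairs$plasma_sample_id,
                             proteins = proteins),
      pairs = pairs,
      orphans = pd$orphans
    ),
    class = "paired_dataset"
  )
}

#' Define a marker panel
#'
#' A named set of protein ids with a direction of interpretation, e.g. the
#' platelet / erythrocyte contamination panels or the plasma-retained and
#' serum-accumulated coagulation panels used for sample-quality scoring and
#' enrichment.
#'
#' @param panel_id Panel name.
#' @param protein_ids Character vector of analyte ids (non-empty).
#' @param direction One of `"contamination"`, `"plasma_retained"`,
#'   `"serum_accumulated"`.
#' @return An object of class `marker_panel`.
#' @export
marker_panel <- function(panel_id, protein_ids,
                         direction = c("contamination", "plasma_retained",
                                       "serum_accumulated")) {
  direction <- match.arg(direction)
  protein_ids <- unique(as.character(protein_ids))
  abort_if(length(protein_ids) == 0, "panel '%s' is empty", panel_id)
  structure(list(panel_id = panel_id, protein_ids = protein_ids,
                 direction = direction),
            class = "marker_panel")
}

#' Read marker panels from plain text
#'
#' Accepts either a one-id-per-line file (single panel, named from the file)
#' or a two-column TSV `protein_id<TAB>panel_id` defining several panels.
#'
#' @param path File path.
#' @param direction Direction applied to all panels read.
#' @return A list of [marker_panel()] objects.
#' @export
read_panels <- function(path, direction = "contamination") {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  abort_if(length(lines) == 0, "panel file %s is empty", path)
  if (any(grepl("\t", lines))) {
    df <- utils::read.table(path, header = FALSE, sep = "\t",
                            col.names = c("protein_id", "panel_id"),
                            stringsAsFactors = FALSE)
    sp <- split(df$protein_id, df$panel_id)
    return(unname(Map(function(nm, ids) marker_panel(nm, ids, direction),
                      names(sp), sp)))
  }
  nm <- sub("\\.[^.]*$", "", basename(path))
  list(marker_panel(nm, trimws(lines), direction))
}

#' Write a scaling-factor set as a TSV table
#'
#' Columns: protein_id, slope, intercept, n_pairs, pearson_r, spearman_r, p,
#' q. Floats are written with 9 significant digits. The matching reader is
#' [read_factor_table()].
#'
#' @param factors A `scaling_factor_set` (see [fit_scaling_factors()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_factor_table <- function(factors, path) {
  cols <- c("protein_id", "slope", "intercept", "n_pairs", "pearson_r",
            "spearman_r", "p", "q")
  if (nrow(factors) == 0) {
    warning("writing empty factor table (header only)", call. = FALSE)
    writeLines(paste(cols, collapse = "\t"), path)
    return(invisible(path))
  }
  df <- as.data.frame(factors)[, cols]
  num <- vapply(df, is.numeric, logical(1)) & names(df) != "n_pairs"
  df[num] <- lapply(df[num], function(x) formatC(x, digits = 9, format = "g"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_factor_table
#' @export
read_factor_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  class(df) <- c("scaling_factor_set", "data.frame")
  df
}
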