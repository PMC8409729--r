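#' Normalise a feature table by a reference feature
#'
#' Divides every feature's area in each sample by the area of a spiked
#' internal-standard feature (e.g. sulfamethazine, [M+H]+ m/z 279.0910) in
#' that sample, removing per-sample injection and extraction scale.
#'
#' @param table A [feature_table()].
#' @param reference_feature_id Id of the reference feature; it must be
#'   strictly positive in every sample.
#' @return The normalised [feature_table()] (the reference feature becomes
#'   1 in every sample).
#' @export
normalize_by_reference <- function(table, reference_feature_id) {
  if (!reference_feature_id %in% table$meta$feature_id) {
    stop("reference feature '", reference_feature_id, "' not in table")
  }
  ref <- table$areas[reference_feature_id, ]
  bad <- colnames(table$areas)[ref <= 0]
  if (length(bad)) {
    stop("reference feature is zero or missing in sample(s): ",
         paste(bad, collapse = ", "))
  }
  table$areas <- sweep(table$areas, 2, ref, "/")
  table
}

#' Find a reference feature by m/z and retention-time window
#'
#' @param table A [feature_table()].
#' @param mz Target m/z (e.g. 279.0910 for sulfamethazine [M+H]+).
#' @param rt Target retention time in minutes, or `NA` to match on m/z only.
#' @param mz_tol m/z window half-width in Da (default 0.01).
#' @param rt_tol RT window half-width in minutes (default 0.2).
#' @return The matching feature id.
#' @export
find_reference_feature <- function(table, mz, rt = NA_real_, mz_tol = 0.01,
                                   rt_tol = 0.2) {
  hit <- abs(table$meta$mz - mz) <= mz_tol
  if (!is.na(rt)) hit <- hit & abs(table$meta$rt - rt) <= rt_tol
  ids <- table$meta$feature_id[hit]
  if (!length(ids)) stop("no feature within ", mz_tol, " Da of m/z ", mz)
  if (length(ids) > 1L) stop("ambiguous reference: ", paste(ids, collapse = ", "))
  ids
}

#' Cube-root transform of a feature table
#'
#' Elementwise x^(1/3), a variance-stabilising transform used to ease
#' comparison across features spanning orders of magnitude.
#'
#' @param table A [feature_table()].
#' @return The transformed [feature_table()].
#' @export
cube_root_transform <- function(table) {
  table$areas <- table$areas^(1 / 3)
  table
}

#' Remove constant and low-variability features
#'
#' First removes features with a single distinct value across all samples,
#' then (if `iqr_quantile` > 0) the lowest-IQR fraction of the remaining
#' features. The interquartile range is the standard detector of
#' near-constant variables in metabolomics preprocessing.
#'
#' @param table A [feature_table()].
#' @param iqr_quantile Fraction of remaining features to drop by lowest
#'   IQR, in \[0, 1) (default 0 = constants only).
#' @param keep Feature ids exempt from removal (e.g. the reference
#'   feature).
#' @return List with `table` (filtered [feature_table()]) and `report`
#'   (n_features_in, n_removed_constant, n_removed_iqr, n_features_out).
#' @export
drop_uninformative <- function(table, iqr_quantile = 0, keep = character(0)) {
  stopifnot(iqr_quantile >= 0, iqr_quantile < 1)
  n_in <- nrow(table$areas)
  distinct <- apply(table$areas, 1, function(x) length(unique(x)))
  const <- distinct <= 1L & !(rownames(table$areas) %in% keep)
  areas <- table$areas[!const, , drop = FALSE]
  n_iqr <- 0L
  if (iqr_quantile > 0 && nrow(areas)) {
    iqr <- apply(areas, 1, stats::IQR)
    n_iqr <- floor(iqr_quantile * nrow(areas))
    if (n_iqr > 0L) {
      ord <- order(iqr, rownames(areas)) # deterministic under IQR ties
      drop_ids <- setdiff(rownames(areas)[ord], keep)[seq_len(n_iqr)]
      areas <- areas[!rownames(areas) %in% drop_ids, , drop = FALSE]
    }
  }
  if (!nrow(areas)) stop("filtering would remove every feature")
  meta <- table$meta[table$meta$feature_id %in% rownames(areas), , drop = FALSE]
  list(
    table = feature_table(meta, areas[meta$feature_id, , drop = FALSE]),
    report = list(
      n_features_in = n_in,
      n_removed_constant = sum(const),
      n_removed_iqr = n_iqr,
      n_features_out = nrow(areas)
    )
  )
}

#' Standard preprocessing of a feature table
#'
#' Fixed order: constant-feature removal, optional IQR variability filter,
#' reference-feature normalisation, optional cube-root transform. The
#' reference feature is exempt from the filters and is re-identified after
#' normalisation in the report.
#'
#' @param table A [feature_table()].
#' @param reference_feature_id Internal-standard feature id.
#' @param iqr_quantile See [drop_uninformative()] (default 0).
#' @param cube_root Apply [cube_root_transform()] after normalisation
#'   (default `FALSE`; the proportionality score is computed on
#'   normalised, untransformed areas).
#' @return List with `table` and `report` (filter counts, reference id,
#'   transform applied).
#' @export
preprocess_table <- function(table, reference_feature_id, iqr_quantile = 0,
                             cube_root = FALSE) {
  filtered <- drop_uninformative(table, iqr_quantile, keep = reference_feature_id)
  out <- normalize_by_reference(filtered$table, reference_feature_id)
  if (cube_root) out <- cube_root_transform(out)
  report <- c(filtered$report, list(
    reference_feature_id = reference_feature_id,
    transform = if (cube_root) "cube_root" else "none"
  ))
  list(table = out, report = report)
}
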