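#' Build a catalog of chemical-transformation mass deltas
#'
#' Each entry maps a label (usually the formula of the gained/lost group)
#' to its exact monoisotopic mass delta. Entries are validated against
#' [monoisotopic_mass()].
#'
#' @param df data.frame with columns `label`, `formula` and optionally
#'   `description`.
#' @return data.frame with class `delta_catalog` and an added `delta`
#'   column (Da).
#' @export
delta_catalog <- function(df) {
  df <- as.data.frame(df)
  stopifnot(all(c("label", "formula") %in% names(df)))
  if (anyDuplicated(df$label)) stop("catalog labels must be unique")
  if (is.null(df$description)) df$description <- ""
  df$delta <- vapply(df$formula, function(f) monoisotopic_mass(parse_formula(f)), 0)
  structure(df[, c("label", "formula", "delta", "description")],
            class = c("delta_catalog", "data.frame"))
}

#' The default transformation catalog
#'
#' Ships the mass shifts most frequently observed between networked
#' features in decomposing plant material: hydrogenation/dehydrogenation
#' (H2), methylation chain steps (CH2, C2H4), oxygen gain/loss (O),
#' C2H4O, glycosylation (C6H10O5) and an amino-alcohol-type C8H21NO2 shift.
#'
#' @return A [delta_catalog()].
#' @export
default_delta_catalog <- function() {
  delta_catalog(data.frame(
    label = c("H2", "CH2", "O", "C2H4", "C2H4O", "C6H10O5", "C8H21NO2"),
    formula = c("H2", "CH2", "O", "C2H4", "C2H4O", "C6H10O5", "C8H21NO2"),
    description = c(
      "oxidation/reduction via loss or addition of H2",
      "methylation step",
      "gain or loss of oxygen",
      "two-carbon chain elongation",
      "acetaldehyde-equivalent shift",
      "glycosyl (sugar) moiety",
      "amino-alcohol-type shift"
    )
  ))
}

#' Read a transformation catalog from delimited text
#'
#' @param path CSV/TSV with header columns `label`, `formula`, optional
#'   `description`.
#' @param sep Field separator (default `,`).
#' @return A [delta_catalog()].
#' @export
read_delta_catalog <- function(path, sep = ",") {
  delta_catalog(utils::read.table(path, sep = sep, header = TRUE,
                                  stringsAsFactors = FALSE))
}

#' Absolute precursor mass difference of a network edge
#'
#' @param edge One row of a network edge table (or any list with
#'   `delta_mz`), or a numeric pair of precursor m/z values.
#' @return |delta m/z| in Da at full precision; round to 3 decimals for
#'   display.
#' @export
edge_delta <- function(edge) {
  if (is.numeric(edge) && length(edge) == 2L) return(abs(edge[1] - edge[2]))
  abs(edge$delta_mz)
}

#' Annotate an observed mass delta against a catalog
#'
#' @param observed Observed |delta m/z| in Da.
#' @param catalog A [delta_catalog()].
#' @param tol Maximum |observed - catalog delta| in Da (default 0.01).
#' @return Named list `label` (or `NA` when nothing is within `tol`) and
#'   `abs_error` in Da. Ties go to the smaller error, then the
#'   lexicographically smaller label.
#' @export
annotate_delta <- function(observed, catalog = default_delta_catalog(), tol = 0.01) {
  err <- abs(catalog$delta - observed)
  ok <- which(err <= tol)
  if (!length(ok)) return(list(label = NA_character_, abs_error = NA_real_))
  ord <- ok[order(err[ok], catalog$label[ok])]
  list(label = catalog$label[ord[1]], abs_error = err[ord[1]])
}

#' Annotate every edge of a network
#'
#' @param network A `molecular_network`.
#' @param catalog A [delta_catalog()].
#' @param tol Annotation tolerance in Da.
#' @return The edge table with added `observed_delta`, `annotation`
#'   (label or `NA`) and `annotation_error` columns.
#' @export
annotate_network_shifts <- function(network, catalog = default_delta_catalog(),
                                    tol = 0.01) {
  ed <- network$edges
  ed$observed_delta <- abs(ed$delta_mz)
  ann <- lapply(ed$observed_delta, annotate_delta, catalog = catalog, tol = tol)
  ed$annotation <- vapply(ann, function(a) a$label, "")
  ed$annotation_error <- vapply(ann, function(a) a$abs_error, 0)
  ed
}

#' Mass-shift frequency table per location pair
#'
#' Counts, for each location pair of the scoring scheme, how many network
#' edges have an absolute proportionality score above `score_cutoff`,
#' grouped by transformation annotation (unannotated edges pooled under
#' `"other"`). Each edge contributes at most once per pair.
#'
#' @param network A `molecular_network`.
#' @param scores Proportionality records from [score_network()]; every
#'   edge x pair combination of the scheme must be present.
#' @param score_cutoff Absolute-score threshold, exclusive (default 1).
#' @param catalog A [delta_catalog()].
#' @param tol Annotation tolerance in Da.
#' @return data.frame with one row per annotation label (rows sorted by
#'   label, `"other"` last) and one column per location pair in scheme
#'   order, holding counts.
#' @export
shift_frequency <- function(network, scores, score_cutoff = 1.0,
                            catalog = default_delta_catalog(), tol = 0.01) {
  ann <- annotate_network_shifts(network, catalog, tol)
  edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  ann$key <- edge_key(ann$id_a, ann$id_b)
  scores$key <- edge_key(scores$id_n, scores$id_m)
  missing <- setdiff(ann$key, scores$key)
  if (length(missing)) {
    stop("incomplete scoring: ", length(missing), " network edge(s) have no ",
         "proportionality record")
  }
  pairs <- unique(scores$pair)
  labels <- c(sort(catalog$label), "other")
  out <- matrix(0L, nrow = length(labels), ncol = length(pairs),
                dimnames = list(labels, pairs))
  hot <- scores[abs(scores$score) > score_cutoff, , drop = FALSE]
  if (nrow(hot)) {
    lab <- ann$annotation[match(hot$key, ann$key)]
    lab[is.na(lab)] <- "other"
    for (i in seq_len(nrow(hot))) {
      out[lab[i], hot$pair[i]] <- out[lab[i], hot$pair[i]] + 1L
    }
  }
  df <- data.frame(annotation = labels, out, check.names = FALSE,
                   row.names = NULL)
  df
}

#' Write a shift-frequency table in wide and long form
#'
#' @param freq Output of [shift_frequency()].
#' @param wide_path CSV path for the annotation x pair matrix.
#' @param long_path Optional CSV path for a long-format
#'   (annotation, pair, count) table convenient for plotting.
#' @return `freq`, invisibly.
#' @export
write_shift_frequency <- function(freq, wide_path, long_path = NULL) {
  utils::write.csv(freq, wide_path, row.names = FALSE)
  if (!is.null(long_path)) {
    pairs <- setdiff(names(freq), "annotation")
    long <- do.call(rbind, lapply(pairs, function(p) {
      data.frame(annotation = freq$annotation, pair = p, count = freq[[p]])
    }))
    utils::write.csv(long, long_path, row.names = FALSE)
  }
  invisible(freq)
}
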