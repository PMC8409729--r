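#' Location-pair schemes for proportionality scoring
#'
#' `chain` compares consecutive locations along the material flow
#' (L:A, A:B, B:C, C:D, D:TT, TT:TM, TM:TB); `leaves_vs_all` compares the
#' leaves against every other location (L:A ... L:TB).
#'
#' @param scheme `"chain"`, `"leaves_vs_all"`, or a two-column matrix /
#'   data.frame of custom (s1, s2) label pairs.
#' @param locations Ordered location vocabulary.
#' @return data.frame with columns `s1`, `s2`, `pair` (label "s1:s2").
#' @export
location_pairs <- function(scheme = c("chain", "leaves_vs_all"),
                           locations = garden_locations) {
  if (is.character(scheme) && length(scheme) == 1L) {
    scheme <- match.arg(scheme)
    df <- if (scheme == "chain") {
      data.frame(s1 = locations[-length(locations)], s2 = locations[-1])
    } else {
      data.frame(s1 = locations[1], s2 = locations[-1])
    }
  } else {
    df <- as.data.frame(scheme)
    names(df)[1:2] <- c("s1", "s2")
  }
  bad <- !(df$s1 %in% locations) | !(df$s2 %in% locations) | df$s1 == df$s2
  if (any(bad)) stop("invalid location pair(s): ",
                     paste(df$s1[bad], df$s2[bad], sep = ":", collapse = ", "))
  df$pair <- paste(df$s1, df$s2, sep = ":")
  df
}

#' Aggregate a feature's peak area over a location's replicate samples
#'
#' @param table A [feature_table()].
#' @param metadata A [sample_metadata()].
#' @param feature_id Feature to aggregate.
#' @param location Location label.
#' @param method `"mean"` (default), `"median"` or `"sum"`.
#' @return Aggregated peak area.
#' @export
aggregate_location <- function(table, metadata, feature_id, location,
                               method = c("mean", "median", "sum")) {
  method <- match.arg(method)
  if (!feature_id %in% table$meta$feature_id) {
    stop("feature '", feature_id, "' not in table")
  }
  samples <- metadata$sample_id[metadata$location == location]
  samples <- intersect(samples, colnames(table$areas))
  if (!length(samples)) stop("location '", location, "' has no samples")
  vals <- table$areas[feature_id, samples]
  switch(method, mean = mean(vals), median = stats::median(vals), sum = sum(vals))
}

# location x feature matrix of aggregated areas, one call instead of
# per-feature aggregate_location when scoring whole networks
aggregate_all <- function(table, metadata, locations, method = "mean") {
  fun <- switch(method, mean = mean, median = stats::median, sum = sum)
  out <- matrix(NA_real_, nrow = nrow(table$areas), ncol = length(locations),
                dimnames = list(rownames(table$areas), locations))
  for (loc in locations) {
    samples <- intersect(metadata$sample_id[metadata$location == loc],
                         colnames(table$areas))
    if (!length(samples)) stop("location '", loc, "' has no samples")
    out[, loc] <- apply(table$areas[, samples, drop = FALSE], 1, fun)
  }
  out # features x locations
}

#' Chemical proportionality score
#'
#' The log ratio-of-ratios between two chemically related features N and M
#' in two sample locations S1 and S2:
#' `log(((n1 + k) / (m1 + k)) / ((n2 + k) / (m2 + k)))`.
#' A score of 0 means the two features keep the same abundance ratio in
#' both locations; |score| = 1 (base 10) means the ratio changes tenfold.
#' The pseudo-count `k` keeps zero areas finite.
#'
#' @param n1,m1 Peak areas of features N and M in location S1.
#' @param n2,m2 Peak areas of features N and M in location S2.
#' @param k Pseudo-count added to every area (default 1e-10).
#' @param base Logarithm base (default 10).
#' @return The signed score (vectorised over the areas).
#' @export
proportionality_score <- function(n1, m1, n2, m2, k = 1e-10, base = 10) {
  if (k <= 0) stop("pseudo-count k must be > 0")
  if (any(c(n1, m1, n2, m2) < 0)) stop("areas must be >= 0")
  log(((n1 + k) / (m1 + k)) / ((n2 + k) / (m2 + k)), base = base)
}

#' Score every network edge across ordered location pairs
#'
#' For each network edge and each location pair of the scheme, aggregates
#' replicate samples per location and computes the proportionality score.
#' By convention N is the edge member with the higher precursor m/z, so a
#' positive score reads "the heavier member is relatively enriched in S1".
#'
#' @param network A `molecular_network`.
#' @param table A [feature_table()] containing every network node.
#' @param metadata A [sample_metadata()] covering every table sample.
#' @param scheme Passed to [location_pairs()].
#' @param k Pseudo-count (default 1e-10).
#' @param cutoff Prioritisation threshold on |score|, exclusive (default 1).
#' @param base Log base (default 10).
#' @param agg Replicate aggregation method (default `"mean"`).
#' @return List with `records` (data.frame: id_n, id_m, pair, s1, s2, n_s1,
#'   m_s1, n_s2, m_s2, score, prioritized) and `prioritized` (the |score| >
#'   cutoff subset). Rows ordered by edge then scheme pair order.
#' @export
score_network <- function(network, table, metadata, scheme = "chain",
                          k = 1e-10, cutoff = 1.0, base = 10, agg = "mean") {
  check_samples_mapped(table, metadata)
  missing <- setdiff(
    unique(c(network$edges$id_a, network$edges$id_b)),
    table$meta$feature_id
  )
  if (length(missing)) {
    stop("network node(s) missing from feature table: ",
         paste(missing, collapse = ", "))
  }
  pairs <- location_pairs(scheme, attr(metadata, "locations"))
  locs <- unique(c(pairs$s1, pairs$s2))
  agg_mat <- aggregate_all(table, metadata, locs, agg)
  ed <- network$edges
  if (!nrow(ed)) {
    rec <- data.frame(id_n = character(0), id_m = character(0), pair = character(0),
                      s1 = character(0), s2 = character(0), n_s1 = numeric(0),
                      m_s1 = numeric(0), n_s2 = numeric(0), m_s2 = numeric(0),
                      score = numeric(0), prioritized = logical(0))
    return(list(records = rec, prioritized = rec))
  }
  prec <- network$nodes$precursor_mz[match(ed$id_a, network$nodes$feature_id)]
  prec_b <- network$nodes$precursor_mz[match(ed$id_b, network$nodes$feature_id)]
  id_n <- ifelse(prec >= prec_b, ed$id_a, ed$id_b)
  id_m <- ifelse(prec >= prec_b, ed$id_b, ed$id_a)
  rec <- do.call(rbind, lapply(seq_len(nrow(ed)), function(i) {
    data.frame(
      id_n = id_n[i], id_m = id_m[i], pair = pairs$pair, s1 = pairs$s1, s2 = pairs$s2,
      n_s1 = agg_mat[id_n[i], pairs$s1], m_s1 = agg_mat[id_m[i], pairs$s1],
      n_s2 = agg_mat[id_n[i], pairs$s2], m_s2 = agg_mat[id_m[i], pairs$s2]
    )
  }))
  rec$score <- proportionality_score(rec$n_s1, rec$m_s1, rec$n_s2, rec$m_s2,
                                     k = k, base = base)
  rec$prioritized <- abs(rec$score) > cutoff
  rownames(rec) <- NULL
  list(records = rec, prioritized = rec[rec$prioritized, , drop = FALSE])
}

#' Write proportionality records with their shift annotations
#'
#' Long-format CSV mirroring a per-location-pair chemical proportionality
#' table: edge ids (N = higher precursor m/z), location pair, the four
#' aggregated areas, the score, the prioritisation flag, and the edge's
#' delta-mass annotation.
#'
#' @param scores Output of [score_network()].
#' @param network The scored `molecular_network`.
#' @param path Output CSV path.
#' @param catalog A [delta_catalog()] for edge annotation.
#' @param tol Annotation tolerance in Da.
#' @return The written data.frame, invisibly.
#' @export
write_proportionality_csv <- function(scores, network, path,
                                      catalog = default_delta_catalog(),
                                      tol = 0.01) {
  ann <- annotate_network_shifts(network, catalog, tol)
  key <- function(a, b) paste(pmin(a, b), pmax(a, b), sep = "\r")
  rec <- scores$records
  m <- match(key(rec$id_n, rec$id_m), key(ann$id_a, ann$id_b))
  rec$observed_delta <- ann$observed_delta[m]
  rec$annotation <- ann$annotation[m]
  utils::write.csv(rec, path, row.names = FALSE)
  invisible(rec)
}
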