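#' Score all spectrum pairs with the modified cosine
#'
#' @param spectra List of [spectrum()] objects (>= 2) with unique ids.
#' @param frag_tol Fragment tolerance in Da passed to [modified_cosine()].
#' @return data.frame of candidate edges, one row per unordered pair in
#'   lexicographic (i, j) index order: `id_a`, `id_b`, `score`,
#'   `matched_peaks`, `delta_mz` (precursor_a - precursor_b, signed),
#'   `abs_delta_mz`.
#' @export
score_all_pairs <- function(spectra, frag_tol = 0.02) {
  n <- length(spectra)
  if (n < 2L) stop("need at least 2 spectra")
  ids <- vapply(spectra, function(s) s$feature_id, "")
  if (anyDuplicated(ids)) stop("duplicate feature ids")
  prec <- vapply(spectra, function(s) s$precursor_mz, 0)
  rows <- vector("list", n * (n - 1L) / 2L)
  k <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sim <- modified_cosine(spectra[[i]], spectra[[j]], frag_tol)
      k <- k + 1L
      rows[[k]] <- data.frame(
        id_a = ids[i], id_b = ids[j],
        score = sim$score, matched_peaks = sim$matched_peaks,
        delta_mz = prec[i] - prec[j], abs_delta_mz = abs(prec[i] - prec[j])
      )
    }
  }
  do.call(rbind, rows)
}

# ranking used by the mutual top-K rule: better score first, ties broken by
# more matched peaks, smaller |delta m/z|, then neighbour id
neighbor_rank_order <- function(df) {
  order(-df$score, -df$matched_peaks, df$abs_delta_mz, df$neighbor)
}

#' Assemble a molecular network from candidate edges
#'
#' Applies the standard feature-based molecular networking topology rules:
#' (1) drop candidate edges with cosine score below `cosine_min` or fewer
#' than `min_matched` matched fragment ions; (2) keep an edge only if each
#' node is among the other's `top_k` most similar surviving neighbours
#' (mutual top-K); (3) while any connected component ("molecular family")
#' exceeds `max_family_size` nodes, remove its lowest-scoring edge(s) and
#' re-check. Nodes left without edges keep their own singleton family.
#'
#' @param spectra The spectra that produced `candidates` (supplies node ids
#'   and precursor m/z).
#' @param candidates Candidate edges from [score_all_pairs()].
#' @param cosine_min Minimum cosine score; edges must exceed this (default 0.7).
#' @param min_matched Minimum matched fragment ions, inclusive (default 6).
#' @param top_k Mutual-rank neighbourhood size (default 10).
#' @param max_family_size Component size cap (default 100).
#' @return An object of class `molecular_network`: list with `nodes`
#'   (feature_id, precursor_mz, family_id) and `edges` (id_a, id_b, score,
#'   matched_peaks, delta_mz, abs_delta_mz, family_id).
#' @export
apply_topology <- function(spectra, candidates, cosine_min = 0.7, min_matched = 6L,
                           top_k = 10L, max_family_size = 100L) {
  ids <- vapply(spectra, function(s) s$feature_id, "")
  prec <- vapply(spectra, function(s) s$precursor_mz, 0)
  ed <- candidates[candidates$score > cosine_min & candidates$matched_peaks >= min_matched, ,
                   drop = FALSE]

  # mutual top-K on the thresholded edge set
  if (nrow(ed)) {
    half <- rbind(
      data.frame(node = ed$id_a, neighbor = ed$id_b, score = ed$score,
                 matched_peaks = ed$matched_peaks, abs_delta_mz = ed$abs_delta_mz,
                 edge = seq_len(nrow(ed))),
      data.frame(node = ed$id_b, neighbor = ed$id_a, score = ed$score,
                 matched_peaks = ed$matched_peaks, abs_delta_mz = ed$abs_delta_mz,
                 edge = seq_len(nrow(ed)))
    )
    in_top <- logical(nrow(half))
    for (v in unique(half$node)) {
      rows <- which(half$node == v)
      ranked <- rows[neighbor_rank_order(half[rows, , drop = FALSE])]
      in_top[utils::head(ranked, top_k)] <- TRUE
    }
    mutual <- tapply(in_top, half$edge, all)
    ed <- ed[as.logical(mutual[as.character(seq_len(nrow(ed)))]), , drop = FALSE]
  }

  # family-size capping: repeatedly drop the lowest-scoring edge(s) of any
  # oversized component (score ties within that component removed together)
  repeat {
    comp <- edge_components(ids, ed)
    sizes <- table(comp)
    big <- names(sizes)[sizes > max_family_size]
    if (!length(big)) break
    cid <- big[1]
    members <- ids[comp == cid]
    in_comp <- ed$id_a %in% members
    worst <- min(ed$score[in_comp])
    ed <- ed[!(in_comp & ed$score == worst), , drop = FALSE]
  }

  comp <- edge_components(ids, ed)
  nodes <- data.frame(feature_id = ids, precursor_mz = prec, family_id = comp)
  edges <- ed
  edges$family_id <- comp[match(edges$id_a, ids)]
  rownames(edges) <- NULL
  structure(list(nodes = nodes, edges = edges), class = "molecular_network")
}

# connected-component labels over all node ids given the surviving edges
edge_components <- function(ids, edges) {
  g <- igraph::graph_from_data_frame(
    edges[, c("id_a", "id_b"), drop = FALSE],
    directed = FALSE,
    vertices = data.frame(name = ids)
  )
  igraph::components(g)$membership[ids]
}

#' @export
print.molecular_network <- function(x, ...) {
  cat(sprintf("<molecular_network> %d nodes, %d edges, %d families\n",
              nrow(x$nodes), nrow(x$edges), length(unique(x$nodes$family_id))))
  invisible(x)
}

#' Build a molecular network from spectra
#'
#' Convenience wrapper: spectral cleaning ([remove_precursor_window()],
#' [window_filter()]), exhaustive pair scoring and topology filtering.
#'
#' @param spectra List of [spectrum()] objects.
#' @param config Pipeline parameters, see [pipeline_config()].
#' @return A `molecular_network`.
#' @export
build_network <- function(spectra, config = pipeline_config()) {
  cleaned <- lapply(spectra, function(s) {
    window_filter(remove_precursor_window(s, config$precursor_window),
                  config$window_top_k, config$window)
  })
  cand <- score_all_pairs(cleaned, config$frag_tol)
  apply_topology(cleaned, cand,
                 cosine_min = config$cosine_min, min_matched = config$min_matched,
                 top_k = config$top_k, max_family_size = config$max_family_size)
}

#' Match query spectra against a spectral library
#'
#' Library spectra are filtered the same way as network input (precursor
#' window removal, window filter) before scoring. A hit requires a modified
#' cosine above `score_min` and at least `min_matched` matched ions; the
#' best hit per query is flagged.
#'
#' @param spectra Query [spectrum()] list (already cleaned or raw; cleaned
#'   with the same parameters here for symmetry).
#' @param library_spectra Library [spectrum()] list with an optional
#'   `annotation` element per spectrum.
#' @param score_min Minimum score, exclusive (default 0.7).
#' @param min_matched Minimum matched ions, inclusive (default 6).
#' @param config Cleaning parameters, see [pipeline_config()].
#' @return data.frame of hits: `feature_id`, `library_id`, `annotation`,
#'   `score`, `matched_peaks`, `best` (logical).
#' @export
library_match <- function(spectra, library_spectra, score_min = 0.7, min_matched = 6L,
                          config = pipeline_config()) {
  clean <- function(s) {
    window_filter(remove_precursor_window(s, config$precursor_window),
                  config$window_top_k, config$window)
  }
  q <- lapply(spectra, clean)
  lib <- lapply(library_spectra, clean)
  hits <- list()
  for (qs in q) {
    for (ls in lib) {
      sim <- modified_cosine(qs, ls, config$frag_tol)
      if (sim$score > score_min && sim$matched_peaks >= min_matched) {
        ann <- if (!is.null(ls$annotation)) ls$annotation else NA_character_
        hits[[length(hits) + 1L]] <- data.frame(
          feature_id = qs$feature_id, library_id = ls$feature_id,
          annotation = ann, score = sim$score, matched_peaks = sim$matched_peaks
        )
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(feature_id = character(0), library_id = character(0),
                      annotation = character(0), score = numeric(0),
                      matched_peaks = integer(0), best = logical(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$feature_id, -out$score, -out$matched_peaks, out$library_id), ]
  out$best <- !duplicated(out$feature_id)
  rownames(out) <- NULL
  out
}

#' Export a molecular network to edge-list and node-attribute CSVs
#'
#' @param network A `molecular_network`.
#' @param edges_path,nodes_path Output CSV paths.
#' @return Invisibly, a list of the two written data.frames.
#' @export
write_network_csv <- function(network, edges_path, nodes_path) {
  utils::write.csv(network$edges, edges_path, row.names = FALSE)
  utils::write.csv(network$nodes, nodes_path, row.names = FALSE)
  invisible(list(edges = network$edges, nodes = network$nodes))
}
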