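#' Remove fragment ions near the precursor
#'
#' Drops every fragment within `window` Da of the precursor m/z (boundary
#' inclusive). This removes residual precursor and near-precursor signals
#' that would otherwise dominate spectral similarity.
#'
#' @param s A [spectrum()].
#' @param window Half-width of the removal window in Da (default 17).
#' @return The filtered spectrum.
#' @export
remove_precursor_window <- function(s, window = 17.0) {
  keep <- abs(s$peaks[, "mz"] - s$precursor_mz) > window
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s
}

#' Window-filter a spectrum to its locally dominant fragments
#'
#' A peak is kept iff its intensity ranks among the `top_k` most intense
#' peaks within +/- `window` Da of its own m/z (itself included). Both window
#' boundaries are inclusive. Intensity ties at the rank boundary are kept.
#'
#' @param s A [spectrum()].
#' @param top_k Number of peaks retained per window (default 6).
#' @param window Half-width of the local window in Da (default 50).
#' @return The filtered spectrum.
#' @export
window_filter <- function(s, top_k = 6L, window = 50.0) {
  mz <- s$peaks[, "mz"]
  int <- s$peaks[, "intensity"]
  n <- length(mz)
  if (n <= top_k) return(s)
  keep <- logical(n)
  for (i in seq_len(n)) {
    local <- int[abs(mz - mz[i]) <= window]
    # rank within own window; ties share the higher rank (kept)
    keep[i] <- sum(local > int[i]) < top_k
  }
  s$peaks <- s$peaks[keep, , drop = FALSE]
  s
}

#' Modified cosine similarity between two fragment spectra
#'
#' Cosine similarity over square-root-weighted, L2-normalised fragment
#' intensities in which peak pairs may match either directly
#' (|mz_a - mz_b| <= `frag_tol`) or shifted by the precursor-mass difference
#' (|mz_a - mz_b - (prec_a - prec_b)| <= `frag_tol`). The shifted pathway is
#' what links molecules that differ by a single chemical modification.
#' Candidate pairs are accepted greedily by descending intensity product,
#' each peak used at most once; ties broken by lower (mz_a, mz_b).
#'
#' @param a,b [spectrum()] objects (pre-filtered; this function does not
#'   re-filter).
#' @param frag_tol Fragment m/z tolerance in Da (default 0.02).
#' @return List with `score` in \[0, 1\], `matched_peaks` (count of accepted
#'   pairs), and `matches` (data.frame of index_a, index_b, kind, product).
#' @export
modified_cosine <- function(a, b, frag_tol = 0.02) {
  empty <- list(
    score = 0, matched_peaks = 0L,
    matches = data.frame(index_a = integer(0), index_b = integer(0),
                         kind = character(0), product = numeric(0))
  )
  na <- nrow(a$peaks); nb <- nrow(b$peaks)
  if (na == 0L || nb == 0L) return(empty)
  wa <- sqrt(a$peaks[, "intensity"])
  wb <- sqrt(b$peaks[, "intensity"])
  norm_a <- sqrt(sum(wa^2)); norm_b <- sqrt(sum(wb^2))
  if (norm_a == 0 || norm_b == 0) return(empty)
  wa <- wa / norm_a; wb <- wb / norm_b
  shift <- a$precursor_mz - b$precursor_mz

  mza <- a$peaks[, "mz"]; mzb <- b$peaks[, "mz"]
  diff <- outer(mza, mzb, "-")
  direct <- which(abs(diff) <= frag_tol, arr.ind = TRUE)
  shifted <- which(abs(diff - shift) <= frag_tol, arr.ind = TRUE)
  cand <- rbind(
    if (nrow(direct)) cbind(direct, kind = 1L),
    if (nrow(shifted)) cbind(shifted, kind = 2L)
  )
  if (is.null(cand) || nrow(cand) == 0L) return(empty)
  # a pair that qualifies both directly and shifted counts once (as direct)
  dup <- duplicated(cand[, 1:2, drop = FALSE])
  cand <- cand[!dup, , drop = FALSE]
  prod <- wa[cand[, 1]] * wb[cand[, 2]]
  ord <- order(-prod, mza[cand[, 1]], mzb[cand[, 2]])
  cand <- cand[ord, , drop = FALSE]
  prod <- prod[ord]

  used_a <- logical(na); used_b <- logical(nb)
  acc <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ia <- cand[i, 1]; ib <- cand[i, 2]
    if (!used_a[ia] && !used_b[ib]) {
      acc[i] <- TRUE
      used_a[ia] <- TRUE
      used_b[ib] <- TRUE
    }
  }
  matches <- data.frame(
    index_a = as.integer(cand[acc, 1]),
    index_b = as.integer(cand[acc, 2]),
    kind = c("direct", "precursor_shifted")[cand[acc, 3]],
    product = prod[acc]
  )
  list(score = min(sum(matches$product), 1), matched_peaks = nrow(matches),
       matches = matches)
}
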