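# Independent reference implementations used as oracles. These deliberately
# share no code with the package: exhaustive search instead of greedy
# matching, explicit loops instead of the package's vectorised paths.

# exhaustive optimal one-to-one matching value of the modified cosine
oracle_modified_cosine <- function(a, b, frag_tol = 0.02) {
  wa <- sqrt(a$peaks[, "intensity"])
  wb <- sqrt(b$peaks[, "intensity"])
  if (!length(wa) || !length(wb) || sum(wa^2) == 0 || sum(wb^2) == 0) return(0)
  wa <- wa / sqrt(sum(wa^2))
  wb <- wb / sqrt(sum(wb^2))
  shift <- a$precursor_mz - b$precursor_mz
  cand <- list()
  for (i in seq_along(wa)) {
    for (j in seq_along(wb)) {
      d <- a$peaks[i, "mz"] - b$peaks[j, "mz"]
      if (abs(d) <= frag_tol || abs(d - shift) <= frag_tol) {
        cand[[length(cand) + 1L]] <- c(i, j, wa[i] * wb[j])
      }
    }
  }
  if (!length(cand)) return(0)
  best <- 0
  recurse <- function(idx, used_a, used_b, acc) {
    if (acc > best) best <<- acc
    if (idx > length(cand)) return()
    recurse(idx + 1L, used_a, used_b, acc) # skip this candidate
    p <- cand[[idx]]
    if (!(p[1] %in% used_a) && !(p[2] %in% used_b)) {
      recurse(idx + 1L, c(used_a, p[1]), c(used_b, p[2]), acc + p[3])
    }
  }
  recurse(1L, integer(0), integer(0), 0)
  best
}

# brute-force window filter: peak kept iff among top_k intensities within
# +/- window of itself
oracle_window_filter_keep <- function(mz, intensity, top_k = 6, window = 50) {
  keep <- logical(length(mz))
  for (i in seq_along(mz)) {
    inside <- which(abs(mz - mz[i]) <= window)
    ranked <- inside[order(-intensity[inside])]
    cut <- intensity[ranked[min(top_k, length(ranked))]]
    keep[i] <- intensity[i] >= cut && sum(intensity[inside] > intensity[i]) < top_k
  }
  keep
}

# straightforward reference network: thresholds, mutual top-K by explicit
# per-node sorting, then iterative family capping
oracle_network <- function(ids, prec, cand, cosine_min = 0.7, min_matched = 6,
                           top_k = 10, max_family_size = 100) {
  ed <- cand[cand$score > cosine_min & cand$matched_peaks >= min_matched, ,
             drop = FALSE]
  if (nrow(ed)) {
    rank_of <- function(node, other, erow) {
      # neighbours of `node`, best first
      nb <- data.frame(other = character(0), score = numeric(0),
                       mp = integer(0), adm = numeric(0))
      for (r in seq_len(nrow(ed))) {
        if (ed$id_a[r] == node) {
          nb <- rbind(nb, data.frame(other = ed$id_b[r], score = ed$score[r],
                                     mp = ed$matched_peaks[r], adm = ed$abs_delta_mz[r]))
        } else if (ed$id_b[r] == node) {
          nb <- rbind(nb, data.frame(other = ed$id_a[r], score = ed$score[r],
                                     mp = ed$matched_peaks[r], adm = ed$abs_delta_mz[r]))
        }
      }
      nb <- nb[order(-nb$score, -nb$mp, nb$adm, nb$other), , drop = FALSE]
      match(other, nb$other)
    }
    ok <- logical(nrow(ed))
    for (r in seq_len(nrow(ed))) {
      ok[r] <- rank_of(ed$id_a[r], ed$id_b[r]) <= top_k &&
        rank_of(ed$id_b[r], ed$id_a[r]) <= top_k
    }
    ed <- ed[ok, , drop = FALSE]
  }
  comps <- function(ed) {
    lab <- stats::setNames(seq_along(ids), ids)
    changed <- TRUE
    while (changed) {
      changed <- FALSE
      for (r in seq_len(nrow(ed))) {
        la <- lab[ed$id_a[r]]; lb <- lab[ed$id_b[r]]
        if (la != lb) {
          lab[lab == max(la, lb)] <- min(la, lb)
          changed <- TRUE
        }
      }
    }
    lab
  }
  repeat {
    lab <- comps(ed)
    sizes <- table(lab)
    big <- names(sizes)[sizes > max_family_size]
    if (!length(big)) break
    members <- ids[lab == big[1]]
    inb <- ed$id_a %in% members & ed$id_b %in% members
    worst <- min(ed$score[inb])
    ed <- ed[!(inb & ed$score == worst), , drop = FALSE]
  }
  list(edges = ed[order(ed$id_a, ed$id_b), , drop = FALSE], membership = comps(ed))
}

# small deterministic random spectra for property tests
random_spectrum <- function(id, n_peaks, precursor = stats::runif(1, 200, 800)) {
  spectrum(id, precursor,
           cbind(sort(stats::runif(n_peaks, 50, precursor - 20)),
                 stats::runif(n_peaks, 1, 1000)))
}

tiny_garden <- function(noise_sigma = 0, seed = 1L, ...) {
  generate_garden(garden_design(noise_sigma = noise_sigma, seed = seed, ...))
}

edge_key <- function(a, b) paste(pmin(a, b), pmax(a, b))
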