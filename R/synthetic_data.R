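#' Design of a synthetic layered fungus garden
#'
#' Describes a toy deconstructed garden: a few parent compounds entering
#' with the plant material, each optionally transformed into products whose
#' formulas differ by a known chemical group. Parent abundances decay
#' geometrically along the material flow (L -> A -> B -> C -> D -> TT ->
#' TM -> TB) while product abundances mirror that profile and accumulate
#' toward the trash; replicate samples scatter lognormally around each
#' location mean. Fragment spectra share a per-family backbone, with a
#' fraction of the product's fragments shifted by the transformation delta
#' so the modified cosine links parent and product.
#'
#' @param parents data.frame with columns `name`, `formula`, `base_area`,
#'   `gradient` (`"decaying"`, `"accumulating"` or `"flat"`).
#' @param transformations data.frame with columns `parent` (a parent name),
#'   `delta` (formula of the gained group) and `gradient` of the product.
#' @param locations Ordered location labels.
#' @param replicates Samples per location (default 5).
#' @param decay Per-location retention factor of decaying profiles, in
#'   (0, 1) (default 0.25; accumulating profiles use its mirror image).
#' @param noise_sigma Lognormal sdlog of replicate scatter (default 0.1;
#'   0 = noise-free).
#' @param n_fragments Backbone fragments per spectrum (default 8).
#' @param intensity_ratio Geometric decay of backbone fragment intensities
#'   (default 0.8, most intense fragment first).
#' @param shift_fraction Fraction of backbone fragments shifted by the
#'   transformation delta in product spectra (default 0.5).
#' @param reference_area Area of the spiked internal standard (default 1e6).
#' @param reference_jitter Lognormal sdlog of the spike across samples
#'   (default 0 = perfectly constant).
#' @param seed Random seed; the same design generates byte-identical files.
#' @return An object of class `garden_design`.
#' @export
garden_design <- function(parents = default_garden_parents(),
                          transformations = default_garden_transformations(),
                          locations = garden_locations,
                          replicates = 5L,
                          decay = 0.25,
                          noise_sigma = 0.1,
                          n_fragments = 8L,
                          intensity_ratio = 0.8,
                          shift_fraction = 0.5,
                          reference_area = 1e6,
                          reference_jitter = 0,
                          seed = 1L) {
  stopifnot(decay > 0, decay < 1, noise_sigma >= 0, replicates >= 1,
            n_fragments >= 2, shift_fraction >= 0, shift_fraction <= 1)
  parents <- as.data.frame(parents)
  transformations <- as.data.frame(transformations)
  stopifnot(all(c("name", "formula", "base_area", "gradient") %in% names(parents)))
  if (nrow(transformations)) {
    stopifnot(all(c("parent", "delta", "gradient") %in% names(transformations)))
    bad <- setdiff(transformations$parent, parents$name)
    if (length(bad)) stop("transformation references unknown parent: ",
                          paste(bad, collapse = ", "))
  }
  structure(
    list(parents = parents, transformations = transformations,
         locations = locations, replicates = as.integer(replicates),
         decay = decay, noise_sigma = noise_sigma,
         n_fragments = as.integer(n_fragments),
         intensity_ratio = intensity_ratio, shift_fraction = shift_fraction,
         reference_area = reference_area, reference_jitter = reference_jitter,
         seed = as.integer(seed)),
    class = "garden_design"
  )
}

#' Default parent compounds of the synthetic garden
#'
#' Plant-derived parents spanning the compound classes typically observed
#' in decomposing leaf material: two flavonoids, an oxylipin and a
#' sphingoid base (the latter flat across locations, as a negative
#' control for gradient detection).
#'
#' @return data.frame accepted by [garden_design()].
#' @export
default_garden_parents <- function() {
  data.frame(
    name = c("flavonol", "quercetin_like", "oxylipin", "sphingoid"),
    formula = c("C15H10O6", "C15H10O7", "C18H30O4", "C18H39NO3"),
    base_area = c(4e6, 5e6, 3e6, 2e6),
    gradient = c("decaying", "decaying", "decaying", "flat")
  )
}

#' Default planted transformations of the synthetic garden
#'
#' Hydrogenation (H2) and oxygenation (O) of a flavonol, chain elongation
#' (C2H4) of an oxylipin, glycosylation (C6H10O5) of a second flavonoid --
#' all with accumulating products -- plus a flat H2 product of the sphingoid
#' parent (no abundance gradient, hence no proportionality signal).
#'
#' @return data.frame accepted by [garden_design()].
#' @export
default_garden_transformations <- function() {
  data.frame(
    parent = c("flavonol", "flavonol", "oxylipin", "quercetin_like", "sphingoid"),
    delta = c("H2", "O", "C2H4", "C6H10O5", "H2"),
    gradient = c("accumulating", "accumulating", "accumulating", "accumulating", "flat")
  )
}

# expected (noise-free) abundance of one feature along the location chain
gradient_profile <- function(gradient, base, decay, n_loc) {
  idx <- seq_len(n_loc) - 1L
  switch(gradient,
    decaying = base * decay^idx,
    accumulating = base * decay^(n_loc - 1L - idx),
    flat = rep(base, n_loc),
    stop("unknown gradient type '", gradient, "'")
  )
}

# backbone fragment grid for family fi: below parent precursor - 20 Da, with
# a family-specific offset and spacing so unrelated families share no peaks
backbone_mz <- function(precursor, n_frag, fi) {
  start <- 60 + 13.7 * fi
  upper <- precursor - 20
  if (upper <= start + n_frag) {
    stop("precursor ", round(precursor, 2), " too light for ", n_frag,
         " backbone fragments")
  }
  start + (seq_len(n_frag) - 1L) * (upper - start) / (n_frag - 1L)
}

#' Generate a synthetic layered-garden dataset
#'
#' Produces MS/MS spectra, a feature quantification table (with the spiked
#' internal-standard reference feature), sample metadata with layered 3D
#' grid coordinates, and the ground truth needed to verify recovery:
#' feature formulas and families, planted transformation edges with their
#' exact mass deltas, and the location pairs of the consecutive-location
#' (chain) scheme where the expected |proportionality score| exceeds 1.
#'
#' @param design A [garden_design()].
#' @param out_dir If non-NULL, writes `spectra.mgf`, `features.csv`,
#'   `metadata.csv` and `ground_truth.json` there.
#' @param min_matched Fragment-match requirement the spectrum model must be
#'   able to satisfy; generation fails (rather than silently producing an
#'   unlinkable family) if `n_fragments` is below it or if unrelated
#'   families could reach it by coincidence.
#' @return List with `spectra`, `table` ([feature_table()], reference
#'   spiked), `metadata` ([sample_metadata()]) and `ground_truth`.
#' @export
generate_garden <- function(design = garden_design(), out_dir = NULL,
                            min_matched = 6L) {
  if (design$n_fragments < min_matched) {
    stop("spectrum model cannot satisfy min_matched = ", min_matched,
         " with only ", design$n_fragments, " backbone fragments")
  }
  set.seed(design$seed)
  locs <- design$locations
  n_loc <- length(locs)

  # --- features: parents then products -----------------------------------
  feats <- list()
  for (i in seq_len(nrow(design$parents))) {
    p <- design$parents[i, ]
    feats[[length(feats) + 1L]] <- data.frame(
      feature_id = p$name, formula = p$formula,
      mz = ion_mz(p$formula), family = i, gradient = p$gradient,
      parent = NA_character_, delta_label = NA_character_,
      base_area = p$base_area
    )
  }
  if (nrow(design$transformations)) {
    for (j in seq_len(nrow(design$transformations))) {
      tr <- design$transformations[j, ]
      pi <- match(tr$parent, design$parents$name)
      parent_f <- parse_formula(design$parents$formula[pi])
      delta_f <- parse_formula(tr$delta)
      counts <- parent_f$counts
      for (el in names(delta_f$counts)) {
        counts[el] <- if (el %in% names(counts)) counts[[el]] + delta_f$counts[[el]] else delta_f$counts[[el]]
      }
      product_formula <- paste0(names(counts), ifelse(counts > 1L, counts, ""),
                                collapse = "")
      feats[[length(feats) + 1L]] <- data.frame(
        feature_id = paste0(tr$parent, "_", tr$delta),
        formula = product_formula,
        mz = ion_mz(design$parents$formula[pi]) + monoisotopic_mass(delta_f),
        family = pi, gradient = tr$gradient,
        parent = tr$parent, delta_label = tr$delta,
        base_area = design$parents$base_area[pi]
      )
    }
  }
  feats <- do.call(rbind, feats)
  if (anyDuplicated(feats$feature_id)) stop("duplicate feature ids in design")

  # --- expected location means and sampled areas -------------------------
  means <- t(vapply(seq_len(nrow(feats)), function(i) {
    gradient_profile(feats$gradient[i], feats$base_area[i], design$decay, n_loc)
  }, numeric(n_loc)))
  dimnames(means) <- list(feats$feature_id, locs)

  sample_ids <- as.vector(t(outer(locs, seq_len(design$replicates), paste, sep = "_")))
  sample_loc <- rep(locs, each = design$replicates)
  areas <- matrix(0, nrow = nrow(feats), ncol = length(sample_ids),
                  dimnames = list(feats$feature_id, sample_ids))
  for (s in seq_along(sample_ids)) {
    mu <- means[, sample_loc[s]]
    if (design$noise_sigma > 0) {
      # mean-preserving lognormal replicate scatter
      mu <- mu * stats::rlnorm(length(mu),
                               meanlog = -design$noise_sigma^2 / 2,
                               sdlog = design$noise_sigma)
    }
    areas[, s] <- mu
  }

  meta_feat <- data.frame(
    feature_id = feats$feature_id, mz = feats$mz,
    rt = 1 + (seq_len(nrow(feats)) - 1L) * 0.35
  )
  table <- feature_table(meta_feat, areas)
  table <- spike_reference(table, design)

  # --- sample metadata: layered 3D grid, one z-slab per location ---------
  rep_idx <- rep(seq_len(design$replicates), times = n_loc)
  metadata <- sample_metadata(data.frame(
    sample_id = sample_ids, location = sample_loc,
    x = (rep_idx - 1L) %% 3L, y = (rep_idx - 1L) %/% 3L,
    z = match(sample_loc, locs) - 1L, radius = 0.5
  ), locations = locs)

  # --- spectra -----------------------------------------------------------
  intens <- 1000 * design$intensity_ratio^(seq_len(design$n_fragments) - 1L)
  spectra <- vector("list", nrow(feats))
  for (i in seq_len(nrow(feats))) {
    parent_id <- if (is.na(feats$parent[i])) feats$feature_id[i] else feats$parent[i]
    parent_mz <- feats$mz[match(parent_id, feats$feature_id)]
    frag <- backbone_mz(parent_mz, design$n_fragments, feats$family[i])
    if (!is.na(feats$parent[i])) {
      dm <- feats$mz[i] - parent_mz
      n_shift <- round(design$shift_fraction * design$n_fragments)
      shift_idx <- seq_len(design$n_fragments) %% 2L == 0L
      if (sum(shift_idx) != n_shift) shift_idx <- seq_len(design$n_fragments) <= n_shift
      frag[shift_idx] <- frag[shift_idx] + dm
    }
    spectra[[i]] <- spectrum(feats$feature_id[i], feats$mz[i],
                             cbind(frag, intens), charge = 1L,
                             rt = meta_feat$rt[i])
  }

  check_family_separation(spectra, feats$family, min_matched)

  # --- ground truth ------------------------------------------------------
  k <- 1e-10
  transformations <- NULL
  if (nrow(design$transformations)) {
    transformations <- do.call(rbind, lapply(
      which(!is.na(feats$parent)), function(i) {
        parent_id <- feats$parent[i]
        n_mean <- means[feats$feature_id[i], ] # product = higher m/z member
        m_mean <- means[parent_id, ]
        chain_scores <- log10(((n_mean[-n_loc] + k) / (m_mean[-n_loc] + k)) /
                              ((n_mean[-1] + k) / (m_mean[-1] + k)))
        planted <- paste(locs[-n_loc], locs[-1], sep = ":")[abs(chain_scores) > 1]
        data.frame(
          parent_id = parent_id, product_id = feats$feature_id[i],
          delta_label = feats$delta_label[i],
          delta_mass = monoisotopic_mass(feats$delta_label[i]),
          planted_pairs = paste(planted, collapse = ";")
        )
      }
    ))
  }
  ground_truth <- list(
    features = feats[, c("feature_id", "formula", "mz", "family", "gradient")],
    transformations = transformations,
    n_families = length(unique(feats$family)),
    location_means = means
  )

  out <- list(spectra = spectra, table = table, metadata = metadata,
              ground_truth = ground_truth)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_mgf(spectra, file.path(out_dir, "spectra.mgf"))
    write_feature_table(table, file.path(out_dir, "features.csv"))
    write_metadata(metadata, file.path(out_dir, "metadata.csv"))
    gt <- ground_truth
    gt$location_means <- data.frame(feature_id = rownames(gt$location_means),
                                    as.data.frame(gt$location_means),
                                    check.names = FALSE, row.names = NULL)
    jsonlite::write_json(gt, file.path(out_dir, "ground_truth.json"),
                         dataframe = "rows", digits = NA, pretty = TRUE)
  }
  out
}

# unrelated families must not be able to reach min_matched fragment matches,
# directly or shifted by their precursor difference
check_family_separation <- function(spectra, family, min_matched, tol = 0.02) {
  n <- length(spectra)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (family[i] == family[j]) next
      d <- outer(spectra[[i]]$peaks[, "mz"], spectra[[j]]$peaks[, "mz"], "-")
      shift <- spectra[[i]]$precursor_mz - spectra[[j]]$precursor_mz
      n_match <- sum(abs(d) <= tol | abs(d - shift) <= tol)
      if (n_match >= min_matched) {
        stop("design flaw: unrelated features ", spectra[[i]]$feature_id,
             " and ", spectra[[j]]$feature_id, " share ", n_match,
             " matchable fragments")
      }
    }
  }
  invisible(TRUE)
}

#' Spike the internal-standard reference feature into a table
#'
#' Adds a constant-area feature at the sulfamethazine [M+H]+ m/z
#' (279.0910, RT 2.55 min) to every sample, optionally with lognormal
#' jitter, for testing reference normalisation.
#'
#' @param table A [feature_table()].
#' @param design A [garden_design()] (supplies `reference_area` and
#'   `reference_jitter`).
#' @return The table with an added `IS_sulfamethazine` feature.
#' @export
spike_reference <- function(table, design = garden_design()) {
  id <- "IS_sulfamethazine"
  if (id %in% table$meta$feature_id) stop("reference feature id collision: ", id)
  n <- ncol(table$areas)
  area <- rep(design$reference_area, n)
  if (design$reference_jitter > 0) {
    area <- area * stats::rlnorm(n, meanlog = -design$reference_jitter^2 / 2,
                                 sdlog = design$reference_jitter)
  }
  meta <- rbind(table$meta,
                data.frame(feature_id = id, mz = 279.0910, rt = 2.55))
  areas <- rbind(table$areas, area)
  rownames(areas) <- meta$feature_id
  feature_table(meta, areas)
}
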