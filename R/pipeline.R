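#' Pipeline configuration
#'
#' Collects every tunable parameter of the analysis with defaults matching
#' the standard feature-based molecular networking settings for Q-TOF data
#' and the proportionality prioritisation cutoff.
#'
#' @param precursor_window Precursor-removal half-window, Da (default 17).
#' @param window_top_k Peaks kept per local window (default 6).
#' @param window Local window half-width, Da (default 50).
#' @param frag_tol Fragment m/z tolerance, Da (default 0.02).
#' @param cosine_min Minimum edge cosine, exclusive (default 0.7).
#' @param min_matched Minimum matched fragment ions, inclusive (default 6).
#' @param top_k Mutual-rank neighbourhood size (default 10).
#' @param max_family_size Molecular-family size cap (default 100).
#' @param k Proportionality pseudo-count (default 1e-10).
#' @param cutoff Prioritisation threshold on |score|, exclusive (default 1).
#' @param log_base Proportionality log base (default 10).
#' @param pair_scheme `"chain"` or `"leaves_vs_all"` (default `"chain"`).
#' @param delta_tol Delta-annotation tolerance, Da (default 0.01).
#' @param reference_mz m/z of the internal-standard reference feature
#'   (default 279.0910, sulfamethazine [M+H]+); `NA` disables reference
#'   normalisation.
#' @param reference_rt Reference retention time, minutes (default 2.55).
#' @param aggregation Replicate aggregation (default `"mean"`).
#' @param cube_root Apply the cube-root transform after normalisation
#'   (default `FALSE`; the transform eases visual comparison but is not
#'   part of the proportionality score).
#' @param iqr_quantile Low-IQR removal fraction (default 0).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(precursor_window = 17, window_top_k = 6L,
                            window = 50, frag_tol = 0.02, cosine_min = 0.7,
                            min_matched = 6L, top_k = 10L,
                            max_family_size = 100L, k = 1e-10, cutoff = 1.0,
                            log_base = 10, pair_scheme = "chain",
                            delta_tol = 0.01, reference_mz = 279.0910,
                            reference_rt = 2.55, aggregation = "mean",
                            cube_root = FALSE, iqr_quantile = 0) {
  cfg <- list(
    precursor_window = precursor_window, window_top_k = window_top_k,
    window = window, frag_tol = frag_tol, cosine_min = cosine_min,
    min_matched = min_matched, top_k = top_k,
    max_family_size = max_family_size, k = k, cutoff = cutoff,
    log_base = log_base, pair_scheme = pair_scheme, delta_tol = delta_tol,
    reference_mz = reference_mz, reference_rt = reference_rt,
    aggregation = aggregation, cube_root = cube_root,
    iqr_quantile = iqr_quantile
  )
  stopifnot(cfg$frag_tol > 0, cfg$k > 0, cfg$cutoff >= 0, cfg$top_k >= 1,
            cfg$max_family_size >= 1, cfg$min_matched >= 0)
  structure(cfg, class = c("pipeline_config", "list"))
}

#' Run the full garden analysis
#'
#' End-to-end orchestration: read spectra, feature table and metadata
#' (paths or in-memory objects); preprocess the table (constant-feature
#' removal, optional IQR filter, reference normalisation, optional cube
#' root); build the molecular network; score every edge across the
#' location-pair scheme; tabulate mass-shift frequencies among prioritised
#' edges; and, when spot coordinates are available, export the
#' molecular-cartography CSV. All outputs plus the exact configuration
#' used and a run log are written to `out_dir`.
#'
#' @param mgf,quant,metadata Paths to the MGF / feature-table CSV /
#'   metadata CSV, or the corresponding in-memory objects.
#' @param out_dir Output directory (created if needed).
#' @param config A [pipeline_config()].
#' @param catalog A [delta_catalog()] for shift annotation.
#' @return Invisibly, a list with `network`, `scores`, `shift_freq`,
#'   `table` (preprocessed), `report` and the output file paths.
#' @export
run_garden_pipeline <- function(mgf, quant, metadata, out_dir,
                                config = pipeline_config(),
                                catalog = default_delta_catalog()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character(0)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, msg)
    message(msg)
  }

  spectra <- if (is.character(mgf)) read_mgf(mgf) else mgf
  table <- if (is.character(quant)) read_feature_table(quant) else quant
  md <- if (is.character(metadata)) read_metadata(metadata) else metadata
  check_samples_mapped(table, md)
  say("inputs: ", length(spectra), " spectra, ", nrow(table$areas),
      " features, ", ncol(table$areas), " samples")

  # preprocessing
  ref_id <- NULL
  if (!is.na(config$reference_mz)) {
    ref_id <- tryCatch(
      find_reference_feature(table, config$reference_mz, config$reference_rt),
      error = function(e) NULL
    )
  }
  if (!is.null(ref_id)) {
    pre <- preprocess_table(table, ref_id, iqr_quantile = config$iqr_quantile,
                            cube_root = config$cube_root)
    table <- pre$table
    report <- pre$report
    say("preprocessing: reference ", ref_id, ", ",
        report$n_removed_constant, " constant and ", report$n_removed_iqr,
        " low-IQR features removed")
  } else {
    pre <- drop_uninformative(table, config$iqr_quantile)
    table <- pre$table
    report <- c(pre$report, list(reference_feature_id = NA, transform = "none"))
    say("preprocessing: no reference feature found; table left unnormalised")
  }

  # networking on the spectra that have quantification rows
  spectra <- Filter(function(s) s$feature_id %in% table$meta$feature_id, spectra)
  network <- build_network(spectra, config)
  say("network: ", nrow(network$nodes), " nodes, ", nrow(network$edges),
      " edges, ", length(unique(network$nodes$family_id)), " families")

  scores <- score_network(network, table, md, scheme = config$pair_scheme,
                          k = config$k, cutoff = config$cutoff,
                          base = config$log_base, agg = config$aggregation)
  say("proportionality: ", nrow(scores$records), " records, ",
      nrow(scores$prioritized), " with |score| > ", config$cutoff)

  shift_freq <- shift_frequency(network, scores$records,
                                score_cutoff = config$cutoff,
                                catalog = catalog, tol = config$delta_tol)

  paths <- list(
    edges = file.path(out_dir, "network_edges.csv"),
    nodes = file.path(out_dir, "network_nodes.csv"),
    proportionality = file.path(out_dir, "proportionality.csv"),
    shift_freq = file.path(out_dir, "shift_frequency.csv"),
    shift_freq_long = file.path(out_dir, "shift_frequency_long.csv"),
    config = file.path(out_dir, "config.json"),
    log = file.path(out_dir, "run_log.txt")
  )
  write_network_csv(network, paths$edges, paths$nodes)
  write_proportionality_csv(scores, network, paths$proportionality,
                            catalog = catalog, tol = config$delta_tol)
  write_shift_frequency(shift_freq, paths$shift_freq, paths$shift_freq_long)

  if (all(c("x", "y", "z", "radius") %in% names(md))) {
    paths$ili <- file.path(out_dir, "cartography.csv")
    write_ili_csv(table, md, table$meta$feature_id, paths$ili)
    say("cartography: ", length(table$meta$feature_id), " features exported")
  }

  jsonlite::write_json(unclass(config), paths$config, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  writeLines(log_lines, paths$log)
  invisible(list(network = network, scores = scores, shift_freq = shift_freq,
                 table = table, report = report, paths = paths))
}

#' Generate a synthetic garden dataset from the command line surface
#'
#' Thin wrapper over [generate_garden()] used by the shipped CLI script.
#'
#' @param out_dir Output directory.
#' @param seed Random seed for the default design.
#' @param noise_sigma Replicate scatter (default 0.1).
#' @return The generated dataset, invisibly.
#' @export
simulate_garden_cli <- function(out_dir, seed = 1L, noise_sigma = 0.1) {
  design <- garden_design(seed = seed, noise_sigma = noise_sigma)
  invisible(generate_garden(design, out_dir = out_dir))
}

#' Formula mass utility
#'
#' Computes the calculated ion m/z of a formula ([M+H]+ for neutral
#' formulas, atom-sum minus an electron for formulas written with a
#' trailing `+`), and, when a detected m/z is supplied, the signed ppm
#' error.
#'
#' @param formula Formula string.
#' @param detected_mz Optional observed m/z.
#' @return List with `formula`, `calc_mz` and (if requested) `ppm`.
#' @examples
#' mass_tool("C28H44O3", 429.3355)
#' @export
mass_tool <- function(formula, detected_mz = NULL) {
  f <- parse_formula(formula)
  calc <- if (f$charge > 0L) ion_mz(f, "as_written_cation") else ion_mz(f)
  out <- list(formula = format(f), calc_mz = calc)
  if (!is.null(detected_mz)) out$ppm <- ppm_error(detected_mz, calc)
  out
}
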