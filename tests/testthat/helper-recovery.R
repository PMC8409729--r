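# shared measurement: fraction of planted (edge x location-pair) signals that
# the full pipeline reports in the prioritised list with the right annotation
recovery_rate <- function(seed, noise_sigma, config = pipeline_config()) {
  dir <- withr::local_tempdir()
  generate_garden(garden_design(seed = seed, noise_sigma = noise_sigma),
                  out_dir = dir)
  res <- suppressMessages(run_garden_pipeline(
    file.path(dir, "spectra.mgf"), file.path(dir, "features.csv"),
    file.path(dir, "metadata.csv"), file.path(dir, "out"), config
  ))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  tr <- gt$transformations
  pr <- res$scores$prioritized
  ann <- annotate_network_shifts(res$network)
  planted <- 0L
  found <- 0L
  for (i in seq_len(nrow(tr))) {
    pairs <- strsplit(tr$planted_pairs[i], ";")[[1]]
    pairs <- pairs[nzchar(pairs)]
    if (!length(pairs)) next
    k <- edge_key(tr$parent_id[i], tr$product_id[i])
    lab <- ann$annotation[edge_key(ann$id_a, ann$id_b) == k]
    hit <- pr$pair[edge_key(pr$id_n, pr$id_m) == k]
    planted <- planted + length(pairs)
    if (length(lab) == 1 && identical(lab, tr$delta_label[i])) {
      found <- found + sum(pairs %in% hit)
    }
  }
  list(rate = found / planted, planted = planted)
}
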