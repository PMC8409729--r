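#' Ordered location vocabulary of the deconstructed garden
#'
#' Sample locations along the material flow: fresh leaves (L), fungus-garden
#' layers top to bottom (A, B, C, D), and trash layers top to bottom
#' (TT, TM, TB).
#' @export
garden_locations <- c("L", "A", "B", "C", "D", "TT", "TM", "TB")

#' Construct an MS/MS spectrum
#'
#' @param feature_id Feature identifier (kept as an opaque string).
#' @param precursor_mz Precursor m/z in Da, positive.
#' @param peaks Two-column numeric matrix or data.frame of fragment
#'   (m/z, intensity); re-sorted ascending by m/z.
#' @param charge Positive integer precursor charge (default 1).
#' @param rt Retention time in minutes, or `NA`.
#' @return An object of class `ms2_spectrum`.
#' @export
spectrum <- function(feature_id, precursor_mz, peaks, charge = 1L, rt = NA_real_) {
  peaks <- as.matrix(peaks)
  if (length(peaks) == 0L) peaks <- matrix(numeric(0), ncol = 2)
  if (ncol(peaks) != 2L) stop("peaks must have two columns (mz, intensity)")
  storage.mode(peaks) <- "double"
  colnames(peaks) <- c("mz", "intensity")
  if (anyNA(peaks) || any(!is.finite(peaks))) stop("peaks contain NA or non-finite values")
  if (any(peaks[, "intensity"] < 0)) stop("peak intensities must be >= 0")
  if (!is.numeric(precursor_mz) || length(precursor_mz) != 1L || !is.finite(precursor_mz) ||
      precursor_mz <= 0) {
    stop("precursor_mz must be a single positive number")
  }
  peaks <- peaks[order(peaks[, "mz"]), , drop = FALSE]
  structure(
    list(
      feature_id = as.character(feature_id),
      precursor_mz = precursor_mz,
      charge = as.integer(charge),
      rt = rt,
      peaks = peaks
    ),
    class = "ms2_spectrum"
  )
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat(sprintf(
    "<ms2_spectrum> id=%s precursor m/z=%.4f charge=%d peaks=%d\n",
    x$feature_id, x$precursor_mz, x$charge, nrow(x$peaks)
  ))
  invisible(x)
}

#' Read spectra from a Mascot generic format (MGF) file
#'
#' Supports the feature-based molecular networking dialect: one
#' `BEGIN IONS`/`END IONS` block per feature with `PEPMASS`, optional
#' `CHARGE` and `RTINSECONDS`, and `FEATURE_ID` or `SCANS` as identifier.
#'
#' @param path Path to the MGF file.
#' @return List of [spectrum()] objects, in file order.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("MGF file not found: ", path)
  lines <- trimws(readLines(path))
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(begins > ends)) {
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path)
  }
  out <- vector("list", length(begins))
  for (b in seq_along(begins)) {
    block <- lines[(begins[b] + 1L):(ends[b] - 1L)]
    block <- block[nzchar(block)]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    getval <- function(key) if (key %in% keys) vals[match(key, keys)] else NA_character_
    pep <- getval("PEPMASS")
    if (is.na(pep)) stop("MGF block ", b, " is missing PEPMASS")
    precursor <- as.numeric(strsplit(pep, "[[:space:]]+")[[1]][1])
    id <- getval("FEATURE_ID")
    if (is.na(id)) id <- getval("SCANS")
    if (is.na(id)) stop("MGF block ", b, " has neither FEATURE_ID nor SCANS")
    charge <- getval("CHARGE")
    charge <- if (is.na(charge)) 1L else as.integer(sub("\\+$", "", charge))
    rtsec <- getval("RTINSECONDS")
    rt <- if (is.na(rtsec)) NA_real_ else as.numeric(rtsec) / 60
    peak_lines <- block[!is_kv]
    peaks <- if (length(peak_lines)) {
      vals2 <- lapply(strsplit(peak_lines, "[[:space:]]+"), as.numeric)
      if (any(vapply(vals2, length, 1L) < 2L) || anyNA(unlist(vals2))) {
        stop("malformed peak line in MGF block ", b)
      }
      do.call(rbind, lapply(vals2, function(v) v[1:2]))
    } else {
      matrix(numeric(0), ncol = 2)
    }
    out[[b]] <- spectrum(id, precursor, peaks, charge = charge, rt = rt)
  }
  out
}

#' Write spectra to an MGF file
#'
#' Inverse of [read_mgf()] up to float formatting; blocks are written in
#' list order.
#'
#' @param spectra List of [spectrum()] objects with unique feature ids.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  ids <- vapply(spectra, function(s) s$feature_id, "")
  if (anyDuplicated(ids)) stop("duplicate feature_id in spectra: ", ids[duplicated(ids)][1])
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("FEATURE_ID=", s$feature_id), con)
    writeLines(sprintf("PEPMASS=%.6f", s$precursor_mz), con)
    writeLines(paste0("CHARGE=", s$charge, "+"), con)
    if (!is.na(s$rt)) writeLines(sprintf("RTINSECONDS=%.4f", s$rt * 60), con)
    if (nrow(s$peaks)) {
      writeLines(sprintf("%.6f %.6f", s$peaks[, "mz"], s$peaks[, "intensity"]), con)
    }
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

#' Construct a feature quantification table
#'
#' @param meta data.frame with columns `feature_id`, `mz`, `rt` (one row per
#'   feature; ids unique).
#' @param areas Numeric matrix of peak areas, features x samples, with
#'   rownames = feature ids and colnames = sample ids; all finite and >= 0.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(meta, areas) {
  meta <- as.data.frame(meta)
  stopifnot(all(c("feature_id", "mz", "rt") %in% names(meta)))
  meta$feature_id <- as.character(meta$feature_id)
  areas <- as.matrix(areas)
  storage.mode(areas) <- "double"
  if (anyDuplicated(meta$feature_id)) stop("feature ids must be unique")
  if (is.null(colnames(areas)) || anyDuplicated(colnames(areas))) {
    stop("sample ids (area column names) must be present and unique")
  }
  if (nrow(areas) != nrow(meta)) stop("meta and areas disagree on feature count")
  rownames(areas) <- meta$feature_id
  if (anyNA(areas) || any(!is.finite(areas))) stop("areas must be finite (no missing values)")
  if (any(areas < 0)) stop("areas must be >= 0")
  structure(list(meta = meta[, c("feature_id", "mz", "rt")], areas = areas),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d features x %d samples\n",
              nrow(x$areas), ncol(x$areas)))
  invisible(x)
}

#' Read a feature quantification table from CSV
#'
#' Expects a header row `feature_id,mz,rt,<sample1>,<sample2>,...`.
#'
#' @param path CSV path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, colClasses = c(feature_id = "character"))
  need <- c("feature_id", "mz", "rt")
  if (!all(need %in% names(df))) {
    stop("feature table must have columns feature_id, mz, rt; found: ",
         paste(names(df), collapse = ", "))
  }
  samp <- setdiff(names(df), need)
  if (!length(samp)) stop("feature table has no sample columns")
  feature_table(df[need], as.matrix(df[samp]))
}

#' Write a feature table to CSV
#' @param table A [feature_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  df <- cbind(table$meta, as.data.frame(table$areas, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct sample metadata
#'
#' @param df data.frame with columns `sample_id`, `location` and optionally
#'   `x`, `y`, `z`, `radius` spot coordinates for cartography export.
#' @param locations Allowed ordered location vocabulary.
#' @return An object of class `sample_metadata` (the validated data.frame
#'   with the location vocabulary attached as attribute `locations`).
#' @export
sample_metadata <- function(df, locations = garden_locations) {
  df <- as.data.frame(df)
  stopifnot(all(c("sample_id", "location") %in% names(df)))
  df$sample_id <- as.character(df$sample_id)
  df$location <- as.character(df$location)
  if (anyDuplicated(df$sample_id)) stop("sample ids must be unique")
  bad <- setdiff(unique(df$location), locations)
  if (length(bad)) {
    stop("unknown location label(s) ", paste(bad, collapse = ", "),
         "; allowed: ", paste(locations, collapse = ", "))
  }
  structure(df, class = c("sample_metadata", "data.frame"), locations = locations)
}

#' Read sample metadata from CSV
#' @param path CSV path with header `sample_id,location[,x,y,z,radius]`.
#' @param locations Allowed ordered location vocabulary.
#' @return A [sample_metadata()].
#' @export
read_metadata <- function(path, locations = garden_locations) {
  sample_metadata(utils::read.csv(path, check.names = FALSE,
                                  colClasses = c(sample_id = "character")),
                  locations = locations)
}

#' Write sample metadata to CSV
#' @param metadata A [sample_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(as.data.frame(metadata), path, row.names = FALSE)
  invisible(path)
}

# every feature-table sample must have a location; error otherwise
check_samples_mapped <- function(table, metadata) {
  missing <- setdiff(colnames(table$areas), metadata$sample_id)
  if (length(missing)) {
    stop("sample(s) without metadata location: ", paste(missing, collapse = ", "))
  }
  invisible(TRUE)
}

#' Export a 3D molecular-cartography spot table
#'
#' Writes the CSV layout consumed by the `'ili` spatial viewer
#' (<https://ili.embl.de/>): `name,X,Y,Z,radius` followed by one column per
#' exported feature carrying its abundance at each spot.
#'
#' @param table A [feature_table()].
#' @param metadata A [sample_metadata()] with `x`, `y`, `z`, `radius`
#'   coordinates for every exported sample.
#' @param features Character vector of feature ids to export (column order
#'   preserved); may be empty.
#' @param path Output CSV path.
#' @return The exported data.frame, invisibly.
#' @export
write_ili_csv <- function(table, metadata, features, path) {
  check_samples_mapped(table, metadata)
  md <- as.data.frame(metadata)
  md <- md[match(colnames(table$areas), md$sample_id), , drop = FALSE]
  coord_cols <- c("x", "y", "z", "radius")
  if (!all(coord_cols %in% names(md))) {
    stop("metadata lacks coordinate columns (x, y, z, radius)")
  }
  nocoord <- md$sample_id[!stats::complete.cases(md[coord_cols])]
  if (length(nocoord)) {
    stop("missing coordinates for sample(s): ", paste(nocoord, collapse = ", "))
  }
  missing_feat <- setdiff(features, table$meta$feature_id)
  if (length(missing_feat)) {
    stop("feature(s) not in table: ", paste(missing_feat, collapse = ", "))
  }
  out <- data.frame(
    name = md$sample_id, X = md$x, Y = md$y, Z = md$z, radius = md$radius,
    check.names = FALSE
  )
  for (f in features) out[[f]] <- table$areas[f, md$sample_id]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
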