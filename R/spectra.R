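#' Construct a µXRF spectrum object
#'
#' A spectrum is the mean photon-count curve of one analysed zone: a strictly
#' increasing energy axis (keV) and the matching non-negative counts (mean
#' counts per pixel, so possibly fractional).
#'
#' @param energy Numeric vector of energies in keV, strictly increasing.
#' @param counts Numeric vector of photon counts, same length as `energy`,
#'   all values `>= 0`.
#' @param zone_id Character scalar identifying the analysed zone.
#' @return An object of class `xrf_spectrum`: a list with elements
#'   `zone_id`, `energy` and `counts`.
#' @export
xrf_spectrum <- function(energy, counts, zone_id = "zone") {
  energy <- as.numeric(energy)
  counts <- as.numeric(counts)
  if (length(energy) != length(counts)) {
    stopf("energy and counts differ in length (%d vs %d)",
          length(energy), length(counts))
  }
  if (length(energy) < 2L) stopf("a spectrum needs at least 2 points")
  if (anyNA(energy) || anyNA(counts)) stopf("spectrum contains NA values")
  d <- diff(energy)
  if (any(d <= 0)) {
    row <- which(d <= 0)[1L] + 1L
    stopf("non-monotone energy axis at row %d (%.6g after %.6g)",
          row, energy[row], energy[row - 1L])
  }
  if (any(counts < 0)) {
    row <- which(counts < 0)[1L]
    stopf("negative counts at row %d (%.6g)", row, counts[row])
  }
  structure(list(zone_id = as.character(zone_id)[1L],
                 energy = energy, counts = counts),
            class = "xrf_spectrum")
}

#' @export
print.xrf_spectrum <- function(x, ...) {
  cat(sprintf("<xrf_spectrum> %s: %d channels, %.3f-%.3f keV\n",
              x$zone_id, length(x$energy), min(x$energy), max(x$energy)))
  invisible(x)
}

#' Read a µXRF spectrum from disk
#'
#' Supports two plain-text layouts: a two-column delimited file
#' (`energy_keV`, `counts`; `#` comments and an optional header line) and
#' EMSA/MAS 1.0 spectral files in XY data mode.
#'
#' @param path Path to the file.
#' @param format `"auto"` (sniff the first line), `"delimited"` or `"emsa"`.
#' @param zone_id Zone identifier; defaults to the file name without
#'   extension.
#' @return An [xrf_spectrum()] object.
#' @export
read_spectrum <- function(path, format = c("auto", "delimited", "emsa"),
                          zone_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("spectrum file not found: %s", path)
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  if (format == "auto") {
    format <- if (any(grepl("^#FORMAT", lines[seq_len(min(3L, length(lines)))],
                            ignore.case = TRUE))) "emsa" else "delimited"
  }
  if (is.null(zone_id)) zone_id <- sub("\\.[^.]*$", "", basename(path))
  if (format == "emsa") {
    return(parse_emsa(lines, zone_id, path))
  }
  parse_delimited_spectrum(lines, zone_id, path)
}

parse_delimited_spectrum <- function(lines, zone_id, path) {
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stopf("no data rows in %s", path)
  # optional single header line: drop it if the first field is not numeric
  first <- strsplit(lines[1L], "[,;\t ]+")[[1L]]
  if (suppressWarnings(is.na(as.numeric(first[1L])))) lines <- lines[-1L]
  if (length(lines) < 2L) stopf("fewer than 2 data rows in %s", path)
  fields <- strsplit(lines, "[,;\t ]+")
  bad <- which(vapply(fields, length, 1L) < 2L)
  if (length(bad)) stopf("row %d of %s has fewer than 2 columns", bad[1L], path)
  energy <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 1L)))
  counts <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  if (anyNA(energy) || anyNA(counts)) {
    row <- which(is.na(energy) | is.na(counts))[1L]
    stopf("non-numeric value at data row %d of %s", row, path)
  }
  xrf_spectrum(energy, counts, zone_id)
}

parse_emsa <- function(lines, zone_id, path) {
  lines <- trimws(lines)
  kw <- grepl("^#", lines)
  header <- lines[kw]
  get_kw <- function(key) {
    hit <- grep(paste0("^#", key, "\\b"), header, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NULL)
    trimws(sub("^[^:]*:", "", hit[1L]))
  }
  datatype <- get_kw("DATATYPE")
  if (!is.null(datatype) && toupper(datatype) != "XY") {
    stopf("EMSA file %s: only DATATYPE XY is supported (got %s)",
          path, datatype)
  }
  start <- grep("^#SPECTRUM", lines, ignore.case = TRUE)
  end <- grep("^#ENDOFDATA", lines, ignore.case = TRUE)
  if (!length(start)) stopf("EMSA file %s lacks a #SPECTRUM block", path)
  end <- if (length(end)) end[1L] else length(lines) + 1L
  data_lines <- lines[seq(start[1L] + 1L, end - 1L)]
  data_lines <- data_lines[nzchar(data_lines)]
  if (length(data_lines) < 2L) stopf("EMSA file %s has fewer than 2 data rows",
                                     path)
  parse_delimited_spectrum(data_lines, zone_id, path)
}

#' Write a spectrum as a two-column delimited file
#'
#' Inverse of [read_spectrum()] for the delimited layout; full-precision
#' round trip.
#'
#' @param spectrum An [xrf_spectrum()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "xrf_spectrum"))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(sprintf("# zone_id: %s", spectrum$zone_id),
               "energy_keV,counts",
               paste(format(spectrum$energy, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     format(spectrum$counts, digits = 17, trim = TRUE,
                            scientific = FALSE),
                     sep = ",")),
             con = con)
  invisible(path)
}

manifest_required_cols <- c("zone_id", "file", "specimen_id", "site", "clade",
                            "zone_type", "session", "mineralogy")

#' Read and validate a specimen manifest
#'
#' The manifest lists every acquired zone spectrum. `zone_id` identifies the
#' physical zone (specimen + zone index), so control zones re-acquired in
#' several sessions share a `zone_id` and differ only in `session`.
#'
#' @param path Path to a delimited (comma/tab) table with columns
#'   `zone_id, file, specimen_id, site, clade, zone_type, session,
#'   mineralogy`.
#' @return A `data.frame` of validated zone metadata.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stopf("manifest not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                        sep = if (grepl("\\.tsv$", path)) "\t" else ",")
  validate_manifest(df)
}

#' Validate a manifest data frame
#'
#' @param df A data frame with the manifest columns.
#' @return The validated data frame (character columns, invariants checked).
#' @export
validate_manifest <- function(df) {
  if (nrow(df) == 0L) stopf("manifest is empty")
  missing <- setdiff(manifest_required_cols, names(df))
  if (length(missing)) {
    stopf("manifest is missing column(s): %s", paste(missing, collapse = ", "))
  }
  for (cl in manifest_required_cols) df[[cl]] <- as.character(df[[cl]])
  bad_type <- setdiff(unique(df$zone_type), c("fossil", "sediment"))
  if (length(bad_type)) {
    stopf("unknown zone_type value(s): %s", paste(bad_type, collapse = ", "))
  }
  key <- paste(df$zone_id, df$session, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- df[duplicated(key), , drop = FALSE][1L, ]
    stopf("duplicate (zone_id, session) in manifest: (%s, %s)",
          dup$zone_id, dup$session)
  }
  df
}

#' Fit an energy calibration from reference emission lines
#'
#' Least-squares affine (optionally quadratic) map from detector channel to
#' energy, anchored on reference peaks such as Ca Ka1 (3.692 keV), Fe Ka1
#' (6.405 keV) and Y Ka1 (14.958 keV).
#'
#' @param reference_lines Two-column matrix or data frame of
#'   `(channel, energy_keV)` pairs; at least two with distinct channels.
#' @param quadratic If `TRUE` (and at least 3 pairs are given) fit a
#'   quadratic term as well.
#' @return An `xrf_calibration` object: `offset`, `gain` (keV/channel),
#'   `quad`, `residuals`.
#' @export
calibrate_energy <- function(reference_lines, quadratic = FALSE) {
  rl <- as.matrix(reference_lines)
  if (nrow(rl) < 2L) stopf("need at least 2 reference (channel, energy) pairs")
  channel <- as.numeric(rl[, 1L])
  energy <- as.numeric(rl[, 2L])
  if (anyDuplicated(channel)) stopf("coincident reference channels")
  if (quadratic && nrow(rl) < 3L) {
    stopf("quadratic calibration needs at least 3 reference pairs")
  }
  fit <- if (quadratic) {
    stats::lm(energy ~ channel + I(channel^2))
  } else {
    stats::lm(energy ~ channel)
  }
  cf <- stats::coef(fit)
  gain <- unname(cf[2L])
  if (gain <= 0) stopf("non-positive calibration gain (%.3g)", gain)
  structure(list(offset = unname(cf[1L]), gain = gain,
                 quad = if (quadratic) unname(cf[3L]) else 0,
                 residuals = unname(stats::resid(fit))),
            class = "xrf_calibration")
}

#' Apply an energy calibration to channel positions
#'
#' @param calibration An `xrf_calibration` object.
#' @param channels Numeric channel positions, or an [xrf_spectrum()] whose
#'   `energy` slot actually holds channels.
#' @return Calibrated energies (keV), or a recalibrated spectrum.
#' @export
apply_calibration <- function(calibration, channels) {
  stopifnot(inherits(calibration, "xrf_calibration"))
  if (inherits(channels, "xrf_spectrum")) {
    e <- apply_calibration(calibration, channels$energy)
    return(xrf_spectrum(e, channels$counts, channels$zone_id))
  }
  calibration$offset + calibration$gain * channels +
    calibration$quad * channels^2
}

#' Reconstruct a spectrum as a continuous curve
#'
#' Linear interpolation between the exported points; exact at the points.
#' Evaluating outside the spectrum's support is an error, never
#' extrapolation.
#'
#' @param spectrum An [xrf_spectrum()] object.
#' @return A function `f(energy)` returning interpolated counts.
#' @export
reconstruct_continuous <- function(spectrum) {
  stopifnot(inherits(spectrum, "xrf_spectrum"))
  lo <- spectrum$energy[1L]
  hi <- spectrum$energy[length(spectrum$energy)]
  f <- stats::approxfun(spectrum$energy, spectrum$counts, method = "linear",
                        rule = 1)
  function(energy) {
    energy <- as.numeric(energy)
    if (any(energy < lo) || any(energy > hi)) {
      stopf("energy query outside spectrum support [%.4g, %.4g]", lo, hi)
    }
    f(energy)
  }
}

#' Subset a spectrum to the analysis energy window
#'
#' Keeps the channels inside `[lo, hi]` and synthesises the two window
#' endpoints by linear interpolation when no exported point falls exactly on
#' them, so every subset spectrum shares the same support.
#'
#' @param spectrum An [xrf_spectrum()] object.
#' @param lo,hi Window bounds in keV; defaults 1.7 and 18.3, the range over
#'   which the detected signal is reliable (P K-edge to below the 18 keV
#'   excitation).
#' @return The subset [xrf_spectrum()].
#' @export
subset_energy <- function(spectrum, lo = 1.7, hi = 18.3) {
  stopifnot(inherits(spectrum, "xrf_spectrum"), lo < hi)
  emin <- spectrum$energy[1L]
  emax <- spectrum$energy[length(spectrum$energy)]
  if (emin > lo || emax < hi) {
    stopf("spectrum support [%.4g, %.4g] does not cover [%.4g, %.4g]",
          emin, emax, lo, hi)
  }
  keep <- spectrum$energy >= lo & spectrum$energy <= hi
  e <- spectrum$energy[keep]
  v <- spectrum$counts[keep]
  f <- reconstruct_continuous(spectrum)
  if (length(e) == 0L || e[1L] > lo) {
    e <- c(lo, e)
    v <- c(f(lo), v)
  }
  if (e[length(e)] < hi) {
    e <- c(e, hi)
    v <- c(v, f(hi))
  }
  xrf_spectrum(e, v, spectrum$zone_id)
}

#' Log-normalise and standardise a spectrum
#'
#' Applies `log10(counts + 1)` then centres and scales to mean 0 and
#' population (divide-by-n) standard deviation 1 over the spectrum's
#' channels. The `+ 1` offset keeps zero-count channels finite while leaving
#' large counts essentially untouched.
#'
#' @param spectrum An [xrf_spectrum()] object (typically already subset to
#'   the analysis window).
#' @return An `xrf_spectrum` whose `counts` hold the standardised
#'   log-intensities (so they may be negative).
#' @export
log_standardize <- function(spectrum) {
  stopifnot(inherits(spectrum, "xrf_spectrum"))
  v <- log10(spectrum$counts + 1)
  n <- length(v)
  mu <- mean(v)
  sdev <- sqrt(sum((v - mu)^2) / n)
  if (sdev == 0) stopf("degenerate spectrum: zero variance after log10")
  out <- spectrum
  out$counts <- (v - mu) / sdev
  class(out) <- c("xrf_spectrum_std", "xrf_spectrum")
  out
}

# standardised spectra may legitimately hold negative values, so bypass the
# non-negativity check when re-wrapping them
#' Landmark energy grid
#'
#' The 831 fixed landmark energies `1.7 + 0.02 k` keV, `k = 0..830`, ending
#' at 18.3 keV.
#'
#' @return Numeric vector of length 831.
#' @export
landmark_grid <- function() {
  1.7 + 0.02 * (0:830)
}

#' Sample a processed spectrum at the landmark grid
#'
#' @param spectrum A standardised [xrf_spectrum()] covering 1.7-18.3 keV.
#' @return Numeric landmark vector of length 831, with the grid attached as
#'   the `grid` attribute.
#' @export
extract_landmarks <- function(spectrum) {
  stopifnot(inherits(spectrum, "xrf_spectrum"))
  grid <- landmark_grid()
  emin <- spectrum$energy[1L]
  emax <- spectrum$energy[length(spectrum$energy)]
  if (emin > grid[1L] || emax < grid[length(grid)]) {
    stopf("spectrum support [%.4g, %.4g] does not cover the landmark grid",
          emin, emax)
  }
  vals <- stats::approx(spectrum$energy, spectrum$counts, xout = grid,
                        method = "linear", rule = 1)$y
  structure(vals, grid = grid)
}

#' Full formatting chain: raw spectrum to landmark vector
#'
#' Subset to 1.7-18.3 keV, log10-normalise and standardise, then sample the
#' 831 landmarks from the continuous reconstruction.
#'
#' @param spectrum An [xrf_spectrum()] object.
#' @return Landmark vector of length 831.
#' @export
format_spectrum <- function(spectrum) {
  extract_landmarks(log_standardize(subset_energy(spectrum)))
}

#' Assemble a landmark matrix from spectra and metadata
#'
#' @param vectors A list of landmark vectors (from [format_spectrum()]), or
#'   a numeric matrix with 831 columns.
#' @param meta A manifest-style data frame with one row per spectrum.
#' @return An `xrf_landmarks` object: `values` (n x 831 matrix), `grid`,
#'   `meta`, and alignment provenance flags.
#' @export
landmark_matrix <- function(vectors, meta) {
  values <- if (is.matrix(vectors)) vectors else do.call(rbind, vectors)
  grid <- landmark_grid()
  if (ncol(values) != length(grid)) {
    stopf("landmark matrix must have %d columns, got %d",
          length(grid), ncol(values))
  }
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(meta) != nrow(values)) {
    stopf("metadata rows (%d) do not match matrix rows (%d)",
          nrow(meta), nrow(values))
  }
  rownames(values) <- paste(meta$zone_id, meta$session, sep = "@")
  structure(list(values = values, grid = grid, meta = meta,
                 aligned_sessions = character(0), averaged = FALSE),
            class = "xrf_landmarks")
}

#' @export
print.xrf_landmarks <- function(x, ...) {
  cat(sprintf(paste0("<xrf_landmarks> %d spectra x %d landmarks ",
                     "(sessions: %s%s%s)\n"),
              nrow(x$values), ncol(x$values),
              paste(unique(x$meta$session), collapse = ", "),
              if (length(x$aligned_sessions)) "; aligned" else "",
              if (x$averaged) "; averaged" else ""))
  invisible(x)
}

#' Read spectra listed in a manifest and build the landmark matrix
#'
#' @param manifest Manifest data frame (see [read_manifest()]) whose `file`
#'   column holds paths, or a path to a manifest file.
#' @param dir Directory that `file` entries are relative to.
#' @return An `xrf_landmarks` object.
#' @export
build_landmark_matrix <- function(manifest, dir = ".") {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  manifest <- validate_manifest(manifest)
  vecs <- lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$file[i]
    if (!file.exists(p)) p <- file.path(dir, manifest$file[i])
    format_spectrum(read_spectrum(p, zone_id = manifest$zone_id[i]))
  })
  landmark_matrix(vecs, manifest)
}

#' Export / import a landmark matrix as delimited text
#'
#' `write_landmark_matrix()` writes the values (first row = grid energies)
#' and the joined metadata alongside; `read_landmark_matrix()` restores the
#' object.
#'
#' @param x An `xrf_landmarks` object.
#' @param path Base path; `<path>.csv` holds values, `<path>_meta.csv` the
#'   metadata.
#' @return `path` invisibly, or the restored `xrf_landmarks`.
#' @export
write_landmark_matrix <- function(x, path) {
  stopifnot(inherits(x, "xrf_landmarks"))
  m <- rbind(x$grid, x$values)
  utils::write.table(m, paste0(path, ".csv"), sep = ",", row.names = FALSE,
                     col.names = FALSE)
  utils::write.csv(x$meta, paste0(path, "_meta.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmark_matrix
#' @export
read_landmark_matrix <- function(path) {
  m <- as.matrix(utils::read.csv(paste0(path, ".csv"), header = FALSE))
  meta <- utils::read.csv(paste0(path, "_meta.csv"), stringsAsFactors = FALSE)
  grid <- m[1L, ]
  if (max(abs(grid - landmark_grid())) > 1e-8) {
    stopf("stored grid does not match the 831-landmark grid")
  }
  landmark_matrix(m[-1L, , drop = FALSE], meta)
}
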