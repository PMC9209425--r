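#' Create an in-memory LC-MS run
#'
#' A `tracer_run` holds the centroided MS1 scans of one LC-MS run: a scan
#' table (scan index, retention time in seconds) and a centroid table
#' (scan index, m/z, intensity) kept sorted by m/z for fast extracted-ion
#' chromatogram (EIC) lookup.
#'
#' @param run_id Run identifier (character scalar).
#' @param rt Numeric vector of scan retention times in seconds, strictly
#'   increasing.
#' @param peaks A data frame with columns `scan` (1-based index into `rt`),
#'   `mz` (Da) and `intensity` (counts).
#' @param polarity `"positive"` or `"negative"`.
#' @return An object of class `tracer_run`.
#' @export
tracer_run <- function(run_id, rt, peaks, polarity = "positive") {
  stopifnot(is.character(run_id), length(run_id) == 1L)
  rt <- as.numeric(rt)
  if (length(rt) && any(diff(rt) <= 0)) {
    abort("scan retention times must be strictly increasing",
          class = "tracerkit_validation_error")
  }
  peaks <- as_tibble(peaks)[, c("scan", "mz", "intensity")]
  if (nrow(peaks)) {
    if (any(peaks$intensity < 0)) {
      abort("centroid intensities must be non-negative",
            class = "tracerkit_validation_error")
    }
    peaks <- arrange(peaks, .data$mz)
  }
  structure(
    list(run_id = run_id, polarity = polarity,
         rt = rt, peaks = peaks),
    class = "tracer_run"
  )
}

#' @export
print.tracer_run <- function(x, ...) {
  cat(sprintf("<tracer_run> %s [%s]: %d MS1 scans, %d centroids, RT %.1f-%.1f s\n",
              x$run_id, x$polarity, length(x$rt), nrow(x$peaks),
              if (length(x$rt)) min(x$rt) else NA, if (length(x$rt)) max(x$rt) else NA))
  invisible(x)
}

#' Read a raw LC-MS run (mzML/mzXML)
#'
#' Reads all MS1 scans of a centroided mzML or mzXML file in retention-time
#' order; MS2 scans are ignored. Profile-mode spectra are rejected.
#'
#' @param path Path to an mzML or mzXML file.
#' @param run_id Run identifier; defaults to the file name without extension.
#' @return A [tracer_run()].
#' @export
read_raw_run <- function(path, run_id = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    abort(sprintf("not a readable mass-spectrometry file: %s", path),
          class = "tracerkit_format_error")
  }
  run_id <- run_id %||% sub("\\.(mzX?ML|mzml|mzxml)$", "", basename(path))
  ms <- tryCatch(mzR::openMSfile(path),
                 error = function(e) abort(
                   sprintf("failed to parse %s: %s", path, conditionMessage(e)),
                   class = "tracerkit_format_error"))
  on.exit(mzR::close(ms), add = TRUE)
  hdr <- mzR::header(ms)
  ms1 <- which(hdr$msLevel == 1L)
  if (!length(ms1)) {
    abort(sprintf("no MS1 scans in %s", path), class = "tracerkit_empty_run_error")
  }
  if (!is.null(hdr$centroided) && any(!hdr$centroided[ms1], na.rm = TRUE)) {
    abort(sprintf("%s contains profile-mode MS1 spectra; centroid the data first", path),
          class = "tracerkit_format_error")
  }
  ord <- ms1[order(hdr$retentionTime[ms1])]
  pk <- mzR::peaks(ms, ord)
  if (is.matrix(pk)) pk <- list(pk)
  peaks <- list_rbind(imap(pk, function(m, i) {
    if (!nrow(m)) return(NULL)
    tibble(scan = i, mz = unname(m[, 1]), intensity = unname(m[, 2]))
  }))
  if (is.null(peaks)) peaks <- tibble(scan = integer(), mz = numeric(), intensity = numeric())
  pol <- if (all(hdr$polarity[ord] == 0L, na.rm = TRUE)) "negative" else "positive"
  tracer_run(run_id, hdr$retentionTime[ord], peaks, polarity = pol)
}

#' Write a run to mzML
#'
#' Serializes a [tracer_run()] to a centroided single-MS-level mzML file.
#'
#' @param run A `tracer_run`.
#' @param path Output file path (`.mzML`).
#' @return `path`, invisibly.
#' @export
write_raw_run <- function(run, path) {
  n <- length(run$rt)
  pk <- split(run$peaks, factor(run$peaks$scan, levels = seq_len(n)))
  pks <- map(pk, function(d) cbind(mz = d$mz, intensity = d$intensity))
  npk <- map_int(pks, nrow)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = if (identical(run$polarity, "negative")) 0L else 1L,
    peaksCount = npk,
    totIonCurrent = map_dbl(pk, ~ sum(.x$intensity)),
    retentionTime = run$rt,
    basePeakMZ = map_dbl(pk, ~ if (nrow(.x)) .x$mz[which.max(.x$intensity)] else 0),
    basePeakIntensity = map_dbl(pk, ~ if (nrow(.x)) max(.x$intensity) else 0),
    collisionEnergy = 0, ionisationEnergy = 0,
    lowMZ = map_dbl(pk, ~ if (nrow(.x)) min(.x$mz) else 0),
    highMZ = map_dbl(pk, ~ if (nrow(.x)) max(.x$mz) else 0),
    precursorScanNum = 0L, precursorMZ = 0, precursorCharge = 0L,
    precursorIntensity = 0, mergedScan = -1L, mergedResultScanNum = -1L,
    mergedResultStartScanNum = -1L, mergedResultEndScanNum = -1L,
    injectionTime = 0, filterString = NA_character_, centroided = TRUE,
    ionMobilityDriftTime = NA_real_, isolationWindowTargetMZ = NA_real_,
    isolationWindowLowerOffset = NA_real_, isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = NA_real_, scanWindowUpperLimit = NA_real_,
    stringsAsFactors = FALSE
  )
  mzR::writeMSData(unname(pks), path, header = hdr)
  invisible(path)
}

#' m/z extraction tolerance
#'
#' 0.01 Da for ions below 400 Da, otherwise 25 ppm.
#'
#' @param mz m/z value(s) in Da.
#' @return Tolerance in Da (half-width of the closed extraction window).
#' @export
mz_tolerance <- function(mz) ifelse(mz < 400, 0.01, mz * 25e-6)

#' Extract an ion chromatogram
#'
#' Sums, scan by scan, the intensities of all centroids within the closed
#' m/z window `mz +/- tol` over a retention-time window. Scans inside the
#' window with no matching centroid contribute explicit zeros, so EIC grids
#' from one run are shared across isotopologues.
#'
#' @param run A [tracer_run()].
#' @param mz Center m/z (Da).
#' @param rt_window Numeric length-2, retention-time window in seconds.
#' @param mz_tol Tolerance in Da; defaults to [mz_tolerance()].
#' @return A tibble of class `tracer_eic` with columns `rt` and `intensity`
#'   and attributes `mz_center`, `mz_tol`, `run_id`.
#' @export
extract_eic <- function(run, mz, rt_window = range(run$rt), mz_tol = NULL) {
  mz_tol <- mz_tol %||% mz_tolerance(mz)
  in_rt <- which(run$rt >= rt_window[1] & run$rt <= rt_window[2])
  intens <- numeric(length(in_rt))
  if (nrow(run$peaks)) {
    lo <- findInterval(mz - mz_tol, run$peaks$mz, left.open = TRUE) + 1L
    hi <- findInterval(mz + mz_tol, run$peaks$mz)
    if (hi >= lo) {
      sub <- run$peaks[lo:hi, ]
      sums <- tapply(sub$intensity, sub$scan, sum)
      idx <- match(as.integer(names(sums)), in_rt)
      keep <- !is.na(idx)
      intens[idx[keep]] <- sums[keep]
    }
  }
  new_eic(run$rt[in_rt], intens, mz_center = mz, mz_tol = mz_tol, run_id = run$run_id)
}

new_eic <- function(rt, intensity, mz_center = NA_real_, mz_tol = NA_real_,
                    run_id = NA_character_) {
  out <- tibble(rt = rt, intensity = intensity)
  class(out) <- c("tracer_eic", class(out))
  attr(out, "mz_center") <- mz_center
  attr(out, "mz_tol") <- mz_tol
  attr(out, "run_id") <- run_id
  out
}

req_cols <- function(df, cols, what, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    abort(sprintf("%s %s is missing required column(s): %s",
                  what, path, paste(miss, collapse = ", ")),
          class = "tracerkit_schema_error")
  }
}

#' Read a metabolite annotation table
#'
#' Reads a delimited annotation table (CSV/TSV) with columns
#' `metabolite_id, name, formula, adduct, mz, rt, msi_level, feature_id`.
#' Rows whose formula cannot be parsed or whose adduct is outside the
#' reliable-adduct vocabulary (`[M+H]+`, `[M+Na]+`, `[M+NH4]+`, `[M-H]-`,
#' `[M+Cl]-`, `[M-H-H2O]-`)
#' are rejected and reported with their row numbers.
#'
#' @param path Path to the table.
#' @return A tibble of accepted annotation records; rejected rows (with a
#'   `reason` column) are available as `attr(x, "rejected")`.
#' @export
read_annotation_table <- function(path) {
  df <- as_tibble(read_delim_auto(path))
  req_cols(df, c("metabolite_id", "name", "formula", "adduct", "mz", "rt",
                 "msi_level", "feature_id"), "annotation table", path)
  df$adduct <- normalize_adduct(df$adduct)
  bad_adduct <- !(df$adduct %in% ADDUCTS$adduct)
  bad_formula <- map_lgl(df$formula, function(f) {
    inherits(tryCatch(parse_formula(f), error = function(e) e), "error")
  })
  bad_mz <- !(df$mz > 0)
  bad_rt <- !(df$rt >= 0)
  bad <- bad_adduct | bad_formula | bad_mz | bad_rt
  if (any(bad)) {
    reason <- dplyr::case_when(
      bad_adduct[bad] ~ "adduct not in reliable-adduct vocabulary",
      bad_formula[bad] ~ "unparseable formula",
      bad_mz[bad] ~ "non-positive m/z",
      TRUE ~ "negative retention time"
    )
    inform(sprintf("annotation table %s: rejected row(s) %s (%s)", path,
                   paste(which(bad), collapse = ", "),
                   paste(unique(reason), collapse = "; ")))
  }
  out <- df[!bad, ]
  attr(out, "rejected") <- bind_cols(df[bad, ],
                                     tibble(row = which(bad),
                                            reason = if (any(bad)) reason else character()))
  out
}

read_delim_auto <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else ","
  read.csv(path, sep = sep, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read an untargeted feature table
#'
#' One row per chromatographic feature from prior peak detection of the
#' unlabeled samples: `feature_id, mz, rt_apex, rt_min, rt_max` plus one
#' numeric column per unlabeled run holding the feature's peak height in
#' that run (column name = run id).
#'
#' @param path Path to the CSV/TSV table.
#' @return A tibble keyed by `feature_id`; per-sample height columns are
#'   gathered into a list-column `heights` of named numeric vectors.
#' @export
read_feature_table <- function(path) {
  df <- as_tibble(read_delim_auto(path))
  req_cols(df, c("feature_id", "mz", "rt_apex", "rt_min", "rt_max"),
           "feature table", path)
  if (anyDuplicated(df$feature_id)) {
    abort(sprintf("feature table %s: duplicate feature_id(s): %s", path,
                  paste(unique(df$feature_id[duplicated(df$feature_id)]), collapse = ", ")),
          class = "tracerkit_validation_error")
  }
  if (any(df$rt_min >= df$rt_max | df$rt_apex <= df$rt_min | df$rt_apex >= df$rt_max)) {
    abort(sprintf("feature table %s: rt bounds must satisfy rt_min < rt_apex < rt_max", path),
          class = "tracerkit_validation_error")
  }
  sample_cols <- setdiff(names(df), c("feature_id", "mz", "rt_apex", "rt_min", "rt_max"))
  heights <- map(seq_len(nrow(df)), function(i) {
    setNames(as.numeric(df[i, sample_cols]), sample_cols)
  })
  out <- df[, c("feature_id", "mz", "rt_apex", "rt_min", "rt_max")]
  out$heights <- heights
  out
}

#' Write / read a mass isotopomer distribution (MID) table
#'
#' The MID table is the pipeline's final output: one row per metabolite,
#' isotopologue and run, with columns `metabolite_id, isotopologue_index,
#' run_id, group, corrected_intensity, labeled_fraction`. Fractions must lie
#' in \[0, 1\]; the write/read round trip preserves doubles exactly.
#'
#' @param mids A tibble with the columns above.
#' @param path Output CSV path.
#' @return `path` invisibly (write); the tibble (read).
#' @export
write_mid_table <- function(mids, path) {
  req_cols(mids, c("metabolite_id", "isotopologue_index", "run_id", "group",
                   "corrected_intensity", "labeled_fraction"), "MID table", "in memory")
  f <- mids$labeled_fraction
  if (any(!is.na(f) & (f < 0 | f > 1))) {
    abort("labeled_fraction outside [0, 1]", class = "tracerkit_validation_error")
  }
  out <- mids[, c("metabolite_id", "isotopologue_index", "run_id", "group",
                  "corrected_intensity", "labeled_fraction")]
  out$corrected_intensity <- sprintf("%.17g", out$corrected_intensity)
  out$labeled_fraction <- sprintf("%.17g", out$labeled_fraction)
  write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_mid_table
#' @export
read_mid_table <- function(path) {
  df <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  req_cols(df, c("metabolite_id", "isotopologue_index", "run_id", "group",
                 "corrected_intensity", "labeled_fraction"), "MID table", path)
  df$isotopologue_index <- as.integer(df$isotopologue_index)
  df$corrected_intensity <- as.numeric(df$corrected_intensity)
  df$labeled_fraction <- as.numeric(df$labeled_fraction)
  df
}
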