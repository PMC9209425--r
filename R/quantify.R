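# Isotopologue quantification: 3-scan apex sums with mandatory extraction,
# natural 13C-abundance correction by non-negative least squares,
# contamination estimation from unlabeled controls, and labeled calling.

#' Apex intensity of one isotopologue
#'
#' The peak intensity proxy is the sum of the three scans around the apex
#' on the EIC grid. Isotopologues without a detected peak are extracted
#' mandatorily at the selected group's apex (or, failing that, at the
#' reference RT). Apexes at the grid edge sum the available scans and are
#' flagged.
#'
#' @param eic `tracer_eic` of the isotopologue over the extended window.
#' @param apex_rt Apex retention time (seconds) at which to integrate.
#' @return Numeric intensity with attributes `edge` (logical).
#' @export
apex_intensity <- function(eic, apex_rt) {
  if (!nrow(eic) || is.na(apex_rt)) return(structure(0, edge = FALSE))
  a <- which.min(abs(eic$rt - apex_rt))
  idx <- (a - 1L):(a + 1L)
  edge <- any(idx < 1L | idx > nrow(eic))
  idx <- idx[idx >= 1L & idx <= nrow(eic)]
  structure(sum(eic$intensity[idx]), edge = edge)
}

#' Quantify all isotopologues of one extracted metabolite
#'
#' @param extraction One row of the result of [extract_sample()] (list with
#'   `group` and `eics`).
#' @param target_rt Fallback apex RT when the group is empty.
#' @return Tibble: `isotopologue_index`, `intensity`, `mandatory`, `edge`.
#' @export
quantify_isotopologues <- function(extraction, target_rt) {
  grp <- extraction$group[[1]]
  eics <- extraction$eics[[1]]
  apex <- if (is.na(grp$apex_rt)) target_rt else grp$apex_rt
  list_rbind(imap(eics, function(e, j) {
    i <- j - 1L
    member <- if (nrow(grp$members)) {
      grp$members[grp$members$isotopologue_index == i, ]
    } else grp$members
    if (!is.null(member) && nrow(member)) {
      v <- apex_intensity(e, member$apex_rt[1])
      tibble(isotopologue_index = i, intensity = as.numeric(v),
             mandatory = FALSE, edge = attr(v, "edge"))
    } else {
      v <- apex_intensity(e, apex)
      tibble(isotopologue_index = i, intensity = as.numeric(v),
             mandatory = TRUE, edge = attr(v, "edge"))
    }
  }))
}

#' Natural-abundance (and tracer-purity) convolution matrix
#'
#' Column `j` (0-based: j labeled carbons) holds the probability
#' distribution of the observed mass shift when each of the `C - j`
#' unlabeled carbons is 13C with probability `p13` and each of the `j`
#' tracer-labeled carbons is 13C with probability `purity`. With
#' `purity = 1` this reduces to `A[i, j] = dbinom(i - j, C - j, p13)` for
#' `i >= j`. Columns sum to 1.
#'
#' @param C Carbon count of the metabolite.
#' @param p13 Natural 13C abundance (default 0.0107).
#' @param purity Tracer isotopic purity (default 1).
#' @return A `(C+1) x (C+1)` matrix.
#' @export
natural_abundance_matrix <- function(C, p13 = NATURAL_13C, purity = 1) {
  stopifnot(C >= 0, p13 >= 0, p13 < 1, purity > 0, purity <= 1)
  n <- C + 1L
  A <- matrix(0, n, n)
  for (j in 0:C) {
    nat <- dbinom(0:(C - j), C - j, p13)
    lab <- dbinom(0:j, j, purity)
    # total shift = (# 13C among labeled) + (# 13C among unlabeled)
    col <- rep(0, n)
    for (s in 0:j) {
      col[(s + 1):(s + 1 + C - j)] <- col[(s + 1):(s + 1 + C - j)] + lab[s + 1] * nat
    }
    A[, j + 1] <- col
  }
  A
}

#' Correct raw isotopologue intensities for natural 13C abundance
#'
#' Solves `min || A x - raw ||_2` subject to `x >= 0` (non-negative least
#' squares), where `A` is the [natural_abundance_matrix()]. The corrected
#' intensities `x` are normalized to the mass isotopomer distribution
#' (MID). All-zero input yields an all-zero MID, flagged.
#'
#' @param raw Numeric vector of raw intensities `I_M0..I_MC`.
#' @param p13,purity Passed to [natural_abundance_matrix()].
#' @return List with `corrected` (length C+1), `mid` (fractions summing to
#'   1, or all zeros), `zeroed` (logical).
#' @export
correct_natural_abundance <- function(raw, p13 = NATURAL_13C, purity = 1) {
  C <- length(raw) - 1L
  stopifnot(C >= 0)
  if (all(raw == 0)) {
    z <- rep(0, C + 1L)
    return(list(corrected = z, mid = z, zeroed = TRUE))
  }
  A <- natural_abundance_matrix(C, p13 = p13, purity = purity)
  x <- pracma::lsqnonneg(A, as.numeric(raw))$x
  s <- sum(x)
  if (s <= 0) {
    z <- rep(0, C + 1L)
    return(list(corrected = x, mid = z, zeroed = TRUE))
  }
  list(corrected = x, mid = x / s, zeroed = FALSE)
}

#' Estimate isotope contamination from unlabeled samples
#'
#' An isotopologue (other than M0) is called contaminated when its labeled
#' fraction exceeds `threshold` in strictly more than `majority` of the
#' unlabeled runs; its contamination level is then the mean labeled
#' fraction across unlabeled runs. A metabolite is flagged absent when its
#' M0 intensity is zero in strictly more than `majority` of unlabeled runs.
#'
#' @param unlabeled_mids Tibble with columns `metabolite_id`,
#'   `isotopologue_index`, `run_id`, `labeled_fraction`,
#'   `corrected_intensity` (unlabeled runs only).
#' @param threshold Contamination fraction threshold (default 0.02).
#' @param majority Majority fraction, strict (default 0.5).
#' @return Tibble `metabolite_id`, `isotopologue_index`, `contamination`
#'   plus per-metabolite attribute column `absent_in_unlabeled`.
#' @export
estimate_contamination <- function(unlabeled_mids, threshold = 0.02, majority = 0.5) {
  stopifnot(nrow(unlabeled_mids) > 0)
  iso <- unlabeled_mids |>
    group_by(.data$metabolite_id, .data$isotopologue_index) |>
    summarise(
      contamination = ifelse(
        .data$isotopologue_index[1] > 0 &&
          mean(.data$labeled_fraction > threshold) > majority,
        mean(.data$labeled_fraction), 0),
      .groups = "drop"
    )
  absent <- unlabeled_mids |>
    filter(.data$isotopologue_index == 0) |>
    group_by(.data$metabolite_id) |>
    summarise(absent_in_unlabeled = mean(.data$corrected_intensity == 0) > majority,
              .groups = "drop")
  left_join(iso, absent, by = "metabolite_id")
}

#' Subtract estimated contamination from labeled-sample MIDs
#'
#' Contaminated isotopologue fractions are reduced by the estimated level
#' (clamped at zero) and the subtracted mass is returned to M0 so each MID
#' still sums to one. Metabolites absent from the unlabeled samples have
#' all fractions set to zero.
#'
#' @param mids Tibble with `metabolite_id`, `isotopologue_index`, `run_id`,
#'   `labeled_fraction` (labeled runs).
#' @param profile Contamination profile from [estimate_contamination()].
#' @return `mids` with corrected `labeled_fraction` and logical columns
#'   `contamination_corrected`, `absent_in_unlabeled`.
#' @export
apply_contamination_correction <- function(mids, profile) {
  out <- left_join(
    mids,
    profile[, c("metabolite_id", "isotopologue_index", "contamination",
                "absent_in_unlabeled")],
    by = c("metabolite_id", "isotopologue_index")
  )
  out$contamination[is.na(out$contamination)] <- 0
  out$absent_in_unlabeled[is.na(out$absent_in_unlabeled)] <- FALSE
  out <- out |>
    group_by(.data$metabolite_id, .data$run_id) |>
    mutate(
      removed = pmin(.data$labeled_fraction, .data$contamination) *
        (.data$isotopologue_index > 0),
      labeled_fraction = dplyr::if_else(
        .data$absent_in_unlabeled, 0,
        .data$labeled_fraction - .data$removed +
          (.data$isotopologue_index == 0) * sum(.data$removed)),
      contamination_corrected = .data$removed > 0
    ) |>
    ungroup() |>
    select(-"removed", -"contamination")
  out
}

#' Call labeled isotopologues and metabolites
#'
#' An isotopologue (other than M0) is labeled when its fraction exceeds
#' `threshold` in strictly more than `majority` of the runs in one labeled
#' group; a metabolite is labeled when at least one of its non-M0
#' isotopologues is labeled.
#'
#' @param mids Tibble (`metabolite_id`, `isotopologue_index`, `run_id`,
#'   `labeled_fraction`) for one group of labeled runs.
#' @param threshold Labeling threshold (default 0.02).
#' @param majority Strict majority fraction (default 0.5).
#' @return List of tibbles `isotopologues` (`metabolite_id`,
#'   `isotopologue_index`, `labeled`) and `metabolites` (`metabolite_id`,
#'   `labeled`).
#' @export
call_labeled <- function(mids, threshold = 0.02, majority = 0.5) {
  stopifnot(nrow(mids) > 0)
  iso <- mids |>
    group_by(.data$metabolite_id, .data$isotopologue_index) |>
    summarise(labeled = .data$isotopologue_index[1] > 0 &&
                mean(.data$labeled_fraction > threshold) > majority,
              .groups = "drop")
  mets <- iso |>
    group_by(.data$metabolite_id) |>
    summarise(labeled = any(.data$labeled), .groups = "drop")
  list(isotopologues = iso, metabolites = mets)
}
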