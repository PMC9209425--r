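# Targeted isotopologue peak extraction: S/N filtering, Gaussian smoothing,
# Mexican-hat CWT ridge detection, peak-shape correlation (PPC), apex
# clustering and group selection.

gaussian_smooth <- function(y, sigma_scans = 1) {
  if (sigma_scans <= 0) return(y)
  half <- max(1L, ceiling(3 * sigma_scans))
  k <- exp(-((-half:half)^2) / (2 * sigma_scans^2))
  k <- k / sum(k)
  n <- length(y)
  ypad <- c(rep(y[1], half), y, rep(y[n], half))
  as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
}

ricker <- function(half, sigma) {
  x <- -half:half
  (1 - (x / sigma)^2) * exp(-x^2 / (2 * sigma^2))
}

#' Estimate noise and baseline of an EIC
#'
#' Noise is the median of nonzero intensities after excluding the top
#' decile; the baseline is the 10th percentile of nonzero intensities.
#' Both are robust to the presence of one or a few chromatographic peaks.
#'
#' @param intensity Numeric intensity vector.
#' @return List with elements `noise` and `baseline`.
#' @export
eic_noise <- function(intensity) {
  nz <- intensity[intensity > 0]
  if (!length(nz)) return(list(noise = 1, baseline = 0))
  kept <- nz[nz <= quantile(nz, 0.9)]
  noise <- if (length(kept)) median(kept) else median(nz)
  list(noise = max(noise, .Machine$double.eps), baseline = unname(quantile(nz, 0.1)))
}

#' Detect chromatographic peaks in one isotopologue EIC
#'
#' EICs whose maximum signal-to-noise ratio falls below `snr_min` yield no
#' candidates. Surviving traces are baseline-subtracted, Gaussian-smoothed
#' (kernel sigma = one scan interval by default) and scanned with a
#' Mexican-hat continuous wavelet transform over scales spanning the
#' expected chromatographic peak widths; ridge maxima become candidate
#' apexes whose boundaries are walked out to local minima.
#'
#' @param eic A `tracer_eic` from [extract_eic()].
#' @param peakwidth Expected chromatographic peak width range (seconds,
#'   roughly full width at half maximum), default `c(5, 30)`.
#' @param snr_min Minimum signal-to-noise ratio (default 3).
#' @param smooth_sigma Gaussian smoothing sigma in scan intervals.
#' @return A tibble of peak candidates: `apex_idx`, `apex_rt`, `rt_lo`,
#'   `rt_hi`, `apex_height` (raw intensity at apex), `snr`.
#' @export
detect_isotopologue_peaks <- function(eic, peakwidth = c(5, 30), snr_min = 3,
                                      smooth_sigma = 1) {
  empty <- tibble(apex_idx = integer(), apex_rt = numeric(), rt_lo = numeric(),
                  rt_hi = numeric(), apex_height = numeric(), snr = numeric())
  y <- eic$intensity
  n <- length(y)
  if (n < 5L || all(y == 0)) return(empty)
  nb <- eic_noise(y)
  if (max(y) / nb$noise < snr_min) return(empty)
  dt <- median(diff(eic$rt))
  ys <- gaussian_smooth(pmax(y - nb$baseline, 0), smooth_sigma)

  # CWT over scales covering peakwidth (FWHM -> sigma via 2.355)
  sig_lo <- peakwidth[1] / 2.355 / dt
  sig_hi <- peakwidth[2] / 2.355 / dt
  scales <- exp(seq(log(max(sig_lo, 1)), log(max(sig_hi, sig_lo + 0.5)), length.out = 8))
  cwt_max <- rep(-Inf, n)
  for (s in scales) {
    half <- min(ceiling(3 * s), n - 1L)
    k <- ricker(half, s)
    k <- k / sqrt(sum(k^2))
    ypad <- c(rep(0, half), ys, rep(0, half))
    cc <- as.numeric(stats::filter(ypad, k, sides = 2))[(half + 1):(half + n)]
    cwt_max <- pmax(cwt_max, cc, na.rm = TRUE)
  }

  # ridge apexes: local maxima of the best-scale CWT coefficient that clear
  # the S/N threshold on the raw trace
  is_max <- c(FALSE, diff(sign(diff(cwt_max))) < 0, FALSE) & cwt_max > 0
  apexes <- which(is_max & y >= snr_min * nb$noise)
  if (!length(apexes)) return(empty)

  # snap each apex to the local maximum of the smoothed trace
  apexes <- unique(map_int(apexes, function(a) {
    w <- max(1L, a - 3L):min(n, a + 3L)
    w[which.max(ys[w])]
  }))

  cands <- list_rbind(map(apexes, function(a) {
    # walk out to the first local minimum or to where the trace has decayed
    # to a negligible share of the apex
    floor_y <- 0.005 * ys[a]
    lo <- a
    while (lo > 1L && ys[lo - 1L] < ys[lo] && ys[lo] > floor_y) lo <- lo - 1L
    hi <- a
    while (hi < n && ys[hi + 1L] < ys[hi] && ys[hi] > floor_y) hi <- hi + 1L
    width <- eic$rt[hi] - eic$rt[lo]
    if (width < peakwidth[1] / 2 || width > peakwidth[2] * 2) return(NULL)
    tibble(apex_idx = a, apex_rt = eic$rt[a], rt_lo = eic$rt[lo], rt_hi = eic$rt[hi],
           apex_height = y[a], snr = y[a] / nb$noise)
  }))
  if (is.null(cands) || !nrow(cands)) return(empty)
  distinct(arrange(cands, dplyr::desc(.data$apex_height)), .data$apex_idx,
           .keep_all = TRUE)
}

#' Peak-peak correlation (PPC)
#'
#' Shape similarity between a detected isotopologue peak and the reference
#' (target) peak: both traces are shifted so their apexes coincide,
#' resampled onto a common grid spanning the union of the apex-centered
#' boundary windows (zero-filled outside each peak's own bounds), and the
#' Pearson correlation of the resampled vectors is returned. A constant
#' vector after resampling yields 0.
#'
#' @param cand_eic `tracer_eic` containing the candidate peak.
#' @param cand Single-row candidate tibble from
#'   [detect_isotopologue_peaks()] (`apex_rt`, `rt_lo`, `rt_hi`).
#' @param target_shape Reference EIC (its apex is its maximum; its bounds
#'   are its RT range).
#' @return PPC in \[-1, 1\].
#' @export
ppc_score <- function(cand_eic, cand, target_shape) {
  if (!nrow(cand_eic) || !nrow(target_shape)) {
    abort("ppc_score needs nonempty traces", class = "tracerkit_validation_error")
  }
  t_apex <- target_shape$rt[which.max(abs(target_shape$intensity))]
  windows <- rbind(
    c(cand$rt_lo - cand$apex_rt, cand$rt_hi - cand$apex_rt),
    c(min(target_shape$rt) - t_apex, max(target_shape$rt) - t_apex)
  )
  span <- c(min(windows[, 1]), max(windows[, 2]))
  du <- min(median(diff(cand_eic$rt)), median(diff(target_shape$rt)))
  grid <- seq(span[1], span[2], by = du)
  v1 <- resample_zero(cand_eic$rt - cand$apex_rt, cand_eic$intensity,
                      grid, windows[1, ])
  v2 <- resample_zero(target_shape$rt - t_apex, target_shape$intensity,
                      grid, windows[2, ])
  # a trace that is constant inside its own bounds carries no shape
  flat1 <- sd(v1[grid >= windows[1, 1] & grid <= windows[1, 2]]) == 0
  flat2 <- sd(v2[grid >= windows[2, 1] & grid <= windows[2, 2]]) == 0
  if (flat1 || flat2 || sd(v1) == 0 || sd(v2) == 0) {
    return(structure(0, flagged = TRUE))
  }
  cor(v1, v2)
}

resample_zero <- function(u, y, grid, bounds) {
  out <- rep(0, length(grid))
  inside <- grid >= bounds[1] & grid <= bounds[2]
  if (any(inside) && length(u) >= 2) {
    out[inside] <- approx(u, y, xout = grid[inside], rule = 2)$y
  }
  out
}

#' Cluster candidate apexes and select the isotopologue peak group
#'
#' Apex retention times of all (PPC-filtered) candidates across
#' isotopologue indices are clustered hierarchically (complete linkage,
#' tree cut at `apex_cutoff` seconds, so the maximum pairwise apex spread
#' within a group is bounded by the cutoff). The group whose mean apex RT
#' is closest to the target RT is selected; ties go to the group holding
#' the tallest peak. The selected group's apex and RT bounds are
#' re-adjusted to those of its tallest member, and at most one candidate
#' per isotopologue index (the tallest) is retained.
#'
#' @param candidates Tibble of candidates with columns `isotopologue_index`,
#'   `apex_rt`, `rt_lo`, `rt_hi`, `apex_height` (and anything else, carried
#'   through).
#' @param target_rt Reference retention time (seconds).
#' @param apex_cutoff Cluster tree cut height in seconds (default 3).
#' @return A list with `members` (tibble, possibly empty), `apex_rt`,
#'   `rt_lo`, `rt_hi` (NA when empty).
#' @export
group_and_select <- function(candidates, target_rt, apex_cutoff = 3) {
  if (is.null(candidates) || !nrow(candidates)) {
    return(list(members = tibble(), apex_rt = NA_real_,
                rt_lo = NA_real_, rt_hi = NA_real_))
  }
  cl <- if (nrow(candidates) == 1L) 1L else {
    cutree(hclust(dist(candidates$apex_rt), method = "complete"), h = apex_cutoff)
  }
  means <- tapply(candidates$apex_rt, cl, mean)
  d <- abs(means - target_rt)
  best <- as.integer(names(d)[d == min(d)])
  if (length(best) > 1L) {
    # tie: the cluster containing the tallest candidate
    tallest <- cl[which.max(candidates$apex_height)]
    best <- if (tallest %in% best) tallest else best[1]
  }
  members <- candidates[cl == best, ]
  members <- distinct(arrange(members, dplyr::desc(.data$apex_height)),
                      .data$isotopologue_index, .keep_all = TRUE)
  top <- members[which.max(members$apex_height), ]
  list(members = members, apex_rt = top$apex_rt,
       rt_lo = top$rt_lo, rt_hi = top$rt_hi)
}

#' Targeted extraction of one labeled run
#'
#' For every metabolite in the target list, extracts the EICs of all
#' isotopologues over the extended RT window (feature bounds widened by
#' `rt_extend` seconds), detects peaks in each trace (so the most intense
#' isotopologue, not necessarily M0, anchors detection in highly labeled
#' samples), filters by PPC against the reference shape, clusters apexes
#' and selects one isotopologue peak group per metabolite.
#'
#' @param run A [tracer_run()].
#' @param targets Target list from [build_target_list()].
#' @param rt_extend RT window extension in seconds (default 15).
#' @param snr_min Minimum S/N (default 3).
#' @param ppc_min Minimum PPC (default 0.6).
#' @param apex_cutoff Apex cluster cut height in seconds (default 3).
#' @param peakwidth Peak width range in seconds (default `c(5, 30)`).
#' @return A tibble with one row per metabolite: `metabolite_id`, `group`
#'   (list: members/apex/bounds), `eics` (list of per-isotopologue EICs),
#'   `n_detected`.
#' @export
extract_sample <- function(run, targets, rt_extend = 15, snr_min = 3,
                           ppc_min = 0.6, apex_cutoff = 3, peakwidth = c(5, 30)) {
  rows <- map(seq_len(nrow(targets)), function(i) {
    tg <- targets[i, ]
    window <- c(tg$rt_lo - rt_extend, tg$rt_hi + rt_extend)
    mzs <- tg$mz_series[[1]]
    eics <- map(mzs, extract_eic, run = run, rt_window = window)
    cands <- list_rbind(imap(eics, function(e, j) {
      d <- detect_isotopologue_peaks(e, peakwidth = peakwidth, snr_min = snr_min)
      if (!nrow(d)) return(NULL)
      d$isotopologue_index <- j - 1L
      d$ppc <- map_dbl(seq_len(nrow(d)), function(r) {
        as.numeric(ppc_score(e, d[r, ], tg$target_shape[[1]]))
      })
      d[d$ppc >= ppc_min, ]
    }))
    grp <- group_and_select(cands, tg$target_rt, apex_cutoff = apex_cutoff)
    tibble(metabolite_id = tg$metabolite_id, group = list(grp), eics = list(eics),
           n_detected = nrow(grp$members))
  })
  out <- list_rbind(rows)
  attr(out, "run_id") <- run$run_id
  out
}
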