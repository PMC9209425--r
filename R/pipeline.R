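#' Run the full isotope-tracing pipeline
#'
#' End-to-end workflow over in-memory runs: builds the isotopologue target
#' list from the unlabeled controls, performs targeted extraction and
#' quantification of every run, corrects for natural 13C abundance by
#' non-negative least squares, estimates isotope contamination from the
#' unlabeled samples and (optionally) subtracts it, and calls labeled
#' isotopologues and metabolites per labeled group.
#'
#' @param runs Named list of [tracer_run()] objects (unlabeled and labeled).
#' @param run_groups Tibble `run_id`, `group`; runs with group
#'   `"unlabeled"` are the controls, all other groups are labeled.
#' @param annotations Annotation tibble ([read_annotation_table()] format).
#' @param features Feature tibble ([read_feature_table()] format).
#' @param p13 Natural 13C abundance (default 0.0107).
#' @param purity Tracer isotopic purity (default 1).
#' @param correct_iso Apply natural-abundance correction (default `TRUE`).
#' @param adj_contaminate Subtract contamination estimated from unlabeled
#'   samples (default `TRUE`).
#' @param label_threshold Labeled-fraction threshold (default 0.02).
#' @param majority Strict majority fraction for calling (default 0.5).
#' @param rt_extend,snr_min,ppc_min,apex_cutoff,peakwidth Extraction
#'   parameters, see [extract_sample()].
#' @return Object of class `tracer_result`: list with `targets`, `quant`
#'   (raw 3-scan intensities), `mids` (final MID table), `mids_uncorrected`
#'   (before contamination subtraction), `contamination`, `calls`
#'   (`metabolites`, `isotopologues`, `by_group`), `params`.
#' @export
run_tracer_pipeline <- function(runs, run_groups, annotations, features,
                                p13 = NATURAL_13C, purity = 1,
                                correct_iso = TRUE, adj_contaminate = TRUE,
                                label_threshold = 0.02, majority = 0.5,
                                rt_extend = 15, snr_min = 3, ppc_min = 0.6,
                                apex_cutoff = 3, peakwidth = c(5, 30)) {
  stopifnot(all(run_groups$run_id %in% names(runs)))
  ul_ids <- run_groups$run_id[run_groups$group == "unlabeled"]
  if (!length(ul_ids)) {
    abort("at least one run with group 'unlabeled' is required",
          class = "tracerkit_validation_error")
  }
  targets <- build_target_list(annotations, features, runs[ul_ids])

  quant <- list_rbind(map(seq_len(nrow(run_groups)), function(ri) {
    run <- runs[[run_groups$run_id[ri]]]
    ext <- extract_sample(run, targets, rt_extend = rt_extend,
                          snr_min = snr_min, ppc_min = ppc_min,
                          apex_cutoff = apex_cutoff, peakwidth = peakwidth)
    list_rbind(map(seq_len(nrow(ext)), function(i) {
      q <- quantify_isotopologues(ext[i, ], targets$target_rt[i])
      q$metabolite_id <- ext$metabolite_id[i]
      q$run_id <- run_groups$run_id[ri]
      q$group <- run_groups$group[ri]
      q
    }))
  }))

  mids <- quant |>
    group_by(.data$metabolite_id, .data$run_id, .data$group) |>
    dplyr::group_modify(function(d, key) {
      d <- arrange(d, .data$isotopologue_index)
      if (correct_iso) {
        cr <- correct_natural_abundance(d$intensity, p13 = p13, purity = purity)
        d$corrected_intensity <- cr$corrected
        d$labeled_fraction <- cr$mid
      } else {
        s <- sum(d$intensity)
        d$corrected_intensity <- d$intensity
        d$labeled_fraction <- if (s > 0) d$intensity / s else rep(0, nrow(d))
      }
      d
    }) |>
    ungroup()

  ul_mids <- filter(mids, .data$group == "unlabeled")
  profile <- estimate_contamination(ul_mids, threshold = label_threshold,
                                    majority = majority)
  mids_uncorrected <- mids
  if (adj_contaminate) {
    mids <- apply_contamination_correction(mids, profile)
  }

  lab_groups <- setdiff(unique(run_groups$group), "unlabeled")
  by_group <- map(setNames(lab_groups, lab_groups), function(g) {
    call_labeled(filter(mids, .data$group == g),
                 threshold = label_threshold, majority = majority)
  })
  metabolites <- if (length(by_group)) {
    list_rbind(map(by_group, ~ .x$metabolites)) |>
      group_by(.data$metabolite_id) |>
      summarise(labeled = any(.data$labeled), .groups = "drop")
  } else tibble(metabolite_id = targets$metabolite_id, labeled = FALSE)
  isotopologues <- if (length(by_group)) {
    list_rbind(map(by_group, ~ .x$isotopologues)) |>
      group_by(.data$metabolite_id, .data$isotopologue_index) |>
      summarise(labeled = any(.data$labeled), .groups = "drop")
  } else NULL

  out <- list(
    targets = targets, quant = quant, mids = mids,
    mids_uncorrected = mids_uncorrected, contamination = profile,
    calls = list(metabolites = metabolites, isotopologues = isotopologues,
                 by_group = by_group),
    params = list(p13 = p13, purity = purity, correct_iso = correct_iso,
                  adj_contaminate = adj_contaminate,
                  label_threshold = label_threshold, majority = majority,
                  rt_extend = rt_extend, snr_min = snr_min, ppc_min = ppc_min,
                  apex_cutoff = apex_cutoff, peakwidth = peakwidth)
  )
  class(out) <- "tracer_result"
  out
}

#' @export
print.tracer_result <- function(x, ...) {
  cat(sprintf("<tracer_result> %d metabolites, %d runs; %d called labeled\n",
              nrow(x$targets), length(unique(x$mids$run_id)),
              sum(x$calls$metabolites$labeled)))
  invisible(x)
}

#' @export
tidy.tracer_result <- function(x, ...) {
  select(x$mids, "metabolite_id", "isotopologue_index", "run_id", "group",
         "corrected_intensity", "labeled_fraction")
}

#' @export
glance.tracer_result <- function(x, ...) {
  tibble(n_metabolites = nrow(x$targets),
         n_runs = length(unique(x$mids$run_id)),
         n_labeled = sum(x$calls$metabolites$labeled),
         n_contaminated = sum(x$contamination$contamination > 0),
         correct_iso = x$params$correct_iso,
         adj_contaminate = x$params$adj_contaminate)
}

#' Labeling-extent table of a pipeline result
#'
#' @param result A `tracer_result`.
#' @param times Optional tibble `group`, `time` (hours) mapping labeled
#'   groups to labeling times; when given, the output gains a `time`
#'   column ready for [fit_labeling_rates()].
#' @return Tibble `metabolite_id`, `run_id`, `group`, `le` (and `time`).
#' @export
result_le_table <- function(result, times = NULL) {
  le <- labeling_extent_table(filter(result$mids, .data$group != "unlabeled"))
  if (!is.null(times)) le <- left_join(le, times, by = "group")
  le
}

#' Plot corrected isotopologue fractions of one metabolite
#'
#' @param result A `tracer_result`.
#' @param metabolite_id Metabolite to plot.
#' @return A ggplot: mean labeled fraction per isotopologue, faceted by
#'   group.
#' @export
plot_mid <- function(result, metabolite_id) {
  d <- result$mids |>
    filter(.data$metabolite_id == !!metabolite_id) |>
    group_by(.data$group, .data$isotopologue_index) |>
    summarise(fraction = mean(.data$labeled_fraction), .groups = "drop")
  ggplot(d, aes(x = .data$isotopologue_index, y = .data$fraction)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~group) +
    labs(x = "isotopologue (M+i)", y = "corrected fraction",
         title = metabolite_id) +
    theme_minimal()
}
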