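# Ground-truthed synthetic LC-MS scenario generator. Isotopologue envelopes
# are rendered as Gaussian chromatographic peaks at their theoretical m/z,
# with per-time-point MIDs following first-order labeling kinetics,
# convolved with natural 13C abundance, plus baseline, noise, optional
# contaminated isotopologues and co-eluting interferences.

# Formula pool for the default roster: common central-carbon metabolites.
ROSTER_POOL <- tibble::tribble(
  ~name, ~formula,
  "glucose", "C6H12O6", "pyruvate", "C3H4O3", "lactate", "C3H6O3",
  "alanine", "C3H7NO2", "serine", "C3H7NO3", "glycine", "C2H5NO2",
  "aspartate", "C4H7NO4", "glutamate", "C5H9NO4", "citrate", "C6H8O7",
  "succinate", "C4H6O4", "malate", "C4H6O5", "fumarate", "C4H4O4",
  "2-oxoglutarate", "C5H6O5", "glutamine", "C5H10N2O3",
  "asparagine", "C4H8N2O3", "proline", "C5H9NO2", "valine", "C5H11NO2",
  "leucine", "C6H13NO2", "threonine", "C4H9NO3", "methionine", "C5H11NO2S",
  "phenylalanine", "C9H11NO2", "tyrosine", "C9H11NO3",
  "tryptophan", "C11H12N2O2", "histidine", "C6H9N3O2",
  "lysine", "C6H14N2O2", "arginine", "C6H14N4O2",
  "ribose 5-phosphate", "C5H11O8P", "glucose 6-phosphate", "C6H13O9P",
  "glycerol 3-phosphate", "C3H9O6P", "AMP", "C10H14N5O7P",
  "IMP", "C10H13N4O8P", "inosine", "C10H12N4O5", "adenosine", "C10H13N5O4",
  "adenine", "C5H5N5", "guanine", "C5H5N5O", "hypoxanthine", "C5H4N4O",
  "uracil", "C4H4N2O2", "uridine", "C9H12N2O6", "citrulline", "C6H13N3O3",
  "ornithine", "C5H12N2O2", "taurine", "C2H7NO3S", "creatine", "C4H9N3O2",
  "carnitine", "C7H15NO3", "pantothenate", "C9H17NO5"
)

#' Define a synthetic tracing scenario
#'
#' Builds the specification of a synthetic continuous-labeling experiment:
#' a metabolite roster with chromatographic and kinetic ground truth, the
#' labeling time course, replication, and the noise model. Defaults mirror
#' a typical continuous [U-13C]glucose feeding design: time points 0, 1, 3,
#' 6, 12, 24 h with 10 replicates per point plus unlabeled controls, 0.5 s
#' scan interval, 3 s chromatographic peak sigma, 10% multiplicative
#' intensity CV and an additive baseline.
#'
#' @param n_metabolites Number of metabolites (default 50); drawn from a
#'   built-in roster of central-carbon metabolites, padded with synthetic
#'   formulas if needed.
#' @param time_points Labeling times in hours.
#' @param replicates Labeled replicates per time point (default 10).
#' @param n_unlabeled Number of unlabeled control runs (default
#'   `replicates`).
#' @param labeled If `FALSE`, only unlabeled runs are generated.
#' @param mid_mode `"full"` places all labeled mass on the fully labeled
#'   isotopologue MC; `"spread"` distributes it binomially over M1..MC.
#' @param cv Multiplicative (log-normal) CV on isotopologue peak areas.
#' @param baseline Additive chromatographic baseline level (counts).
#' @param noise_sd Additive scan-noise standard deviation (counts).
#' @param contaminants Optional tibble `metabolite_id`,
#'   `isotopologue_index`, `fraction`: constant isotope contamination
#'   present in all runs including unlabeled controls.
#' @param interferences Optional tibble `mz`, `rt`, `sigma`, `height`:
#'   co-eluting decoy peaks.
#' @param peak_sigma Chromatographic peak sigma in seconds.
#' @param scan_interval Scan interval in seconds.
#' @param p13 Natural 13C abundance used for the truth convolution.
#' @param seed Integer seed; the whole scenario is reproducible from it.
#' @return Object of class `scenario_spec`.
#' @export
scenario_spec <- function(n_metabolites = 50,
                          time_points = c(0, 1, 3, 6, 12, 24),
                          replicates = 10,
                          n_unlabeled = replicates,
                          labeled = TRUE,
                          mid_mode = c("full", "spread"),
                          cv = 0.1,
                          baseline = 200,
                          noise_sd = 50,
                          contaminants = NULL,
                          interferences = NULL,
                          peak_sigma = 3,
                          scan_interval = 0.5,
                          p13 = NATURAL_13C,
                          seed = 1) {
  mid_mode <- match.arg(mid_mode)
  stopifnot(n_metabolites >= 1, replicates >= 1, n_unlabeled >= 1)
  set.seed(seed)
  pool <- ROSTER_POOL
  if (n_metabolites > nrow(pool)) {
    extra <- n_metabolites - nrow(pool)
    nC <- sample(3:12, extra, replace = TRUE)
    pool <- bind_rows(pool, tibble(
      name = sprintf("synthetic-%02d", seq_len(extra)),
      formula = sprintf("C%dH%dO%d", nC, 2 * nC, pmax(2, nC - 2))
    ))
  }
  roster <- pool[seq_len(n_metabolites), ]
  roster$metabolite_id <- sprintf("MET%03d", seq_len(n_metabolites))
  roster$adduct <- "[M-H]-"
  roster$feature_id <- sprintf("F%04d", seq_len(n_metabolites))
  slots <- sample(seq_len(n_metabolites))
  roster$rt <- 90 + (slots - 1) * 9 + runif(n_metabolites, -1.5, 1.5)
  roster$peak_sigma <- peak_sigma
  roster$base_intensity <- 10^runif(n_metabolites, 5, 6.3)
  roster$a <- -runif(n_metabolites, 0.2, 0.95)
  roster$k <- runif(n_metabolites, 0.05, 1.0)
  roster$carbon_count <- map_int(roster$formula,
                                 ~ carbon_count(parse_formula(.x)))
  structure(
    list(roster = roster, time_points = if (labeled) time_points else numeric(),
         replicates = replicates, n_unlabeled = n_unlabeled,
         mid_mode = mid_mode, cv = cv, baseline = baseline, noise_sd = noise_sd,
         contaminants = contaminants, interferences = interferences,
         peak_sigma = peak_sigma, scan_interval = scan_interval,
         p13 = p13, seed = seed),
    class = "scenario_spec"
  )
}

# Tracer-space truth MID for one metabolite at labeling extent `le`.
truth_mid <- function(le, C, mode = "full", contamination = NULL) {
  mid <- numeric(C + 1)
  if (C == 0 || le <= 0) {
    mid[1] <- 1
  } else if (mode == "full") {
    mid[1] <- 1 - le
    mid[C + 1] <- le
  } else {
    # per-carbon enrichment e such that 1 - (1 - e)^C = le
    e <- 1 - (1 - le)^(1 / C)
    mid <- dbinom(0:C, C, e)
  }
  if (!is.null(contamination) && nrow(contamination)) {
    for (i in seq_len(nrow(contamination))) {
      j <- contamination$isotopologue_index[i]
      f <- min(contamination$fraction[i], mid[1])
      mid[j + 1] <- mid[j + 1] + f
      mid[1] <- mid[1] - f
    }
  }
  mid
}

#' Generate the ground-truth manifest of a scenario
#'
#' Evaluates the first-order labeling model `LE(t) = a exp(-kt) - a` for
#' every metabolite and time point, builds tracer-space truth MIDs
#' (labeled mass on MC by default), convolves them with natural abundance
#' to measured-space envelopes, and lays out the run table (labeled
#' time-course replicates plus unlabeled controls), the annotation table
#' and the feature table the pipeline consumes.
#'
#' @param spec A [scenario_spec()].
#' @return Object of class `tracer_manifest`: list with `spec`, `runs`
#'   (run table), `truth` (per metabolite x time: `le_true`, list-columns
#'   `mid_tracer`, `mid_measured`), `annotations`, `features`.
#' @export
generate_scenario <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  r <- spec$roster
  times <- c(spec$time_points)
  truth <- list_rbind(map(seq_len(nrow(r)), function(i) {
    C <- r$carbon_count[i]
    A <- natural_abundance_matrix(C, p13 = spec$p13)
    cont <- if (!is.null(spec$contaminants)) {
      spec$contaminants[spec$contaminants$metabolite_id == r$metabolite_id[i], ]
    }
    list_rbind(map(c(NA_real_, times), function(tt) {
      le <- if (is.na(tt)) 0 else -r$a[i] * (1 - exp(-r$k[i] * tt))
      mid <- truth_mid(le, C, spec$mid_mode, cont)
      tibble(metabolite_id = r$metabolite_id[i], time = tt,
             le_true = 1 - mid[1],
             mid_tracer = list(mid), mid_measured = list(as.numeric(A %*% mid)))
    }))
  }))
  runs <- bind_rows(
    tibble(run_id = sprintf("UL%02d", seq_len(spec$n_unlabeled)),
           group = "unlabeled", time = NA_real_,
           replicate = seq_len(spec$n_unlabeled)),
    if (length(times)) list_rbind(map(seq_along(times), function(j) {
      tibble(run_id = sprintf("T%02d_R%02d", j, seq_len(spec$replicates)),
             group = sprintf("%gh", times[j]), time = times[j],
             replicate = seq_len(spec$replicates))
    }))
  )
  annotations <- tibble(
    metabolite_id = r$metabolite_id, name = r$name, formula = r$formula,
    adduct = r$adduct,
    mz = map_dbl(seq_len(nrow(r)),
                 ~ isotopologue_mz_series(r$formula[.x], r$adduct[.x])[1]),
    rt = r$rt, msi_level = 1L, feature_id = r$feature_id
  )
  features <- tibble(
    feature_id = r$feature_id, mz = annotations$mz, rt_apex = r$rt,
    rt_min = r$rt - 3 * r$peak_sigma, rt_max = r$rt + 3 * r$peak_sigma,
    heights = map(r$base_intensity, ~ setNames(rep(.x, spec$n_unlabeled),
                                               sprintf("UL%02d", seq_len(spec$n_unlabeled))))
  )
  structure(list(spec = spec, runs = runs, truth = truth,
                 annotations = annotations, features = features),
            class = "tracer_manifest")
}

#' @export
print.tracer_manifest <- function(x, ...) {
  cat(sprintf("<tracer_manifest> %d metabolites, %d runs (%d unlabeled), %d time points\n",
              nrow(x$spec$roster), nrow(x$runs),
              sum(x$runs$group == "unlabeled"), length(x$spec$time_points)))
  invisible(x)
}

#' Render the LC-MS runs of a scenario
#'
#' Renders every run in the manifest as centroided MS1 scans: each
#' isotopologue becomes a Gaussian chromatographic peak at its theoretical
#' m/z with apex height proportional to its measured-space abundance,
#' multiplied by log-normal noise (CV from the spec); an additive baseline
#' with Gaussian scan noise covers each metabolite's neighbourhood; decoy
#' interference peaks are added last. Deterministic given the spec seed.
#'
#' @param manifest A `tracer_manifest` from [generate_scenario()].
#' @param dir Optional directory; when given, each run is also written as
#'   mzML.
#' @return Named list of [tracer_run()] objects (names = run ids).
#' @export
render_runs <- function(manifest, dir = NULL) {
  spec <- manifest$spec
  r <- spec$roster
  mz_series <- map(seq_len(nrow(r)),
                   ~ isotopologue_mz_series(r$formula[.x], r$adduct[.x]))
  rt_max <- max(r$rt) + 60
  grid <- seq(0, rt_max, by = spec$scan_interval)
  runs <- map(seq_len(nrow(manifest$runs)), function(ri) {
    meta <- manifest$runs[ri, ]
    set.seed(spec$seed * 10000L + ri)
    rows <- map(seq_len(nrow(r)), function(i) {
      tr <- manifest$truth
      tr <- tr[tr$metabolite_id == r$metabolite_id[i] &
                 (if (is.na(meta$time)) is.na(tr$time) else !is.na(tr$time) & tr$time == meta$time), ]
      env <- tr$mid_measured[[1]]
      near <- which(abs(grid - r$rt[i]) <= 50)
      peak <- which(abs(grid - r$rt[i]) <= 4 * r$peak_sigma[i])
      shape <- exp(-(grid[peak] - r$rt[i])^2 / (2 * r$peak_sigma[i]^2))
      list_rbind(map(seq_along(env), function(j) {
        h <- r$base_intensity[i] * env[j] *
          rlnorm(1, -log(1 + spec$cv^2) / 2, sqrt(log(1 + spec$cv^2)))
        sig <- numeric(length(near))
        sig[match(peak, near)] <- h * shape
        intens <- sig + spec$baseline + rnorm(length(near), 0, spec$noise_sd)
        keep <- intens > 0
        if (!any(keep)) return(NULL)
        tibble(scan = near[keep],
               mz = mz_series[[i]][j] * (1 + rnorm(sum(keep), 0, 2e-6)),
               intensity = intens[keep])
      }))
    })
    rows <- list_rbind(rows)
    if (!is.null(spec$interferences) && nrow(spec$interferences)) {
      intf <- list_rbind(map(seq_len(nrow(spec$interferences)), function(q) {
        it <- spec$interferences[q, ]
        w <- which(abs(grid - it$rt) <= 4 * it$sigma)
        if (!length(w)) return(NULL)
        tibble(scan = w, mz = it$mz,
               intensity = it$height * exp(-(grid[w] - it$rt)^2 / (2 * it$sigma^2)))
      }))
      rows <- bind_rows(rows, intf)
    }
    run <- tracer_run(meta$run_id, grid, rows, polarity = "negative")
    if (!is.null(dir)) {
      write_raw_run(run, file.path(dir, paste0(meta$run_id, ".mzML")))
    }
    run
  })
  setNames(runs, manifest$runs$run_id)
}

#' Score pipeline output against the ground truth
#'
#' Compares a pipeline result with the generating manifest: recall and
#' precision of labeled-metabolite calling, the root-mean-square error of
#' corrected isotopologue fractions against the tracer-space truth, and
#' (when kinetic fits are supplied) relative errors of recovered rate
#' constants.
#'
#' @param result Pipeline result from [run_tracer_pipeline()].
#' @param manifest The generating `tracer_manifest`.
#' @param fits Optional tibble from [fit_labeling_rates()].
#' @return List with `recall`, `precision`, `mid_rmse`, and tibbles
#'   `metabolites` (call vs truth) and `k_recovery` (when `fits` given).
#' @export
evaluate_recovery <- function(result, manifest, fits = NULL) {
  spec <- manifest$spec
  final_t <- max(spec$time_points)
  truly <- manifest$truth |>
    filter(!is.na(.data$time), .data$time == final_t) |>
    mutate(true_labeled = .data$le_true > 0.02) |>
    select("metabolite_id", "true_labeled")
  calls <- result$calls$metabolites
  if (length(setdiff(calls$metabolite_id, truly$metabolite_id))) {
    abort("metabolite ids in result do not match the manifest",
          class = "tracerkit_validation_error")
  }
  mets <- inner_join(calls, truly, by = "metabolite_id")
  tp <- sum(mets$labeled & mets$true_labeled)
  recall <- tp / sum(mets$true_labeled)
  precision <- if (sum(mets$labeled)) tp / sum(mets$labeled) else NA_real_
  truth_long <- manifest$truth |>
    filter(!is.na(.data$time)) |>
    mutate(truth = map2(.data$metabolite_id, .data$mid_tracer, function(id, mid) {
      tibble(isotopologue_index = seq_along(mid) - 1L, true_fraction = mid)
    })) |>
    select("metabolite_id", "time", "truth") |>
    tidyr::unnest("truth")
  obs <- result$mids |>
    filter(.data$group != "unlabeled") |>
    left_join(manifest$runs[, c("run_id", "time")], by = "run_id") |>
    inner_join(truth_long, by = c("metabolite_id", "time", "isotopologue_index"))
  mid_rmse <- sqrt(mean((obs$labeled_fraction - obs$true_fraction)^2))
  out <- list(recall = recall, precision = precision, mid_rmse = mid_rmse,
              metabolites = mets)
  if (!is.null(fits)) {
    out$k_recovery <- inner_join(
      fits[, c("metabolite_id", "k", "r", "converged")],
      spec$roster[, c("metabolite_id", "a", "k")] |>
        rename(a_true = "a", k_true = "k"),
      by = "metabolite_id") |>
      mutate(k_rel_err = abs(.data$k - .data$k_true) / .data$k_true)
  }
  out
}
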