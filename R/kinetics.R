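# Labeling-extent and labeling-rate quantification. Time is in hours in
# this module; conversion from chromatographic seconds happens upstream.

#' Labeling extent of one metabolite
#'
#' The labeling extent LE = 1 - L_M0: the total fraction of the metabolite
#' pool carrying at least one tracer carbon. It depends only on the M0
#' fraction, not on how labeled mass is distributed among M1..MC. An
#' all-zero MID (metabolite zeroed out) yields `NA`, not 0.
#'
#' @param mid Numeric MID vector (fractions summing to 1, or all zeros).
#' @return LE in \[0, 1\], or `NA_real_` for an all-zero MID.
#' @export
#' @examples
#' labeling_extent(c(0.16, 0, 0, 0.84))
labeling_extent <- function(mid) {
  if (all(mid == 0)) return(NA_real_)
  1 - mid[1] / sum(mid)
}

#' Labeling extents from a MID table
#'
#' @param mids Long MID tibble (`metabolite_id`, `isotopologue_index`,
#'   `run_id`, `group`, `labeled_fraction`).
#' @return Tibble `metabolite_id`, `run_id`, `group`, `le`.
#' @export
labeling_extent_table <- function(mids) {
  mids |>
    group_by(.data$metabolite_id, .data$run_id, .data$group) |>
    summarise(le = labeling_extent(
      .data$labeled_fraction[order(.data$isotopologue_index)]),
      .groups = "drop")
}

#' Fit the first-order labeling model
#'
#' Fits `LE(t) = a * exp(-k * t) - a` with `a < 0` by nonlinear least
#' squares; `-a` is the plateau labeling extent and `k` (1/h) the apparent
#' first-order rate of tracer incorporation. Replicate LE values are
#' averaged per time point before fitting. The goodness of fit `R` is the
#' Pearson correlation between observed and fitted LE; fits with `R <= 0.8`
#' are flagged unreliable.
#'
#' @param t Time points in hours (>= 3 distinct values).
#' @param le Labeling extents, same length as `t`; `NA`s dropped.
#' @param r_min Reliability threshold on R (default 0.8).
#' @return Object of class `kinetic_fit`: list with `a`, `k`, `r`,
#'   `plateau`, `converged`, `reliable`, `data` (per-time-point means) and
#'   the underlying `nls` fit (or `NULL`).
#' @export
fit_labeling_rate <- function(t, le, r_min = 0.8) {
  keep <- !is.na(le) & !is.na(t)
  t <- t[keep]; le <- le[keep]
  if (length(unique(t)) < 3L) {
    abort("kinetic fitting needs at least 3 distinct time points",
          class = "tracerkit_validation_error")
  }
  d <- tibble(t = t, le = le) |>
    group_by(t) |>
    summarise(le = mean(.data$le), .groups = "drop") |>
    arrange(t)

  out <- list(a = NA_real_, k = NA_real_, r = NA_real_, plateau = NA_real_,
              converged = FALSE, reliable = FALSE, data = d, fit = NULL)
  class(out) <- "kinetic_fit"
  if (max(d$le) <= 0) return(out)  # never labeled: non-identifiable

  a0 <- -min(max(max(d$le) * 1.05, 0.05), 0.99)
  # initial rate from log-linear decay of the unlabeled residual
  z <- 1 - d$le / (-a0)
  ok <- z > 1e-6 & d$t > 0
  k0 <- if (sum(ok) >= 2) {
    max(1e-3, -unname(coef(stats::lm(log(z[ok]) ~ 0 + d$t[ok]))[1]))
  } else 0.1
  fit <- tryCatch(
    minpack.lm::nlsLM(le ~ a * exp(-k * t) - a, data = d,
                      start = list(a = a0, k = k0),
                      lower = c(a = -1 + 1e-9, k = 1e-9),
                      upper = c(a = -1e-9, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  cf <- coef(fit)
  pred <- fitted(fit)
  r <- if (sd(pred) == 0 || sd(d$le) == 0) 0 else cor(d$le, pred)
  out$a <- unname(cf["a"]); out$k <- unname(cf["k"])
  out$plateau <- -out$a
  out$r <- r
  out$converged <- TRUE
  out$reliable <- r > r_min
  out$fit <- fit
  out
}

#' @export
print.kinetic_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf("<kinetic_fit> a = %.4f, k = %.4f 1/h, plateau = %.4f, R = %.4f%s\n",
                x$a, x$k, x$plateau, x$r,
                if (x$reliable) "" else " (unreliable)"))
  } else {
    cat("<kinetic_fit> not converged\n")
  }
  invisible(x)
}

#' @export
tidy.kinetic_fit <- function(x, ...) {
  tibble(term = c("a", "k"), estimate = c(x$a, x$k))
}

#' @export
glance.kinetic_fit <- function(x, ...) {
  tibble(a = x$a, k = x$k, plateau = x$plateau, r = x$r,
         converged = x$converged, reliable = x$reliable,
         n_timepoints = nrow(x$data))
}

#' @export
augment.kinetic_fit <- function(x, ...) {
  d <- x$data
  d$.fitted <- if (x$converged) x$a * exp(-x$k * d$t) - x$a else NA_real_
  d
}

#' Fit labeling rates for every metabolite in an LE table
#'
#' @param le_table Tibble `metabolite_id`, `time` (hours), `le`.
#' @param r_min Reliability threshold (default 0.8).
#' @return Tibble with one row per metabolite (`a`, `k`, `plateau`, `r`,
#'   `converged`, `reliable`) and a list-column `fit`.
#' @export
fit_labeling_rates <- function(le_table, r_min = 0.8) {
  le_table |>
    group_by(.data$metabolite_id) |>
    dplyr::group_modify(function(d, key) {
      f <- tryCatch(fit_labeling_rate(d$time, d$le, r_min = r_min),
                    error = function(e) NULL)
      if (is.null(f)) {
        tibble(a = NA_real_, k = NA_real_, plateau = NA_real_, r = NA_real_,
               converged = FALSE, reliable = FALSE, fit = list(NULL))
      } else {
        bind_cols(glance(f)[, c("a", "k", "plateau", "r", "converged", "reliable")],
                  tibble(fit = list(f)))
      }
    }) |>
    ungroup()
}

#' Pathway-level labeling summaries
#'
#' The labeling rate of a pathway is the median labeling rate of its
#' labeled member metabolites; the labeling extent of a pathway is the mean
#' labeling extent of its members. Empty pathways are omitted.
#'
#' @param fits Tibble with `metabolite_id` and `k` (e.g. from
#'   [fit_labeling_rates()]); may be `NULL`.
#' @param les Tibble with `metabolite_id` and `le`; may be `NULL`.
#' @param pathway_map Tibble `pathway_id`, `metabolite_id` (KEGG-style
#'   membership).
#' @return Tibble `pathway_id`, `n_members`, `k_median`, `le_mean`.
#' @export
summarize_pathway <- function(fits = NULL, les = NULL, pathway_map) {
  base <- pathway_map |> distinct(.data$pathway_id, .data$metabolite_id)
  ks <- if (!is.null(fits)) {
    inner_join(base, fits[, c("metabolite_id", "k")], by = "metabolite_id") |>
      group_by(.data$pathway_id) |>
      summarise(n_k = sum(!is.na(.data$k)),
                k_median = median(.data$k, na.rm = TRUE), .groups = "drop")
  }
  ls <- if (!is.null(les)) {
    inner_join(base, les[, c("metabolite_id", "le")], by = "metabolite_id") |>
      group_by(.data$pathway_id) |>
      summarise(n_le = sum(!is.na(.data$le)),
                le_mean = mean(.data$le, na.rm = TRUE), .groups = "drop")
  }
  out <- base |> group_by(.data$pathway_id) |>
    summarise(n_members = dplyr::n_distinct(.data$metabolite_id), .groups = "drop")
  if (!is.null(ks)) out <- left_join(out, ks, by = "pathway_id")
  if (!is.null(ls)) out <- left_join(out, ls, by = "pathway_id")
  out[out$n_members > 0, ]
}

#' Normalize labeled fractions to the tracer's reference isotopologue
#'
#' Divides each sample's labeled fraction by the same sample's tracer
#' fraction (e.g. glucose M+6). Samples whose reference fraction is zero or
#' missing yield `NA` and are reported.
#'
#' @param fractions Tibble with `run_id` and `value` (a labeled fraction
#'   per sample).
#' @param tracer_fraction Tibble with `run_id` and `reference` (the tracer
#'   isotopologue's fraction per sample).
#' @return `fractions` with an added `normalized` column.
#' @export
normalize_to_tracer <- function(fractions, tracer_fraction) {
  out <- left_join(fractions, tracer_fraction[, c("run_id", "reference")],
                   by = "run_id")
  bad <- is.na(out$reference) | out$reference <= 0
  if (any(bad)) {
    inform(sprintf("tracer normalization: %d sample(s) with zero/missing reference: %s",
                   sum(bad), paste(unique(out$run_id[bad]), collapse = ", ")))
  }
  out$normalized <- ifelse(bad, NA_real_, out$value / out$reference)
  select(out, -"reference")
}

#' Relative error between two labeling-extent estimates
#'
#' `(le_test - le_reference) / le_reference`; undefined (NA) when the
#' reference is zero.
#'
#' @param le_test,le_reference Numeric vectors.
#' @return Signed relative errors.
#' @export
relative_error <- function(le_test, le_reference) {
  ifelse(le_reference == 0, NA_real_, (le_test - le_reference) / le_reference)
}

#' Share of metabolites whose two estimates agree within a tolerance
#'
#' @param le_test,le_reference Numeric vectors (paired by position).
#' @param tol Relative-error tolerance (default 0.3).
#' @return Consistency fraction over the defined (nonzero-reference) pairs.
#' @export
consistency_rate <- function(le_test, le_reference, tol = 0.3) {
  re <- relative_error(le_test, le_reference)
  mean(abs(re[!is.na(re)]) <= tol)
}

#' @export
autoplot.kinetic_fit <- function(object, ...) {
  d <- augment(object)
  curve <- if (object$converged) {
    tt <- seq(min(d$t), max(d$t), length.out = 100)
    tibble(t = tt, le = object$a * exp(-object$k * tt) - object$a)
  } else tibble(t = numeric(), le = numeric())
  ggplot(d, aes(x = .data$t, y = .data$le)) +
    geom_point() +
    geom_line(data = curve, aes(y = .data$le), colour = "steelblue") +
    labs(x = "time (h)", y = "labeling extent",
         subtitle = if (object$converged)
           sprintf("k = %.3f 1/h, plateau = %.2f, R = %.2f",
                   object$k, object$plateau, object$r) else "not converged") +
    theme_minimal()
}
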