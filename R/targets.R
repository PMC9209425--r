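#' Parse an elemental formula
#'
#' Parses a Hill-notation formula (no charges, brackets or isotope labels)
#' into element counts.
#'
#' @param formula Formula string, e.g. `"C6H12O6"`.
#' @return A named integer vector of element counts with attribute
#'   `carbon_count` (number of carbons, 0 if none).
#' @export
#' @examples
#' parse_formula("C6H12O6")
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L)
  f <- gsub("\\s", "", formula)
  if (!nzchar(f)) abort("empty formula", class = "tracerkit_parse_error")
  pos <- 1L
  counts <- integer()
  while (pos <= nchar(f)) {
    m <- regmatches(substr(f, pos, nchar(f)),
                    regexpr("^([A-Z][a-z]?)([0-9]*)", substr(f, pos, nchar(f))))
    if (!length(m) || !nzchar(m)) {
      abort(sprintf("cannot parse formula '%s' at position %d", formula, pos),
            class = "tracerkit_parse_error")
    }
    elem <- sub("[0-9]*$", "", m)
    if (!elem %in% names(MONOISOTOPIC_MASS)) {
      abort(sprintf("unknown element '%s' in formula '%s' at position %d",
                    elem, formula, pos),
            class = "tracerkit_parse_error")
    }
    num <- sub("^[A-Za-z]+", "", m)
    k <- if (nzchar(num)) as.integer(num) else 1L
    prev <- if (elem %in% names(counts)) counts[[elem]] else 0L
    counts[elem] <- prev + k
    pos <- pos + nchar(m)
  }
  structure(counts, carbon_count = unname(counts["C"] %||% 0L))
}

monoisotopic_mass <- function(comp) {
  sum(MONOISOTOPIC_MASS[names(comp)] * as.numeric(comp))
}

carbon_count <- function(comp) {
  cc <- attr(comp, "carbon_count")
  if (is.null(cc)) cc <- if ("C" %in% names(comp)) comp[["C"]] else 0L
  if (is.na(cc)) 0L else as.integer(cc)
}

#' Theoretical isotopologue m/z series
#'
#' Computes the m/z of all 13C isotopologues M0..MC of a metabolite under a
#' given adduct: M0 is the adduct-adjusted monoisotopic m/z and each further
#' isotopologue adds exactly 1.003355 Da (the 13C-12C mass difference). `C`
#' is the carbon count of the neutral metabolite; the adduct vocabulary is
#' carbon-free by construction.
#'
#' @param comp A formula string or the result of [parse_formula()].
#' @param adduct One of `[M+H]+`, `[M+Na]+`, `[M+NH4]+`, `[M-H]-`,
#'   `[M+Cl]-`, `[M-H-H2O]-`.
#' @param polarity Optional; if given, must match the adduct's polarity.
#' @return Numeric vector of length C+1 of isotopologue m/z values.
#' @export
#' @examples
#' isotopologue_mz_series("C6H12O6", "[M-H]-")
isotopologue_mz_series <- function(comp, adduct, polarity = NULL) {
  if (is.character(comp)) comp <- parse_formula(comp)
  adduct <- normalize_adduct(adduct)
  row <- ADDUCTS[ADDUCTS$adduct == adduct, ]
  if (!nrow(row)) {
    abort(sprintf("unsupported adduct '%s'", adduct), class = "tracerkit_adduct_error")
  }
  if (!is.null(polarity) && !identical(polarity, row$polarity)) {
    abort(sprintf("adduct %s is %s mode but polarity %s was given",
                  adduct, row$polarity, polarity),
          class = "tracerkit_adduct_error")
  }
  m0 <- monoisotopic_mass(comp) + row$delta
  m0 + MASS_DELTA_13C * (0:carbon_count(comp))
}

#' Build the isotopologue target list
#'
#' Step one of the workflow. For every accepted annotation the theoretical
#' isotopologue m/z series is computed, the M0 EIC is extracted from every
#' unlabeled run over the feature's retention-time bounds, and the run with
#' the highest apex height supplies the reference ("target") peak shape,
#' retention time and bounds. Metabolites whose M0 EIC is zero in all
#' unlabeled runs are dropped and reported.
#'
#' @param annotations Annotation tibble from [read_annotation_table()].
#' @param features Feature tibble from [read_feature_table()].
#' @param unlabeled_runs List of [tracer_run()] objects (unlabeled controls).
#' @return A tibble with one row per retained metabolite: `metabolite_id`,
#'   `name`, `formula`, `adduct`, `carbon_count`, `target_rt`, `rt_lo`,
#'   `rt_hi`, `source_run_id`, and list-columns `mz_series` (numeric vector
#'   M0..MC) and `target_shape` (reference EIC). Class `tracer_targets`.
#' @export
build_target_list <- function(annotations, features, unlabeled_runs) {
  stopifnot(length(unlabeled_runs) > 0)
  miss <- setdiff(annotations$feature_id, features$feature_id)
  if (length(miss)) {
    abort(sprintf("annotation feature_id(s) not in feature table: %s",
                  paste(miss, collapse = ", ")),
          class = "tracerkit_validation_error")
  }
  feats <- features[match(annotations$feature_id, features$feature_id), ]
  rows <- map(seq_len(nrow(annotations)), function(i) {
    ann <- annotations[i, ]
    ft <- feats[i, ]
    comp <- parse_formula(ann$formula)
    mzs <- isotopologue_mz_series(comp, ann$adduct)
    eics <- map(unlabeled_runs, extract_eic, mz = mzs[1],
                rt_window = c(ft$rt_min, ft$rt_max))
    apex <- map_dbl(eics, ~ if (nrow(.x)) max(.x$intensity) else 0)
    if (all(apex == 0)) return(NULL)
    # argmax; ties broken by lexicographic run_id
    ids <- map_chr(unlabeled_runs, "run_id")
    best <- which(apex == max(apex))
    best <- best[order(ids[best])][1]
    shape <- eics[[best]]
    tibble(
      metabolite_id = ann$metabolite_id, name = ann$name,
      formula = ann$formula, adduct = ann$adduct,
      carbon_count = carbon_count(comp),
      mz_series = list(mzs),
      target_rt = shape$rt[which.max(shape$intensity)],
      rt_lo = ft$rt_min, rt_hi = ft$rt_max,
      source_run_id = ids[best],
      target_shape = list(shape)
    )
  })
  dropped <- annotations$metabolite_id[map_lgl(rows, is.null)]
  if (length(dropped)) {
    inform(sprintf("dropped %d metabolite(s) with all-zero M0 EICs in unlabeled runs: %s",
                   length(dropped), paste(dropped, collapse = ", ")))
  }
  out <- list_rbind(rows)
  class(out) <- c("tracer_targets", class(out))
  attr(out, "dropped") <- dropped
  out
}

#' @importFrom purrr map_chr
#' @export
print.tracer_targets <- function(x, ...) {
  cat(sprintf("<tracer_targets> %d metabolites, %d isotopologue targets\n",
              nrow(x), sum(x$carbon_count + 1L)))
  NextMethod()
}

#' Flatten a target list to one row per isotopologue
#'
#' @param targets A `tracer_targets` tibble.
#' @return A plain tibble (`metabolite_id`, `isotopologue_index`, `mz`,
#'   `target_rt`, `rt_lo`, `rt_hi`) suitable for CSV export.
#' @export
target_table <- function(targets) {
  list_rbind(map(seq_len(nrow(targets)), function(i) {
    mzs <- targets$mz_series[[i]]
    tibble(metabolite_id = targets$metabolite_id[i],
           isotopologue_index = seq_along(mzs) - 1L,
           mz = mzs,
           target_rt = targets$target_rt[i],
           rt_lo = targets$rt_lo[i], rt_hi = targets$rt_hi[i])
  }))
}
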