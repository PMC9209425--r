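# tracerkit

Metabolome-wide quantification of stable-isotope (13C) labeling from LC-MS
data.

## The problem

Continuous feeding of a [U-13C] tracer (e.g. glucose) gradually replaces
12C by 13C in downstream metabolites. A metabolite with C carbons then
shows up to C+1 *isotopologues* M0..MC, spaced by 1.003355 Da. Two
quantities summarize tracer incorporation per metabolite:

* **Labeling extent** — `LE = 1 - L(M0)`, the fraction of the pool carrying
  at least one tracer carbon, where `L(M0)` is the corrected fraction of
  the monoisotopic isotopologue;
* **Labeling rate** — the apparent first-order constant `k` (1/h) of
  `LE(t) = a·e^(-kt) - a` (with `a < 0`, plateau `-a`) under continuous
  feeding.

Untargeted isotope-tracing tools are limited by metabolite coverage;
`tracerkit` instead starts from the annotation and feature tables of an
untargeted analysis of *unlabeled* control samples and extracts all
isotopologues *targetedly* from the labeled runs: theoretical m/z series
per annotated metabolite, reference ("target") peak shape and RT from the
unlabeled runs, S/N and peak-shape (PPC) filtered detection, apex
clustering, 3-scan apex quantification, natural-abundance deconvolution by
non-negative least squares, and contamination correction against the
unlabeled controls. Downstream tools cover kinetic fitting, profile
clustering, FDR-controlled metabolite-metabolite correlation networks,
hypergeometric pathway enrichment, and a false-positive-rate protocol run
on unlabeled samples. A ground-truthed synthetic LC-MS generator makes the
whole chain testable end to end.

The package is tidyverse-native: tabular inputs and outputs are tibbles,
fitted objects have `tidy()`/`glance()`/`augment()` methods, and result
types have `autoplot()`/`plot_*()` functions. See the methods vignette
(`vignettes/isotope-tracing-methods.Rmd`) for the model, parameter and
design details.

## Worked example

Simulate a small continuous-labeling experiment (10 metabolites, 6 time
points, 3 replicates, 4 unlabeled controls), run the pipeline, and fit
labeling rates:

```r
library(tracerkit)
library(dplyr)

spec <- scenario_spec(n_metabolites = 10, replicates = 3, n_unlabeled = 4, seed = 2)
man  <- generate_scenario(spec)
runs <- render_runs(man)                       # in-memory runs; dir= writes mzML

res <- run_tracer_pipeline(runs, man$runs[, c("run_id", "group")],
                           man$annotations, man$features)
res
#> <tracer_result> 10 metabolites, 22 runs; 10 called labeled

times <- distinct(man$runs[!is.na(man$runs$time), c("group", "time")])
fits  <- fit_labeling_rates(result_le_table(res, times = times))
head(select(fits, -fit), 5)
#> # A tibble: 5 × 7
#>   metabolite_id      a     k plateau     r converged reliable
#>   <chr>          <dbl> <dbl>   <dbl> <dbl> <lgl>     <lgl>
#> 1 MET001        -0.837 0.226   0.837 1.000 TRUE      TRUE
#> 2 MET002        -0.600 0.915   0.600 0.999 TRUE      TRUE
#> 3 MET003        -0.656 0.834   0.656 0.996 TRUE      TRUE
#> 4 MET004        -0.839 1.05    0.839 0.998 TRUE      TRUE
#> 5 MET005        -0.421 0.384   0.421 0.996 TRUE      TRUE

fits$fit[[which(fits$metabolite_id == "MET007")]]   # aspartate in this roster
#> <kinetic_fit> a = -0.3210, k = 0.7695 1/h, plateau = 0.3210, R = 0.9863
```

Every metabolite is called labeled (all were simulated with `k > 0`), and
the fitted plateau/rate recover the generating truth (aspartate was
simulated with `a = -0.313`, `k = 0.82`): each row gives the plateau
labeling extent `-a`, the incorporation rate `k` in 1/h, and the
goodness-of-fit `R` (Pearson correlation of observed vs fitted LE; fits
with `R <= 0.8` are flagged unreliable). `write_mid_table(res$mids, ...)`
exports the final MID table; `autoplot()` on a fit or a
`correlation_network()` draws the standard figures.

Real data enter through `read_raw_run()` (mzML/mzXML),
`read_annotation_table()` and `read_feature_table()`; a thin command-line
wrapper over the same functions ships in `inst/cli/tracerkit.R`
(subcommands `simulate`, `pipeline`, `kinetics`, `network`, `fpr`).

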