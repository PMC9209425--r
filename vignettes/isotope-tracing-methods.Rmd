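---
title: "Methods: metabolome-wide quantification of 13C labeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolome-wide quantification of 13C labeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tracerkit)
library(dplyr)
```

## The problem

Continuous feeding of a [U-13C] tracer (typically glucose) progressively
replaces 12C with 13C in downstream metabolites. Each metabolite with C
carbons then appears in the mass spectrometer as up to C+1 *isotopologues*
M0..MC, spaced by the 13C-12C mass difference (1.003355 Da). The fraction
of each isotopologue — the mass isotopomer distribution (MID) — and its
change over feeding time carry the metabolic information: how much of the
pool has turned over (*labeling extent*) and how fast (*labeling rate*).

Untargeted metabolomics of *unlabeled* control samples yields a large
annotated feature set; `tracerkit` leverages it to extract isotopologue
signals *targetedly* from labeled runs, which is what makes metabolome-wide
coverage possible: the annotation table tells us which m/z series to look
for and the unlabeled runs tell us where (retention time) and what shape to
expect.

## Workflow and assumptions

1. **Targets.** For every annotated metabolite the theoretical m/z of all
   isotopologues is computed from the neutral formula and its (carbon-free,
   singly charged) adduct. The monoisotopic M0 trace is extracted from each
   unlabeled run over the feature's RT bounds; the run with the tallest
   apex supplies the reference peak ("target EIC": RT, bounds, shape). Ties
   are broken lexicographically by run id so the procedure is
   deterministic.
2. **Extraction.** In every labeled run, ion chromatograms of all
   isotopologues are pulled over the RT window widened by `rt_extend` (15 s
   default) at a tolerance of 0.01 Da below 400 Da and 25 ppm above, as a
   hard (closed-interval) cutoff. Traces whose maximum S/N is below 3 are
   discarded. Peaks are detected on every isotopologue trace — so in a
   highly labeled sample, where M0 may be at noise level, the most intense
   isotopologue anchors the detection. Candidates are filtered by
   peak-shape correlation (PPC >= 0.6) against the target EIC, apexes are
   clustered (complete linkage, tree cut at 3 s), and the cluster nearest
   the target RT is selected; its apex and bounds are re-adjusted to the
   tallest member.
3. **Quantification.** Each isotopologue's intensity is the sum of the
   three scans around the apex on the raw (unsmoothed) trace; isotopologues
   without a detected peak are integrated mandatorily at the group apex.
   Natural 13C abundance is deconvolved by non-negative least squares
   against the binomial convolution matrix, giving corrected intensities
   and the MID. Isotope contamination is estimated in the unlabeled
   controls (fraction > 0.02 in a strict majority of runs) and subtracted;
   metabolites whose M0 is zero in a strict majority of unlabeled runs are
   zeroed out entirely.
4. **Kinetics and statistics.** The labeling extent LE = 1 - L(M0) is
   fitted per metabolite with the first-order model LE(t) = a e^(-kt) - a
   (a < 0), so -a is the plateau and k (1/h) the incorporation rate.
   Downstream, LE profiles are clustered (correlation distance), labeling
   extents at the final time point feed an FDR-controlled Pearson
   correlation network, and pathway enrichment uses the hypergeometric
   upper tail.

Key assumptions: centroided MS1 data; a single chromatographic batch
(no RT alignment is performed); singly charged, carbon-free adducts; 13C is
the only enriched isotope (high mass resolution is assumed to separate
non-carbon isotopes); contamination levels are the same in labeled and
unlabeled samples.

## Parameters that matter

| Parameter | Default | Unit | Why |
|---|---|---|---|
| `mz_tol` | 0.01 Da (< 400 Da), 25 ppm above | Da/ppm | matches high-resolution instrument accuracy; hard cutoff, no taper |
| `rt_extend` | 15 | s | allows modest apex drift between unlabeled and labeled runs |
| `snr_min` | 3 | — | discards traces indistinguishable from noise |
| `ppc_min` | 0.6 | — | co-eluting interferences rarely reproduce the reference shape |
| `apex_cutoff` | 3 | s | isotopologues of one metabolite must co-elute; complete linkage guarantees the max pairwise spread equals the cut height |
| `peakwidth` | (5, 30) | s | chromatographic peak width range enforced by the detector |
| `p13` | 0.0107 | — | natural 13C abundance |
| `purity` | 1.0 | — | tracer isotopic purity, folded into the convolution matrix when < 1 |
| `label_threshold` | 0.02 | fraction | calling and contamination threshold |
| `majority` | 0.5 (strict) | fraction | robustness against single-sample artifacts |
| `r_min` | 0.8 | — | kinetic fits with R at or below this are flagged unreliable |

Retention time is seconds everywhere; the kinetics layer alone works in
hours, converted explicitly at its boundary — a single internal unit
prevents factor-of-60 mistakes.

## Numerical and design choices

* **Noise and baseline.** The noise level of a trace is the median of its
  nonzero intensities after excluding the top decile; the baseline is the
  10th percentile of nonzero intensities. Both are robust to the presence
  of a few genuine peaks, simple to reason about, and configurable.
* **Peak detector.** A Mexican-hat (ricker) continuous wavelet transform
  over eight log-spaced scales spanning `peakwidth`, on the
  Gaussian-smoothed (sigma = one scan interval), baseline-subtracted
  trace. Ridge maxima that clear the S/N floor on the raw trace become
  candidates; boundaries walk out to the first local minimum or to where
  the smoothed trace decays below 0.5% of the apex. This is behaviorally
  equivalent to wavelet-based chromatographic detectors for well-formed
  peaks while staying small and fully testable.
* **PPC definition.** "Shape similarity" is made concrete as: shift both
  peaks so their apexes coincide, resample both onto a shared grid covering
  the union of the apex-centered boundary windows (zero-filled outside each
  peak's own bounds), and take the Pearson correlation. A trace constant
  inside its bounds has no shape; its PPC is defined as 0 and flagged.
  Whether apexes should be aligned before correlating was an open choice;
  aligning makes the score a pure shape comparison and leaves RT proximity
  to the separate clustering step, which already handles it.
* **Apex clustering linkage.** Complete linkage with the tree cut at 3 s is
  the only linkage for which "maximum pairwise apex difference <= 3 s in a
  group" holds by construction, so it is the default (average linkage would
  only bound the mean). Group-to-target distance is measured from the group
  mean apex; ties go to the group holding the tallest peak.
* **NNLS, not matrix inversion.** The convolution matrix is
  well-conditioned, but plain inversion can return small negative
  intensities at low signal; non-negative least squares keeps the corrected
  vector physical and is exact on noiseless input (verified to 1e-6 up to
  C = 40).
* **Contamination subtraction conserves mass.** The subtracted fraction is
  returned to M0 so every corrected MID still sums to 1. Renormalization
  after subtraction is not otherwise specified by the estimation procedure;
  conservation keeps LE = 1 - L(M0) internally consistent and the choice is
  recorded in the output (`contamination_corrected` flags).
* **Three-scan sums use the raw trace.** Smoothing is a detection aid;
  quantification on the raw trace avoids kernel-dependent intensity bias.
  Mandatory extraction integrates at the selected group apex when one
  exists, else at the target RT.
* **Kinetic fitting.** Replicate LE values are averaged per time point
  before Levenberg-Marquardt NLS (means are the natural sufficient summary
  under i.i.d. noise and stabilize the fit; per-replicate fitting is
  available by simply not pre-aggregating). Initialization: a0 = -1.05 x
  max(LE) (clamped to (-1, 0)), k0 from a log-linear regression of the
  unlabeled residual; bounds a in (-1, 0), k > 0. R is the Pearson
  correlation of observed versus fitted LE — a regression R-squared would
  penalize the (deliberate) constraint LE(0) = 0.
* **Isomers sharing m/z and RT** are both emitted as targets and share the
  extracted signal; disambiguation is an annotation problem upstream of
  this package.

## The synthetic-data generator

The generator is first-class code: it renders complete centroided mzML runs
whose ground truth is known exactly, so every pipeline stage can be tested
end to end without external data.

What it emulates: Gaussian chromatographic isotopologue clusters at the
theoretical m/z series (2 ppm centroid jitter), apex areas proportional to
the measured-space envelope (tracer-space truth MID convolved with natural
abundance through the same binomial matrix the correction inverts — the
test is only meaningful because the *inverse* path runs through NNLS on
rendered, integrated, noisy peaks), first-order labeling kinetics per
metabolite, log-normal multiplicative area noise (CV 10% default), an
additive baseline with Gaussian scan noise, optional contaminated
isotopologues present in all runs, and co-eluting interference peaks.

Default conditions mirror a continuous-feeding design: time points 0, 1,
3, 6, 12, 24 h, 10 replicates per point, unlabeled controls, scan interval
0.5 s, peak sigma 3 s, apex intensities log-uniform between 1e5 and 2e6
counts, plateaus -a uniform in (0.2, 0.95) and rates k uniform in
(0.05, 1.0) 1/h — a realistic span from fast carbohydrate turnover to slow
nucleotide/fatty-acid labeling. Labeled mass defaults to the fully labeled
isotopologue (steady-state [U-13C] incorporation); a "spread" mode places
it binomially across M1..MC.

What it does **not** emulate: RT drift across batches, chemical-noise
libraries, detector saturation, profile-mode peak shapes, isotope fine
structure, or annotation errors. Passing the synthetic benchmarks therefore
demonstrates correctness of the extraction/correction/quantification
machinery under the stated noise model — not robustness to every artifact
of real chromatography.

## Problem sizes in the shipped checks

The package's acceptance experiments run on one CPU in a few minutes: the
NNLS inversion check uses 30 random MIDs up to C = 40; kinetic recovery
uses a 10 x 10 (a, k) grid with sigma = 0.02 noise and 10 replicates per
time point; the end-to-end benchmark renders 50 metabolites x 6 time
points x 3 replicates plus 5 unlabeled controls (23 runs); FPR fixtures
use 20 metabolites x 6 unlabeled runs; the null-network simulation uses
100 draws of 50 independent metabolites over 10 samples. These sizes were
chosen to exercise every code path at stable statistics while staying
desk-scale; the generator accepts larger designs unchanged.

## Known limitations

* Only 13C tracing is implemented; the mass-difference and element count
  are isolated in the target builder, but 15N/2H tracers would need their
  own correction matrices.
* Only carbon natural-abundance correction is performed, on the
  high-resolution assumption that non-carbon isotopologues are resolved
  away.
* No RT alignment: all runs are assumed to share one chromatographic
  batch, as in single-study designs.
* Absolute fluxes are out of reach by design: k is an apparent first-order
  incorporation rate, not a flux estimate, and no attempt is made at
  kinetic flux profiling.
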