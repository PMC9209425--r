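# Shared fixtures, all built in code.

# A Gaussian chromatographic trace on a regular scan grid.
gaussian_eic <- function(apex_rt = 100, sigma = 3, height = 1000,
                         rt = seq(50, 150, by = 0.5), noise_sd = 0,
                         baseline = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- height * exp(-(rt - apex_rt)^2 / (2 * sigma^2)) + baseline
  if (noise_sd > 0) y <- pmax(y + rnorm(length(rt), 0, noise_sd), 0)
  tracerkit:::new_eic(rt, y, mz_center = 100, mz_tol = 0.01, run_id = "fix")
}

# A tiny three-scan run with explicit centroids.
toy_run <- function(run_id = "toy") {
  tracer_run(
    run_id,
    rt = c(10, 20, 30),
    peaks = data.frame(
      scan = c(1L, 1L, 2L, 3L),
      mz = c(100.00, 250.00, 100.00, 100.00),
      intensity = c(500, 80, 900, 400)
    ),
    polarity = "negative"
  )
}

# Cached small labeled scenario shared across test files (built once).
.fixture_env <- new.env(parent = emptyenv())

small_scenario <- function() {
  if (is.null(.fixture_env$small)) {
    spec <- scenario_spec(n_metabolites = 8, replicates = 2, n_unlabeled = 4,
                          seed = 42)
    man <- generate_scenario(spec)
    runs <- render_runs(man)
    res <- run_tracer_pipeline(runs, man$runs[, c("run_id", "group")],
                               man$annotations, man$features)
    .fixture_env$small <- list(spec = spec, manifest = man, runs = runs,
                               result = res)
  }
  .fixture_env$small
}

# Adjusted Rand index between two label vectors (closed form from the
# pair-counting contingency table); used as an independent clustering check.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  sij <- sum(choose(tab, 2))
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  np <- choose(sum(tab), 2)
  expected <- si * sj / np
  (sij - expected) / ((si + sj) / 2 - expected)
}

write_csv_text <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  path
}
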