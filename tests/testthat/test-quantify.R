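test_that("apex intensity is the 3-scan sum, with edge handling", {
  eic <- tracerkit:::new_eic(c(10, 10.5, 11, 11.5, 12), c(50, 100, 200, 150, 30))
  v <- apex_intensity(eic, 11)
  expect_equal(as.numeric(v), 450)
  expect_false(attr(v, "edge"))
  # apex at the first scan: available scans summed, flagged
  v2 <- apex_intensity(tracerkit:::new_eic(c(10, 10.5), c(200, 150)), 10)
  expect_equal(as.numeric(v2), 350)
  expect_true(attr(v2, "edge"))
  # undetected isotopologue with zero trace
  v3 <- apex_intensity(tracerkit:::new_eic(c(10, 10.5, 11), c(0, 0, 0)), 10.5)
  expect_equal(as.numeric(v3), 0)
})

test_that("natural-abundance matrix matches hand-computed binomials", {
  A1 <- natural_abundance_matrix(1, 0.0107)
  expect_equal(A1, matrix(c(0.9893, 0.0107, 0, 1), 2, 2), tolerance = 1e-12)
  A2 <- natural_abundance_matrix(2, 0.0107)
  expect_equal(A2[, 1], c(0.9893^2, 2 * 0.0107 * 0.9893, 0.0107^2),
               tolerance = 1e-12)
  expect_equal(A2[, 1], c(0.97871, 0.021171, 0.00011449), tolerance = 1e-4)
  # p13 = 0 gives the identity
  expect_equal(natural_abundance_matrix(5, 0), diag(6))
  # columns are probability distributions
  for (C in c(0, 1, 7, 23)) {
    expect_equal(colSums(natural_abundance_matrix(C)), rep(1, C + 1))
  }
  # imperfect tracer purity shifts labeled mass down, still a distribution
  Ap <- natural_abundance_matrix(3, 0.0107, purity = 0.99)
  expect_equal(colSums(Ap), rep(1, 4))
  expect_gt(Ap[3, 4], 0)  # M3 column leaks into M2
})

test_that("NNLS correction inverts the convolution for random MIDs up to C = 40", {
  set.seed(101)
  for (C in c(1, 2, 6, 17, 40)) {
    for (rep in 1:4) {
      x <- runif(C + 1); x <- x / sum(x)
      raw <- as.numeric(natural_abundance_matrix(C) %*% x) * 1e6
      got <- correct_natural_abundance(raw)
      expect_lt(max(abs(got$mid - x)), 1e-6)
      expect_equal(sum(got$mid), 1, tolerance = 1e-9)
    }
  }
})

test_that("pure-unlabeled raw spectra deconvolve to a delta at M0", {
  raw <- c(0.97871, 0.021171, 0.00011449) * 1e6
  got <- correct_natural_abundance(raw)
  expect_equal(got$mid, c(1, 0, 0), tolerance = 1e-5)
  # all-zero raw input: all-zero MID, flagged
  z <- correct_natural_abundance(c(0, 0, 0))
  expect_equal(z$mid, c(0, 0, 0))
  expect_true(z$zeroed)
})

test_that("contamination is called by the strict majority rule and averaged", {
  mk <- function(fracs_m1, m0_int = 1e5) {
    n <- length(fracs_m1)
    tibble::tibble(
      metabolite_id = "M1",
      isotopologue_index = rep(c(0L, 1L), each = n),
      run_id = rep(sprintf("UL%02d", 1:n), 2),
      labeled_fraction = c(1 - fracs_m1, fracs_m1),
      corrected_intensity = c(rep(m0_int, n), fracs_m1 * m0_int)
    )
  }
  # 0.05 in 7 of 10 runs -> contaminated at the mean level
  prof <- estimate_contamination(mk(c(rep(0.05, 7), rep(0, 3))))
  m1 <- prof[prof$isotopologue_index == 1, ]
  expect_equal(m1$contamination, mean(c(rep(0.05, 7), rep(0, 3))))
  # 0.05 in exactly 5 of 10 runs -> NOT contaminated (strictly > 50%)
  prof2 <- estimate_contamination(mk(c(rep(0.05, 5), rep(0, 5))))
  expect_equal(prof2$contamination[prof2$isotopologue_index == 1], 0)
  # M0 never flags as contaminated even when its "fraction" is high
  expect_equal(prof$contamination[prof$isotopologue_index == 0], 0)
})

test_that("metabolites with mostly-zero M0 in unlabeled runs are flagged absent", {
  n <- 10
  mids <- tibble::tibble(
    metabolite_id = "M1", isotopologue_index = 0L,
    run_id = sprintf("UL%02d", 1:n),
    labeled_fraction = 0,
    corrected_intensity = c(rep(0, 6), rep(1e5, 4))
  )
  prof <- estimate_contamination(mids)
  expect_true(all(prof$absent_in_unlabeled))
  # exactly half zero is not enough (strict majority)
  mids$corrected_intensity <- c(rep(0, 5), rep(1e5, 5))
  expect_false(any(estimate_contamination(mids)$absent_in_unlabeled))
})

test_that("contamination subtraction clamps at zero and conserves the MID sum", {
  mids <- tibble::tibble(
    metabolite_id = "M1",
    isotopologue_index = rep(0:2, 2),
    run_id = rep(c("L1", "L2"), each = 3),
    group = "24h",
    labeled_fraction = c(0.60, 0.30, 0.10, 0.95, 0.03, 0.02)
  )
  prof <- tibble::tibble(metabolite_id = "M1", isotopologue_index = 0:2,
                         contamination = c(0, 0.05, 0), absent_in_unlabeled = FALSE)
  out <- apply_contamination_correction(mids, prof)
  l1 <- out[out$run_id == "L1", ]
  expect_equal(l1$labeled_fraction, c(0.65, 0.25, 0.10))
  # clamped: only the available 0.03 is moved
  l2 <- out[out$run_id == "L2", ]
  expect_equal(l2$labeled_fraction, c(0.98, 0.00, 0.02))
  # sums conserved
  expect_equal(tapply(out$labeled_fraction, out$run_id, sum),
               tapply(mids$labeled_fraction, mids$run_id, sum))
  # absent metabolite zeroed out entirely
  prof_abs <- dplyr::mutate(prof, absent_in_unlabeled = TRUE)
  out_abs <- apply_contamination_correction(mids, prof_abs)
  expect_true(all(out_abs$labeled_fraction == 0))
})

test_that("contamination correction is idempotent", {
  mids <- tibble::tibble(
    metabolite_id = "M1", isotopologue_index = rep(0:2, 2),
    run_id = rep(c("L1", "L2"), each = 3), group = "24h",
    labeled_fraction = c(0.60, 0.30, 0.10, 0.95, 0.03, 0.02)
  )
  prof <- tibble::tibble(metabolite_id = "M1", isotopologue_index = 0:2,
                         contamination = c(0, 0.05, 0), absent_in_unlabeled = FALSE)
  once <- apply_contamination_correction(mids, prof)
  # re-estimating on corrected unlabeled data yields a zero profile, so a
  # second pass with that profile changes nothing
  zero_prof <- dplyr::mutate(prof, contamination = 0)
  twice <- apply_contamination_correction(
    once[, names(mids)], zero_prof)
  expect_equal(twice$labeled_fraction, once$labeled_fraction)
})

test_that("labeled calling uses a strict majority above the 2% threshold", {
  mk <- function(fracs, iso = 2L) {
    n <- length(fracs)
    tibble::tibble(metabolite_id = "M1",
                   isotopologue_index = rep(c(0L, iso), each = n),
                   run_id = rep(sprintf("L%02d", 1:n), 2),
                   labeled_fraction = c(1 - fracs, fracs))
  }
  # 0.03 in 6 of 10 runs -> labeled
  calls <- call_labeled(mk(c(rep(0.03, 6), rep(0, 4))))
  expect_true(calls$metabolites$labeled)
  # 0.021 in exactly 5 of 10 -> not labeled (strict majority)
  calls2 <- call_labeled(mk(c(rep(0.021, 5), rep(0, 5))))
  expect_false(calls2$metabolites$labeled)
  # only M0 nonzero -> never labeled
  calls3 <- call_labeled(mk(rep(0, 10)))
  expect_false(calls3$metabolites$labeled)
})

test_that("MID fractions stay in [0,1] and sum to 1 (or 0) through the pipeline stages", {
  fx <- small_scenario()
  sums <- fx$result$mids |>
    dplyr::group_by(metabolite_id, run_id) |>
    dplyr::summarise(s = sum(labeled_fraction), .groups = "drop")
  expect_true(all(abs(sums$s - 1) < 1e-9 | sums$s == 0))
  expect_true(all(fx$result$mids$labeled_fraction >= 0 &
                    fx$result$mids$labeled_fraction <= 1 + 1e-12))
})
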