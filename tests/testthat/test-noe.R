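# NOE calibration, distance prediction and restraint generation.

test_that("calibration recovers k exactly on noiseless data", {
  expect_equal(fit_noe_calibration(
    tibble::tibble(intensity = 1, distance = 1))$k, 1)

  r <- c(2, 2.5, 3)
  fit <- fit_noe_calibration(tibble::tibble(intensity = 64 * r^-6,
                                            distance = r))
  expect_equal(fit$k, 64, tolerance = 1e-12)
  expect_lt(fit$fit_residual, 1e-20)

  set.seed(7)
  for (i in 1:25) {
    k_true <- 10^stats::runif(1, -3, 3)
    r <- stats::runif(5, 1.8, 3.8)
    fit <- fit_noe_calibration(tibble::tibble(intensity = k_true * r^-6,
                                              distance = r))
    expect_lt(abs(fit$k - k_true) / k_true, 1e-9)
  }
})

test_that("calibration rejects degenerate input", {
  expect_error(fit_noe_calibration(tibble::tibble(intensity = numeric(),
                                                  distance = numeric())),
               "at least one")
  expect_error(fit_noe_calibration(tibble::tibble(intensity = 0,
                                                  distance = 2)), "positive")
  expect_error(fit_noe_calibration(tibble::tibble(intensity = 1,
                                                  distance = -1)), "positive")
})

test_that("predict_distance inverts the spin-pair model", {
  fit <- fit_noe_calibration(tibble::tibble(intensity = 64 * 2^-6,
                                            distance = 2))
  expect_equal(predict_distance(fit$k, fit), 1)
  expect_equal(predict_distance(1, fit), 2)
  r <- seq(1.5, 4, by = 0.25)
  expect_equal(predict_distance(fit$k * r^-6, fit), r, tolerance = 1e-12)
  expect_error(predict_distance(-1, fit), "positive")
})

test_that("back-prediction compresses multiplicative noise about six-fold", {
  r <- c(2.2, 2.4, 2.6, 2.9, 3.2)
  set.seed(42)
  rel_err_10 <- replicate(400, {
    i_noisy <- 100 * r^-6 * exp(stats::rnorm(5, 0, 0.10))
    fit <- fit_noe_calibration(tibble::tibble(intensity = i_noisy,
                                              distance = r))
    bp <- back_predict_references(fit)
    stats::median(bp$abs_error / bp$distance)
  })
  expect_lt(stats::median(rel_err_10), 0.017)

  # noiseless references give zero error
  fit0 <- fit_noe_calibration(tibble::tibble(intensity = 100 * r^-6,
                                             distance = r))
  expect_true(all(back_predict_references(fit0)$abs_error < 1e-12))
})

test_that("overlap normalisation divides by multiplicity", {
  pk <- tibble::tibble(intensity = c(9, 4, 5), multiplicity = c(3, 2, 1))
  out <- normalize_overlapped(pk)
  expect_equal(out$intensity_per_linkage, c(3, 2, 5))
  expect_error(normalize_overlapped(tibble::tibble(intensity = 1,
                                                   multiplicity = 0)),
               "multiplicity")
})

test_that("normalised overlapped peaks recover per-linkage intensities", {
  s <- cn6_noe_setup()
  ungrouped <- simulate_noesy(s$model, k_true = 100, overlap_grouping = FALSE)
  grouped <- normalize_overlapped(s$peaks)
  g13 <- grouped$intensity_per_linkage[grouped$atom_a == "H3" &
                                         grouped$role == "conformational"]
  per_link <- ungrouped$intensity[ungrouped$atom_a == "H3" &
                                    ungrouped$role == "conformational"]
  expect_equal(g13, mean(per_link), tolerance = 1e-9)
})

test_that("distance binning uses the strong/medium bounds and the 2.75 split", {
  out <- bin_restraint(c(2.0, 3.0))
  expect_equal(out$bin, c("strong", "medium"))
  expect_equal(out$lower, c(1.8, 2.8))
  expect_equal(out$upper, c(2.7, 3.8))

  expect_equal(bin_restraint(2.749)$bin, "strong")
  expect_equal(bin_restraint(2.751)$bin, "medium")
  expect_equal(bin_restraint(3.8)$bin, "medium")
  expect_warning(out <- bin_restraint(4.5), "unbinnable")
  expect_true(is.na(out$bin))

  # idempotent and total on (0, 3.8]
  r <- seq(0.05, 3.8, by = 0.05)
  b1 <- bin_restraint(r)
  expect_false(anyNA(b1$bin))
  expect_equal(bin_restraint(r), b1)
})

test_that("build_restraint_set emits the eight hexasaccharide restraints", {
  s <- cn6_noe_setup()
  rs <- s$restraints
  expect_equal(nrow(rs), 8)
  expect_equal(rs$force_constant, rep(10, 8))

  # published pattern: HN-H1 medium and H3-H1 strong across each
  # beta(1->3) linkage, H1-H4 strong across each beta(1->4) linkage
  expect_equal(rs$bin[rs$atom_a == "HN"], rep("medium", 3))
  expect_equal(rs$bin[rs$atom_a == "H3"], rep("strong", 3))
  expect_equal(rs$bin[rs$type == "b14"], rep("strong", 2))

  # same result from ungrouped per-linkage peaks
  pk2 <- simulate_noesy(s$model, k_true = 100, overlap_grouping = FALSE)
  rs2 <- build_restraint_set(pk2, s$fit)
  expect_equal(rs2$bin, rs$bin)
  # grouped peaks average the near-identical per-linkage distances
  expect_equal(rs2$distance, rs$distance, tolerance = 0.02)
})

test_that("missing expected peaks are reported by name", {
  s <- cn6_noe_setup()
  pk <- simulate_noesy(s$model, k_true = 100, overlap_grouping = FALSE)
  pk <- pk[!(pk$res_a == "N3" & pk$atom_a == "H1"), ]
  expect_error(build_restraint_set(pk, s$fit), "N3:U2 H1/H4")
})

test_that("uniformly intense peaks give eight strong restraints", {
  s <- cn6_noe_setup()
  pk <- expected_conformational_noes(6)
  pk$intensity <- s$fit$k / 2.0^6     # every distance calibrates to 2.0 A
  pk$multiplicity <- 1
  rs <- build_restraint_set(pk, s$fit)
  expect_equal(rs$bin, rep("strong", 8))
  expect_equal(rs$lower, rep(1.8, 8))
  expect_equal(rs$upper, rep(2.7, 8))
})
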