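# Superposition RMSD, circular torsion statistics, hydrogen bonds and
# cross-structure comparisons.

test_that("superposition removes rigid motion and is symmetric", {
  fx <- cn6_fixture()
  expect_equal(superpose_rmsd(fx, fx), 0, tolerance = 1e-9)
  moved <- rigid_copy(fx, angle = 113, axis = c(-1, 2, 0.5),
                      shift = c(10, 0, -4))
  expect_equal(superpose_rmsd(fx, moved), 0, tolerance = 1e-9)

  jit <- perturb_ensemble(fx, torsion_jitter_sd = 6, n = 3, seed = 5)
  a <- jit$model[[2]]
  b <- jit$model[[3]]
  expect_equal(superpose_rmsd(a, b), superpose_rmsd(b, a), tolerance = 1e-12)
  expect_gt(superpose_rmsd(a, b), 0)
})

test_that("two-atom toy superposition gives the closed-form 0.5 A", {
  # {(0,0,0),(1,0,0)} vs {(0,0,0),(2,0,0)}: after centring, residuals +/-0.5
  expect_equal(
    gagnmr:::kabsch_rmsd(rbind(c(0, 0, 0), c(1, 0, 0)),
                         rbind(c(0, 0, 0), c(2, 0, 0))),
    0.5, tolerance = 1e-12
  )
})

test_that("atom selections behave and mismatches error", {
  fx <- cn6_fixture()
  sub <- fx[fx$atom != "HO1" | fx$label != "N1", ]
  expect_error(superpose_rmsd(fx, sub), "atom mismatch")
  # heavy selection drops all hydrogens
  expect_equal(superpose_rmsd(fx, rigid_copy(fx), selection = "heavy"), 0,
               tolerance = 1e-9)
  expect_error(superpose_rmsd(fx, fx, selection = "backbone"), "unknown")
})

test_that("circular torsion statistics handle the wrap correctly", {
  expect_equal(gagnmr:::circular_mean(c(0, 10)), 5)
  expect_equal(gagnmr:::circular_mean(c(179, -179)), 180)
  expect_equal(gagnmr:::circular_sd(c(5, 5, 5)), 0)
  expect_error(torsion_statistics(list()), "empty")

  fx <- cn6_fixture()
  same <- perturb_ensemble(fx, torsion_jitter_sd = 0, n = 4, seed = 1)
  st <- torsion_statistics(same)
  expect_equal(st$phi_sd, rep(0, 5), tolerance = 1e-9)
  expect_equal(st$psi_sd, rep(0, 5), tolerance = 1e-9)
  expect_equal(st$phi_mean, c(-73, -73, -73, -73, -72), tolerance = 1e-9)
  expect_equal(st$psi_mean, c(108, -118, 107, -116, 109), tolerance = 1e-9)
})

test_that("hydrogen bonds are detected by distance and angle criteria", {
  # constructed O-H...O geometry: donor O at origin, H along x, acceptor
  # placed at 2.0 A from H with a 165-degree D-H...A angle
  build <- function(h_a, angle_deg) {
    th <- (180 - angle_deg) * pi / 180
    acc <- c(0.96 + h_a * cos(th), h_a * sin(th), 0)
    tibble::tibble(
      residue = c(1, 1, 2), kind = "GlcA", label = c("U1", "U1", "U2"),
      atom = c("O2", "HO2", "O5"), element = c("O", "H", "O"),
      x = c(0, 0.96, acc[1]), y = c(0, 0, acc[2]), z = 0
    )
  }
  found <- hydrogen_bonds(gagnmr:::model_from_atoms(build(2.0, 165)))
  expect_equal(nrow(found), 1)
  expect_equal(found$distance, 2.0, tolerance = 1e-9)
  expect_equal(found$angle, 165, tolerance = 1e-6)
  expect_equal(found$donor, "O2")
  expect_equal(found$acceptor, "O5")

  expect_equal(nrow(hydrogen_bonds(gagnmr:::model_from_atoms(build(3.0, 165)))), 0)
  expect_equal(nrow(hydrogen_bonds(gagnmr:::model_from_atoms(build(2.0, 90)))), 0)
})

test_that("structure comparison uses circular absolute differences", {
  ref <- tibble::tibble(type = c("b14", "b13"), torsion = c("phi", "phi"),
                        value = c(-73, -72))
  other <- tibble::tibble(type = c("b14", "b13"), torsion = c("phi", "phi"),
                          value = c(-98, -80))
  cmp <- compare_structures(ref, other)
  expect_equal(cmp$abs_delta, c(25, 8))

  # wrap: -170 vs 170 differ by 20, not 340
  w <- compare_structures(tibble::tibble(k = 1, value = -170),
                          tibble::tibble(k = 1, value = 170))
  expect_equal(w$abs_delta, 20)

  self <- compare_structures(ref, ref)
  expect_equal(self$abs_delta, c(0, 0))

  other_bad <- tibble::tibble(type = "b12", torsion = "phi", value = 0)
  expect_error(compare_structures(ref, other_bad), "key mismatch")
})

test_that("jittered ensembles recover their generating spread", {
  fx <- cn6_fixture()
  ens <- perturb_ensemble(fx, torsion_jitter_sd = 5, n = 400, seed = 31)
  st <- torsion_statistics(ens)
  # estimator consistency: circular sd close to the generating 5 degrees
  expect_true(all(st$phi_sd > 4.3 & st$phi_sd < 5.7))
  expect_true(all(st$psi_sd > 4.3 & st$psi_sd < 5.7))

  # RMSD to the unperturbed model grows with the jitter in expectation
  mean_rmsd <- vapply(c(1, 5, 15), function(sd) {
    e <- perturb_ensemble(fx, sd, n = 12, seed = 17)
    mean(vapply(e$model, function(m) superpose_rmsd(fx, m), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_rmsd) > 0))
})
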