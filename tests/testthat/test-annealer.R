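# Restraint potential and torsion-space simulated annealing.

test_that("flat-bottom restraint energy matches hand calculations", {
  s <- cn6_noe_setup()
  fx <- s$model
  # the fixture satisfies its own restraints
  re <- restraint_energy(fx, s$restraints)
  expect_equal(re$energy, 0)
  expect_equal(re$max_violation, 0)

  # one restraint 0.1 A above its upper bound: E = 10 * 0.1^2 = 0.1
  d <- gagnmr:::model_distance(fx, "N1", "H3", "U2", "H1")
  tight <- tibble::tibble(res_a = "N1", atom_a = "H3",
                          res_b = "U2", atom_b = "H1",
                          lower = d - 1, upper = d - 0.1,
                          force_constant = 10)
  re2 <- restraint_energy(fx, tight)
  expect_equal(re2$energy, 0.1, tolerance = 1e-9)
  expect_equal(re2$max_violation, 0.1, tolerance = 1e-9)

  # symmetric: 0.1 A below the lower bound gives the same energy
  tight$lower <- d + 0.1
  tight$upper <- d + 1
  re3 <- restraint_energy(fx, tight)
  expect_equal(re3$energy, re2$energy, tolerance = 1e-12)

  bad <- tight
  bad$atom_a <- "HX"
  expect_error(restraint_energy(fx, bad), "HX")
})

test_that("ring restraint energy is a flat-bottom well in the ring torsions", {
  fx <- cn6_fixture()
  expect_equal(ring_restraint_energy(fx), 0)

  # excursion arithmetic: a torsion at 85 degrees is 5 degrees outside the
  # +(60 +/- 20) window -> E = 100 * (5 * pi/180)^2
  excess <- gagnmr:::ring_torsion_excess(c(85, 75, -85, -40, 39),
                                         c(1, 1, -1, -1, -1))
  # the +39 torsion sits on the wrong side of its expected -60 window
  expect_equal(excess, c(5, 0, 5, 0, 79))
  e_85 <- 100 * (5 * pi / 180)^2
  expect_equal(100 * (excess[1] * pi / 180)^2, e_85)

  # flattened ring -> far outside the window, large positive energy
  flat <- fx
  ring <- c("O5", "C1", "C2", "C3", "C4", "C5")
  idx <- which(flat$label == "N1" & flat$atom %in% ring)
  flat$z[idx] <- mean(flat$z[idx])
  expect_gt(ring_restraint_energy(flat), 10)
})

test_that("total energy is invariant under rigid motion and sums terms", {
  s <- cn6_noe_setup()
  te <- total_energy(s$model, s$restraints)
  expect_equal(te$energy,
               te$restraint_energy + te$ring_energy + te$steric_energy)
  expect_equal(te$restraint_energy, 0)

  moved <- rigid_copy(s$model)
  te2 <- total_energy(moved, s$restraints)
  expect_equal(te2$energy, te$energy, tolerance = 1e-9)

  # a self-clashing conformer is dominated by the steric term
  clash <- suppressWarnings(assemble_chain(
    6, tibble::tibble(phi = c(60, 60, 60, 60, 60),
                      psi = c(-60, -60, -60, -60, -60))
  ))
  expect_gt(steric_energy(clash), 1)
})

test_that("annealing is deterministic and tolerates degenerate schedules", {
  s <- cn6_noe_setup()
  sch <- anneal_schedule(heat_steps = 5, hold_steps = 5, cool_steps = 10,
                         quench_moves = 20, polish_maxit = 100)
  r1 <- anneal_once(s$model, s$restraints, sch, seed = 3)
  r2 <- anneal_once(s$model, s$restraints, sch, seed = 3)
  expect_identical(attr(r1$model, "par"), attr(r2$model, "par"))
  r3 <- anneal_once(s$model, s$restraints, sch, seed = 4)
  expect_false(identical(attr(r1$model, "par"), attr(r3$model, "par")))

  hot <- anneal_schedule(heat_steps = 5, hold_steps = 0, cool_steps = 0,
                         quench_moves = 0, polish_maxit = 0)
  rh <- anneal_once(s$model, s$restraints, hot, seed = 1)
  expect_true(is.finite(rh$energy))
})

test_that("annealed models keep their rings in the 4C1 windows", {
  s <- cn6_noe_setup()
  sch <- anneal_schedule(heat_steps = 10, hold_steps = 10, cool_steps = 20,
                         quench_moves = 30, polish_maxit = 200)
  r <- anneal_once(s$model, s$restraints, sch, seed = 11)
  rp <- ring_pucker_torsions(r$model)
  expect_true(all(gagnmr:::ring_torsion_excess(rp$angle,
                                               rp$expected_sign) == 0))
})

test_that("generate_ensemble keeps a sorted lowest-energy prefix", {
  s <- cn6_noe_setup()
  sch <- anneal_schedule(heat_steps = 5, hold_steps = 5, cool_steps = 10,
                         quench_moves = 10, polish_maxit = 60)
  ens <- generate_ensemble(s$model, s$restraints, n_rounds = 10,
                           keep_fraction = 0.5, schedule = sch, seed = 9)
  expect_s3_class(ens, "conformer_ensemble")
  expect_equal(nrow(ens), 5)
  expect_equal(attr(ens, "n_generated"), 10)
  expect_false(is.unsorted(ens$energy))
  expect_equal(ens$rank, 1:5)

  # the kept energies are exactly the 5 smallest of all 10 rounds
  all_e <- vapply(1:10, function(i) {
    anneal_once(s$model, s$restraints, sch, seed = 9 + i - 1)$energy
  }, numeric(1))
  expect_equal(ens$energy, sort(all_e)[1:5], tolerance = 1e-12)

  # keep = round(fraction * n)
  ens2 <- generate_ensemble(s$model, s$restraints, n_rounds = 4,
                            keep_fraction = 0.26, schedule = sch, seed = 2)
  expect_equal(nrow(ens2), 1)
})

test_that("ensemble tidiers expose the ranking", {
  s <- cn6_noe_setup()
  sch <- anneal_schedule(heat_steps = 3, hold_steps = 3, cool_steps = 6,
                         quench_moves = 5, polish_maxit = 40)
  ens <- generate_ensemble(s$model, s$restraints, n_rounds = 4,
                           keep_fraction = 0.5, schedule = sch, seed = 21)
  td <- tidy(ens)
  expect_named(td, c("rank", "round", "energy", "max_violation"))
  gl <- glance(ens)
  expect_equal(gl$n_kept, 2)
  expect_equal(gl$energy_min, ens$energy[1])
})
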