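# Residue templates, chain assembly and torsion geometry.

test_that("measure_torsion matches an independent oracle and the sign convention", {
  # frozen convention checks
  expect_equal(measure_torsion(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                               c(1, 1, 0)), 0)
  expect_equal(measure_torsion(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                               c(-1, 1, 0)), 180)
  expect_equal(measure_torsion(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                               c(0, 1, 1)), -90)

  set.seed(101)
  for (i in 1:200) {
    p <- matrix(rnorm(12, sd = 3), 4, 3)
    # reject near-degenerate quadruples the same way the oracle would
    ok <- tryCatch({
      ours <- measure_torsion(p[1, ], p[2, ], p[3, ], p[4, ])
      theirs <- oracle_dihedral(p[1, ], p[2, ], p[3, ], p[4, ])
      expect_lt(abs(gagnmr:::wrap_angle(ours - theirs)), 1e-9)
      TRUE
    }, error = function(e) FALSE)
  }
  expect_error(measure_torsion(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0),
                               c(1, 1, 1)), "coincide")
  expect_error(measure_torsion(c(0, 0, 2), c(0, 0, 0), c(0, 0, 1),
                               c(1, 1, 1)), "collinear")
})

test_that("templates are 4C1 chairs with correct configurations", {
  for (kind in c("GalNAc", "GlcA")) {
    tpl <- build_residue_template(kind)
    expect_s3_class(tpl, "glycan_residue")
    expect_false(anyDuplicated(tpl$atoms$atom) > 0)

    rp <- ring_pucker_torsions(tpl)
    expect_equal(nrow(rp), 6)
    expect_equal(sign(rp$angle), rp$expected_sign)
    expect_true(all(abs(abs(rp$angle) - 60) <= 20 + 1e-9))

    # bonded heavy-atom distances within 1.2-1.7 A
    atoms <- tpl$atoms[tpl$atoms$element != "H", ]
    xyz <- as.matrix(atoms[, c("x", "y", "z")])
    d <- as.matrix(stats::dist(xyz))
    bonded <- d[d > 0 & d < 1.75]
    expect_true(all(bonded > 1.2 & bonded < 1.7))
  }

  glcA <- build_residue_template("GlcA")
  expect_true(all(c("C1", "C2", "C3", "C4", "C5", "C6", "O5", "O6A", "O6B")
                  %in% glcA$atoms$atom))
  expect_error(build_residue_template("xylose"), "unknown residue kind")
})

test_that("galacto vs gluco configuration shows in the H3-H4 dihedral", {
  h_dihedral <- function(tpl, i, j) {
    p <- function(a) unlist(tpl$atoms[tpl$atoms$atom == a, c("x", "y", "z")])
    measure_torsion(p(paste0("H", i)), p(paste0("C", i)),
                    p(paste0("C", j)), p(paste0("H", j)))
  }
  gal <- build_residue_template("GalNAc")
  glc <- build_residue_template("GlcA")
  expect_lt(abs(h_dihedral(gal, 3, 4)), 90)        # gauche (axial O4)
  expect_gt(abs(h_dihedral(glc, 3, 4)), 150)       # trans (all-equatorial)
})

test_that("assemble_chain round-trips requested torsions exactly", {
  tors <- tibble::tibble(phi = c(-73, -73, -73, -73, -72),
                         psi = c(108, -117, 108, -117, 109))
  m <- assemble_chain(6, tors)
  got <- measure_glycosidic_torsions(m)
  expect_equal(got$phi, tors$phi, tolerance = 1e-9)
  expect_equal(got$psi, tors$psi, tolerance = 1e-9)
  expect_equal(got$type, c("b13", "b14", "b13", "b14", "b13"))

  m2 <- assemble_chain(2, tibble::tibble(phi = -72, psi = 109))
  expect_equal(nrow(measure_glycosidic_torsions(m2)), 1)
})

test_that("set-then-measure holds across a phi/psi grid", {
  grid <- expand.grid(phi = seq(-170, 170, by = 40),
                      psi = seq(-170, 170, by = 40))
  worst <- 0
  for (i in seq_len(nrow(grid))) {
    m <- suppressWarnings(assemble_chain(
      2, tibble::tibble(phi = grid$phi[i], psi = grid$psi[i])
    ))
    got <- measure_glycosidic_torsions(m)
    worst <- max(worst, abs(got$phi - grid$phi[i]), abs(got$psi - grid$psi[i]))
  }
  expect_lt(worst, 1e-6)
})

test_that("assemble_chain validates its inputs", {
  expect_error(assemble_chain(5), "even")
  expect_error(assemble_chain(1), "even")
  expect_error(assemble_chain(4, tibble::tibble(phi = -73, psi = 108)),
               "per linkage")
  # a torsion combination that drives residues into each other is reported
  expect_warning(
    assemble_chain(4, tibble::tibble(phi = c(60, 60, 60),
                                     psi = c(-60, -60, -60))),
    "closer than 1.5"
  )
})

test_that("exocyclic torsions are set exactly and default to trans", {
  m <- assemble_chain(6, omega = c(60, -60, 180),
                      acetamido = c(150, 180, -120))
  p <- function(lab, at) gagnmr:::model_atom(m, lab, at)
  expect_equal(measure_torsion(p("N1", "O5"), p("N1", "C5"), p("N1", "C6"),
                               p("N1", "O6")), 60, tolerance = 1e-9)
  expect_equal(measure_torsion(p("N3", "H2"), p("N3", "C2"), p("N3", "N"),
                               p("N3", "HN")), 180, tolerance = 1e-9)
  expect_equal(measure_torsion(p("N5", "H2"), p("N5", "C2"), p("N5", "N"),
                               p("N5", "HN")), -120, tolerance = 1e-9)

  deflt <- cn6_fixture()
  q <- function(lab, at) gagnmr:::model_atom(deflt, lab, at)
  expect_equal(abs(measure_torsion(q("N3", "H2"), q("N3", "C2"),
                                   q("N3", "N"), q("N3", "HN"))), 180,
               tolerance = 1e-9)
})

test_that("ring pucker torsions flag distorted rings", {
  fx <- cn6_fixture()
  rp <- ring_pucker_torsions(fx)
  expect_equal(nrow(rp), 36)
  expect_true(all(abs(abs(rp$angle) - 60) <= 20 + 1e-9))

  # flatten one ring -> near-zero torsions, flagged as non-chair
  flat <- fx
  ring <- c("O5", "C1", "C2", "C3", "C4", "C5")
  idx <- which(flat$label == "N1" & flat$atom %in% ring)
  flat$z[idx] <- mean(flat$z[idx])
  rp_flat <- ring_pucker_torsions(flat)
  n1 <- rp_flat[rp_flat$label == "N1", ]
  expect_true(all(abs(n1$angle) < 25))

  # displacing one ring atom breaks the +/-(60 +/- 20) window
  broken <- fx
  j <- which(broken$label == "N1" & broken$atom == "C3")
  broken$z[j] <- broken$z[j] + 1.5
  rp_b <- ring_pucker_torsions(broken)
  excess <- gagnmr:::ring_torsion_excess(rp_b$angle, rp_b$expected_sign)
  expect_gt(max(excess), 0)

  # missing ring atom is a structural error naming the atom
  gone <- fx[!(fx$label == "N1" & fx$atom == "O5"), ]
  expect_error(ring_pucker_torsions(gone), "O5")
})
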