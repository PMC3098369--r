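# Shared fixtures, built in code once per test run.

cn6_fixture <- local({
  val <- NULL
  function() {
    if (is.null(val)) val <<- reference_torsion_fixture()
    val
  }
})

# noiseless synthetic peaks, calibration and the eight restraints
cn6_noe_setup <- local({
  val <- NULL
  function() {
    if (is.null(val)) {
      fx <- cn6_fixture()
      peaks <- simulate_noesy(fx, k_true = 100, overlap_grouping = TRUE)
      refs <- peaks[peaks$role == "reference", c("intensity", "distance")]
      fit <- fit_noe_calibration(refs)
      val <<- list(model = fx, peaks = peaks, fit = fit,
                   restraints = build_restraint_set(peaks, fit))
    }
    val
  }
})

# independent dihedral oracle: projection formula, coded differently from
# the cross-product implementation in the package
oracle_dihedral <- function(p1, p2, p3, p4) {
  b0 <- p1 - p2
  b1 <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  b2 <- p4 - p3
  v <- b0 - sum(b0 * b1) * b1
  w <- b2 - sum(b2 * b1) * b1
  x <- sum(v * w)
  cross <- c(b1[2] * v[3] - b1[3] * v[2],
             b1[3] * v[1] - b1[1] * v[3],
             b1[1] * v[2] - b1[2] * v[1])
  y <- sum(cross * w)
  atan2(y, x) * 180 / pi
}

# rigidly transform a model's coordinates (preserving all attributes)
rigid_copy <- function(model, angle = 37, axis = c(1, 2, 3),
                       shift = c(5, -3, 2)) {
  k <- axis / sqrt(sum(axis^2))
  th <- angle * pi / 180
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  r <- diag(3) * cos(th) + sin(th) * kx + (1 - cos(th)) * (k %o% k)
  xyz <- as.matrix(tibble::as_tibble(model)[, c("x", "y", "z")]) %*% t(r)
  out <- model
  out$x <- xyz[, 1] + shift[1]
  out$y <- xyz[, 2] + shift[2]
  out$z <- xyz[, 3] + shift[3]
  out
}
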