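test_that("instrument matrix matches the five-state construction", {
  A <- instrument_matrix(pi / 2)
  expect_equal(unname(A$a),
               rbind(c(1, 0, 0, -1), c(1, 1, 0, 0), c(1, 0, 1, 0),
                     c(1, -1, 0, 0), c(1, 0, -1, 0)))
  ## RCP row is exact for any chi
  for (chi in c(0.1, 0.5, 1.0, 2.0)) {
    a <- instrument_matrix(chi)
    expect_identical(unname(a$a["RCP", ]), c(1, 0, 0, -1))
    expect_equal(qr(a$a)$rank, 4L)
    ## pseudo-inverse is a left inverse
    expect_equal(unname(a$pinv %*% a$a), diag(4), tolerance = 1e-10)
  }
  expect_error(instrument_matrix(0), "degenerate instrument")
  expect_error(instrument_matrix(pi), "degenerate instrument")
})

test_that("forward model reproduces hand-derived intensity vectors", {
  chi <- 0.7
  A <- instrument_matrix(chi)
  ## empty specimen: RCP extinguished by the crossed circular analyzer
  I <- forward_intensities(mueller_coefficients(1, 1, 0, 0), A)
  expect_equal(as.numeric(I), c(0, rep(1 - cos(chi), 4)), tolerance = 1e-12)
  ## half-wave voxel at omega = 0: m = (1, 0, -1, 0)
  m <- mueller_coefficients(1, 1, pi / 2, 0)
  expect_equal(as.numeric(m), c(1, 0, -1, 0), tolerance = 1e-12)
  I2 <- forward_intensities(m, A)
  expect_equal(as.numeric(I2), c(1, 1, 1 - sin(chi), 1, 1 + sin(chi)),
               tolerance = 1e-12)
  ## linearity in m
  set.seed(1)
  mr <- mueller_coefficients(runif(50, 0.1, 2), runif(50, 0.1, 1),
                             runif(50, 0, 1.4), runif(50, 0, pi))
  expect_equal(as.numeric(forward_intensities(mueller_stack(2.5 * mr), A)),
               as.numeric(2.5 * forward_intensities(mr, A)),
               tolerance = 1e-12)
})

test_that("inversion is exact on noiseless data and matches the LS oracle", {
  A <- instrument_matrix(0.06 * pi)
  set.seed(42)
  n <- 1000
  m <- mueller_coefficients(runif(n, 1e-3, 2), runif(n, 1e-3, 1),
                            runif(n, 0, pi / 2 * 0.999), runif(n, 0, pi))
  I <- forward_intensities(m, A)
  m2 <- invert_intensities(I, A)
  expect_lt(max(abs(m - m2)), 1e-12)
  ## exact data in the range: columns of A recover unit vectors
  ## columns of A can be negative (not physical camera counts), so pass
  ## the raw array to the solver rather than the validated container
  for (k in 1:4) {
    got <- invert_intensities(array(A$a[, k], c(1, 1, 5)), A)
    expect_equal(as.numeric(got), as.numeric(diag(4)[k, ]),
                 tolerance = 1e-10)
  }
  ## noisy data: least squares equals the dense normal-equations oracle
  set.seed(7)
  n <- 10000
  mr <- mueller_coefficients(runif(n, 0.1, 2), runif(n, 0.1, 1),
                             runif(n, 0, 1.4), runif(n, 0, pi))
  Im <- qpli:::stack_mat(forward_intensities(mr, A)) +
    matrix(rnorm(n * 5, 0, 0.01), n, 5)
  Im <- pmax(Im, 0)
  got <- invert_intensities(polarization_stack(array(Im, c(n, 1, 5))), A)
  want <- normal_eq_solve(A$a, Im)
  expect_lt(max(abs(qpli:::stack_mat(got) - want)), 1e-10)
})

test_that("least-squares inversion is unbiased under zero-mean noise", {
  A <- instrument_matrix(0.06 * pi)
  m_true <- as.numeric(mueller_coefficients(1.2, 0.8, 0.3, 1.0))
  I0 <- as.numeric(A$a %*% m_true)
  set.seed(11)
  nrep <- 20000
  sigma <- 0.05
  In <- matrix(rep(I0, each = nrep), nrep, 5) +
    matrix(rnorm(nrep * 5, 0, sigma), nrep, 5)
  mh <- In %*% t(A$pinv)
  se <- apply(mh, 2, sd) / sqrt(nrep)
  expect_true(all(abs(colMeans(mh) - m_true) < 3 * se + 1e-12))
})

test_that("stack containers validate their contracts", {
  expect_error(polarization_stack(array(1, c(2, 2, 4))), "last dimension")
  expect_error(polarization_stack(array(-1, c(2, 2, 5))), "non-negative")
  expect_error(polarization_stack(array(NA_real_, c(2, 2, 5))), "finite")
  expect_error(polarization_stack(array(1, c(2, 2, 5)),
                                  channels = c("0", "45", "90", "135",
                                               "RCP")),
               "order")
  ## non-positive m0 voxels are flagged, not silently used
  A <- instrument_matrix(0.06 * pi)
  I <- array(0, c(2, 1, 5))
  I[1, 1, ] <- as.numeric(A$a %*% c(1, 0, 0, 0.5))
  got <- invert_intensities(polarization_stack(I), A)
  v <- attr(got, "valid")
  expect_true(v[1, 1])
  expect_false(v[2, 1])
})
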