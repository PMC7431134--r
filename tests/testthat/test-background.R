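test_that("coefficient transform matches direct arithmetic", {
  tc <- transform_coefficients(mueller_stack(array(c(1, 0, 0, 1),
                                                   c(1, 1, 4))))
  expect_equal(c(tc$m1_bar, tc$m2_bar, tc$dop), c(0, 0, 1))
  tc2 <- transform_coefficients(mueller_stack(array(c(1, 0.1, -0.1, 0.99),
                                                    c(1, 1, 4))))
  expect_equal(as.numeric(tc2$m1_bar), 0.1 / 0.99, tolerance = 1e-12)
  expect_equal(as.numeric(tc2$m2_bar), -0.1 / 0.99, tolerance = 1e-12)
  expect_equal(as.numeric(tc2$dop), sqrt(0.01 + 0.01 + 0.9801),
               tolerance = 1e-12)
  ## near-half-wave voxel (m3 = 0) flagged invalid, not divided
  m4 <- mueller_stack(array(0, c(2, 1, 4)))
  m4[1, 1, ] <- c(1, 0, 0, 1); m4[2, 1, ] <- c(1, 0.5, 0.5, 0)
  tc3 <- transform_coefficients(m4)
  expect_true(tc3$valid[1, 1])
  expect_false(tc3$valid[2, 1])
  expect_true(is.nan(tc3$m1_bar[2, 1]))
})

test_that("property extraction inverts the Mueller parameterization", {
  A <- instrument_matrix(0.06 * pi)
  pipe <- function(t, p, rho, omega) {
    sm <- invert_intensities(
      forward_intensities(mueller_coefficients(t, p, rho, omega), A), A)
    bg <- invert_intensities(
      forward_intensities(mueller_coefficients(
        rep(1, length(t)), rep(1, length(t)), rep(0, length(t)),
        rep(0, length(t))), A), A)
    compute_properties(transform_coefficients(sm),
                       transform_coefficients(bg))
  }
  ## self-correction: sm == bg
  pr0 <- compute_properties(
    transform_coefficients(mueller_coefficients(1.3, 0.7, 0.2, 1.1)),
    transform_coefficients(mueller_coefficients(1.3, 0.7, 0.2, 1.1)))
  expect_equal(as.numeric(pr0$retardance), 0)
  expect_equal(as.numeric(pr0$brightfield), 1)
  expect_equal(as.numeric(pr0$dop), 1)
  expect_equal(as.numeric(pr0$slow_axis), 0)   # tie-break
  ## stated example: rho = 0.1, omega = pi/4 -> m = (1, sin rho, 0, cos rho)
  m <- mueller_coefficients(1, 1, 0.1, pi / 4)
  expect_equal(as.numeric(m), c(1, sin(0.1), 0, cos(0.1)),
               tolerance = 1e-14)
  pr <- pipe(1, 1, 0.1, pi / 4)
  expect_equal(as.numeric(pr$retardance), 0.1, tolerance = 1e-9)
  expect_equal(as.numeric(pr$slow_axis), pi / 4, tolerance = 1e-9)
  ## axis symmetry: omega and omega + pi are the same physical axis
  om <- seq(0, pi - 1e-6, length.out = 11)
  pr1 <- pipe(rep(1, 11), rep(1, 11), rep(0.3, 11), om)
  pr2 <- pipe(rep(1, 11), rep(1, 11), rep(0.3, 11), om + pi)
  expect_equal(pr1$slow_axis, pr2$slow_axis, tolerance = 1e-9)
  ## dense grid recovery and invariances (property-style)
  g <- expand.grid(t = seq(0.2, 2, length.out = 6),
                   p = seq(0.2, 1, length.out = 6),
                   rho = seq(0.07, 1.4, length.out = 6),
                   omega = seq(0, pi * 0.95, length.out = 6))
  pr <- pipe(g$t, g$p, g$rho, g$omega)
  expect_lt(max(abs(pr$retardance - g$rho)), 1e-8)
  derr <- abs(pr$slow_axis - (g$omega %% pi))
  expect_lt(max(pmin(derr, pi - derr)), 1e-8)
  expect_equal(as.numeric(pr$dop), g$p, tolerance = 1e-8)
  expect_equal(as.numeric(pr$brightfield), g$t, tolerance = 1e-8)
  expect_lt(max(pr$dop / g$p), 1 + 1e-6)
  ## retardance invariant to global intensity rescaling of both stacks
  sm <- forward_intensities(mueller_coefficients(g$t, g$p, g$rho,
                                                 g$omega), A)
  bg <- forward_intensities(mueller_coefficients(g$t * 0 + 1, g$p * 0 + 1,
                                                 g$rho * 0, g$omega * 0), A)
  prs <- compute_properties(
    transform_coefficients(invert_intensities(
      qpli:::mat_stack(qpli:::stack_mat(sm) * 37, dim(sm), 5L), A)),
    transform_coefficients(invert_intensities(
      qpli:::mat_stack(qpli:::stack_mat(bg) * 37, dim(bg), 5L), A)))
  expect_equal(prs$retardance, pr$retardance, tolerance = 1e-9)
})

test_that("polynomial background surfaces are recovered from median bins", {
  ## constant map
  cmap <- matrix(3.7, 70, 60)
  expect_equal(fit_background_surface(cmap, bin = 16), cmap,
               tolerance = 1e-10)
  ## exact plane lies in the order-2 model space
  ny <- 96; nx <- 80
  yy <- matrix(seq_len(ny), ny, nx); xx <- matrix(seq_len(nx), ny, nx,
                                                  byrow = TRUE)
  plane <- 0.2 + 0.001 * xx + 0.002 * yy
  fit <- fit_background_surface(plane, bin = 16, order = 2)
  expect_lt(max(abs(fit - plane)) / max(abs(plane)), 1e-8)
  ## minority outlier block inside one bin is rejected by the median.
  ## exactly so on a background that is constant within the bin:
  flat <- matrix(0.25, ny, nx)
  dirty <- flat
  dirty[5:24, 35:54] <- dirty[5:24, 35:54] + 50     # 20x20 block, 32x32 bin
  fit2 <- fit_background_surface(dirty, bin = 32, order = 2)
  expect_lt(max(abs(fit2 - flat)), 1e-12)
  ## on a sloped background the median can only shift by (within-bin
  ## variation) x (outlier fraction); with realistic slow backgrounds
  ## that bound is far below the signal
  slow <- 0.2 + 1e-8 * xx + 1e-8 * yy
  dirty2 <- slow
  dirty2[5:24, 35:54] <- dirty2[5:24, 35:54] + 50
  fit3 <- fit_background_surface(dirty2, bin = 32, order = 2)
  expect_lt(max(abs(fit3 - slow)), 1e-6)
  expect_error(fit_background_surface(matrix(1, 4, 4), bin = 32),
               "smaller than one bin")
})

test_that("two-round correction suppresses residual low-order background", {
  ny <- nx <- 128
  yy <- matrix(seq_len(ny), ny, nx) / ny
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE) / nx
  ph <- make_phantom("spokes", c(ny, nx, 1),
                     params = list(n_bars = 6, rho_amp = 0.3,
                                   bar_width = 3, r_inner = 20,
                                   r_outer = 60), seed = 1)
  rend <- render_polarization_stack(
    ph, NULL,
    background = list(rho = 0.02 + 0.01 * xx, omega = pi / 3),
    residual_background = list(rho = 0.02 * yy + 0.015 * xx * yy,
                               omega = pi / 6))
  A <- instrument_matrix(0.06 * pi)
  m_sm <- invert_intensities(rend$sample, A)
  m_bg <- invert_intensities(rend$background, A)
  empty <- ph$rho_map[, , 1] == 0
  r1 <- correct_background(m_sm, m_bg, rounds = 1, bin = 16)
  r2 <- correct_background(m_sm, m_bg, rounds = 2, bin = 16)
  res1 <- median(abs(r1$retardance[, , 1][empty]))
  res2 <- median(abs(r2$retardance[, , 1][empty]))
  expect_lt(res2, 0.1 * res1)
  ## specimen retardance preserved within 5% (specimen occupies < 50%)
  spk <- ph$rho_map[, , 1] > 0
  expect_lt(mean(spk), 0.5)
  expect_lt(abs(median(r2$retardance[, , 1][spk]) - 0.3) / 0.3, 0.05)
  ## zero residual background: rounds 1 and 2 agree up to fit tolerance
  rend0 <- render_polarization_stack(ph, NULL)
  s0 <- invert_intensities(rend0$sample, A)
  b0 <- invert_intensities(rend0$background, A)
  q1 <- correct_background(s0, b0, rounds = 1, bin = 16)
  q2 <- correct_background(s0, b0, rounds = 2, bin = 16)
  expect_lt(median(abs(q1$retardance - q2$retardance), na.rm = TRUE), 1e-3)
  expect_error(correct_background(s0, b0, rounds = 3), "rounds")
})

test_that("orientation composite encodes axis as hue, retardance as value", {
  ph <- make_phantom("spokes", c(32, 32, 1), seed = 1)
  rend <- render_polarization_stack(ph, NULL)
  A <- instrument_matrix(0.06 * pi)
  pr <- correct_background(invert_intensities(rend$sample, A),
                           invert_intensities(rend$background, A),
                           rounds = 1)
  comp <- orientation_composite(pr)
  expect_equal(dim(comp), c(32L, 32L, 3L))
  expect_true(all(comp >= 0 & comp <= 1))
  ## empty pixels (rho = 0) are black
  expect_true(all(abs(comp[1, 1, ]) < 1e-6))
})
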