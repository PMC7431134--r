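opt_ph <- optics_config(0.532, 0.55, 0.4, 0.2, 0.5)

test_that("3D Tikhonov deconvolution recovers a noiseless phantom", {
  tf <- transfer_functions(opt_ph, c(32, 32, 8), "3D")
  ph <- make_phantom("beads", c(32, 32, 8),
                     params = list(n = 3, phi_amp = 0.1), seed = 2)
  m0 <- forward_brightfield(ph$phi_map, tf)
  tau <- 1e-4 * max(Mod(tf$h_phase3)^2)
  rec <- reconstruct_phase_3d(m0, tf, reg_config(tau_phase = tau))
  expect_gt(cor(as.numeric(rec), as.numeric(ph$phi_map)), 0.9)
  ## zero input -> zero output
  expect_equal(reconstruct_phase_3d(array(1, c(32, 32, 8)), tf,
                                    reg_config(tau_phase = tau)),
               array(0, c(32, 32, 8)), tolerance = 1e-12)
  ## Tikhonov shrinkage: solution norm non-increasing in tau
  norms <- sapply(10^seq(-6, 0, by = 1), function(tau)
    sqrt(sum(reconstruct_phase_3d(m0, tf, reg_config(tau_phase = tau))^2)))
  expect_true(all(diff(norms) <= 1e-12))
  ## deterministic
  rec2 <- reconstruct_phase_3d(m0, tf, reg_config(tau_phase = tau))
  expect_identical(rec, rec2)
})

test_that("forward model is linear in the weak-object regime", {
  tf <- transfer_functions(opt_ph, c(32, 32, 8), "3D")
  ph1 <- make_phantom("beads", c(32, 32, 8),
                      params = list(n = 2, phi_amp = 0.05), seed = 3)
  ph2 <- make_phantom("beads", c(32, 32, 8),
                      params = list(n = 2, phi_amp = 0.05), seed = 4)
  f1 <- forward_brightfield(ph1$phi_map, tf) - 1
  f2 <- forward_brightfield(ph2$phi_map, tf) - 1
  f12 <- forward_brightfield(ph1$phi_map + ph2$phi_map, tf) - 1
  expect_equal(f12, f1 + f2, tolerance = 1e-10)
})

test_that("dry-mass proxy scales linearly with phase amplitude", {
  tf <- transfer_functions(opt_ph, c(32, 32, 8), "3D")
  ph <- make_phantom("beads", c(32, 32, 8),
                     params = list(n = 1, phi_amp = 1), seed = 5)
  amps <- c(0.02, 0.04, 0.06, 0.08, 0.10)
  tau <- 1e-4 * max(Mod(tf$h_phase3)^2)
  ## the reconstruction is dc-free (H_phi(0) = 0), so integrate over the
  ## bead support rather than the whole volume
  bead <- ph$phi_map > 0
  mass <- sapply(amps, function(a) {
    m0 <- forward_brightfield(a * ph$phi_map, tf)
    sum(reconstruct_phase_3d(m0, tf, reg_config(tau_phase = tau))[bead])
  })
  expect_gt(cor(mass, amps)^2, 0.99)
})

test_that("TV solver is monotone and limits to the least-squares solution", {
  tf <- transfer_functions(opt_ph, c(32, 32, 8), "3D")
  ph <- make_phantom("beads", c(32, 32, 8),
                     params = list(n = 3, phi_amp = 0.1), seed = 2)
  m0 <- forward_brightfield(ph$phi_map, tf)
  set.seed(9)
  m0n <- m0 + array(rnorm(length(m0), 0, 0.002), dim(m0))
  rec <- reconstruct_phase_3d(m0n, tf,
                              reg_config(tau_phase = 1e-4, method = "TV",
                                         tv_iterations = 50))
  obj <- attr(rec, "objective")
  expect_length(obj, 50L)
  expect_true(all(diff(obj) <= 1e-10 * obj[1]))
  ## as the TV weight vanishes, the Tikhonov solution is a fixed point
  tik <- suppressWarnings(
    reconstruct_phase_3d(m0, tf, reg_config(tau_phase = 0)))
  g <- m0 / mean(m0) - 1
  st <- tv_denoise_step(tik, g, tf$h_phase3,
                        reg_config(tau_phase = 1e-12, method = "TV"))
  expect_lt(sqrt(mean((st$phi - tik)^2)) / sqrt(mean(tik^2)), 1e-4)
})

test_that("TV beats Tikhonov on a noisy piecewise-constant phantom", {
  tf <- transfer_functions(opt_ph, c(32, 32, 8), "3D")
  ph <- make_phantom("star", c(32, 32, 8), params = list(phi_amp = 0.1),
                     seed = 3)
  set.seed(13)
  m0 <- forward_brightfield(ph$phi_map, tf) +
    array(rnorm(32 * 32 * 8, 0, 0.005), c(32, 32, 8))
  tau <- 2e-3
  r_tik <- reconstruct_phase_3d(m0, tf, reg_config(tau_phase = tau))
  r_tv <- reconstruct_phase_3d(m0, tf,
                               reg_config(tau_phase = tau, method = "TV",
                                          tv_iterations = 50))
  rmse <- function(a) sqrt(mean((a - ph$phi_map)^2))
  expect_lt(rmse(r_tv), rmse(r_tik))
})

test_that("2D joint solve separates phase from absorption", {
  tf <- transfer_functions(opt_ph, c(48, 48, 7), "2D")
  phi0 <- qpli:::gauss_blur({m <- matrix(0, 48, 48)
                             m[15:30, 15:30] <- 0.1; m}, 2)
  reg <- reg_config(tau_phase = 1e-6, tau_abs = 1e-6)
  ## pure phase phantom
  res <- reconstruct_phase_2d(forward_brightfield(phi0, tf), tf, reg)
  expect_gt(cor(as.numeric(res$phase), as.numeric(phi0)), 0.95)
  expect_lt(max(abs(res$absorption)), 0.05 * max(abs(res$phase)))
  ## pure weak absorber
  resa <- reconstruct_phase_2d(forward_brightfield(0 * phi0, tf, mu = phi0),
                               tf, reg)
  expect_gt(cor(as.numeric(resa$absorption), as.numeric(phi0)), 0.95)
  expect_lt(max(abs(resa$phase)), 0.05 * max(abs(resa$absorption)))
  ## single plane is ill-posed
  tf1 <- transfer_functions(opt_ph, c(48, 48, 1), "2D")
  expect_error(reconstruct_phase_2d(forward_brightfield(phi0, tf1), tf1,
                                    reg),
               "ill-posed")
})

test_that("more defocus diversity never hurts noiseless 2D recovery", {
  phi0 <- qpli:::gauss_blur({m <- matrix(0, 32, 32)
                             m[10:22, 10:22] <- 0.1; m}, 2)
  reg <- reg_config(tau_phase = 1e-6, tau_abs = 1e-6)
  cors <- sapply(c(3, 5, 9), function(nz) {
    tf <- transfer_functions(opt_ph, c(32, 32, nz), "2D")
    res <- reconstruct_phase_2d(forward_brightfield(phi0, tf), tf, reg)
    cor(as.numeric(res$phase), as.numeric(phi0))
  })
  expect_true(all(diff(cors) >= -1e-6))
})

test_that("2D TV variant reports a non-increasing objective", {
  tf <- transfer_functions(opt_ph, c(32, 32, 5), "2D")
  phi0 <- qpli:::gauss_blur({m <- matrix(0, 32, 32)
                             m[10:22, 10:22] <- 0.1; m}, 2)
  set.seed(21)
  m0 <- forward_brightfield(phi0, tf) +
    array(rnorm(32 * 32 * 5, 0, 0.003), c(32, 32, 5))
  res <- reconstruct_phase_2d(m0, tf,
                              reg_config(tau_phase = 1e-4, tau_abs = 1e-4,
                                         method = "TV",
                                         tv_iterations = 30))
  obj <- attr(res, "objective")
  expect_true(all(diff(obj) <= 1e-10 * obj[1]))
  expect_gt(cor(as.numeric(res$phase), as.numeric(phi0)), 0.9)
})
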