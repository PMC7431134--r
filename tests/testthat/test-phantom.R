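test_that("phantom kinds honour their construction contracts", {
  ## no beads -> empty phantom
  ph0 <- make_phantom("beads", c(16, 16, 2), params = list(n = 0), seed = 1)
  expect_true(all(ph0$t_map == 1) && all(ph0$p_map == 1) &&
                all(ph0$rho_map == 0) && all(ph0$phi_map == 0))
  ## spokes: slow axis perpendicular to each bar
  nb <- 8L
  ph <- make_phantom("spokes", c(64, 64, 1),
                     params = list(n_bars = nb, bar_width = 2,
                                   rho_amp = 0.2), seed = 1)
  angles <- (seq_len(nb) - 1) * pi / nb
  for (b in seq_len(nb)) {
    a <- angles[b]
    yy <- matrix(seq_len(64), 64, 64) - 32.5
    xx <- matrix(seq_len(64), 64, 64, byrow = TRUE) - 32.5
    on_bar <- abs(-sin(a) * xx + cos(a) * yy) <= 0.5 &
      (cos(a) * xx + sin(a) * yy) > 10 &
      (cos(a) * xx + sin(a) * yy) < 28 & ph$rho_map[, , 1] > 0
    if (any(on_bar))
      expect_true(all(abs(ph$omega_map[, , 1][on_bar] -
                            (a + pi / 2) %% pi) < 1e-12))
  }
  ## determinism
  expect_identical(make_phantom("beads", c(16, 16, 2), seed = 5),
                   make_phantom("beads", c(16, 16, 2), seed = 5))
  expect_false(identical(
    make_phantom("beads", c(16, 16, 2), seed = 5)$phi_map,
    make_phantom("beads", c(16, 16, 2), seed = 6)$phi_map))
  expect_error(make_phantom("nonsense"), "arg")
  ## ranges
  pl <- make_phantom("layered_tissue", c(32, 32, 2), seed = 2)
  expect_true(all(pl$t_map > 0 & pl$t_map <= 2))
  expect_true(all(pl$p_map > 0 & pl$p_map <= 1))
  expect_true(all(pl$rho_map >= 0 & pl$rho_map < pi / 2))
  expect_true(all(pl$omega_map >= 0 & pl$omega_map < pi))
})

test_that("renderer produces constant channels for an empty specimen", {
  ph <- make_phantom("beads", c(8, 8, 1), params = list(n = 0), seed = 1)
  rend <- render_polarization_stack(ph, NULL)
  A <- instrument_matrix(0.06 * pi)
  want <- as.numeric(A$a %*% c(1, 0, 0, 1))
  for (ch in 1:5) {
    plane <- rend$sample[, , 1, ch]
    expect_lt(diff(range(plane)), 1e-14)
    expect_equal(plane[1, 1], want[ch], tolerance = 1e-12)
  }
})

test_that("render -> invert -> correct recovers the phantom maps", {
  ph <- make_phantom("spokes", c(48, 48, 1),
                     params = list(rho_amp = 0.25, bar_width = 3), seed = 3)
  rend <- render_polarization_stack(ph, NULL)
  A <- instrument_matrix(0.06 * pi)
  pr <- correct_background(invert_intensities(rend$sample, A),
                           invert_intensities(rend$background, A),
                           rounds = 1)
  sel <- ph$rho_map[, , 1] > 0
  expect_lt(max(abs(pr$retardance[, , 1][sel] - 0.25)), 1e-6)
  derr <- abs(pr$slow_axis[, , 1][sel] - ph$omega_map[, , 1][sel]) %% pi
  expect_lt(max(pmin(derr, pi - derr)), 1e-6)
})

test_that("shot-noise error scales with the photon budget", {
  ph <- make_phantom("spokes", c(48, 48, 1),
                     params = list(rho_amp = 0.2), seed = 1)
  A <- instrument_matrix(0.06 * pi)
  rmse_at <- function(budget) {
    mean(sapply(1:20, function(rep) {
      rend <- render_polarization_stack(ph, NULL, photon_budget = budget,
                                        seed = rep * 7)
      pr <- correct_background(invert_intensities(rend$sample, A),
                               invert_intensities(rend$background, A),
                               rounds = 1)
      sel <- ph$rho_map[, , 1] > 0
      sqrt(mean((pr$retardance[, , 1][sel] - 0.2)^2, na.rm = TRUE))
    }))
  }
  ratio <- rmse_at(1e2) / rmse_at(1e4)
  expect_gt(ratio, 10 / 1.5)   # ~ sqrt(100), allow 50% slack
  expect_lt(ratio, 10 * 1.5)
  ## reproducible given seed
  r1 <- render_polarization_stack(ph, NULL, photon_budget = 100, seed = 3)
  r2 <- render_polarization_stack(ph, NULL, photon_budget = 100, seed = 3)
  expect_identical(r1$sample, r2$sample)
})

test_that("defocus contrast appears only through the optics", {
  ph <- make_phantom("beads", c(32, 32, 8),
                     params = list(n = 2, phi_amp = 0.1), seed = 4)
  opt <- optics_config(0.532, 0.55, 0.4, 0.2, 0.5)
  rend <- render_polarization_stack(ph, opt)
  ## defocus contrast makes z-planes differ
  expect_gt(max(abs(rend$sample[, , 1, 2] - rend$sample[, , 5, 2])), 1e-6)
  ## without optics, z planes are identical
  rend0 <- render_polarization_stack(ph, NULL)
  expect_equal(rend0$sample[, , 1, 2], rend0$sample[, , 8, 2],
               tolerance = 1e-14)
})

test_that("fluorescence targets are deterministic functions of the maps", {
  ph <- make_phantom("spokes", c(24, 24, 2), seed = 2)
  t1 <- make_fluorescence_target(ph, list(name = "rho"), seed = 4)
  expect_equal(t1, ph$rho_map)
  t2 <- make_fluorescence_target(ph, list(name = "rho_phi", a = 2, b = 1,
                                          gaussian_sd = 0.01), seed = 4)
  t2b <- make_fluorescence_target(ph, list(name = "rho_phi", a = 2, b = 1,
                                           gaussian_sd = 0.01), seed = 4)
  expect_identical(t2, t2b)
  expect_true(all(t2 >= 0))
  expect_error(make_fluorescence_target(ph, list(name = "wat")),
               "unknown generator")
})

test_that("paired datasets split 70/15/15 with floored val/test", {
  phs <- lapply(1:20, function(i)
    make_phantom("spokes", c(16, 16, 3), seed = i))
  ds <- make_paired_dataset(phs, seed = 1)
  expect_equal(sapply(ds[c("train", "val", "test")], length),
               c(train = 14L, val = 3L, test = 3L))
  ## deterministic membership, never shared
  ds2 <- make_paired_dataset(phs, seed = 1)
  expect_identical(ds$manifest, ds2$manifest)
  expect_equal(sort(unname(unlist(lapply(ds[c("train", "val", "test")],
                                         function(g)
                                           sapply(g, `[[`, "id"))))),
               1:20)
  expect_error(make_paired_dataset(phs, split = c(0.7, 0.2, 0.2)),
               "sum to 1")
  expect_error(make_paired_dataset(phs[1:2]), "3")
  ## orientation channels encode the angle continuously
  ic <- phantom_input_channels(phs[[1]])
  expect_equal(sqrt(ic[, , , 4]^2 + ic[, , , 5]^2),
               phs[[1]]$rho_map, tolerance = 1e-12)
})
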