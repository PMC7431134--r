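test_that("pearson matches the textbook formula and its invariances", {
  expect_equal(pearson(1:10, 1:10), 1)
  expect_equal(pearson(1:10, -(1:10) + 7), -1)
  t <- c(1, 2, 3, 4); p <- c(1, 2, 3, 5)
  expect_equal(pearson(t, p), brute_pearson(t, p), tolerance = 1e-12)
  set.seed(1)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(pearson(a, b), brute_pearson(a, b), tolerance = 1e-12)
  ## invariant to positive affine transforms
  expect_equal(pearson(3 * a + 2, b), pearson(a, b), tolerance = 1e-12)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:4, 1:5), "shapes")
})

test_that("ssim matches the windowed definition and a brute-force oracle", {
  set.seed(2)
  t <- matrix(runif(15 * 14), 15, 14)
  expect_equal(ssim(t, t), 1, tolerance = 1e-12)
  ## ten random pairs against the independent per-window loop
  for (i in 1:10) {
    p <- t + matrix(rnorm(15 * 14, 0, 0.1 * i), 15, 14)
    L <- max(t) - min(t)
    expect_equal(ssim(t, p, 7, L), brute_ssim(t, p, 7, L),
                 tolerance = 1e-6)
  }
  ## two constant images: sigma terms vanish, closed form survives
  c1v <- 0.4; c2v <- 0.7; L <- 1
  tC <- matrix(c1v, 9, 9); pC <- matrix(c2v, 9, 9)
  want <- (2 * c1v * c2v + (0.01 * L)^2) * (0.03 * L)^2 /
    ((c1v^2 + c2v^2 + (0.01 * L)^2) * (0.03 * L)^2)
  expect_equal(ssim(tC, pC, 7, dynamic_range = L), want,
               tolerance = 1e-12)
  ## scale sensitivity vs Pearson scale invariance
  set.seed(3)
  tv <- matrix(runif(20 * 20), 20, 20)
  pv <- tv + matrix(rnorm(400, 0, 0.05), 20, 20)
  L <- max(tv) - min(tv)
  shift <- 0.5 * IQR(tv)
  expect_lt(ssim(tv, pv + shift, 7, L), ssim(tv, pv, 7, L))
  expect_equal(pearson(tv, pv + shift), pearson(tv, pv),
               tolerance = 1e-12)
  ## symmetry given a shared dynamic range
  expect_equal(ssim(tv, pv, 7, L), ssim(pv, tv, 7, L), tolerance = 1e-12)
  expect_error(ssim(matrix(1, 3, 3), matrix(1, 3, 3), 7), "window larger")
  ## 3D windows agree with the brute-force volumetric oracle
  tv3 <- array(runif(9 * 9 * 8), c(9, 9, 8))
  pv3 <- tv3 + array(rnorm(9 * 9 * 8, 0, 0.1), c(9, 9, 8))
  expect_error(ssim(tv3, pv3, 9), "window larger")
  L3 <- max(tv3) - min(tv3)
  expect_equal(ssim(tv3, pv3, 7, L3), brute_ssim(tv3, pv3, 7, L3),
               tolerance = 1e-6)
})

test_that("plane-wise metrics aggregate with the median", {
  set.seed(4)
  t <- array(runif(16 * 16 * 9), c(16, 16, 9))
  rep0 <- metrics_by_plane(t, t)
  expect_equal(rep0$summary$median_r, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep0$summary$median_ssim, rep(1, 3), tolerance = 1e-12)
  expect_equal(rep0$summary$n, c(9L, 16L, 1L))
  ## one corrupted slice moves the min, not the median
  p <- t
  p[, , 5] <- matrix(runif(256), 16, 16)
  rep1 <- metrics_by_plane(t, p)
  xy <- rep1$slices[rep1$slices$axis == "xy", ]
  expect_gt(rep1$summary$median_r[1], 0.99)
  expect_lt(min(xy$r), 0.5)
  ## axis permutation consistency: transposing y and z swaps xy and xz
  tp <- aperm(t, c(3, 2, 1)); pp <- aperm(p, c(3, 2, 1))
  rep2 <- metrics_by_plane(tp, pp)
  s1 <- rep1$summary; s2 <- rep2$summary
  expect_equal(s2$median_r[s2$axis == "xz"], s1$median_r[s1$axis == "xy"],
               tolerance = 1e-12)
  expect_equal(s2$median_r[s2$axis == "xy"], s1$median_r[s1$axis == "xz"],
               tolerance = 1e-12)
  ## CSV export round trip
  f <- tempfile(fileext = ".csv")
  write_metrics_csv(rep1, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(rep1$slices))
  expect_equal(back$r, rep1$slices$r, tolerance = 1e-12)
})

test_that("otsu and rosin thresholds land where the histograms say", {
  set.seed(5)
  ## bimodal: threshold strictly between the modes
  v <- c(rnorm(4000, 10, 5), rnorm(1000, 100, 5))
  th <- otsu_threshold(v)
  expect_gt(th, 15); expect_lt(th, 95)
  ## binary image: both methods separate the classes exactly
  b <- matrix(rep(c(0, 1), each = 50), 10, 10)
  expect_true(otsu_threshold(b) > 0 && otsu_threshold(b) < 1)
  expect_true(rosin_threshold(b) > 0 && rosin_threshold(b) < 1)
  m <- foreground_mask(b, "otsu")
  expect_equal(m, b > 0.5)
  ## unimodal with exponential tail: rosin falls past the mode,
  ## before the tail end
  ve <- c(rnorm(20000, 0, 1), rexp(400, 1 / 20) + 2)
  tr <- rosin_threshold(ve)
  expect_gt(tr, 1)
  expect_lt(tr, max(ve) * 0.8)
  expect_error(otsu_threshold(matrix(1, 4, 4)), "constant image")
  expect_error(rosin_threshold(matrix(2, 4, 4)), "constant image")
})
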