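test_that("unfold follows the row-major convention and refold inverts it", {
  cube <- array(rnorm(2 * 3 * 7), dim = c(2, 3, 7))
  m <- hyperspec_map(cube, wn_axis(725, 731, 1),
                     labels = matrix(letters[1:6], 2, 3))
  sm <- unfold(m)
  expect_equal(dim(sm$X), c(6L, 7L))
  # pixel (0,1) is matrix row index 1 (0-based), i.e. the second row
  expect_equal(sm$X[2, ], cube[1, 2, ])
  expect_equal(unname(sm$pixel_index[2, ]), c(0L, 1L))
  expect_equal(sm$labels[2], m$labels[1, 2])
  back <- refold(sm)
  expect_identical(back$intensities, m$intensities)
  expect_identical(back$labels, m$labels)
})

test_that("refold rejects incomplete or duplicated pixel sets", {
  cube <- array(rnorm(2 * 3 * 5), dim = c(2, 3, 5))
  sm <- unfold(hyperspec_map(cube, wn_axis(725, 729, 1)))
  short <- spectra_matrix(sm$X[1:5, ], sm$axis, pixel_index = sm$pixel_index[1:5, ])
  expect_error(refold(short, shape = c(2, 3)), "6 pixels expected, 5 given")
  dup <- spectra_matrix(sm$X, sm$axis,
                        pixel_index = sm$pixel_index[c(1, 1, 3:6), ])
  expect_error(refold(dup, shape = c(2, 3)), "duplicate")
})

test_that("SG smoothing reproduces polynomials up to its order exactly", {
  x <- seq(0, 1, length.out = 120)
  expect_equal(sg_smooth(rep(5, 120), 21, 2), rep(5, 120), tolerance = 1e-12)
  y <- 2 * x^2 - 3 * x + 1
  expect_equal(sg_smooth(y, 21, 2), y, tolerance = 1e-9)
})

test_that("SG smoothing matches the sliding local least-squares oracle", {
  set.seed(101)
  y <- rnorm(200)
  expect_lt(max(abs(sg_smooth(y, 21, 2) - oracle_sg(y, 21, 2))), 1e-10)
  y2 <- cumsum(rnorm(150))
  expect_lt(max(abs(sg_smooth(y2, 11, 3) - oracle_sg(y2, 11, 3))), 1e-10)
})

test_that("SG smoothing is linear and validates its arguments", {
  set.seed(5)
  a <- rnorm(80); b <- rnorm(80)
  lhs <- sg_smooth(2 * a + 3 * b, 21, 2)
  rhs <- 2 * sg_smooth(a, 21, 2) + 3 * sg_smooth(b, 21, 2)
  expect_lt(max(abs(lhs - rhs)), 1e-9)
  expect_error(sg_smooth(a, 20, 2), "odd")
  expect_error(sg_smooth(rnorm(10), 21, 2), "shorter")
})

test_that("AWLS fixed points and exact-solve oracle", {
  expect_equal(awls_baseline(rep(0, 100))$baseline, rep(0, 100))
  expect_equal(awls_baseline(rep(0, 100))$corrected, rep(0, 100))
  # peak-free constant offset: baseline returns the offset
  cval <- 7.3
  res <- awls_baseline(rep(cval, 500), lambda = 1e5)
  expect_lt(max(abs(res$baseline - cval)), 1e-3 * cval)
  expect_lt(max(abs(res$corrected)), 1e-3 * cval)
  # oracle: dense penalised-least-squares solve with the final weights
  set.seed(9)
  y <- 2 + sin(seq(0, 3, length.out = 120)) + rnorm(120, 0, 0.05)
  lam <- 1e4
  fit <- awls_baseline(y, lambda = lam)
  D <- diff(diag(120), differences = 2)
  z_exact <- solve(diag(fit$weights) + lam * crossprod(D), fit$weights * y)
  expect_lt(max(abs(fit$baseline - z_exact)), 1e-8)
})

test_that("AWLS recovers known peak heights on a cubic baseline", {
  ax <- seq(725, 1813, by = 1)
  u <- (ax - 725) / (1813 - 725)
  base <- 0.8 + 1.2 * u - 0.8 * u^2 + 0.3 * u^3
  g <- function(c, h, w) h * exp(-4 * log(2) * (ax - c)^2 / w^2)
  truth <- c(`900` = 1, `1300` = 0.8, `1650` = 0.6)
  y <- base + g(900, 1, 15) + g(1300, 0.8, 15) + g(1650, 0.6, 15)
  res <- awls_baseline(y, lambda = 1e5)
  expect_true(res$converged)
  for (ctr in names(truth)) {
    i <- which(abs(ax - as.numeric(ctr)) <= 20)
    expect_equal(max(res$corrected[i]), unname(truth[ctr]), tolerance = 0.03)
  }
})

test_that("AWLS baseline is smoother than the input and losses are bounded", {
  set.seed(21)
  second_diff_energy <- function(z) sum(diff(z, differences = 2)^2)
  for (k in 1:4) {
    y <- cumsum(rnorm(150)) + rnorm(150)
    fit <- awls_baseline(y, lambda = max(1, 10^k))
    expect_lte(second_diff_energy(fit$baseline), second_diff_energy(y))
  }
  # on noisy synthetic input, corrected stays above -5 * noise_sd nearly everywhere
  noise_sd <- 0.02
  ax <- seq_len(600)
  y <- 1 + 0.002 * ax + 0.5 * exp(-((ax - 300) / 30)^2) + rnorm(600, 0, noise_sd)
  fit <- awls_baseline(y, lambda = 1e5)
  expect_gte(mean(fit$corrected >= -5 * noise_sd), 0.95)
})

test_that("preprocess_matrix is row-independent and order-sensitive", {
  ax <- wn_axis(725, 824, 1)
  x <- as.numeric(ax)
  base <- 1 + 0.01 * (x - 725)
  spec <- base + exp(-((x - 770) / 5)^2)
  X <- rbind(spec, spec, spec)
  out <- preprocess_matrix(spectra_matrix(X, ax))
  expect_equal(out$X[1, ], out$X[2, ])
  expect_equal(out$X[1, ], out$X[3, ])
  # smoothing-then-baseline differs from baseline-then-smoothing on a peaked
  # noisy fixture
  set.seed(33)
  noisy <- spec + rnorm(length(spec), 0, 0.05)
  cfg <- preprocess_config()
  sb <- awls_baseline(sg_smooth(noisy, 21, 2), lambda = cfg$awls_lambda)$corrected
  bs <- sg_smooth(awls_baseline(noisy, lambda = cfg$awls_lambda)$corrected, 21, 2)
  expect_gt(max(abs(sb - bs)), 1e-4)
  # the pipeline applies smoothing first
  got <- preprocess_matrix(spectra_matrix(rbind(noisy), ax))$X[1, ]
  expect_equal(got, sb, tolerance = 1e-10)
})

test_that("preprocess_matrix handles the empty matrix and permutes cleanly", {
  ax <- wn_axis(725, 774, 1)
  empty <- spectra_matrix(matrix(numeric(0), 0, 50), ax)
  out <- preprocess_matrix(empty)
  expect_equal(nrow(out$X), 0L)
  set.seed(8)
  X <- matrix(rnorm(6 * 50, mean = 3), 6, 50)
  perm <- c(4, 1, 6, 2, 3, 5)
  a <- preprocess_matrix(spectra_matrix(X, ax))$X[perm, ]
  b <- preprocess_matrix(spectra_matrix(X[perm, ], ax))$X
  expect_equal(a, b, tolerance = 1e-12)
})
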