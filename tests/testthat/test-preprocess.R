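make_run <- function(arr, tr = 2) bold_run(arr, voxel_size = 3, tr = tr)

test_that("discard_initial_volumes drops exactly the leading frames", {
  set.seed(1)
  arr <- array(rnorm(4 * 4 * 2 * 240), c(4, 4, 2, 240))
  run <- make_run(arr)
  out <- discard_initial_volumes(run, 4)
  expect_identical(dim(out$data)[4], 236L)
  expect_identical(out$data[, , , 1], arr[, , , 5])
  expect_identical(discard_initial_volumes(run, 0)$data, arr)
  expect_error(discard_initial_volumes(run, 240), "smaller than")
  nuis <- data.frame(matrix(rnorm(240 * 8), 240, 8))
  expect_identical(discard_initial_volumes(nuis, 4),
                   nuis[5:240, , drop = FALSE])
})

test_that("nuisance regression matches a normal-equations oracle and leaves orthogonal residuals", {
  set.seed(2)
  n <- 60
  nuis <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(nuis) <- c(paste0("mot", 1:6), "wm", "csf")
  arr <- array(rnorm(3 * 3 * 2 * n), c(3, 3, 2, n))
  run <- make_run(arr)
  out <- regress_nuisance(run, nuis)
  X <- cbind(1, as.matrix(nuis))
  for (v in 1:5) {
    ijk <- arrayInd(sample(prod(dim(arr)[1:3]), 1), dim(arr)[1:3])
    y <- arr[ijk[1], ijk[2], ijk[3], ]
    expect_lt(max(abs(out$data[ijk[1], ijk[2], ijk[3], ] -
                        oracle_resid(y, X))), 1e-8)
  }
  # residual-regressor correlations vanish
  res1 <- out$data[1, 1, 1, ]
  for (k in 1:8) expect_lt(abs(cor(res1, nuis[[k]])), 1e-10)
})

test_that("nuisance regression edge cases behave as specified", {
  set.seed(3)
  n <- 40
  nuis <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(nuis) <- c(paste0("mot", 1:6), "wm", "csf")
  arr <- array(rnorm(2 * 2 * 1 * n), c(2, 2, 1, n))
  # a voxel equal to mot1 leaves a zero residual
  arr[1, 1, 1, ] <- nuis$mot1
  out <- regress_nuisance(make_run(arr), nuis)
  expect_lt(max(abs(out$data[1, 1, 1, ])), 1e-10)
  # zero nuisance matrix + intercept = mean-centering
  zero <- as.data.frame(matrix(0, n, 8))
  names(zero) <- names(nuis)
  out0 <- regress_nuisance(make_run(arr), zero)
  expect_equal(out0$data[2, 1, 1, ], arr[2, 1, 1, ] - mean(arr[2, 1, 1, ]),
               tolerance = 1e-12)
  # duplicated regressor -> error naming the collinear column
  dup <- nuis
  dup$csf <- dup$mot1
  expect_error(regress_nuisance(make_run(arr), dup), "collinear.*csf")
  # length mismatch
  expect_error(regress_nuisance(make_run(arr), nuis[1:10, ]), "frames")
})

test_that("bandpass filter meets its gain contract with zero phase distortion", {
  tr <- 2
  n <- 236
  t_s <- (seq_len(n) - 1) * tr
  pass <- sin(2 * pi * 0.05 * t_s)
  stopb <- sin(2 * pi * 0.2 * t_s)
  out_pass <- bandpass(pass, c(0.01, 0.1), tr)
  out_stop <- bandpass(stopb, c(0.01, 0.1), tr)
  expect_gte(fft_amplitude(out_pass, 0.05, tr) / fft_amplitude(pass, 0.05, tr),
             0.9)
  expect_lte(fft_amplitude(out_stop, 0.2, tr) / fft_amplitude(stopb, 0.2, tr),
             0.1)
  # zero phase: Fourier phase at the passband frequency is unchanged
  bin <- round(0.05 * n * tr) + 1L
  dphase <- Arg(fft(out_pass)[bin]) - Arg(fft(pass)[bin])
  expect_lt(abs(dphase), 1e-6)
  # DC removed entirely
  dc <- bandpass(rep(3, n), c(0.01, 0.1), tr)
  expect_lt(max(abs(dc)), 1e-6)
  expect_error(bandpass(pass, c(0.01, 0.3), tr), "Nyquist")
  expect_error(preproc_config(band = c(0.01, 0.25), tr = 2), "band")
})

test_that("Gaussian smoothing has the right kernel width and conserves mass", {
  vox <- 3
  arr3 <- array(0, c(15, 15, 15))
  arr3[8, 8, 8] <- 1
  sm <- smooth_spatial(arr3, fwhm_mm = 6, voxel_size = vox)
  # fitted sigma from the second moment of the profile through the peak
  prof <- sm[, 8, 8]
  x_mm <- (seq_len(15) - 8) * vox
  sigma_fit <- sqrt(sum(prof * x_mm^2) / sum(prof))
  expect_lt(abs(sigma_fit - 6 / 2.3548) / (6 / 2.3548), 0.05)
  # mass conserved (kernel support fully interior)
  expect_lt(abs(sum(sm) - 1), 1e-3)
  # fwhm 0 is the identity; uniform images are untouched
  expect_identical(smooth_spatial(arr3, 0, vox), arr3)
  uni <- array(2, c(8, 8, 8))
  expect_equal(smooth_spatial(uni, 6, vox), uni, tolerance = 1e-12)
  expect_error(smooth_spatial(arr3, -1, vox), "non-negative")
})

test_that("the preprocessing chain is linear, deterministic, and records its order", {
  set.seed(4)
  n <- 48
  spec_nuis <- as.data.frame(matrix(rnorm(n * 8), n, 8))
  names(spec_nuis) <- c(paste0("mot", 1:6), "wm", "csf")
  arr <- array(rnorm(6 * 6 * 4 * n), c(6, 6, 4, n))
  cfg <- preproc_config(n_discard = 4, tr = 2)
  run1 <- preprocess_run(make_run(arr), spec_nuis, cfg)
  run2 <- preprocess_run(make_run(arr), spec_nuis, cfg)
  expect_identical(run1$data, run2$data)
  runs <- preprocess_run(make_run(3.5 * arr), spec_nuis, cfg)
  expect_equal(runs$data, 3.5 * run1$data, tolerance = 1e-10)
  stages <- vapply(run1$provenance, `[[`, "", "stage")
  expect_identical(stages[1:4], c("discard", "regress", "bandpass", "smooth"))
})
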