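make_series <- function(data, tr = 3) bold_series(data, tr = tr)

test_that("initial-frame trimming follows the acquisition convention", {
  s <- make_series(matrix(rnorm(10 * 165), 10, 165))
  expect_equal(ncol(discard_initial_frames(s, 5)$data), 160)
  expect_identical(discard_initial_frames(s, 0), s)
  short <- matrix(rnorm(10 * 25), 10, 25)
  expect_error(discard_initial_frames(make_series(short), 25), "too few")
})

test_that("tCompCor removes a planted nuisance confined to high-variance voxels", {
  set.seed(4)
  V <- 100; Tn <- 120
  nuis <- rnorm(Tn)
  X <- matrix(rnorm(V * Tn), V, Tn)
  noisy <- 1:3                              # planted noise-dominated voxels
  X[noisy, ] <- X[noisy, ] + 8 * rep(1, 3) %o% nuis
  out <- tcompcor_denoise(make_series(X), mask_fraction = 0.03,
                          n_components = 3)
  expect_setequal(attr(out, "noise_mask"), noisy)
  clean_cor <- apply(out$data[-noisy, ], 1, cor, y = nuis)
  expect_true(all(abs(clean_cor) < 0.1))

  # n_components = 0 -> identity up to per-voxel linear detrend
  out0 <- tcompcor_denoise(make_series(X), n_components = 0)
  t1 <- seq_len(Tn) - (Tn + 1) / 2
  manual <- t(apply(X, 1, function(z) residuals(lm(z ~ t1))))
  expect_equal(unname(out0$data), unname(manual), tolerance = 1e-8)

  # identical variance everywhere: mask is the deterministic lowest-index set
  Xc <- matrix(rep(rnorm(Tn), each = 10), 10, Tn)
  outc <- tcompcor_denoise(make_series(Xc), mask_fraction = 0.3,
                           n_components = 1)
  expect_equal(attr(outc, "noise_mask"), 1:3)
  expect_error(tcompcor_denoise(make_series(X), n_components = 120), "frame")
})

test_that("band-pass filter passes in-band tones and rejects stopband", {
  tone <- function(f, tr, n = 400) sin(2 * pi * f * seq_len(n) * tr)
  gain <- function(f, tr) {
    s <- make_series(rbind(tone(f, tr), tone(f, tr)), tr = tr)
    y <- bandpass(s)$data[1, ]
    mid <- 100:300
    max(abs(y[mid])) / max(abs(tone(f, tr)[mid]))
  }
  expect_equal(gain(0.05, tr = 3), 1, tolerance = 0.05)      # in band
  expect_lt(gain(0.005, tr = 1), 10^(-20 / 20))              # 0.5 x low edge
  expect_lt(gain(0.32, tr = 1), 10^(-20 / 20))               # 2 x high edge
  # constant series -> all-zero output (DC removal)
  s <- make_series(matrix(5, 2, 100))
  expect_equal(max(abs(bandpass(s)$data)), 0)
  # high edge above Nyquist is rejected: Nyquist = 1/6 Hz at TR = 3
  expect_error(bandpass(make_series(matrix(rnorm(200), 2), tr = 3),
                        high = 0.2), "Nyquist")
})

test_that("FCD matches the hand-worked 6-voxel construction", {
  set.seed(1)
  a <- rnorm(60); b <- rnorm(60)
  b <- residuals(lm(b ~ a))                 # orthogonalize
  noise <- rnorm(60) * 1e-3
  X <- rbind(a, a, a, b, b, noise)
  map <- compute_fcd(make_series(X))
  expect_equal(map$degree, c(2L, 2L, 2L, 1L, 1L, 0L))
  expect_equal(map$values,
               c(log(3) / log(2), log(3) / log(2), log(3) / log(2), 1, 1, 0))
})

test_that("FCD link rule is strict and handles degenerate maps", {
  # all identical nonconstant series: complete graph, normalized map all 1
  z <- rnorm(50)
  map <- compute_fcd(make_series(matrix(rep(z, 5), 5, byrow = TRUE)))
  expect_equal(map$degree, rep(4L, 5))
  expect_equal(map$values, rep(1, 5))

  # correlation exactly at the threshold makes no link (strict inequality);
  # the threshold is taken from the same correlation code path
  x <- rep(c(1, 2, 3, 4, 5), 4); y <- rep(c(1, 3, 2, 5, 4), 4)
  r <- cor(t(rbind(x, y)))[1, 2]
  m <- compute_fcd(make_series(rbind(x, y)), threshold = r,
                   normalization = "none")
  expect_equal(m$degree, c(0L, 0L))

  # no links anywhere: median-normalization must fail loudly
  set.seed(2)
  X0 <- matrix(rnorm(20 * 200), 20, 200)
  expect_error(compute_fcd(make_series(X0)), "median")
  expect_silent(m0 <- compute_fcd(make_series(X0), normalization = "none"))
  expect_true(all(m0$values == 0))

  # constant voxel: degree 0 with a warning, not an abort
  Xc <- rbind(matrix(rep(rnorm(100), 3), 3, byrow = TRUE), 0)
  expect_warning(mc <- compute_fcd(make_series(Xc)), "constant")
  expect_equal(mc$degree[4], 0L)
})

test_that("FCD is invariant to affine rescaling and equivariant to voxel order", {
  set.seed(3)
  X <- shared_latent_series(30, 80, k = 20, a = 2)
  m1 <- compute_fcd(make_series(X))
  scl <- runif(30, 0.1, 5); off <- rnorm(30, 0, 10)
  m2 <- compute_fcd(make_series(X * scl + off))
  expect_equal(m1$values, m2$values)
  perm <- sample(30)
  m3 <- compute_fcd(make_series(X[perm, ]))
  expect_equal(m3$values, m1$values[perm])
  # median (order-statistic convention) of every returned map is exactly 1
  expect_equal(quantile(m1$values, 0.5, type = 1, names = FALSE), 1)
  # log base choice only rescales before normalization: median-ratio maps match
  m10 <- compute_fcd(make_series(X), log_base = 10)
  expect_equal(m10$values, m1$values)
})

test_that("FCD equals the brute-force O(V^2) oracle on random instances", {
  set.seed(10)
  for (rep in 1:10) {
    V <- sample(10:60, 1); Tn <- sample(30:80, 1)
    X <- shared_latent_series(V, Tn, k = ceiling(0.7 * V), a = 3, seed = rep)
    m <- compute_fcd(make_series(X))
    expect_identical(m$values, fcd_bruteforce(X))
  }
})

test_that("masked Gaussian smoothing preserves constants and matches the kernel", {
  cfg <- cohort_config(n_voxels = 1000, grid_dim = c(10, 10, 10))
  mask <- fcdstrat:::.grid_mask(cfg)
  mk_map <- function(v) structure(list(values = v, degree = NULL,
                                       threshold = 0.7,
                                       normalization = "median-ratio",
                                       smoothed = FALSE, mask = mask),
                                  class = "fcd_map")
  expect_equal(smooth_map(mk_map(rep(2, 1000)))$values, rep(2, 1000))

  # unit impulse in the grid interior: ratio to center equals the closed-form
  # Gaussian with sigma = fwhm / 2.3548
  v <- numeric(1000)
  center <- which(mask$x == 5 & mask$y == 5 & mask$z == 5)
  v[center] <- 1
  sm <- smooth_map(mk_map(v), fwhm_voxels = 2.5)$values
  sigma <- 2.5 / sqrt(8 * log(2))
  nb1 <- which(mask$x == 6 & mask$y == 5 & mask$z == 5)
  nb2 <- which(mask$x == 6 & mask$y == 6 & mask$z == 5)
  expect_equal(sm[nb1] / sm[center], exp(-1 / (2 * sigma^2)), tolerance = 1e-6)
  expect_equal(sm[nb2] / sm[center], exp(-2 / (2 * sigma^2)), tolerance = 1e-6)

  # fwhm -> 0 limit approaches identity
  v2 <- runif(1000)
  expect_equal(smooth_map(mk_map(v2), fwhm_voxels = 0.05)$values, v2,
               tolerance = 1e-6)
  expect_error(smooth_map(mk_map(v2), fwhm_voxels = 0), "positive")
})

test_that("motion QC applies the strict more-than-10-frames rule", {
  fd11 <- c(rep(0.7, 11), rep(0.1, 100))
  fd10 <- c(rep(0.7, 10), rep(0.1, 100))
  expect_equal(motion_qc(fd11), "exclude")
  expect_equal(motion_qc(fd10), "retain")          # exactly 10 -> retain
  ms <- motion_summary(rep(0, 50))
  expect_equal(motion_qc(ms), "retain")
  expect_equal(ms$fd_mean, 0)
  expect_equal(motion_summary(fd11)$n_frames_above, 11)
  expect_error(motion_summary(c(-0.1, 0.2)), "non-negative")
})

test_that("NIfTI and CSV round trips preserve maps and traces", {
  skip_if_not_installed("RNifti")
  tmp <- withr::local_tempdir()
  # build a small 4-D volume + mask, read back, FCD, write, re-read
  arr <- array(rnorm(4 * 4 * 3 * 40), c(4, 4, 3, 40))
  maskarr <- array(1L, c(4, 4, 3)); maskarr[1, 1, 1] <- 0L
  bold_path <- file.path(tmp, "bold.nii.gz")
  mask_path <- file.path(tmp, "mask.nii.gz")
  RNifti::writeNifti(RNifti::asNifti(arr), bold_path)
  RNifti::writeNifti(RNifti::asNifti(maskarr), mask_path)
  bs <- read_bold_nifti(bold_path, mask_path, tr = 3)
  expect_equal(nrow(bs$data), 47)
  expect_equal(ncol(bs$data), 40)
  map <- suppressWarnings(compute_fcd(bs, normalization = "none"))
  out_nii <- file.path(tmp, "fcd.nii.gz"); out_csv <- file.path(tmp, "fcd.csv")
  write_fcd_map(map, nifti_path = out_nii, csv_path = out_csv)
  back <- utils::read.csv(out_csv)
  expect_equal(back$value, map$values)
  vol <- RNifti::readNifti(out_nii)
  expect_equal(dim(vol), c(4, 4, 3))
  # motion trace round trip
  fd <- abs(rnorm(30, 0.2, 0.1))
  trace_path <- file.path(tmp, "fd.txt")
  writeLines(format(fd, digits = 10), trace_path)
  ms <- read_motion_trace(trace_path)
  expect_equal(ms$fd_per_frame, fd, tolerance = 1e-8)
})
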