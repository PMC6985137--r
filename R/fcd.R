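#' BOLD series container
#'
#' @param data voxel x frame numeric matrix.
#' @param tr Sampling interval in seconds.
#' @param mask Data frame mapping voxel index to grid coordinates
#'   (columns `voxel`, `x`, `y`, `z`).
#' @param subject_id,visit Identifiers carried through preprocessing.
#' @return A `bold_series` object.
#' @export
bold_series <- function(data, tr, mask = NULL, subject_id = NA_character_,
                        visit = NA_integer_) {
  data <- as.matrix(data)
  if (!all(is.finite(data))) stop("bold_series: non-finite values in data")
  if (ncol(data) < 20L) stop("bold_series: fewer than 20 frames")
  structure(list(data = data, tr = tr, mask = mask,
                 subject_id = subject_id, visit = as.integer(visit)),
            class = "bold_series")
}

#' @export
print.bold_series <- function(x, ...) {
  cat(sprintf("<bold_series> %s visit %s: %d voxels x %d frames, TR = %gs\n",
              x$subject_id, x$visit, nrow(x$data), ncol(x$data), x$tr))
  invisible(x)
}

#' Discard unsteady initial frames
#'
#' @param series A [bold_series()].
#' @param n_discard Number of leading frames to drop (default 5).
#' @return The trimmed `bold_series`.
#' @export
discard_initial_frames <- function(series, n_discard = 5L) {
  stopifnot(inherits(series, "bold_series"))
  if (n_discard < 0) stop("n_discard must be non-negative")
  if (ncol(series$data) <= n_discard)
    stop("too few frames: all frames would be discarded")
  if (n_discard == 0L) return(series)
  series$data <- series$data[, -seq_len(n_discard), drop = FALSE]
  series
}

# per-row linear detrend (used by tCompCor's variance ranking)
.detrend_rows <- function(m) {
  Tn <- ncol(m)
  t1 <- seq_len(Tn) - (Tn + 1) / 2
  beta <- (m %*% t1) / sum(t1^2)
  m - rowMeans(m) - beta %*% t(t1)
}

#' tCompCor nuisance removal
#'
#' Identifies a noise-dominated voxel set -- the top `mask_fraction` of voxels
#' by temporal standard deviation after linear detrending -- and regresses the
#' top `n_components` principal component time courses of that set out of
#' every voxel (each voxel is linearly detrended in the process).
#'
#' Variance ties are broken deterministically by voxel index (lower index
#' ranks first).
#'
#' @param series A [bold_series()].
#' @param mask_fraction Fraction of voxels in the noise mask (default 0.02).
#' @param n_components Number of nuisance components to remove (default 5).
#' @return The residual `bold_series`; attribute `"noise_mask"` holds the
#'   noise voxel indices.
#' @export
tcompcor_denoise <- function(series, mask_fraction = 0.02, n_components = 5L) {
  stopifnot(inherits(series, "bold_series"))
  Tn <- ncol(series$data)
  if (n_components >= Tn) stop("n_components must be smaller than the frame count")
  det <- .detrend_rows(series$data)
  if (n_components == 0L) {
    series$data <- det
    return(series)
  }
  sds <- sqrt(rowSums(det^2) / (Tn - 1))
  n_noise <- max(1L, ceiling(mask_fraction * nrow(det)))
  noise_idx <- order(-sds, seq_along(sds))[seq_len(n_noise)]
  nm <- t(det[noise_idx, , drop = FALSE])              # frames x noise voxels
  nc <- min(n_components, ncol(nm), Tn - 1L)
  pcs <- svd(scale(nm, center = TRUE, scale = FALSE), nu = nc, nv = 0)$u
  # regress PCs (plus implicit intercept; det rows are centered) out of all rows
  proj <- det %*% pcs %*% t(pcs)
  series$data <- det - proj
  attr(series, "noise_mask") <- sort(noise_idx)
  series
}

#' Zero-phase band-pass filter
#'
#' Fourth-order Butterworth applied forward-backward (zero phase) to each
#' voxel series. Series are demeaned first: the DC component lies in the
#' stopband anyway, and removing it avoids edge transients from the low
#' high-pass corner.
#'
#' @param series A [bold_series()].
#' @param low,high Pass-band edges in Hz (defaults 0.01 and 0.16).
#' @param order Butterworth order (default 4).
#' @return The filtered `bold_series`.
#' @export
bandpass <- function(series, low = 0.01, high = 0.16, order = 4L) {
  stopifnot(inherits(series, "bold_series"))
  nyq <- 1 / (2 * series$tr)
  if (high >= nyq) stop(sprintf("high edge %g Hz >= Nyquist %g Hz", high, nyq))
  if (low <= 0 || low >= high) stop("need 0 < low < high")
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  d <- series$data - rowMeans(series$data)
  series$data <- t(apply(d, 1, function(x) signal::filtfilt(bf, x)))
  series
}

#' Functional connectivity density map
#'
#' Builds the voxel-level correlation graph (links are pairwise Pearson
#' correlations strictly above `threshold`; self-pairs excluded), takes
#' `log(degree + 1)`, and normalizes the map by its median log-degree.
#'
#' Constant-variance voxels have undefined correlations; they receive degree 0
#' with a warning. A map whose median log-degree is 0 (no links anywhere)
#' cannot be median-normalized and raises an error. The median is the
#' order-statistic (type-1) median, so the baseline reference is always an
#' attained map value.
#'
#' @param series A [bold_series()] (or a plain voxel x frame matrix).
#' @param threshold Correlation link cutoff (strict `>`; default 0.7).
#' @param normalization `"median-ratio"` (divide by median, default),
#'   `"median-diff"` (subtract median), or `"none"`.
#' @param log_base Base of the degree logarithm (default `exp(1)`).
#' @return An `fcd_map`: list with `values` (voxel vector), `degree`,
#'   `threshold`, `normalization`, `smoothed`, `mask`.
#' @export
compute_fcd <- function(series, threshold = 0.7,
                        normalization = c("median-ratio", "median-diff", "none"),
                        log_base = exp(1)) {
  normalization <- match.arg(normalization)
  if (inherits(series, "bold_series")) {
    data <- series$data; mask <- series$mask
    subject_id <- series$subject_id; visit <- series$visit
  } else {
    data <- as.matrix(series); mask <- NULL
    subject_id <- NA_character_; visit <- NA_integer_
  }
  V <- nrow(data)
  if (V < 2) stop("compute_fcd needs at least 2 voxels")
  sds <- apply(data, 1, stats::sd)
  const <- sds == 0 | !is.finite(sds)
  if (any(const))
    warning(sprintf("%d constant-variance voxel(s): degree set to 0", sum(const)))
  r <- suppressWarnings(stats::cor(t(data)))
  r[!is.finite(r)] <- 0
  diag(r) <- 0
  degree <- as.integer(rowSums(r > threshold))
  degree[const] <- 0L
  lg <- log(degree + 1, base = log_base)
  # order-statistic (type-1) median: the baseline reference is an attained
  # map value even for even voxel counts
  med <- stats::quantile(lg, 0.5, type = 1, names = FALSE)
  values <- switch(normalization,
                   "median-ratio" = {
                     if (med == 0)
                       stop("median log-degree is 0 (no links anywhere); cannot median-normalize")
                     lg / med
                   },
                   "median-diff" = lg - med,
                   "none" = lg)
  structure(list(values = values, degree = degree, threshold = threshold,
                 normalization = normalization, smoothed = FALSE,
                 mask = mask, subject_id = subject_id, visit = visit),
            class = "fcd_map")
}

#' @export
print.fcd_map <- function(x, ...) {
  cat(sprintf(
    "<fcd_map> %d voxels, threshold %g, normalization %s%s; median degree %g\n",
    length(x$values), x$threshold, x$normalization,
    if (x$smoothed) ", smoothed" else "", stats::median(x$degree)))
  invisible(x)
}

#' Masked Gaussian smoothing of an FCD map
#'
#' 3-D Gaussian kernel with `sigma = fwhm / sqrt(8 * log(2))` voxels,
#' convolved over the mask grid; kernel weights are renormalized over in-mask
#' voxels so values at the mask boundary are not attenuated.
#'
#' @param map An `fcd_map` with grid geometry in `$mask`.
#' @param fwhm_voxels Full width at half maximum, in voxels (default 2.5).
#' @return The smoothed `fcd_map`.
#' @export
smooth_map <- function(map, fwhm_voxels = 2.5) {
  stopifnot(inherits(map, "fcd_map"))
  if (fwhm_voxels <= 0) stop("fwhm_voxels must be positive")
  if (is.null(map$mask)) stop("smooth_map needs grid geometry in map$mask")
  sigma <- fwhm_voxels / sqrt(8 * log(2))
  rad <- max(1L, ceiling(3 * sigma))
  dims <- c(max(map$mask$x), max(map$mask$y), max(map$mask$z))
  vol <- array(0, dims); wt <- array(0, dims); inmask <- array(FALSE, dims)
  idx <- cbind(map$mask$x, map$mask$y, map$mask$z)
  vol[idx] <- map$values
  inmask[idx] <- TRUE

  acc <- array(0, dims)
  offs <- expand.grid(dx = -rad:rad, dy = -rad:rad, dz = -rad:rad)
  kern <- exp(-(offs$dx^2 + offs$dy^2 + offs$dz^2) / (2 * sigma^2))
  for (k in seq_len(nrow(offs))) {
    sh <- .shift3(vol * inmask, offs$dx[k], offs$dy[k], offs$dz[k])
    shm <- .shift3(inmask + 0, offs$dx[k], offs$dy[k], offs$dz[k])
    acc <- acc + kern[k] * sh
    wt <- wt + kern[k] * shm
  }
  sm <- acc / pmax(wt, .Machine$double.eps)
  map$values <- sm[idx]
  map$smoothed <- TRUE
  map
}

# shift a 3-D array by integer offsets, zero-padding
.shift3 <- function(a, dx, dy, dz) {
  d <- dim(a)
  out <- array(0, d)
  sx <- max(1, 1 + dx):min(d[1], d[1] + dx)
  sy <- max(1, 1 + dy):min(d[2], d[2] + dy)
  sz <- max(1, 1 + dz):min(d[3], d[3] + dz)
  if (!length(sx) || !length(sy) || !length(sz)) return(out)
  out[sx, sy, sz] <- a[sx - dx, sy - dy, sz - dz]
  out
}

#' Motion summary from a per-frame displacement trace
#'
#' @param fd_per_frame Relative framewise displacement per frame, in mm.
#' @param displacement_threshold High-motion frame cutoff in mm (default 0.6).
#' @return A `motion_summary`: `fd_per_frame`, `fd_mean`, `n_frames_above`.
#' @export
motion_summary <- function(fd_per_frame, displacement_threshold = 0.6) {
  if (any(fd_per_frame < 0)) stop("framewise displacement must be non-negative")
  structure(list(fd_per_frame = fd_per_frame,
                 fd_mean = mean(fd_per_frame),
                 n_frames_above = sum(fd_per_frame > displacement_threshold),
                 displacement_threshold = displacement_threshold),
            class = "motion_summary")
}

#' Motion quality control decision
#'
#' A scan is excluded if and only if strictly more than `max_frames` frames
#' have relative displacement above `displacement_threshold` mm.
#'
#' @param motion A [motion_summary()] or numeric per-frame displacement vector.
#' @param max_frames Maximum tolerated count of high-motion frames (default 10).
#' @param displacement_threshold mm cutoff per frame (default 0.6).
#' @return `"retain"` or `"exclude"`.
#' @export
motion_qc <- function(motion, max_frames = 10L, displacement_threshold = 0.6) {
  if (!inherits(motion, "motion_summary"))
    motion <- motion_summary(motion, displacement_threshold)
  n_above <- sum(motion$fd_per_frame > displacement_threshold)
  if (n_above > max_frames) "exclude" else "retain"
}

#' Full preprocessing chain for one BOLD series
#'
#' Frame trimming, tCompCor nuisance removal, and zero-phase band-pass
#' filtering, in that order.
#'
#' @param series A [bold_series()].
#' @param n_discard,mask_fraction,n_components,low,high Stage parameters; see
#'   [discard_initial_frames()], [tcompcor_denoise()], [bandpass()].
#' @return The preprocessed `bold_series`.
#' @export
preprocess_bold <- function(series, n_discard = 5L, mask_fraction = 0.02,
                            n_components = 5L, low = 0.01, high = 0.16) {
  series <- discard_initial_frames(series, n_discard)
  series <- tcompcor_denoise(series, mask_fraction, n_components)
  bandpass(series, low, high)
}

#' FCD feature matrix for a synthetic cohort
#'
#' Streams subject-visit BOLD generation, preprocessing and FCD computation so
#' the full 4-D data never needs to be held in memory.
#'
#' @inheritParams generate_bold
#' @param visit Which imaging visit to use (default 1).
#' @param preprocess Run the preprocessing chain before FCD (default TRUE).
#' @param threshold,normalization Passed to [compute_fcd()].
#' @return Subject x voxel matrix of FCD values, rows named by subject id.
#' @export
fcd_from_cohort <- function(cohort, config, seed = config$seed, visit = 1L,
                            preprocess = TRUE, threshold = 0.7,
                            normalization = "median-ratio") {
  st <- .bold_structure(cohort, config, seed)
  mask <- .grid_mask(config)
  n <- nrow(cohort)
  out <- matrix(NA_real_, n, config$n_voxels,
                dimnames = list(cohort$subject_id, NULL))
  for (i in seq_len(n)) {
    bs <- bold_series(.bold_one(cohort, config, st, i, visit, seed),
                      tr = config$tr_seconds, mask = mask,
                      subject_id = cohort$subject_id[i], visit = visit)
    if (preprocess) bs <- preprocess_bold(bs)
    out[i, ] <- compute_fcd(bs, threshold = threshold,
                            normalization = normalization)$values
  }
  out
}

#' Read a 4-D NIfTI BOLD volume into a bold_series
#'
#' @param bold_path Path to a 4-D NIfTI file.
#' @param mask_path Path to a 3-D NIfTI mask (nonzero = in mask); `NULL` keeps
#'   every voxel.
#' @param tr Sampling interval in seconds; taken from the NIfTI header when
#'   `NULL`.
#' @param subject_id,visit Identifiers.
#' @return A [bold_series()] of in-mask voxels.
#' @export
read_bold_nifti <- function(bold_path, mask_path = NULL, tr = NULL,
                            subject_id = NA_character_, visit = NA_integer_) {
  img <- RNifti::readNifti(bold_path)
  d <- dim(img)
  if (length(d) != 4) stop("expected a 4-D BOLD volume")
  if (is.null(tr)) tr <- RNifti::pixdim(img)[4]
  vol <- matrix(img, prod(d[1:3]), d[4])
  keep <- seq_len(prod(d[1:3]))
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    if (!all(dim(m)[1:3] == d[1:3])) stop("mask geometry does not match BOLD")
    keep <- which(as.vector(m) != 0)
  }
  idx <- arrayInd(keep, d[1:3])
  mask <- data.frame(voxel = seq_along(keep), x = idx[, 1], y = idx[, 2],
                     z = idx[, 3])
  bold_series(vol[keep, , drop = FALSE], tr = tr, mask = mask,
              subject_id = subject_id, visit = visit)
}

#' Write an FCD map as 3-D NIfTI and/or flat CSV
#'
#' @param map An `fcd_map` with grid geometry.
#' @param nifti_path,csv_path Output paths (`NULL` skips that format). The CSV
#'   has columns `voxel_id`, `value`.
#' @return Invisibly, the written paths.
#' @export
write_fcd_map <- function(map, nifti_path = NULL, csv_path = NULL) {
  stopifnot(inherits(map, "fcd_map"))
  if (!is.null(nifti_path)) {
    if (is.null(map$mask)) stop("NIfTI export needs grid geometry in map$mask")
    dims <- c(max(map$mask$x), max(map$mask$y), max(map$mask$z))
    vol <- array(0, dims)
    vol[cbind(map$mask$x, map$mask$y, map$mask$z)] <- map$values
    RNifti::writeNifti(RNifti::asNifti(vol), nifti_path)
  }
  if (!is.null(csv_path))
    utils::write.csv(data.frame(voxel_id = seq_along(map$values),
                                value = map$values),
                     csv_path, row.names = FALSE)
  invisible(c(nifti = nifti_path, csv = csv_path))
}

#' Read a plain-text per-frame displacement trace
#'
#' One displacement value per line, in mm.
#'
#' @param path File path.
#' @param displacement_threshold Passed to [motion_summary()].
#' @return A [motion_summary()].
#' @export
read_motion_trace <- function(path, displacement_threshold = 0.6) {
  motion_summary(scan(path, quiet = TRUE), displacement_threshold)
}
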