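#' Temporal preprocessing configuration
#'
#' Parameters of the fixed preprocessing order: discard initial volumes,
#' regress nuisance signals, bandpass filter, smooth spatially.
#'
#' @param n_discard initial volumes to drop (signal reaches steady state).
#' @param band passband in Hz, `c(low, high)`; must sit below the Nyquist
#'   frequency `1/(2 tr)`.
#' @param fwhm_pre_mm Gaussian smoothing FWHM applied to the 4D data before
#'   entropy mapping, mm.
#' @param include_intercept include an intercept column in the nuisance
#'   design (default TRUE; keeps residual means at zero, which stabilizes
#'   the downstream `r = r_frac * SD` tolerance).
#' @param tr repetition time, seconds.
#' @return object of class `preproc_config`.
#' @export
preproc_config <- function(n_discard = 4L, band = c(0.01, 0.1),
                           fwhm_pre_mm = 6, include_intercept = TRUE,
                           tr = 2) {
  stopifnot(n_discard >= 0, length(band) == 2L, fwhm_pre_mm >= 0, tr > 0)
  if (!(0 <= band[1] && band[1] < band[2] && band[2] < 1 / (2 * tr)))
    stop("band must satisfy 0 <= low < high < Nyquist = ", 1 / (2 * tr),
         " Hz")
  structure(list(n_discard = as.integer(n_discard), band = band,
                 fwhm_pre_mm = fwhm_pre_mm,
                 include_intercept = isTRUE(include_intercept), tr = tr),
            class = "preproc_config")
}

#' Discard initial volumes
#'
#' Drops the first `n_discard` frames of a run (or the matching rows of a
#' nuisance table) so the signal has reached steady state.
#'
#' @param x a [bold_run()] or a nuisance data frame.
#' @param n_discard number of frames to drop.
#' @return same type as `x`, shortened.
#' @export
discard_initial_volumes <- function(x, n_discard = 4L) {
  UseMethod("discard_initial_volumes")
}

#' @export
discard_initial_volumes.bold_run <- function(x, n_discard = 4L) {
  nt <- n_frames(x)
  if (n_discard >= nt) stop("n_discard (", n_discard,
                            ") must be smaller than the number of frames (",
                            nt, ")")
  if (n_discard == 0L) return(x)
  x$data <- x$data[, , , (n_discard + 1L):nt, drop = FALSE]
  x$provenance <- c(x$provenance,
                    list(list(stage = "discard", n_discard = n_discard)))
  x
}

#' @export
discard_initial_volumes.data.frame <- function(x, n_discard = 4L) {
  if (n_discard >= nrow(x)) stop("n_discard (", n_discard,
                                 ") must be smaller than the number of rows (",
                                 nrow(x), ")")
  if (n_discard == 0L) return(x)
  x[(n_discard + 1L):nrow(x), , drop = FALSE]
}

#' Regress nuisance signals out of every voxel
#'
#' Ordinary least squares of each voxel series on the eight nuisance
#' regressors (six motion parameters, WM mean, CSF mean), optionally
#' augmented with an intercept; the run is replaced by the residuals.
#' Global signal regression is deliberately not performed.
#'
#' @param run a [bold_run()].
#' @param nuis nuisance data frame, one row per frame of `run`.
#' @param include_intercept prepend an intercept column (default TRUE).
#' @return residual [bold_run()].
#' @export
regress_nuisance <- function(run, nuis, include_intercept = TRUE) {
  nt <- n_frames(run)
  if (nrow(nuis) != nt)
    stop("nuisance table has ", nrow(nuis), " rows but run has ", nt,
         " frames")
  X <- as.matrix(nuis)
  X <- X[, colSums(abs(X)) > 0, drop = FALSE]  # all-zero regressor = absent
  if (include_intercept) X <- cbind(intercept = 1, X)
  if (ncol(X) == 0L) return(run)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    stop("nuisance design is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "))
  }
  Y <- matrix(run$data, nrow = prod(dim(run$data)[1:3]), ncol = nt,
              byrow = FALSE)
  # voxels in rows: transpose so time runs down columns for qr.resid
  R <- qr.resid(qrX, t(Y))
  run$data <- array(t(R), dim(run$data))
  run$provenance <- c(run$provenance,
                      list(list(stage = "regress",
                                regressors = colnames(X))))
  run
}

# Squared magnitude response of a zero-phase (forward-backward) order-`ord`
# Butterworth bandpass at frequency f (Hz).
butterworth_gain2 <- function(f, low, high, ord = 4L) {
  lp <- 1 / sqrt(1 + (f / high)^(2 * ord))
  hp <- ifelse(f == 0, 0, 1 / sqrt(1 + (low / pmax(f, .Machine$double.xmin))^
                                     (2 * ord)))
  (lp * hp)^2
}

#' Temporal bandpass filter
#'
#' Zero-phase bandpass restricting each voxel series to the slow BOLD
#' fluctuation band (default 0.01-0.1 Hz). Realized in the frequency domain
#' with the squared magnitude response of an order-4 Butterworth bandpass
#' (the forward-backward gain), which has exactly zero phase so entropy is
#' not biased by phase distortion. DC is removed entirely.
#'
#' @param x a [bold_run()], or a numeric vector/matrix of series in columns.
#' @param band `c(low, high)` in Hz.
#' @param tr sampling interval in seconds (taken from the run if omitted).
#' @return same type as `x`, filtered.
#' @export
bandpass <- function(x, band = c(0.01, 0.1), tr = NULL) UseMethod("bandpass")

#' @export
bandpass.bold_run <- function(x, band = c(0.01, 0.1), tr = NULL) {
  tr <- if (is.null(tr)) x$tr else tr
  nt <- n_frames(x)
  Y <- matrix(x$data, nrow = prod(dim(x$data)[1:3]), ncol = nt)
  x$data <- array(t(bandpass_matrix(t(Y), band, tr)), dim(x$data))
  x$provenance <- c(x$provenance,
                    list(list(stage = "bandpass", band = band, tr = tr)))
  x
}

#' @export
bandpass.numeric <- function(x, band = c(0.01, 0.1), tr = 2) {
  drop(bandpass_matrix(matrix(x, ncol = 1), band, tr))
}

#' @export
bandpass.matrix <- function(x, band = c(0.01, 0.1), tr = 2) {
  bandpass_matrix(x, band, tr)
}

bandpass_matrix <- function(X, band, tr) {
  stopifnot(length(band) == 2L, band[1] >= 0)
  nyq <- 1 / (2 * tr)
  if (band[2] >= nyq)
    stop("upper band edge ", band[2], " Hz must be below Nyquist ", nyq,
         " Hz")
  if (band[1] >= band[2]) stop("band low edge must be below high edge")
  n <- nrow(X)
  freqs <- c(seq_len(n) - 1)
  freqs <- ifelse(freqs > n / 2, freqs - n, freqs) / (n * tr)
  g <- butterworth_gain2(abs(freqs), band[1], band[2])
  Re(mvfft(mvfft(X) * g, inverse = TRUE)) / n
}

#' Isotropic Gaussian spatial smoothing
#'
#' Separable per-axis Gaussian convolution with
#' `sigma_mm = fwhm / (2 sqrt(2 ln 2))`, sigma expressed per axis in voxel
#' units (handles anisotropic voxels), boundary mode "nearest" (edge
#' replication). For entropy maps the smoothing is mask-aware: NaN voxels are
#' excluded and the kernel renormalized over valid neighbours.
#'
#' @param x a [bold_run()] (smoothed frame by frame), a [ben_map()], or a 3D
#'   array.
#' @param fwhm_mm full width at half maximum, mm; 0 is the identity.
#' @param voxel_size mm per voxel (scalar or length-3); taken from the object
#'   when available.
#' @return same type as `x`.
#' @export
smooth_spatial <- function(x, fwhm_mm, voxel_size = NULL) {
  UseMethod("smooth_spatial")
}

#' @export
smooth_spatial.bold_run <- function(x, fwhm_mm, voxel_size = NULL) {
  vs <- if (is.null(voxel_size)) x$voxel_size else rep_len(voxel_size, 3L)
  x$data <- gaussian_smooth_array(x$data, fwhm_mm, vs)
  x$provenance <- c(x$provenance,
                    list(list(stage = "smooth", fwhm_mm = fwhm_mm)))
  x
}

#' @export
smooth_spatial.array <- function(x, fwhm_mm, voxel_size = 1) {
  gaussian_smooth_array(x, fwhm_mm, rep_len(voxel_size, 3L))
}

gaussian_kernel <- function(sigma_vox) {
  if (sigma_vox <= 0) return(1)
  radius <- max(1L, ceiling(4 * sigma_vox))
  w <- exp(-((-radius):radius)^2 / (2 * sigma_vox^2))
  w / sum(w)
}

# Smooth a 3D or 4D array along its first three axes; "nearest" boundary.
gaussian_smooth_array <- function(a, fwhm_mm, voxel_size) {
  if (fwhm_mm < 0) stop("fwhm must be non-negative")
  if (fwhm_mm == 0) return(a)
  sigma_mm <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(a)
  idx <- lapply(d, seq_len)
  for (axis in 1:3) {
    w <- gaussian_kernel(sigma_mm / voxel_size[axis])
    if (length(w) == 1L) next
    radius <- (length(w) - 1L) %/% 2L
    out <- array(0, d)
    for (k in seq_along(w)) {
      off <- k - radius - 1L
      sel <- idx
      sel[[axis]] <- pmin(pmax(idx[[axis]] + off, 1L), d[axis])
      out <- out + w[k] * do.call(`[`, c(list(a), sel, list(drop = FALSE)))
    }
    a <- out
  }
  a
}

# NaN-aware smoothing of a 3D map: kernel renormalized over valid voxels.
gaussian_smooth_masked <- function(v, fwhm_mm, voxel_size) {
  ok <- is.finite(v)
  if (all(ok)) return(gaussian_smooth_array(v, fwhm_mm, voxel_size))
  v0 <- v
  v0[!ok] <- 0
  num <- gaussian_smooth_array(v0, fwhm_mm, voxel_size)
  den <- gaussian_smooth_array(ok + 0, fwhm_mm, voxel_size)
  out <- num / den
  out[!ok] <- NA_real_
  out
}

#' Run the full temporal preprocessing chain
#'
#' Fixed order: discard initial volumes -> nuisance regression -> bandpass ->
#' spatial smoothing. The order is recorded in the run's provenance.
#'
#' @param run a [bold_run()].
#' @param nuis nuisance data frame aligned to the *untrimmed* run.
#' @param config a [preproc_config()].
#' @return preprocessed [bold_run()].
#' @export
preprocess_run <- function(run, nuis, config = preproc_config(tr = run$tr)) {
  stopifnot(inherits(config, "preproc_config"))
  run <- discard_initial_volumes(run, config$n_discard)
  nuis <- discard_initial_volumes(nuis, config$n_discard)
  run <- regress_nuisance(run, nuis, config$include_intercept)
  run <- bandpass(run, config$band, config$tr)
  run <- smooth_spatial(run, config$fwhm_pre_mm)
  run$provenance <- c(run$provenance,
                      list(list(stage = "preprocess_complete",
                                order = c("discard", "regress", "bandpass",
                                          "smooth"))))
  run
}
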