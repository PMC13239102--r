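#' Sample-entropy (BEN) parameters
#'
#' @param m template (embedding) length, the "window length"; default 3.
#' @param r_frac match tolerance as a fraction of the per-voxel series
#'   standard deviation (population SD); default 0.6.
#' @param fwhm_post_mm Gaussian FWHM applied to the entropy map after
#'   resampling, mm.
#' @param target_voxel_mm edge length of the analysis grid, mm.
#' @return object of class `ben_params`.
#' @export
ben_params <- function(m = 3L, r_frac = 0.6, fwhm_post_mm = 10,
                       target_voxel_mm = 3) {
  stopifnot(m >= 1, r_frac > 0, fwhm_post_mm >= 0, target_voxel_mm > 0)
  structure(list(m = as.integer(m), r_frac = r_frac,
                 fwhm_post_mm = fwhm_post_mm,
                 target_voxel_mm = target_voxel_mm),
            class = "ben_params")
}

#' Sample entropy of a time series
#'
#' SampEn(m, r) = -ln(A/B), where B counts pairs of length-`m` templates
#' whose Chebyshev distance is at most `r = r_frac * SD(x)` (population SD)
#' and A counts the same for length-`(m+1)` templates. Both counts use
#' template start indices `1..N-m` so every length-m template has a
#' length-(m+1) extension (Richman-Moorman convention); self-matches are
#' excluded. This guarantees `A <= B`, hence a non-negative value, and a
#' value of exactly 0 for a constant series. Degenerate series (A or B zero)
#' return `NA` rather than raising.
#'
#' @param x numeric time series of length at least `m + 2`.
#' @param m template length.
#' @param r_frac tolerance as a fraction of SD(x).
#' @return entropy in nats, or `NA` if degenerate.
#' @export
sample_entropy <- function(x, m = 3L, r_frac = 0.6) {
  stopifnot(is.numeric(x), m >= 1, r_frac > 0)
  if (length(x) < m + 2)
    stop("series length ", length(x), " is too short for m = ", m,
         " (need at least m + 2)")
  sampen_matrix_cpp(matrix(as.numeric(x), ncol = 1), as.integer(m), r_frac)[1]
}

#' A 3D brain-entropy map
#'
#' @param values 3D numeric array; `NA` outside the mask or where the voxel
#'   series was degenerate.
#' @param voxel_size mm, scalar or length-3.
#' @param mask logical 3D array (analysis mask).
#' @param params the [ben_params()] used.
#' @param subject,scanner,condition provenance labels.
#' @param n_degenerate count of in-mask voxels with degenerate entropy.
#' @return object of class `ben_map`.
#' @export
ben_map_obj <- function(values, voxel_size, mask, params,
                        subject = NA_character_, scanner = NA_character_,
                        condition = NA_character_, n_degenerate = 0L) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  structure(list(values = values, voxel_size = as.numeric(voxel_size),
                 mask = mask, params = params, subject = subject,
                 scanner = scanner, condition = condition,
                 n_degenerate = as.integer(n_degenerate)),
            class = "ben_map")
}

#' @export
print.ben_map <- function(x, ...) {
  cat(sprintf(
    "<ben_map> %s/%s/%s: %s grid, %.3g mm; m=%d r=%.2g; %d masked voxels, %d degenerate\n",
    x$subject, x$scanner, x$condition, paste(dim(x$values), collapse = "x"),
    x$voxel_size[1], x$params$m, x$params$r_frac, sum(x$mask),
    x$n_degenerate))
  invisible(x)
}

#' Voxel-wise sample-entropy map of a preprocessed run
#'
#' @param run a preprocessed [bold_run()].
#' @param mask logical 3D array on the run grid; `NULL` means all voxels.
#' @param params a [ben_params()].
#' @return a `ben_map` with `NA` outside the mask; degenerate voxels are
#'   `NA` and counted in `n_degenerate`.
#' @export
ben_map <- function(run, mask = NULL, params = ben_params()) {
  d <- dim(run$data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  stopifnot(identical(dim(mask), d[1:3]))
  if (!any(mask)) stop("mask is empty")
  if (d[4] < params$m + 2)
    stop("run has too few frames (", d[4], ") for m = ", params$m)
  Y <- matrix(run$data, nrow = prod(d[1:3]), ncol = d[4])
  sel <- which(mask)
  vals <- sampen_matrix_cpp(t(Y[sel, , drop = FALSE]), params$m,
                            params$r_frac)
  out <- array(NA_real_, d[1:3])
  out[sel] <- vals
  ben_map_obj(out, run$voxel_size, mask, params,
              subject = run$subject, scanner = run$scanner,
              condition = run$condition,
              n_degenerate = sum(is.na(vals)))
}

#' Trilinear resampling of a 3D map onto an isotropic target grid
#'
#' Voxel centers follow the cell-centered convention `((i - 1/2) * size)`;
#' target sample points are clamped to the source volume (edge replication),
#' so constant maps stay constant and a source grid resampled onto itself is
#' returned unchanged.
#'
#' @param map a [ben_map()] (or plain 3D array with `voxel_size` given).
#' @param target_voxel_mm target isotropic voxel size, mm.
#' @param voxel_size source voxel size when `map` is a plain array.
#' @return resampled `ben_map` (or array).
#' @export
resample_to_grid <- function(map, target_voxel_mm = 3, voxel_size = NULL) {
  is_map <- inherits(map, "ben_map")
  v <- if (is_map) map$values else map
  vs <- if (is_map) map$voxel_size else rep_len(voxel_size, 3L)
  stopifnot(all(is.finite(vs)), all(vs > 0), target_voxel_mm > 0)
  d <- dim(v)
  extent <- d * vs
  nd <- pmax(1L, as.integer(round(extent / target_voxel_mm)))
  if (identical(as.numeric(rep(target_voxel_mm, 3)), as.numeric(vs)) &&
      identical(nd, as.integer(d))) {
    out_vals <- v
  } else {
    # continuous source index of each target voxel center, per axis
    coords <- lapply(1:3, function(ax) {
      x_mm <- (seq_len(nd[ax]) - 0.5) * target_voxel_mm
      pmin(pmax(x_mm / vs[ax] + 0.5, 1), d[ax])
    })
    i0 <- lapply(seq_along(coords),
                 function(ax) pmin(floor(coords[[ax]]), d[ax] - 1L))
    fr <- lapply(seq_along(coords), function(ax) coords[[ax]] - i0[[ax]])
    out_vals <- array(0, nd)
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
      w <- outer(outer(ifelse(rep(cx, nd[1]) == 1, fr[[1]], 1 - fr[[1]]),
                       ifelse(rep(cy, nd[2]) == 1, fr[[2]], 1 - fr[[2]])),
                 ifelse(rep(cz, nd[3]) == 1, fr[[3]], 1 - fr[[3]]))
      out_vals <- out_vals +
        w * v[i0[[1]] + cx, i0[[2]] + cy, i0[[3]] + cz, drop = FALSE]
    }
  }
  if (!is_map) return(out_vals)
  mask_num <- resample_to_grid(map$mask + 0, target_voxel_mm,
                               voxel_size = vs)
  ben_map_obj(out_vals, target_voxel_mm, mask_num > 0.5, map$params,
              subject = map$subject, scanner = map$scanner,
              condition = map$condition, n_degenerate = map$n_degenerate)
}

#' @export
smooth_spatial.ben_map <- function(x, fwhm_mm, voxel_size = NULL) {
  vs <- if (is.null(voxel_size)) x$voxel_size else rep_len(voxel_size, 3L)
  x$values <- gaussian_smooth_masked(x$values, fwhm_mm, vs)
  x
}

#' Full BEN mapping stage for one preprocessed run
#'
#' Entropy on the native grid, trilinear resampling to the analysis grid,
#' then post-smoothing (mask-aware), mirroring the standard BEN protocol
#' (entropy first, then 3 mm resampling, then 10 mm FWHM).
#'
#' @param run preprocessed [bold_run()].
#' @param mask optional logical 3D mask on the run grid.
#' @param params a [ben_params()].
#' @return smoothed analysis-grid `ben_map`.
#' @export
ben_map_analysis <- function(run, mask = NULL, params = ben_params()) {
  bm <- ben_map(run, mask, params)
  bm <- resample_to_grid(bm, params$target_voxel_mm)
  smooth_spatial(bm, params$fwhm_post_mm)
}

#' Write a BEN map as NIfTI + JSON sidecar
#'
#' @param map a [ben_map()].
#' @param path output `.nii.gz` path; the sidecar gets extension `.json`.
#' @return `path`, invisibly.
#' @export
write_ben_map <- function(map, path) {
  write_map_nifti(map$values, map$voxel_size, path)
  sidecar <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(m = map$params$m, r_frac = map$params$r_frac,
         n_degenerate = map$n_degenerate, subject = map$subject,
         scanner = map$scanner, condition = map$condition),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
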