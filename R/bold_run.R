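#' A single 4D BOLD run
#'
#' Container for one subject x scanner x condition acquisition: a 4D array
#' (x, y, z, time) on an aligned grid, with voxel geometry, repetition time
#' and provenance labels.
#'
#' @param data 4D numeric array (x, y, z, time).
#' @param voxel_size voxel edge length(s) in mm; scalar or length-3.
#' @param tr repetition time in seconds.
#' @param subject,scanner,condition provenance labels.
#' @param provenance list of processing-stage records (appended to by each
#'   preprocessing stage).
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, voxel_size, tr, subject = NA_character_,
                     scanner = NA_character_, condition = NA_character_,
                     provenance = list()) {
  stopifnot(is.array(data), length(dim(data)) == 4L)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  stopifnot(length(voxel_size) == 3L, all(voxel_size > 0), tr > 0)
  structure(
    list(data = data, voxel_size = as.numeric(voxel_size), tr = as.numeric(tr),
         subject = subject, scanner = scanner, condition = condition,
         provenance = provenance),
    class = "bold_run")
}

#' @export
print.bold_run <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<bold_run> %s / %s / %s: %dx%dx%d voxels x %d frames, %.3g mm, TR %.3g s\n",
              x$subject, x$scanner, x$condition, d[1], d[2], d[3], d[4],
              x$voxel_size[1], x$tr))
  if (length(x$provenance))
    cat("  stages:", paste(vapply(x$provenance, `[[`, "", "stage"),
                           collapse = " -> "), "\n")
  invisible(x)
}

#' @export
dim.bold_run <- function(x) dim(x$data)

n_frames <- function(run) dim(run$data)[4]

#' Write a BOLD run to NIfTI-1
#'
#' Stores voxel size and TR in `pixdim`; values are written as doubles so
#' re-reading is bit-identical.
#'
#' @param run a [bold_run()].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_bold_run <- function(run, path) {
  arr <- run$data
  attr(arr, "pixdim") <- c(run$voxel_size, run$tr)
  img <- RNifti::asNifti(arr, datatype = "double")
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a BOLD run from NIfTI-1
#'
#' @param path NIfTI file path.
#' @param subject,scanner,condition provenance labels to attach.
#' @return A [bold_run()].
#' @export
read_bold_run <- function(path, subject = NA_character_,
                          scanner = NA_character_,
                          condition = NA_character_) {
  img <- RNifti::readNifti(path)
  pd <- RNifti::pixdim(img)
  arr <- as.array(img)
  if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
  bold_run(arr, voxel_size = pd[1:3], tr = if (length(pd) >= 4) pd[4] else 1,
           subject = subject, scanner = scanner, condition = condition)
}

#' Write a 3D map (label image or entropy map) to NIfTI-1
#' @param values 3D array.
#' @param voxel_size mm, scalar or length-3.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_map_nifti <- function(values, voxel_size, path) {
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3L)
  attr(values, "pixdim") <- voxel_size
  RNifti::writeNifti(RNifti::asNifti(values, datatype = "double"), path)
  invisible(path)
}

#' Read and write nuisance regressor tables
#'
#' A nuisance set is a data frame with one row per retained volume and
#' columns `mot1..mot6` (head motion), `wm` and `csf` (tissue mean signals),
#' stored as headered TSV.
#'
#' @param nuis data frame of regressors.
#' @param path TSV path.
#' @return `path` / the data frame.
#' @export
write_nuisance <- function(nuis, path) {
  stopifnot(identical(names(nuis), nuisance_columns()))
  write.table(format(nuis, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_nuisance
#' @export
read_nuisance <- function(path) {
  nuis <- read.delim(path, check.names = FALSE)
  stopifnot(identical(names(nuis), nuisance_columns()))
  nuis
}

nuisance_columns <- function() c(paste0("mot", 1:6), "wm", "csf")
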