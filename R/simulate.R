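#' Generate a stationary AR(1) time series
#'
#' The one-parameter complexity knob of the synthetic cohort: an AR(1)
#' process `x_t = phi * x_{t-1} + e_t` with Gaussian innovations. Higher
#' `phi` yields a smoother, more regular series and hence lower sample
#' entropy; the marginal variance is `sd^2 / (1 - phi^2)`.
#'
#' @param phi AR(1) coefficient in `[0, 1)`.
#' @param sd innovation standard deviation.
#' @param n series length (>= 10).
#' @param seed optional integer seed (scoped locally; the global RNG state is
#'   untouched).
#' @return numeric vector of length `n`.
#' @export
generate_voxel_series <- function(phi, sd = 1, n = 240, seed = NULL) {
  if (phi >= 1 || phi < 0) stop("non-stationary process requested")
  stopifnot(n >= 10, sd >= 0)
  draw <- function() {
    burn <- 50L
    e <- rnorm(n + burn, sd = sd)
    x <- numeric(n + burn)
    x[1] <- e[1] / sqrt(max(1 - phi^2, .Machine$double.eps))
    for (t in 2:(n + burn)) x[t] <- phi * x[t - 1] + e[t]
    x[(burn + 1):(burn + n)]
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Evaluate `expr` under a local RNG seed, restoring global state afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

# Deterministic per-run seed from the cohort seed and run indices (kept well
# below 2^31).
run_seed <- function(spec, subj, scanner_idx, cond_idx) {
  idx <- ((subj - 1L) * length(spec$scanners) + (scanner_idx - 1L)) *
    length(spec$conditions) + (cond_idx - 1L)
  ((spec$seed %% 1000003L) * 1009L + idx * 97L + 17L) %% 2147483647L
}

# AR(1) field with per-voxel phi: matrix n x V, unit marginal variance.
ar1_field <- function(phi_vec, n, burn = 50L) {
  nv <- length(phi_vec)
  innov_sd <- sqrt(1 - phi_vec^2)
  e <- matrix(rnorm((n + burn) * nv), n + burn, nv)
  e <- sweep(e, 2L, innov_sd, `*`)
  x <- matrix(0, n + burn, nv)
  x[1, ] <- e[1, ] / innov_sd  # marginal-variance start
  for (t in 2:(n + burn)) x[t, ] <- phi_vec * x[t - 1L, ] + e[t, ]
  x[(burn + 1L):(burn + n), , drop = FALSE]
}

# Six motion parameters as smoothed random walks (3 translations mm,
# 3 rotations rad), WM/CSF as low-frequency sinusoid + noise.
simulate_nuisance <- function(n, tr) {
  smooth5 <- function(x) as.numeric(stats::filter(x, rep(1 / 5, 5),
                                                  sides = 2L,
                                                  circular = TRUE))
  mot <- vapply(1:6, function(k) {
    scale <- if (k <= 3) 0.02 else 0.0005
    smooth5(cumsum(rnorm(n, sd = scale)))
  }, numeric(n))
  lowfreq <- function() {
    f <- stats::runif(1, 0.005, 0.02)
    sin(2 * pi * f * tr * seq_len(n) + stats::runif(1, 0, 2 * pi)) +
      rnorm(n, sd = 0.3)
  }
  nuis <- data.frame(mot, wm = lowfreq(), csf = lowfreq())
  names(nuis) <- nuisance_columns()
  nuis
}

#' Generate one synthetic BOLD run
#'
#' Deterministic given the spec: each (subject, scanner, condition) cell has
#' its own derived seed, so runs can be generated independently in any order
#' and still reproduce [generate_cohort()] exactly.
#'
#' @param spec a [cohort_spec()].
#' @param subject subject index (1-based).
#' @param scanner scanner label or index.
#' @param condition condition label or index.
#' @param region_masks label image from [default_region_masks()] (computed if
#'   missing).
#' @return list with elements `run` ([bold_run()]) and `nuisance` (data
#'   frame, one row per frame).
#' @export
generate_run <- function(spec, subject, scanner, condition,
                         region_masks = default_region_masks(spec)) {
  sc_idx <- if (is.character(scanner)) match(scanner, spec$scanners)
            else as.integer(scanner)
  cd_idx <- if (is.character(condition)) match(condition, spec$conditions)
            else as.integer(condition)
  stopifnot(!is.na(sc_idx), !is.na(cd_idx),
            subject >= 1, subject <= spec$n_subjects)
  scanner <- spec$scanners[sc_idx]
  condition <- spec$conditions[cd_idx]
  n <- spec$n_volumes
  nv <- prod(spec$grid_shape)
  regions <- attr(region_masks, "regions")

  # per-voxel AR coefficient for this condition (background = 0)
  phi_vec <- numeric(nv)
  for (rg in names(regions)) {
    eff <- spec$region_effects[[rg]]
    phi <- if (condition %in% names(eff)) eff[[condition]] else 0
    phi_vec[region_masks == regions[[rg]]] <- phi
  }

  off <- spec$scanner_offsets[
    spec$scanner_offsets$scanner == scanner, , drop = FALSE]

  with_seed(run_seed(spec, subject, sc_idx, cd_idx), {
    signal <- ar1_field(phi_vec, n)
    nuis <- simulate_nuisance(n, spec$tr)
    # shared contamination: standardized regressors with per-voxel loadings
    Z <- scale(as.matrix(nuis))
    load <- matrix(rnorm(ncol(Z) * nv, sd = c(rep(0.15, 6), 0.3, 0.3)),
                   ncol(Z), nv)
    contam <- Z %*% load
    noise <- matrix(rnorm(n * nv, sd = spec$noise_sd * off$noise_factor),
                    n, nv)
    y <- off$gain * (signal + contam + noise) + off$additive
    arr <- array(t(y), c(spec$grid_shape, n))
    list(run = bold_run(arr, spec$voxel_size, spec$tr,
                        subject = sprintf("sub%02d", subject),
                        scanner = scanner, condition = condition),
         nuisance = nuis)
  })
}

#' Generate a full synthetic cohort in memory
#'
#' One run (plus nuisance table) per subject x scanner x condition cell, and
#' the ground truth: region label image and expected sign of each
#' (region, contrast) entropy difference.
#'
#' @param spec a [cohort_spec()].
#' @return list of class `synthetic_cohort`: `runs` (list with `$run`,
#'   `$nuisance`), `manifest` (data frame subject/scanner/condition/index),
#'   `ground_truth` (list: `region_masks`, `expected_contrast_sign`), `spec`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  masks <- default_region_masks(spec)
  cells <- expand.grid(condition = spec$conditions, scanner = spec$scanners,
                       subject = seq_len(spec$n_subjects),
                       stringsAsFactors = FALSE)[, 3:1]
  runs <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    runs[[i]] <- generate_run(spec, cells$subject[i], cells$scanner[i],
                              cells$condition[i], region_masks = masks)
  }
  manifest <- data.frame(subject = sprintf("sub%02d", cells$subject),
                         scanner = cells$scanner,
                         condition = cells$condition,
                         index = seq_len(nrow(cells)),
                         stringsAsFactors = FALSE)
  structure(list(runs = runs, manifest = manifest,
                 ground_truth = ground_truth(spec, masks), spec = spec),
            class = "synthetic_cohort")
}

#' Ground truth for a synthetic cohort
#'
#' Expected sign of the mean entropy difference for every region and ordered
#' condition pair, derived from the planted AR coefficients (entropy
#' decreases in `phi`, so sign(a vs b) = sign(phi_b - phi_a)).
#'
#' @param spec a [cohort_spec()].
#' @param region_masks label image (computed if missing).
#' @return list with `region_masks` and data frame `expected_contrast_sign`
#'   (region, cond_a, cond_b, sign).
#' @export
ground_truth <- function(spec, region_masks = default_region_masks(spec)) {
  pairs <- expand.grid(cond_a = spec$conditions, cond_b = spec$conditions,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$cond_a != pairs$cond_b, ]
  rows <- do.call(rbind, lapply(names(spec$region_effects), function(rg) {
    eff <- spec$region_effects[[rg]]
    phi <- function(cond) if (cond %in% names(eff)) eff[[cond]] else 0
    data.frame(region = rg, cond_a = pairs$cond_a, cond_b = pairs$cond_b,
               sign = sign(vapply(pairs$cond_b, phi, 0) -
                             vapply(pairs$cond_a, phi, 0)),
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  list(region_masks = region_masks, expected_contrast_sign = rows)
}

#' Write a synthetic cohort to disk
#'
#' Emits one NIfTI-1 `.nii.gz` per run, one nuisance TSV per run, the ground
#' truth label image (NIfTI + JSON sidecar of expected contrast signs) and a
#' cohort manifest TSV (subject, scanner, condition, path, nuisance_path).
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @return path of the manifest TSV, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$path <- file.path(dir, sprintf("%s_%s_%s_bold.nii.gz", man$subject,
                                     man$scanner, man$condition))
  man$nuisance_path <- sub("_bold\\.nii\\.gz$", "_nuisance.tsv", man$path)
  for (i in seq_len(nrow(man))) {
    write_bold_run(cohort$runs[[man$index[i]]]$run, man$path[i])
    write_nuisance(cohort$runs[[man$index[i]]]$nuisance, man$nuisance_path[i])
  }
  gt <- cohort$ground_truth
  write_map_nifti(gt$region_masks + 0, cohort$spec$voxel_size,
                  file.path(dir, "ground_truth_regions.nii.gz"))
  jsonlite::write_json(
    list(regions = as.list(attr(gt$region_masks, "regions")),
         expected_contrast_sign = gt$expected_contrast_sign),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  man_out <- man[, c("subject", "scanner", "condition", "path",
                     "nuisance_path")]
  manifest_path <- file.path(dir, "manifest.tsv")
  write.table(man_out, manifest_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(manifest_path)
}
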