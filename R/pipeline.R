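#' Pipeline run configuration
#'
#' @param contrasts list of ordered condition pairs to test (defaults to the
#'   three mental-state contrasts: rumination vs sad, distraction vs sad,
#'   rumination vs distraction).
#' @param rest_condition label of the resting-state condition used to build
#'   the task-vs-rest restriction mask.
#' @param alpha uncorrected two-sided voxel threshold.
#' @param preproc a [preproc_config()].
#' @param ben a [ben_params()].
#' @param p_adjust multiple-comparison adjustment for the voxel-wise maps:
#'   `"none"` (default, exploratory uncorrected maps) or `"fdr"`.
#' @return object of class `run_config`.
#' @export
run_config <- function(contrasts = list(c("rumination", "sad"),
                                        c("distraction", "sad"),
                                        c("rumination", "distraction")),
                       rest_condition = "rest",
                       alpha = 0.05,
                       preproc = preproc_config(),
                       ben = ben_params(),
                       p_adjust = c("none", "fdr")) {
  p_adjust <- match.arg(p_adjust)
  stopifnot(alpha > 0, alpha < 1, is.list(contrasts),
            all(lengths(contrasts) == 2L))
  structure(list(contrasts = contrasts, rest_condition = rest_condition,
                 alpha = alpha, preproc = preproc, ben = ben,
                 p_adjust = p_adjust),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of [run_config()], [preproc_config()] and
#' [ben_params()]; missing keys take their defaults.
#'
#' @param path YAML file path.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  pp <- do.call(preproc_config, y$preproc %||% list())
  bp <- do.call(ben_params, y$ben %||% list())
  contrasts <- y$contrasts %||% list(c("rumination", "sad"),
                                     c("distraction", "sad"),
                                     c("rumination", "distraction"))
  contrasts <- lapply(contrasts, unlist)
  run_config(contrasts = contrasts,
             rest_condition = y$rest_condition %||% "rest",
             alpha = y$alpha %||% 0.05, preproc = pp, ben = bp,
             p_adjust = y$p_adjust %||% "none")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Validate a cohort manifest
#'
#' Checks the manifest TSV (columns subject, scanner, condition, path,
#' nuisance_path) for missing files, incomplete subject x scanner x
#' condition cells, inconsistent grids/TR and frame counts.
#'
#' @param manifest data frame or TSV path.
#' @return list with `problems` (character vector, empty when clean) and a
#'   per-run summary data frame.
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read.delim(manifest)
  problems <- character()
  need <- c("subject", "scanner", "condition", "path")
  if (!all(need %in% names(manifest)))
    return(list(problems = paste("missing manifest columns:",
                                 paste(setdiff(need, names(manifest)),
                                       collapse = ", ")),
                runs = NULL))
  cells <- expand.grid(subject = unique(manifest$subject),
                       scanner = unique(manifest$scanner),
                       condition = unique(manifest$condition),
                       stringsAsFactors = FALSE)
  key <- function(d) paste(d$subject, d$scanner, d$condition)
  missing_cells <- setdiff(key(cells), key(manifest))
  for (mc in missing_cells)
    problems <- c(problems, paste("missing cell:", mc))
  info <- data.frame(subject = manifest$subject, scanner = manifest$scanner,
                     condition = manifest$condition, exists = FALSE,
                     frames = NA_integer_, tr = NA_real_,
                     grid = NA_character_, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    p <- manifest$path[i]
    if (!file.exists(p)) {
      problems <- c(problems,
                    paste0("unreadable file for ", key(manifest[i, ]), ": ",
                           p))
      next
    }
    hdr <- try(RNifti::niftiHeader(p), silent = TRUE)
    if (inherits(hdr, "try-error")) {
      problems <- c(problems, paste0("unreadable NIfTI: ", p))
      next
    }
    info$exists[i] <- TRUE
    info$frames[i] <- hdr$dim[5]
    info$tr[i] <- hdr$pixdim[5]
    info$grid[i] <- paste(hdr$dim[2:4], collapse = "x")
  }
  got <- info[info$exists, ]
  if (nrow(got)) {
    if (length(unique(got$grid)) > 1)
      problems <- c(problems, paste("inconsistent grids:",
                                    paste(unique(got$grid), collapse = " vs ")))
    if (length(unique(got$tr)) > 1)
      problems <- c(problems,
                    paste("TR inconsistency across runs:",
                          paste(unique(got$tr), collapse = " vs ")))
    if (length(unique(got$frames)) > 1)
      problems <- c(problems,
                    paste("frame-count inconsistency:",
                          paste(unique(got$frames), collapse = " vs ")))
  }
  list(problems = problems, runs = info)
}

# Compute all analysis-grid BEN maps for a cohort, streaming run by run so
# only entropy maps (not 4D volumes) are held in memory.
cohort_ben_maps <- function(source, config, mask = NULL,
                            verbose = FALSE) {
  if (inherits(source, "cohort_spec")) {
    spec <- source
    region_masks <- default_region_masks(spec)
    manifest <- expand.grid(condition = spec$conditions,
                            scanner = spec$scanners,
                            subject = seq_len(spec$n_subjects),
                            stringsAsFactors = FALSE)[, 3:1]
    subject_index <- manifest$subject
    fetch <- function(i) generate_run(spec, subject_index[i],
                                      manifest$scanner[i],
                                      manifest$condition[i],
                                      region_masks = region_masks)
    manifest$subject <- sprintf("sub%02d", manifest$subject)
  } else if (inherits(source, "synthetic_cohort")) {
    manifest <- source$manifest
    fetch <- function(i) source$runs[[manifest$index[i]]]
  } else {  # manifest data frame or path
    manifest <- if (is.character(source)) read.delim(source) else source
    v <- validate_manifest(manifest)
    if (length(v$problems))
      stop("manifest validation failed:\n  ",
           paste(v$problems, collapse = "\n  "))
    fetch <- function(i) {
      list(run = read_bold_run(manifest$path[i], manifest$subject[i],
                               manifest$scanner[i], manifest$condition[i]),
           nuisance = read_nuisance(manifest$nuisance_path[i]))
    }
  }
  maps <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    cell <- fetch(i)
    pp <- preprocess_run(cell$run, cell$nuisance, config$preproc)
    maps[[i]] <- ben_map_analysis(pp, mask, config$ben)
    if (verbose && i %% 25 == 0)
      message("  BEN maps: ", i, "/", nrow(manifest))
  }
  list(maps = maps, manifest = manifest)
}

#' Run the full entropy-mapping and conjunction pipeline
#'
#' Stages: (synthetic generation or manifest loading) -> preprocessing ->
#' voxel-wise sample entropy -> resampling + post-smoothing -> per-scanner
#' paired t-maps -> signed masks -> three-scanner sign-consistent
#' conjunctions -> task-vs-rest restriction -> ROI labelling -> per-subject
#' ROI means -> individual-level paired tests. When the source is synthetic,
#' planted-effect recovery metrics are computed against the ground truth.
#'
#' @param source a [cohort_spec()] (runs generated on the fly, memory-lean),
#'   a `synthetic_cohort`, or a manifest data frame / TSV path.
#' @param config a [run_config()].
#' @param mask optional logical analysis mask on the native grid.
#' @param out_dir optional directory; when given, NIfTI maps, TSV tables,
#'   figures and a JSON provenance log are written there.
#' @param verbose print stage progress.
#' @return list of class `ben_results`: `contrasts` (nested
#'   contrast/scanner [contrast_result()]), `overlap` (per contrast),
#'   `task_mask`, `restricted`, `roi_labels`, `roi_table`, `roi_tests`,
#'   `recovery` (synthetic sources only), `config`, `provenance`.
#' @export
run_pipeline <- function(source, config = run_config(), mask = NULL,
                         out_dir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  cb <- cohort_ben_maps(source, config, mask, verbose)
  maps <- cb$maps
  manifest <- cb$manifest
  scanners <- unique(manifest$scanner)
  subjects <- unique(manifest$subject)
  pick <- function(scanner, condition) {
    idx <- which(manifest$scanner == scanner & manifest$condition == condition)
    idx[match(subjects, manifest$subject[idx])]
  }
  conditions <- unique(manifest$condition)
  rest <- config$rest_condition
  test_pair <- function(a, b, scanner)
    paired_t_map(maps[pick(scanner, a)], maps[pick(scanner, b)],
                 contrast = c(a, b), scanner = scanner)

  adj_mask <- function(res) {
    p <- res$p_map
    if (config$p_adjust == "fdr")
      p <- array(stats::p.adjust(p, "BH"), dim(p))
    res$p_map <- p
    signed_significance_mask(res, config$alpha)
  }

  # task-vs-rest restriction mask
  task_mask <- NULL
  task_overlaps <- NULL
  if (!is.null(rest) && rest %in% conditions) {
    task_conditions <- setdiff(conditions, rest)
    task_overlaps <- lapply(task_conditions, function(tc) {
      res <- lapply(scanners, function(sc) test_pair(tc, rest, sc))
      conjunction(lapply(res, adj_mask), contrast = c(tc, rest),
                  scanners = scanners)
    })
    names(task_overlaps) <- paste0(task_conditions, "_vs_", rest)
    task_mask <- sign_consistent_union(task_overlaps)
  }
  if (verbose) message("  task-vs-rest mask done")

  contrasts <- config$contrasts
  cname <- vapply(contrasts, paste, "", collapse = "_vs_")
  results <- list(); overlaps <- list(); restricted <- list()
  roi_labels <- list(); roi_tables <- list(); roi_tests <- list()
  for (ci in seq_along(contrasts)) {
    ctr <- contrasts[[ci]]
    res <- lapply(scanners, function(sc) test_pair(ctr[1], ctr[2], sc))
    names(res) <- scanners
    ov <- conjunction(lapply(res, adj_mask), contrast = ctr,
                      scanners = scanners)
    rst <- if (is.null(task_mask)) ov else restrict_to_task_mask(ov, task_mask)
    zbar <- Reduce(`+`, lapply(res, `[[`, "z_map")) / length(res)
    lab <- label_rois(rst, zbar)
    results[[cname[ci]]] <- res
    overlaps[[cname[ci]]] <- ov
    restricted[[cname[ci]]] <- rst
    roi_labels[[cname[ci]]] <- lab
    if (nrow(attr(lab, "rois"))) {
      tab <- roi_mean_table(maps, lab)
      roi_tables[[cname[ci]]] <- tab
      roi_tests[[cname[ci]]] <- roi_paired_tests(tab, ctr)
    }
    if (verbose) message("  contrast ", cname[ci], " done")
  }

  recovery <- NULL
  gt <- if (inherits(source, "synthetic_cohort")) source$ground_truth
        else if (inherits(source, "cohort_spec")) ground_truth(source)
  if (!is.null(gt)) recovery <- recovery_metrics(restricted, gt)

  provenance <- list(
    package = "benmapr", version = as.character(packageVersion("benmapr")),
    r_version = as.character(getRversion()),
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S"),
    alpha = config$alpha, p_adjust = config$p_adjust,
    preproc = unclass(config$preproc), ben = unclass(config$ben),
    n_subjects = length(subjects), scanners = scanners,
    source = if (inherits(source, "cohort_spec"))
      list(type = "cohort_spec", seed = source$seed)
    else if (inherits(source, "synthetic_cohort"))
      list(type = "synthetic_cohort", seed = source$spec$seed)
    else list(type = "manifest",
              md5 = if (is.character(source))
                unname(tools::md5sum(source)) else NA),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")))

  out <- structure(
    list(contrasts = results, overlap = overlaps, task_mask = task_mask,
         task_overlaps = task_overlaps, restricted = restricted,
         roi_labels = roi_labels, roi_table = roi_tables,
         roi_tests = roi_tests, recovery = recovery, maps_manifest = manifest,
         config = config, provenance = provenance),
    class = "ben_results")
  if (!is.null(out_dir)) write_results(out, maps, out_dir)
  out
}

#' Planted-effect recovery metrics for a synthetic cohort
#'
#' For every (region, contrast) pair with a nonzero expected sign: `recall`
#' is the fraction of planted voxels carrying the expected sign in the
#' restricted overlap mask; `false_sign_rate` is the fraction of voxels
#' outside the planted region whose overlap sign is *opposite* to the
#' planted sign (smoothing legitimately spreads correct-sign signal a few
#' voxels past the region boundary, so same-sign spillover is not counted
#' as an error).
#'
#' A detection outside every planted region counts as false unless its sign
#' matches a nearby planted effect: each region's indicator is smoothed with
#' the post-entropy FWHM, and a voxel where some region's kernel weight
#' exceeds 1% "expects" the sign of the dominant such region. Smoothing
#' legitimately spreads correct-sign signal over that halo in any faithful
#' implementation, so only wrong-sign or out-of-halo detections are errors.
#'
#' @param restricted named list of restricted `overlap_mask` per contrast
#'   (names `"a_vs_b"`).
#' @param ground_truth ground truth from [generate_cohort()] /
#'   [ground_truth()].
#' @param fwhm_mm smoothing FWHM (mm) defining the spillover halo.
#' @param voxel_size mm per voxel of the analysis grid.
#' @return data frame: region, contrast, expected_sign, n_planted, recall,
#'   false_sign_rate (false detections outside planted regions / outside
#'   voxels, shared across regions of a contrast).
#' @export
recovery_metrics <- function(restricted, ground_truth, fwhm_mm = 10,
                             voxel_size = 3) {
  gt <- ground_truth$expected_contrast_sign
  masks <- ground_truth$region_masks
  regions <- attr(masks, "regions")
  halo <- lapply(regions, function(lv)
    gaussian_smooth_array((masks == lv) + 0, fwhm_mm,
                          rep_len(voxel_size, 3L)))
  out <- list()
  for (nm in names(restricted)) {
    pair <- strsplit(nm, "_vs_", fixed = TRUE)[[1]]
    ov <- restricted[[nm]]$mask
    sub <- gt[gt$cond_a == pair[1] & gt$cond_b == pair[2] & gt$sign != 0, ]
    if (!nrow(sub)) next
    # locally expected sign: dominant planted region within the halo
    wmax <- array(0, dim(masks))
    esign <- array(0L, dim(masks))
    for (i in seq_len(nrow(sub))) {
      w <- halo[[sub$region[i]]]
      upd <- w > pmax(wmax, 0.01)
      esign[upd] <- sub$sign[i]
      wmax <- pmax(wmax, w)
    }
    planted_any <- array(FALSE, dim(masks))
    for (i in seq_len(nrow(sub)))
      planted_any <- planted_any | masks == regions[[sub$region[i]]]
    outside <- !planted_any
    false_rate <- mean(ov[outside] != 0L & ov[outside] != esign[outside])
    for (i in seq_len(nrow(sub))) {
      inside <- masks == regions[[sub$region[i]]]
      out[[length(out) + 1L]] <- data.frame(
        region = sub$region[i], contrast = nm,
        expected_sign = sub$sign[i], n_planted = sum(inside),
        recall = mean(ov[inside] == sub$sign[i]),
        false_sign_rate = false_rate,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Per-scanner ROI tests for each planted effect
#'
#' Matches every planted (region, contrast) effect to the recovered ROI with
#' the largest voxel overlap and returns that ROI's individual-level paired
#' t-test per scanner, alongside the expected sign.
#'
#' @param results a `ben_results` bundle from [run_pipeline()].
#' @param ground_truth ground truth of the synthetic cohort.
#' @return data frame: region, contrast, expected_sign, roi_label, scanner,
#'   n, df, t, p (empty when nothing was recovered).
#' @export
planted_roi_summary <- function(results, ground_truth) {
  gt <- ground_truth$expected_contrast_sign
  masks <- ground_truth$region_masks
  regions <- attr(masks, "regions")
  out <- list()
  for (nm in names(results$roi_labels)) {
    pair <- strsplit(nm, "_vs_", fixed = TRUE)[[1]]
    sub <- gt[gt$cond_a == pair[1] & gt$cond_b == pair[2] & gt$sign != 0, ]
    lab <- results$roi_labels[[nm]]
    rois <- attr(lab, "rois")
    tests <- results$roi_tests[[nm]]
    if (is.null(tests) || !nrow(rois)) next
    for (i in seq_len(nrow(sub))) {
      inside <- masks == regions[[sub$region[i]]]
      ovl <- vapply(rois$label, function(l) sum(lab[inside] == l), 0L)
      if (!any(ovl > 0)) next
      best <- rois$name[which.max(ovl)]
      rows <- tests[tests$roi_label == best, ]
      if (!nrow(rows)) next
      rows$region <- sub$region[i]
      rows$contrast <- nm
      rows$expected_sign <- sub$sign[i]
      out[[length(out) + 1L]] <- rows
    }
  }
  if (!length(out))
    return(data.frame(region = character(), contrast = character(),
                      expected_sign = integer(), roi_label = character(),
                      scanner = character(), n = integer(), df = integer(),
                      t = numeric(), p = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("region", "contrast", "expected_sign", "roi_label", "scanner",
          "n", "df", "t", "p")]
}

# Write pipeline outputs: NIfTI maps, TSV tables, figures, provenance JSON.
write_results <- function(res, maps, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  vs <- maps[[1]]$voxel_size
  for (nm in names(res$contrasts)) {
    for (sc in names(res$contrasts[[nm]])) {
      cr <- res$contrasts[[nm]][[sc]]
      for (fld in c("t_map", "p_map", "z_map"))
        write_map_nifti(cr[[fld]], vs,
                        file.path(out_dir, sprintf("%s_%s_%s.nii.gz", nm, sc,
                                                   sub("_map", "", fld))))
    }
    write_map_nifti(res$overlap[[nm]]$mask + 0, vs,
                    file.path(out_dir, sprintf("%s_overlap.nii.gz", nm)))
    write_map_nifti(res$restricted[[nm]]$mask + 0, vs,
                    file.path(out_dir, sprintf("%s_overlap_restricted.nii.gz",
                                               nm)))
    if (!is.null(res$roi_table[[nm]]))
      write.table(res$roi_table[[nm]],
                  file.path(out_dir, sprintf("%s_roi_means.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$roi_tests[[nm]]))
      write.table(res$roi_tests[[nm]],
                  file.path(out_dir, sprintf("%s_roi_tests.tsv", nm)),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(res$roi_table[[nm]])) {
      fig <- try(plot_roi_spaghetti(res$roi_table[[nm]]), silent = TRUE)
      if (!inherits(fig, "try-error"))
        ggplot2::ggsave(file.path(out_dir, sprintf("%s_roi_spaghetti.png",
                                                   nm)),
                        fig, width = 9, height = 4, dpi = 120)
    }
  }
  if (!is.null(res$task_mask))
    write_map_nifti(res$task_mask$mask + 0, vs,
                    file.path(out_dir, "task_vs_rest_mask.nii.gz"))
  if (!is.null(res$recovery))
    write.table(res$recovery, file.path(out_dir, "recovery_metrics.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(res$provenance, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Per-subject ROI mean ("spaghetti") plot across conditions
#'
#' One line per participant, faceted by scanner and ROI: the standard
#' visualization of individual-level consistency of condition effects.
#'
#' @param roi_table a [roi_mean_table()].
#' @param conditions optional condition ordering for the x axis.
#' @return a ggplot object.
#' @export
plot_roi_spaghetti <- function(roi_table, conditions = NULL) {
  tab <- roi_table[!roi_table$missing, ]
  if (!is.null(conditions))
    tab$condition <- factor(tab$condition, levels = conditions)
  ggplot2::ggplot(tab, ggplot2::aes(x = condition, y = mean_ben,
                                    group = subject, color = subject)) +
    ggplot2::geom_line(alpha = 0.5, show.legend = FALSE) +
    ggplot2::geom_point(size = 0.6, show.legend = FALSE) +
    ggplot2::facet_grid(roi_label ~ scanner) +
    ggplot2::labs(x = NULL, y = "mean BEN (nats)") +
    ggplot2::theme_minimal(base_size = 9)
}
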