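#' Per-scanner voxel-wise paired t-test result
#'
#' @param t_map,p_map,z_map 3D arrays.
#' @param df scalar nominal degrees of freedom (`n - 1`), or 3D array where
#'   voxels lost subjects to missing data.
#' @param contrast ordered pair `c(condition_a, condition_b)` (a minus b).
#' @param scanner scanner label.
#' @return object of class `contrast_result`.
#' @export
contrast_result <- function(t_map, p_map, z_map, df, contrast,
                            scanner = NA_character_) {
  structure(list(t_map = t_map, p_map = p_map, z_map = z_map, df = df,
                 contrast = contrast, scanner = scanner),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf("<contrast_result> %s: %s - %s, df=%s, %s voxels\n",
              x$scanner, x$contrast[1], x$contrast[2],
              paste(unique(range(x$df, na.rm = TRUE)), collapse = "-"),
              length(x$t_map)))
  invisible(x)
}

#' Voxel-wise paired t-test between two per-subject map sets
#'
#' Computes `d = a - b` per subject and voxel, then
#' `t = mean(d) / (sd(d)/sqrt(n))` with `sd` the sample SD (ddof = 1) and a
#' two-sided p-value from the Student-t distribution with `df = n - 1`.
#' Voxels where a subject is `NA` are dropped pairwise with a per-voxel df
#' adjustment. Zero-variance voxels follow the rule: if the mean difference
#' is also zero, `t = 0, p = 1`; otherwise `t = +/-Inf` (sentinel, `p = 0`).
#'
#' @param maps_a,maps_b lists of [ben_map()] (or plain 3D arrays), same
#'   ordered subjects on both sides.
#' @param mask optional logical 3D array restricting the test.
#' @param contrast ordered pair of condition labels (defaults taken from the
#'   first maps when available).
#' @param scanner scanner label.
#' @return a [contrast_result()].
#' @export
paired_t_map <- function(maps_a, maps_b, mask = NULL, contrast = NULL,
                         scanner = NA_character_) {
  stopifnot(length(maps_a) == length(maps_b), length(maps_a) >= 2)
  get_vals <- function(m) if (inherits(m, "ben_map")) m$values else m
  subj <- function(ms) vapply(ms, function(m)
    if (inherits(m, "ben_map")) m$subject else NA_character_, "")
  sa <- subj(maps_a); sb <- subj(maps_b)
  if (!all(is.na(sa)) && !identical(sa, sb))
    stop("subject lists differ between the two sides of the contrast")
  if (is.null(contrast) && inherits(maps_a[[1]], "ben_map"))
    contrast <- c(maps_a[[1]]$condition, maps_b[[1]]$condition)
  dims <- dim(get_vals(maps_a[[1]]))
  n <- length(maps_a)
  D <- vapply(seq_len(n),
              function(i) get_vals(maps_a[[i]]) - get_vals(maps_b[[i]]),
              array(0, dims))
  dim(D) <- c(prod(dims), n)
  if (!is.null(mask)) D[!mask, ] <- NA_real_
  ok <- !is.na(D)
  nv <- rowSums(ok)
  D0 <- D
  D0[!ok] <- 0
  mu <- rowSums(D0) / nv
  ss <- rowSums((D0 - ifelse(ok, mu, 0))^2)
  sdv <- sqrt(ss / pmax(nv - 1, 1))
  se <- sdv / sqrt(nv)
  t <- mu / se
  # zero-variance rule (relative tolerance: a numerically constant nonzero
  # difference leaves rounding-level variance)
  zv <- is.finite(mu) & (sdv == 0 | sdv <= abs(mu) * 1e-12)
  t[zv & mu == 0] <- 0
  t[zv & mu > 0] <- Inf
  t[zv & mu < 0] <- -Inf
  t[nv < 2] <- NA_real_
  dfv <- nv - 1
  dfv[nv < 2] <- NA_real_
  p <- 2 * pt(-abs(t), dfv)
  p[is.infinite(t)] <- 0
  z <- t_to_z(t, dfv)
  shape <- function(x) array(x, dims)
  df_out <- if (length(unique(dfv[!is.na(dfv)])) == 1L)
    unique(dfv[!is.na(dfv)]) else shape(dfv)
  contrast_result(shape(t), shape(p), shape(z), df_out,
                  contrast = contrast, scanner = scanner)
}

#' Convert t statistics to z scores
#'
#' `z = Phi^{-1}(F_t(t, df))`, evaluated through tail-symmetric survival
#' functions in log space so that `sign(z) == sign(t)` and `|z|` stays
#' finite for `|t|` up to about 40 at moderate df.
#'
#' @param t numeric vector/array of t statistics.
#' @param df degrees of freedom (scalar or same shape as `t`), `>= 1`.
#' @return z scores, same shape as `t`.
#' @export
t_to_z <- function(t, df) {
  if (any(df < 1, na.rm = TRUE)) stop("df must be >= 1")
  log_p_lower <- pt(-abs(t), df, log.p = TRUE)  # log P(T <= -|t|)
  z_mag <- -qnorm(log_p_lower, log.p = TRUE)    # |z|
  out <- sign(t) * z_mag
  out[is.infinite(t)] <- sign(t[is.infinite(t)]) * Inf
  if (!is.null(dim(t))) dim(out) <- dim(t)
  out
}

#' Signed significance mask at an uncorrected threshold
#'
#' `+1` where `p < alpha` and `t > 0`, `-1` where `p < alpha` and `t < 0`,
#' `0` elsewhere (strict inequality, per "p < 0.05").
#'
#' @param result a [contrast_result()].
#' @param alpha two-sided significance level in (0, 1).
#' @return integer 3D array in `{-1, 0, +1}` (NA voxels give 0).
#' @export
signed_significance_mask <- function(result, alpha = 0.05) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  m <- array(0L, dim(result$t_map))
  sig <- !is.na(result$p_map) & result$p_map < alpha
  m[sig & result$t_map > 0] <- 1L
  m[sig & result$t_map < 0] <- -1L
  m
}

#' Sign-consistent conjunction across scanners
#'
#' `+1` where every input mask is `+1`, `-1` where every input is `-1`, `0`
#' otherwise: a voxel survives only if it is significant with the same
#' effect direction on all platforms.
#'
#' @param masks list of signed masks (3D arrays in `{-1,0,+1}`) on a common
#'   grid, one per scanner; at least 2.
#' @param contrast,scanners optional labels.
#' @return object of class `overlap_mask` with fields `mask`,
#'   `contributing_scanners`, `contrast`, `restricted_to`.
#' @export
conjunction <- function(masks, contrast = NULL, scanners = NULL) {
  stopifnot(is.list(masks), length(masks) >= 2)
  d <- dim(masks[[1]])
  for (m in masks) if (!identical(dim(m), d))
    stop("signed masks are not on a common grid")
  pos <- Reduce(`&`, lapply(masks, function(m) m == 1L))
  neg <- Reduce(`&`, lapply(masks, function(m) m == -1L))
  out <- array(0L, d)
  out[pos] <- 1L
  out[neg] <- -1L
  structure(list(mask = out, contributing_scanners = scanners,
                 contrast = contrast, restricted_to = NA_character_),
            class = "overlap_mask")
}

#' Sign-consistent union of overlap masks
#'
#' Used to build the composite task-vs-rest mask: a voxel is nonzero when at
#' least one contributing overlap is nonzero and all nonzero contributions
#' share the same sign; conflicting signs give 0.
#'
#' @param overlaps list of `overlap_mask` (or signed 3D arrays).
#' @return an `overlap_mask`.
#' @export
sign_consistent_union <- function(overlaps) {
  arrs <- lapply(overlaps, function(o)
    if (inherits(o, "overlap_mask")) o$mask else o)
  d <- dim(arrs[[1]])
  any_pos <- Reduce(`|`, lapply(arrs, function(m) m == 1L))
  any_neg <- Reduce(`|`, lapply(arrs, function(m) m == -1L))
  out <- array(0L, d)
  out[any_pos & !any_neg] <- 1L
  out[any_neg & !any_pos] <- -1L
  structure(list(mask = out, contributing_scanners = NULL,
                 contrast = "task_vs_rest_union",
                 restricted_to = NA_character_),
            class = "overlap_mask")
}

#' Restrict an overlap mask to task-responsive voxels
#'
#' Voxels where `task_mask` is zero are set to zero; an empty task mask
#' yields a warning and an empty result.
#'
#' @param overlap an `overlap_mask`.
#' @param task_mask an `overlap_mask` (or signed 3D array) on the same grid.
#' @return restricted `overlap_mask`.
#' @export
restrict_to_task_mask <- function(overlap, task_mask) {
  tm <- if (inherits(task_mask, "overlap_mask")) task_mask$mask else task_mask
  stopifnot(identical(dim(overlap$mask), dim(tm)))
  if (!any(tm != 0)) warning("task mask is empty; restriction removes everything")
  overlap$mask[tm == 0L] <- 0L
  overlap$restricted_to <- "task_vs_rest"
  overlap
}

#' Label connected components of a signed mask (26-connectivity)
#'
#' Components never mix signs. Each ROI is named by the grid coordinate of
#' its peak `|z|` voxel and its sign, e.g. `"roi_x12_y11_z5_pos"`.
#'
#' @param mask signed 3D array (or `overlap_mask`).
#' @param z_map optional 3D z-map used to locate each component's peak.
#' @return integer label array with attribute `rois`: data frame
#'   (label, name, sign, n_voxels, peak_x, peak_y, peak_z).
#' @export
label_rois <- function(mask, z_map = NULL) {
  m <- if (inherits(mask, "overlap_mask")) mask$mask else mask
  d <- dim(m)
  lab <- array(0L, d)
  nbr <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nbr <- nbr[rowSums(nbr != 0) > 0, ]
  nxt <- 0L
  info <- list()
  todo <- which(m != 0L & lab == 0L)
  for (start in todo) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    s <- m[start]
    queue <- start
    lab[start] <- nxt
    members <- start
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      ijk <- arrayInd(v, d)
      cand <- sweep(nbr, 2L, as.integer(ijk), `+`)
      keep <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
              cand[, 2] >= 1 & cand[, 2] <= d[2] &
              cand[, 3] >= 1 & cand[, 3] <= d[3]
      cand <- cand[keep, , drop = FALSE]
      lin <- cand[, 1] + d[1] * (cand[, 2] - 1L) + d[1] * d[2] * (cand[, 3] - 1L)
      lin <- lin[m[lin] == s & lab[lin] == 0L]
      if (length(lin)) {
        lab[lin] <- nxt
        queue <- c(queue, lin)
        members <- c(members, lin)
      }
    }
    zvals <- if (is.null(z_map)) rep(0, length(members)) else
      abs(z_map[members])
    peak <- arrayInd(members[which.max(zvals)], d)
    info[[nxt]] <- data.frame(
      label = nxt,
      name = sprintf("roi_x%d_y%d_z%d_%s", peak[1], peak[2], peak[3],
                     if (s > 0) "pos" else "neg"),
      sign = s, n_voxels = length(members),
      peak_x = peak[1], peak_y = peak[2], peak_z = peak[3])
  }
  attr(lab, "rois") <- if (length(info)) do.call(rbind, info) else
    data.frame(label = integer(), name = character(), sign = integer(),
               n_voxels = integer(), peak_x = integer(), peak_y = integer(),
               peak_z = integer())
  lab
}

#' Per-subject ROI mean table
#'
#' Arithmetic mean BEN over each labelled ROI for every map, excluding `NA`
#' voxels; rows with an all-`NA` ROI are flagged missing.
#'
#' @param ben_maps list of [ben_map()] objects (any subjects / scanners /
#'   conditions).
#' @param roi_labels label array from [label_rois()].
#' @return data frame: subject, scanner, condition, roi_label, mean_ben,
#'   n_voxels, missing.
#' @export
roi_mean_table <- function(ben_maps, roi_labels) {
  rois <- attr(roi_labels, "rois")
  if (is.null(rois) || nrow(rois) == 0L) stop("no ROIs in label image")
  rows <- lapply(ben_maps, function(bm) {
    do.call(rbind, lapply(seq_len(nrow(rois)), function(i) {
      vals <- bm$values[roi_labels == rois$label[i]]
      ok <- is.finite(vals)
      data.frame(subject = bm$subject, scanner = bm$scanner,
                 condition = bm$condition, roi_label = rois$name[i],
                 mean_ben = if (any(ok)) mean(vals[ok]) else NA_real_,
                 n_voxels = sum(ok), missing = !any(ok),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Individual-level paired t-tests on ROI means
#'
#' Scalar paired t-test per scanner and ROI between two conditions, from a
#' [roi_mean_table()]. Zero-variance differences follow the same sentinel
#' rule as [paired_t_map()] and are flagged.
#'
#' @param table ROI mean table.
#' @param contrast ordered pair `c(condition_a, condition_b)`.
#' @return data frame: scanner, roi_label, n, df, t, p, flagged.
#' @export
roi_paired_tests <- function(table, contrast) {
  stopifnot(length(contrast) == 2L,
            all(contrast %in% table$condition))
  cells <- unique(table[, c("scanner", "roi_label")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    sub <- table[table$scanner == cells$scanner[i] &
                   table$roi_label == cells$roi_label[i], ]
    a <- sub[sub$condition == contrast[1], c("subject", "mean_ben")]
    b <- sub[sub$condition == contrast[2], c("subject", "mean_ben")]
    m <- merge(a, b, by = "subject", suffixes = c("_a", "_b"))
    m <- m[complete.cases(m), ]
    if (nrow(m) < 2)
      stop("fewer than 2 complete pairs for scanner ", cells$scanner[i],
           ", ROI ", cells$roi_label[i])
    d <- m$mean_ben_a - m$mean_ben_b
    n <- length(d)
    sdd <- sd(d)
    flagged <- FALSE
    if (sdd == 0 || sdd <= abs(mean(d)) * 1e-12) {
      if (mean(d) == 0) { tval <- 0; pval <- 1 }
      else { tval <- sign(mean(d)) * Inf; pval <- 0 }
      flagged <- TRUE
    } else {
      tval <- mean(d) / (sdd / sqrt(n))
      pval <- 2 * pt(-abs(tval), n - 1)
    }
    data.frame(scanner = cells$scanner[i], roi_label = cells$roi_label[i],
               n = n, df = n - 1, t = tval, p = pval, flagged = flagged,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
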