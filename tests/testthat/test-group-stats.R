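# helpers to build single-scanner map sets quickly
mapify <- function(mat, dims, subjects, condition = "a",
                   scanner = "S1") {
  lapply(seq_along(subjects), function(i)
    ben_map_obj(array(mat[i, ], dims), 3, array(TRUE, dims), ben_params(),
                subject = subjects[i], scanner = scanner,
                condition = condition))
}

test_that("paired_t_map matches the closed-form oracle and its symmetries", {
  dims <- c(2, 2, 1)
  subj <- paste0("s", 1:4)
  a <- matrix(0, 4, 4)
  a[, 1] <- c(1, 2, 3, 4)  # one voxel with d = 1:4, others zero difference
  maps_a <- mapify(a, dims, subj, "x")
  maps_b <- mapify(matrix(0, 4, 4), dims, subj, "y")
  res <- paired_t_map(maps_a, maps_b)
  o <- oracle_paired_t(c(1, 2, 3, 4), rep(0, 4))
  expect_equal(res$t_map[1, 1, 1], 3.872983, tolerance = 1e-6)
  expect_equal(res$t_map[1, 1, 1], o$t, tolerance = 1e-10)
  expect_identical(res$df, 3)
  expect_equal(res$p_map[1, 1, 1], o$p, tolerance = 1e-12)
  # zero difference voxels follow the zero-variance rule
  expect_identical(res$t_map[2, 1, 1], 0)
  expect_identical(res$p_map[2, 1, 1], 1)
  # antisymmetry
  rev <- paired_t_map(maps_b, maps_a)
  expect_equal(rev$t_map, -res$t_map, tolerance = 1e-12)
  # mismatched subject lists error
  maps_b2 <- mapify(matrix(0, 4, 4), dims, rev(subj), "y")
  expect_error(paired_t_map(maps_a, maps_b2), "subject lists differ")
})

test_that("paired_t_map drops NA subjects pairwise with df adjustment", {
  dims <- c(2, 1, 1)
  subj <- paste0("s", 1:5)
  a <- matrix(rnorm(10), 5, 2)
  b <- matrix(rnorm(10), 5, 2)
  maps_a <- mapify(a, dims, subj, "x")
  maps_b <- mapify(b, dims, subj, "y")
  maps_a[[2]]$values[2, 1, 1] <- NA
  res <- paired_t_map(maps_a, maps_b)
  expect_identical(dim(res$df), as.integer(dims))  # per-voxel df once subjects drop out
  expect_identical(res$df[1, 1, 1], 4)
  expect_identical(res$df[2, 1, 1], 3)
  keep <- c(1, 3, 4, 5)
  o <- oracle_paired_t(a[keep, 2], b[keep, 2])
  expect_equal(res$t_map[2, 1, 1], o$t, tolerance = 1e-10)
})

test_that("t_to_z preserves sign, matches the normal limit and a quadrature oracle", {
  expect_identical(t_to_z(0, 5), 0)
  expect_lt(abs(t_to_z(1.96, 1e6) - 1.96), 1e-3)
  expect_lt(abs(t_to_z(2.021, 40) - oracle_t_to_z(2.021, 40)), 1e-8)
  expect_lt(abs(t_to_z(-2.021, 40) - oracle_t_to_z(-2.021, 40)), 1e-8)
  expect_identical(t_to_z(2.021, 40), -t_to_z(-2.021, 40))
  # finite for large t
  expect_true(is.finite(t_to_z(39, 40)))
  expect_error(t_to_z(1, 0.5), "df")
})

test_that("signed significance mask applies the strict p < alpha rule", {
  t_map <- array(c(2.1, 1.9, -3, 0), c(4, 1, 1))
  p_map <- array(c(0.049, 0.05, 0.01, 1), c(4, 1, 1))
  res <- contrast_result(t_map, p_map, t_map, 9, c("a", "b"))
  m <- signed_significance_mask(res, 0.05)
  expect_identical(as.integer(m), c(1L, 0L, -1L, 0L))
  expect_error(signed_significance_mask(res, 1.2), "alpha")
})

test_that("conjunction takes the sign-consistent intersection", {
  d <- c(5, 1, 1)
  m1 <- array(c(1L, 1L, 1L, -1L, 0L), d)
  m2 <- array(c(1L, 1L, 0L, -1L, 0L), d)
  m3 <- array(c(1L, -1L, 1L, -1L, 1L), d)
  ov <- conjunction(list(m1, m2, m3))
  expect_identical(as.integer(ov$mask), c(1L, 0L, 0L, -1L, 0L))
  # idempotence
  self <- conjunction(list(m1, m1))
  expect_identical(self$mask, m1)
  expect_error(conjunction(list(m1, array(0L, c(2, 1, 1)))), "common grid")
})

test_that("three-scanner conjunction of independent null maps matches the analytic rate", {
  set.seed(17)
  nvox <- 2e5
  df <- 40
  masks <- lapply(1:3, function(s) {
    tv <- array(rt(nvox, df), c(nvox, 1, 1))
    pv <- 2 * pt(-abs(tv), df)
    signed_significance_mask(contrast_result(tv, pv, tv, df, c("a", "b")),
                             0.05)
  })
  rate <- mean(conjunction(masks)$mask != 0)
  p0 <- 2 * 0.025^3
  expect_lt(abs(rate - p0), 3 * sqrt(p0 * (1 - p0) / nvox))
})

test_that("sign-consistent union and task-mask restriction behave as defined", {
  d <- c(4, 1, 1)
  o1 <- array(c(1L, 0L, -1L, 0L), d)
  o2 <- array(c(1L, 1L, 1L, 0L), d)
  u <- sign_consistent_union(list(o1, o2))
  expect_identical(as.integer(u$mask), c(1L, 1L, 0L, 0L))
  ov <- conjunction(list(o2, o2))
  # all-nonzero task mask is the identity
  full <- u; full$mask <- array(1L, d)
  expect_identical(restrict_to_task_mask(ov, full)$mask, ov$mask)
  # disjoint task mask empties the overlap, empty task mask warns
  disj <- u; disj$mask <- array(c(0L, 0L, 0L, 1L), d)
  expect_identical(as.integer(restrict_to_task_mask(ov, disj)$mask),
                   c(0L, 0L, 0L, 0L))
  none <- u; none$mask <- array(0L, d)
  expect_warning(restrict_to_task_mask(ov, none), "empty")
})

test_that("label_rois finds 26-connected signed components with peak naming", {
  d <- c(6, 6, 3)
  m <- array(0L, d)
  m[1:2, 1:2, 1] <- 1L
  m[3, 3, 2] <- 1L        # touches (2,2,1) only diagonally -> same component
  m[5:6, 5:6, 3] <- -1L   # separate, negative
  z <- array(0, d)
  z[1, 2, 1] <- 5; z[5, 5, 3] <- -4
  lab <- label_rois(m, z)
  rois <- attr(lab, "rois")
  expect_identical(nrow(rois), 2L)
  expect_setequal(rois$sign, c(1L, -1L))
  pos <- rois[rois$sign == 1, ]
  expect_identical(pos$n_voxels, 5L)
  expect_identical(pos$name, "roi_x1_y2_z1_pos")
  neg <- rois[rois$sign == -1, ]
  expect_identical(neg$name, "roi_x5_y5_z3_neg")
})

test_that("roi_mean_table matches direct means and flags missing cells", {
  d <- c(3, 3, 1)
  lab <- array(0L, d)
  lab[1, 1, 1] <- 1L           # single-voxel ROI
  lab[2:3, 2:3, 1] <- 2L
  attr(lab, "rois") <- data.frame(label = 1:2, name = c("one", "blk"),
                                  sign = c(1L, 1L), n_voxels = c(1L, 4L),
                                  peak_x = 1, peak_y = 1, peak_z = 1)
  set.seed(18)
  v <- array(rnorm(9), d)
  bm <- ben_map_obj(v, 3, array(TRUE, d), ben_params(), subject = "s1",
                    scanner = "A", condition = "rest")
  tab <- roi_mean_table(list(bm), lab)
  expect_identical(tab$mean_ben[tab$roi_label == "one"], v[1, 1, 1])
  expect_equal(tab$mean_ben[tab$roi_label == "blk"],
               mean(v[lab == 2L]), tolerance = 1e-12)
  # constant map gives the constant; all-NaN ROI flagged missing
  bm2 <- bm; bm2$values[] <- 3; bm2$values[lab == 2L] <- NA
  tab2 <- roi_mean_table(list(bm2), lab)
  expect_identical(tab2$mean_ben[tab2$roi_label == "one"], 3)
  expect_true(tab2$missing[tab2$roi_label == "blk"])
})

test_that("roi_paired_tests reproduces the scalar formula and handles degeneracy", {
  set.seed(19)
  n <- 41
  subjects <- sprintf("s%02d", 1:n)
  vals_a <- rnorm(n); vals_b <- rnorm(n)
  tab <- rbind(
    data.frame(subject = subjects, scanner = "A", condition = "x",
               roi_label = "r1", mean_ben = vals_a, n_voxels = 5,
               missing = FALSE),
    data.frame(subject = subjects, scanner = "A", condition = "y",
               roi_label = "r1", mean_ben = vals_b, n_voxels = 5,
               missing = FALSE))
  res <- roi_paired_tests(tab, c("x", "y"))
  o <- oracle_paired_t(vals_a, vals_b)
  expect_identical(res$df, 40)      # 41 complete pairs -> df 40
  expect_equal(res$t, o$t, tolerance = 1e-10)
  expect_equal(res$p, o$p, tolerance = 1e-10)
  # constant nonzero difference -> infinite-t sentinel, flagged
  tab2 <- tab
  tab2$mean_ben[tab2$condition == "x"] <-
    tab2$mean_ben[tab2$condition == "y"] + 0.1
  res2 <- roi_paired_tests(tab2, c("x", "y"))
  expect_identical(res2$t, Inf)
  expect_true(res2$flagged)
  # fewer than two complete pairs -> error
  tab3 <- tab[tab$subject == "s01", ]
  expect_error(roi_paired_tests(tab3, c("x", "y")), "complete pairs")
})
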