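test_that("AR(1) generator has the requested autocorrelation structure", {
  ac1 <- function(x) cor(x[-1], x[-length(x)])
  white <- generate_voxel_series(phi = 0, sd = 1, n = 10000, seed = 1)
  expect_lt(abs(ac1(white)), 0.03)
  reg <- generate_voxel_series(phi = 0.9, sd = 1, n = 10000, seed = 2)
  expect_lt(abs(ac1(reg) - 0.9), 0.03)
  # marginal variance sd^2 / (1 - phi^2)
  expect_lt(abs(var(reg) - 1 / (1 - 0.81)) / (1 / (1 - 0.81)), 0.15)
})

test_that("AR(1) generator is seeded-deterministic and rejects phi >= 1", {
  a <- generate_voxel_series(0.5, 1, 100, seed = 7)
  b <- generate_voxel_series(0.5, 1, 100, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, generate_voxel_series(0.5, 1, 100, seed = 8)))
  expect_error(generate_voxel_series(1.0, 1, 100), "non-stationary")
  expect_error(cohort_spec(region_effects = list(A = c(rest = 1.2))),
               "non-stationary")
})

test_that("mean sample entropy of AR(1) series is non-increasing in phi", {
  set.seed(42)
  phis <- c(0, 0.3, 0.6, 0.9)
  means <- vapply(phis, function(phi) {
    mean(replicate(200, sample_entropy(
      generate_voxel_series(phi, 1, 236), m = 3, r_frac = 0.6)),
      na.rm = TRUE)
  }, 0)
  expect_true(all(diff(means) <= 0))
  expect_lt(means[4], means[1])  # strict overall decrease
})

test_that("generate_cohort emits one run + nuisance set per cell", {
  spec <- cohort_spec(n_subjects = 2, scanners = c("A", "B"),
                      conditions = c("rest", "rumination"),
                      region_effects = list(
                        VCish = c(rest = 0.1, rumination = 0.8)),
                      grid_shape = c(8L, 8L, 8L), n_volumes = 16L, seed = 5)
  coh <- generate_cohort(spec)
  expect_length(coh$runs, 8L)
  for (cell in coh$runs) {
    expect_s3_class(cell$run, "bold_run")
    expect_identical(dim(cell$run$data), c(8L, 8L, 8L, 16L))
    expect_identical(nrow(cell$nuisance), 16L)
    expect_identical(names(cell$nuisance),
                     c(paste0("mot", 1:6), "wm", "csf"))
  }
  expect_error(cohort_spec(region_effects = list()), "at least one region")
})

test_that("cohort generation is bit-identical under a fixed seed, including NIfTI payloads", {
  spec <- tiny_spec(n_subjects = 2, seed = 9, grid = c(6L, 6L, 4L),
                    n_volumes = 20L)
  c1 <- generate_cohort(spec)
  c2 <- generate_cohort(spec)
  expect_identical(c1$runs, c2$runs)
  # on-disk payloads
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(c1, d1); write_cohort(c2, d2)
  f1 <- sort(list.files(d1, "nii\\.gz$", full.names = TRUE))
  f2 <- sort(list.files(d2, "nii\\.gz$", full.names = TRUE))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  # run-level generation reproduces the cohort regardless of order
  one <- generate_run(spec, 2, "PKUGE", "distraction")
  idx <- which(c1$manifest$subject == "sub02" &
                 c1$manifest$scanner == "PKUGE" &
                 c1$manifest$condition == "distraction")
  expect_identical(one, c1$runs[[c1$manifest$index[idx]]])
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("regressing the emitted nuisance set out of a pure-nuisance voxel removes it", {
  spec <- tiny_spec(n_subjects = 2, seed = 13, grid = c(4L, 4L, 2L),
                    n_volumes = 40L)
  cell <- generate_run(spec, 1, 1, 1)
  run <- cell$run
  Z <- scale(as.matrix(cell$nuisance))
  pure <- Z %*% c(0.5, -0.2, 0.3, 0.1, -0.4, 0.2, 0.6, -0.3)
  run$data[1, 1, 1, ] <- pure
  res <- regress_nuisance(run, cell$nuisance)
  expect_lt(var(res$data[1, 1, 1, ]) / var(as.numeric(pure)), 0.01)
})

test_that("planted regional regularity separates conditions at the subject level", {
  # strong contrast: rumination phi 0.9 vs distraction phi 0 in one region
  spec <- cohort_spec(
    n_subjects = 8, scanners = "A",
    conditions = c("rumination", "distraction"),
    region_effects = list(
      VCish = c(rumination = 0.9, distraction = 0)),
    grid_shape = c(8L, 8L, 4L), n_volumes = 240L, seed = 21)
  masks <- default_region_masks(spec)
  inside <- which(masks == 1L)
  cfg <- preproc_config()
  region_mean_ben <- function(subj, cond) {
    cell <- generate_run(spec, subj, 1, cond, region_masks = masks)
    pp <- preprocess_run(cell$run, cell$nuisance, cfg)
    bm <- ben_map(pp)
    mean(bm$values[inside], na.rm = TRUE)
  }
  lower <- vapply(seq_len(spec$n_subjects), function(s)
    region_mean_ben(s, "rumination") < region_mean_ben(s, "distraction"),
    TRUE)
  expect_gte(mean(lower), 0.9)
})

test_that("ground truth signs follow the planted AR coefficients", {
  spec <- tiny_spec()
  gt <- ground_truth(spec)
  pick <- function(rg, a, b)
    gt$expected_contrast_sign$sign[
      gt$expected_contrast_sign$region == rg &
        gt$expected_contrast_sign$cond_a == a &
        gt$expected_contrast_sign$cond_b == b]
  expect_identical(pick("VCish", "rumination", "sad"), -1)
  expect_identical(pick("PCCish", "rumination", "distraction"), 1)
  expect_identical(pick("PCCish", "distraction", "sad"), -1)
  expect_identical(pick("VCish", "distraction", "sad"), 0)
  # masks disjoint and present for every region
  m <- gt$region_masks
  expect_identical(sort(names(attr(m, "regions"))),
                   sort(names(spec$region_effects)))
  expect_true(all(table(m[m > 0]) > 0))
})
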