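test_that("target files parse labels and coordinates in both dialects", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# exported targets", "label\tx\ty\tz",
               "CZ\t-1.0\t-22.0\t99.9"), f)
  pts <- read_targets(f, "s1", "scalp")
  expect_equal(nrow(pts), 1)
  expect_equal(pts$electrode, "CZ")
  expect_equal(as.numeric(pts[1, c("x", "y", "z")]), c(-1, -22, 99.9))
  # comma-separated, no header, extra trailing columns tolerated
  writeLines(c("FZ,0.5,43.0,78.0,0.1,0.2,0.3", "PZ,-2.2,-80.0,79.6"), f)
  pts <- read_targets(f, "s1", "cortex")
  expect_equal(pts$electrode, c("FZ", "PZ"))
  expect_equal(pts$surface, c("cortex", "cortex"))
  expect_equal(pts$y, c(43, -80))
})

test_that("degenerate and malformed target files are handled", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("label\tx\ty\tz", f)
  expect_equal(nrow(read_targets(f, "s1", "scalp")), 0)
  writeLines(c("CZ\t1\t2\t3", "FZ\t4\t5"), f)
  expect_error(read_targets(f, "s1", "scalp"), "line 2")
  writeLines(c("CZ\t1\t2\t3", "FZ\t4\tfive\t6"), f)
  expect_error(read_targets(f, "s1", "scalp"), "non-numeric")
  writeLines(c("CZ\t1\t2\t3", "CZ\t4\t5\t6"), f)
  expect_error(read_targets(f, "s1", "scalp"), "duplicate")
  expect_error(read_targets(file.path(tempdir(), "absent.txt"),
                            "s1", "scalp"), "no such file")
})

test_that("a full montage of targets round-trips exactly", {
  co <- simulate_cohort(simulation_config(n_subjects = 1, seed = 3,
                                          cap_sizes_cm = 56))
  f <- withr::local_tempfile(fileext = ".txt")
  write_targets(co$points, f)
  back <- read_targets(f, co$points$subject_id[1], "scalp")
  expect_equal(back$electrode, co$points$electrode)
  expect_equal(back$x, co$points$x, tolerance = 1e-12)
  expect_equal(back$y, co$points$y, tolerance = 1e-12)
  expect_equal(back$z, co$points$z, tolerance = 1e-12)
})

test_that("affine files validate shape, homogeneity and invertibility", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 0 0 0", "0 1 0 0", "0 0 1 0", "0 0 0 1"), f)
  t <- read_affine(f)
  expect_equal(t$matrix, diag(4))
  expect_equal(t$from, "subject")
  writeLines(c("1 0 0 0", "0 1 0 0", "0 0 1 0", "0 0 0 2"), f)
  expect_error(read_affine(f), "last row")
  writeLines(c("1 0 0 0", "2 0 0 0", "0 0 1 0", "0 0 0 1"), f)
  expect_error(read_affine(f), "singular")
  writeLines(c("1 0 0", "0 1 0", "0 0 1"), f)
  expect_error(read_affine(f), "16 values")
})

test_that("affine write/read round-trips to 1e-12", {
  set.seed(8)
  m <- diag(4)
  m[1:3, 1:3] <- diag(3) + matrix(stats::rnorm(9, 0, 0.1), 3)
  m[1:3, 4] <- stats::rnorm(3, 0, 20)
  t <- affine_transform(m)
  f <- withr::local_tempfile(fileext = ".txt")
  write_affine(t, f)
  expect_equal(read_affine(f)$matrix, t$matrix, tolerance = 1e-12)
})

test_that("summary CSV round-trips and keeps the tabular contract", {
  co <- simulate_cohort(jitter_only_config(n_subjects = 5, sd = 2,
                                           seed = 21))
  mni <- normalize_cohort(co$points, co$affines)
  s <- summarize_electrodes(mni)
  f <- withr::local_tempfile(fileext = ".csv")
  write_summary_csv(s, f)
  back <- read_summary_csv(f)
  expect_equal(names(back),
               c("electrode", "surface", "n", "mean_x", "mean_y", "mean_z",
                 "sd_x", "sd_y", "sd_z", "skew_x", "skew_y", "skew_z",
                 "overall_deviation"))
  expect_equal(back$electrode, sort(s$electrode))
  ord <- order(s$electrode)
  expect_equal(back$sd_x, s$sd_x[ord], tolerance = 1e-9)
  expect_equal(back$overall_deviation, s$overall_deviation[ord],
               tolerance = 1e-9)
  expect_error(write_summary_csv(s[0, ], f), "no summaries")
})

test_that("tally CSV percentages sum to 100 per electrode", {
  outcomes <- data.frame(
    subject_id = rep(sprintf("s%d", 1:10), 2),
    electrode = rep(c("CZ", "PZ"), each = 10),
    outcome = c(rep("REGION", 10), rep("REGION", 7), rep("TIE", 2), "NONE"),
    region = c(rep("A", 6), rep("B", 4), rep("A", 5), rep("B", 2),
               rep(NA, 3)), stringsAsFactors = FALSE)
  tal <- tally_cohort(outcomes)
  f <- withr::local_tempfile(fileext = ".csv")
  write_tally_csv(tal, f)
  back <- utils::read.csv(f)
  sums <- tapply(back$percent, back$electrode, sum)
  expect_true(all(abs(sums - 100) < 0.01))
})

test_that("manifests round-trip and validate their references", {
  dir <- withr::local_tempdir()
  co <- simulate_cohort(simulation_config(n_subjects = 3, seed = 2))
  mpath <- write_cohort(co, dir, write_masks = FALSE)
  man <- read_manifest(mpath)
  expect_equal(length(man$subjects), 3)
  expect_equal(man$subjects[[1]]$subject_id, "sub-01")
  expect_true(file.exists(man$subjects[[2]]$scalp_targets))
  # a manifest referencing a missing file is rejected
  man2 <- man
  man2$subjects[[1]]$scalp_targets <- "gone.txt"
  p2 <- file.path(dir, "bad.yaml")
  write_manifest(man2, p2)
  expect_error(read_manifest(p2), "missing file")
  # duplicate subject ids are rejected
  man3 <- man
  man3$subjects[[2]]$subject_id <- "sub-01"
  p3 <- file.path(dir, "dup.yaml")
  write_manifest(man3, p3)
  expect_error(read_manifest(p3), "duplicate")
})

test_that("NIfTI volumes round-trip data and affine", {
  h <- sphere_head(scalp_r = 10, brain_r = 6)
  vols <- make_head_volumes(h, c(24, 26, 28), 1)
  f <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(vols$brain_mask, f)
  back <- read_volume(f)
  expect_equal(back$data, vols$brain_mask$data, tolerance = 1e-6)
  expect_equal(back$affine, vols$brain_mask$affine, tolerance = 1e-5)
  # 4-D probabilistic atlas round-trip with a names sidecar
  at <- make_synthetic_prob_atlas(c(12, 12, 12), 2, n_regions = 2,
                                  seed = 1)
  fa <- withr::local_tempfile(fileext = ".nii.gz")
  fn <- withr::local_tempfile(fileext = ".txt")
  write_volume(at, fa)
  writeLines(at$region_names, fn)
  back <- read_volume(fa, fn)
  expect_s3_class(back, "prob_atlas")
  expect_equal(back$data, at$data, tolerance = 1e-6)
  expect_equal(back$region_names, at$region_names)
})
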