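test_that("probabilistic atlas queries use nearest-voxel lookup", {
  at <- make_synthetic_prob_atlas(c(20, 20, 20), 2, n_regions = 2,
                                  seed = 6)
  expect_equal(nrow(query_prob_atlas(at, c(500, 500, 500))), 0)
  # read-back oracle: values written at a constructed voxel come back
  tv <- attr(at, "tie_voxel")
  world <- as.numeric(at$affine[1:3, 1:3] %*% (tv - 1) + at$affine[1:3, 4])
  q <- query_prob_atlas(at, world)
  expect_equal(sort(q$probability), c(50, 50))
  # sub-voxel offsets round to the same voxel
  q2 <- query_prob_atlas(at, world + 0.4 * c(1, -1, 1))
  expect_equal(q2, q)
  expect_error(query_prob_atlas(at, c(NA, 0, 0)), "finite")
})

test_that("max_label implements the highest-probability rule with exclusions", {
  q <- data.frame(region = c("A", "B"), probability = c(80, 20))
  expect_equal(max_label(q), list(outcome = "REGION", region = "A"))
  q <- data.frame(region = c("A", "B"), probability = c(50, 50))
  expect_equal(max_label(q)$outcome, "TIE")
  q <- data.frame(region = character(), probability = numeric())
  expect_equal(max_label(q)$outcome, "NONE")
  # a tie below the maximum does not exclude
  q <- data.frame(region = c("A", "B", "C"), probability = c(60, 20, 20))
  expect_equal(max_label(q), list(outcome = "REGION", region = "A"))
})

test_that("region tallies apply the exclusion arithmetic", {
  mk_outcomes <- function(regions, n_tie, n_none, el = "CZ") {
    data.frame(
      subject_id = sprintf("s%02d", seq_len(length(regions) + n_tie +
                                              n_none)),
      electrode = el,
      outcome = c(rep("REGION", length(regions)), rep("TIE", n_tie),
                  rep("NONE", n_none)),
      region = c(regions, rep(NA, n_tie + n_none)),
      stringsAsFactors = FALSE)
  }
  t <- tally_regions(mk_outcomes(rep("A", 20), 0, 0))
  expect_equal(t$usable_n, 20)
  expect_equal(t$rows$percent, 100)
  # hand computation: 10 A, 5 B, 3 ties, 2 no-label -> usable 15
  t <- tally_regions(mk_outcomes(c(rep("A", 10), rep("B", 5)), 3, 2))
  expect_equal(t$usable_n, 15)
  expect_equal(t$rows$region, c("A", "B"))
  expect_equal(t$rows$percent, c(100 * 10 / 15, 100 * 5 / 15),
               tolerance = 1e-9)
  expect_equal(sum(t$rows$percent), 100, tolerance = 0.01)
  # bookkeeping invariant: usable + ties + nones = observations
  expect_equal(t$usable_n + t$n_tie + t$n_none, 20)
  # all excluded: flagged, empty
  t <- tally_regions(mk_outcomes(character(0), 4, 0))
  expect_equal(t$usable_n, 0)
  expect_true(t$flagged)
  expect_equal(nrow(t$rows), 0)
})

test_that("tally percentages always sum to 100 across random mixes", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(5:25, 1)
    outcome <- sample(c("REGION", "TIE", "NONE"), n, replace = TRUE,
                      prob = c(0.7, 0.15, 0.15))
    df <- data.frame(
      subject_id = sprintf("s%02d", 1:n), electrode = "CZ",
      outcome = outcome,
      region = ifelse(outcome == "REGION",
                      sample(LETTERS[1:4], n, replace = TRUE), NA),
      stringsAsFactors = FALSE)
    t <- tally_regions(df)
    if (t$usable_n > 0)
      expect_equal(sum(t$rows$percent), 100, tolerance = 0.01)
    expect_equal(t$usable_n + t$n_tie + t$n_none, n)
  }
})

test_that("usable-subject counts summarize with mean and n-1 SD", {
  mk <- function(u) structure(list(usable_n = u), class = "region_tally")
  expect_equal(mean_usable(list(mk(20L), mk(20L), mk(20L))),
               c(mean = 20, sd = 0))
  expect_equal(mean_usable(list(mk(15L), mk(17L), mk(19L))),
               c(mean = 17, sd = 2))
  expect_true(is.na(mean_usable(list(mk(12L)))["sd"]))
})

test_that("small-jitter cohorts tally 100% for their true region", {
  at <- hemisphere_z_atlas()
  co <- simulate_cohort(jitter_only_config(n_subjects = 8, sd = 1,
                                           seed = 55))
  mni <- normalize_cohort(co$points, co$affines)
  outcomes <- label_cohort(at, mni)
  tal <- tally_cohort(outcomes)
  montage <- default_montage()
  truth <- ifelse(montage$dz > 0, "Upper", "Lower")
  names(truth) <- montage$electrode
  expect_equal(unique(tal$usable_n), 8)
  for (el in unique(tal$electrode)) {
    rows <- tal[tal$electrode == el, ]
    expect_equal(nrow(rows), 1)
    expect_equal(rows$region, unname(truth[el]))
    expect_equal(rows$percent, 100)
  }
})

test_that("nearest labeled voxel wins within the search radius", {
  vol <- array(0L, dim = c(21, 21, 21))
  vol[8:14, 8:14, 8:14] <- 1L   # blob around the center
  vol[1, 1, 1] <- 2L
  aff <- diag(4); aff[1:3, 4] <- c(-10, -10, -10)  # 1 mm, centered
  at <- labeled_atlas(vol, aff, c("1" = "BA4", "2" = "BA18"))
  expect_equal(nearest_label(at, c(0, 0, 0)), "BA4")
  # 1 mm outside the blob face: brute-force scan over labeled voxels
  p <- c(4.6, 0, 0)
  idx <- which(vol != 0, arr.ind = TRUE)
  centers <- sweep(idx - 1, 2, c(-10, -10, -10), "+")
  d <- sqrt(rowSums(sweep(centers, 2, p, "-")^2))
  expect_equal(nearest_label(at, p),
               c("1" = "BA4", "2" = "BA18")[[as.character(
                 vol[idx[which.min(d), , drop = FALSE]])]])
  # beyond the radius: no label
  expect_true(is.na(nearest_label(at, c(0, 0, 400), max_radius_mm = 10)))
  expect_error(nearest_label(at, c(Inf, 0, 0)), "finite")
  expect_error(labeled_atlas(vol, aff, c("1" = "BA4")), "without a name")
})

test_that("equidistant labels resolve to the smaller label integer", {
  vol <- array(0L, dim = c(5, 5, 5))
  vol[1, 3, 3] <- 7L
  vol[5, 3, 3] <- 3L
  aff <- diag(4); aff[1:3, 4] <- c(-2, -2, -2)
  at <- labeled_atlas(vol, aff, c("7" = "High", "3" = "Low"))
  expect_equal(nearest_label(at, c(0, 0, 0), max_radius_mm = 5), "Low")
})

test_that("hemisphere is reported mechanically from mean x", {
  expect_equal(hemisphere_of(-30), "left")
  expect_equal(hemisphere_of(30), "right")
  expect_equal(hemisphere_of(0.5), "midline")
  expect_equal(hemisphere_of(c(-5, 5, 1)),
               c("left", "right", "midline"))
})
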