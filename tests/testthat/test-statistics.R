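points_for <- function(el, x, y = x, z = x, subj = NULL) {
  n <- length(x)
  if (is.null(subj)) subj <- sprintf("s%02d", seq_len(n))
  electrode_points(subj, rep(el, n), "scalp", "mni", x, y, z)
}

test_that("electrode summaries compute mean, SD and skewness per axis", {
  s <- electrode_summary(points_for("CZ", c(1, 1, 1)))
  expect_equal(as.numeric(s[, c("mean_x", "mean_y", "mean_z")]),
               c(1, 1, 1))
  expect_equal(as.numeric(s[, c("sd_x", "sd_y", "sd_z")]), c(0, 0, 0))
  expect_equal(s$n, 3)
  # hand computation with the n - 1 denominator: {0, 1, 2}
  s <- electrode_summary(points_for("CZ", c(0, 1, 2)))
  expect_equal(s$mean_x, 1)
  expect_equal(s$sd_x, 1)
  expect_equal(s$overall_deviation, 1)
  # symmetric samples have zero skewness
  s <- electrode_summary(points_for("CZ", c(-3, -1, 1, 3)))
  expect_equal(as.numeric(s[, c("skew_x", "skew_y", "skew_z")]),
               c(0, 0, 0))
})

test_that("a single observation yields missing SD and skewness, not zero", {
  s <- electrode_summary(points_for("CZ", 5))
  expect_equal(s$n, 1)
  expect_true(is.na(s$sd_x) && is.na(s$skew_x) &&
                is.na(s$overall_deviation))
})

test_that("skewness estimators agree with an independent implementation", {
  set.seed(12)
  x <- stats::rexp(15)
  s <- electrode_summary(points_for("CZ", x))
  expect_equal(s$skew_x, e1071::skewness(x, type = 1), tolerance = 1e-12)
  s_adj <- electrode_summary(points_for("CZ", x), adjusted_skewness = TRUE)
  expect_equal(s_adj$skew_x, e1071::skewness(x, type = 2),
               tolerance = 1e-12)
})

test_that("grand SD averages per-electrode SDs per axis", {
  two <- rbind(points_for("AA", c(0, 2)), points_for("BB", c(0, 4)))
  g <- grand_sd(summarize_electrodes(two))
  expect_equal(unname(g["x"]), mean(c(stats::sd(c(0, 2)),
                                      stats::sd(c(0, 4)))))
  # constant per-electrode SDs pass through unchanged
  s <- summarize_electrodes(rbind(points_for("AA", c(0, 2)),
                                  points_for("BB", c(10, 12))))
  expect_equal(unname(grand_sd(s)), rep(stats::sd(c(0, 2)), 3))
  # electrodes without an SD are excluded with a warning
  s1 <- summarize_electrodes(rbind(points_for("AA", c(0, 2)),
                                   points_for("CC", 7)))
  expect_warning(g <- grand_sd(s1), "excluded")
  expect_equal(unname(g["x"]), stats::sd(c(0, 2)))
})

test_that("grand SD is invariant under a uniform rigid translation", {
  co <- simulate_cohort(jitter_only_config(n_subjects = 6, sd = 4,
                                           seed = 9))
  mni <- normalize_cohort(co$points, co$affines)
  g1 <- grand_sd(summarize_electrodes(mni))
  shifted <- mni
  shifted[, c("x", "y", "z")] <-
    sweep(as.matrix(mni[, c("x", "y", "z")]), 2, c(13, -7, 40), "+")
  expect_equal(grand_sd(summarize_electrodes(shifted)), g1,
               tolerance = 1e-10)
})

test_that("extreme-electrode ranking orders by overall deviation", {
  pts <- rbind(points_for("AA", c(0, 1)), points_for("BB", c(0, 2)),
               points_for("CC", c(0, 3)), points_for("DD", c(0, 4)))
  s <- summarize_electrodes(pts)
  ex <- rank_extremes(s, 2)
  expect_equal(ex$smallest$electrodes, c("AA", "BB"))
  expect_equal(ex$largest$electrodes, c("CC", "DD"))
  expect_equal(ex$smallest$mean_overall_deviation,
               mean(s$overall_deviation[s$electrode %in% c("AA", "BB")]))
  # k = all electrodes: both means equal the overall mean
  ex_all <- rank_extremes(s, 4)
  expect_equal(ex_all$smallest$mean_overall_deviation,
               mean(s$overall_deviation))
  expect_equal(ex_all$largest$mean_overall_deviation,
               mean(s$overall_deviation))
  # extremes bracket the overall mean
  expect_lte(ex$smallest$mean_overall_deviation,
             mean(s$overall_deviation))
  expect_gte(ex$largest$mean_overall_deviation,
             mean(s$overall_deviation))
  expect_error(rank_extremes(s, 0), "positive")
  expect_error(rank_extremes(s, 9), "exceeds")
})

test_that("deviation ties in the ranking break alphabetically", {
  pts <- rbind(points_for("BB", c(0, 2)), points_for("AA", c(0, 2)),
               points_for("CC", c(0, 2)))
  ex <- rank_extremes(summarize_electrodes(pts), 2)
  # alphabetical tie-break applies to both sets
  expect_equal(ex$smallest$electrodes, c("AA", "BB"))
  expect_equal(ex$largest$electrodes, c("AA", "BB"))
})

test_that("cap-size grouping recomputes SDs within each subgroup", {
  # two groups with different jitter scales must recover the ordering
  mk <- function(ids, sd, seed) {
    set.seed(seed)
    n <- length(ids)
    rbind(points_for("AA", stats::rnorm(n, 0, sd), stats::rnorm(n, 0, sd),
                     stats::rnorm(n, 0, sd), subj = ids),
          points_for("BB", stats::rnorm(n, 5, sd), stats::rnorm(n, 5, sd),
                     stats::rnorm(n, 5, sd), subj = ids))
  }
  small <- sprintf("a%d", 1:8); large <- sprintf("b%d", 1:8)
  pts <- rbind(mk(small, 3, 1), mk(large, 6, 2))
  caps <- c(stats::setNames(rep(54, 8), small),
            stats::setNames(rep(58, 8), large))
  g <- group_by_cap_size(pts, caps)
  expect_equal(g$cap_size, c("54", "58", "All"))
  expect_equal(g$n_subjects, c(8, 8, 16))
  expect_lt(g$grand_sd_x[g$cap_size == "54"],
            g$grand_sd_x[g$cap_size == "58"])
})

test_that("cap-size bookkeeping handles missing and singleton groups", {
  ids <- sprintf("s%d", 1:5)
  set.seed(3)
  pts <- points_for("AA", stats::rnorm(5), subj = ids)
  caps <- stats::setNames(c(54, 54, 56, 56, NA), ids)
  g <- group_by_cap_size(pts, caps)
  # the unrecorded-cap subject appears only in the All row
  expect_equal(g$n_subjects[g$cap_size == "All"],
               sum(g$n_subjects[g$cap_size != "All"]) + 1)
  # a single-subject group reports missing SDs
  caps2 <- stats::setNames(c(54, 56, 56, 56, 56), ids)
  g2 <- group_by_cap_size(pts, caps2)
  expect_true(is.na(g2$grand_sd_x[g2$cap_size == "54"]))
  # identical cap sizes: group row equals the All row
  caps3 <- stats::setNames(rep(56, 5), ids)
  g3 <- group_by_cap_size(pts, caps3)
  expect_equal(g3$grand_sd_x[1], g3$grand_sd_x[2])
})
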