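#' Cross-subject summary of one electrode's positions
#'
#' Per-axis arithmetic mean, sample standard deviation (n - 1
#' denominator), and skewness of one electrode's coordinates across the
#' subjects contributing it, plus the overall deviation (the mean of the
#' three per-axis SDs). Skewness is the plain Fisher-Pearson coefficient
#' g1 = m3 / m2^(3/2) by default, with the bias-adjusted version
#' G1 = g1 * sqrt(n(n-1)) / (n-2) available. With a single contributing
#' subject, SD and skewness are `NA` (not zero); a degenerate sample with
#' zero variance has skewness 0.
#'
#' @param points Electrode points for one electrode on one surface.
#' @param adjusted_skewness Use the bias-adjusted skewness estimator.
#' @return One-row data.frame: `electrode`, `surface`, `n`,
#'   `mean_x/y/z`, `sd_x/y/z`, `skew_x/y/z`, `overall_deviation`.
#' @export
electrode_summary <- function(points, adjusted_skewness = FALSE) {
  points <- validate_points(points)
  if (nrow(points) == 0) stop("no points for electrode", call. = FALSE)
  if (length(unique(points$electrode)) != 1 ||
      length(unique(points$surface)) != 1)
    stop("electrode_summary expects a single electrode and surface",
         call. = FALSE)
  xyz <- base::as.matrix(points[, c("x", "y", "z")])
  n <- nrow(xyz)
  mu <- colMeans(xyz)
  if (n >= 2) {
    sdv <- apply(xyz, 2, stats::sd)
    skw <- apply(xyz, 2, skewness_g1, adjusted = adjusted_skewness)
  } else {
    sdv <- rep(NA_real_, 3); skw <- rep(NA_real_, 3)
  }
  data.frame(electrode = points$electrode[1], surface = points$surface[1],
             n = n, mean_x = mu[1], mean_y = mu[2], mean_z = mu[3],
             sd_x = sdv[1], sd_y = sdv[2], sd_z = sdv[3],
             skew_x = skw[1], skew_y = skw[2], skew_z = skw[3],
             overall_deviation = mean(sdv), stringsAsFactors = FALSE,
             row.names = NULL)
}

# Fisher-Pearson skewness; adjusted = TRUE applies the small-sample
# bias correction sqrt(n(n-1))/(n-2) (needs n >= 3).
skewness_g1 <- function(x, adjusted = FALSE) {
  n <- length(x)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) return(0)  # degenerate sample: symmetric by convention
  g1 <- mean((x - m)^3) / m2^1.5
  if (adjusted) {
    if (n < 3) return(NA_real_)
    g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  }
  g1
}

#' Summarize every electrode of a cohort
#'
#' Applies [electrode_summary()] per (electrode, surface); subjects
#' missing an electrode are simply excluded and `n` records the count
#' actually used.
#'
#' @param points Electrode points (normally MNI space).
#' @param surface Optional filter: `"scalp"` or `"cortex"`.
#' @param adjusted_skewness Passed to [electrode_summary()].
#' @return A data.frame of per-electrode summaries, sorted by electrode.
#' @export
summarize_electrodes <- function(points, surface = NULL,
                                 adjusted_skewness = FALSE) {
  points <- validate_points(points)
  if (!is.null(surface)) points <- points[points$surface == surface, ]
  if (nrow(points) == 0) stop("no points to summarize", call. = FALSE)
  keys <- unique(points[, c("electrode", "surface")])
  keys <- keys[order(keys$electrode, keys$surface), , drop = FALSE]
  out <- lapply(seq_len(nrow(keys)), function(i)
    electrode_summary(points[points$electrode == keys$electrode[i] &
                               points$surface == keys$surface[i], ],
                      adjusted_skewness = adjusted_skewness))
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Grand standard deviation across electrodes
#'
#' The unweighted mean, over electrodes, of the per-electrode per-axis
#' sample SDs: the "mean standard deviation" of a cohort per axis.
#' Summaries with missing SD (n < 2) are excluded with a warning.
#'
#' @param summaries Electrode summaries ([summarize_electrodes()]).
#' @return Named numeric 3-vector `c(x = , y = , z = )` in mm.
#' @export
grand_sd <- function(summaries) {
  if (nrow(summaries) == 0) stop("no summaries", call. = FALSE)
  ok <- !is.na(summaries$sd_x) & !is.na(summaries$sd_y) &
    !is.na(summaries$sd_z)
  if (any(!ok))
    warning(sum(!ok), " electrode(s) without SD excluded from grand SD")
  if (!any(ok)) stop("no summaries with defined SD", call. = FALSE)
  c(x = mean(summaries$sd_x[ok]), y = mean(summaries$sd_y[ok]),
    z = mean(summaries$sd_z[ok]))
}

#' Electrodes with the smallest and largest overall deviation
#'
#' Ranks electrodes by overall deviation (mean of the three per-axis SDs)
#' and reports the k most stable and k most variable electrodes along
#' with the mean overall deviation of each set. Ties are broken
#' alphabetically by label.
#'
#' @param summaries Electrode summaries.
#' @param k Size of each extreme set (1 <= k <= number of electrodes).
#' @return A list with `smallest` and `largest`, each holding
#'   `electrodes` (character, sorted alphabetically) and
#'   `mean_overall_deviation` (mm).
#' @export
rank_extremes <- function(summaries, k = 5L) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  ok <- !is.na(summaries$overall_deviation)
  s <- summaries[ok, ]
  if (k > nrow(s))
    stop("k exceeds the number of ranked electrodes", call. = FALSE)
  ord <- order(s$overall_deviation, s$electrode)
  take <- function(idx) list(
    electrodes = sort(s$electrode[idx]),
    mean_overall_deviation = mean(s$overall_deviation[idx]))
  ord_desc <- order(-s$overall_deviation, s$electrode)
  list(smallest = take(ord[seq_len(k)]),
       largest = take(ord_desc[seq_len(k)]))
}

#' Grand SDs grouped by cap size
#'
#' Recomputes per-electrode SDs within each cap-size subgroup and
#' averages them over electrodes, reproducing the cap-size breakdown of
#' cohort variability. Subjects with unrecorded cap size contribute only
#' to the `"All"` row. Groups with a single subject are reported with
#' missing SDs.
#'
#' @param points MNI electrode points for one surface.
#' @param cap_sizes Named numeric vector: cap size (cm) per subject id,
#'   `NA` = unrecorded.
#' @return A data.frame: `cap_size` (character, including `"All"`),
#'   `n_subjects`, `grand_sd_x/y/z`.
#' @export
group_by_cap_size <- function(points, cap_sizes) {
  points <- validate_points(points)
  if (length(unique(points$surface)) > 1)
    stop("group_by_cap_size expects a single surface", call. = FALSE)
  subj <- unique(points$subject_id)
  missing_cap <- setdiff(subj, names(cap_sizes))
  if (length(missing_cap) > 0)
    stop("no cap size entry for subject(s): ",
         paste(missing_cap, collapse = ", "), call. = FALSE)
  sizes <- sort(unique(cap_sizes[subj][!is.na(cap_sizes[subj])]))
  one_group <- function(ids, label) {
    gp <- points[points$subject_id %in% ids, ]
    gs <- if (length(ids) >= 2) {
      suppressWarnings(grand_sd(summarize_electrodes(gp)))
    } else c(x = NA_real_, y = NA_real_, z = NA_real_)
    data.frame(cap_size = label, n_subjects = length(ids),
               grand_sd_x = gs[["x"]], grand_sd_y = gs[["y"]],
               grand_sd_z = gs[["z"]], stringsAsFactors = FALSE)
  }
  rows <- lapply(sizes, function(cs)
    one_group(subj[!is.na(cap_sizes[subj]) & cap_sizes[subj] == cs],
              as.character(cs)))
  rows <- c(rows, list(one_group(subj, "All")))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Expected sample SD shrinkage factor c4(n)
#'
#' For iid Gaussian data, the sample SD with the n - 1 denominator has
#' expectation c4(n) * sigma with
#' c4(n) = sqrt(2 / (n - 1)) * gamma(n / 2) / gamma((n - 1) / 2).
#' Used to benchmark parameter recovery on simulated cohorts.
#'
#' @param n Sample size (>= 2).
#' @return The unbiasing constant c4(n).
#' @export
c4_constant <- function(n) {
  stopifnot(n >= 2)
  sqrt(2 / (n - 1)) * exp(lgamma(n / 2) - lgamma((n - 1) / 2))
}
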