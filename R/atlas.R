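#' Query a probabilistic atlas at an MNI coordinate
#'
#' Maps the world coordinate to a voxel through the inverse of the
#' atlas's voxel-to-world affine with nearest-voxel rounding (the
#' single-coordinate behavior of atlas query tools; probabilities are not
#' interpolated), then returns every region with probability > 0 at that
#' voxel, in descending probability order. A point outside the grid, or a
#' background (all-zero) voxel, yields an empty result.
#'
#' @param atlas A `prob_atlas` (see [make_synthetic_prob_atlas()] /
#'   [read_volume()]).
#' @param point MNI coordinate (mm), finite length-3.
#' @return Data.frame with columns `region`, `probability`, possibly
#'   0 rows.
#' @export
query_prob_atlas <- function(atlas, point) {
  stopifnot(inherits(atlas, "prob_atlas"))
  p <- as.numeric(point)
  if (length(p) != 3 || any(!is.finite(p)))
    stop("point must be a finite 3-vector", call. = FALSE)
  shape <- dim(atlas$data)[1:3]
  vox <- round(world_to_voxel(p, atlas$affine))
  empty <- data.frame(region = character(), probability = numeric(),
                      stringsAsFactors = FALSE)
  if (any(vox < 0) || any(vox > shape - 1)) return(empty)
  probs <- atlas$data[vox[1] + 1, vox[2] + 1, vox[3] + 1, ]
  keep <- which(probs > 0)
  if (length(keep) == 0) return(empty)
  out <- data.frame(region = atlas$region_names[keep],
                    probability = probs[keep], stringsAsFactors = FALSE)
  out[order(-out$probability, out$region), , drop = FALSE]
}

#' Highest-probability label with tie and no-label outcomes
#'
#' Applies the labeling rule used for per-subject electrode regions: the
#' region with the strictly highest probability wins; if two or more
#' regions share the maximum (exact equality at the atlas's stored
#' precision) the outcome is `TIE`; an empty query (no label available)
#' is `NONE`. `TIE` and `NONE` observations are excluded from region
#' percentage tallies.
#'
#' @param query Result of [query_prob_atlas()].
#' @return A list: `outcome` (`"REGION"`, `"TIE"` or `"NONE"`) and
#'   `region` (the winning region name, or `NA`).
#' @export
max_label <- function(query) {
  if (nrow(query) == 0)
    return(list(outcome = "NONE", region = NA_character_))
  top <- max(query$probability)
  winners <- query$region[query$probability == top]
  if (length(winners) > 1)
    return(list(outcome = "TIE", region = NA_character_))
  list(outcome = "REGION", region = winners[1])
}

#' Label every electrode observation of a cohort
#'
#' Runs [query_prob_atlas()] + [max_label()] for each (subject,
#' electrode) point.
#'
#' @param atlas A `prob_atlas`.
#' @param points MNI electrode points (one surface).
#' @return Data.frame: `subject_id`, `electrode`, `outcome`, `region`.
#' @export
label_cohort <- function(atlas, points) {
  points <- validate_points(points)
  if (nrow(points) == 0) stop("no points to label", call. = FALSE)
  res <- lapply(seq_len(nrow(points)), function(i)
    max_label(query_prob_atlas(atlas,
                               as.numeric(points[i, c("x", "y", "z")]))))
  data.frame(subject_id = points$subject_id, electrode = points$electrode,
             outcome = vapply(res, `[[`, "", "outcome"),
             region = vapply(res, `[[`, "", "region"),
             stringsAsFactors = FALSE)
}

#' Tally one electrode's region outcomes as percentages
#'
#' Percentage breakdown of labeled regions across subjects for one
#' electrode: `usable_n` counts the `REGION` outcomes (ties and no-label
#' observations are excluded), and each region's percentage is
#' 100 * count / usable_n. With no usable subjects the tally is empty and
#' flagged.
#'
#' @param outcomes Data.frame of label outcomes for one electrode
#'   (columns `outcome`, `region`, see [label_cohort()]).
#' @return A list of class `region_tally`: `electrode`, `usable_n`,
#'   `n_tie`, `n_none`, `rows` (data.frame `region`, `percent`, sorted by
#'   descending percent then name), `flagged` (TRUE when usable_n = 0).
#' @export
tally_regions <- function(outcomes) {
  if (nrow(outcomes) == 0) stop("no outcomes to tally", call. = FALSE)
  electrode <- if ("electrode" %in% names(outcomes))
    outcomes$electrode[1] else NA_character_
  usable <- outcomes[outcomes$outcome == "REGION", ]
  usable_n <- nrow(usable)
  rows <- if (usable_n > 0) {
    counts <- table(usable$region)
    df <- data.frame(region = names(counts),
                     percent = 100 * as.numeric(counts) / usable_n,
                     stringsAsFactors = FALSE)
    df[order(-df$percent, df$region), , drop = FALSE]
  } else data.frame(region = character(), percent = numeric(),
                    stringsAsFactors = FALSE)
  structure(list(electrode = electrode, usable_n = usable_n,
                 n_tie = sum(outcomes$outcome == "TIE"),
                 n_none = sum(outcomes$outcome == "NONE"),
                 rows = rows, flagged = usable_n == 0),
            class = "region_tally")
}

#' Tally all electrodes of a cohort
#'
#' @param outcomes Data.frame from [label_cohort()].
#' @return Long-format data.frame: `electrode`, `usable_n`, `region`,
#'   `percent` (electrodes with usable_n = 0 appear with an `NA` region
#'   row). Attribute `tallies` holds the per-electrode `region_tally`
#'   objects.
#' @export
tally_cohort <- function(outcomes) {
  tallies <- lapply(split(outcomes, outcomes$electrode), tally_regions)
  rows <- lapply(tallies, function(t) {
    if (t$usable_n == 0)
      return(data.frame(electrode = t$electrode, usable_n = 0L,
                        region = NA_character_, percent = NA_real_,
                        stringsAsFactors = FALSE))
    data.frame(electrode = t$electrode, usable_n = t$usable_n,
               region = t$rows$region, percent = t$rows$percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  attr(out, "tallies") <- tallies
  out
}

#' Mean and SD of usable-subject counts across electrodes
#'
#' @param tallies Output of [tally_cohort()], or a list of
#'   `region_tally` objects.
#' @return Named vector `c(mean = , sd = )` of `usable_n` across
#'   electrodes (SD with n - 1 denominator, `NA` for a single electrode).
#' @export
mean_usable <- function(tallies) {
  usable <- if (is.data.frame(tallies)) {
    u <- unique(tallies[, c("electrode", "usable_n")]); u$usable_n
  } else vapply(tallies, `[[`, 0L, "usable_n")
  c(mean = mean(usable),
    sd = if (length(usable) >= 2) stats::sd(usable) else NA_real_)
}

#' Nearest label in a deterministic atlas
#'
#' Looks up the label at an MNI coordinate in a labeled (e.g.
#' Brodmann-area) atlas. If the point's voxel is labeled that label is
#' returned; otherwise the label of the nearest labeled voxel center
#' within `max_radius_mm` (distance ties broken by the smaller label
#' integer). Beyond the radius the lookup reports no label - e.g. for
#' electrodes whose mean position sits over cerebellum in a
#' cortex-only parcellation.
#'
#' @param atlas A [labeled_atlas()].
#' @param point MNI coordinate (mm), finite.
#' @param max_radius_mm Search radius, default 10 mm.
#' @return The label name, or `NA_character_` when nothing is within
#'   reach.
#' @export
nearest_label <- function(atlas, point, max_radius_mm = 10) {
  stopifnot(inherits(atlas, "labeled_atlas"))
  p <- as.numeric(point)
  if (length(p) != 3 || any(!is.finite(p)))
    stop("point must be a finite 3-vector", call. = FALSE)
  shape <- dim(atlas$data)
  vox <- round(world_to_voxel(p, atlas$affine))
  if (all(vox >= 0) && all(vox <= shape - 1)) {
    val <- atlas$data[vox[1] + 1, vox[2] + 1, vox[3] + 1]
    if (val != 0) return(atlas$label_names[[as.character(val)]])
  }
  lab_idx <- which(atlas$data != 0, arr.ind = TRUE)
  if (nrow(lab_idx) == 0) return(NA_character_)
  centers <- sweep((lab_idx - 1) %*% t(atlas$affine[1:3, 1:3]), 2,
                   atlas$affine[1:3, 4], "+")
  d <- sqrt(rowSums(sweep(centers, 2, p, "-")^2))
  within <- d <= max_radius_mm
  if (!any(within)) return(NA_character_)
  vals <- atlas$data[lab_idx[within, , drop = FALSE]]
  dw <- d[within]
  best <- which(dw == min(dw))
  if (length(best) > 1) best <- best[which.min(vals[best])]
  atlas$label_names[[as.character(vals[best])]]
}

#' Hemisphere of a mean MNI x-coordinate
#'
#' Mechanical left/right report from the sign of x (negative = left),
#' with positions within 2 mm of the midsagittal plane flagged
#' `"midline"` rather than assigned a side.
#'
#' @param x Mean MNI x in mm.
#' @param midline_mm Half-width of the midline band, default 2 mm.
#' @return `"left"`, `"right"` or `"midline"`.
#' @export
hemisphere_of <- function(x, midline_mm = 2) {
  ifelse(abs(x) < midline_mm, "midline", ifelse(x < 0, "left", "right"))
}
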