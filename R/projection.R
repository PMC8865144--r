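#' Parameters of the scalp-to-cortex projection
#'
#' Mirrors the parameter set of neuro-navigation curvilinear ("peeled")
#' brain reconstructions. `peel_depth_mm` controls the metric erosion of
#' the brain mask before its surface is extracted; `slice_spacing_mm` and
#' `end_depth_mm` are accepted for interface fidelity with those tools but
#' do not alter the geometry of the nearest-point projection used here.
#' `max_search_mm` bounds the scalp-to-surface distance beyond which an
#' electrode is flagged unprojectable.
#'
#' @param slice_spacing_mm,end_depth_mm,peel_depth_mm,max_search_mm
#'   Non-negative scalars, defaults 2 / 16 / 0 / 50 mm.
#' @return An object of class `projection_params`.
#' @export
projection_params <- function(slice_spacing_mm = 2, end_depth_mm = 16,
                              peel_depth_mm = 0, max_search_mm = 50) {
  v <- c(slice_spacing_mm, end_depth_mm, peel_depth_mm, max_search_mm)
  if (any(v < 0) || any(!is.finite(v)))
    stop("projection parameters must be non-negative", call. = FALSE)
  structure(list(slice_spacing_mm = slice_spacing_mm,
                 end_depth_mm = end_depth_mm,
                 peel_depth_mm = peel_depth_mm,
                 max_search_mm = max_search_mm),
            class = "projection_params")
}

# Shift a logical 3-D array by integer voxel offsets; out-of-grid = FALSE.
shift_mask <- function(mask, off) {
  d <- dim(mask)
  out <- array(FALSE, d)
  src_from <- pmax(1, 1 + off); src_to <- pmin(d, d + off)
  if (any(src_from > src_to)) return(out)
  dst_from <- pmax(1, 1 - off); dst_to <- pmin(d, d - off)
  out[dst_from[1]:dst_to[1], dst_from[2]:dst_to[2],
      dst_from[3]:dst_to[3]] <-
    mask[src_from[1]:src_to[1], src_from[2]:src_to[2],
         src_from[3]:src_to[3]]
  out
}

# Metric erosion by a ball of radius r mm: a voxel survives iff every
# voxel within r (by voxel-center distance) is inside the mask; the grid
# border counts as background.
erode_metric <- function(mask, radius_mm, voxel_size) {
  if (radius_mm <= 0) return(mask)
  nv <- ceiling(radius_mm / voxel_size)
  offs <- expand.grid(i = -nv[1]:nv[1], j = -nv[2]:nv[2], k = -nv[3]:nv[3])
  dist <- sqrt((offs$i * voxel_size[1])^2 + (offs$j * voxel_size[2])^2 +
                 (offs$k * voxel_size[3])^2)
  offs <- offs[dist <= radius_mm & dist > 0, , drop = FALSE]
  out <- mask
  for (r in seq_len(nrow(offs))) {
    out <- out & shift_mask(mask, as.integer(offs[r, ]))
    if (!any(out)) break
  }
  out
}

# Outer boundary: mask voxels with >= 1 background face-neighbor (grid
# border counts as background).
boundary_mask <- function(mask) {
  interior <- mask
  for (off in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                   c(0, 0, 1), c(0, 0, -1)))
    interior <- interior & shift_mask(mask, off)
  mask & !interior
}

#' Extract a peeled brain surface as a point cloud
#'
#' Erodes the binary brain mask by `peel_depth_mm` (metric erosion with a
#' spherical structuring element on voxel-center distances) and returns
#' the world coordinates of the eroded mask's outer boundary voxels (mask
#' voxels with at least one background face-neighbor). With peel depth 0
#' the boundary of the original mask is returned, i.e. the curvilinear
#' surface at depth 0.
#'
#' @param brain_mask A binary [volume_grid()].
#' @param peel_depth_mm Non-negative peel depth in mm.
#' @return An n x 3 matrix of surface point world coordinates (mm).
#' @export
peel_surface <- function(brain_mask, peel_depth_mm = 0) {
  stopifnot(inherits(brain_mask, "volume_grid"))
  mask <- brain_mask$data > 0.5
  if (!any(mask)) stop("brain mask is empty", call. = FALSE)
  eroded <- erode_metric(mask, peel_depth_mm, brain_mask$voxel_size)
  if (!any(eroded))
    stop(sprintf("peel depth %.1f mm erodes the mask to nothing",
                 peel_depth_mm), call. = FALSE)
  surf <- boundary_mask(eroded)
  idx <- which(surf, arr.ind = TRUE) - 1  # 0-based voxel indices
  pts <- sweep(idx %*% t(brain_mask$affine[1:3, 1:3]), 2,
               brain_mask$affine[1:3, 4], "+")
  colnames(pts) <- c("x", "y", "z")
  pts
}

#' Snap a scalp point to the nearest surface point
#'
#' Deterministic replacement for proprietary "snap to" projection: returns
#' the surface point with the smallest Euclidean distance to the scalp
#' point. Exact distance ties are broken by the smallest x, then y, then
#' z. If the nearest distance exceeds `max_search_mm` the electrode is
#' unprojectable and `NA`s are returned (with attribute
#' `unprojectable = TRUE`).
#'
#' @param point Length-3 world coordinate (mm).
#' @param surface n x 3 surface point cloud from [peel_surface()].
#' @param params A [projection_params()].
#' @return Length-3 coordinate of the snapped point (or `NA`s).
#' @export
snap_to_cortex <- function(point, surface, params = projection_params()) {
  if (is.null(dim(surface)) || nrow(surface) == 0)
    stop("surface point cloud is empty", call. = FALSE)
  p <- as.numeric(point)
  d2 <- (surface[, 1] - p[1])^2 + (surface[, 2] - p[2])^2 +
    (surface[, 3] - p[3])^2
  m <- min(d2)
  if (sqrt(m) > params$max_search_mm)
    return(structure(c(NA_real_, NA_real_, NA_real_),
                     unprojectable = TRUE))
  cand <- which(d2 == m)
  if (length(cand) > 1)
    cand <- cand[order(surface[cand, 1], surface[cand, 2],
                       surface[cand, 3])[1]]
  as.numeric(surface[cand, ])
}

#' Project a cohort's scalp electrodes onto each subject's cortex
#'
#' For every subject, peels that subject's brain mask and snaps each of
#' the subject's scalp points to the peeled surface. Unprojectable
#' electrodes (beyond `max_search_mm`) are dropped from the output and
#' reported in the `unprojectable` attribute.
#'
#' @param points Scalp electrode points (subject space).
#' @param brain_masks Named list (by subject id) of binary
#'   [volume_grid()]s, or paths to NIfTI mask files.
#' @param params A [projection_params()].
#' @return Cortex electrode points (same space as input,
#'   `surface = "cortex"`); attribute `unprojectable` is a data.frame of
#'   dropped (subject_id, electrode).
#' @export
project_cohort <- function(points, brain_masks,
                           params = projection_params()) {
  points <- validate_points(points)
  stopifnot(all(points$surface == "scalp"))
  out <- list(); dropped <- list()
  for (sid in unique(points$subject_id)) {
    mask <- brain_masks[[sid]]
    if (is.null(mask))
      stop("no brain mask for subject ", sid, call. = FALSE)
    if (is.character(mask)) mask <- read_volume(mask)
    surface <- peel_surface(mask, params$peel_depth_mm)
    sub <- points[points$subject_id == sid, ]
    snapped <- t(vapply(seq_len(nrow(sub)), function(i)
      snap_to_cortex(as.numeric(sub[i, c("x", "y", "z")]), surface, params),
      numeric(3)))
    ok <- !is.na(snapped[, 1])
    if (any(!ok))
      dropped[[sid]] <- data.frame(subject_id = sid,
                                   electrode = sub$electrode[!ok],
                                   stringsAsFactors = FALSE)
    res <- sub[ok, ]
    res[, c("x", "y", "z")] <- snapped[ok, , drop = FALSE]
    res$surface <- "cortex"
    out[[sid]] <- res
  }
  result <- do.call(rbind, c(out, make.row.names = FALSE))
  attr(result, "unprojectable") <-
    if (length(dropped) > 0)
      do.call(rbind, c(dropped, make.row.names = FALSE))
    else data.frame(subject_id = character(), electrode = character())
  result
}
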