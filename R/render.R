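#' The conventional MNI152 template grid
#'
#' An empty [volume_grid()] with the standard MNI152 bounding box
#' (91 x 109 x 91 voxels at 2 mm by default) and the conventional
#' voxel-to-world affine placing the anterior commissure at world
#' (0, 0, 0), suitable for overlaying rendered electrode maps on an MNI
#' template in standard viewers.
#'
#' @param voxel_size_mm Isotropic voxel size, default 2 mm.
#' @return A [volume_grid()] of zeros.
#' @export
mni_template_grid <- function(voxel_size_mm = 2) {
  shape <- as.integer(round(c(182, 218, 182) / voxel_size_mm))
  if (voxel_size_mm == 2) shape <- c(91L, 109L, 91L)
  aff <- make_affine_matrix(
    diag(c(-voxel_size_mm, voxel_size_mm, voxel_size_mm)),
    c(90, -126, -72))
  volume_grid(array(0, dim = shape), aff)
}

#' Render electrode points into a volume
#'
#' Sets each point's nearest voxel to 1, accumulating counts where points
#' collide in one voxel. Points falling outside the grid are skipped with
#' a warning.
#'
#' @param points Electrode points (MNI space for an MNI grid).
#' @param grid Template [volume_grid()], default [mni_template_grid()].
#' @return A [volume_grid()] of point counts.
#' @export
render_points <- function(points, grid = mni_template_grid()) {
  points <- validate_points(points)
  stopifnot(inherits(grid, "volume_grid"))
  shape <- dim(grid$data)
  data <- array(0, dim = shape)
  skipped <- 0L
  for (i in seq_len(nrow(points))) {
    vox <- round(world_to_voxel(as.numeric(points[i, c("x", "y", "z")]),
                                grid$affine))
    if (any(vox < 0) || any(vox > shape - 1)) {
      skipped <- skipped + 1L
      next
    }
    data[vox[1] + 1, vox[2] + 1, vox[3] + 1] <-
      data[vox[1] + 1, vox[2] + 1, vox[3] + 1] + 1
  }
  if (skipped > 0)
    warning(skipped, " point(s) outside the grid were skipped")
  volume_grid(data, grid$affine)
}

#' Render electrode summaries as intensity-coded spheres
#'
#' Convolves each electrode's mean coordinate with a sphere: every voxel
#' whose center lies within `radius_mm` of the mean (Euclidean, the shared
#' voxel-center inclusion rule) is set to the electrode's overall
#' deviation - so color encodes positional variability - or to 1 with
#' `intensity = "constant"`. Overlapping spheres resolve to the maximum.
#'
#' @param summaries Electrode summaries ([summarize_electrodes()]).
#' @param radius_mm Sphere radius, default 4 mm.
#' @param intensity `"overall_sd"` (default) or `"constant"`.
#' @param grid Template [volume_grid()], default [mni_template_grid()].
#' @return A [volume_grid()].
#' @export
render_sphere_map <- function(summaries, radius_mm = 4,
                              intensity = c("overall_sd", "constant"),
                              grid = mni_template_grid()) {
  intensity <- match.arg(intensity)
  if (radius_mm <= 0) stop("radius_mm must be positive", call. = FALSE)
  stopifnot(inherits(grid, "volume_grid"))
  shape <- dim(grid$data)
  data <- array(0, dim = shape)
  inv <- solve(grid$affine)
  for (i in seq_len(nrow(summaries))) {
    center <- as.numeric(summaries[i, c("mean_x", "mean_y", "mean_z")])
    value <- if (intensity == "constant") 1 else
      summaries$overall_deviation[i]
    if (is.na(value)) next
    cv <- world_to_voxel(center, grid$affine)
    half <- ceiling(radius_mm / grid$voxel_size) + 1
    lo <- pmax(0, floor(cv - half)); hi <- pmin(shape - 1, ceiling(cv + half))
    if (any(lo > hi)) next
    idx <- base::as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2],
                                       k = lo[3]:hi[3]))
    wc <- sweep(idx %*% t(grid$affine[1:3, 1:3]), 2, grid$affine[1:3, 4],
                "+")
    inside <- rowSums(sweep(wc, 2, center, "-")^2) <= radius_mm^2
    sel <- idx[inside, , drop = FALSE] + 1
    data[sel] <- pmax(data[sel], value)
  }
  volume_grid(data, grid$affine)
}
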