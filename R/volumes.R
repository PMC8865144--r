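#' A 3-D scalar lattice with a voxel-to-world affine
#'
#' Thin container pairing a 3-D array with the 4x4 affine mapping 0-based
#' voxel indices to world (RAS+ mm) coordinates, as in the NIfTI-1
#' convention.
#'
#' @param data 3-D numeric/logical array.
#' @param affine 4x4 voxel-to-world matrix (0-based indices).
#' @return An object of class `volume_grid` with fields `data`, `affine`,
#'   `voxel_size` (mm, per axis).
#' @export
volume_grid <- function(data, affine) {
  if (length(dim(data)) != 3 || any(dim(data) <= 0))
    stop("data must be a 3-D array with positive extents", call. = FALSE)
  aff <- affine_transform(affine, from = "voxel", to = "world")$matrix
  structure(list(data = data, affine = aff,
                 voxel_size = sqrt(colSums(aff[1:3, 1:3]^2))),
            class = "volume_grid")
}

# Grid helpers ---------------------------------------------------------

# Default affine: axis-aligned voxels centered on `center`.
centered_grid_affine <- function(shape, voxel_size, center = c(0, 0, 0)) {
  origin <- center - voxel_size * (shape - 1) / 2
  make_affine_matrix(diag(voxel_size, 3), origin)
}

# World coordinates of all voxel centers, n x 3 (voxel index order =
# column-major array order).
voxel_centers <- function(shape, affine) {
  idx <- base::as.matrix(expand.grid(i = 0:(shape[1] - 1),
                                     j = 0:(shape[2] - 1),
                                     k = 0:(shape[3] - 1)))
  sweep(idx %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

# World -> 0-based voxel index (continuous).
world_to_voxel <- function(points, affine) {
  inv <- solve(affine)
  single <- is.null(dim(points))
  p <- if (single) base::matrix(points, nrow = 1) else base::as.matrix(points)
  out <- sweep(p %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
  if (single) as.numeric(out) else out
}

in_grid <- function(vox, shape) {
  all(vox >= -0.5 & vox < rep(shape, each = NROW(vox)) - 0.5)
}

#' Voxelize a head model into scalp and brain masks
#'
#' Produces binary masks of the head's scalp and brain ellipsoids on a
#' common grid: a voxel is set when its center lies inside the ellipsoid
#' (the single geometry predicate shared with the sphere renderer). The
#' brain mask is a strict subset of the scalp mask.
#'
#' @param head A [head_model()].
#' @param grid_shape Integer 3-vector of voxel counts.
#' @param voxel_size_mm Numeric 3-vector (or scalar), mm.
#' @param center Grid center in world mm; default the head center.
#' @return List with `scalp_mask` and `brain_mask`, both [volume_grid()]s
#'   (0/1 data).
#' @export
make_head_volumes <- function(head, grid_shape, voxel_size_mm,
                              center = head$center) {
  stopifnot(inherits(head, "head_model"))
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape <= 0))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  aff <- centered_grid_affine(grid_shape, voxel_size_mm, center)
  lo <- aff[1:3, 4] - voxel_size_mm / 2
  hi <- aff[1:3, 4] + voxel_size_mm * (grid_shape - 0.5)
  if (any(head$center - head$scalp_semiaxes < lo) ||
      any(head$center + head$scalp_semiaxes > hi))
    stop("scalp ellipsoid exceeds the grid extent", call. = FALSE)
  centers <- voxel_centers(grid_shape, aff)
  rel <- sweep(centers, 2, head$center, "-")
  inside <- function(semiaxes)
    rowSums(sweep(rel, 2, semiaxes, "/")^2) <= 1
  scalp <- array(as.numeric(inside(head$scalp_semiaxes)), dim = grid_shape)
  brain <- array(as.numeric(inside(head$brain_semiaxes)), dim = grid_shape)
  list(scalp_mask = volume_grid(scalp, aff),
       brain_mask = volume_grid(brain, aff))
}

#' Build a synthetic probabilistic atlas
#'
#' Test double for a probabilistic cortical atlas (e.g. Harvard-Oxford):
#' a 4-D lattice of per-region probabilities in \[0, 100\]. Regions are
#' spatially contiguous spherical blobs with probability decaying linearly
#' from 100 at the center to 0 at the blob radius, quantized to integers
#' (ties are only meaningful at stored precision). When `n_regions >= 2`
#' one designated voxel is written with two regions tied at the maximum
#' (to exercise the tie-exclusion rule); background voxels hold all-zero
#' probabilities (to exercise the no-label rule).
#'
#' @param grid_shape Integer 3-vector.
#' @param voxel_size_mm Numeric 3-vector (or scalar), mm.
#' @param n_regions Number of regions (>= 1).
#' @param seed Integer seed for blob center placement.
#' @param center Grid center in world mm, default the origin.
#' @return An object of class `prob_atlas`: `data` (4-D array
#'   x,y,z,region), `affine`, `region_names`. Attributes `centers` (region
#'   blob centers, world mm), `radius_mm` (blob radius) and `tie_voxel`
#'   (1-based index of the constructed tie voxel, or `NULL`) expose the
#'   ground truth for testing.
#' @export
make_synthetic_prob_atlas <- function(grid_shape, voxel_size_mm, n_regions,
                                      seed = 1L, center = c(0, 0, 0)) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3 || any(grid_shape <= 0))
    stop("grid_shape must be 3 positive integers", call. = FALSE)
  if (n_regions < 1) stop("n_regions must be >= 1", call. = FALSE)
  if (length(voxel_size_mm) == 1) voxel_size_mm <- rep(voxel_size_mm, 3)
  aff <- centered_grid_affine(grid_shape, voxel_size_mm, center)
  extent <- voxel_size_mm * grid_shape
  radius <- min(extent) / 4
  # blob centers: jittered ring in the central half of the grid, so blobs
  # stay inside and background remains all-zero
  set.seed(as.integer(seed) %% 2147483629L)
  ang <- seq(0, 2 * pi, length.out = n_regions + 1)[seq_len(n_regions)] +
    stats::runif(n_regions, -0.1, 0.1)
  ring_r <- if (n_regions == 1) 0 else min(extent) / 4
  centers <- cbind(center[1] + ring_r * cos(ang),
                   center[2] + ring_r * sin(ang),
                   center[3] + stats::runif(n_regions, -1, 1))
  vox <- voxel_centers(grid_shape, aff)
  vol <- array(0, dim = c(grid_shape, n_regions))
  for (r in seq_len(n_regions)) {
    d <- sqrt(rowSums(sweep(vox, 2, centers[r, ], "-")^2))
    p <- round(pmax(0, 100 * (1 - d / radius)))
    vol[, , , r] <- array(p, dim = grid_shape)
  }
  tie_voxel <- NULL
  if (n_regions >= 2) {
    tie_voxel <- c(1L, 1L, 1L)  # grid corner: background otherwise
    vol[1, 1, 1, ] <- 0
    vol[1, 1, 1, 1] <- 50
    vol[1, 1, 1, 2] <- 50
  }
  structure(list(data = vol, affine = aff,
                 region_names = sprintf("Region %s",
                                        make.unique(rep(LETTERS, length.out =
                                                          n_regions)))),
            class = "prob_atlas",
            centers = centers, radius_mm = radius, tie_voxel = tie_voxel)
}

#' A labeled (deterministic) atlas volume
#'
#' Integer-labeled parcellation volume, e.g. a Brodmann-area atlas:
#' voxel value 0 = unlabeled, every nonzero value has a name.
#'
#' @param data 3-D integer array (0 = unlabeled).
#' @param affine 4x4 voxel-to-world matrix.
#' @param label_names Named character vector: names are the integer label
#'   values as strings, values the region names.
#' @return An object of class `labeled_atlas`.
#' @export
labeled_atlas <- function(data, affine, label_names) {
  if (length(dim(data)) != 3)
    stop("data must be a 3-D array", call. = FALSE)
  vals <- setdiff(unique(as.vector(data)), 0)
  unnamed <- setdiff(as.character(vals), names(label_names))
  if (length(unnamed) > 0)
    stop("labels without a name: ", paste(unnamed, collapse = ", "),
         call. = FALSE)
  aff <- affine_transform(affine, from = "voxel", to = "world")$matrix
  structure(list(data = data, affine = aff, label_names = label_names),
            class = "labeled_atlas")
}

# NIfTI-1 I/O -----------------------------------------------------------

#' Write a volume grid to a NIfTI-1 file
#' @param volume A [volume_grid()] (or `prob_atlas`, written 4-D).
#' @param path Output `.nii` / `.nii.gz` path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (!inherits(volume, c("volume_grid", "prob_atlas")))
    stop("volume must be a volume_grid or prob_atlas", call. = FALSE)
  img <- RNifti::asNifti(volume$data)
  RNifti::pixdim(img) <- sqrt(colSums(volume$affine[1:3, 1:3]^2))
  RNifti::qform(img) <- structure(volume$affine, code = 2L)
  RNifti::sform(img) <- structure(volume$affine, code = 2L)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a NIfTI-1 file as a volume grid or probabilistic atlas
#'
#' 3-D images become a [volume_grid()]; 4-D images a `prob_atlas` whose
#' region names are read from `names_path` (one name per line) when given,
#' else auto-numbered.
#'
#' @param path NIfTI file.
#' @param names_path Optional sidecar text file of region names.
#' @return A `volume_grid` or `prob_atlas`.
#' @export
read_volume <- function(path, names_path = NULL) {
  img <- RNifti::readNifti(path)
  aff <- base::matrix(RNifti::xform(img), 4, 4)
  dims <- dim(img)
  if (length(dims) == 3)
    return(volume_grid(array(as.numeric(img), dim = dims), aff))
  if (length(dims) == 4) {
    nm <- if (!is.null(names_path)) readLines(names_path, warn = FALSE)
      else sprintf("region_%02d", seq_len(dims[4]))
    if (length(nm) != dims[4])
      stop("region name count does not match 4th dimension", call. = FALSE)
    return(structure(list(data = array(as.numeric(img), dim = dims),
                          affine = aff, region_names = nm),
                     class = "prob_atlas"))
  }
  stop("unsupported NIfTI dimensionality: ", length(dims), call. = FALSE)
}
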