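#' Construct an affine transform between coordinate spaces
#'
#' An `affine_transform` is a 4x4 homogeneous matrix mapping points (mm)
#' from one named coordinate space to another, e.g. from a subject's native
#' scanner space to MNI space (the matrix produced by SPM-style affine
#' normalization), or from voxel indices to world coordinates.
#'
#' @param matrix Numeric 4x4 matrix. The last row must be `(0, 0, 0, 1)`
#'   (within 1e-9) and the upper-left 3x3 block must be invertible.
#' @param from,to Names of the source and destination spaces
#'   (e.g. `"subject"`, `"mni"`, `"voxel"`).
#' @return An object of class `affine_transform` with fields `matrix`,
#'   `from`, `to`.
#' @examples
#' t <- affine_transform(diag(4), from = "subject", to = "mni")
#' apply_affine(t, c(10, -20, 30))
#' @export
affine_transform <- function(matrix, from = "subject", to = "mni") {
  m <- base::as.matrix(matrix)
  if (!is.numeric(m) || !identical(dim(m), c(4L, 4L)))
    stop("affine matrix must be a numeric 4x4 matrix", call. = FALSE)
  if (any(!is.finite(m)))
    stop("affine matrix contains non-finite entries", call. = FALSE)
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-9)
    stop("affine matrix last row must be (0, 0, 0, 1)", call. = FALSE)
  if (abs(det(m[1:3, 1:3])) <= 1e-12)
    stop("affine matrix is singular (|det| <= 1e-12)", call. = FALSE)
  structure(list(matrix = m, from = from, to = to),
            class = "affine_transform")
}

#' @export
print.affine_transform <- function(x, ...) {
  cat(sprintf("<affine_transform: %s -> %s>\n", x$from, x$to))
  print(x$matrix)
  invisible(x)
}

is_affine <- function(x) inherits(x, "affine_transform")

#' Apply an affine transform to points
#'
#' Computes the exact homogeneous product: rotation/scale/shear block times
#' the point, plus the translation column. No resampling is involved.
#'
#' @param transform An [affine_transform()].
#' @param points A length-3 numeric vector, or an n x 3 matrix/data.frame
#'   of row vectors, in mm.
#' @return Points in the destination space, same shape as the input.
#' @export
apply_affine <- function(transform, points) {
  stopifnot(is_affine(transform))
  single <- is.null(dim(points))
  p <- if (single) base::matrix(as.numeric(points), nrow = 1) else
    base::as.matrix(points)
  if (ncol(p) != 3L) stop("points must have 3 columns", call. = FALSE)
  if (any(!is.finite(p))) stop("points must be finite", call. = FALSE)
  out <- p %*% t(transform$matrix[1:3, 1:3])
  out <- sweep(out, 2, transform$matrix[1:3, 4], "+")
  if (single) as.numeric(out) else out
}

#' Invert an affine transform
#'
#' @param transform An [affine_transform()].
#' @return The inverse transform, with `from` and `to` swapped, such that
#'   `apply_affine(invert_affine(t), apply_affine(t, p))` returns `p`
#'   to numerical precision.
#' @export
invert_affine <- function(transform) {
  stopifnot(is_affine(transform))
  affine_transform(solve(transform$matrix),
                   from = transform$to, to = transform$from)
}

#' Compose two affine transforms
#'
#' `compose_affine(a, b)` is the transform applying `b` first, then `a`;
#' the spaces must chain (`b$to == a$from`).
#'
#' @param a,b [affine_transform()] objects.
#' @return The composed transform from `b$from` to `a$to`.
#' @export
compose_affine <- function(a, b) {
  stopifnot(is_affine(a), is_affine(b))
  if (!identical(b$to, a$from))
    stop(sprintf("cannot compose: spaces do not chain (%s -> %s then %s -> %s)",
                 b$from, b$to, a$from, a$to), call. = FALSE)
  affine_transform(a$matrix %*% b$matrix, from = b$from, to = a$to)
}

# Build a 4x4 from a 3x3 linear part and a translation vector.
make_affine_matrix <- function(linear, translation = c(0, 0, 0)) {
  m <- diag(4)
  m[1:3, 1:3] <- linear
  m[1:3, 4] <- translation
  m
}

# Rotation matrix from small Euler angles (degrees), applied x then y then z.
rotation_matrix <- function(rx_deg, ry_deg, rz_deg) {
  a <- rx_deg * pi / 180; b <- ry_deg * pi / 180; c <- rz_deg * pi / 180
  rx <- rbind(c(1, 0, 0), c(0, cos(a), -sin(a)), c(0, sin(a), cos(a)))
  ry <- rbind(c(cos(b), 0, sin(b)), c(0, 1, 0), c(-sin(b), 0, cos(b)))
  rz <- rbind(c(cos(c), -sin(c), 0), c(sin(c), cos(c), 0), c(0, 0, 1))
  rz %*% ry %*% rx
}

#' Transform a cohort's electrode points into MNI space
#'
#' Applies each subject's own subject-to-MNI affine to every electrode
#' point of that subject. Scalp and cortex surfaces are mapped
#' independently (the same linear map applies to both); electrodes absent
#' for a subject simply stay absent.
#'
#' @param points Electrode points data.frame (columns `subject_id`,
#'   `electrode`, `surface`, `space`, `x`, `y`, `z`) in subject space.
#' @param affines Named list of [affine_transform()], one per subject id,
#'   each mapping subject space to MNI space.
#' @return The points with coordinates mapped and `space` set to `"mni"`.
#' @export
normalize_cohort <- function(points, affines) {
  points <- validate_points(points)
  if (!all(points$space == "subject"))
    stop("normalize_cohort expects points in subject space", call. = FALSE)
  missing_aff <- setdiff(unique(points$subject_id), names(affines))
  if (length(missing_aff) > 0)
    stop("no affine for subject(s): ", paste(missing_aff, collapse = ", "),
         call. = FALSE)
  for (sid in unique(points$subject_id)) {
    idx <- points$subject_id == sid
    xyz <- apply_affine(affines[[sid]],
                        base::as.matrix(points[idx, c("x", "y", "z")]))
    points[idx, c("x", "y", "z")] <- xyz
  }
  points$space <- "mni"
  points
}
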