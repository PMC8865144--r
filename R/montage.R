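#' The 65-electrode 10-10 montage as unit directions
#'
#' Builds the canonical 10-10 electrode layout (64-channel fixed cap plus
#' ground and reference, 65 labels) as unit direction vectors from the head
#' center, computed from the 10-10 angular proportions rather than copied
#' from any digitizer file. The construction follows the classical
#' spherical head model:
#'
#' * the midline (inion-nasion) arc is split in 10% steps, so FPZ sits 18
#'   degrees above the equatorial plane at the front, CZ at the vertex, OZ
#'   18 degrees above the equator at the back;
#' * the circumferential ring (FPZ, FP1/2, AF7/8, F7/8, FT7/8, T7/8,
#'   TP7/8, P7/8, PO7/8, O1/2, OZ) lies at 72 degrees inclination from the
#'   vertex, at 18-degree azimuthal steps (5% of the circumference);
#' * inner electrodes of each coronal row are placed by spherical
#'   interpolation between the row's ring electrode and its midline
#'   electrode in 25% steps (50% for the AF and PO rows);
#' * FT9/FT10 and TP9/TP10 sit one 10% step below the ring (inclination
#'   108 degrees), so they project below the equator, toward inferior
#'   temporal cortex and cerebellum.
#'
#' Coordinates follow the RAS convention: +x right, +y anterior,
#' +z superior.
#'
#' @return A data.frame of class `montage` with columns `electrode`,
#'   `dx`, `dy`, `dz` (unit direction vectors), 65 rows, unique labels.
#' @examples
#' m <- default_montage()
#' nrow(m)           # 65
#' m[m$electrode == "CZ", ]  # the vertex
#' @export
default_montage <- function() {
  # direction from inclination (deg from +z) and azimuth
  # (deg from anterior midline, positive toward the left ear)
  dir_ia <- function(incl, az) {
    i <- incl * pi / 180; a <- az * pi / 180
    c(-sin(i) * sin(a), sin(i) * cos(a), cos(i))
  }
  # spherical linear interpolation between unit vectors
  slerp <- function(u, v, t) {
    o <- acos(max(-1, min(1, sum(u * v))))
    if (o < 1e-12) return(u)
    (sin((1 - t) * o) * u + sin(t * o) * v) / sin(o)
  }

  ring_incl <- 72
  # left-hemisphere / midline ring electrodes: azimuth in 18-degree steps
  ring <- list(FPZ = 0, FP1 = 18, AF7 = 36, F7 = 54, FT7 = 72, T7 = 90,
               TP7 = 108, P7 = 126, PO7 = 144, O1 = 162, OZ = 180)
  # midline electrodes: fraction of the nasion-inion arc
  midline <- list(AFZ = 0.2, FZ = 0.3, FCZ = 0.4, CZ = 0.5,
                  CPZ = 0.6, PZ = 0.7, POZ = 0.8)
  # inner rows: (ring anchor, midline anchor, labels from lateral to medial)
  rows <- list(
    list(ring = "AF7", mid = "AFZ", labels = c("AF3")),
    list(ring = "F7",  mid = "FZ",  labels = c("F5", "F3", "F1")),
    list(ring = "FT7", mid = "FCZ", labels = c("FC5", "FC3", "FC1")),
    list(ring = "T7",  mid = "CZ",  labels = c("C5", "C3", "C1")),
    list(ring = "TP7", mid = "CPZ", labels = c("CP5", "CP3", "CP1")),
    list(ring = "P7",  mid = "PZ",  labels = c("P5", "P3", "P1")),
    list(ring = "PO7", mid = "POZ", labels = c("PO3")))

  dirs <- list()
  for (lab in names(ring)) dirs[[lab]] <- dir_ia(ring_incl, ring[[lab]])
  for (lab in names(midline)) {
    s <- midline[[lab]]
    dirs[[lab]] <- c(0, cos(pi * s), sin(pi * s))
  }
  for (row in rows) {
    k <- length(row$labels)
    for (j in seq_len(k))
      dirs[[row$labels[j]]] <- slerp(dirs[[row$ring]], dirs[[row$mid]],
                                     j / (k + 1))
  }
  # inferior temporal ring, one 10% step below the circumferential ring
  dirs[["FT9"]] <- dir_ia(ring_incl + 36, 72)
  dirs[["TP9"]] <- dir_ia(ring_incl + 36, 108)

  # mirror the left hemisphere to the right (negate x)
  mirror <- c(FP1 = "FP2", AF7 = "AF8", AF3 = "AF4",
              F7 = "F8", F5 = "F6", F3 = "F4", F1 = "F2",
              FT7 = "FT8", FC5 = "FC6", FC3 = "FC4", FC1 = "FC2",
              T7 = "T8", C5 = "C6", C3 = "C4", C1 = "C2",
              TP7 = "TP8", CP5 = "CP6", CP3 = "CP4", CP1 = "CP2",
              P7 = "P8", P5 = "P6", P3 = "P4", P1 = "P2",
              PO7 = "PO8", PO3 = "PO4", O1 = "O2",
              FT9 = "FT10", TP9 = "TP10")
  for (left in names(mirror)) {
    d <- dirs[[left]]
    dirs[[mirror[[left]]]] <- c(-d[1], d[2], d[3])
  }

  labels <- sort(names(dirs))
  mat <- do.call(rbind, dirs[labels])
  mat <- mat / sqrt(rowSums(mat^2))
  out <- data.frame(electrode = labels, dx = mat[, 1], dy = mat[, 2],
                    dz = mat[, 3], stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("montage", "data.frame")
  out
}

#' Describe a subject's head as nested scalp and brain ellipsoids
#'
#' The synthetic head model is a pair of concentric ellipsoids: the scalp
#' surface on which electrodes sit, and the brain surface onto which they
#' are projected. Semiaxes are in mm and the brain must lie strictly
#' inside the scalp. `cap_size_cm` is the head-circumference category of
#' the fitted cap (54/56/58 cm in the emulated cohort); the 56 cm cap is
#' treated as the reference size and other sizes scale both ellipsoids
#' proportionally.
#'
#' @param center Head center in mm (3-vector). The default sits slightly
#'   posterior and superior of the MNI origin, so that the scalp surface
#'   spans roughly the coordinate ranges observed for real MNI-normalized
#'   heads (frontal pole near y = 80, vertex near z = 97) and stays
#'   inside the standard MNI152 bounding box.
#' @param scalp_semiaxes,brain_semiaxes Ellipsoid semiaxes in mm
#'   (3-vectors); brain strictly inside scalp, componentwise.
#' @param cap_size_cm Cap size in cm, or `NA` if unrecorded.
#' @return An object of class `head_model`.
#' @export
head_model <- function(center = c(0, -18, 15),
                       scalp_semiaxes = c(78, 98, 82),
                       brain_semiaxes = c(66, 86, 70),
                       cap_size_cm = NA_real_) {
  stopifnot(length(center) == 3, length(scalp_semiaxes) == 3,
            length(brain_semiaxes) == 3)
  if (any(scalp_semiaxes <= 0) || any(brain_semiaxes <= 0))
    stop("semiaxes must be positive", call. = FALSE)
  if (any(brain_semiaxes >= scalp_semiaxes))
    stop("brain semiaxes must be strictly inside scalp semiaxes",
         call. = FALSE)
  if (!is.na(cap_size_cm)) {
    if (cap_size_cm <= 0) stop("cap_size_cm must be positive", call. = FALSE)
    sc <- cap_size_cm / 56
    scalp_semiaxes <- scalp_semiaxes * sc
    brain_semiaxes <- brain_semiaxes * sc
  }
  structure(list(center = as.numeric(center),
                 scalp_semiaxes = as.numeric(scalp_semiaxes),
                 brain_semiaxes = as.numeric(brain_semiaxes),
                 cap_size_cm = cap_size_cm),
            class = "head_model")
}

# Radial projection of direction vectors onto an ellipsoid surface:
# p = center + r * d with r chosen so that sum(((p - c)/semiaxes)^2) = 1.
project_to_ellipsoid <- function(directions, center, semiaxes) {
  d <- base::as.matrix(directions)
  r <- 1 / sqrt(rowSums(sweep(d, 2, semiaxes, "/")^2))
  sweep(d * r, 2, center, "+")
}

#' Canonical electrode positions on a head's scalp
#'
#' Projects the montage's unit directions radially onto the scalp
#' ellipsoid, yielding the noise-free electrode positions for that head.
#'
#' @param montage A [default_montage()]-shaped data.frame.
#' @param head A [head_model()].
#' @return An n x 3 matrix of scalp positions in mm, rownames = electrode
#'   labels.
#' @export
montage_on_scalp <- function(montage, head) {
  stopifnot(inherits(head, "head_model"))
  p <- project_to_ellipsoid(base::as.matrix(montage[, c("dx", "dy", "dz")]),
                            head$center, head$scalp_semiaxes)
  rownames(p) <- montage$electrode
  colnames(p) <- c("x", "y", "z")
  p
}
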