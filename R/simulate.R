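#' Configuration for synthetic cohort simulation
#'
#' Defines the noise model of the synthetic cohort: a per-subject cap
#' perturbation (small rigid rotation + translation + isotropic scale of
#' the whole cap, re-seated on the scalp) composed with independent
#' per-electrode Gaussian placement jitter, plus a random per-subject
#' pose (the subject's native scanner space), and independent electrode
#' missingness. Random streams are keyed by (seed, subject, electrode) so
#' that dropping one electrode never shifts another electrode's draws.
#'
#' Defaults emulate a 20-subject fixed-cap cohort: 3 mm per-axis electrode
#' jitter and a mild cap-level perturbation (2 degrees rotation, 3 mm
#' translation, 2% scale), which lands per-axis grand SDs in the 4-7 mm
#' range typical of MRI-localized fixed-cap cohorts; cap sizes 54/56/58 cm
#' split 4/12/3 with one unrecorded.
#'
#' @param n_subjects Number of subjects (positive integer).
#' @param jitter_sd_mm Per-axis SD (mm) of independent per-electrode
#'   placement jitter; length-3 non-negative.
#' @param cap_rotation_sd_deg,cap_translation_sd_mm,cap_scale_sd SDs of
#'   the per-subject cap perturbation: rotation per Euler axis (degrees),
#'   translation per axis (mm), isotropic scale (unitless, about 1).
#' @param pose_rotation_sd_deg,pose_translation_sd_mm,pose_scale_sd SDs of
#'   the random subject pose (head position/size in native scanner space);
#'   undone exactly by the returned subject-to-MNI affine.
#' @param missing_electrode_rate Probability in \[0, 1\] that any given
#'   electrode is missing for a subject.
#' @param cap_sizes_cm Optional numeric vector (length `n_subjects`) of
#'   cap sizes, `NA` = unrecorded. Default: 54/56/58 split 4/12/3 plus one
#'   `NA` for 20 subjects, extended proportionally otherwise.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_subjects = 20L,
                              jitter_sd_mm = c(3, 3, 3),
                              cap_rotation_sd_deg = 2,
                              cap_translation_sd_mm = 3,
                              cap_scale_sd = 0.02,
                              pose_rotation_sd_deg = 5,
                              pose_translation_sd_mm = 8,
                              pose_scale_sd = 0.05,
                              missing_electrode_rate = 0.02,
                              cap_sizes_cm = NULL,
                              seed = 1L) {
  n_subjects <- as.integer(n_subjects)
  if (is.na(n_subjects) || n_subjects < 1)
    stop("n_subjects must be a positive integer", call. = FALSE)
  if (length(jitter_sd_mm) == 1) jitter_sd_mm <- rep(jitter_sd_mm, 3)
  if (length(jitter_sd_mm) != 3 || any(jitter_sd_mm < 0))
    stop("jitter_sd_mm must be a non-negative 3-vector", call. = FALSE)
  for (nm in c("cap_rotation_sd_deg", "cap_translation_sd_mm",
               "cap_scale_sd", "pose_rotation_sd_deg",
               "pose_translation_sd_mm", "pose_scale_sd")) {
    v <- get(nm)
    if (length(v) != 1 || is.na(v) || v < 0)
      stop(nm, " must be a non-negative scalar", call. = FALSE)
  }
  if (missing_electrode_rate < 0 || missing_electrode_rate > 1)
    stop("missing_electrode_rate must be in [0, 1]", call. = FALSE)
  if (is.null(cap_sizes_cm)) cap_sizes_cm <- default_cap_sizes(n_subjects)
  if (length(cap_sizes_cm) != n_subjects)
    stop("cap_sizes_cm must have length n_subjects", call. = FALSE)
  structure(list(n_subjects = n_subjects,
                 jitter_sd_mm = as.numeric(jitter_sd_mm),
                 cap_rotation_sd_deg = cap_rotation_sd_deg,
                 cap_translation_sd_mm = cap_translation_sd_mm,
                 cap_scale_sd = cap_scale_sd,
                 pose_rotation_sd_deg = pose_rotation_sd_deg,
                 pose_translation_sd_mm = pose_translation_sd_mm,
                 pose_scale_sd = pose_scale_sd,
                 missing_electrode_rate = missing_electrode_rate,
                 cap_sizes_cm = as.numeric(cap_sizes_cm),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Cap-size assignment mirroring the emulated cohort: 4 x 54 cm,
# 12 x 56 cm, 3 x 58 cm, one unrecorded (n = 20); proportional otherwise.
default_cap_sizes <- function(n_subjects) {
  if (n_subjects == 20L)
    return(c(rep(54, 4), rep(56, 12), rep(58, 3), NA_real_))
  pool <- c(rep(54, 4), rep(56, 12), rep(58, 3), NA_real_)
  rep_len(pool, n_subjects)
}

# Deterministic per-(subject, electrode) stream seeding. Stream 0 carries
# the subject-level draws (cap perturbation + pose); streams 1..n_electrode
# the per-electrode draws. Kept well below 2^31.
stream_seed <- function(seed, subject_index, stream) {
  base <- (as.integer(seed) %% 1000003L) * 2011L
  (base + subject_index * 997L + stream) %% 2147483629L
}

#' Simulate one subject's electrode placements
#'
#' Generates a subject's scalp electrode positions under the configured
#' noise model: the canonical montage-on-scalp positions are perturbed by
#' the subject's cap transform (rotation, translation, scale) and
#' re-projected radially onto the scalp ellipsoid, then each present
#' electrode receives independent zero-mean Gaussian jitter with the
#' configured per-axis SD. The points are finally expressed in a
#' randomized subject space; the returned affine maps that subject space
#' back to the canonical (MNI-like template) space exactly.
#'
#' @param montage A [default_montage()]-shaped montage.
#' @param head A [head_model()].
#' @param config A [simulation_config()].
#' @param subject_index 1-based subject index (`<= config$n_subjects`).
#' @return A list: `points` (electrode points data.frame, subject space,
#'   scalp surface; missing electrodes absent), `affine` (subject-to-MNI
#'   [affine_transform()]), `truth` (noise-free canonical scalp positions,
#'   matrix), and `subject_id`.
#' @export
simulate_subject <- function(montage, head, config, subject_index) {
  stopifnot(inherits(config, "simulation_config"),
            inherits(head, "head_model"))
  if (subject_index < 1 || subject_index > config$n_subjects)
    stop("subject_index out of range", call. = FALSE)
  subject_id <- sprintf("sub-%02d", subject_index)
  canonical <- montage_on_scalp(montage, head)
  n_elec <- nrow(canonical)

  # subject-level draws: cap perturbation then subject pose
  set.seed(stream_seed(config$seed, subject_index, 0L))
  cap_rot <- rotation_matrix(stats::rnorm(1, 0, config$cap_rotation_sd_deg),
                             stats::rnorm(1, 0, config$cap_rotation_sd_deg),
                             stats::rnorm(1, 0, config$cap_rotation_sd_deg))
  cap_shift <- stats::rnorm(3, 0, config$cap_translation_sd_mm)
  cap_scale <- 1 + stats::rnorm(1, 0, config$cap_scale_sd)
  pose_rot <- rotation_matrix(
    stats::rnorm(1, 0, config$pose_rotation_sd_deg),
    stats::rnorm(1, 0, config$pose_rotation_sd_deg),
    stats::rnorm(1, 0, config$pose_rotation_sd_deg))
  pose_shift <- stats::rnorm(3, 0, config$pose_translation_sd_mm)
  pose_scale <- 1 + stats::rnorm(1, 0, config$pose_scale_sd)

  # cap transform applied about the head center, then re-seated on the
  # scalp by radial projection (the cap slides on the head surface)
  centered <- sweep(canonical, 2, head$center, "-")
  displaced <- sweep(cap_scale * (centered %*% t(cap_rot)), 2,
                     cap_shift, "+")
  reseated <- project_to_ellipsoid(
    displaced / sqrt(rowSums(displaced^2)),
    head$center, head$scalp_semiaxes)

  # per-electrode draws: missingness flag then jitter, one stream each
  present <- logical(n_elec)
  jitter <- base::matrix(0, n_elec, 3)
  for (e in seq_len(n_elec)) {
    set.seed(stream_seed(config$seed, subject_index, e))
    present[e] <- stats::runif(1) >= config$missing_electrode_rate
    jitter[e, ] <- stats::rnorm(3, 0, config$jitter_sd_mm)
  }
  noisy <- reseated + jitter

  # subject pose: canonical -> subject; returned affine is its inverse
  pose <- affine_transform(
    make_affine_matrix(pose_scale * pose_rot, pose_shift),
    from = "mni", to = "subject")
  subject_points <- apply_affine(pose, noisy)

  pts <- electrode_points(subject_id, montage$electrode[present],
                          "scalp", "subject",
                          subject_points[present, 1],
                          subject_points[present, 2],
                          subject_points[present, 3])
  list(points = pts, affine = invert_affine(pose),
       truth = canonical, subject_id = subject_id)
}

#' Simulate a full cohort in memory
#'
#' Runs [simulate_subject()] for every subject, with per-subject heads
#' scaled by the configured cap sizes.
#'
#' @param config A [simulation_config()].
#' @param montage Montage (default [default_montage()]).
#' @param base_head Reference 56 cm head (default [head_model()] scaled
#'   per subject cap size; `NA` cap sizes use the reference size).
#' @return A list of class `synthetic_cohort`: `points` (all subjects'
#'   scalp points, subject space), `affines` (named list of
#'   subject-to-MNI transforms), `heads` (named list of per-subject
#'   [head_model()]), `cap_sizes` (named vector), `config`.
#' @export
simulate_cohort <- function(config, montage = default_montage(),
                            base_head = head_model()) {
  stopifnot(inherits(config, "simulation_config"))
  points <- list(); affines <- list(); heads <- list()
  cap_sizes <- numeric(0)
  for (i in seq_len(config$n_subjects)) {
    cap <- config$cap_sizes_cm[i]
    head_i <- head_model(center = base_head$center,
                         scalp_semiaxes = base_head$scalp_semiaxes,
                         brain_semiaxes = base_head$brain_semiaxes,
                         cap_size_cm = cap)
    sim <- simulate_subject(montage, head_i, config, i)
    points[[sim$subject_id]] <- sim$points
    affines[[sim$subject_id]] <- sim$affine
    heads[[sim$subject_id]] <- head_i
    cap_sizes[sim$subject_id] <- cap
  }
  structure(list(points = do.call(rbind, c(points, make.row.names = FALSE)),
                 affines = affines, heads = heads, cap_sizes = cap_sizes,
                 config = config),
            class = "synthetic_cohort")
}

#' Write a simulated cohort to disk as a loadable dataset
#'
#' Materializes a [simulate_cohort()] result in the on-disk layout the
#' rest of the pipeline consumes: per-subject scalp target files and
#' affine files, optional per-subject brain/scalp mask NIfTIs, and a YAML
#' manifest binding them together.
#'
#' @param cohort A `synthetic_cohort`.
#' @param out_dir Output directory (created if needed).
#' @param write_masks Also voxelize and write per-subject brain masks (in
#'   subject space) for the projection stage. Default `TRUE`.
#' @param grid_shape,voxel_size_mm Grid for the masks.
#' @return Path to the written manifest, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, write_masks = TRUE,
                         grid_shape = c(60, 72, 62),
                         voxel_size_mm = c(4, 4, 4)) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  subjects <- list()
  for (sid in names(cohort$affines)) {
    scalp_file <- paste0(sid, "_scalp.txt")
    affine_file <- paste0(sid, "_affine.txt")
    write_targets(cohort$points[cohort$points$subject_id == sid, ],
                  file.path(out_dir, scalp_file))
    write_affine(cohort$affines[[sid]], file.path(out_dir, affine_file))
    rec <- list(subject_id = sid,
                cap_size_cm = if (is.na(cohort$cap_sizes[[sid]])) NULL else
                  cohort$cap_sizes[[sid]],
                scalp_targets = scalp_file, affine = affine_file)
    if (write_masks) {
      # masks are produced in subject space: voxelize the canonical head
      # then carry it through the subject pose via the mask grid affine
      mask_file <- paste0(sid, "_brainmask.nii.gz")
      vols <- make_head_volumes(cohort$heads[[sid]], grid_shape,
                                voxel_size_mm)
      pose <- invert_affine(cohort$affines[[sid]])  # mni -> subject
      brain <- vols$brain_mask
      brain$affine <- compose_affine(
        pose, affine_transform(brain$affine, from = "voxel", to = "mni")
      )$matrix
      write_volume(brain, file.path(out_dir, mask_file))
      rec$brain_mask <- mask_file
    }
    subjects[[sid]] <- rec
  }
  manifest_path <- file.path(out_dir, "manifest.yaml")
  write_manifest(structure(list(subjects = unname(subjects)),
                           class = "cohort_manifest"), manifest_path)
  invisible(manifest_path)
}

#' Load a cohort from a manifest
#'
#' Reads every subject's target files and affine into memory.
#'
#' @param manifest A `cohort_manifest` or path to one.
#' @return A list: `points` (scalp + any cortex points, subject space),
#'   `affines` (named list), `cap_sizes` (named vector), `brain_masks`
#'   (named list of file paths or `NULL`), `manifest`.
#' @export
load_cohort <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  stopifnot(inherits(manifest, "cohort_manifest"))
  points <- list(); affines <- list()
  cap_sizes <- numeric(0); brain_masks <- list()
  for (s in manifest$subjects) {
    sid <- s$subject_id
    pts <- read_targets(s$scalp_targets, sid, "scalp")
    if (!is.null(s$cortex_targets))
      pts <- rbind(pts, read_targets(s$cortex_targets, sid, "cortex"))
    points[[sid]] <- pts
    affines[[sid]] <- read_affine(s$affine)
    cap_sizes[sid] <- s$cap_size_cm
    brain_masks[sid] <- list(s$brain_mask)
  }
  list(points = do.call(rbind, c(points, make.row.names = FALSE)),
       affines = affines, cap_sizes = cap_sizes,
       brain_masks = brain_masks, manifest = manifest)
}
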