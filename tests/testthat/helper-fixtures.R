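# Shared fixtures for the test suite: small deterministic cohorts and
# synthetic atlases built in code.

# A noise-free simulation configuration: identical subjects, identity
# pose, so downstream outputs must agree across subjects exactly.
zero_noise_config <- function(n_subjects = 4, seed = 42, pose_sd = 0) {
  simulation_config(n_subjects = n_subjects, jitter_sd_mm = c(0, 0, 0),
                    cap_rotation_sd_deg = 0, cap_translation_sd_mm = 0,
                    cap_scale_sd = 0,
                    pose_rotation_sd_deg = pose_sd,
                    pose_translation_sd_mm = pose_sd,
                    pose_scale_sd = pose_sd / 100,
                    missing_electrode_rate = 0,
                    cap_sizes_cm = rep(56, n_subjects), seed = seed)
}

# Jitter-only configuration (no cap-level noise, no missingness).
jitter_only_config <- function(n_subjects = 20, sd = 5, seed = 1) {
  simulation_config(n_subjects = n_subjects, jitter_sd_mm = rep(sd, 3),
                    cap_rotation_sd_deg = 0, cap_translation_sd_mm = 0,
                    cap_scale_sd = 0, missing_electrode_rate = 0,
                    cap_sizes_cm = rep(56, n_subjects), seed = seed)
}

# Spherical test head (radii in mm), convenient for analytic oracles.
sphere_head <- function(scalp_r = 30, brain_r = 20) {
  head_model(center = c(0, 0, 0), scalp_semiaxes = rep(scalp_r, 3),
             brain_semiaxes = rep(brain_r, 3))
}

# A two-region atlas splitting the head by the z = 0 plane, covering the
# whole electrode cloud; every electrode's true region is known from the
# sign of its z coordinate.
hemisphere_z_atlas <- function() {
  shape <- c(50L, 50L, 50L)
  aff <- rbind(cbind(diag(c(5, 5, 5)), c(-122.5, -122.5, -122.5)),
               c(0, 0, 0, 1))
  zc <- -122.5 + 5 * (0:49)
  vol <- array(0, dim = c(shape, 2))
  vol[, , zc > 0, 1] <- 100
  vol[, , zc < 0, 2] <- 100
  structure(list(data = vol, affine = aff,
                 region_names = c("Upper", "Lower")),
            class = "prob_atlas")
}

# Per-subject brain masks expressed in each subject's native space:
# voxelize the canonical head, then push the grid affine through the
# subject pose (the inverse of the subject-to-MNI transform).
subject_space_masks <- function(cohort, grid_shape, voxel_size) {
  masks <- list()
  for (sid in names(cohort$heads)) {
    m <- make_head_volumes(cohort$heads[[sid]], grid_shape,
                           voxel_size)$brain_mask
    pose <- invert_affine(cohort$affines[[sid]])  # mni -> subject
    masks[[sid]] <- volume_grid(m$data, pose$matrix %*% m$affine)
  }
  masks
}

# Brute-force nearest-neighbor oracle with the same tie rule as
# snap_to_cortex (smallest x, then y, then z), written as an explicit
# scan independent of the implementation.
nn_oracle <- function(p, surface) {
  best <- NULL; best_d <- Inf
  for (i in seq_len(nrow(surface))) {
    d <- sum((surface[i, ] - p)^2)
    if (d < best_d - 1e-15) {
      best <- surface[i, ]; best_d <- d
    } else if (abs(d - best_d) <= 1e-15) {
      cand <- surface[i, ]
      for (ax in 1:3) {
        if (cand[ax] < best[ax]) { best <- cand; break }
        if (cand[ax] > best[ax]) break
      }
    }
  }
  as.numeric(best)
}

# Brute-force count of integer-lattice points within Euclidean distance
# r of a center (1 mm isotropic grid assumed by the caller).
lattice_ball_count <- function(center, r, lo = -200, hi = 200) {
  n <- 0L
  rng <- function(c) seq(ceiling(c - r), floor(c + r))
  for (i in rng(center[1])) for (j in rng(center[2]))
    for (k in rng(center[3]))
      if ((i - center[1])^2 + (j - center[2])^2 + (k - center[3])^2 <=
          r^2) n <- n + 1L
  n
}
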