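#' Configuration for the end-to-end pipeline
#'
#' Bundles every knob of [run_all()]: the input manifest, output
#' directory, which surfaces to analyze, projection parameters, optional
#' atlas inputs, the extreme-set size, and the rendering radius.
#'
#' @param manifest Path to a cohort manifest, or a `cohort_manifest`.
#' @param out_dir Output directory.
#' @param surfaces Surfaces to summarize (subset of `c("scalp",
#'   "cortex")`).
#' @param projection A [projection_params()].
#' @param prob_atlas Optional `prob_atlas` object or NIfTI path.
#' @param atlas_names Optional sidecar region-name file (when
#'   `prob_atlas` is a path).
#' @param labeled_atlas Optional [labeled_atlas()] for nearest-label
#'   lookup at mean coordinates.
#' @param label_surface Surface whose coordinates feed atlas labeling
#'   (default `"cortex"`, falling back to scalp when no cortex
#'   coordinates exist).
#' @param k Extreme-set size for [rank_extremes()], default 5.
#' @param sphere_radius_mm Sphere radius for [render_sphere_map()],
#'   default 4.
#' @param render Write NIfTI outputs (per-subject point maps + sphere
#'   map), default `TRUE`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(manifest, out_dir,
                            surfaces = c("scalp", "cortex"),
                            projection = projection_params(),
                            prob_atlas = NULL, atlas_names = NULL,
                            labeled_atlas = NULL,
                            label_surface = "cortex",
                            k = 5L, sphere_radius_mm = 4,
                            render = TRUE) {
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  stopifnot(all(surfaces %in% c("scalp", "cortex")))
  structure(list(manifest = manifest, out_dir = out_dir,
                 surfaces = surfaces, projection = projection,
                 prob_atlas = prob_atlas, atlas_names = atlas_names,
                 labeled_atlas = labeled_atlas,
                 label_surface = label_surface, k = as.integer(k),
                 sphere_radius_mm = sphere_radius_mm, render = render),
            class = "pipeline_config")
}

#' Run the full electrode-variability pipeline
#'
#' Orchestrates load -> normalize -> project -> summarize -> label ->
#' render from a cohort manifest, writing all output tables and volumes
#' into one directory:
#'
#' * `summary_<surface>.csv` - per-electrode mean/SD/skewness and overall
#'   deviation (MNI mm);
#' * `grand_summary.csv` - per-axis grand SDs per surface, overall and by
#'   cap size;
#' * `extremes.csv` - the k most stable / most variable electrodes per
#'   surface;
#' * `region_tally.csv` - percentage region breakdown per electrode (when
#'   an atlas is configured; otherwise the stage is skipped with a logged
#'   notice);
#' * `<subject>_points.nii.gz` and `sphere_map_<surface>.nii.gz` (when
#'   `render = TRUE`);
#' * `run_log.json` - machine-readable stage log (parameters and record
#'   counts).
#'
#' Cortex coordinates come from per-subject cortex target files when the
#' manifest provides them, else are computed by scalp-to-cortex projection
#' when brain masks are available, else the cortex surface is skipped.
#' Any stage error aborts the run, removes partial outputs created by
#' this invocation, and names the failing stage.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the main in-memory results
#'   (`summaries`, `grand`, `extremes`, `tallies`, `log`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out_dir <- config$out_dir
  created <- !dir.exists(out_dir)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  log <- list()
  stage <- "setup"
  emit <- function(path) written <<- c(written, path)

  result <- tryCatch({
    stage <- "load"
    cohort <- load_cohort(config$manifest)
    log$load <- list(n_subjects = length(cohort$affines),
                     n_points = nrow(cohort$points))

    stage <- "normalize"
    mni <- normalize_cohort(cohort$points, cohort$affines)
    log$normalize <- list(n_points = nrow(mni))

    stage <- "project"
    has_cortex <- any(mni$surface == "cortex")
    masks_ok <- all(!vapply(cohort$brain_masks, is.null, TRUE))
    if (!has_cortex && "cortex" %in% config$surfaces && masks_ok) {
      scalp_subj <- cohort$points[cohort$points$surface == "scalp", ]
      cortex_subj <- project_cohort(scalp_subj, cohort$brain_masks,
                                    config$projection)
      cortex_mni <- normalize_cohort(cortex_subj, cohort$affines)
      mni <- rbind(mni, cortex_mni)
      log$project <- list(
        n_points = nrow(cortex_mni),
        n_unprojectable = nrow(attr(cortex_subj, "unprojectable")))
    } else {
      log$project <- list(skipped = TRUE,
                          reason = if (has_cortex)
                            "cortex coordinates supplied" else
                              "no brain masks configured")
    }

    stage <- "summarize"
    surfaces <- intersect(config$surfaces, unique(mni$surface))
    summaries <- list(); grand_rows <- list(); extreme_rows <- list()
    for (surf in surfaces) {
      s <- summarize_electrodes(mni, surface = surf)
      summaries[[surf]] <- s
      f <- file.path(out_dir, sprintf("summary_%s.csv", surf))
      write_summary_csv(s, f); emit(f)
      caps <- group_by_cap_size(mni[mni$surface == surf, ],
                                cohort$cap_sizes)
      caps$surface <- surf
      grand_rows[[surf]] <- caps
      ex <- rank_extremes(s, config$k)
      extreme_rows[[surf]] <- data.frame(
        surface = surf, set = c("smallest", "largest"),
        electrodes = c(paste(ex$smallest$electrodes, collapse = ";"),
                       paste(ex$largest$electrodes, collapse = ";")),
        mean_overall_deviation = c(ex$smallest$mean_overall_deviation,
                                   ex$largest$mean_overall_deviation),
        stringsAsFactors = FALSE)
    }
    grand <- do.call(rbind, c(grand_rows, make.row.names = FALSE))
    f <- file.path(out_dir, "grand_summary.csv")
    utils::write.csv(grand, f, row.names = FALSE); emit(f)
    extremes <- do.call(rbind, c(extreme_rows, make.row.names = FALSE))
    f <- file.path(out_dir, "extremes.csv")
    utils::write.csv(extremes, f, row.names = FALSE); emit(f)
    log$summarize <- list(surfaces = surfaces,
                          n_electrodes = vapply(summaries, nrow, 0L))

    stage <- "label"
    tallies <- NULL
    atlas <- config$prob_atlas
    if (!is.null(atlas)) {
      if (is.character(atlas))
        atlas <- read_volume(atlas, config$atlas_names)
      surf <- if (config$label_surface %in% surfaces)
        config$label_surface else surfaces[1]
      outcomes <- label_cohort(atlas, mni[mni$surface == surf, ])
      tallies <- tally_cohort(outcomes)
      f <- file.path(out_dir, "region_tally.csv")
      write_tally_csv(tallies, f); emit(f)
      mu <- mean_usable(tallies)
      log$label <- list(surface = surf,
                        usable_mean = unname(mu["mean"]),
                        usable_sd = unname(mu["sd"]))
    } else {
      log$label <- list(skipped = TRUE, reason = "no atlas configured")
    }

    stage <- "render"
    if (config$render) {
      grid <- mni_template_grid()
      for (sid in names(cohort$affines)) {
        vol <- render_points(mni[mni$subject_id == sid, ], grid)
        f <- file.path(out_dir, sprintf("%s_points.nii.gz", sid))
        write_volume(vol, f); emit(f)
      }
      for (surf in surfaces) {
        vol <- render_sphere_map(summaries[[surf]],
                                 config$sphere_radius_mm, grid = grid)
        f <- file.path(out_dir, sprintf("sphere_map_%s.nii.gz", surf))
        write_volume(vol, f); emit(f)
      }
      log$render <- list(n_subject_maps = length(cohort$affines),
                         sphere_radius_mm = config$sphere_radius_mm)
    } else {
      log$render <- list(skipped = TRUE)
    }

    log$params <- list(k = config$k,
                       peel_depth_mm = config$projection$peel_depth_mm,
                       surfaces = config$surfaces)
    f <- file.path(out_dir, "run_log.json")
    jsonlite::write_json(log, f, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    emit(f)
    list(summaries = summaries, grand = grand, extremes = extremes,
         tallies = tallies, log = log)
  }, error = function(e) {
    unlink(written)
    if (created) unlink(out_dir, recursive = TRUE)
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
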