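#' Electrode points data.frame
#'
#' All electrode coordinates in the package travel as a plain data.frame
#' with one row per (subject, electrode, surface) and explicit bookkeeping
#' columns: nothing is ever inferred from file names or sign conventions.
#'
#' @param subject_id Character subject identifiers.
#' @param electrode Character electrode labels (non-empty).
#' @param surface `"scalp"` or `"cortex"`.
#' @param space `"subject"` or `"mni"`.
#' @param x,y,z Coordinates in mm (finite).
#' @return A data.frame with columns `subject_id`, `electrode`, `surface`,
#'   `space`, `x`, `y`, `z`.
#' @export
electrode_points <- function(subject_id, electrode, surface, space, x, y, z) {
  validate_points(data.frame(
    subject_id = as.character(subject_id),
    electrode = as.character(electrode),
    surface = as.character(surface), space = as.character(space),
    x = as.numeric(x), y = as.numeric(y), z = as.numeric(z),
    stringsAsFactors = FALSE))
}

validate_points <- function(points) {
  req <- c("subject_id", "electrode", "surface", "space", "x", "y", "z")
  miss <- setdiff(req, names(points))
  if (length(miss) > 0)
    stop("points missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(points) > 0) {
    if (any(!nzchar(points$electrode)))
      stop("electrode labels must be non-empty", call. = FALSE)
    if (!all(points$surface %in% c("scalp", "cortex")))
      stop("surface must be 'scalp' or 'cortex'", call. = FALSE)
    if (!all(points$space %in% c("subject", "mni")))
      stop("space must be 'subject' or 'mni'", call. = FALSE)
    if (any(!is.finite(base::as.matrix(points[, c("x", "y", "z")]))))
      stop("coordinates must be finite", call. = FALSE)
  }
  points
}

# Full-precision number formatting for text round-trips.
fmt_num <- function(x) formatC(x, digits = 17, format = "g")

#' Read an electrode target file
#'
#' Parses a plain-text target table in the dialect of neuro-navigation
#' review exports: one row per electrode, `label, x, y, z` separated by
#' tabs or commas, coordinates in mm. Lines starting with `#` and a single
#' optional header row are skipped; extra trailing columns (e.g.
#' orientation vectors in real exports) are tolerated and ignored.
#'
#' @param path File to read.
#' @param subject_id Subject id to stamp on the points.
#' @param surface `"scalp"` or `"cortex"`.
#' @param space Coordinate space of the file, default `"subject"`.
#' @return An electrode points data.frame (possibly 0 rows).
#' @export
read_targets <- function(path, subject_id, surface, space = "subject") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  parse_row <- function(ln) {
    sep <- if (grepl("\t", ln)) "\t" else ","
    trimws(strsplit(ln, sep, fixed = TRUE)[[1]])
  }
  rows <- lapply(lines, parse_row)
  # a single optional header row: coordinates fields not numeric
  is_header <- function(f) length(f) >= 4 &&
    any(is.na(suppressWarnings(as.numeric(f[2:4]))))
  if (length(rows) > 0 && is_header(rows[[1]])) {
    rows <- rows[-1]; lineno <- lineno[-1]
  }
  if (length(rows) == 0)
    return(electrode_points(character(), character(), character(),
                            character(), numeric(), numeric(), numeric()))
  labels <- character(length(rows))
  xyz <- base::matrix(NA_real_, length(rows), 3)
  for (i in seq_along(rows)) {
    f <- rows[[i]]
    if (length(f) < 4)
      stop(sprintf("%s: line %d has %d field(s), need at least 4 (label, x, y, z)",
                   path, lineno[i], length(f)), call. = FALSE)
    v <- suppressWarnings(as.numeric(f[2:4]))
    if (any(is.na(v)) || any(!is.finite(v)))
      stop(sprintf("%s: line %d has non-numeric coordinates", path,
                   lineno[i]), call. = FALSE)
    labels[i] <- f[1]
    xyz[i, ] <- v
  }
  dup <- unique(labels[duplicated(labels)])
  if (length(dup) > 0)
    stop(sprintf("%s: duplicate electrode label(s): %s", path,
                 paste(dup, collapse = ", ")), call. = FALSE)
  electrode_points(subject_id, labels, surface, space,
                   xyz[, 1], xyz[, 2], xyz[, 3])
}

#' Write an electrode target file
#'
#' Writes the strict form of the target dialect: a header row then
#' tab-separated `label, x, y, z` rows at full precision, so that
#' `read_targets()` round-trips exactly.
#'
#' @param points Electrode points for one subject and surface.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_targets <- function(points, path) {
  points <- validate_points(points)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("label\tx\ty\tz", con)
  if (nrow(points) > 0)
    writeLines(paste(points$electrode, fmt_num(points$x), fmt_num(points$y),
                     fmt_num(points$z), sep = "\t"), con)
  invisible(path)
}

#' Read a 4x4 affine matrix file
#'
#' Parses a whitespace-separated 4x4 matrix (the subject-to-MNI matrix as
#' written by SPM-style normalization), validating the homogeneous last
#' row and invertibility.
#'
#' @param path File containing 16 whitespace-separated numbers (4 rows).
#' @param from,to Space names to attach, defaults subject -> mni.
#' @return An [affine_transform()].
#' @export
read_affine <- function(path, from = "subject", to = "mni") {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(
    lines[nzchar(trimws(lines))]), "\\s+|,"))))
  if (length(vals) != 16 || any(is.na(vals)))
    stop(path, ": expected a 4x4 numeric matrix (16 values)", call. = FALSE)
  affine_transform(base::matrix(vals, 4, 4, byrow = TRUE),
                   from = from, to = to)
}

#' Write a 4x4 affine matrix file
#' @param transform An [affine_transform()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_affine <- function(transform, path) {
  stopifnot(is_affine(transform))
  rows <- apply(transform$matrix, 1, function(r)
    paste(fmt_num(r), collapse = " "))
  writeLines(rows, path)
  invisible(path)
}

#' Read or write a cohort manifest
#'
#' The manifest is a YAML file binding the per-subject artifacts together:
#' for each subject its id, cap size (cm, optional), scalp target file,
#' optional cortex target file, subject-to-MNI affine file, and optional
#' brain-mask NIfTI for scalp-to-cortex projection. Relative paths are
#' resolved against the manifest's directory.
#'
#' @param path Manifest file.
#' @param check_paths Verify that referenced files exist (default `TRUE`).
#' @return A list of class `cohort_manifest` with element `subjects`, a
#'   list of per-subject records.
#' @export
read_manifest <- function(path, check_paths = TRUE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  if (is.null(raw$subjects) || length(raw$subjects) == 0)
    stop(path, ": manifest has no subjects", call. = FALSE)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    if (grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  subjects <- lapply(raw$subjects, function(s) {
    if (is.null(s$subject_id) || is.null(s$scalp_targets) ||
        is.null(s$affine))
      stop(path, ": each subject needs subject_id, scalp_targets, affine",
           call. = FALSE)
    list(subject_id = as.character(s$subject_id),
         cap_size_cm = if (is.null(s$cap_size_cm)) NA_real_ else
           as.numeric(s$cap_size_cm),
         scalp_targets = resolve(s$scalp_targets),
         cortex_targets = resolve(s$cortex_targets),
         affine = resolve(s$affine),
         brain_mask = resolve(s$brain_mask))
  })
  ids <- vapply(subjects, `[[`, "", "subject_id")
  if (anyDuplicated(ids))
    stop(path, ": duplicate subject ids", call. = FALSE)
  if (check_paths) {
    for (s in subjects) {
      for (field in c("scalp_targets", "cortex_targets", "affine",
                      "brain_mask")) {
        p <- s[[field]]
        if (!is.null(p) && !file.exists(p))
          stop(sprintf("%s: subject %s references missing file %s",
                       path, s$subject_id, p), call. = FALSE)
      }
    }
  }
  structure(list(subjects = subjects), class = "cohort_manifest")
}

#' @rdname read_manifest
#' @param manifest A `cohort_manifest` (paths taken as given).
#' @export
write_manifest <- function(manifest, path) {
  subjects <- lapply(manifest$subjects, function(s)
    Filter(Negate(is.null), list(
      subject_id = s$subject_id,
      cap_size_cm = if (!is.null(s$cap_size_cm) && !is.na(s$cap_size_cm))
        s$cap_size_cm,
      scalp_targets = s$scalp_targets,
      cortex_targets = s$cortex_targets,
      affine = s$affine,
      brain_mask = s$brain_mask)))
  yaml::write_yaml(list(subjects = subjects), path)
  invisible(path)
}

#' Write per-electrode summary statistics to CSV
#'
#' Columns: `electrode`, `surface`, `n`, `mean_x/y/z`, `sd_x/y/z`,
#' `skew_x/y/z`, `overall_deviation`, sorted by electrode label. This is
#' the on-disk form of the per-electrode mean/SD table plus the
#' supplementary skewness columns.
#'
#' @param summaries Data.frame of electrode summaries
#'   (see [summarize_electrodes()]).
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  if (nrow(summaries) == 0) stop("no summaries to write", call. = FALSE)
  cols <- c("electrode", "surface", "n", "mean_x", "mean_y", "mean_z",
            "sd_x", "sd_y", "sd_z", "skew_x", "skew_y", "skew_z",
            "overall_deviation")
  out <- summaries[order(summaries$electrode), cols]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a summary CSV written by [write_summary_csv()]
#' @param path CSV file.
#' @return The summaries data.frame.
#' @export
read_summary_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(electrode = "character",
                                 surface = "character"))
}

#' Write per-electrode region tallies to CSV
#'
#' Long-format breakdown of underlying brain regions: columns `electrode`,
#' `usable_n`, `region`, `percent`, one row per (electrode, region),
#' sorted by electrode then descending percent.
#'
#' @param tallies Data.frame from [tally_cohort()].
#' @param path Output CSV.
#' @return `path`, invisibly.
#' @export
write_tally_csv <- function(tallies, path) {
  if (nrow(tallies) == 0) stop("no tallies to write", call. = FALSE)
  out <- tallies[order(tallies$electrode, -tallies$percent,
                       tallies$region), ]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Published per-electrode MNI summary of a 20-subject 10-10 cohort
#'
#' Loads the bundled reference table of published electrode position
#' statistics: for each of the 65 electrodes of a 64-channel 10-10 cap
#' (plus ground and reference), the across-subject mean and standard
#' deviation of its MNI coordinates, measured in 20 adults both on the
#' scalp and projected onto the cortical surface. Useful as a benchmark
#' input for the summary statistics (grand SDs, extreme-electrode
#' rankings) without access to the underlying scans.
#'
#' @return A data.frame with columns `electrode`, and
#'   `scalp_mean_x/sd_x/...`, `cortex_mean_x/sd_x/...` (mm), 65 rows.
#' @export
published_reference_summary <- function() {
  path <- system.file("extdata", "published_mni_electrode_summary.csv",
                      package = "electrovar", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Recast the published reference table as electrode summaries
#'
#' @param surface `"scalp"` or `"cortex"`: which coordinate set to
#'   extract.
#' @param n Number of subjects behind the published table (20).
#' @return An electrode-summaries data.frame as produced by
#'   [summarize_electrodes()] (skewness columns `NA`: not published
#'   per electrode at full precision).
#' @export
reference_summaries <- function(surface = c("scalp", "cortex"), n = 20L) {
  surface <- match.arg(surface)
  ref <- published_reference_summary()
  pre <- paste0(surface, "_")
  out <- data.frame(
    electrode = ref$electrode, surface = surface, n = n,
    mean_x = ref[[paste0(pre, "mean_x")]],
    mean_y = ref[[paste0(pre, "mean_y")]],
    mean_z = ref[[paste0(pre, "mean_z")]],
    sd_x = ref[[paste0(pre, "sd_x")]],
    sd_y = ref[[paste0(pre, "sd_y")]],
    sd_z = ref[[paste0(pre, "sd_z")]],
    skew_x = NA_real_, skew_y = NA_real_, skew_z = NA_real_,
    stringsAsFactors = FALSE)
  out$overall_deviation <- (out$sd_x + out$sd_y + out$sd_z) / 3
  out
}
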