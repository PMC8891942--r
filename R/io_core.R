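#' Brain mask container
#'
#' A brain mask fixes three things shared by every stage of the pipeline:
#' the grid shape, which voxels are analysed, and the single grid-to-world
#' affine (0-based voxel indices to mm). All per-voxel vectors in the
#' package follow the mask's in-mask ordering, which is the natural array
#' order of the grid, so maps are comparable across subjects that share a
#' normalized space.
#'
#' @param mask logical 3D array (TRUE = in mask).
#' @param affine 4x4 numeric grid-to-world matrix; must be invertible.
#' @return an object of class `brain_mask` with fields `mask`, `dim`,
#'   `affine` and `indices` (linear grid indices of in-mask voxels).
#' @export
brain_mask <- function(mask, affine = diag(4)) {
  if (!is.array(mask) || length(dim(mask)) != 3L) {
    stop("`mask` must be a logical 3D array")
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (anyNA(mask)) stop("mask contains NA")
  if (!any(mask)) stop("mask has no TRUE voxel")
  stopifnot(is.matrix(affine), all(dim(affine) == c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps) stop("mask affine is not invertible")
  structure(
    list(mask = mask, dim = dim(mask), affine = affine,
         indices = which(mask)),
    class = "brain_mask"
  )
}

#' @export
print.brain_mask <- function(x, ...) {
  cat(sprintf("brain_mask: grid %s, %d in-mask voxels\n",
              paste(x$dim, collapse = "x"), length(x$indices)))
  invisible(x)
}

#' Number of in-mask voxels
#' @param mask a `brain_mask`.
#' @export
n_voxels <- function(mask) length(mask$indices)

#' 0-based grid coordinates of in-mask voxels
#'
#' @param mask a `brain_mask`.
#' @return integer matrix, one row per in-mask voxel, columns i/j/k
#'   (0-based, matching the NIfTI affine convention).
#' @export
voxel_coords <- function(mask) {
  arr <- arrayInd(mask$indices, mask$dim)
  storage.mode(arr) <- "integer"
  arr - 1L
}

#' World (mm) coordinates of in-mask voxels
#' @param mask a `brain_mask`.
#' @export
voxel_world_coords <- function(mask) {
  ijk <- voxel_coords(mask)
  xyz <- cbind(ijk, 1) %*% t(mask$affine[1:3, , drop = FALSE])
  colnames(xyz) <- c("x", "y", "z")
  xyz
}

#' Read / write a brain mask as NIfTI
#' @param path file path (`.nii` or `.nii.gz`).
#' @param threshold values strictly above this count as in-mask on read.
#' @rdname mask_io
#' @export
read_mask <- function(path, threshold = 0.5) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3L) stop("mask volume must be 3D: ", path)
  brain_mask(nii$data > threshold, nii$affine)
}

#' @param mask a `brain_mask`.
#' @rdname mask_io
#' @export
write_mask <- function(mask, path) {
  write_nifti(array(as.double(mask$mask), dim = mask$dim), mask$affine, path)
}

#' One subject's masked BOLD time series
#'
#' @param subject_id character scalar.
#' @param data time-by-voxel numeric matrix (arbitrary units); columns
#'   follow the mask's in-mask ordering.
#' @param mask the `brain_mask` the series were extracted with.
#' @param tr sampling interval in seconds; must be positive.
#' @param frame_keep logical per time point, TRUE = retained after
#'   scrubbing. Defaults to all TRUE.
#' @return an object of class `bold_dataset`.
#' @export
bold_dataset <- function(subject_id, data, mask, tr, frame_keep = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("BOLD data must be numeric")
  if (nrow(data) < 2L) stop("BOLD series needs at least 2 time points")
  if (ncol(data) != n_voxels(mask)) {
    stop(sprintf("BOLD has %d voxels but mask has %d in-mask voxels",
                 ncol(data), n_voxels(mask)))
  }
  if (!is.numeric(tr) || length(tr) != 1L || !is.finite(tr) || tr <= 0) {
    stop("`tr` must be a positive number (seconds)")
  }
  if (is.null(frame_keep)) frame_keep <- rep(TRUE, nrow(data))
  stopifnot(is.logical(frame_keep), length(frame_keep) == nrow(data))
  structure(
    list(subject_id = as.character(subject_id), data = data, mask = mask,
         tr = tr, frame_keep = frame_keep),
    class = "bold_dataset"
  )
}

#' @export
print.bold_dataset <- function(x, ...) {
  cat(sprintf("bold_dataset '%s': %d frames (%d retained) x %d voxels, TR %gs\n",
              x$subject_id, nrow(x$data), sum(x$frame_keep), ncol(x$data), x$tr))
  invisible(x)
}

#' Read a 4D BOLD NIfTI restricted to a mask
#'
#' The volume grid and affine must match the mask (affines to 1e-4 mm).
#'
#' @param path 3D+time NIfTI file.
#' @param mask a `brain_mask` on the same grid.
#' @param subject_id defaults to the file name without extension.
#' @return a `bold_dataset` with all frames retained.
#' @export
read_bold <- function(path, mask, subject_id = NULL) {
  nii <- read_nifti(path)
  d <- dim(nii$data)
  if (length(d) != 4L) stop("expected a 4D volume: ", path)
  if (!all(d[1:3] == mask$dim)) {
    stop(sprintf("grid mismatch: volume %s vs mask %s",
                 paste(d[1:3], collapse = "x"), paste(mask$dim, collapse = "x")))
  }
  if (max(abs(nii$affine - mask$affine)) > 1e-4) {
    stop("affine mismatch between volume and mask: ", path)
  }
  if (d[4] < 2L) stop("fewer than 2 time points in ", path)
  flat <- matrix(nii$data, prod(d[1:3]), d[4])
  if (is.null(subject_id)) {
    subject_id <- sub("\\.nii(\\.gz)?$", "", basename(path))
  }
  tr <- if (is.finite(nii$tr) && nii$tr > 0) nii$tr else 1
  bold_dataset(subject_id, t(flat[mask$indices, , drop = FALSE]), mask, tr)
}

#' Write a `bold_dataset` back to a 4D NIfTI (zeros outside the mask)
#' @param bold a `bold_dataset`.
#' @param path output path.
#' @export
write_bold <- function(bold, path) {
  d <- c(bold$mask$dim, nrow(bold$data))
  flat <- matrix(0, prod(bold$mask$dim), nrow(bold$data))
  flat[bold$mask$indices, ] <- t(bold$data)
  write_nifti(array(flat, dim = d), bold$mask$affine, path, tr = bold$tr)
}

#' Write / read a per-voxel statistic map
#'
#' Values are placed at in-mask cells (mask order); everything outside the
#' mask is exactly zero.
#'
#' @param values numeric, one value per in-mask voxel.
#' @param mask a `brain_mask`.
#' @param path output NIfTI path.
#' @rdname stat_map_io
#' @export
write_stat_map <- function(values, mask, path) {
  if (length(values) != n_voxels(mask)) {
    stop(sprintf("expected %d values (one per in-mask voxel), got %d",
                 n_voxels(mask), length(values)))
  }
  vol <- array(0, dim = mask$dim)
  vol[mask$indices] <- as.double(values)
  write_nifti(vol, mask$affine, path)
}

#' @rdname stat_map_io
#' @return `read_stat_map()` returns the in-mask values in mask order.
#' @export
read_stat_map <- function(path, mask) {
  nii <- read_nifti(path)
  if (length(dim(nii$data)) != 3L || !all(dim(nii$data) == mask$dim)) {
    stop("stat map grid does not match mask: ", path)
  }
  as.double(nii$data[mask$indices])
}

.group_levels <- c("GI_MDD", "NGI_MDD", "HC")
.gender_levels <- c("male", "female")

.subject_required_cols <- c("subject_id", "group", "age", "gender", "education")
.subject_numeric_cols <- c(
  "age", "education", "mean_fd", "illness_duration", "hrsd17_total",
  "anxiety_somatization", "weight_loss", "cognitive_disturbance",
  "retardation", "sleep_disturbance", "gi_item"
)

#' Read the subject table
#'
#' Tab-separated UTF-8 with a header row; empty fields are missing values.
#' Required columns: `subject_id`, `group` (GI_MDD / NGI_MDD / HC), `age`,
#' `gender` (male / female), `education`. Recognised optional columns:
#' `mean_fd`, `illness_duration`, `hrsd17_total`, the five HRSD-17 factor
#' scores (`anxiety_somatization`, `weight_loss`, `cognitive_disturbance`,
#' `retardation`, `sleep_disturbance`) and `gi_item` (HRSD item 12).
#'
#' @param path TSV file path.
#' @return a `data.frame` of class `subject_table`.
#' @export
read_subject_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, na.strings = "",
                          check.names = FALSE)
  validate_subject_table(df)
}

#' Validate (and type) a subject data frame
#' @param df a data frame with the columns documented in
#'   [read_subject_table()].
#' @export
validate_subject_table <- function(df) {
  missing_cols <- setdiff(.subject_required_cols, names(df))
  if (length(missing_cols)) {
    stop("subject table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  bad_group <- which(!df$group %in% .group_levels)
  if (length(bad_group)) {
    stop("unknown group label in row(s) ", paste(bad_group, collapse = ", "),
         ": ", paste(unique(df$group[bad_group]), collapse = ", "),
         " (expected ", paste(.group_levels, collapse = "/"), ")")
  }
  bad_gender <- which(!df$gender %in% .gender_levels)
  if (length(bad_gender)) {
    stop("unknown gender in row(s) ", paste(bad_gender, collapse = ", "))
  }
  for (col in intersect(.subject_numeric_cols, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  core <- c("age", "education")
  bad <- which(rowSums(is.na(df[core])) > 0)
  if (length(bad)) {
    stop("missing covariate value(s) in row(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.na(df$hrsd17_total) & df$hrsd17_total < 0)) {
    stop("hrsd17_total must be non-negative")
  }
  df$subject_id <- as.character(df$subject_id)
  class(df) <- c("subject_table", "data.frame")
  df
}

#' @rdname read_subject_table
#' @param table a subject table.
#' @export
write_subject_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a rigid-body motion trace
#'
#' TSV with header `trans_x  trans_y  trans_z  rot_x  rot_y  rot_z`:
#' translations in mm, rotations in radians, one row per retained volume.
#'
#' @param path TSV path.
#' @return a list of class `motion_trace` with a time-by-6 `params` matrix.
#' @rdname motion_io
#' @export
read_motion <- function(path, subject_id = NULL) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE)
  motion_cols <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  missing_cols <- setdiff(motion_cols, names(df))
  if (length(missing_cols)) {
    stop("motion file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(subject_id)) subject_id <- sub("\\.[^.]*$", "", basename(path))
  motion_trace(subject_id, as.matrix(df[motion_cols]))
}

#' @param subject_id character scalar.
#' @param params time-by-6 numeric matrix (3 translations mm, 3 rotations rad).
#' @rdname motion_io
#' @export
motion_trace <- function(subject_id, params) {
  params <- as.matrix(params)
  if (ncol(params) != 6L) stop("motion trace must have 6 columns")
  if (nrow(params) < 1L) stop("motion trace is empty")
  if (any(!is.finite(params))) stop("motion trace contains non-finite values")
  colnames(params) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
  structure(list(subject_id = as.character(subject_id), params = params),
            class = "motion_trace")
}

#' @param motion a `motion_trace`.
#' @rdname motion_io
#' @export
write_motion <- function(motion, path) {
  utils::write.table(as.data.frame(motion$params), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run configuration
#'
#' One declarative home for every analysis threshold, with the conventional
#' defaults: connectivity threshold r > 0.2, scrubbing at FD > 0.2 mm,
#' band-pass 0.01-0.08 Hz, motion exclusion at 2 mm / 2 degrees, FDR alpha
#' 0.05, 26-connectivity clusters.
#'
#' @param fc_threshold correlations at or below this are discarded before
#'   Fisher-z averaging; must be in `[0, 1)`.
#' @param fd_scrub_threshold_mm frames with FD above this are censored.
#' @param bandpass_hz length-2 numeric, (low, high) in Hz.
#' @param max_translation_mm,max_rotation_deg subject-level exclusion rule.
#' @param alpha_fdr FDR significance level.
#' @param cluster_connectivity 6, 18 or 26.
#' @param min_cluster_extent smallest reported cluster size in voxels.
#' @param svm_kernel,svm_cost SVM settings (`"radial"` or `"linear"`; cost C).
#' @param seed integer random seed recorded with runs.
#' @export
pas_config <- function(fc_threshold = 0.2,
                       fd_scrub_threshold_mm = 0.2,
                       bandpass_hz = c(0.01, 0.08),
                       max_translation_mm = 2,
                       max_rotation_deg = 2,
                       alpha_fdr = 0.05,
                       cluster_connectivity = 26,
                       min_cluster_extent = 0,
                       svm_kernel = "radial",
                       svm_cost = 1,
                       seed = 1L) {
  if (fc_threshold < 0 || fc_threshold >= 1) stop("fc_threshold must be in [0, 1)")
  if (length(bandpass_hz) != 2L || bandpass_hz[1] <= 0 ||
      bandpass_hz[1] >= bandpass_hz[2]) {
    stop("bandpass_hz must satisfy 0 < low < high")
  }
  if (max_translation_mm <= 0 || max_rotation_deg <= 0) {
    stop("motion exclusion thresholds must be positive")
  }
  if (alpha_fdr <= 0 || alpha_fdr >= 1) stop("alpha_fdr must be in (0, 1)")
  if (!cluster_connectivity %in% c(6, 18, 26)) {
    stop("cluster_connectivity must be 6, 18 or 26")
  }
  if (min_cluster_extent < 0) stop("min_cluster_extent must be >= 0")
  if (!svm_kernel %in% c("radial", "linear")) {
    stop("svm_kernel must be 'radial' or 'linear'")
  }
  structure(
    list(fc_threshold = fc_threshold,
         fd_scrub_threshold_mm = fd_scrub_threshold_mm,
         bandpass_hz = as.numeric(bandpass_hz),
         max_translation_mm = max_translation_mm,
         max_rotation_deg = max_rotation_deg,
         alpha_fdr = alpha_fdr,
         cluster_connectivity = as.integer(cluster_connectivity),
         min_cluster_extent = as.integer(min_cluster_extent),
         svm_kernel = svm_kernel,
         svm_cost = svm_cost,
         seed = as.integer(seed)),
    class = "pas_config"
  )
}

#' Read / write a run configuration file
#'
#' Plain `key<TAB>value` text; unknown keys are an error so typos are loud.
#' Values are validated through [pas_config()] on load.
#'
#' @param path config file path.
#' @rdname config_io
#' @export
read_config <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed config line(s): ", paste(lines[bad], collapse = "; "))
  keys <- vapply(parts, `[[`, "", 1L)
  vals <- vapply(parts, `[[`, "", 2L)
  args <- formals(pas_config)
  known <- c(names(args)[names(args) != "bandpass_hz"], "bandpass_low_hz", "bandpass_high_hz")
  unknown <- setdiff(keys, known)
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  kv <- stats::setNames(as.list(vals), keys)
  num <- function(k, default) if (k %in% keys) as.numeric(kv[[k]]) else default
  chr <- function(k, default) if (k %in% keys) kv[[k]] else default
  pas_config(
    fc_threshold = num("fc_threshold", 0.2),
    fd_scrub_threshold_mm = num("fd_scrub_threshold_mm", 0.2),
    bandpass_hz = c(num("bandpass_low_hz", 0.01), num("bandpass_high_hz", 0.08)),
    max_translation_mm = num("max_translation_mm", 2),
    max_rotation_deg = num("max_rotation_deg", 2),
    alpha_fdr = num("alpha_fdr", 0.05),
    cluster_connectivity = num("cluster_connectivity", 26),
    min_cluster_extent = num("min_cluster_extent", 0),
    svm_kernel = chr("svm_kernel", "radial"),
    svm_cost = num("svm_cost", 1),
    seed = num("seed", 1)
  )
}

#' @param config a `pas_config`.
#' @rdname config_io
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pas_config"))
  kv <- c(
    fc_threshold = config$fc_threshold,
    fd_scrub_threshold_mm = config$fd_scrub_threshold_mm,
    bandpass_low_hz = config$bandpass_hz[1],
    bandpass_high_hz = config$bandpass_hz[2],
    max_translation_mm = config$max_translation_mm,
    max_rotation_deg = config$max_rotation_deg,
    alpha_fdr = config$alpha_fdr,
    cluster_connectivity = config$cluster_connectivity,
    min_cluster_extent = config$min_cluster_extent,
    svm_cost = config$svm_cost,
    seed = config$seed
  )
  lines <- c(sprintf("%s\t%.15g", names(kv), as.numeric(kv)),
             sprintf("svm_kernel\t%s", config$svm_kernel))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
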