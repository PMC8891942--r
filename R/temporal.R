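#' Framewise displacement (Power convention)
#'
#' FD at frame t (t >= 2) is the sum of absolute backward differences of
#' the six rigid-body parameters, with rotations converted to arc length on
#' a sphere of `rotation_radius_mm` (50 mm by convention). The first frame
#' has FD 0 by definition.
#'
#' @param motion a `motion_trace` (translations mm, rotations radians).
#' @param rotation_radius_mm sphere radius for the rotation-to-mm mapping.
#' @return numeric FD series (mm), same length as the trace.
#' @export
framewise_displacement <- function(motion, rotation_radius_mm = 50) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  if (nrow(p) < 2L) stop("framewise displacement needs >= 2 time points")
  if (!is.finite(rotation_radius_mm) || rotation_radius_mm <= 0) {
    stop("rotation_radius_mm must be a positive finite number")
  }
  d <- abs(diff(p))
  fd <- c(0, rowSums(d[, 1:3, drop = FALSE]) +
            rotation_radius_mm * rowSums(d[, 4:6, drop = FALSE]))
  fd
}

#' Subject-level motion exclusion rule
#'
#' Excludes a subject when any translation exceeds `max_translation_mm` or
#' any rotation exceeds `max_rotation_deg` (strict inequalities; rotations
#' stored in radians are compared in degrees).
#'
#' @param motion a `motion_trace`.
#' @param max_translation_mm,max_rotation_deg exclusion thresholds.
#' @return TRUE if the subject should be excluded.
#' @export
exclude_subject_by_motion <- function(motion, max_translation_mm = 2,
                                      max_rotation_deg = 2) {
  stopifnot(inherits(motion, "motion_trace"))
  if (max_translation_mm <= 0 || max_rotation_deg <= 0) {
    stop("motion thresholds must be positive")
  }
  p <- motion$params
  any(abs(p[, 1:3]) > max_translation_mm) ||
    any(abs(p[, 4:6]) * 180 / pi > max_rotation_deg)
}

#' Friston-24 motion confound expansion
#'
#' The 6 rigid-body parameters, their one-frame-back values (first row
#' zero-padded), and the element-wise squares of both sets: 24 regressors.
#'
#' @param motion a `motion_trace`.
#' @return time-by-24 numeric matrix with descriptive column names.
#' @export
friston24 <- function(motion) {
  stopifnot(inherits(motion, "motion_trace"))
  p <- motion$params
  if (nrow(p) < 2L) stop("Friston-24 expansion needs >= 2 time points")
  lagged <- rbind(0, p[-nrow(p), , drop = FALSE])
  out <- cbind(p, lagged, p^2, lagged^2)
  base <- colnames(motion$params)
  colnames(out) <- c(base, paste0(base, "_lag"),
                     paste0(base, "_sq"), paste0(base, "_lag_sq"))
  out
}

#' Build a full confound matrix (motion + tissue signals)
#'
#' @param motion a `motion_trace`.
#' @param csf,wm optional mean cerebrospinal-fluid / white-matter signals
#'   (numeric, one value per frame). Tissue segmentation itself is upstream
#'   of this package; the signals arrive as columns.
#' @return time-by-regressor matrix (24 motion terms plus any tissue columns).
#' @export
confound_matrix <- function(motion, csf = NULL, wm = NULL) {
  out <- friston24(motion)
  n <- nrow(out)
  if (!is.null(csf)) {
    if (length(csf) != n) stop("csf signal length != number of frames")
    out <- cbind(out, csf = as.numeric(csf))
  }
  if (!is.null(wm)) {
    if (length(wm) != n) stop("wm signal length != number of frames")
    out <- cbind(out, wm = as.numeric(wm))
  }
  out
}

#' Regress confounds out of every voxel series
#'
#' Each voxel series is replaced by its least-squares residual against an
#' intercept plus the confound columns. Rank-deficient designs are handled
#' through the singular value decomposition (minimum-norm projection), so
#' duplicated or constant-zero confounds are harmless.
#'
#' @param bold a `bold_dataset`.
#' @param confounds time-by-regressor numeric matrix (no intercept needed).
#' @return a `bold_dataset` of residuals.
#' @export
regress_confounds <- function(bold, confounds) {
  stopifnot(inherits(bold, "bold_dataset"))
  confounds <- as.matrix(confounds)
  if (nrow(confounds) != nrow(bold$data)) {
    stop(sprintf("confounds have %d rows but BOLD has %d frames",
                 nrow(confounds), nrow(bold$data)))
  }
  X <- cbind(1, confounds)
  sv <- svd(X)
  keep <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  U <- sv$u[, keep, drop = FALSE]
  resid <- bold$data - U %*% crossprod(U, bold$data)
  bold$data <- resid
  bold
}

#' Linear detrend and Fourier band-pass filter
#'
#' Removes each voxel's linear trend, then zeroes every Fourier component
#' whose frequency falls outside `[low_hz, high_hz]` (hard frequency-domain
#' mask; the DC component is always removed). Applied to the full series
#' before any scrubbing, so the spectral estimate is well defined.
#'
#' @param bold a `bold_dataset`.
#' @param low_hz,high_hz pass band in Hz; requires
#'   `0 < low_hz < high_hz < 1 / (2 * tr)`.
#' @return a filtered `bold_dataset` (voxelwise mean ~ 0).
#' @export
detrend_and_bandpass <- function(bold, low_hz = 0.01, high_hz = 0.08) {
  stopifnot(inherits(bold, "bold_dataset"))
  nyquist <- 1 / (2 * bold$tr)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    stop(sprintf("band [%g, %g] Hz must satisfy 0 < low < high < Nyquist (%g Hz)",
                 low_hz, high_hz, nyquist))
  }
  n <- nrow(bold$data)
  t_idx <- seq_len(n)
  X <- cbind(1, t_idx - mean(t_idx))
  beta <- solve(crossprod(X), crossprod(X, bold$data))
  detr <- bold$data - X %*% beta

  freqs <- (seq_len(n) - 1) / (n * bold$tr)
  folded <- pmin(freqs, 1 / bold$tr - freqs)   # two-sided spectrum
  keep <- folded >= low_hz & folded <= high_hz
  keep[1] <- FALSE                              # DC always removed
  fy <- stats::mvfft(detr)
  fy[!keep, ] <- 0
  bold$data <- Re(stats::mvfft(fy, inverse = TRUE)) / n
  bold
}

#' Scrub high-motion frames
#'
#' Marks frames with FD strictly above `threshold_mm` as censored;
#' downstream correlation uses retained frames only (censored frames are
#' deleted, not interpolated). Fewer than 3 retained frames is allowed here
#' but will make any later correlation fail, so a warning is raised.
#'
#' @param bold a `bold_dataset`.
#' @param fd numeric FD series, one value per frame.
#' @param threshold_mm censoring threshold (mm).
#' @return the `bold_dataset` with an updated `frame_keep` mask.
#' @export
scrub <- function(bold, fd, threshold_mm = 0.2) {
  stopifnot(inherits(bold, "bold_dataset"))
  if (length(fd) != nrow(bold$data)) {
    stop(sprintf("FD has %d values but BOLD has %d frames",
                 length(fd), nrow(bold$data)))
  }
  if (any(fd < 0)) stop("FD values must be non-negative")
  keep <- bold$frame_keep & (fd <= threshold_mm)
  if (sum(keep) < 3L) {
    warning(sprintf("only %d frame(s) retained after scrubbing; correlation will fail",
                    sum(keep)))
  }
  bold$frame_keep <- keep
  bold
}

#' Per-subject motion quality-control summary
#'
#' @param motion a `motion_trace`.
#' @param fd optional precomputed FD series.
#' @param fd_threshold_mm scrubbing threshold used for the retained count.
#' @return one-row data frame: max translation (mm), max rotation (deg),
#'   mean FD (mm), frames retained / total.
#' @export
motion_qc <- function(motion, fd = NULL, fd_threshold_mm = 0.2) {
  if (is.null(fd)) fd <- framewise_displacement(motion)
  p <- motion$params
  data.frame(
    subject_id = motion$subject_id,
    max_translation_mm = max(abs(p[, 1:3])),
    max_rotation_deg = max(abs(p[, 4:6])) * 180 / pi,
    mean_fd = mean(fd),
    frames_retained = sum(fd <= fd_threshold_mm),
    frames_total = nrow(p),
    stringsAsFactors = FALSE
  )
}
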