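#' Temporal preprocessing configuration
#'
#' @param fd_threshold framewise-displacement censoring threshold, mm.
#' @param detrend_order polynomial detrend order (>= 0).
#' @param bandpass pass band `c(low, high)` in Hz; must satisfy
#'   `0 < low < high < 1/(2 tr)`.
#' @param head_radius radius (mm) used to convert rotation increments to arc
#'   displacement in the FD sum.
#' @param min_kept_frames minimum surviving frames after censoring.
#' @param filter_before_censor if `TRUE`, band-pass the full series before
#'   frame deletion instead of filtering the concatenated kept frames.
#' @return list of class `preproc_config`.
#' @export
preproc_config <- function(fd_threshold = 0.2, detrend_order = 3L,
                           bandpass = c(0.01, 0.10), head_radius = 50,
                           min_kept_frames = 50L, filter_before_censor = FALSE) {
  stopifnot(fd_threshold > 0, detrend_order >= 0, length(bandpass) == 2,
            bandpass[1] > 0, bandpass[1] < bandpass[2], head_radius > 0,
            min_kept_frames >= 4)
  structure(list(fd_threshold = fd_threshold, detrend_order = as.integer(detrend_order),
                 bandpass = bandpass, head_radius = head_radius,
                 min_kept_frames = as.integer(min_kept_frames),
                 filter_before_censor = filter_before_censor),
            class = "preproc_config")
}

#' Framewise displacement of a motion trace
#'
#' Power-style FD: per frame, the sum of absolute backward differences of the
#' three translations (mm) plus `head_radius` times the sum of absolute
#' backward differences of the three rotations (radians). The first frame has
#' FD 0 by convention.
#'
#' @param motion t x 6 matrix: translations (mm) then rotations (radians).
#' @param head_radius mm; default 50.
#' @return numeric vector of per-frame FD (mm).
#' @examples
#' m <- matrix(0, 10, 6); m[5:10, 1] <- 0.3
#' framewise_displacement(m)
#' @export
framewise_displacement <- function(motion, head_radius = 50) {
  motion <- as.matrix(motion)
  if (ncol(motion) < 6) stop("motion trace must have 6 columns")
  if (nrow(motion) < 2) stop("need at least 2 frames")
  d <- abs(diff(motion))
  c(0, rowSums(d[, 1:3, drop = FALSE]) + head_radius * rowSums(d[, 4:6, drop = FALSE]))
}

#' Censor frames by framewise displacement
#'
#' @param fd per-frame FD vector.
#' @param threshold censoring threshold, mm; frames with `fd > threshold` are dropped.
#' @param min_kept_frames error if fewer frames survive.
#' @return list of class `censor_mask`: `keep` (logical), `threshold`, `n_kept`.
#' @export
censor_frames <- function(fd, threshold = 0.2, min_kept_frames = 4L) {
  keep <- fd <= threshold
  if (sum(keep) < min_kept_frames)
    stop("too few frames survive censoring: ", sum(keep), " kept of ", length(fd),
         " (minimum ", min_kept_frames, ")")
  structure(list(keep = keep, threshold = threshold, n_kept = sum(keep)),
            class = "censor_mask")
}

# orthonormal polynomial basis incl. intercept, t x (order+1)
.poly_basis <- function(t_len, order) {
  b <- cbind(rep(1 / sqrt(t_len), t_len),
             if (order > 0) stats::poly(seq_len(t_len), degree = order))
  qr.Q(qr(b))
}

#' Remove a least-squares polynomial trend from every voxel series
#'
#' @param series_matrix voxels x time matrix.
#' @param order polynomial order (0 = demean).
#' @return residual matrix; residuals are orthogonal to the polynomial basis.
#' @export
detrend_poly <- function(series_matrix, order = 3L) {
  t_len <- ncol(series_matrix)
  if (t_len <= order + 1) stop("need t > order + 1 frames to detrend")
  q <- .poly_basis(t_len, order)
  series_matrix - (series_matrix %*% q) %*% t(q)
}

#' Regress motion confounds out of voxel series
#'
#' Ordinary least squares of each voxel series on an intercept, the 6 motion
#' parameters and their backward-difference derivatives (first row 0).
#' Constant (zero-variance) confound columns are dropped; any remaining rank
#' deficiency is an error naming the offending columns.
#'
#' @param series_matrix voxels x time matrix.
#' @param motion t x 6 motion trace.
#' @return residual matrix, orthogonal to all retained regressors.
#' @export
regress_confounds <- function(series_matrix, motion) {
  motion <- as.matrix(motion)
  if (ncol(motion) < 6) stop("motion trace must have 6 columns")
  t_len <- ncol(series_matrix)
  if (nrow(motion) != t_len) stop("motion length must match series length")
  derivs <- rbind(0, diff(motion))
  X <- cbind(motion, derivs)
  colnames(X) <- c(paste0(colnames(motion) %||% paste0("m", 1:6)),
                   paste0("d_", colnames(motion) %||% paste0("m", 1:6)))
  keep <- apply(X, 2, function(col) stats::sd(col) > 0)
  X <- X[, keep, drop = FALSE]
  X <- cbind(intercept = 1, X)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("confound matrix is rank deficient; offending columns: ",
         paste(bad, collapse = ", "))
  }
  q <- qr.Q(qrX)[, seq_len(qrX$rank), drop = FALSE]
  series_matrix - (series_matrix %*% q) %*% t(q)
}

#' Zero-phase band-pass filter voxel series
#'
#' 4th-order Butterworth band-pass applied forward and backward (zero phase),
#' row-wise over the matrix. Pass-band gain is within 10% of unity at
#' mid-band and stop-band gain below 0.1 an octave outside the edges; DC is
#' removed.
#'
#' @param series_matrix voxels x time matrix.
#' @param low,high band edges, Hz.
#' @param tr repetition time, seconds.
#' @return filtered matrix.
#' @export
bandpass <- function(series_matrix, low = 0.01, high = 0.10, tr = 2) {
  bf <- .bandpass_filter(low, high, tr)
  .filtfilt_rows(bf, series_matrix - rowMeans(series_matrix))
}

#' Preprocess one subject's scan
#'
#' Applies the temporal pipeline to every ROI matrix: polynomial detrend,
#' FD-based frame censoring (frame deletion), zero-phase band-pass of the
#' concatenated kept frames, then regression of the censored-and-filtered
#' motion confounds. The censoring decision is made once, from the
#' acquisition motion trace; a scan that already carries a censor mask is not
#' re-censored (stored kept-frame FDs are all at or below threshold), making
#' the stage idempotent.
#'
#' @param scan a `subject_scan`.
#' @param config a [preproc_config()].
#' @return the prepared `subject_scan`; `meta` gains `fd`, `keep`,
#'   `n_censored`, `preprocessed = TRUE`.
#' @export
preprocess_subject <- function(scan, config = preproc_config()) {
  stopifnot(inherits(scan, "subject_scan"))
  if (is.null(scan$motion)) stop("scan has no motion trace")
  tr <- scan$meta$tr %||% 2

  if (isTRUE(scan$meta$preprocessed)) {
    fd <- scan$meta$fd_kept
  } else {
    fd <- framewise_displacement(scan$motion, config$head_radius)
  }
  mask <- censor_frames(fd, config$fd_threshold, config$min_kept_frames)
  keep <- mask$keep

  do_filter <- function(m) bandpass(m, config$bandpass[1], config$bandpass[2], tr)
  motion_kept <- scan$motion[keep, , drop = FALSE]
  conf <- do_filter(t(motion_kept))  # filter confounds like the data
  roi <- lapply(scan$roi_data, function(m) {
    m <- detrend_poly(m, config$detrend_order)
    if (config$filter_before_censor) {
      m <- do_filter(m)[, keep, drop = FALSE]
    } else {
      m <- do_filter(m[, keep, drop = FALSE])
    }
    regress_confounds(m, t(conf))
  })

  scan$roi_data <- roi
  scan$motion <- motion_kept
  scan$meta$fd <- fd
  scan$meta$fd_kept <- fd[keep]
  scan$meta$keep <- keep
  scan$meta$n_censored <- (scan$meta$n_censored %||% 0L) + sum(!keep)
  scan$meta$preprocessed <- TRUE
  scan
}
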