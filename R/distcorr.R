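# Multivariate distance-correlation connectivity between ROI voxel patches.
# Each ROI is a voxels x time matrix; dependence between two ROIs is measured
# on the t x t matrices of Euclidean distances between time-point voxel
# patterns, after U-centering (the unbiased estimator: every row and column
# sum vanishes and the diagonal is zero).

#' Standardize each voxel's time course
#'
#' z-scores every row (voxel) to mean 0, SD 1 (denominator t - 1). Constant
#' voxels are mapped to all-zero rows with a warning.
#'
#' @param roi_matrix voxels x time matrix.
#' @return standardized matrix of the same shape.
#' @export
ztransfer_voxels <- function(roi_matrix) {
  t_len <- ncol(roi_matrix)
  if (t_len < 2) stop("need at least 2 time points")
  mu <- rowMeans(roi_matrix)
  ctr <- roi_matrix - mu
  s <- sqrt(rowSums(ctr^2) / (t_len - 1))
  degen <- s == 0
  if (any(degen)) {
    warning(sum(degen), " constant voxel(s) mapped to zero rows")
    s[degen] <- 1
  }
  ctr / s
}

#' Euclidean distances between time points of a voxel patch
#'
#' `d[t1, t2]` is the Euclidean distance between the voxel-pattern columns at
#' frames t1 and t2; symmetric with zero diagonal.
#'
#' @param roi_matrix voxels x time matrix (standardized upstream).
#' @return t x t distance matrix.
#' @export
time_distance_matrix <- function(roi_matrix) {
  as.matrix(stats::dist(t(roi_matrix)))
}

#' U-center a time-point distance matrix
#'
#' Subtracts row and column means scaled by `1/(t-2)` and adds back the grand
#' sum scaled by `1/((t-1)(t-2))`, with the diagonal forced to zero. The
#' result has every row and column sum equal to zero, which makes the plug-in
#' distance covariance an unbiased (signed) U-statistic.
#'
#' @param d t x t symmetric non-negative distance matrix, zero diagonal.
#' @return U-centered t x t matrix.
#' @export
u_center <- function(d) {
  t_len <- nrow(d)
  if (t_len < 4) stop("U-centering needs t >= 4 time points")
  rs <- rowSums(d)
  U <- d - outer(rs, rep(1, t_len)) / (t_len - 2) -
    outer(rep(1, t_len), colSums(d)) / (t_len - 2) +
    sum(d) / ((t_len - 1) * (t_len - 2))
  diag(U) <- 0
  U
}

#' Distance covariance / variance of U-centered matrices
#'
#' `dcov_u` is `sum(UA * UB) / (t (t - 3))`: an unbiased estimator that may
#' be negative for independent inputs. `dvar_u(UA)` equals `dcov_u(UA, UA)`
#' and is non-negative, zero only for an all-zero U-centered matrix.
#'
#' @param UA,UB U-centered t x t matrices (same t >= 4).
#' @return scalar.
#' @export
dcov_u <- function(UA, UB) {
  t_len <- nrow(UA)
  if (!all(dim(UA) == dim(UB))) stop("U-centered matrices must have equal shape")
  if (t_len < 4) stop("distance covariance needs t >= 4")
  sum(UA * UB) / (t_len * (t_len - 3))
}

#' @rdname dcov_u
#' @export
dvar_u <- function(UA) dcov_u(UA, UA)

#' Distance correlation between two ROI voxel patches
#'
#' Computes `sqrt(dCov / sqrt(dVar_A dVar_B))` from the U-centered time-point
#' distance matrices, clamped to 0 whenever the (signed) distance covariance
#' is non-positive, so the result lies in `[0, 1]`. If either ROI has zero
#' distance variance (a constant patch) the result is 0 with a warning.
#'
#' @param A,B voxels x time matrices with the same number of time points
#'   (t >= 4); voxel counts may differ.
#' @param standardize z-score voxels first (the pipeline default, which also
#'   makes the statistic invariant to affine rescaling of either ROI).
#' @return scalar in `[0, 1]`.
#' @examples
#' set.seed(1)
#' A <- matrix(rnorm(3 * 30), 3); dcor(A, A)
#' @export
dcor <- function(A, B, standardize = TRUE) {
  if (ncol(A) != ncol(B)) stop("ROIs must share the same number of time points")
  if (ncol(A) < 4) stop("distance correlation needs t >= 4 time points")
  if (standardize) { A <- ztransfer_voxels(A); B <- ztransfer_voxels(B) }
  UA <- u_center(time_distance_matrix(A))
  UB <- u_center(time_distance_matrix(B))
  va <- dvar_u(UA); vb <- dvar_u(UB)
  if (va <= 0 || vb <= 0) {
    warning("zero distance variance; returning dCor = 0")
    return(0)
  }
  cv <- dcov_u(UA, UB)
  if (cv <= 0) 0 else sqrt(cv / sqrt(va * vb))
}

#' Fisher z transform of a distance correlation
#'
#' `z = 0.5 log((1 + r)/(1 - r))`; values at or above `1 - 1e-7` are clamped
#' there (with a warning) since z(1) is infinite.
#'
#' @param r value in `[0, 1]`.
#' @return non-negative scalar.
#' @export
fisher_z <- function(r) {
  if (any(r < 0 | r > 1)) stop("dCor values must lie in [0, 1]")
  hi <- r >= 1 - 1e-7
  if (any(hi)) {
    warning("dCor value(s) clamped to 1 - 1e-7 before Fisher transform")
    r[hi] <- 1 - 1e-7
  }
  0.5 * log((1 + r) / (1 - r))
}

#' Subject-level connectivity matrix
#'
#' Fisher-z distance correlation between every pair of atlas nodes of a
#' prepared scan: a symmetric N x N matrix (19 x 19 for the built-in atlas)
#' with zero diagonal, node labels as dimnames, and the subject id attached.
#' U-centered distance matrices are computed once per node and reused across
#' pairs.
#'
#' @param scan a prepared `subject_scan`.
#' @param atlas the `roi_atlas` defining node order.
#' @param min_frames minimum time points required (>= 4).
#' @return matrix of class `connectivity_matrix`.
#' @export
connectivity_matrix <- function(scan, atlas = load_builtin_atlas(), min_frames = 4L) {
  labs <- atlas$nodes$label
  if (!all(labs %in% names(scan$roi_data)))
    stop("scan is missing ROI(s): ",
         paste(setdiff(labs, names(scan$roi_data)), collapse = ", "))
  t_len <- ncol(scan$roi_data[[labs[1]]])
  if (t_len < max(4L, min_frames))
    stop("scan has ", t_len, " frames; need at least ", max(4L, min_frames))
  U <- vector("list", length(labs))
  dv <- numeric(length(labs))
  for (i in seq_along(labs)) {
    Ui <- u_center(time_distance_matrix(ztransfer_voxels(scan$roi_data[[labs[i]]])))
    U[[i]] <- Ui
    dv[i] <- dvar_u(Ui)
  }
  n <- length(labs)
  z <- matrix(0, n, n, dimnames = list(labs, labs))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (dv[i] <= 0 || dv[j] <= 0) {
      warning("zero distance variance for edge ", labs[i], "-", labs[j])
      r <- 0
    } else {
      cv <- dcov_u(U[[i]], U[[j]])
      r <- if (cv <= 0) 0 else sqrt(cv / sqrt(dv[i] * dv[j]))
    }
    z[i, j] <- z[j, i] <- suppressWarnings(fisher_z(r))
  }
  structure(z, class = c("connectivity_matrix", "matrix"),
            subject_id = scan$subject_id, group = scan$group)
}

#' Write / read a connectivity matrix as labelled TSV
#' @param C a `connectivity_matrix`.
#' @param path TSV path (node labels as header row and first column).
#' @export
write_connectivity_tsv <- function(C, path) {
  df <- data.frame(node = rownames(C), as.data.frame(unclass(C)), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_connectivity_tsv
#' @export
read_connectivity_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df[[1]]
  structure(m, class = c("connectivity_matrix", "matrix"))
}
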