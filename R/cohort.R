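#' Synthetic two-group cohort configuration
#'
#' Bundles every knob of the synthetic resting-state cohort generator. The
#' generator emulates a two-group (patient vs. control) visual-network design:
#' per-network latent factors plus one global factor, all band-limited to the
#' resting-state band, drive each node's voxel patch, with the patient group's
#' intra-network coupling reduced in HVN and VSN but not PVN.
#'
#' The signal model for node i of network k in group g is
#' `s_i(t) = a * f_k(t) + b * g(t) + sqrt(1 - a^2 - b^2) * e_i(t)`
#' with `a` the subject's intra-network coupling (drawn once per subject and
#' network around the group mean `intra_coupling[[k]][g]` with SD
#' `coupling_sd`), `b = inter_coupling` the global-factor weight, and all
#' factors independent unit-variance band-limited (0.01-0.10 Hz) series.
#' Voxel v of node i is `s_i(t) + voxel_noise_sd * eta_v(t)` (white noise).
#'
#' @param n_per_group subjects per group (default 18, the study design size).
#' @param t_frames time points per scan (default 180 at `tr = 2` s).
#' @param tr repetition time, seconds.
#' @param voxels_per_roi voxels per node (default 33, a 6 mm sphere on a 3 mm grid).
#' @param intra_coupling named list (HVN, PVN, VSN), each `c(control=, patient=)`
#'   group-mean coupling in `[0, 1)`. Defaults encode the patient deficit in
#'   HVN and VSN and equal coupling in PVN.
#' @param coupling_sd between-subject SD of the per-network coupling draw.
#' @param inter_coupling global shared-factor weight `b` in `[0, 1)`.
#' @param voxel_noise_sd SD of white voxel-level noise added to the node signal.
#' @param band band-limiting edges in Hz for all latent factors.
#' @param motion_walk_sd per-frame SD (mm) of the translation random walk.
#' @param motion_rot_walk_sd per-frame SD (radians) of the rotation random walk.
#' @param motion_spike_rate per-frame probability of a motion spike.
#' @param motion_spike_mm size (mm) of a spike; spikes are persistent step
#'   offsets so each spike censors exactly one frame downstream.
#' @param acuity_params list with `patient` and `control` entries, each
#'   `c(amblyopic_mean, amblyopic_sd, fellow_mean, fellow_sd)` in logMAR.
#' @param drift_sd amplitude of an optional linear+quadratic scanner drift
#'   added to every voxel (0 disables; exercises polynomial detrending).
#' @param seed root RNG seed; per-subject seeds are derived deterministically.
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = 18L,
                          t_frames = 180L,
                          tr = 2,
                          voxels_per_roi = 33L,
                          intra_coupling = list(
                            HVN = c(control = 0.50, patient = 0.31),
                            PVN = c(control = 0.50, patient = 0.50),
                            VSN = c(control = 0.50, patient = 0.38)),
                          coupling_sd = 0.10,
                          inter_coupling = 0.30,
                          voxel_noise_sd = 1,
                          band = c(0.01, 0.10),
                          motion_walk_sd = 0.02,
                          motion_rot_walk_sd = 4e-4,
                          motion_spike_rate = 0.02,
                          motion_spike_mm = 0.5,
                          acuity_params = list(
                            patient = c(amblyopic_mean = 0.59, amblyopic_sd = 0.23,
                                        fellow_mean = 0.01, fellow_sd = 0.06),
                            control = c(amblyopic_mean = 0.02, amblyopic_sd = 0.04,
                                        fellow_mean = 0.00, fellow_sd = 0.03)),
                          drift_sd = 0,
                          seed = 1L) {
  cfg <- list(n_per_group = as.integer(n_per_group), t_frames = as.integer(t_frames),
              tr = tr, voxels_per_roi = as.integer(voxels_per_roi),
              intra_coupling = intra_coupling, coupling_sd = coupling_sd,
              inter_coupling = inter_coupling, voxel_noise_sd = voxel_noise_sd,
              band = band, motion_walk_sd = motion_walk_sd,
              motion_rot_walk_sd = motion_rot_walk_sd,
              motion_spike_rate = motion_spike_rate,
              motion_spike_mm = motion_spike_mm,
              acuity_params = acuity_params, drift_sd = drift_sd,
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

#' @rdname cohort_config
#' @export
validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_per_group >= 1, cfg$t_frames >= 10, cfg$tr > 0,
            cfg$voxels_per_roi >= 1, cfg$coupling_sd >= 0,
            cfg$inter_coupling >= 0, cfg$inter_coupling < 1,
            cfg$voxel_noise_sd >= 0,
            setequal(names(cfg$intra_coupling), c("HVN", "PVN", "VSN")))
  for (net in names(cfg$intra_coupling)) {
    a <- cfg$intra_coupling[[net]]
    if (!all(c("control", "patient") %in% names(a)))
      stop("intra_coupling$", net, " needs named control and patient values")
    if (any(a < 0 | a >= 1)) stop("intra_coupling values must lie in [0, 1)")
    bad <- a^2 + cfg$inter_coupling^2
    if (any(bad >= 1))
      stop("invalid variance budget: intra^2 + inter^2 = ", signif(max(bad), 4),
           " >= 1 for network ", net)
  }
  invisible(cfg)
}

# internal constructor shared by the generator and the ROI extractor
new_subject_scan <- function(subject_id, group, roi_data, motion = NULL,
                             acuity = NULL, meta = list()) {
  t_len <- unique(vapply(roi_data, ncol, 1L))
  if (length(t_len) != 1) stop("all ROI matrices must share the same t")
  if (!is.null(motion) && nrow(motion) != t_len)
    stop("motion trace length must equal the number of frames")
  structure(list(subject_id = subject_id, group = group, roi_data = roi_data,
                 motion = motion, acuity = acuity, meta = meta),
            class = "subject_scan")
}

#' @export
print.subject_scan <- function(x, ...) {
  cat(sprintf("subject_scan %s [%s]: %d ROIs x %d voxels x %d frames\n",
              x$subject_id, x$group, length(x$roi_data),
              nrow(x$roi_data[[1]]), ncol(x$roi_data[[1]])))
  invisible(x)
}

# band-limited unit-variance factor rows: white noise, zero-phase band-pass,
# generation padding trimmed, then standardized
.bandlimited_rows <- function(n, t, band, tr) {
  pad <- 64L
  w <- matrix(stats::rnorm(n * (t + 2L * pad)), nrow = n)
  bf <- .bandpass_filter(band[1], band[2], tr)
  f <- .filtfilt_rows(bf, w)[, pad + seq_len(t), drop = FALSE]
  f <- f - rowMeans(f)
  f / sqrt(rowSums(f^2) / (t - 1))
}

.truncnorm1 <- function(mean, sd, lo, hi) min(hi, max(lo, stats::rnorm(1, mean, sd)))

#' Simulate one subject's scan
#'
#' Draws a single subject from the generative model described in
#' [cohort_config()]: band-limited network/global/idiosyncratic factors mixed
#' by the group's coupling, white voxel noise, a slow random-walk motion trace
#' with occasional persistent spikes, and logMAR acuities.
#'
#' @param config a [cohort_config()].
#' @param group `"patient"` or `"control"`.
#' @param subject_seed integer seed; identical arguments give a bit-identical scan.
#' @param subject_id id string stored in the scan.
#' @return a `subject_scan`: list with `subject_id`, `group`, `roi_data`
#'   (named list of voxels x time matrices in atlas node order), `motion`
#'   (t x 6: translations mm, rotations radians), `acuity`
#'   (amblyopic/fellow logMAR), `meta`.
#' @export
simulate_subject <- function(config, group = c("patient", "control"),
                             subject_seed = config$seed, subject_id = "sub-01") {
  group <- match.arg(group)
  validate_cohort_config(config)
  set.seed(subject_seed)
  nodes <- .builtin_nodes()
  nt <- config$t_frames; nv <- config$voxels_per_roi
  b <- config$inter_coupling
  nets <- c("HVN", "PVN", "VSN")

  # 1 global + 3 network + 19 idiosyncratic band-limited factors
  fac <- .bandlimited_rows(1L + length(nets) + nrow(nodes), nt, config$band, config$tr)
  g_t <- fac[1, ]
  f_net <- fac[1L + seq_along(nets), , drop = FALSE]
  rownames(f_net) <- nets
  e_roi <- fac[-(1:(1L + length(nets))), , drop = FALSE]

  # subject-level coupling: one draw per network around the group mean
  a_max <- sqrt(0.995 - b^2)  # keep residual variance strictly positive
  a_sub <- vapply(nets, function(net)
    .truncnorm1(config$intra_coupling[[net]][[group]], config$coupling_sd, 0, a_max),
    numeric(1))

  drift <- if (config$drift_sd > 0) {
    u <- seq(-1, 1, length.out = nt)
    config$drift_sd * (stats::rnorm(1) * u + stats::rnorm(1) * u^2) * sqrt(nt)
  } else numeric(nt)

  roi_data <- vector("list", nrow(nodes))
  names(roi_data) <- nodes$label
  for (i in seq_len(nrow(nodes))) {
    net <- as.character(nodes$network[i])
    a <- a_sub[[net]]
    s_i <- a * f_net[net, ] + b * g_t + sqrt(1 - a^2 - b^2) * e_roi[i, ]
    noise <- matrix(stats::rnorm(nv * nt, sd = config$voxel_noise_sd), nrow = nv)
    roi_data[[i]] <- sweep(noise, 2, s_i + drift, `+`)
  }

  # motion: slow random walk + Bernoulli persistent step spikes
  motion <- cbind(
    vapply(1:3, function(k) cumsum(stats::rnorm(nt, 0, config$motion_walk_sd)), numeric(nt)),
    vapply(1:3, function(k) cumsum(stats::rnorm(nt, 0, config$motion_rot_walk_sd)), numeric(nt)))
  n_spikes <- 0L
  if (config$motion_spike_rate > 0 && nt > 1) {
    spike_at <- which(stats::runif(nt - 1L) < config$motion_spike_rate) + 1L
    n_spikes <- length(spike_at)
    for (k in spike_at) {
      axis <- sample.int(3L, 1L)
      motion[k:nt, axis] <- motion[k:nt, axis] +
        sample(c(-1, 1), 1L) * config$motion_spike_mm
    }
  }
  colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")

  ap <- config$acuity_params[[group]]
  acuity <- c(amblyopic = .truncnorm1(ap[["amblyopic_mean"]], ap[["amblyopic_sd"]], -0.1, 1.3),
              fellow = .truncnorm1(ap[["fellow_mean"]], ap[["fellow_sd"]], -0.1, 1.3))

  new_subject_scan(subject_id, group, roi_data, motion, acuity,
                   meta = list(tr = config$tr, coupling = a_sub,
                               n_spikes = n_spikes, seed = subject_seed))
}

# deterministic per-subject seed derivation, kept under 2^31
.derive_seed <- function(root, i) as.integer((as.numeric(root) + 99991 * i) %% 2147483647)

#' Simulate a full two-group cohort
#'
#' @param config a [cohort_config()]. Per-subject seeds are derived from
#'   `config$seed`, so identical configs give identical cohorts.
#' @return list of `subject_scan` (patients first, then controls).
#' @examples
#' cfg <- cohort_config(n_per_group = 2, t_frames = 40, voxels_per_roi = 4)
#' cohort <- simulate_cohort(cfg)
#' length(cohort)
#' @export
simulate_cohort <- function(config) {
  validate_cohort_config(config)
  n <- config$n_per_group
  scans <- vector("list", 2L * n)
  for (i in seq_len(n)) {
    scans[[i]] <- simulate_subject(config, "patient", .derive_seed(config$seed, i),
                                   sprintf("sub-P%02d", i))
    scans[[n + i]] <- simulate_subject(config, "control", .derive_seed(config$seed, n + i),
                                       sprintf("sub-C%02d", i))
  }
  scans
}

#' Participants table of a cohort
#' @param cohort list of `subject_scan`.
#' @return data frame: subject_id, group, acuity_amblyopic, acuity_fellow.
#' @export
participants_table <- function(cohort) {
  data.frame(subject_id = vapply(cohort, `[[`, "", "subject_id"),
             group = vapply(cohort, `[[`, "", "group"),
             acuity_amblyopic = vapply(cohort, function(s) s$acuity[["amblyopic"]], 1),
             acuity_fellow = vapply(cohort, function(s) s$acuity[["fellow"]], 1),
             stringsAsFactors = FALSE)
}

#' Write a cohort to disk
#'
#' Writes a participants TSV, a YAML echo of the configuration, and one
#' directory per subject holding either per-ROI TSV matrices (`format="tsv"`,
#' t rows x voxel columns) or a packed 4D NIfTI built through the atlas masks
#' (`format="nifti"`), plus a whitespace 6-column motion trace. The tree
#' round-trips losslessly through [read_cohort()] (to float precision for
#' NIfTI, which stores single precision).
#'
#' @param cohort list of `subject_scan`.
#' @param dir output directory (created if missing).
#' @param config optional [cohort_config()] to echo as `config.yaml`.
#' @param format `"tsv"` or `"nifti"`.
#' @param atlas `roi_atlas` with masks; required for `format="nifti"`.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, config = NULL,
                         format = c("tsv", "nifti"), atlas = NULL) {
  format <- match.arg(format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(participants_table(cohort), file.path(dir, "participants.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(config)) yaml::write_yaml(unclass(config), file.path(dir, "config.yaml"))
  for (s in cohort) {
    sd_ <- file.path(dir, s$subject_id)
    dir.create(sd_, showWarnings = FALSE)
    utils::write.table(s$motion, file.path(sd_, "motion.par"), sep = " ",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    if (format == "tsv") {
      for (lab in names(s$roi_data)) {
        m <- t(s$roi_data[[lab]])
        colnames(m) <- sprintf("v%03d", seq_len(ncol(m)))
        utils::write.table(m, file.path(sd_, paste0("roi_", lab, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    } else {
      if (is.null(atlas) || is.null(atlas$masks))
        stop("format='nifti' needs an atlas with masks")
      nt <- ncol(s$roi_data[[1]])
      vol <- array(0, c(atlas$grid$dim, nt))
      flat <- matrix(vol, nrow = prod(atlas$grid$dim))
      for (k in seq_along(atlas$masks)) flat[atlas$masks[[k]], ] <- s$roi_data[[k]]
      vol <- array(flat, c(atlas$grid$dim, nt))
      img <- RNifti::asNifti(vol)
      RNifti::pixdim(img) <- c(rep(atlas$grid$voxel_mm, 3), s$meta$tr %||% 2)
      RNifti::writeNifti(img, file.path(sd_, "bold.nii.gz"))
    }
  }
  invisible(dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a cohort written by [write_cohort()]
#' @param dir cohort directory.
#' @param atlas required to unpack NIfTI subjects (masks + node order).
#' @return list of `subject_scan`.
#' @export
read_cohort <- function(dir, atlas = NULL) {
  part <- utils::read.delim(file.path(dir, "participants.tsv"),
                            stringsAsFactors = FALSE)
  lapply(seq_len(nrow(part)), function(i) {
    sd_ <- file.path(dir, part$subject_id[i])
    motion <- as.matrix(utils::read.table(file.path(sd_, "motion.par")))
    colnames(motion) <- c("trans_x", "trans_y", "trans_z", "rot_x", "rot_y", "rot_z")
    acuity <- c(amblyopic = part$acuity_amblyopic[i], fellow = part$acuity_fellow[i])
    nii <- file.path(sd_, "bold.nii.gz")
    if (file.exists(nii)) {
      if (is.null(atlas) || is.null(atlas$masks))
        stop("reading NIfTI subjects needs an atlas with masks")
      extract_roi_timeseries(as.array(RNifti::readNifti(nii)), atlas,
                             subject_id = part$subject_id[i],
                             group = part$group[i], acuity = acuity, motion = motion)
    } else {
      files <- list.files(sd_, pattern = "^roi_.*\\.tsv$")
      labs <- sub("^roi_(.*)\\.tsv$", "\\1", files)
      ord <- if (!is.null(atlas)) match(atlas$nodes$label, labs) else order(labs)
      roi_data <- lapply(files[ord], function(f)
        t(as.matrix(utils::read.delim(file.path(sd_, f)))))
      names(roi_data) <- labs[ord]
      new_subject_scan(part$subject_id[i], part$group[i], roi_data, motion, acuity)
    }
  })
}
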