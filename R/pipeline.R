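# End-to-end orchestration: simulate -> preprocess -> connectivity -> graph
# metrics -> group statistics, with deterministic seeding, a config echo and
# a run manifest for auditability.

#' Pipeline configuration
#'
#' Merges the cohort, preprocessing and graph/stats settings under one root
#' seed. Every stage validates before any stage runs.
#'
#' @param cohort a [cohort_config()].
#' @param preproc a [preproc_config()].
#' @param sparsity_grid sparsity sweep for local efficiency.
#' @param lambda Storey lambda for all FDR families.
#' @param compute_le compute the local-efficiency sweep and aLE statistics.
#' @param seed root seed; overrides `cohort$seed` so one integer drives the run.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            preproc = preproc_config(),
                            sparsity_grid = default_sparsity_grid(),
                            lambda = 0.5,
                            compute_le = TRUE,
                            seed = cohort$seed) {
  validate_cohort_config(cohort)
  stopifnot(inherits(preproc, "preproc_config"),
            all(diff(sparsity_grid) > 0), lambda >= 0, lambda < 1)
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, preproc = preproc,
                 sparsity_grid = sparsity_grid, lambda = lambda,
                 compute_le = isTRUE(compute_le), seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run one subject through preprocessing, connectivity and (optionally) the
#' local-efficiency sweep
#'
#' @param scan a `subject_scan`.
#' @param config a [pipeline_config()].
#' @param atlas the `roi_atlas`.
#' @return list: `scan` (prepared), `matrix` (`connectivity_matrix`),
#'   `profile` (`le_profile` with aLE, or `NULL`).
#' @export
process_subject <- function(scan, config = pipeline_config(),
                            atlas = load_builtin_atlas()) {
  prepared <- preprocess_subject(scan, config$preproc)
  C <- connectivity_matrix(prepared, atlas,
                           min_frames = config$preproc$min_kept_frames)
  profile <- if (config$compute_le) le_auc(le_curve(C, config$sparsity_grid))
  list(scan = prepared, matrix = C, profile = profile)
}

#' Simulate a cohort and write it to disk
#'
#' @param config a [pipeline_config()].
#' @param outdir output directory.
#' @param format cohort storage format, `"tsv"` or `"nifti"`.
#' @param atlas atlas (masks attached on demand for NIfTI packing).
#' @return the cohort (list of `subject_scan`), invisibly.
#' @export
cmd_simulate <- function(config, outdir, format = "tsv",
                         atlas = load_builtin_atlas()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (format == "nifti" && is.null(atlas$masks))
    atlas <- attach_spherical_masks(atlas)
  cohort <- simulate_cohort(config$cohort)
  write_cohort(cohort, outdir, config = config$cohort, format = format,
               atlas = atlas)
  .write_manifest(outdir, "simulate", config,
                  counts = list(n_subjects = length(cohort),
                                t_frames = config$cohort$t_frames))
  invisible(cohort)
}

#' Run the full pipeline
#'
#' Simulates (or loads) a cohort, preprocesses every subject, computes the
#' Fisher-z distance-correlation matrices and local-efficiency profiles, and
#' runs the group analysis. When `outdir` is given, writes per-subject
#' matrices and profiles, the group report, a log and a manifest.
#'
#' @param config a [pipeline_config()].
#' @param outdir optional output directory.
#' @param cohort optional pre-built cohort (list of `subject_scan`); simulated
#'   from `config` when `NULL`.
#' @param atlas the `roi_atlas`.
#' @return list of class `pipeline_result`: `report` (a `group_report`),
#'   `matrices`, `profiles`, `participants`, `kept_frames`.
#' @export
cmd_run_all <- function(config = pipeline_config(), outdir = NULL,
                        cohort = NULL, atlas = load_builtin_atlas()) {
  stopifnot(inherits(config, "pipeline_config"))
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    log_lines <<- c(log_lines, msg)
    message(msg)
  }
  if (is.null(cohort)) {
    cohort <- simulate_cohort(config$cohort)
    say("simulated %d subjects (%d per group, %d frames)", length(cohort),
        config$cohort$n_per_group, config$cohort$t_frames)
  }
  participants <- participants_table(cohort)
  matrices <- vector("list", length(cohort))
  profiles <- if (config$compute_le) vector("list", length(cohort))
  kept <- integer(length(cohort))
  for (i in seq_along(cohort)) {
    res <- process_subject(cohort[[i]], config, atlas)
    matrices[[i]] <- res$matrix
    if (config$compute_le) profiles[[i]] <- res$profile
    kept[i] <- ncol(res$scan$roi_data[[1]])
  }
  say("connectivity: %d matrices of %dx%d; kept frames %d-%d", length(matrices),
      nrow(matrices[[1]]), ncol(matrices[[1]]), min(kept), max(kept))
  report <- analyze_cohort(matrices, participants, profiles, atlas, config$lambda)
  say("group tests: %d intra, %d inter%s", nrow(report$intra$tests),
      nrow(report$inter$tests),
      if (!is.null(report$ale)) sprintf(", %d node", nrow(report$ale$tests)) else "")
  result <- structure(list(report = report, matrices = matrices,
                           profiles = profiles, participants = participants,
                           kept_frames = kept),
                      class = "pipeline_result")
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    mdir <- file.path(outdir, "matrices"); dir.create(mdir, showWarnings = FALSE)
    idx <- data.frame(participants, kept_frames = kept,
                      matrix_file = sprintf("matrices/%s.tsv", participants$subject_id))
    for (i in seq_along(matrices))
      write_connectivity_tsv(matrices[[i]],
                             file.path(mdir, paste0(participants$subject_id[i], ".tsv")))
    if (config$compute_le) {
      pdir <- file.path(outdir, "profiles"); dir.create(pdir, showWarnings = FALSE)
      for (i in seq_along(profiles))
        write_le_profile_tsv(profiles[[i]],
                             file.path(pdir, paste0(participants$subject_id[i], ".tsv")))
    }
    utils::write.table(idx, file.path(outdir, "index.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_group_report(report, file.path(outdir, "report"))
    writeLines(log_lines, file.path(outdir, "run.log"))
    .write_manifest(outdir, "run_all", config,
                    counts = list(n_subjects = length(cohort),
                                  censored_frames = sum(config$cohort$t_frames - kept)))
  }
  result
}

# manifest: stage, config hash, output file hashes, timestamp (informational)
.write_manifest <- function(outdir, stage, config, counts = list()) {
  files <- setdiff(list.files(outdir, recursive = TRUE),
                   c("manifest.json", "run.log"))
  hashes <- as.list(tools::md5sum(file.path(outdir, files)))
  names(hashes) <- files
  manifest <- list(stage = stage,
                   config_hash = unname(tools::md5sum(
                     .config_tempfile(config))),
                   seed = config$seed,
                   counts = counts,
                   files = hashes,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

.config_tempfile <- function(config) {
  f <- tempfile(fileext = ".yaml")
  yaml::write_yaml(rapply(unclass(config), unclass, how = "replace"), f)
  f
}

#' Render summary figures from a pipeline output directory
#'
#' Writes three PNG figures: group-mean heatmaps with the difference matrix,
#' the thresholded network rendered at an illustration sparsity with node
#' size proportional to aLE, and block-connectivity bar charts with SD error
#' bars.
#'
#' @param results_dir directory written by [cmd_run_all()].
#' @param outdir where to write figures (default `results_dir/figures`).
#' @param sparsity illustration sparsity for the graph rendering.
#' @param atlas the `roi_atlas`.
#' @return character vector of figure paths.
#' @export
cmd_report <- function(results_dir, outdir = file.path(results_dir, "figures"),
                       sparsity = 0.35, atlas = load_builtin_atlas()) {
  idx_path <- file.path(results_dir, "index.tsv")
  if (!file.exists(idx_path)) stop("missing inputs: no index.tsv in ", results_dir)
  idx <- utils::read.delim(idx_path)
  mats <- lapply(file.path(results_dir, idx$matrix_file), read_connectivity_tsv)
  pat <- idx$group == "patient"
  arr <- simplify2array(lapply(mats, unclass))
  mp <- apply(arr[, , pat], 1:2, mean)
  mc <- apply(arr[, , !pat], 1:2, mean)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()

  heat <- function(m, main) {
    graphics::image(seq_len(nrow(m)), seq_len(ncol(m)), t(m[nrow(m):1, ]),
                    col = grDevices::hcl.colors(64, "viridis"), axes = FALSE,
                    xlab = "", ylab = "", main = main)
    graphics::axis(1, seq_len(ncol(m)), colnames(m), las = 2, cex.axis = 0.5)
    graphics::axis(2, seq_len(nrow(m)), rev(rownames(m)), las = 2, cex.axis = 0.5)
  }
  f1 <- file.path(outdir, "group_matrices.png")
  grDevices::png(f1, 1500, 520, res = 110)
  graphics::par(mfrow = c(1, 3), mar = c(4, 4, 2, 1))
  heat(mp, "patients"); heat(mc, "controls"); heat(mp - mc, "difference")
  grDevices::dev.off(); paths <- c(paths, f1)

  f2 <- file.path(outdir, "network_graph.png")
  pdir <- file.path(results_dir, "profiles")
  ale <- if (dir.exists(pdir)) {
    prof <- utils::read.delim(file.path(pdir, paste0(idx$subject_id[1], ".tsv")))
    all_ale <- vapply(idx$subject_id, function(s)
      utils::read.delim(file.path(pdir, paste0(s, ".tsv")))$aLE,
      numeric(nrow(prof)))
    rowMeans(all_ale)
  } else rep(1, nrow(mp))
  g <- sparsity_threshold((mp + mc) / 2, sparsity)
  ig <- igraph::graph_from_adjacency_matrix(g$adj, mode = "undirected",
                                            weighted = TRUE, diag = FALSE)
  net <- atlas$nodes$network[match(g$labels, atlas$nodes$label)]
  grDevices::png(f2, 900, 900, res = 110)
  igraph::plot.igraph(ig, vertex.size = 30 * ale / max(ale),
                      vertex.color = c("tomato", "gold", "steelblue")[as.integer(net)],
                      vertex.label.cex = 0.7,
                      main = sprintf("mean network at sparsity %.2f", sparsity))
  grDevices::dev.off(); paths <- c(paths, f2)

  f3 <- file.path(outdir, "block_connectivity.png")
  bs <- lapply(mats, block_means, atlas = atlas)
  blocks <- cbind(t(vapply(bs, `[[`, numeric(3), "intra")),
                  t(vapply(bs, `[[`, numeric(3), "inter")))
  grDevices::png(f3, 1000, 500, res = 110)
  mu <- rbind(colMeans(blocks[pat, ]), colMeans(blocks[!pat, ]))
  sdv <- rbind(apply(blocks[pat, ], 2, stats::sd), apply(blocks[!pat, ], 2, stats::sd))
  bp <- graphics::barplot(mu, beside = TRUE, col = c("tomato", "steelblue"),
                          ylim = c(0, max(mu + sdv) * 1.15),
                          legend.text = c("patients", "controls"),
                          ylab = "mean Fisher-z dCor")
  graphics::arrows(bp, mu - sdv, bp, mu + sdv, angle = 90, code = 3, length = 0.03)
  grDevices::dev.off(); paths <- c(paths, f3)
  paths
}
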