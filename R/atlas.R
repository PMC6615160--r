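# 19 visual-network nodes: three intrinsic connectivity networks (ICNs) --
# visuospatial (VSN, 13 nodes), higher visual (HVN, 4), primary visual (PVN, 2).
# Row order is the canonical node order used by every downstream matrix.
.builtin_nodes <- function() {
  nodes <- read.table(text = "
label network x y z
lFEF  VSN -27  -6  55
lPFt  VSN -45 -39  47
lhIP3 VSN -33 -55  46
lBA7p VSN -24 -73  45
lBA7a VSN -27 -61  56
lBA44 VSN -48   5  33
lBA45 VSN -48  21  21
lIT   VSN -52 -68 -11
rFEF  VSN  27  -3  59
rhIP3 VSN  30 -61  49
rPFt  VSN  48 -30  44
rBA44 VSN  48   8  30
rIT   VSN  48 -61 -18
lV3v  HVN -30 -90 -12
rV3v  HVN  27 -92 -16
rV4   HVN  42 -83 -16
rV2   HVN  21 -97  11
rV1   PVN   0 -81   6
lV1   PVN -12 -62   0
", header = TRUE, stringsAsFactors = FALSE)
  nodes$network <- factor(nodes$network, levels = c("HVN", "PVN", "VSN"))
  nodes
}

#' MNI-like sampling grid
#'
#' Describes the voxel grid that masks and volumes live on: array dimensions,
#' isotropic voxel size in mm, and the world (MNI) coordinate of the first
#' voxel center. The default is the standard 3 mm MNI152 bounding box.
#'
#' @param dim integer length-3 array dimensions.
#' @param voxel_mm isotropic voxel edge length in mm.
#' @param origin_mm MNI coordinate (mm) of voxel (1,1,1)'s center.
#' @return a list of class `mni_grid`.
#' @export
mni_grid <- function(dim = c(61L, 73L, 61L), voxel_mm = 3,
                     origin_mm = c(-90, -126, -72)) {
  stopifnot(length(dim) == 3, all(dim >= 1), voxel_mm > 0, length(origin_mm) == 3)
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm,
                 origin_mm = as.numeric(origin_mm)),
            class = "mni_grid")
}

# world mm coordinates of the voxel centers given by integer index matrix (n x 3, 1-based)
.index_to_mm <- function(idx, grid) {
  sweep(sweep(idx - 1, 2, rep(grid$voxel_mm, 3), `*`), 2, grid$origin_mm, `+`)
}

#' Load the built-in 19-node visual atlas
#'
#' Returns the fixed 19-node atlas covering the higher visual network (HVN),
#' primary visual network (PVN) and visuospatial network (VSN), with node
#' labels, network membership and MNI center coordinates. Node order is fixed
#' (VSN block, then HVN, then PVN) and is preserved by every downstream
#' matrix: row/column i of a connectivity matrix always refers to node i of
#' the atlas. No voxel masks are attached; see [attach_spherical_masks()].
#'
#' @return an object of class `roi_atlas`: list with `nodes` (data frame of
#'   label, network, x, y, z), `masks` (`NULL` until attached) and `grid`.
#' @examples
#' atl <- load_builtin_atlas()
#' table(atl$nodes$network)
#' @export
load_builtin_atlas <- function() {
  structure(list(nodes = .builtin_nodes(), masks = NULL, grid = NULL),
            class = "roi_atlas")
}

#' @export
print.roi_atlas <- function(x, ...) {
  cat("ROI atlas:", nrow(x$nodes), "nodes (",
      paste(sprintf("%s: %d", levels(x$nodes$network),
                    tabulate(x$nodes$network)), collapse = ", "), ")\n")
  cat("masks:", if (is.null(x$masks)) "none" else
    sprintf("attached (%d-%d voxels)", min(lengths(x$masks)), max(lengths(x$masks))), "\n")
  invisible(x)
}

#' Attach spherical voxel masks to an atlas
#'
#' Builds, for every node, the set of grid voxels whose centers lie within
#' `radius_mm` of the node's MNI center. Masks are stored as sorted 1-based
#' column-major flat indices so that voxel order is deterministic. Stands in
#' for a volumetric parcellation when only node centers are available.
#'
#' @param atlas a `roi_atlas`.
#' @param radius_mm sphere radius in mm (> 0); default 6 mm, which on the
#'   default 3 mm grid yields 33 voxels per node.
#' @param grid an [mni_grid()].
#' @return the atlas with `masks` (named list of integer vectors) and `grid` set.
#' @export
attach_spherical_masks <- function(atlas, radius_mm = 6, grid = mni_grid()) {
  stopifnot(inherits(atlas, "roi_atlas"), inherits(grid, "mni_grid"))
  if (radius_mm <= 0) stop("radius_mm must be > 0")
  masks <- vector("list", nrow(atlas$nodes))
  names(masks) <- atlas$nodes$label
  for (i in seq_len(nrow(atlas$nodes))) {
    ctr <- as.numeric(atlas$nodes[i, c("x", "y", "z")])
    # bounding box in index space, clamped to the grid
    lo <- pmax(1L, floor((ctr - radius_mm - grid$origin_mm) / grid$voxel_mm) + 1L)
    hi <- pmin(grid$dim, ceiling((ctr + radius_mm - grid$origin_mm) / grid$voxel_mm) + 1L)
    if (any(lo > hi)) stop("empty mask for node ", atlas$nodes$label[i])
    idx <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
    mm <- .index_to_mm(idx, grid)
    keep <- rowSums(sweep(mm, 2, ctr)^2) <= radius_mm^2
    if (!any(keep)) stop("empty mask for node ", atlas$nodes$label[i])
    flat <- idx[keep, 1] + (idx[keep, 2] - 1L) * grid$dim[1] +
      (idx[keep, 3] - 1L) * prod(grid$dim[1:2])
    masks[[i]] <- sort(as.integer(flat))
  }
  for (i in seq_along(masks)) for (j in seq_len(i - 1L)) {
    if (length(intersect(masks[[i]], masks[[j]])))
      stop("masks overlap for nodes ", names(masks)[j], " and ", names(masks)[i],
           " at radius ", radius_mm, " mm")
  }
  atlas$masks <- masks
  atlas$grid <- grid
  atlas
}

#' Extract per-ROI voxel time series from a 4D volume
#'
#' Pulls, for each atlas node, the voxels-by-time matrix of the node's mask
#' voxels. Voxel row order is the sorted flat index order of the mask.
#'
#' @param volume4d 4D numeric array (x, y, z, t) on the atlas grid.
#' @param atlas a `roi_atlas` with masks attached.
#' @param subject_id,group,acuity,motion optional subject metadata forwarded
#'   into the returned scan.
#' @return a `subject_scan` (see [simulate_subject()] for the structure).
#' @export
extract_roi_timeseries <- function(volume4d, atlas, subject_id = "subject",
                                   group = NA_character_, acuity = NULL,
                                   motion = NULL) {
  stopifnot(inherits(atlas, "roi_atlas"))
  if (is.null(atlas$masks)) stop("atlas has no masks; call attach_spherical_masks() first")
  volume4d <- unclass(volume4d)
  d <- dim(volume4d)
  if (length(d) != 4) stop("volume4d must be a 4D array")
  if (!all(d[1:3] == atlas$grid$dim))
    stop("grid mismatch: volume is ", paste(d[1:3], collapse = "x"),
         " but atlas grid is ", paste(atlas$grid$dim, collapse = "x"))
  nt <- d[4]
  nvox <- prod(d[1:3])
  mat <- matrix(volume4d, nrow = nvox, ncol = nt)
  roi_data <- lapply(atlas$masks, function(m) {
    if (any(m < 1L | m > nvox)) stop("mask outside volume bounds")
    mat[m, , drop = FALSE]
  })
  new_subject_scan(subject_id = subject_id, group = group, roi_data = roi_data,
                   motion = motion, acuity = acuity)
}

#' Write an atlas as an integer label volume plus node table
#'
#' The label volume holds value k at the voxels of node k (0 elsewhere); the
#' node table (label, network, x, y, z) is written as a TSV sidecar so the
#' volume can be reloaded losslessly with [read_atlas_volume()].
#'
#' @param atlas a `roi_atlas` with masks.
#' @param nifti_path output NIfTI file path.
#' @param tsv_path output node-table TSV path.
#' @export
write_atlas_volume <- function(atlas, nifti_path, tsv_path) {
  stopifnot(!is.null(atlas$masks))
  vol <- array(0L, atlas$grid$dim)
  for (k in seq_along(atlas$masks)) vol[atlas$masks[[k]]] <- k
  img <- RNifti::asNifti(vol, reference = NULL)
  RNifti::pixdim(img) <- rep(atlas$grid$voxel_mm, 3)
  RNifti::writeNifti(img, nifti_path)
  write_atlas_tsv(atlas, tsv_path)
  invisible(nifti_path)
}

#' Read an atlas from a label volume plus node table
#' @param nifti_path NIfTI label volume written by [write_atlas_volume()].
#' @param tsv_path node-table TSV.
#' @param grid the [mni_grid()] the volume lives on.
#' @return a `roi_atlas` with masks.
#' @export
read_atlas_volume <- function(nifti_path, tsv_path, grid = mni_grid()) {
  vol <- as.array(RNifti::readNifti(nifti_path))
  if (!all(dim(vol) == grid$dim)) stop("grid mismatch reading label volume")
  nodes <- utils::read.delim(tsv_path, stringsAsFactors = FALSE)
  nodes$network <- factor(nodes$network, levels = c("HVN", "PVN", "VSN"))
  masks <- lapply(seq_len(nrow(nodes)), function(k) sort(which(vol == k)))
  names(masks) <- nodes$label
  if (any(lengths(masks) == 0)) stop("label volume has empty node(s)")
  structure(list(nodes = nodes, masks = masks, grid = grid), class = "roi_atlas")
}

#' @rdname write_atlas_volume
#' @export
write_atlas_tsv <- function(atlas, tsv_path) {
  utils::write.table(atlas$nodes, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(tsv_path)
}
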