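# Sparsity-thresholded weighted graphs and nodal local efficiency.
#
# Edge "length" follows the weighted-efficiency convention: after rescaling
# all retained weights by the matrix maximum, length(e) = 1/weight(e) >= 1,
# so inverse shortest-path lengths -- and hence local efficiency -- lie in
# [0, 1]. The literal sum-of-raw-weights path length is available behind
# `lengths = "raw"` for comparison.

.round_half_up <- function(x) floor(x + 0.5)

#' Threshold a connectivity matrix at a given sparsity
#'
#' Retains the `round(s * N(N-1)/2)` largest-weight off-diagonal edges
#' (rounding half away from zero), keeping their weights. Ties are broken
#' deterministically by ascending (i, j), so the edge set at a lower sparsity
#' is always a subset of the edge set at a higher one.
#'
#' @param W symmetric weight matrix (e.g. a `connectivity_matrix`).
#' @param s sparsity in (0, 1]: fraction of possible edges kept.
#' @return list of class `weighted_graph`: `n`, `labels`, `edges` (data frame
#'   i, j, weight), `adj` (weighted adjacency), `sparsity`.
#' @examples
#' W <- as.matrix(dist(1:5)); g <- sparsity_threshold(W, 0.5); nrow(g$edges)
#' @export
sparsity_threshold <- function(W, s) {
  if (!(s > 0 && s <= 1)) stop("sparsity must lie in (0, 1]")
  W <- unclass(W)
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  m <- .round_half_up(s * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1], ut[, 2])
  keep <- ord[seq_len(min(m, length(w)))]
  edges <- data.frame(i = ut[keep, 1], j = ut[keep, 2], weight = w[keep])
  edges <- edges[edges$weight > 0, ]  # a zero weight is no edge

  adj <- matrix(0, n, n, dimnames = dimnames(W))
  adj[cbind(edges$i, edges$j)] <- edges$weight
  adj[cbind(edges$j, edges$i)] <- edges$weight
  structure(list(n = n, labels = rownames(W) %||% as.character(seq_len(n)),
                 edges = edges, adj = adj, sparsity = s),
            class = "weighted_graph")
}

# shortest-path lengths between all pairs of `nodes` within the subgraph they
# induce, with edge lengths as given in `len` (0 = absent)
.subgraph_spl <- function(len, nodes) {
  sub <- len[nodes, nodes, drop = FALSE]
  g <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::distances(g, algorithm = "dijkstra")
}

#' Nodal local efficiency of a weighted graph
#'
#' For node i, take the subgraph induced by i's direct neighbors (i itself
#' excluded); the local efficiency is the mean over ordered neighbor pairs
#' (j, k) of `1 / l_jk`, where `l_jk` is the shortest path length between j
#' and k *within that subgraph*. Nodes with fewer than two neighbors score 0,
#' and disconnected neighbor pairs contribute 0. With the default inverse
#' (max-normalized) edge lengths the score lies in `[0, 1]`.
#'
#' @param g a `weighted_graph` from [sparsity_threshold()].
#' @param node node index or label; omit to get all nodes.
#' @param lengths `"inverse"` (length = max(W)/w, the standard convention) or
#'   `"raw"` (length = w, the literal sum-of-weights reading).
#' @return scalar (or named vector over all nodes) in `[0, 1]`.
#' @export
local_efficiency <- function(g, node = NULL, lengths = c("inverse", "raw")) {
  lengths <- match.arg(lengths)
  stopifnot(inherits(g, "weighted_graph"))
  len <- g$adj
  if (lengths == "inverse") {
    mx <- max(len)
    if (mx > 0) {
      pos <- len > 0
      len[pos] <- mx / len[pos]
    }
  }
  one_node <- function(i) {
    nb <- which(g$adj[i, ] > 0)
    n_nb <- length(nb)
    if (n_nb < 2) return(0)
    l <- .subgraph_spl(len, nb)
    inv <- 1 / l
    diag(inv) <- 0
    sum(inv[is.finite(inv)]) / (n_nb * (n_nb - 1))
  }
  if (!is.null(node)) {
    if (is.character(node)) {
      node <- match(node, g$labels)
      if (is.na(node)) stop("unknown node label")
    }
    if (node < 1 || node > g$n) stop("unknown node index")
    return(one_node(node))
  }
  stats::setNames(vapply(seq_len(g$n), one_node, numeric(1)), g$labels)
}

#' Default sparsity grid
#'
#' 0.20 to 0.80 in steps of 0.05 (13 points).
#' @return numeric vector.
#' @export
default_sparsity_grid <- function() seq(0.20, 0.80, by = 0.05)

#' Local-efficiency profile across a sparsity sweep
#'
#' Thresholds the matrix at every grid sparsity and records each node's local
#' efficiency, giving a node x sparsity profile.
#'
#' @param W symmetric weight matrix.
#' @param grid strictly increasing sparsities in (0, 1].
#' @param lengths see [local_efficiency()].
#' @return list of class `le_profile`: `labels`, `grid`, `le` (node x grid
#'   matrix), `ale` (`NULL` until [le_auc()] is applied).
#' @export
le_curve <- function(W, grid = default_sparsity_grid(), lengths = "inverse") {
  if (any(diff(grid) <= 0) || any(grid <= 0) || any(grid > 1))
    stop("sparsity grid must be strictly increasing within (0, 1]")
  le <- vapply(grid, function(s) local_efficiency(sparsity_threshold(W, s),
                                                  lengths = lengths),
               numeric(nrow(W)))
  le <- matrix(le, nrow = nrow(W),
               dimnames = list(rownames(W), sprintf("s%.2f", grid)))
  structure(list(labels = rownames(W) %||% as.character(seq_len(nrow(W))),
                 grid = grid, le = le, ale = NULL),
            class = "le_profile")
}

#' Area under the local-efficiency curve (aLE)
#'
#' Trapezoidal integral of each node's local efficiency over the sparsity
#' grid: a threshold-free scalar summary per node.
#'
#' @param profile an `le_profile` from [le_curve()].
#' @return the profile with `ale` (named numeric per node) filled in.
#' @export
le_auc <- function(profile) {
  stopifnot(inherits(profile, "le_profile"))
  if (length(profile$grid) < 2) stop("AUC needs a grid with at least 2 points")
  if (any(diff(profile$grid) <= 0)) stop("sparsity grid must be increasing")
  profile$ale <- stats::setNames(
    apply(profile$le, 1, function(y) pracma::trapz(profile$grid, y)),
    profile$labels)
  profile
}

#' Write an LE profile as TSV (rows = nodes, columns = grid + aLE)
#' @param profile an `le_profile` with `ale` computed.
#' @param path output TSV path.
#' @export
write_le_profile_tsv <- function(profile, path) {
  df <- data.frame(node = profile$labels, profile$le,
                   aLE = profile$ale, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
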