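# Independent brute-force oracles. These deliberately re-derive every
# quantity with naive loops, separate from the package implementation.

# distance correlation via explicit loops over the defining sums
naive_dcor <- function(A, B) {
  zt <- function(M) {
    for (v in seq_len(nrow(M))) {
      mu <- mean(M[v, ]); s <- stats::sd(M[v, ])
      M[v, ] <- (M[v, ] - mu) / s
    }
    M
  }
  A <- zt(A); B <- zt(B)
  t_len <- ncol(A)
  dmat <- function(M) {
    d <- matrix(0, t_len, t_len)
    for (i in seq_len(t_len)) for (j in seq_len(t_len))
      d[i, j] <- sqrt(sum((M[, i] - M[, j])^2))
    d
  }
  dA <- dmat(A); dB <- dmat(B)
  uc <- function(d) {
    D <- matrix(0, t_len, t_len)
    for (i in seq_len(t_len)) for (j in seq_len(t_len)) if (i != j)
      D[i, j] <- d[i, j] - sum(d[i, ]) / (t_len - 2) - sum(d[, j]) / (t_len - 2) +
        sum(d) / ((t_len - 1) * (t_len - 2))
    D
  }
  DA <- uc(dA); DB <- uc(dB)
  dcv <- sum(DA * DB) / (t_len * (t_len - 3))
  dva <- sum(DA^2) / (t_len * (t_len - 3))
  dvb <- sum(DB^2) / (t_len * (t_len - 3))
  if (dcv <= 0) 0 else sqrt(dcv / sqrt(dva * dvb))
}

# nodal local efficiency by exhaustive simple-path enumeration
brute_local_efficiency <- function(adj, i, lengths = "inverse") {
  len <- adj
  if (lengths == "inverse") {
    mx <- max(adj)
    len[adj > 0] <- mx / adj[adj > 0]
  }
  nb <- which(adj[i, ] > 0)
  k <- length(nb)
  if (k < 2) return(0)
  sub_len <- len[nb, nb, drop = FALSE]
  sub_adj <- adj[nb, nb, drop = FALSE]
  shortest <- function(a, b) {
    best <- Inf
    walk <- function(cur, visited, acc) {
      if (acc >= best) return()
      if (cur == b) { best <<- acc; return() }
      for (nx in which(sub_adj[cur, ] > 0))
        if (!(nx %in% visited)) walk(nx, c(visited, nx), acc + sub_len[cur, nx])
    }
    walk(a, a, 0)
    best
  }
  tot <- 0
  for (a in seq_len(k)) for (b in seq_len(k)) if (a != b) {
    l <- shortest(a, b)
    if (is.finite(l)) tot <- tot + 1 / l
  }
  tot / (k * (k - 1))
}

# Floyd-Warshall all-pairs shortest paths on a length matrix (0 = no edge)
floyd_warshall <- function(len) {
  n <- nrow(len)
  d <- ifelse(len > 0, len, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  d
}

# split-plot ANOVA from textbook sums of squares (balanced, 2 groups)
anova_ss_oracle <- function(values, groups) {
  values <- as.matrix(values)
  g <- factor(groups)
  n <- nrow(values); nc <- ncol(values)
  ng <- as.vector(table(g))
  grand <- mean(values)
  subj_means <- rowMeans(values)
  group_means <- tapply(subj_means, g, mean)
  cond_means <- colMeans(values)
  cell_means <- rowsum(values, g) / ng
  ss_group <- nc * sum(ng * (group_means - grand)^2)
  ss_subj <- nc * sum((subj_means - group_means[g])^2)
  ss_cond <- n * sum((cond_means - grand)^2)
  ss_int <- sum(ng * (cell_means - outer(group_means, cond_means, `+`) + grand)^2)
  ss_tot <- sum((values - grand)^2)
  ss_res <- ss_tot - ss_group - ss_subj - ss_cond - ss_int
  df_group <- nlevels(g) - 1; df_subj <- n - nlevels(g)
  df_cond <- nc - 1; df_int <- df_group * df_cond; df_res <- df_subj * df_cond
  list(
    F_group = (ss_group / df_group) / (ss_subj / df_subj),
    F_cond = (ss_cond / df_cond) / (ss_res / df_res),
    F_int = (ss_int / df_int) / (ss_res / df_res),
    df = list(group = c(df_group, df_subj), cond = c(df_cond, df_res),
              int = c(df_int, df_res)))
}

# Storey q-values by direct arithmetic on the sorted vector
storey_oracle <- function(p, lambda = 0.5) {
  m <- length(p)
  pi0 <- min(1, sum(p > lambda) / ((1 - lambda) * m))
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cand <- Inf
    for (j in i:m) cand <- min(cand, pi0 * m * p[ord][j] / j)
    q_sorted[i] <- min(cand, 1)
  }
  out <- numeric(m)
  out[ord] <- q_sorted
  out
}

# small helper: random symmetric weight matrix with distinct positive weights
random_weight_matrix <- function(n, labels = NULL) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2)
  W <- W + t(W)
  if (!is.null(labels)) dimnames(W) <- list(labels, labels)
  W
}

# tiny subject scan built directly from given per-ROI matrices
make_scan <- function(roi_data, motion = NULL, group = "control",
                      id = "sub-T1", tr = 2) {
  t_len <- ncol(roi_data[[1]])
  if (is.null(motion)) motion <- matrix(0, t_len, 6)
  vicnet:::new_subject_scan(id, group, roi_data, motion,
                            acuity = c(amblyopic = 0, fellow = 0),
                            meta = list(tr = tr))
}
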