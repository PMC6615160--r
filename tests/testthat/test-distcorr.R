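test_that("voxelwise z-transfer standardizes rows and flags constants", {
  z <- ztransfer_voxels(matrix(c(1, 2, 3), 1))
  expect_equal(mean(z), 0)
  expect_equal(sd(as.vector(z)), 1)
  expect_warning(z <- ztransfer_voxels(rbind(c(1, 2, 3), c(5, 5, 5))), "constant")
  expect_equal(z[2, ], c(0, 0, 0))
  x <- rbind(scale(rnorm(20))[, 1])
  expect_equal(ztransfer_voxels(x), x, tolerance = 1e-12)
})

test_that("time-point distance matrices match the defining double loop", {
  expect_equal(time_distance_matrix(matrix(c(0, 3), 1)),
               matrix(c(0, 3, 3, 0), 2), ignore_attr = TRUE)
  m <- matrix(c(0, 0, 3, 4), 2)  # columns (0,0) and (3,4): 3-4-5 triangle
  expect_equal(time_distance_matrix(m)[1, 2], 5)
  set.seed(7)
  X <- matrix(rnorm(5 * 20), 5)
  d <- time_distance_matrix(X)
  for (i in 1:20) for (j in 1:20)
    expect_equal(d[i, j], sqrt(sum((X[, i] - X[, j])^2)))
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 20))
})

test_that("U-centering zeroes the diagonal and all row/column sums", {
  # constant off-diagonal distances collapse to the zero matrix
  d <- matrix(2.5, 7, 7); diag(d) <- 0
  expect_equal(u_center(d), matrix(0, 7, 7), tolerance = 1e-12)
  set.seed(13)
  for (rep in 1:20) {
    t_len <- sample(4:12, 1)
    d <- as.matrix(dist(matrix(rnorm(t_len * 3), t_len)))
    U <- u_center(d)
    expect_equal(unname(diag(U)), rep(0, t_len))
    expect_lt(max(abs(rowSums(U))), 1e-10 * t_len * max(d))
    expect_lt(max(abs(colSums(U))), 1e-10 * t_len * max(d))
  }
  expect_error(u_center(matrix(0, 3, 3)), "t >= 4")
})

test_that("distance covariance and variance match the loop oracle and each other", {
  set.seed(19)
  A <- matrix(rnorm(3 * 12), 3); B <- matrix(rnorm(2 * 12), 2)
  UA <- u_center(time_distance_matrix(A))
  UB <- u_center(time_distance_matrix(B))
  expect_equal(dcov_u(UA, UA), dvar_u(UA))
  expect_gte(dvar_u(UA), 0)
  t_len <- 12
  expect_equal(dcov_u(UA, UB), sum(UA * UB) / (t_len * (t_len - 3)))
  expect_equal(dvar_u(u_center(matrix(0, 6, 6) + 0)), 0)
  expect_error(dcov_u(UA, u_center(as.matrix(dist(rnorm(5))))), "equal shape")
})

test_that("unbiasedness: mean distance covariance of independent data is ~0", {
  set.seed(23)
  vals <- replicate(500, {
    A <- matrix(rnorm(8), 1); B <- matrix(rnorm(8), 1)
    dcov_u(u_center(time_distance_matrix(A)), u_center(time_distance_matrix(B)))
  })
  se <- sd(vals) / sqrt(length(vals))
  expect_lt(abs(mean(vals)), 2 * se)
})

test_that("dcor matches an independent naive implementation on random patches", {
  set.seed(29)
  for (rep in 1:50) {
    t_len <- sample(8:40, 1)
    A <- matrix(rnorm(sample(1:10, 1) * t_len), ncol = t_len)
    B <- matrix(rnorm(sample(1:10, 1) * t_len), ncol = t_len)
    expect_equal(dcor(A, B), naive_dcor(A, B), tolerance = 1e-12)
  }
})

test_that("dcor identities: self-correlation, symmetry, invariances, clamping", {
  set.seed(37)
  A <- matrix(rnorm(3 * 30), 3); B <- matrix(rnorm(5 * 30), 5)
  expect_equal(dcor(A, A), 1, tolerance = 1e-12)
  expect_equal(dcor(A, B), dcor(B, A))
  # voxel permutation leaves distances unchanged
  expect_equal(dcor(A[c(3, 1, 2), ], B), dcor(A, B))
  # affine rescaling is absorbed by the z-transfer
  expect_equal(dcor(-2.5 * A + 7, B), dcor(A, B), tolerance = 1e-12)
  # negative distance covariance clamps to zero
  found <- FALSE
  for (i in 1:100) {
    a <- matrix(rnorm(6), 1); b <- matrix(rnorm(6), 1)
    cv <- dcov_u(u_center(time_distance_matrix(ztransfer_voxels(a))),
                 u_center(time_distance_matrix(ztransfer_voxels(b))))
    if (cv <= 0) { expect_equal(dcor(a, b), 0); found <- TRUE; break }
  }
  expect_true(found)
  w <- capture_warnings(r <- dcor(matrix(1, 2, 30), B))
  expect_true(any(grepl("zero distance variance", w)))
  expect_equal(r, 0)
  expect_error(dcor(A, B[, 1:10]), "same number of time points")
})

test_that("Fisher transform matches the closed form and clamps near 1", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  expect_gt(fisher_z(0.6), fisher_z(0.5))
  expect_warning(z <- fisher_z(1), "clamped")
  expect_equal(z, 0.5 * log((2 - 1e-7) / 1e-7))
  expect_error(fisher_z(1.2), "\\[0, 1\\]")
  expect_error(fisher_z(-0.1), "\\[0, 1\\]")
})

test_that("subject connectivity matrices are symmetric labelled Fisher-z maps", {
  cfg <- cohort_config(n_per_group = 1, t_frames = 40, voxels_per_roi = 3,
                       motion_spike_rate = 0, seed = 43)
  s <- simulate_subject(cfg, "control", 43)
  C <- connectivity_matrix(s)
  expect_equal(dim(C), c(19, 19))
  expect_equal(rownames(C), load_builtin_atlas()$nodes$label)
  expect_equal(unclass(C), t(unclass(C)), ignore_attr = TRUE)
  expect_equal(diag(C), rep(0, 19), ignore_attr = TRUE)
  expect_true(all(C >= 0) && all(is.finite(C)))

  # identical ROI signals with zero noise give the clamped maximal edge
  s2 <- s
  s2$roi_data[["rV1"]] <- s2$roi_data[["lV1"]]
  C2 <- connectivity_matrix(s2)
  expect_equal(C2["rV1", "lV1"], 0.5 * log((2 - 1e-7) / 1e-7))

  # permuting atlas node order permutes rows/columns consistently
  atl <- load_builtin_atlas()
  perm <- rev(seq_len(19))
  atl_rev <- atl
  atl_rev$nodes <- atl$nodes[perm, ]
  C3 <- connectivity_matrix(s, atl_rev)
  expect_equal(unclass(C3), unclass(C)[perm, perm], ignore_attr = TRUE)
})

test_that("connectivity TSVs round-trip with labels", {
  set.seed(47)
  C <- structure(random_weight_matrix(5, letters[1:5]),
                 class = c("connectivity_matrix", "matrix"))
  f <- tempfile(fileext = ".tsv")
  write_connectivity_tsv(C, f)
  back <- read_connectivity_tsv(f)
  expect_equal(unclass(back), unclass(C), tolerance = 1e-12)
})

test_that("circular-shift surrogate test on independent signals is calibrated", {
  set.seed(59)
  t_len <- 80; nperm <- 19
  rej <- replicate(300, {
    f <- vicnet:::.bandlimited_rows(2, t_len, c(0.01, 0.10), 2)
    UA <- u_center(time_distance_matrix(rbind(f[1, ])))
    UB <- u_center(time_distance_matrix(rbind(f[2, ])))
    obs <- dcov_u(UA, UB)
    shifts <- sample(4:(t_len - 4), nperm)
    null <- vapply(shifts, function(s0) {
      idx <- c((s0 + 1):t_len, 1:s0)
      dcov_u(UA, UB[idx, idx])
    }, numeric(1))
    mean(c(obs, null) >= obs) <= 0.05
  })
  rate <- mean(rej)
  se <- sqrt(0.05 * 0.95 / 300)
  expect_lt(rate, 0.05 + 2.58 * se)
  expect_gt(rate, 0.05 - 2.58 * se)
})
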