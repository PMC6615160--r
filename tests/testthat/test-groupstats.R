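fake_cmatrix <- function(values, id = "s", group = "control") {
  labs <- load_builtin_atlas()$nodes$label
  structure(values, dimnames = list(labs, labs),
            class = c("connectivity_matrix", "matrix"),
            subject_id = id, group = group)
}

test_that("block means average the correct intra/inter entries", {
  atl <- load_builtin_atlas()
  C <- fake_cmatrix(matrix(0.4, 19, 19) - diag(0.4, 19))
  bs <- block_means(C, atl)
  expect_equal(unname(bs$intra), rep(0.4, 3))
  expect_equal(unname(bs$inter), rep(0.4, 3))
  expect_named(bs$intra, c("HVN", "PVN", "VSN"))
  expect_named(bs$inter, c("HVN-PVN", "HVN-VSN", "PVN-VSN"))

  # PVN has exactly two nodes: its intra value is the single lV1-rV1 edge
  set.seed(89)
  M <- random_weight_matrix(19, atl$nodes$label)
  bs <- block_means(fake_cmatrix(M), atl)
  expect_equal(unname(bs$intra["PVN"]), M["rV1", "lV1"])

  # hand-enumerated 4-node toy: two networks of two nodes
  toy <- load_builtin_atlas()
  toy$nodes <- data.frame(label = c("h1", "h2", "p1", "p2"),
                          network = factor(c("HVN", "HVN", "PVN", "PVN"),
                                           levels = c("HVN", "PVN", "VSN")),
                          x = 0, y = 0, z = 0)
  W <- matrix(0, 4, 4, dimnames = list(toy$nodes$label, toy$nodes$label))
  W["h1", "h2"] <- 1; W["p1", "p2"] <- 2
  W["h1", "p1"] <- 3; W["h1", "p2"] <- 4; W["h2", "p1"] <- 5; W["h2", "p2"] <- 6
  W <- W + t(W)
  expect_error(block_means(structure(W, class = c("connectivity_matrix", "matrix")),
                           toy), "fewer than 2")  # VSN empty
  toy$nodes$network <- factor(c("HVN", "HVN", "VSN", "VSN"),
                              levels = c("HVN", "PVN", "VSN"))
  toy2 <- toy
  expect_error(block_means(structure(W, class = c("connectivity_matrix", "matrix")),
                           toy2), "fewer than 2")  # PVN empty now
})

test_that("split-plot ANOVA reproduces the design dfs and the SS oracle", {
  set.seed(97)
  vals <- matrix(rnorm(36 * 3), 36)
  grp <- rep(c("patient", "control"), each = 18)
  tab <- mixed_anova(vals, grp)
  expect_equal(tab$df1, c(1, 2, 2))
  expect_equal(tab$df2, c(34, 68, 68))
  # location invariance
  tab2 <- mixed_anova(vals + 5, grp)
  expect_equal(tab$F, tab2$F, tolerance = 1e-10)
  # random small balanced tables against the independent sums-of-squares oracle
  for (rep in 1:10) {
    n <- 2 * sample(3:6, 1); nc <- sample(2:4, 1)
    v <- matrix(rnorm(n * nc), n)
    g <- rep(c("a", "b"), each = n / 2)
    got <- mixed_anova(v, g)
    want <- anova_ss_oracle(v, g)
    expect_equal(got$F, c(want$F_group, want$F_cond, want$F_int), tolerance = 1e-10)
    expect_equal(got$p[1], stats::pf(want$F_group, want$df$group[1],
                                     want$df$group[2], lower.tail = FALSE),
                 tolerance = 1e-10)
  }
  expect_error(mixed_anova(vals[1:35, ], grp[1:35]), "balanced")
  expect_error(mixed_anova(vals, rep("a", 36)), "two groups")
})

test_that("for 2x2 designs the interaction F equals the squared difference t", {
  set.seed(101)
  vals <- matrix(rnorm(16 * 2), 16)
  grp <- rep(c("a", "b"), each = 8)
  tab <- mixed_anova(vals, grp)
  dif <- vals[, 1] - vals[, 2]
  tt <- two_sample_t(dif[grp == "a"], dif[grp == "b"])
  expect_equal(tab$F[tab$effect == "interaction"], tt$t^2, tolerance = 1e-10)
})

test_that("pooled two-sample t matches hand arithmetic", {
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  got <- two_sample_t(x, y)
  # pooled SD = 1, t = -1 / sqrt(2/3)
  expect_equal(got$t, -1 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(got$df, 4)
  same <- two_sample_t(c(1, 2, 3), c(3, 2, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  big <- two_sample_t(rnorm(18), rnorm(18))
  expect_equal(big$df, 34)
  expect_error(two_sample_t(c(1, 1), c(1, 1)), "zero pooled variance")
  expect_error(two_sample_t(1, c(1, 2)), ">= 2")
})

test_that("Storey q-values match the hand oracle and stay monotone", {
  expect_equal(storey_q(c(0.005, 0.1, 0.3, 0.9), lambda = 0.5),
               c(0.01, 0.1, 0.2, 0.45))
  expect_equal(storey_q(rep(1, 5)), rep(1, 5))
  set.seed(103)
  for (rep in 1:10) {
    p <- runif(sample(5:40, 1))
    q <- storey_q(p)
    expect_equal(q, storey_oracle(p), tolerance = 1e-12)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
    expect_true(all(q >= 0 & q <= 1))
  }
  # pFDR variant applies the finite-sample factor
  p <- c(0.01, 0.2, 0.6, 0.8)
  q <- storey_q(p, pfdr = TRUE)
  expect_true(all(q >= storey_q(p)))
  expect_error(storey_q(numeric(0)), "empty")
  expect_error(storey_q(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(storey_q(0.5, lambda = 1), "lambda")
})

test_that("acuity correlations recover exact linear dependence and reject degenerates", {
  x <- seq(0.2, 1, length.out = 10)
  out <- pearson_acuity(data.frame(blockA = 2 * x + 1), x)
  expect_equal(out$r, 1, tolerance = 1e-12)
  set.seed(107)
  out <- pearson_acuity(data.frame(a = rnorm(10), b = rnorm(10)), x)
  expect_equal(nrow(out), 2)
  expect_error(pearson_acuity(data.frame(a = rnorm(10)), rep(0.5, 10)),
               "zero variance")
  expect_error(pearson_acuity(data.frame(a = rnorm(2)), c(1, 2)), "3 patients")
})

test_that("independent acuity correlations reject at the nominal rate", {
  set.seed(109)
  crit <- abs(qt(0.025, 16)) / sqrt(16 + abs(qt(0.025, 16))^2)  # |r| at p=0.05, n=18
  hits <- replicate(500, abs(cor(rnorm(18), rnorm(18))) > crit)
  expect_lt(abs(mean(hits) - 0.05), 2.58 * sqrt(0.05 * 0.95 / 500))
})

test_that("cohort analysis assembles the three FDR families and matrices", {
  set.seed(113)
  n <- 4
  labs <- load_builtin_atlas()$nodes$label
  mats <- lapply(seq_len(2 * n), function(i)
    fake_cmatrix(random_weight_matrix(19, labs),
                 id = sprintf("s%02d", i),
                 group = if (i <= n) "patient" else "control"))
  parts <- data.frame(subject_id = sprintf("s%02d", seq_len(2 * n)),
                      group = rep(c("patient", "control"), each = n),
                      acuity_amblyopic = c(runif(n, 0.3, 1), runif(n, 0, 0.1)),
                      acuity_fellow = runif(2 * n, 0, 0.1))
  profs <- lapply(seq_len(2 * n), function(i) le_auc(le_curve(mats[[i]])))
  rep_ <- analyze_cohort(mats, parts, profs)
  expect_equal(nrow(rep_$intra$tests), 3)
  expect_equal(nrow(rep_$inter$tests), 3)
  expect_equal(nrow(rep_$ale$tests), 19)
  expect_equal(dim(rep_$difference), c(19, 19))
  expect_equal(rep_$difference, rep_$mean_patient - rep_$mean_control)
  expect_equal(nrow(rep_$acuity), 6)
  # report files
  dir <- tempfile(); on.exit(unlink(dir, recursive = TRUE))
  write_group_report(rep_, dir)
  expect_true(all(file.exists(file.path(dir, c("report.json", "intra_tests.tsv",
                                               "ale_tests.tsv",
                                               "difference_matrix.tsv")))))
  js <- jsonlite::read_json(file.path(dir, "report.json"))
  expect_length(js$ale$tests, 19)
})
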