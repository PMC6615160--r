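# Block connectivity summaries and group-level statistics: split-plot
# repeated-measures ANOVA, pooled two-sample t-tests, Storey q-values,
# acuity correlations.

#' Intra- and inter-network block means of a connectivity matrix
#'
#' Intra-network value for network k = mean of the upper-triangle edges among
#' k's nodes (one edge for the two-node PVN); inter-network value for a pair
#' (k, l) = mean over all cross-network node pairs.
#'
#' @param C a `connectivity_matrix` with labels matching the atlas.
#' @param atlas the `roi_atlas`.
#' @return list of class `block_summary`: `subject_id`, `group`, `intra`
#'   (named HVN/PVN/VSN), `inter` (named HVN-PVN/HVN-VSN/PVN-VSN).
#' @export
block_means <- function(C, atlas = load_builtin_atlas()) {
  labs <- atlas$nodes$label
  if (!identical(rownames(C), labs)) {
    if (!all(labs %in% rownames(C))) stop("matrix labels do not match the atlas")
    C <- C[labs, labs]
  }
  net <- as.character(atlas$nodes$network)
  nets <- c("HVN", "PVN", "VSN")
  intra <- vapply(nets, function(k) {
    idx <- which(net == k)
    if (length(idx) < 2) stop("network ", k, " has fewer than 2 nodes")
    sub <- C[idx, idx, drop = FALSE]
    mean(sub[upper.tri(sub)])
  }, numeric(1))
  pairs <- utils::combn(nets, 2)
  inter <- apply(pairs, 2, function(kl)
    mean(C[net == kl[1], net == kl[2], drop = FALSE]))
  names(inter) <- apply(pairs, 2, paste, collapse = "-")
  structure(list(subject_id = attr(C, "subject_id"), group = attr(C, "group"),
                 intra = intra, inter = inter),
            class = "block_summary")
}

#' Mixed-design (split-plot) repeated-measures ANOVA
#'
#' One between-subject factor (group) and one within-subject factor
#' (condition) on a balanced complete subject x condition table. The group
#' effect is tested against between-subject error (subjects within groups);
#' the condition and interaction effects against the within-subject residual.
#' With n subjects per group and c conditions the dfs are
#' `(1, 2n - 2)` and `(c - 1, (c - 1)(2n - 2))`.
#'
#' @param values subjects x conditions numeric matrix.
#' @param groups factor/character of length `nrow(values)` with 2 levels.
#' @return list of class `anova_table` with one row per effect
#'   (group, condition, interaction): F, df1, df2, p.
#' @export
mixed_anova <- function(values, groups) {
  values <- as.matrix(values)
  groups <- factor(groups)
  if (nlevels(groups) != 2) stop("exactly two groups required")
  if (any(table(groups) < 2)) stop("need at least 2 subjects per group")
  if (length(unique(table(groups))) != 1) stop("groups must be balanced")
  if (anyNA(values)) stop("table must be complete (no missing cells)")
  n_sub <- nrow(values); n_cond <- ncol(values)
  df <- data.frame(
    value = as.vector(values),
    subject = factor(rep(seq_len(n_sub), n_cond)),
    group = rep(groups, n_cond),
    cond = factor(rep(seq_len(n_cond), each = n_sub)))
  fit <- stats::aov(value ~ group * cond + Error(subject), data = df)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  tab <- data.frame(
    effect = c("group", "condition", "interaction"),
    F = c(between["group", "F value"], within["cond", "F value"],
          within["group:cond", "F value"]),
    df1 = c(between["group", "Df"], within["cond", "Df"],
            within["group:cond", "Df"]),
    df2 = c(between["Residuals", "Df"], within["Residuals", "Df"],
            within["Residuals", "Df"]),
    p = c(between["group", "Pr(>F)"], within["cond", "Pr(>F)"],
          within["group:cond", "Pr(>F)"]),
    row.names = NULL)
  structure(tab, class = c("anova_table", "data.frame"))
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance, `df = n1 + n2 - 2`, two-sided p.
#'
#' @param x,y numeric vectors (each length >= 2).
#' @return list: `t`, `df`, `p`, `mean_x`, `mean_y`.
#' @export
two_sample_t <- function(x, y) {
  if (length(x) < 2 || length(y) < 2) stop("each group needs >= 2 values")
  if (stats::sd(c(x - mean(x), y - mean(y))) == 0) stop("zero pooled variance")
  ht <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value,
       mean_x = mean(x), mean_y = mean(y))
}

#' Storey q-values
#'
#' Estimates the null proportion as
#' `pi0 = min(1, #(p > lambda) / ((1 - lambda) m))` and converts the sorted
#' p-values with `q_(i) = min over j >= i of pi0 m p_(j) / j`, returned in
#' input order. `pfdr = TRUE` applies the finite-sample positive-FDR factor
#' `1 / (1 - (1 - p)^m)`.
#'
#' @param pvals p-values in `[0, 1]`.
#' @param lambda tuning parameter in `[0, 1)`; default 0.5.
#' @param pfdr use the finite-sample pFDR estimator.
#' @return q-values, same order as `pvals`; monotone non-decreasing in p.
#' @examples
#' storey_q(c(0.005, 0.1, 0.3, 0.9))
#' @export
storey_q <- function(pvals, lambda = 0.5, pfdr = FALSE) {
  if (length(pvals) == 0) stop("empty p-value vector")
  if (any(pvals < 0 | pvals > 1)) stop("p-values must lie in [0, 1]")
  if (lambda < 0 || lambda >= 1) stop("lambda must lie in [0, 1)")
  m <- length(pvals)
  pi0 <- min(1, sum(pvals > lambda) / ((1 - lambda) * m))
  ord <- order(pvals)
  ps <- pvals[ord]
  q <- pi0 * m * ps / seq_len(m)
  if (pfdr) q <- q / (1 - (1 - ps)^m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

#' Pearson correlation of block connectivity with visual acuity
#'
#' Correlates each intra-/inter-network summary with the patients'
#' amblyopic-eye logMAR acuity.
#'
#' @param summaries data frame with one row per patient and one column per
#'   block measure.
#' @param acuity amblyopic-eye logMAR, same length.
#' @return data frame: block, r, p.
#' @export
pearson_acuity <- function(summaries, acuity) {
  if (nrow(summaries) < 3) stop("need at least 3 patients")
  if (stats::sd(acuity) == 0) stop("acuity has zero variance")
  res <- lapply(names(summaries), function(b) {
    v <- summaries[[b]]
    if (stats::sd(v) == 0) stop("block ", b, " has zero variance")
    ct <- stats::cor.test(v, acuity)
    data.frame(block = b, r = unname(ct$estimate), p = ct$p.value)
  })
  do.call(rbind, res)
}

# family of pooled t-tests (patient vs control) + Storey q over the family
.t_family <- function(values, groups, lambda) {
  pat <- groups == "patient"
  res <- lapply(colnames(values), function(u) {
    tt <- two_sample_t(values[pat, u], values[!pat, u])
    data.frame(unit = u, mean_patient = tt$mean_x, mean_control = tt$mean_y,
               t = tt$t, df = tt$df, p = tt$p)
  })
  out <- do.call(rbind, res)
  out$q <- storey_q(out$p, lambda)
  out
}

#' Full group-level analysis of a cohort
#'
#' Produces (a) group-mean and difference connectivity matrices, (b) the
#' intra-network mixed ANOVA plus 3 pooled t-tests with Storey q over that
#' family, (c) the same for the 3 inter-network pairs, (d) the aLE mixed
#' ANOVA (group x nodes) plus per-node t-tests with q over the 19-node
#' family, and (e) Pearson correlations of the patients' block connectivity
#' with amblyopic-eye acuity. FDR families are corrected separately.
#'
#' @param matrices list of `connectivity_matrix`, one per subject.
#' @param participants data frame from [participants_table()].
#' @param profiles optional list of `le_profile` with aLE (skipped if `NULL`).
#' @param atlas the `roi_atlas`.
#' @param lambda Storey lambda.
#' @return list of class `group_report`.
#' @export
analyze_cohort <- function(matrices, participants, profiles = NULL,
                           atlas = load_builtin_atlas(), lambda = 0.5) {
  stopifnot(length(matrices) == nrow(participants))
  groups <- participants$group
  if (any(table(groups) < 2)) stop("need at least 2 subjects per group")
  bs <- lapply(matrices, block_means, atlas = atlas)
  intra <- t(vapply(bs, `[[`, numeric(3), "intra"))
  inter <- t(vapply(bs, `[[`, numeric(3), "inter"))
  rownames(intra) <- rownames(inter) <- participants$subject_id

  pat <- groups == "patient"
  arr <- simplify2array(lapply(matrices, unclass))
  mean_patient <- apply(arr[, , pat], 1:2, mean)
  mean_control <- apply(arr[, , !pat], 1:2, mean)

  report <- list(
    n_per_group = unname(table(groups)[c("patient", "control")]),
    mean_patient = mean_patient,
    mean_control = mean_control,
    difference = mean_patient - mean_control,
    intra = list(values = intra, anova = mixed_anova(intra, groups),
                 tests = .t_family(intra, groups, lambda)),
    inter = list(values = inter, anova = mixed_anova(inter, groups),
                 tests = .t_family(inter, groups, lambda)))

  if (!is.null(profiles)) {
    ale <- t(vapply(profiles, function(p) {
      if (is.null(p$ale)) p <- le_auc(p)
      p$ale
    }, numeric(nrow(atlas$nodes))))
    rownames(ale) <- participants$subject_id
    report$ale <- list(values = ale, anova = mixed_anova(ale, groups),
                       tests = .t_family(ale, groups, lambda))
  }

  blocks <- data.frame(intra, inter, check.names = FALSE)[pat, , drop = FALSE]
  report$acuity <- if (sum(pat) >= 3)
    pearson_acuity(blocks, participants$acuity_amblyopic[pat])
  structure(report, class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("Group report:", x$n_per_group[1], "patients vs", x$n_per_group[2], "controls\n")
  fmt_an <- function(a) paste(sprintf("%s F(%d,%d)=%.2f p=%.3g", a$effect,
                                      a$df1, a$df2, a$F, a$p), collapse = "; ")
  cat("Intra-network ANOVA:", fmt_an(x$intra$anova), "\n")
  print(x$intra$tests, digits = 3)
  cat("Inter-network ANOVA:", fmt_an(x$inter$anova), "\n")
  print(x$inter$tests, digits = 3)
  if (!is.null(x$ale)) {
    cat("aLE ANOVA:", fmt_an(x$ale$anova), "\n")
    sig <- x$ale$tests[x$ale$tests$q < 0.05, ]
    cat("aLE nodes with q < 0.05:",
        if (nrow(sig)) paste(sig$unit, collapse = ", ") else "none", "\n")
  }
  invisible(x)
}

#' Write a group report to disk
#'
#' Summary JSON (all F/t/p/q with dfs), per-family TSV tables, and
#' group-mean / difference matrices as TSV.
#'
#' @param report a `group_report`.
#' @param dir output directory.
#' @export
write_group_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(d, f) utils::write.table(d, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  for (fam in c("intra", "inter", "ale")) {
    if (is.null(report[[fam]])) next
    wt(report[[fam]]$tests, paste0(fam, "_tests.tsv"))
    wt(as.data.frame(report[[fam]]$anova), paste0(fam, "_anova.tsv"))
  }
  if (!is.null(report$acuity)) wt(report$acuity, "acuity_correlations.tsv")
  for (m in c("mean_patient", "mean_control", "difference")) {
    df <- data.frame(node = rownames(report[[m]]), report[[m]], check.names = FALSE)
    wt(df, paste0(m, "_matrix.tsv"))
  }
  summary <- list(
    n_per_group = as.list(report$n_per_group),
    intra = list(anova = report$intra$anova, tests = report$intra$tests),
    inter = list(anova = report$inter$anova, tests = report$inter$tests),
    ale = if (!is.null(report$ale))
      list(anova = report$ale$anova, tests = report$ale$tests),
    acuity = report$acuity)
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
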