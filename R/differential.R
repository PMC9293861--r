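#' Two-group differential test on count data
#'
#' A Wald-style test for differential abundance between two conditions,
#' applied identically to gene counts and per-peak tag counts. Counts are
#' size-factor normalized; the log2 fold change is computed on pseudocount-
#' shrunk group means, `log2((mean_b + pc) / (mean_a + pc))`. The standard
#' error comes from a negative-binomial variance model `mu + phi * mu^2` with
#' a per-feature method-of-moments dispersion estimate floored at the
#' bias-corrected median dispersion across features (the moment estimator at
#' `df` residual degrees of freedom scales like a chi-square, so the raw
#' cross-feature median underestimates the trend by `qchisq(0.5, df) / df`).
#' P-values are from the standard normal and are BH-adjusted.
#'
#' With a single replicate per group the dispersion cannot be estimated from
#' the data; the test then falls back to the floor alone and the result is
#' flagged unreliable.
#'
#' @param counts Data frame, `feature_id` plus one column per sample.
#' @param design Data frame with columns `sample_id`, `condition` (and
#'   optionally `replicate`).
#' @param group_a,group_b Condition labels to compare; fold changes are
#'   reported as b over a.
#' @param size_factors Optional precomputed [estimate_size_factors()] output.
#' @param pseudocount Shrinkage offset for means and fold changes (default 1).
#' @return A `tlr_de` tibble with columns `feature_id`, `base_mean_a`,
#'   `base_mean_b`, `log2_fc`, `stat`, `p_value`, `padj`.
#' @examples
#' ds <- simulate_tlr_dataset(seed = 1, n_genes = 200, n_peaks_per_cluster = 10)
#' de <- differential_test(ds$rna_counts, ds$design, "Unstim", "CpG")
#' head(dplyr::arrange(de, padj))
#' @export
differential_test <- function(counts, design, group_a, group_b,
                              size_factors = NULL, pseudocount = 1) {
  design <- check_design(counts, design)
  sa <- condition_samples(design, group_a)
  sb <- condition_samples(design, group_b)
  norm <- counts_matrix(normalize_counts(counts, size_factors))
  A <- norm[, sa, drop = FALSE]
  B <- norm[, sb, drop = FALSE]
  nA <- length(sa); nB <- length(sb)
  mA <- rowMeans(A); mB <- rowMeans(B)
  pc <- pseudocount
  lfc <- log2((mB + pc) / (mA + pc))

  df_resid <- (nA - 1) + (nB - 1)
  unreliable <- df_resid < 1
  if (unreliable) {
    warn("only one replicate per group: dispersion is not estimable, p-values are unreliable")
    dhat <- rep(0, nrow(norm))
    floor_d <- 0.1 # conventional fallback dispersion, flagged via the warning
  } else {
    vA <- if (nA > 1) apply(A, 1, stats::var) else 0
    vB <- if (nB > 1) apply(B, 1, stats::var) else 0
    num <- (nA - 1) * (vA - mA) + (nB - 1) * (vB - mB)
    den <- (nA - 1) * mA^2 + (nB - 1) * mB^2
    dhat <- pmax(0, ifelse(den > 0, num / den, 0))
    correction <- df_resid / stats::qchisq(0.5, df = df_resid)
    floor_d <- max(1e-8, stats::median(dhat[mA + mB > 0]) * correction)
  }
  d_used <- pmax(dhat, floor_d)

  var_log2 <- function(m, n) (m + d_used * m^2) / n / ((m + pc)^2 * log(2)^2)
  se <- sqrt(var_log2(mA, nA) + var_log2(mB, nB))
  stat <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * stats::pnorm(-abs(stat))
  out <- tibble::tibble(
    feature_id = rownames(norm),
    base_mean_a = unname(mA),
    base_mean_b = unname(mB),
    log2_fc = unname(lfc),
    stat = unname(stat),
    p_value = unname(p),
    padj = unname(stats::p.adjust(p, method = "BH"))
  )
  new_result(out, "tlr_de",
             group_a = group_a, group_b = group_b,
             dispersion_floor = floor_d, unreliable = unreliable)
}

#' Across-condition variability test
#'
#' One-way F-test on vst-like values across all conditions, used to keep
#' only features whose signal genuinely varies with stimulation (the
#' condition-specificity filter for acetylated regions). Constant features
#' return p = 1. P-values are BH-adjusted.
#'
#' @inheritParams differential_test
#' @return A tibble with `feature_id`, `f_stat`, `df1`, `df2`, `p_value`,
#'   `padj`.
#' @export
variability_test <- function(counts, design, size_factors = NULL) {
  design <- check_design(counts, design)
  conds <- unique(design$condition)
  k <- length(conds)
  n <- nrow(design)
  if (k < 2) abort("variability_test needs at least 2 conditions")
  if (n - k < 1) abort("degenerate design: need more samples than conditions")
  v <- counts_matrix(vst_transform(counts, size_factors))
  v <- v[, design$sample_id, drop = FALSE]
  grp <- factor(design$condition, levels = conds)
  grand <- rowMeans(v)
  ss_tot <- rowSums((v - grand)^2)
  group_means <- vapply(conds, function(cd) {
    rowMeans(v[, design$condition == cd, drop = FALSE])
  }, numeric(nrow(v)))
  n_per <- vapply(conds, function(cd) sum(design$condition == cd), numeric(1))
  ss_between <- rowSums(sweep((group_means - grand)^2, 2, n_per, `*`))
  ss_within <- pmax(0, ss_tot - ss_between)
  df1 <- k - 1
  df2 <- n - k
  f <- ifelse(ss_within > 1e-12, (ss_between / df1) / (ss_within / df2), NA_real_)
  p <- ifelse(is.na(f), NA_real_, stats::pf(f, df1, df2, lower.tail = FALSE))
  # constant features (no variance at all) are definitionally non-variable
  constant <- ss_tot < 1e-12
  p[constant] <- 1
  f[constant] <- 0
  # non-constant features with zero within-group variance are maximally variable
  p[is.na(p)] <- 0
  f[is.na(f)] <- Inf
  tibble::tibble(
    feature_id = rownames(v),
    f_stat = unname(f),
    df1 = df1,
    df2 = df2,
    p_value = unname(p),
    padj = unname(stats::p.adjust(p, method = "BH"))
  )
}
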