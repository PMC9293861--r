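# Fold-change patterns on per-peak tag counts, rule-based five-cluster
# classification of co-repressor binding, enhancer filtering/clustering, and
# the delta-binding vs delta-acetylation correlation.

#' Per-condition fold-change pattern of peak tag counts
#'
#' Normalizes tag counts by size factors, averages replicates per condition,
#' and exposes pseudocount-regularized fold changes between any ordered
#' condition pair: `FC(c1, c2) = (mean_c1 + pc) / (mean_c2 + pc)`.
#'
#' @param tag_counts Tag-count tibble (`feature_id` + sample columns).
#' @param design A [tlr_design()] tibble.
#' @param size_factors Optional [estimate_size_factors()] output.
#' @param pseudocount Regularizer (default 1).
#' @return A `fc_pattern` tibble of per-condition normalized means
#'   (`feature_id`, one column per condition) with the pseudocount attached.
#' @export
fold_enrichment_matrix <- function(tag_counts, design, size_factors = NULL,
                                   pseudocount = 1) {
  design <- check_design(tag_counts, design)
  norm <- counts_matrix(normalize_counts(tag_counts, size_factors))
  conds <- unique(design$condition)
  means <- vapply(conds, function(cd) {
    rowMeans(norm[, condition_samples(design, cd), drop = FALSE])
  }, numeric(nrow(norm)))
  out <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(norm)),
                          tibble::as_tibble(means))
  new_result(out, "fc_pattern", pseudocount = pseudocount)
}

#' Fold change between two conditions of a pattern
#'
#' @param fp A `fc_pattern` from [fold_enrichment_matrix()].
#' @param c1,c2 Condition labels (numerator, denominator).
#' @return Numeric vector of fold changes, one per feature.
#' @export
fold_change <- function(fp, c1, c2) {
  pc <- attr(fp, "pseudocount")
  for (cd in c(c1, c2)) if (!cd %in% names(fp)) abort(paste0("unknown condition: '", cd, "'"))
  (fp[[c1]] + pc) / (fp[[c2]] + pc)
}

#' Rule-based five-cluster classification of co-repressor peaks
#'
#' Applies the study's five fold-change rules to each peak's per-condition
#' pattern, in precedence order I > II > III > V > IV (first match wins):
#' \itemize{
#'   \item I: at least `threshold`-fold increase vs unstimulated in all three
#'     stimulations (CpG, pIC, combined);
#'   \item II: increase in the combined stimulation vs both CpG and pIC;
#'   \item III: increase in pIC vs both CpG and the combined stimulation;
#'   \item V: at least `threshold`-fold decrease vs unstimulated in all three
#'     stimulations;
#'   \item IV: no rule matched (no significant change).
#' }
#' The rule trace (which raw rules matched) is retained so the precedence is
#' auditable; peaks matching more than one raw rule are countable from it.
#'
#' @param fp A `fc_pattern` from [fold_enrichment_matrix()].
#' @param threshold Fold-change cutoff (default 2).
#' @param conditions Named mapping of roles (`unstim`, `cpg`, `pic`,
#'   `combined`) to condition labels.
#' @return A `tlr_clusters` tibble: `peak_id`, `cluster`, logical rule-trace
#'   columns `rule_I`, `rule_II`, `rule_III`, `rule_V`.
#' @export
classify_ncor1_clusters <- function(fp, threshold = 2,
                                    conditions = c(unstim = "Unstim", cpg = "CpG",
                                                   pic = "pIC", combined = "CpG_pIC_IFNg")) {
  for (cd in conditions) if (!cd %in% names(fp)) abort(paste0("missing condition: '", cd, "'"))
  un <- conditions[["unstim"]]; cg <- conditions[["cpg"]]
  pi_ <- conditions[["pic"]]; cb <- conditions[["combined"]]
  fc <- function(a, b) fold_change(fp, a, b)
  rule_I <- fc(cg, un) >= threshold & fc(pi_, un) >= threshold & fc(cb, un) >= threshold
  rule_II <- fc(cb, cg) >= threshold & fc(cb, pi_) >= threshold
  rule_III <- fc(pi_, cg) >= threshold & fc(pi_, cb) >= threshold
  rule_V <- fc(un, cg) >= threshold & fc(un, pi_) >= threshold & fc(un, cb) >= threshold
  cluster <- dplyr::case_when(
    rule_I ~ "I",
    rule_II ~ "II",
    rule_III ~ "III",
    rule_V ~ "V",
    TRUE ~ "IV"
  )
  out <- tibble::tibble(peak_id = fp$feature_id, cluster = cluster,
                        rule_I = rule_I, rule_II = rule_II,
                        rule_III = rule_III, rule_V = rule_V)
  new_result(out, "tlr_clusters", threshold = threshold, label_set = c("I", "II", "III", "IV", "V"))
}

#' Filter peaks to variable, well-covered regions
#'
#' Keeps peaks that pass all three of: total vst-like signal across samples
#' at least `vst_sum_min`; at least `fold_min`-fold change (either direction)
#' between some stimulation and the unstimulated condition; and an adjusted
#' across-condition variability p below `padj_max`. The vst-sum constant is a
#' scale-dependent re-tuned analog of a sum-of-vst filter quoted on a
#' different transform scale.
#'
#' @param tag_counts Tag-count tibble.
#' @param design A [tlr_design()] tibble.
#' @param size_factors Optional size factors.
#' @param vst_sum_min Minimum sum of vst-like values across samples
#'   (default 40 on this package's log2(normalized + 1) scale).
#' @param fold_min Minimum fold change vs unstimulated (default 2).
#' @param padj_max Variability-test adjusted-p cutoff (default 0.05).
#' @param unstim Unstimulated condition label.
#' @return The tag-count rows passing all filters, with attribute `filter`
#'   holding the per-peak filter table.
#' @export
select_variable_regions <- function(tag_counts, design, size_factors = NULL,
                                    vst_sum_min = 40, fold_min = 2,
                                    padj_max = 0.05, unstim = "Unstim") {
  design <- check_design(tag_counts, design)
  if (is.null(size_factors)) size_factors <- estimate_size_factors(tag_counts)
  v <- counts_matrix(vst_transform(tag_counts, size_factors))
  vst_sum <- rowSums(v)
  fp <- fold_enrichment_matrix(tag_counts, design, size_factors)
  stim <- setdiff(unique(design$condition), unstim)
  fc_max <- Reduce(pmax, lapply(stim, function(cd) {
    pmax(fold_change(fp, cd, unstim), fold_change(fp, unstim, cd))
  }))
  vt <- variability_test(tag_counts, design, size_factors)
  filt <- tibble::tibble(
    peak_id = tag_counts$feature_id,
    vst_sum = unname(vst_sum),
    fc_max = fc_max,
    padj = vt$padj,
    pass = vst_sum >= vst_sum_min & fc_max >= fold_min & vt$padj < padj_max
  )
  out <- tag_counts[filt$pass, , drop = FALSE]
  attr(out, "filter") <- filt
  out
}

#' Cluster enhancer peaks into condition-specific patterns
#'
#' Each retained peak's per-condition mean vst-like profile is z-scaled and
#' peaks are clustered by average-linkage hierarchical clustering with
#' distance `1 - Pearson`, cut into `k` clusters. Cluster labels are assigned
#' from the centroid on the normalized-count scale: a cluster whose centroid
#' peaks in the unstimulated condition is `down`; one whose CpG and pIC
#' centroids are within 25% of each other and both above unstimulated is
#' `common`; otherwise the larger of the CpG/pIC centroids names the cluster
#' (`CpG-specific` / `pIC-specific`). Peaks are processed in `peak_id` order
#' so the assignment does not depend on input row order.
#'
#' @param tag_counts Tag counts of the retained peaks.
#' @param design A [tlr_design()] tibble.
#' @param k Number of clusters (default 4).
#' @param size_factors Optional size factors.
#' @param conditions Named role mapping as in [classify_ncor1_clusters()].
#' @param common_tol Relative CpG-vs-pIC centroid difference below which a
#'   cluster is `common` (default 0.25).
#' @return A `tlr_clusters` tibble: `peak_id`, `cluster` (raw cut index),
#'   `label`.
#' @export
cluster_enhancer_patterns <- function(tag_counts, design, k = 4, size_factors = NULL,
                                      conditions = c(unstim = "Unstim", cpg = "CpG",
                                                     pic = "pIC", combined = "CpG_pIC_IFNg"),
                                      common_tol = 0.25) {
  design <- check_design(tag_counts, design)
  if (nrow(tag_counts) < k) abort("fewer peaks than clusters requested")
  ord <- order(tag_counts$feature_id)
  tag_counts <- tag_counts[ord, , drop = FALSE]
  v <- counts_matrix(vst_transform(tag_counts, size_factors))
  conds <- unique(design$condition)
  prof <- vapply(conds, function(cd) {
    rowMeans(v[, condition_samples(design, cd), drop = FALSE])
  }, numeric(nrow(v)))
  z <- t(scale(t(prof)))
  z[is.na(z)] <- 0 # constant profiles carry no pattern
  d <- stats::as.dist(1 - stats::cor(t(z)))
  d[is.na(d)] <- 1
  hc <- stats::hclust(d, method = "average")
  cut <- stats::cutree(hc, k = k)
  # label by centroid on the normalized-count scale (vst differences compress)
  lin <- 2^prof - 1
  un <- conditions[["unstim"]]; cg <- conditions[["cpg"]]; pi_ <- conditions[["pic"]]
  labels <- vapply(seq_len(k), function(cl) {
    cen <- colMeans(lin[cut == cl, , drop = FALSE])
    if (names(cen)[which.max(cen)] == un) return("down")
    close <- abs(cen[[cg]] - cen[[pi_]]) / max(cen[[cg]], cen[[pi_]]) <= common_tol
    if (close && cen[[cg]] > cen[[un]] && cen[[pi_]] > cen[[un]]) return("common")
    if (cen[[cg]] >= cen[[pi_]]) "CpG-specific" else "pIC-specific"
  }, character(1))
  out <- tibble::tibble(peak_id = tag_counts$feature_id,
                        cluster = unname(cut),
                        label = labels[cut])
  new_result(out, "tlr_clusters", k = k,
             label_set = c("CpG-specific", "pIC-specific", "common", "down"))
}

#' Correlation of binding change with acetylation change
#'
#' Pearson correlation, over paired peaks, of the log2 fold change (condition
#' vs unstimulated) of one mark against the other, with a Fisher-z 95%
#' confidence interval.
#'
#' @param pairs Pair table from [pair_by_center_window()].
#' @param fp_a,fp_b `fc_pattern` objects for the two marks (`a` keyed by
#'   `a_id`, `b` by `b_id`).
#' @param condition Stimulation condition to contrast against `unstim`.
#' @param unstim Unstimulated condition label.
#' @param conf_level Confidence level (default 0.95).
#' @return A one-row tibble: `condition`, `n`, `r`, `ci_lo`, `ci_hi`.
#' @export
delta_delta_correlation <- function(pairs, fp_a, fp_b, condition,
                                    unstim = "Unstim", conf_level = 0.95) {
  if (nrow(pairs) < 3) abort("need at least 3 paired peaks")
  ia <- match(pairs$a_id, fp_a$feature_id)
  ib <- match(pairs$b_id, fp_b$feature_id)
  if (anyNA(ia) || anyNA(ib)) abort("pairs reference peaks absent from the patterns")
  da <- log2(fold_change(fp_a, condition, unstim))[ia]
  db <- log2(fold_change(fp_b, condition, unstim))[ib]
  r <- stats::cor(da, db)
  n <- length(da)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- atanh(r)
  se <- 1 / sqrt(n - 3)
  tibble::tibble(condition = condition, n = n, r = r,
                 ci_lo = tanh(z - zq * se), ci_hi = tanh(z + zq * se))
}
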