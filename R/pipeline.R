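# End-to-end pipeline over a simulated (or equivalently structured) dataset.

#' Run the full multi-omics integration pipeline
#'
#' Executes every analysis stage on a dataset shaped like
#' [simulate_tlr_dataset()] output: RNA differential testing against the
#' unstimulated condition, response-class calling, synergy/antagonism
#' scoring; blacklist filtering, fold-change patterns and five-cluster
#' classification of the co-repressor track; enhancer filtering, four-way
#' pattern clustering and super-enhancer calling on the acetylation track;
#' center-window pairing of the two marks with the delta-binding vs
#' delta-acetylation correlation per stimulation; nearest-TSS annotation and
#' response-gene association odds ratios for the co-repressor clusters. All
#' stages are deterministic given the dataset and `perm_seed`.
#'
#' @param ds A `tlr_dataset` (or a list with the same components).
#' @param lfc_min,padj_max Response-class thresholds.
#' @param synergy_upper,synergy_lower Synergy/antagonism ratio thresholds.
#' @param vst_sum_min Enhancer signal-sum filter on the vst-like scale.
#' @param pair_window Center-to-center pairing window (bp).
#' @param n_perm,perm_seed Region-overlap permutation settings.
#' @return A named list of results (`de`, `response`, `synergy`,
#'   `ncor1_clusters`, `k27_selected`, `k27_clusters`, `delta_delta`,
#'   `superenhancers`, `association`, `region_overlap`).
#' @export
run_tlr_pipeline <- function(ds, lfc_min = 1, padj_max = 0.05,
                             synergy_upper = 1.2, synergy_lower = 0.5,
                             vst_sum_min = 40, pair_window = 500,
                             n_perm = 200, perm_seed = 1) {
  design <- ds$design
  conds <- unique(design$condition)
  unstim <- conds[1]; cpg <- conds[2]; pic <- conds[3]; combined <- conds[4]

  # ---- RNA: response classes and synergy ----
  sf <- estimate_size_factors(ds$rna_counts)
  de_cpg <- differential_test(ds$rna_counts, design, unstim, cpg, sf)
  de_pic <- differential_test(ds$rna_counts, design, unstim, pic, sf)
  response <- classify_tlr_response(de_cpg, de_pic, lfc_min, padj_max)
  gene_sets <- response_gene_sets(response, "up")
  norm <- normalize_counts(ds$rna_counts, sf)
  eligible <- sort(unique(unlist(gene_sets, use.names = FALSE)))
  synergy <- synergy_antagonism(norm, design, eligible,
                                combined = combined, cpg = cpg, pic = pic,
                                upper = synergy_upper, lower = synergy_lower)

  # ---- NCoR1 track: five-cluster rule classification ----
  ncor1_peaks <- subtract_blacklist(ds$ncor1$peaks, ds$blacklist)
  ncor1_tags <- ds$ncor1$tag_counts[ds$ncor1$tag_counts$feature_id %in% ncor1_peaks$peak_id, ]
  fp_ncor1 <- fold_enrichment_matrix(ncor1_tags, design)
  cond_map <- c(unstim = unstim, cpg = cpg, pic = pic, combined = combined)
  ncor1_clusters <- classify_ncor1_clusters(fp_ncor1, conditions = cond_map)

  # ---- H3K27ac track: filter, cluster, super-enhancers ----
  k27_peaks <- subtract_blacklist(ds$k27$peaks, ds$blacklist)
  k27_tags <- ds$k27$tag_counts[ds$k27$tag_counts$feature_id %in% k27_peaks$peak_id, ]
  k27_sf <- estimate_size_factors(k27_tags)
  k27_selected <- select_variable_regions(k27_tags, design, k27_sf,
                                          vst_sum_min = vst_sum_min,
                                          unstim = unstim)
  k27_clusters <- cluster_enhancer_patterns(k27_selected, design,
                                            size_factors = k27_sf,
                                            conditions = cond_map)
  norm_k27 <- counts_matrix(normalize_counts(k27_tags, k27_sf))
  signal <- rowSums(norm_k27)
  se_input <- dplyr::mutate(k27_peaks, signal = unname(signal[.data$peak_id]))
  stitched <- stitch_peaks(se_input)
  superenhancers <- call_super_enhancers(stitched)

  # ---- Integration: pairing, delta-delta correlation, associations ----
  fp_k27 <- fold_enrichment_matrix(k27_tags, design, k27_sf)
  pairs <- pair_by_center_window(ncor1_peaks, k27_peaks, window = pair_window)
  delta_delta <- purrr::map_dfr(setdiff(conds, unstim), function(cd) {
    delta_delta_correlation(pairs, fp_ncor1, fp_k27, cd, unstim = unstim)
  })

  ann <- annotate_nearest_tss(ncor1_peaks, ds$genes)
  cluster_genes <- ncor1_clusters %>%
    dplyr::left_join(ann, by = "peak_id") %>%
    dplyr::filter(!is.na(.data$gene_id))
  cluster_sets <- split(cluster_genes$gene_id, cluster_genes$cluster)
  cluster_sets <- lapply(cluster_sets, unique)
  universe <- ds$rna_counts$feature_id
  association <- fisher_overlap_matrix(gene_sets, cluster_sets, universe)

  up_cluster_peaks <- ncor1_peaks[ncor1_peaks$peak_id %in%
    ncor1_clusters$peak_id[ncor1_clusters$cluster %in% c("I", "II", "III")], ]
  up_k27_ids <- attr(k27_selected, "filter")$peak_id[attr(k27_selected, "filter")$pass]
  region_overlap <- region_overlap_permutation(
    up_cluster_peaks, k27_peaks[k27_peaks$peak_id %in% up_k27_ids, ],
    ds$genome, n_perm = n_perm, seed = perm_seed
  )

  list(
    size_factors = sf, de = list(cpg = de_cpg, pic = de_pic),
    response = response, gene_sets = gene_sets, synergy = synergy,
    ncor1_clusters = ncor1_clusters, fp_ncor1 = fp_ncor1,
    k27_selected = k27_selected, k27_clusters = k27_clusters, fp_k27 = fp_k27,
    pairs = pairs, delta_delta = delta_delta,
    stitched = stitched, superenhancers = superenhancers,
    annotation = ann, association = association,
    region_overlap = region_overlap
  )
}
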