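# Response-class gene calling and synergy/antagonism scoring.

#' Classify genes into TLR response classes
#'
#' Combines two differential results (CpG vs unstimulated, pIC vs
#' unstimulated) into response classes. A gene is called regulated in a
#' direction when `|log2_fc| >= lfc_min` with the matching sign and
#' `padj < padj_max` (the log2 fold-change threshold is inclusive). The up
#' and down channels are classified separately: up-regulated calls yield the
#' induced CpG-specific / pIC-specific / common classes the study names; the
#' analogous down-channel classification is emitted alongside.
#'
#' @param de_cpg,de_pic [differential_test()] results sharing the same
#'   feature universe (unstimulated as group a).
#' @param lfc_min Minimum absolute log2 fold change (default 1, inclusive).
#' @param padj_max Adjusted-p threshold (default 0.05, exclusive).
#' @return A tibble with one row per gene per direction: `gene_id`,
#'   `direction` (`up`/`down`), `class` (`CpG-specific`, `pIC-specific`,
#'   `common`, `none`), and the underlying calls `cpg_called`, `pic_called`.
#' @export
classify_tlr_response <- function(de_cpg, de_pic, lfc_min = 1, padj_max = 0.05) {
  if (!setequal(de_cpg$feature_id, de_pic$feature_id)) {
    abort("the two differential results must share the same feature universe")
  }
  de_pic <- de_pic[match(de_cpg$feature_id, de_pic$feature_id), ]
  one_channel <- function(sgn, label) {
    cpg <- sgn * de_cpg$log2_fc >= lfc_min & de_cpg$padj < padj_max
    pic <- sgn * de_pic$log2_fc >= lfc_min & de_pic$padj < padj_max
    tibble::tibble(
      gene_id = de_cpg$feature_id,
      direction = label,
      class = dplyr::case_when(
        cpg & pic ~ "common",
        cpg ~ "CpG-specific",
        pic ~ "pIC-specific",
        TRUE ~ "none"
      ),
      cpg_called = cpg,
      pic_called = pic
    )
  }
  dplyr::bind_rows(one_channel(1, "up"), one_channel(-1, "down"))
}

#' Extract response gene sets
#'
#' Named list of gene ID vectors per class for one direction, the form the
#' overlap statistics consume.
#'
#' @param classification Output of [classify_tlr_response()].
#' @param direction `"up"` (default) or `"down"`.
#' @export
response_gene_sets <- function(classification, direction = "up") {
  cls <- classification[classification$direction == direction &
                          classification$class != "none", ]
  split(cls$gene_id, cls$class)
}

#' Synergy/antagonism ratio in combined stimulation
#'
#' For each eligible gene, the ratio of the mean normalized count in the
#' combined stimulation to the sum of the mean normalized counts in the two
#' single stimulations:
#' `R = mean(combined) / (mean(CpG) + mean(pIC))`.
#' Genes with `R > upper` are called synergy, `R < lower` antagonist,
#' otherwise neither (strict inequalities). When the denominator is below
#' `eps` the ratio is undefined and flagged.
#'
#' @param norm_counts Normalized counts ([normalize_counts()] output).
#' @param design A [tlr_design()] tibble.
#' @param eligible Gene IDs to score (the union of the response classes);
#'   defaults to all features.
#' @param combined,cpg,pic Condition labels.
#' @param upper,lower Call thresholds (defaults 1.2 and 0.5).
#' @param agg Replicate aggregation function (default `mean`).
#' @param eps Denominator tolerance below which the call is `undefined`.
#' @return A `tlr_synergy` tibble: `gene_id`, `mean_cpg`, `mean_pic`,
#'   `mean_combined`, `ratio`, `call`.
#' @export
synergy_antagonism <- function(norm_counts, design, eligible = NULL,
                               combined = "CpG_pIC_IFNg", cpg = "CpG", pic = "pIC",
                               upper = 1.2, lower = 0.5, agg = mean, eps = 1e-6) {
  design <- check_design(norm_counts, design)
  m <- counts_matrix(norm_counts)
  if (is.null(eligible)) eligible <- rownames(m)
  missing <- setdiff(eligible, rownames(m))
  if (length(missing) > 0) abort(paste0("eligible genes absent from counts: ",
                                        paste(utils::head(missing, 5), collapse = ", ")))
  m <- m[eligible, , drop = FALSE]
  agg_cond <- function(cond) {
    apply(m[, condition_samples(design, cond), drop = FALSE], 1, agg)
  }
  mc <- agg_cond(cpg); mp <- agg_cond(pic); mb <- agg_cond(combined)
  denom <- mc + mp
  ratio <- ifelse(denom > eps, mb / denom, NA_real_)
  out <- tibble::tibble(
    gene_id = eligible,
    mean_cpg = unname(mc),
    mean_pic = unname(mp),
    mean_combined = unname(mb),
    ratio = unname(ratio),
    call = dplyr::case_when(
      is.na(ratio) ~ "undefined",
      ratio > upper ~ "synergy",
      ratio < lower ~ "antagonist",
      TRUE ~ "neither"
    )
  )
  new_result(out, "tlr_synergy", upper = upper, lower = lower,
             conditions = c(combined = combined, cpg = cpg, pic = pic))
}
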