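# Association statistics: gene-set overlap odds ratios and genomic-region
# overlap significance by permutation.

# Merge possibly-overlapping intervals on one chromosome into disjoint sorted
# runs; returns a list(start, end).
reduce_runs <- function(start, end) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  cm <- cummax(end)
  brk <- c(TRUE, start[-1] > cm[-length(cm)])
  grp <- cumsum(brk)
  list(start = as.numeric(tapply(start, grp, min)),
       end = as.numeric(tapply(end, grp, max)))
}

# Total bp intersection of two disjoint sorted interval runs, by an
# elementary-segment sweep over the combined breakpoints.
union_intersect_bp <- function(a, b) {
  pts <- sort(unique(c(a$start, a$end, b$start, b$end)))
  if (length(pts) < 2) return(0)
  left <- pts[-length(pts)]
  width <- diff(pts)
  ia <- findInterval(left, a$start)
  in_a <- ia >= 1 & left < a$end[pmax(ia, 1)]
  ib <- findInterval(left, b$start)
  in_b <- ib >= 1 & left < b$end[pmax(ib, 1)]
  sum(width[in_a & in_b])
}

#' Fisher overlap test between two gene sets
#'
#' Builds the 2x2 table (both, A only, B only, neither) against a stated
#' universe, reports the sample odds ratio `OR = ad / bc` (infinite when
#' `bc = 0` and `ad > 0`), its log, and the two-sided Fisher exact p-value
#' from hypergeometric enumeration.
#'
#' @param set_a,set_b Character vectors of gene IDs; must be subsets of
#'   `universe`.
#' @param universe Character vector defining the sampling frame (an explicit,
#'   deliberate choice — e.g. all expressed genes).
#' @return A one-row `tlr_overlap` tibble: `a`, `b`, `c`, `d`, `odds_ratio`,
#'   `log_odds`, `p_value`, `universe_size`.
#' @export
fisher_overlap <- function(set_a, set_b, universe) {
  off_a <- setdiff(set_a, universe)
  off_b <- setdiff(set_b, universe)
  if (length(off_a) + length(off_b) > 0) {
    abort(paste0("sets must be subsets of the universe; offenders: ",
                 paste(utils::head(c(off_a, off_b), 5), collapse = ", ")))
  }
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  a <- length(intersect(set_a, set_b))
  b <- length(set_a) - a
  c_ <- length(set_b) - a
  d <- length(universe) - a - b - c_
  or <- if (b * c_ == 0) {
    if (a * d > 0) Inf else NaN
  } else (a * d) / (b * c_)
  p <- stats::fisher.test(matrix(c(a, b, c_, d), 2, 2))$p.value
  out <- tibble::tibble(a = a, b = b, c = c_, d = d,
                        odds_ratio = or, log_odds = log(or),
                        p_value = p, universe_size = length(universe))
  new_result(out, "tlr_overlap")
}

#' All-pairs Fisher overlap with BH adjustment
#'
#' Applies [fisher_overlap()] to every pair of one named list of sets against
#' another, adjusting p-values by Benjamini-Hochberg within the family. This
#' is also the over-representation machinery: pass a gene-set collection as
#' `sets_b`.
#'
#' @param sets_a,sets_b Named lists of gene ID vectors.
#' @param universe Sampling frame for all tests.
#' @return A tibble with `set_a`, `set_b`, the table counts, `odds_ratio`,
#'   `log_odds`, `p_value`, `padj`.
#' @export
fisher_overlap_matrix <- function(sets_a, sets_b, universe) {
  grid <- tidyr::expand_grid(set_a = names(sets_a), set_b = names(sets_b))
  out <- purrr::pmap_dfr(grid, function(set_a, set_b) {
    res <- fisher_overlap(sets_a[[set_a]], sets_b[[set_b]], universe)
    dplyr::bind_cols(tibble::tibble(set_a = set_a, set_b = set_b), res)
  })
  dplyr::mutate(out, padj = stats::p.adjust(.data$p_value, method = "BH"))
}

#' Permutation test of genomic-region overlap
#'
#' The observed statistic is the total intersection (bp) between the unions
#' of two interval sets. The null shuffles the `a` regions uniformly within
#' their own chromosome, preserving lengths and counts, with `b` fixed; the
#' empirical p-value uses add-one smoothing:
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)`.
#'
#' @param a,b Interval tibbles.
#' @param genome A [genome_spec()] tibble covering both sets.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed (the test is deterministic given it).
#' @return A one-row `tlr_perm` tibble: `observed_bp`, `null_mean`,
#'   `null_sd`, `n_perm`, `p_value`, `seed`; the null draws are in attribute
#'   `null_bp`.
#' @export
region_overlap_permutation <- function(a, b, genome, n_perm = 1000, seed = 1) {
  check_peaks(a); check_peaks(b)
  len <- stats::setNames(genome$length, genome$chrom)
  if (!all(c(a$chrom, b$chrom) %in% names(len))) {
    abort("regions on chromosomes absent from genome")
  }
  if (any(a$end - a$start > len[a$chrom])) {
    abort("a region is longer than its chromosome")
  }
  b_red <- lapply(split(b[c("start", "end")], b$chrom), function(df) {
    reduce_runs(df$start, df$end)
  })
  overlap_bp <- function(chrom, start, end) {
    total <- 0
    for (ch in unique(chrom)) {
      bb <- b_red[[ch]]
      if (is.null(bb)) next
      sel <- chrom == ch
      aa <- reduce_runs(start[sel], end[sel])
      total <- total + union_intersect_bp(aa, bb)
    }
    total
  }
  observed <- overlap_bp(a$chrom, a$start, a$end)
  widths <- a$end - a$start
  max_start <- len[a$chrom] - widths
  withr::local_seed(seed)
  null_bp <- vapply(seq_len(n_perm), function(i) {
    new_start <- floor(stats::runif(nrow(a), 0, max_start + 1))
    overlap_bp(a$chrom, new_start, new_start + widths)
  }, numeric(1))
  p <- (1 + sum(null_bp >= observed)) / (n_perm + 1)
  out <- tibble::tibble(observed_bp = observed,
                        null_mean = mean(null_bp), null_sd = stats::sd(null_bp),
                        n_perm = n_perm, p_value = p, seed = seed)
  new_result(out, "tlr_perm", null_bp = null_bp)
}
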