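# Genomic-interval operations. All user-facing coordinates are 0-based,
# half-open tibbles; GenomicRanges (1-based, closed) is used internally with
# conversion at the boundary.

#' Merge overlapping and abutting intervals
#'
#' Returns the minimal set of disjoint intervals covering the union of the
#' input. Abutting half-open intervals (`end == start`) are merged.
#' Constituent peak IDs are retained in a list-column.
#'
#' @param peaks Interval tibble with `chrom`, `start`, `end`, `peak_id`.
#' @param id_prefix Prefix for merged-region IDs.
#' @return A sorted tibble of disjoint intervals with `n_constituents` and a
#'   `constituents` list-column.
#' @export
merge_intervals <- function(peaks, id_prefix = "merged") {
  check_peaks(peaks)
  if (nrow(peaks) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          peak_id = character(), n_constituents = integer(),
                          constituents = list()))
  }
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  chrom <- peaks$chrom[ord]
  start <- as.numeric(peaks$start[ord])
  end <- as.numeric(peaks$end[ord])
  id <- peaks$peak_id[ord]
  n <- length(start)
  # single-pass cumulative-max scan; abutting half-open intervals
  # (start == running max end) merge, a positive gap starts a new region
  grp <- integer(n)
  g <- 0L
  cm <- -Inf
  for (i in seq_len(n)) {
    if (i == 1L || chrom[i] != chrom[i - 1L]) cm <- -Inf
    if (start[i] > cm) g <- g + 1L
    grp[i] <- g
    cm <- max(cm, end[i])
  }
  starts <- tapply(start, grp, min)
  ends <- tapply(end, grp, max)
  chroms <- tapply(chrom, grp, `[`, 1)
  constituents <- unname(split(id, grp))
  constituents <- lapply(constituents, sort)
  tibble::tibble(
    chrom = unname(as.character(chroms)),
    start = unname(as.numeric(starts)),
    end = unname(as.numeric(ends)),
    peak_id = sprintf("%s_%05d", id_prefix, seq_along(starts)),
    n_constituents = lengths(constituents),
    constituents = constituents
  )
}

#' Extend peak summits and merge
#'
#' Each peak becomes `[summit - flank, summit + flank)`, clamped to the
#' chromosome, and the extended set is merged with [merge_intervals()].
#'
#' @param peaks Interval tibble with a `summit` column (absolute bp).
#' @param genome A [genome_spec()] tibble used for clamping.
#' @param flank Half-width of the extension (default 1000 bp).
#' @return Merged interval tibble (see [merge_intervals()]).
#' @export
extend_summits <- function(peaks, genome, flank = 1000) {
  check_peaks(peaks, require_summit = TRUE)
  len <- stats::setNames(genome$length, genome$chrom)
  if (!all(peaks$chrom %in% names(len))) abort("peaks on chromosomes absent from genome")
  ext <- peaks %>%
    dplyr::mutate(start = pmax(0, .data$summit - flank),
                  end = pmin(len[.data$chrom], .data$summit + flank))
  merge_intervals(ext, id_prefix = "ext")
}

#' Remove peaks overlapping a blacklist
#'
#' Any peak overlapping a blacklist interval by at least 1 bp is removed
#' entirely (removal, not trimming).
#'
#' @param peaks,blacklist Interval tibbles.
#' @return The filtered `peaks` tibble.
#' @export
subtract_blacklist <- function(peaks, blacklist) {
  check_peaks(peaks)
  if (is.null(blacklist) || nrow(blacklist) == 0) return(peaks)
  hits <- GenomicRanges::findOverlaps(peaks_to_gr(peaks), peaks_to_gr(blacklist))
  drop <- unique(S4Vectors::queryHits(hits))
  if (length(drop) == 0) peaks else peaks[-drop, , drop = FALSE]
}

#' Annotate peaks to their nearest TSS
#'
#' The nearest gene is chosen by distance from the peak center to the TSS,
#' ties broken by lexicographically smallest gene ID. The signed distance is
#' strand-aware (positive = peak downstream of the TSS); `promoter_flag`
#' marks peaks whose center lies within +/- 1 kb of the TSS.
#'
#' @param peaks Interval tibble.
#' @param genes Gene models (`gene_id`, `chrom`, `tss`, `strand`).
#' @param promoter_distance Promoter window half-width (default 1000 bp).
#' @return A tibble `peak_id`, `gene_id`, `distance`, `promoter_flag`; peaks
#'   on chromosomes without genes get `NA` annotation.
#' @export
annotate_nearest_tss <- function(peaks, genes, promoter_distance = 1000) {
  check_peaks(peaks)
  ann <- purrr::map_dfr(split(peaks, peaks$chrom), function(pk) {
    g <- genes[genes$chrom == pk$chrom[1], , drop = FALSE]
    center <- (pk$start + pk$end) / 2
    if (nrow(g) == 0) {
      return(tibble::tibble(peak_id = pk$peak_id, gene_id = NA_character_,
                            distance = NA_real_, promoter_flag = NA))
    }
    # order TSS; resolve exact-distance ties by smallest gene_id
    g <- g[order(g$tss, g$gene_id), , drop = FALSE]
    idx <- findInterval(center, g$tss)
    lo <- pmax(idx, 1L)
    hi <- pmin(idx + 1L, nrow(g))
    d_lo <- abs(center - g$tss[lo])
    d_hi <- abs(center - g$tss[hi])
    use_lo <- (idx >= 1) & (d_lo < d_hi |
      (d_lo == d_hi & g$gene_id[lo] <= g$gene_id[hi]))
    pick <- ifelse(use_lo, lo, hi)
    signed <- (center - g$tss[pick]) * ifelse(g$strand[pick] == "-", -1, 1)
    tibble::tibble(peak_id = pk$peak_id, gene_id = g$gene_id[pick],
                   distance = signed,
                   promoter_flag = abs(signed) <= promoter_distance)
  })
  ann[match(peaks$peak_id, ann$peak_id), ]
}

#' Pair peaks of two sets by center proximity
#'
#' Pairs each peak of `a` with the peak of `b` whose center is nearest and
#' within `window` bp (inclusive), one-to-one by greedy ascending distance;
#' ties go to the leftmost `b` peak. Unpaired peaks are omitted.
#'
#' @param a,b Interval tibbles.
#' @param window Maximum center-to-center distance (default 500 bp).
#' @return A tibble `a_id`, `b_id`, `distance`.
#' @export
pair_by_center_window <- function(a, b, window = 500) {
  check_peaks(a); check_peaks(b)
  ca <- dplyr::mutate(a, center = (.data$start + .data$end) / 2)
  cb <- dplyr::mutate(b, center = (.data$start + .data$end) / 2)
  cand <- purrr::map_dfr(intersect(unique(ca$chrom), unique(cb$chrom)), function(ch) {
    pa <- ca[ca$chrom == ch, ]
    pb <- cb[cb$chrom == ch, ]
    # candidate b centers within the window of each a center
    idx <- order(pb$center, pb$peak_id)
    pb <- pb[idx, ]
    purrr::map_dfr(seq_len(nrow(pa)), function(i) {
      j <- which(abs(pb$center - pa$center[i]) <= window)
      if (length(j) == 0) return(NULL)
      tibble::tibble(a_id = pa$peak_id[i], b_id = pb$peak_id[j],
                     b_center = pb$center[j],
                     distance = abs(pb$center[j] - pa$center[i]))
    })
  })
  if (nrow(cand) == 0) {
    return(tibble::tibble(a_id = character(), b_id = character(), distance = numeric()))
  }
  cand <- dplyr::arrange(cand, .data$distance, .data$b_center, .data$b_id, .data$a_id)
  used_a <- character(); used_b <- character()
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    if (!(cand$a_id[i] %in% used_a) && !(cand$b_id[i] %in% used_b)) {
      keep[i] <- TRUE
      used_a <- c(used_a, cand$a_id[i])
      used_b <- c(used_b, cand$b_id[i])
    }
  }
  dplyr::select(cand[keep, ], "a_id", "b_id", "distance")
}
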