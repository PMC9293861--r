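# Super-enhancer calling: stitch acetylated peaks, rank by aggregate signal,
# find the tangent-line cutoff on the scaled rank-signal curve.

#' Stitch peaks into regions
#'
#' Peaks whose end-to-start gap to the next peak on the same chromosome is at
#' most `gap` bp are transitively joined; the region signal is the sum of its
#' constituents' signal.
#'
#' @param peaks Interval tibble with a numeric `signal` column (e.g. total
#'   normalized tag count per peak).
#' @param gap Maximum stitching distance (default 12000 bp, no TSS
#'   exclusion).
#' @return A tibble of stitched regions: `chrom`, `start`, `end`,
#'   `region_id`, `signal`, `n_constituents`, `constituents` (list-column).
#' @export
stitch_peaks <- function(peaks, gap = 12000) {
  check_peaks(peaks)
  if (!"signal" %in% names(peaks)) abort("peaks need a 'signal' column")
  pk <- sort_peaks(peaks) %>%
    dplyr::mutate(start = as.numeric(.data$start), end = as.numeric(.data$end))
  grp <- pk %>%
    dplyr::group_by(.data$chrom) %>%
    dplyr::mutate(
      gap_prev = .data$start - dplyr::lag(cummax(.data$end), default = -Inf),
      new_region = as.integer(.data$gap_prev > gap),
      region = cumsum(.data$new_region)
    ) %>%
    dplyr::ungroup()
  out <- grp %>%
    dplyr::group_by(.data$chrom, .data$region) %>%
    dplyr::summarise(
      start = min(.data$start), end = max(.data$end),
      signal = sum(.data$signal),
      n_constituents = dplyr::n(),
      constituents = list(sort(.data$peak_id)),
      .groups = "drop"
    ) %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(region_id = sprintf("stitched_%05d", dplyr::row_number())) %>%
    dplyr::select("chrom", "start", "end", "region_id", "signal",
                  "n_constituents", "constituents")
  out
}

#' Call super-enhancers by the tangent-line cutoff
#'
#' Regions are sorted by ascending signal; rank and signal are rescaled to
#' the unit square. The cutoff is the point where a line of slope 1 is
#' tangent to the ranked-signal "hockey stick" from below — the point
#' maximizing `scaled_rank - scaled_signal`, which is where the discrete
#' slope of the curve crosses 1 for a convex ranked curve (the support-line
#' form is used because a pointwise first-crossing of the noisy discrete
#' slope is unstable). Regions with signal strictly above the cutoff signal
#' are super-enhancers; an all-equal or perfectly uniform (diagonal) signal
#' vector yields none. Ties at the cutoff resolve toward fewer
#' super-enhancers.
#'
#' @param regions Output of [stitch_peaks()] (or any tibble with `region_id`
#'   and `signal`).
#' @return A `tlr_secall` tibble sorted by ascending signal: `region_id`,
#'   `signal`, `rank`, `scaled_rank`, `scaled_signal`, `is_super`; attributes
#'   `cutoff_index` and `cutoff_signal` (NA when nothing exceeds slope 1).
#' @export
call_super_enhancers <- function(regions) {
  stopifnot(is.data.frame(regions), all(c("region_id", "signal") %in% names(regions)))
  if (nrow(regions) < 2) abort("need at least 2 regions")
  if (any(regions$signal < 0)) abort("signals must be non-negative")
  out <- regions %>%
    dplyr::arrange(.data$signal, .data$region_id) %>%
    dplyr::mutate(rank = dplyr::row_number())
  n <- nrow(out)
  span <- max(out$signal) - min(out$signal)
  out$scaled_rank <- (out$rank - 1) / (n - 1)
  out$scaled_signal <- if (span > 0) (out$signal - min(out$signal)) / span else rep(0, n)
  x <- out$scaled_rank
  y <- out$scaled_signal
  gap <- x - y
  if (max(gap) <= 0) {
    # curve on or above the diagonal everywhere: no tangent point, no calls
    cutoff_index <- NA_integer_
    cutoff_signal <- NA_real_
    out$is_super <- FALSE
  } else {
    # ties toward fewer super-enhancers: the highest-ranked tangent point
    cutoff_index <- max(which(gap == max(gap)))
    cutoff_signal <- out$signal[cutoff_index]
    out$is_super <- out$signal > cutoff_signal
  }
  new_result(out, "tlr_secall", cutoff_index = cutoff_index,
             cutoff_signal = cutoff_signal)
}

#' Annotate super-enhancer calls to nearest genes
#'
#' @param secall A `tlr_secall` tibble (must retain `chrom`, `start`, `end`).
#' @param genes Gene models.
#' @return The call tibble with `gene_id`, `distance`, `promoter_flag`.
#' @export
annotate_super_enhancers <- function(secall, genes) {
  regions <- dplyr::mutate(secall, peak_id = .data$region_id)
  ann <- annotate_nearest_tss(regions, genes)
  dplyr::bind_cols(secall, dplyr::select(ann, "gene_id", "distance", "promoter_flag"))
}
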