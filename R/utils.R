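# Internal helpers shared across modules.

#' @importFrom rlang %||% abort warn
#' @importFrom dplyr %>%
NULL

# Convert a counts/expression tibble (feature_id + one numeric column per
# sample) into a base matrix with feature_id rownames.
counts_matrix <- function(counts) {
  stopifnot(is.data.frame(counts), "feature_id" %in% names(counts))
  m <- as.matrix(counts[setdiff(names(counts), "feature_id")])
  if (!is.numeric(m)) abort("all sample columns must be numeric")
  rownames(m) <- counts$feature_id
  m
}

# Inverse of counts_matrix().
matrix_counts <- function(m) {
  tibble::as_tibble(m, rownames = "feature_id")
}

check_design <- function(counts, design) {
  stopifnot(is.data.frame(design), all(c("sample_id", "condition") %in% names(design)))
  samples <- setdiff(names(counts), "feature_id")
  missing <- setdiff(samples, design$sample_id)
  if (length(missing) > 0) {
    abort(paste0("samples absent from design: ", paste(missing, collapse = ", ")))
  }
  invisible(design[match(samples, design$sample_id), , drop = FALSE])
}

condition_samples <- function(design, condition) {
  if (!condition %in% design$condition) {
    abort(paste0("unknown condition label: '", condition, "'"))
  }
  design$sample_id[design$condition == condition]
}

check_peaks <- function(peaks, require_summit = FALSE) {
  stopifnot(is.data.frame(peaks))
  need <- c("chrom", "start", "end", "peak_id")
  missing <- setdiff(need, names(peaks))
  if (length(missing) > 0) {
    abort(paste0("peak table lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (nrow(peaks) > 0) {
    if (any(peaks$start < 0) || any(peaks$end <= peaks$start)) {
      abort("invalid intervals: need 0 <= start < end")
    }
    if (anyDuplicated(peaks$peak_id)) abort("peak_id values must be unique")
  }
  if (require_summit) {
    if (!"summit" %in% names(peaks) || anyNA(peaks$summit)) {
      bad <- if ("summit" %in% names(peaks)) peaks$peak_id[is.na(peaks$summit)][1] else peaks$peak_id[1]
      abort(paste0("summit required but missing (first offender: ", bad, ")"))
    }
  }
  invisible(peaks)
}

# 0-based half-open tibble -> GRanges (1-based closed) and back.
peaks_to_gr <- function(peaks) {
  GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start + 1L, end = peaks$end),
    peak_id = peaks$peak_id
  )
}

gr_to_peaks <- function(gr, id_prefix = "region") {
  tibble::tibble(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peak_id = if (!is.null(gr$peak_id)) gr$peak_id else sprintf("%s_%05d", id_prefix, seq_along(gr))
  )
}

sort_peaks <- function(peaks) {
  dplyr::arrange(peaks, .data$chrom, .data$start, .data$end, .data$peak_id)
}

new_result <- function(x, class, ...) {
  attrs <- list(...)
  for (nm in names(attrs)) attr(x, nm) <- attrs[[nm]]
  class(x) <- c(class, class(x))
  x
}

#' @importFrom rlang .data
NULL
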