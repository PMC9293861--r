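# Readers/writers for the plain-text interchange formats used by the
# pipeline. All coordinates are written as 0-based half-open, matching the
# BED convention; round-trips are byte-stable for valid files.

#' Read and write BED6
#'
#' BED6 columns: chrom, start, end, name, score, strand. Gene models are
#' written with `start = tss`, `end = tss + 1`.
#'
#' @param path File path.
#' @return `read_bed()` returns an interval tibble (`chrom`, `start`, `end`,
#'   `peak_id`, `score`, `strand`).
#' @export
read_bed <- function(path) {
  readr::read_tsv(path, col_names = c("chrom", "start", "end", "peak_id", "score", "strand"),
                  col_types = "ciicdc", progress = FALSE)
}

#' @rdname read_bed
#' @param peaks Interval tibble; missing `score`/`strand` become `0`/`.`.
#' @export
write_bed <- function(peaks, path) {
  out <- tibble::tibble(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    peak_id = peaks$peak_id,
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else "."
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' @rdname read_bed
#' @param genes Gene-model tibble from [build_gene_models()].
#' @export
write_gene_bed <- function(genes, path) {
  write_bed(tibble::tibble(chrom = genes$chrom, start = genes$tss,
                           end = genes$tss + 1, peak_id = genes$gene_id,
                           score = 0, strand = genes$strand), path)
}

#' @rdname read_bed
#' @export
read_gene_bed <- function(path) {
  bed <- read_bed(path)
  tibble::tibble(gene_id = bed$peak_id, chrom = bed$chrom,
                 tss = bed$start, strand = bed$strand)
}

#' Read and write narrowPeak
#'
#' The 10-column ENCODE narrowPeak format; column 10 is the summit offset
#' from `start` (-1 when absent). The absolute `summit` column of the
#' interval tibble is converted to/from that offset.
#'
#' @param path File path.
#' @return `read_narrowpeak()` returns an interval tibble with `summit`.
#' @export
read_narrowpeak <- function(path) {
  np <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", "peak_id", "score", "strand",
                  "signalValue", "pValue", "qValue", "peak"),
    col_types = "ciicdcdddi", progress = FALSE
  )
  np %>%
    dplyr::mutate(summit = dplyr::if_else(.data$peak < 0, NA_real_,
                                          as.numeric(.data$start + .data$peak))) %>%
    dplyr::select("chrom", "start", "end", "peak_id", "score", "strand",
                  "signalValue", "pValue", "qValue", "summit")
}

#' @rdname read_narrowpeak
#' @param peaks Interval tibble; `summit` (absolute) is encoded as an offset.
#' @export
write_narrowpeak <- function(peaks, path) {
  out <- tibble::tibble(
    chrom = peaks$chrom,
    start = as.integer(peaks$start),
    end = as.integer(peaks$end),
    peak_id = peaks$peak_id,
    score = if ("score" %in% names(peaks)) peaks$score else 0,
    strand = if ("strand" %in% names(peaks)) peaks$strand else ".",
    signalValue = if ("signalValue" %in% names(peaks)) peaks$signalValue else 0,
    pValue = if ("pValue" %in% names(peaks)) peaks$pValue else -1,
    qValue = if ("qValue" %in% names(peaks)) peaks$qValue else -1,
    peak = if ("summit" %in% names(peaks)) {
      as.integer(ifelse(is.na(peaks$summit), -1L, peaks$summit - peaks$start))
    } else -1L
  )
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read and write count matrices as TSV
#'
#' First column `feature_id`, one column per sample, with a header line.
#'
#' @param path File path.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    feature_id = readr::col_character(), .default = readr::col_double()
  ), progress = FALSE)
}

#' @rdname read_counts_tsv
#' @param counts Counts tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' Write a simulated dataset to a directory
#'
#' Serializes every component of a [simulate_tlr_dataset()] result as plain
#' text: counts as TSV, gene models as BED6, peaks as narrowPeak plus
#' tag-count TSV, planted truth as JSON, and the generating configuration as
#' YAML.
#'
#' @param ds A `tlr_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tlr_dataset <- function(ds, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_counts_tsv(ds$rna_counts, p("rna_counts.tsv"))
  write_gene_bed(ds$genes, p("genes.bed"))
  readr::write_tsv(ds$design, p("design.tsv"))
  write_bed(ds$blacklist, p("blacklist.bed"))
  write_narrowpeak(ds$ncor1$peaks, p("ncor1_peaks.narrowPeak"))
  write_counts_tsv(ds$ncor1$tag_counts, p("ncor1_tags.tsv"))
  write_narrowpeak(ds$k27$peaks, p("k27_peaks.narrowPeak"))
  write_counts_tsv(ds$k27$tag_counts, p("k27_tags.tsv"))
  truth <- list(
    gene_class = ds$truth$gene_class,
    synergy_class = ds$truth$synergy_class,
    ncor1_cluster = ds$truth$ncor1_cluster,
    k27_cluster = ds$truth$k27_cluster
  )
  jsonlite::write_json(truth, p("truth.json"), dataframe = "columns")
  yaml::write_yaml(ds$params, p("config.yaml"))
  invisible(dir)
}
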