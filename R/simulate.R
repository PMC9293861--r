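# Synthetic-data generator with planted ground truth.
#
# Emulates the statistical structure of a TLR stimulation study in dendritic
# cells: negative-binomial gene counts with condition-specific log2 effects
# (including planted synergy/antagonism in the combined stimulation), and two
# ChIP tracks (co-repressor binding, enhancer acetylation) whose per-condition
# enrichment follows archetypal cluster patterns. Coordinates are 0-based,
# half-open throughout.

#' Default stimulation design
#'
#' Conditions mirror the study design: unstimulated, TLR9 ligand (CpG), TLR3
#' ligand (pIC), and the combined stimulation (CpG + pIC + IFNg), each with a
#' fixed number of replicates.
#'
#' @param conditions Character vector of condition labels.
#' @param replicates Replicates per condition (default 2).
#' @return A tibble with columns `sample_id`, `condition`, `replicate`.
#' @export
tlr_design <- function(conditions = c("Unstim", "CpG", "pIC", "CpG_pIC_IFNg"),
                       replicates = 2) {
  tidyr::expand_grid(condition = conditions, replicate = seq_len(replicates)) %>%
    dplyr::mutate(sample_id = paste0(.data$condition, "_r", .data$replicate)) %>%
    dplyr::select("sample_id", "condition", "replicate")
}

#' Genome specification
#'
#' @param lengths Named numeric vector of chromosome lengths (bp).
#' @return A tibble with columns `chrom`, `length`.
#' @export
genome_spec <- function(lengths = c(chr1 = 1e6, chr2 = 1e6)) {
  if (is.null(names(lengths)) || anyDuplicated(names(lengths)) || any(lengths <= 0)) {
    abort("chromosome lengths must be a named vector with unique names and positive values")
  }
  tibble::tibble(chrom = names(lengths), length = as.numeric(lengths))
}

#' Place gene models on a genome
#'
#' Genes are allocated to chromosomes proportionally to length and placed at
#' random TSS positions at least `min_spacing` bp apart, sorted within each
#' chromosome. Strands are drawn uniformly. Deterministic given `seed`.
#'
#' @param genome A [genome_spec()] tibble.
#' @param n_genes Number of genes to place.
#' @param min_spacing Minimum pairwise TSS distance (bp).
#' @param seed Integer seed.
#' @return A tibble with `gene_id`, `chrom`, `tss` (0-based), `strand`.
#' @export
build_gene_models <- function(genome, n_genes, min_spacing = 5000, seed = 1) {
  stopifnot(n_genes >= 0, min_spacing >= 1)
  if (n_genes == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          tss = numeric(), strand = character()))
  }
  total <- sum(genome$length)
  if (n_genes * min_spacing > total) {
    abort("infeasible packing: n_genes * min_spacing exceeds total genome length")
  }
  caps <- floor(genome$length / min_spacing)
  if (sum(caps) < n_genes) {
    abort("infeasible packing: chromosomes cannot hold the requested gene count at this spacing")
  }
  # proportional allocation by largest remainder, clamped to per-chromosome capacity
  quota <- n_genes * genome$length / total
  alloc <- pmin(floor(quota), caps)
  while (sum(alloc) < n_genes) {
    room <- which(alloc < caps)
    pick <- room[which.max((quota - alloc)[room])]
    alloc[pick] <- alloc[pick] + 1
  }
  withr::local_seed(seed)
  models <- purrr::pmap_dfr(
    list(genome$chrom, genome$length, alloc),
    function(chrom, len, n_c) {
      if (n_c == 0) return(NULL)
      slack <- len - n_c * min_spacing
      offsets <- sort(stats::runif(n_c, 0, slack))
      tibble::tibble(
        chrom = chrom,
        tss = floor((seq_len(n_c) - 1) * min_spacing + offsets),
        strand = sample(c("+", "-"), n_c, replace = TRUE)
      )
    }
  )
  models %>%
    dplyr::mutate(gene_id = sprintf("gene_%05d", dplyr::row_number())) %>%
    dplyr::select("gene_id", "chrom", "tss", "strand")
}

#' Combined-condition log2 effect for a target synergy ratio
#'
#' Given single-stimulation log2 effects and a target ratio of the combined-
#' condition mean to the sum of the single-condition means, returns the log2
#' effect that plants that ratio exactly in expectation:
#' `log2(ratio * (2^effect_cpg + 2^effect_pic))`.
#'
#' @param effect_cpg,effect_pic Log2 effects in the single stimulations.
#' @param ratio Target combined/(CpG + pIC) mean ratio.
#' @return Log2 effect for the combined condition.
#' @export
synergy_combined_effect <- function(effect_cpg, effect_pic, ratio) {
  stopifnot(all(ratio >= 0), all(is.finite(effect_cpg)), all(is.finite(effect_pic)))
  log2(ratio * (2^effect_cpg + 2^effect_pic))
}

#' Simulate a negative-binomial count matrix
#'
#' Counts for feature i in sample j are drawn from a negative binomial with
#' mean `base_mean_i * 2^effect(i, condition(j)) * f_j` and variance
#' `mu + dispersion * mu^2`, where `f_j` are sample library-size factors
#' (drawn log-normal(0, 0.1^2) unless supplied, so normalization is
#' non-trivial). `dispersion = 0` gives the Poisson limit.
#'
#' @param effects Data frame with `gene_id` and one numeric log2-effect
#'   column per condition.
#' @param design A [tlr_design()] tibble; its conditions must all appear in
#'   `effects`.
#' @param base_mean Scalar or per-gene baseline mean (> 0).
#' @param dispersion Negative-binomial dispersion (>= 0).
#' @param lib_factors Optional named vector of library-size factors.
#' @param seed Integer seed.
#' @return Counts tibble (`feature_id` + sample columns) with the realized
#'   library factors in attribute `lib_factors`.
#' @export
simulate_counts <- function(effects, design, base_mean = 200, dispersion = 0.05,
                            lib_factors = NULL, seed = 1) {
  stopifnot(is.data.frame(effects), "gene_id" %in% names(effects))
  if (any(base_mean <= 0)) abort("base_mean must be positive")
  if (dispersion < 0) abort("dispersion must be >= 0")
  miss <- setdiff(unique(design$condition), names(effects))
  if (length(miss) > 0) abort(paste0("effects lacks conditions: ", paste(miss, collapse = ", ")))
  eff <- as.matrix(effects[unique(design$condition)])
  if (any(!is.finite(eff))) abort("effects must be finite")
  n <- nrow(effects)
  withr::local_seed(seed)
  if (is.null(lib_factors)) {
    lib_factors <- stats::setNames(stats::rlnorm(nrow(design), 0, 0.1), design$sample_id)
  }
  base <- rep_len(base_mean, n)
  cols <- lapply(seq_len(nrow(design)), function(j) {
    mu <- base * 2^eff[, design$condition[j]] * lib_factors[[design$sample_id[j]]]
    if (dispersion == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  })
  counts <- tibble::as_tibble(stats::setNames(cols, design$sample_id))
  counts <- dplyr::bind_cols(tibble::tibble(feature_id = effects$gene_id), counts)
  attr(counts, "lib_factors") <- lib_factors
  counts
}

#' Archetypal per-condition enrichment patterns
#'
#' Mean tag-count multipliers (relative to `tag_depth`) per condition for the
#' co-repressor (NCoR1) five-cluster family and the enhancer (H3K27ac)
#' four-cluster family. Stimulation-responsive conditions use a 4x multiplier
#' so the planted patterns sit safely beyond the 2-fold classification rules.
#'
#' @param conditions Condition labels in design order
#'   (unstimulated, CpG, pIC, combined).
#' @return Named list of named numeric multiplier vectors.
#' @export
ncor1_archetypes <- function(conditions = c("Unstim", "CpG", "pIC", "CpG_pIC_IFNg")) {
  mk <- function(x) stats::setNames(x, conditions)
  list(
    I   = mk(c(1, 4, 4, 4)),  # increased binding in all stimulations
    II  = mk(c(1, 1, 1, 4)),  # increased in combined vs both single ligands
    III = mk(c(1, 1, 4, 1)),  # increased in pIC vs CpG and combined
    IV  = mk(c(1, 1, 1, 1)),  # no change
    V   = mk(c(4, 1, 1, 1))   # decreased after stimulation
  )
}

#' @rdname ncor1_archetypes
#' @export
k27_archetypes <- function(conditions = c("Unstim", "CpG", "pIC", "CpG_pIC_IFNg")) {
  mk <- function(x) stats::setNames(x, conditions)
  list(
    CpG    = mk(c(1, 4, 1, 4)),
    pIC    = mk(c(1, 1, 4, 4)),
    common = mk(c(1, 4, 4, 4)),
    down   = mk(c(4, 1, 1, 1))
  )
}

# Draw NB tag counts for peaks given realized per-condition log2 multipliers.
sample_tag_counts <- function(peak_ids, log2_mult, design, tag_depth, dispersion,
                              lib_factors) {
  n <- length(peak_ids)
  cols <- lapply(seq_len(nrow(design)), function(j) {
    mu <- tag_depth * 2^log2_mult[, design$condition[j]] * lib_factors[[design$sample_id[j]]]
    if (dispersion == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
  })
  dplyr::bind_cols(tibble::tibble(feature_id = peak_ids),
                   tibble::as_tibble(stats::setNames(cols, design$sample_id)))
}

# Rejection-sample non-overlapping peak centers; promoter peaks near TSS,
# distal peaks kept away from every TSS and from `avoid` centers.
place_peak_centers <- function(genome, genes, n, width, frac_promoter, blacklist,
                               avoid = NULL, distal_margin = 1500) {
  n_prom <- round(frac_promoter * n)
  tss_by_chrom <- split(genes$tss, genes$chrom)
  placed <- stats::setNames(vector("list", nrow(genome)), genome$chrom)
  bl_by_chrom <- if (!is.null(blacklist) && nrow(blacklist) > 0) {
    split(blacklist[c("start", "end")], blacklist$chrom)
  } else NULL
  avoid_by_chrom <- if (!is.null(avoid) && nrow(avoid) > 0) {
    split(avoid$center, avoid$chrom)
  } else NULL
  half <- ceiling(width / 2)
  ok_candidate <- function(chrom, center, need_promoter) {
    len <- genome$length[genome$chrom == chrom]
    if (center - half < 0 || center + half > len) return(FALSE)
    tss <- tss_by_chrom[[chrom]]
    if (!need_promoter && !is.null(tss) && length(tss) > 0 &&
        min(abs(tss - center)) <= distal_margin) return(FALSE)
    prev <- placed[[chrom]]
    if (length(prev) > 0 && min(abs(prev - center)) <= width) return(FALSE)
    av <- avoid_by_chrom[[chrom]]
    if (!is.null(av) && length(av) > 0 && min(abs(av - center)) <= distal_margin) return(FALSE)
    bl <- bl_by_chrom[[chrom]]
    if (!is.null(bl) && nrow(bl) > 0 &&
        any(center + half > bl$start & center - half < bl$end)) return(FALSE)
    TRUE
  }
  centers <- tibble::tibble(chrom = character(n), center = numeric(n))
  max_tries <- 200L * n
  tries <- 0L
  gene_pool <- genes[sample.int(nrow(genes)), , drop = FALSE]
  gi <- 1L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > max_tries) {
        abort("capacity error: genome too small for the requested peaks")
      }
      if (i <= n_prom && nrow(genes) > 0) {
        g <- gene_pool[((gi - 1L) %% nrow(gene_pool)) + 1L, ]
        gi <- gi + 1L
        chrom <- g$chrom
        center <- floor(g$tss + stats::runif(1, -500, 500))
      } else {
        chrom <- sample(genome$chrom, 1, prob = genome$length)
        center <- floor(stats::runif(1, half, genome$length[genome$chrom == chrom] - half))
      }
      if (ok_candidate(chrom, center, need_promoter = i <= n_prom)) break
    }
    placed[[chrom]] <- c(placed[[chrom]], center)
    centers$chrom[i] <- chrom
    centers$center[i] <- center
  }
  centers
}

#' Simulate a peak set with planted cluster archetypes
#'
#' Places non-overlapping fixed-width peaks (a configurable fraction within
#' +/- 500 bp of a TSS, the remainder distal), assigns each peak a cluster
#' archetype, and draws per-sample negative-binomial tag counts whose
#' expected per-condition means follow the archetype multipliers times
#' `tag_depth`. An optional per-peak, per-condition log2 jitter
#' (`effect_sd`) individualizes peaks around their archetype.
#'
#' @param genome A [genome_spec()] tibble.
#' @param genes Gene models from [build_gene_models()].
#' @param design A [tlr_design()] tibble.
#' @param archetypes Named list of per-condition multiplier vectors, e.g.
#'   [ncor1_archetypes()].
#' @param n_per_cluster Peaks per archetype (scalar or named vector).
#' @param width Peak width in bp.
#' @param tag_depth Baseline expected tag count per peak per sample.
#' @param dispersion Negative-binomial dispersion of tag counts.
#' @param frac_promoter Fraction of peaks placed within +/- 500 bp of a TSS.
#' @param blacklist Optional interval tibble peaks must avoid.
#' @param effect_sd Standard deviation of the shared per-peak log2 jitter
#'   applied to non-reference conditions (0 = pure archetypes).
#' @param seed Integer seed.
#' @param id_prefix Prefix for generated peak IDs.
#' @return List with `peaks` (interval tibble with summits), `tag_counts`,
#'   `truth` (peak_id -> cluster), `log2_mult` (realized per-condition log2
#'   multipliers), and `lib_factors`.
#' @export
simulate_peaks <- function(genome, genes, design, archetypes = ncor1_archetypes(),
                           n_per_cluster = 200, width = 400, tag_depth = 200,
                           dispersion = 0.05, frac_promoter = 0.2,
                           blacklist = NULL, effect_sd = 0, seed = 1,
                           id_prefix = "peak") {
  stopifnot(width > 0, tag_depth > 0, dispersion >= 0)
  labels <- names(archetypes)
  n_per <- if (length(n_per_cluster) == 1) {
    stats::setNames(rep(n_per_cluster, length(labels)), labels)
  } else n_per_cluster[labels]
  n <- sum(n_per)
  withr::local_seed(seed)
  centers <- place_peak_centers(genome, genes, n, width, frac_promoter, blacklist)
  # cluster assignment independent of placement order
  cluster <- sample(rep(labels, times = n_per))
  half <- ceiling(width / 2)
  peaks <- centers %>%
    dplyr::mutate(
      start = .data$center - half,
      end = .data$center + half,
      summit = floor(.data$center),
      cluster = cluster
    ) %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(peak_id = sprintf("%s_%05d", id_prefix, dplyr::row_number()))
  base_mult <- t(vapply(peaks$cluster, function(cl) log2(archetypes[[cl]]),
                        numeric(length(archetypes[[1]]))))
  colnames(base_mult) <- names(archetypes[[1]])
  ref <- colnames(base_mult)[1]
  if (effect_sd > 0) {
    jitter <- matrix(stats::rnorm(length(base_mult), 0, effect_sd),
                     nrow(base_mult), ncol(base_mult),
                     dimnames = dimnames(base_mult))
    jitter[, ref] <- 0
    base_mult <- base_mult + jitter
  }
  rownames(base_mult) <- peaks$peak_id
  lib_factors <- stats::setNames(stats::rlnorm(nrow(design), 0, 0.1), design$sample_id)
  tags <- sample_tag_counts(peaks$peak_id, base_mult, design, tag_depth,
                            dispersion, lib_factors)
  list(
    peaks = dplyr::select(peaks, "chrom", "start", "end", "peak_id", "summit"),
    tag_counts = tags,
    truth = dplyr::select(peaks, "peak_id", "cluster"),
    log2_mult = base_mult,
    lib_factors = lib_factors
  )
}

#' Simulate the full multi-omics study dataset
#'
#' Generates a complete dataset with planted ground truth mirroring the study
#' design: four conditions (unstimulated, CpG, pIC, combined) with two
#' replicates; an RNA count matrix with planted CpG-specific, pIC-specific,
#' common and unresponsive genes plus synergy/antagonist/neither classes
#' among the responsive genes (target ratios 1.5 / 0.3 / 1.0); a co-repressor
#' (NCoR1) peak track with the five-cluster archetypes; and an enhancer
#' (H3K27ac) peak track with the four-cluster archetypes. When
#' `couple_marks` is TRUE, a fraction of NCoR1 cluster-I and cluster-V peaks
#' receive an enhancer counterpart peak at the same position (within
#' +/- 200 bp) sharing the realized per-condition pattern, so that changes in
#' binding and changes in acetylation correlate across paired peaks as they
#' do in the study system.
#'
#' @param seed Integer seed; all randomness derives from it.
#' @param n_genes Number of genes.
#' @param n_class Named vector of planted response-class gene counts
#'   (`cpg`, `pic`, `common`, `down`).
#' @param n_synergy,n_antagonist Planted synergy/antagonist gene counts among
#'   the responsive classes.
#' @param effect_lfc Planted log2 effect of responsive genes (default 3,
#'   i.e. 8-fold).
#' @param ratio_targets Planted combined/(CpG + pIC) ratios for
#'   synergy/antagonist/neither.
#' @param base_mean,rna_dispersion RNA negative-binomial parameters.
#' @param n_peaks_per_cluster Peaks per archetype for both ChIP tracks.
#' @param n_k27_background Invariant background peaks in the enhancer track
#'   (consensus acetylation peak sets are dominated by condition-stable
#'   regions, which also anchor the normalization).
#' @param tag_depth,chip_dispersion ChIP tag-count parameters.
#' @param peak_effect_sd Per-peak log2 jitter around archetypes.
#' @param couple_marks Couple the enhancer track to the NCoR1 track (see
#'   above).
#' @param couple_frac Fraction of NCoR1 cluster-I/V peaks given an enhancer
#'   counterpart.
#' @param replicates Replicates per condition.
#' @return A `tlr_dataset` list: `genome`, `genes`, `design`, `rna_counts`,
#'   `ncor1`, `k27` (each with `peaks`, `tag_counts`, `truth`), `blacklist`,
#'   `truth` (gene classes and synergy classes), `params`.
#' @export
simulate_tlr_dataset <- function(seed = 42,
                                 n_genes = 1800,
                                 n_class = c(cpg = 150, pic = 300, common = 150, down = 100),
                                 n_synergy = 80, n_antagonist = 120,
                                 effect_lfc = 3,
                                 ratio_targets = c(synergy = 1.5, antagonist = 0.3, neither = 1),
                                 base_mean = 200, rna_dispersion = 0.05,
                                 n_peaks_per_cluster = 150,
                                 n_k27_background = 1200,
                                 tag_depth = 200, chip_dispersion = 0.05,
                                 peak_effect_sd = 0.25,
                                 couple_marks = TRUE, couple_frac = 0.8,
                                 replicates = 2) {
  conditions <- c("Unstim", "CpG", "pIC", "CpG_pIC_IFNg")
  design <- tlr_design(conditions, replicates)
  genome <- genome_spec(c(chr1 = 3e6, chr2 = 3e6, chr3 = 3e6, chr4 = 3e6))
  genes <- build_gene_models(genome, n_genes, min_spacing = 3000, seed = seed + 1)

  withr::local_seed(seed + 2)
  # blacklist: a few artifact regions per chromosome, placed away from genes
  blacklist <- purrr::map_dfr(genome$chrom, function(ch) {
    len <- genome$length[genome$chrom == ch]
    start <- floor(stats::runif(3, 0, len - 5000))
    tibble::tibble(chrom = ch, start = start, end = start + 2000)
  }) %>%
    dplyr::arrange(.data$chrom, .data$start) %>%
    dplyr::mutate(peak_id = sprintf("blacklist_%03d", dplyr::row_number()))

  # ---- RNA track: planted response classes and synergy classes ----
  stopifnot(sum(n_class) <= n_genes)
  ids <- sample(genes$gene_id)
  splits <- split(
    ids[seq_len(sum(n_class))],
    rep(names(n_class), times = n_class)
  )
  gene_class <- tibble::tibble(gene_id = genes$gene_id) %>%
    dplyr::mutate(class = dplyr::case_when(
      .data$gene_id %in% splits$cpg ~ "CpG-specific",
      .data$gene_id %in% splits$pic ~ "pIC-specific",
      .data$gene_id %in% splits$common ~ "common",
      TRUE ~ "none"
    ),
    direction = dplyr::if_else(.data$gene_id %in% splits$down, "down", "up"))
  eligible <- unlist(splits[c("cpg", "pic", "common")], use.names = FALSE)
  syn_ids <- sample(eligible)
  synergy_class <- tibble::tibble(gene_id = genes$gene_id) %>%
    dplyr::mutate(class = dplyr::case_when(
      .data$gene_id %in% syn_ids[seq_len(n_synergy)] ~ "synergy",
      .data$gene_id %in% syn_ids[n_synergy + seq_len(n_antagonist)] ~ "antagonist",
      .data$gene_id %in% eligible ~ "neither",
      TRUE ~ "not-eligible"
    ))

  e <- effect_lfc
  effects <- gene_class %>%
    dplyr::left_join(synergy_class, by = "gene_id", suffix = c("", "_syn")) %>%
    dplyr::mutate(
      sign = dplyr::if_else(.data$direction == "down", -1, 1),
      CpG = dplyr::if_else(.data$class %in% c("CpG-specific", "common"), .data$sign * e, 0),
      pIC = dplyr::if_else(.data$class %in% c("pIC-specific", "common"), .data$sign * e, 0),
      Unstim = 0,
      ratio = dplyr::case_when(
        .data$class_syn == "synergy" ~ ratio_targets[["synergy"]],
        .data$class_syn == "antagonist" ~ ratio_targets[["antagonist"]],
        .data$class_syn == "neither" ~ ratio_targets[["neither"]],
        TRUE ~ NA_real_
      ),
      CpG_pIC_IFNg = dplyr::if_else(
        is.na(.data$ratio),
        log2((2^.data$CpG + 2^.data$pIC) / 2),
        synergy_combined_effect(.data$CpG, .data$pIC, dplyr::coalesce(.data$ratio, 1))
      )
    ) %>%
    dplyr::select("gene_id", dplyr::all_of(conditions))
  rna_counts <- simulate_counts(effects, design, base_mean = base_mean,
                                dispersion = rna_dispersion, seed = seed + 3)

  # ---- NCoR1 track: five-cluster archetypes ----
  ncor1 <- simulate_peaks(genome, genes, design,
                          archetypes = ncor1_archetypes(conditions),
                          n_per_cluster = n_peaks_per_cluster,
                          tag_depth = tag_depth, dispersion = chip_dispersion,
                          blacklist = blacklist, effect_sd = peak_effect_sd,
                          seed = seed + 4, id_prefix = "ncor1")

  # ---- H3K27ac track: four-cluster archetypes (+ coupled counterparts) ----
  ncor1_centers <- ncor1$peaks %>%
    dplyr::mutate(center = (.data$start + .data$end) / 2) %>%
    dplyr::select("chrom", "center")
  k27 <- simulate_k27_track(genome, genes, design, ncor1, conditions,
                            n_peaks_per_cluster, tag_depth, chip_dispersion,
                            blacklist, peak_effect_sd, couple_marks, couple_frac,
                            ncor1_centers, seed, n_background = n_k27_background)

  structure(list(
    genome = genome, genes = genes, design = design,
    rna_counts = rna_counts, ncor1 = ncor1, k27 = k27, blacklist = blacklist,
    truth = list(gene_class = gene_class,
                 synergy_class = synergy_class,
                 ncor1_cluster = ncor1$truth,
                 k27_cluster = k27$truth),
    params = list(seed = seed, n_genes = n_genes, n_class = n_class,
                  n_synergy = n_synergy, n_antagonist = n_antagonist,
                  effect_lfc = effect_lfc, ratio_targets = ratio_targets,
                  base_mean = base_mean, rna_dispersion = rna_dispersion,
                  n_peaks_per_cluster = n_peaks_per_cluster,
                  tag_depth = tag_depth, chip_dispersion = chip_dispersion,
                  peak_effect_sd = peak_effect_sd, couple_marks = couple_marks,
                  couple_frac = couple_frac, replicates = replicates)
  ), class = "tlr_dataset")
}

# Enhancer track: independent four-archetype peaks placed away from NCoR1
# peaks, plus (optionally) counterpart peaks sharing NCoR1 cluster-I/V
# realized patterns at the same loci. Counterparts are genuine members of
# the "common" (from I) and "down" (from V) enhancer archetypes.
simulate_k27_track <- function(genome, genes, design, ncor1, conditions,
                               n_per_cluster, tag_depth, dispersion, blacklist,
                               effect_sd, couple_marks, couple_frac,
                               ncor1_centers, seed, n_background = 1200) {
  withr::local_seed(seed + 5)
  arch <- k27_archetypes(conditions)
  # invariant background peaks: consensus acetylation peak sets are dominated
  # by condition-stable regions, which also anchor the normalization
  arch$background <- stats::setNames(rep(1, length(conditions)), conditions)
  labels <- names(arch)
  n_ind <- stats::setNames(c(rep(n_per_cluster, length(labels) - 1), n_background),
                           labels)
  n <- sum(n_ind)
  centers <- place_peak_centers(genome, genes, n, width = 400,
                                frac_promoter = 0.2, blacklist = blacklist,
                                avoid = ncor1_centers)
  cluster <- sample(rep(labels, times = n_ind))
  half <- 200
  peaks <- centers %>%
    dplyr::mutate(start = .data$center - half, end = .data$center + half,
                  summit = floor(.data$center), cluster = cluster,
                  source = "independent")
  log2_mult <- t(vapply(peaks$cluster, function(cl) log2(arch[[cl]]),
                        numeric(length(conditions))))
  colnames(log2_mult) <- conditions
  if (effect_sd > 0) {
    jit <- matrix(stats::rnorm(length(log2_mult), 0, effect_sd),
                  nrow(log2_mult), ncol(log2_mult),
                  dimnames = dimnames(log2_mult))
    jit[, conditions[1]] <- 0
    jit[peaks$cluster == "background", ] <- 0 # background is invariant
    log2_mult <- log2_mult + jit
  }

  if (couple_marks) {
    src <- ncor1$truth$peak_id[ncor1$truth$cluster %in% c("I", "V")]
    src <- sort(src)
    take <- sort(sample(src, size = floor(couple_frac * length(src))))
    src_peaks <- ncor1$peaks[match(take, ncor1$peaks$peak_id), ]
    src_cluster <- ncor1$truth$cluster[match(take, ncor1$truth$peak_id)]
    ctr <- floor((src_peaks$start + src_peaks$end) / 2 +
                   stats::runif(length(take), -200, 200))
    coupled <- tibble::tibble(
      chrom = src_peaks$chrom, center = ctr,
      start = ctr - half, end = ctr + half, summit = ctr,
      cluster = dplyr::if_else(src_cluster == "I", "common", "down"),
      source = "coupled"
    )
    # shared realized pattern with small mark-specific deviation
    cm <- ncor1$log2_mult[take, , drop = FALSE] +
      matrix(stats::rnorm(length(take) * length(conditions), 0, 0.1),
             length(take), length(conditions))
    cm[, conditions[1]] <- ncor1$log2_mult[take, conditions[1]]
    peaks <- dplyr::bind_rows(peaks, coupled)
    log2_mult <- rbind(log2_mult, cm)
  }

  ord <- order(peaks$chrom, peaks$start)
  peaks <- peaks[ord, ]
  log2_mult <- log2_mult[ord, , drop = FALSE]
  peaks$peak_id <- sprintf("k27_%05d", seq_len(nrow(peaks)))
  rownames(log2_mult) <- peaks$peak_id
  lib_factors <- stats::setNames(stats::rlnorm(nrow(design), 0, 0.1), design$sample_id)
  tags <- sample_tag_counts(peaks$peak_id, log2_mult, design, tag_depth,
                            dispersion, lib_factors)
  list(
    peaks = dplyr::select(peaks, "chrom", "start", "end", "peak_id", "summit"),
    tag_counts = tags,
    truth = dplyr::select(peaks, "peak_id", "cluster", "source"),
    log2_mult = log2_mult,
    lib_factors = lib_factors
  )
}

#' @export
print.tlr_dataset <- function(x, ...) {
  cat("Synthetic TLR stimulation dataset (seed ", x$params$seed, ")\n", sep = "")
  cat("  genes: ", nrow(x$genes), ", samples: ", nrow(x$design), "\n", sep = "")
  cat("  NCoR1 peaks: ", nrow(x$ncor1$peaks),
      ", H3K27ac peaks: ", nrow(x$k27$peaks), "\n", sep = "")
  invisible(x)
}
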