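test_that("gene models respect spacing, sorting and determinism", {
  genome <- genome_spec(c(chr1 = 1e6, chr2 = 1e6))
  g1 <- build_gene_models(genome, 100, min_spacing = 5000, seed = 1)
  expect_equal(nrow(g1), 100)
  expect_equal(anyDuplicated(g1$gene_id), 0)
  for (ch in unique(g1$chrom)) {
    tss <- g1$tss[g1$chrom == ch]
    expect_true(all(diff(tss) >= 5000))
    expect_true(all(tss >= 0 & tss < genome$length[genome$chrom == ch]))
  }
  g2 <- build_gene_models(genome, 100, min_spacing = 5000, seed = 1)
  expect_identical(g1, g2)
  expect_equal(nrow(build_gene_models(genome, 0, 5000, seed = 1)), 0)
  expect_error(build_gene_models(genome, 1000, min_spacing = 5000, seed = 1),
               "infeasible")
})

test_that("simulated counts match their negative-binomial targets", {
  # 1,000 replicate draws realized as 1,000 iid genes in one sample
  design1 <- tibble::tibble(sample_id = "s1", condition = "CpG", replicate = 1)
  effects <- tibble::tibble(gene_id = sprintf("g%04d", 1:1000), CpG = 3)
  counts <- simulate_counts(effects, design1, base_mean = 50, dispersion = 0.05,
                            lib_factors = c(s1 = 1), seed = 7)
  draws <- counts$s1
  # expected mean 50 * 2^3 = 400; CV of the mean ~ sqrt((0.05 + 1/400)/1000)
  expect_lt(abs(mean(draws) - 400) / 400, 0.1)

  # Poisson limit: dispersion 0 gives variance ~ mean at 10,000 draws
  effP <- tibble::tibble(gene_id = sprintf("g%05d", 1:10000), CpG = 3)
  cP <- simulate_counts(effP, design1, base_mean = 50, dispersion = 0,
                        lib_factors = c(s1 = 1), seed = 8)
  expect_gt(var(cP$s1) / mean(cP$s1), 0.8)
  expect_lt(var(cP$s1) / mean(cP$s1), 1.2)

  # NB moment fidelity: empirical mean/variance within 3 SE of targets
  mu <- 400; disp <- 0.05; nv <- 10000
  cNB <- simulate_counts(effP, design1, base_mean = 50, dispersion = disp,
                         lib_factors = c(s1 = 1), seed = 9)
  v_target <- mu + disp * mu^2
  se_mean <- sqrt(v_target / nv)
  expect_lt(abs(mean(cNB$s1) - mu), 3 * se_mean)
  # SE of the sample variance from the NB fourth moment, approximated by
  # the empirical fourth central moment
  m4 <- mean((cNB$s1 - mean(cNB$s1))^4)
  se_var <- sqrt((m4 - v_target^2) / nv)
  expect_lt(abs(var(cNB$s1) - v_target), 3 * se_var)

  # determinism and input validation
  design <- toy_design()
  eff4 <- tibble::tibble(gene_id = sprintf("g%03d", 1:50), Unstim = 0, CpG = 1,
                         pIC = 0, CpG_pIC_IFNg = 1)
  expect_identical(simulate_counts(eff4, design, seed = 3),
                   simulate_counts(eff4, design, seed = 3))
  expect_error(simulate_counts(eff4, design, base_mean = -5), "base_mean")
  expect_error(simulate_counts(eff4, design, dispersion = -1), "dispersion")
})

test_that("planted synergy ratios are exact in expectation", {
  e_comb <- synergy_combined_effect(3, 0, 1.5)
  expect_equal(2^e_comb / (2^3 + 2^0), 1.5, tolerance = 1e-12)
  ratios <- c(1.5, 0.3, 1)
  for (r in ratios) {
    ec <- synergy_combined_effect(2, 1, r)
    expect_lt(abs(2^ec / (2^2 + 2^1) - r), 1e-9)
  }
})

test_that("simulated peaks satisfy their archetype, bounds and blacklist", {
  genome <- genome_spec(c(chr1 = 2e6, chr2 = 2e6))
  genes <- build_gene_models(genome, 200, min_spacing = 4000, seed = 2)
  blacklist <- tibble::tibble(chrom = "chr1", start = c(1e5, 5e5),
                              end = c(1e5 + 5e3, 5e5 + 5e3),
                              peak_id = c("bl1", "bl2"))
  sim <- simulate_peaks(genome, genes, toy_design(),
                        archetypes = ncor1_archetypes()["I"],
                        n_per_cluster = 100, tag_depth = 200, dispersion = 0.05,
                        blacklist = blacklist, seed = 7)
  pk <- sim$peaks
  len <- stats::setNames(genome$length, genome$chrom)
  expect_true(all(pk$start >= 0 & pk$end <= len[pk$chrom]))
  hits <- nrow(dplyr::inner_join(pk, blacklist, by = "chrom",
                                 relationship = "many-to-many") %>%
                 dplyr::filter(.data$start.x < .data$end.y, .data$end.x > .data$start.y))
  expect_equal(hits, 0)

  # cluster-I archetype: >= 95% of peaks satisfy the two-fold rule in their
  # empirical pattern. A single-archetype set gives median-of-ratios nothing
  # invariant to anchor on, so normalize by the generator's own library factors.
  sfac <- tibble::tibble(sample_id = names(sim$lib_factors),
                         size_factor = unname(sim$lib_factors))
  fp <- fold_enrichment_matrix(sim$tag_counts, toy_design(), sfac)
  ok <- fold_change(fp, "CpG", "Unstim") >= 2 &
    fold_change(fp, "pIC", "Unstim") >= 2 &
    fold_change(fp, "CpG_pIC_IFNg", "Unstim") >= 2
  expect_gte(mean(ok), 0.95)
})

test_that("dataset generation is deterministic and internally consistent", {
  ds <- simulate_tlr_dataset(seed = 5, n_genes = 300,
                             n_class = c(cpg = 30, pic = 30, common = 30, down = 10),
                             n_synergy = 20, n_antagonist = 20,
                             n_peaks_per_cluster = 20, n_k27_background = 80)
  ds2 <- simulate_tlr_dataset(seed = 5, n_genes = 300,
                              n_class = c(cpg = 30, pic = 30, common = 30, down = 10),
                              n_synergy = 20, n_antagonist = 20,
                              n_peaks_per_cluster = 20, n_k27_background = 80)
  expect_identical(ds$rna_counts, ds2$rna_counts)
  expect_identical(ds$ncor1, ds2$ncor1)
  expect_identical(ds$k27, ds2$k27)
  # counts non-negative integers; same design across tracks
  expect_true(all(as.matrix(ds$rna_counts[-1]) >= 0))
  expect_identical(names(ds$ncor1$tag_counts), names(ds$k27$tag_counts))
  # each planted feature has exactly one class per track
  expect_equal(anyDuplicated(ds$truth$gene_class$gene_id), 0)
  expect_equal(anyDuplicated(ds$truth$ncor1_cluster$peak_id), 0)
  expect_equal(anyDuplicated(ds$truth$k27_cluster$peak_id), 0)
  # all peaks inside the genome
  len <- stats::setNames(ds$genome$length, ds$genome$chrom)
  for (tr in list(ds$ncor1$peaks, ds$k27$peaks)) {
    expect_true(all(tr$start >= 0 & tr$end <= len[tr$chrom]))
  }
})

test_that("dataset serialization round-trips and is byte-stable", {
  ds <- simulate_tlr_dataset(seed = 9, n_genes = 200,
                             n_class = c(cpg = 20, pic = 20, common = 20, down = 5),
                             n_synergy = 10, n_antagonist = 10,
                             n_peaks_per_cluster = 10, n_k27_background = 40)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_tlr_dataset(ds, d1)
  write_tlr_dataset(ds, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  cnt <- read_counts_tsv(file.path(d1, "rna_counts.tsv"))
  expect_equal(as.data.frame(cnt), as.data.frame(ds$rna_counts),
               ignore_attr = TRUE)
  genes <- read_gene_bed(file.path(d1, "genes.bed"))
  expect_equal(genes$tss, ds$genes$tss)
  np <- read_narrowpeak(file.path(d1, "ncor1_peaks.narrowPeak"))
  expect_equal(np$summit, ds$ncor1$peaks$summit)
  expect_equal(np$start, ds$ncor1$peaks$start)
})
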