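mk_fp <- function(means_mat) {
  out <- dplyr::bind_cols(
    tibble::tibble(feature_id = rownames(means_mat)),
    tibble::as_tibble(means_mat)
  )
  attr(out, "pseudocount") <- 1
  class(out) <- c("fc_pattern", class(out))
  out
}

conds <- c("Unstim", "CpG", "pIC", "CpG_pIC_IFNg")

test_that("fold changes are pseudocount-regularized and reciprocal", {
  m <- matrix(c(10, 25, 10, 0), 1, 4, dimnames = list("p1", conds))
  fp <- mk_fp(m)
  expect_equal(fold_change(fp, "CpG", "Unstim"), 26 / 11, tolerance = 1e-12)
  expect_equal(fold_change(fp, "Unstim", "pIC"), 1)       # equal means
  expect_equal(fold_change(fp, "CpG_pIC_IFNg", "CpG_pIC_IFNg"), 1) # zero vs zero
  expect_equal(fold_change(fp, "CpG", "pIC") * fold_change(fp, "pIC", "CpG"), 1,
               tolerance = 1e-9)
  expect_error(fold_change(fp, "CpG", "nope"), "unknown condition")
})

test_that("the five-cluster rules match the definitions on exemplar patterns", {
  pat <- rbind(
    c(10, 25, 25, 25),   # I: all stimulations doubled
    c(10, 10, 10, 10),   # IV: flat
    c(40, 15, 15, 15),   # V: all stimulations at least halved
    c(10, 10, 10, 40),   # II: combined above both single ligands
    c(10, 10, 40, 10)    # III: pIC above CpG and combined
  )
  dimnames(pat) <- list(paste0("p", 1:5), conds)
  cl <- classify_ncor1_clusters(mk_fp(pat))
  expect_equal(cl$cluster, c("I", "IV", "V", "II", "III"))
  expect_error(classify_ncor1_clusters(mk_fp(pat[, 1:3])), "missing condition")
})

test_that("rule engine agrees with exhaustive brute-force evaluation on a grid", {
  vals <- c(0.25, 0.5, 1, 2, 4)
  grid <- expand.grid(Unstim = vals, CpG = vals, pIC = vals, CpG_pIC_IFNg = vals)
  base <- 40 # scale so pseudocount matters little but identically in both routes
  m <- as.matrix(grid) * base
  rownames(m) <- sprintf("p%03d", seq_len(nrow(m)))
  got <- classify_ncor1_clusters(mk_fp(m))
  fcb <- function(a, b) (m[, a] + 1) / (m[, b] + 1)
  rI <- fcb("CpG", "Unstim") >= 2 & fcb("pIC", "Unstim") >= 2 & fcb("CpG_pIC_IFNg", "Unstim") >= 2
  rII <- fcb("CpG_pIC_IFNg", "CpG") >= 2 & fcb("CpG_pIC_IFNg", "pIC") >= 2
  rIII <- fcb("pIC", "CpG") >= 2 & fcb("pIC", "CpG_pIC_IFNg") >= 2
  rV <- fcb("Unstim", "CpG") >= 2 & fcb("Unstim", "pIC") >= 2 & fcb("Unstim", "CpG_pIC_IFNg") >= 2
  expected <- ifelse(rI, "I", ifelse(rII, "II", ifelse(rIII, "III",
                     ifelse(rV, "V", "IV"))))
  expect_equal(got$cluster, unname(expected))
  expect_equal(nrow(got), 625)
  # the trace records every raw rule, so precedence is auditable
  expect_equal(got$rule_I, unname(rI))
  expect_gte(sum(rowSums(cbind(rI, rII, rIII, rV)) > 1), 1)
})

test_that("variable-region selection applies all three filters", {
  design <- toy_design()
  n <- 60
  means <- matrix(150, n, 4, dimnames = list(sprintf("p%03d", 1:n), conds))
  means[1:15, "CpG"] <- 1200         # 8-fold: BH-adjusted F power ~0.93
  means[16:30, ] <- 3                # low signal, flat
  # rows 31:60: high signal, flat (condition-invariant)
  tags <- toy_counts(means, design, dispersion = 0.05, seed = 11)
  sel <- select_variable_regions(tags, design,
                                 size_factors = tibble::tibble(
                                   sample_id = design$sample_id, size_factor = 1))
  f <- attr(sel, "filter")
  expect_gte(mean(f$pass[1:15]), 0.8)
  expect_true(all(!f$pass[16:30]))      # sum filter
  expect_lte(mean(f$pass[31:60]), 0.2)  # variability filter
})

test_that("enhancer pattern clustering recovers archetypes and is order-stable", {
  design <- toy_design()
  arch <- k27_archetypes()
  n_per <- 30
  mult <- do.call(rbind, lapply(arch, function(a) {
    matrix(rep(a, n_per), n_per, 4, byrow = TRUE)
  }))
  truth <- rep(names(arch), each = n_per)
  rownames(mult) <- sprintf("p%03d", seq_len(nrow(mult)))
  colnames(mult) <- conds
  # zero noise: exact profiles
  m0 <- mult[, rep(conds, each = 2)] * 100
  colnames(m0) <- design$sample_id[order(match(design$condition, conds))]
  tags0 <- dplyr::bind_cols(tibble::tibble(feature_id = rownames(mult)),
                            tibble::as_tibble(m0))
  cl0 <- cluster_enhancer_patterns(tags0, design,
                                   size_factors = tibble::tibble(
                                     sample_id = design$sample_id, size_factor = 1))
  expect_equal(adjusted_rand_index(cl0$label, truth), 1)
  expect_equal(sort(unique(cl0$label)),
               sort(c("CpG-specific", "pIC-specific", "common", "down")))

  # with NB noise: high recovery
  tags <- toy_counts(mult * 200, design, dispersion = 0.05, seed = 42)
  cl <- cluster_enhancer_patterns(tags, design)
  expect_gte(adjusted_rand_index(cl$label, truth), 0.8)

  # permuting input rows leaves per-peak labels unchanged
  perm <- withr::with_seed(3, sample.int(nrow(tags)))
  cl_perm <- cluster_enhancer_patterns(tags[perm, ], design)
  j <- dplyr::inner_join(cl, cl_perm, by = "peak_id")
  expect_equal(j$label.x, j$label.y)
  expect_error(cluster_enhancer_patterns(tags[1:3, ], design), "fewer peaks")
})

test_that("delta-delta correlation is exact in the deterministic limits", {
  n <- 20
  withr::with_seed(8, {
    delta <- rnorm(n, 0, 2)
    mk <- function(d) {
      m <- cbind(Unstim = rep(100, n), CpG = 100 * 2^d,
                 pIC = rep(100, n), CpG_pIC_IFNg = rep(100, n))
      rownames(m) <- sprintf("p%02d", 1:n)
      mk_fp(m)
    }
    pairs <- tibble::tibble(a_id = sprintf("p%02d", 1:n),
                            b_id = sprintf("p%02d", 1:n), distance = 0)
    same <- delta_delta_correlation(pairs, mk(delta), mk(delta), "CpG")
    expect_equal(same$r, 1, tolerance = 1e-9)
    # reversed pattern gives r = -1 (pseudocount keeps it approximate)
    opp <- delta_delta_correlation(pairs, mk(delta), mk(-delta), "CpG")
    expect_lt(opp$r, -0.99)
    expect_error(delta_delta_correlation(pairs[1:2, ], mk(delta), mk(delta), "CpG"),
                 "at least 3")
  })
})

test_that("independent deltas give near-zero correlation with covering CI", {
  n <- 500
  withr::with_seed(3, {
    ma <- cbind(Unstim = rep(100, n), CpG = 100 * 2^rnorm(n),
                pIC = rep(100, n), CpG_pIC_IFNg = rep(100, n))
    mb <- cbind(Unstim = rep(100, n), CpG = 100 * 2^rnorm(n),
                pIC = rep(100, n), CpG_pIC_IFNg = rep(100, n))
    rownames(ma) <- rownames(mb) <- sprintf("p%03d", 1:n)
    pairs <- tibble::tibble(a_id = rownames(ma), b_id = rownames(mb), distance = 0)
    res <- delta_delta_correlation(pairs, mk_fp(ma), mk_fp(mb), "CpG")
    expect_lt(abs(res$r), 0.15)
    expect_lt(res$ci_lo, 0)
    expect_gt(res$ci_hi, 0)
  })
})
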