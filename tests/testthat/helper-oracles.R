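# Brute-force oracles and small fixture builders, independent of the package
# implementations they check.

# Union length of 0-based half-open intervals by integer-position enumeration
# (only safe for small coordinates).
bf_union_length <- function(starts, ends) {
  pos <- unique(unlist(mapply(function(s, e) seq(s, e - 1), starts, ends,
                              SIMPLIFY = FALSE)))
  length(pos)
}

# Brute-force merged intervals via covered-position runs.
bf_merge <- function(starts, ends) {
  covered <- sort(unique(unlist(mapply(function(s, e) seq(s, e - 1), starts, ends,
                                       SIMPLIFY = FALSE))))
  breaks <- c(0, which(diff(covered) > 1), length(covered))
  data.frame(
    start = covered[breaks[-length(breaks)] + 1],
    end = covered[breaks[-1]] + 1
  )
}

# O(n*m) nearest-TSS scan with smallest-gene-id tie-break.
bf_nearest <- function(center, tss, gene_id) {
  d <- abs(center - tss)
  cand <- which(d == min(d))
  cand[order(gene_id[cand])][1]
}

# Benjamini-Hochberg from first principles.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Two-sided Fisher exact p by full hypergeometric enumeration over the table
# margins.
bf_fisher_p <- function(a, b, c, d) {
  m <- a + b      # size of set A
  n2 <- c + d     # complement of A
  k <- a + c      # size of set B
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tangent cutoff oracle by an independent route: build the lower convex hull
# of the scaled ranked-signal curve (monotone chain) and walk its segments to
# the vertex where the hull slope crosses 1 - the tangent point of a slope-1
# support line.
bf_se_cutoff <- function(signal) {
  s <- sort(signal)
  n <- length(s)
  span <- max(s) - min(s)
  if (span == 0) return(list(index = NA_integer_, n_super = 0L))
  x <- (seq_len(n) - 1) / (n - 1)
  y <- (s - min(s)) / span
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      a <- hull[length(hull) - 1]; b <- hull[length(hull)]
      if ((y[b] - y[a]) * (x[i] - x[a]) >= (y[i] - y[a]) * (x[b] - x[a])) {
        hull <- hull[-length(hull)]
      } else break
    }
    hull <- c(hull, i)
  }
  idx <- hull[1]
  for (k in seq_len(length(hull) - 1)) {
    sl <- (y[hull[k + 1]] - y[hull[k]]) / (x[hull[k + 1]] - x[hull[k]])
    if (sl > 1) { idx <- hull[k]; break }
    idx <- hull[k + 1]
  }
  list(index = idx, n_super = sum(s > s[idx]))
}

# Random interval fixture on a single small chromosome.
random_peaks <- function(n, max_pos = 2000, max_len = 120) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  tibble::tibble(chrom = "chr1", start = start, end = start + len,
                 peak_id = sprintf("p%04d", seq_len(n)))
}

toy_design <- function(replicates = 2) tlr_design(replicates = replicates)

# Small counts fixture with known per-condition means.
toy_counts <- function(means, design, dispersion = 0, seed = 1) {
  withr::with_seed(seed, {
    cols <- lapply(seq_len(nrow(design)), function(j) {
      mu <- means[, design$condition[j]]
      if (dispersion == 0) rpois(length(mu), mu) else
        rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    })
    dplyr::bind_cols(
      tibble::tibble(feature_id = rownames(means)),
      tibble::as_tibble(stats::setNames(cols, design$sample_id))
    )
  })
}

# Shared default dataset for pipeline-level tests (built once per test run).
default_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_tlr_dataset(seed = 42)
    cache
  }
})

k27_truth_map <- c(CpG = "CpG-specific", pIC = "pIC-specific",
                   common = "common", down = "down")
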