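# Simplified weighted co-expression analysis: soft-power selection,
# topological overlap, module detection by static tree cut with eigengene
# merging, and regulator ranking against condition-specific DEG sets.

expr_matrix <- function(expr) {
  m <- counts_matrix(expr)
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    warn(paste0("removing ", sum(sds == 0), " constant genes"))
    m <- m[sds > 0, , drop = FALSE]
  }
  m
}

#' Unsigned adjacency from expression
#'
#' `a_ij = |cor(i, j)|^power` across samples; diagonal set to 0 so that
#' connectivity and shared-neighbor sums exclude the gene itself.
#'
#' @param expr Expression tibble (`feature_id` + sample columns), typically
#'   vst-like values.
#' @param power Soft-threshold exponent.
#' @return Symmetric adjacency matrix with zero diagonal.
#' @export
adjacency_matrix <- function(expr, power) {
  m <- expr_matrix(expr)
  a <- abs(stats::cor(t(m)))^power
  diag(a) <- 0
  a
}

#' Pick the soft-threshold power by scale-free fit
#'
#' For each candidate power, computes gene connectivity `k_i = sum_j a_ij`,
#' bins `k` into equal-width bins, and regresses log10 frequency on log10
#' mean connectivity per bin. The selected power is the smallest one whose
#' fit R-squared reaches `fit_min` with a negative slope while keeping mean
#' connectivity at least `min_mean_k` (without the connectivity floor,
#' arbitrarily high powers shrink every adjacency toward zero and produce
#' spuriously good log-log fits on pure noise); if none qualifies, the
#' best-fitting power is returned and flagged.
#'
#' @param expr Expression tibble.
#' @param powers Candidate powers (default 1:20).
#' @param fit_min Minimum scale-free fit R-squared (default 0.8).
#' @param n_bins Number of connectivity bins (default 10).
#' @param min_mean_k Minimum mean connectivity for an eligible power
#'   (default 1).
#' @return A list: `power`, `flagged` (TRUE when no power reached `fit_min`),
#'   and `fit` (tibble of `power`, `r_squared`, `slope`, `mean_k`).
#' @export
pick_soft_power <- function(expr, powers = 1:20, fit_min = 0.8, n_bins = 10,
                            min_mean_k = 1) {
  m <- expr_matrix(expr)
  if (ncol(m) < 4) abort("need at least 4 samples")
  cors <- abs(stats::cor(t(m)))
  diag(cors) <- 0
  fit <- purrr::map_dfr(powers, function(p) {
    k <- rowSums(cors^p)
    breaks <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, breaks = breaks, include.lowest = TRUE)
    freq <- tapply(k, bin, length)
    kmean <- tapply(k, bin, mean)
    keep <- !is.na(freq) & freq > 0 & kmean > 0
    if (sum(keep) < 3) {
      return(tibble::tibble(power = p, r_squared = NA_real_, slope = NA_real_,
                            mean_k = mean(k)))
    }
    lf <- log10(freq[keep]); lk <- log10(kmean[keep])
    f <- stats::lm(lf ~ lk)
    tibble::tibble(power = p,
                   r_squared = summary(f)$r.squared,
                   slope = stats::coef(f)[[2]],
                   mean_k = mean(k))
  })
  ok <- which(!is.na(fit$r_squared) & fit$r_squared >= fit_min &
                fit$slope < 0 & fit$mean_k >= min_mean_k)
  if (length(ok) > 0) {
    list(power = fit$power[ok[1]], flagged = FALSE, fit = fit)
  } else {
    best <- which.max(ifelse(fit$slope < 0, fit$r_squared, -Inf))
    list(power = fit$power[best], flagged = TRUE, fit = fit)
  }
}

#' Topological overlap matrix
#'
#' From an unsigned adjacency `a` (zero diagonal), with connectivity
#' `k_i = sum_j a_ij` and shared-neighbor term
#' `l_ij = sum_u a_iu a_uj` (u != i, j):
#' `TOM_ij = (l_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)`, diagonal 1.
#' Values lie in `[0, 1]`; 1 means the two genes share all neighbors.
#'
#' @param expr Expression tibble.
#' @param power Soft-threshold power (e.g. from [pick_soft_power()]).
#' @return Symmetric TOM matrix with unit diagonal.
#' @export
tom_matrix <- function(expr, power) {
  m <- counts_matrix(expr)
  if (nrow(m) < 3) abort("need at least 3 genes")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0)) {
    abort(paste0("constant gene(s): ", paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", ")))
  }
  tom_from_adjacency(adjacency_matrix(expr, power))
}

#' @rdname tom_matrix
#' @param adjacency Symmetric adjacency matrix in `[0, 1]` (diagonal
#'   ignored).
#' @export
tom_from_adjacency <- function(adjacency) {
  a <- as.matrix(adjacency)
  stopifnot(nrow(a) == ncol(a))
  diag(a) <- 0
  k <- rowSums(a)
  l <- a %*% a
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  tom
}

module_eigengene <- function(expr_m, genes, sample_ids) {
  x <- t(expr_m[genes, sample_ids, drop = FALSE]) # samples x genes
  xs <- scale(x)
  xs[is.na(xs)] <- 0
  pc <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  me <- pc$x[, 1]
  if (stats::cor(me, rowMeans(xs)) < 0) me <- -me
  me / sqrt(sum(me^2))
}

#' Detect co-expression modules
#'
#' Average-linkage hierarchical clustering of `1 - TOM`, cut statically at
#' `cut_height`; clusters smaller than `min_module_size` are left
#' unassigned. Modules whose eigengenes (first principal component of the
#' z-scaled module expression, sign-fixed to correlate positively with the
#' module mean) correlate at or above `merge_cor` are merged iteratively,
#' most correlated pair first. Modules are labelled `M1`, `M2`, ... by
#' decreasing size (ties by smallest member gene ID), so labels do not
#' depend on input gene order.
#'
#' @param expr Expression tibble (needed for eigengenes).
#' @param tom TOM matrix from [tom_matrix()]; computed from `expr` and
#'   `power` when NULL.
#' @param power Soft power, used when `tom` is NULL.
#' @param min_module_size Minimum module size (default 30).
#' @param cut_height Static dendrogram cut height (default 0.98).
#' @param merge_cor Eigengene correlation at or above which modules merge
#'   (default 0.85, i.e. an eigengene dissimilarity threshold of 0.15).
#' @return A `tlr_modules` list: `assignment` (tibble `gene_id`, `module`),
#'   `eigengenes` (tibble `sample_id` + one column per module), `params`.
#' @export
detect_modules <- function(expr, tom = NULL, power = 6, min_module_size = 30,
                           cut_height = 0.98, merge_cor = 0.85) {
  m <- expr_matrix(expr)
  ord <- order(rownames(m))
  m <- m[ord, , drop = FALSE]
  if (is.null(tom)) {
    tom <- tom_from_adjacency(abs(stats::cor(t(m)))^power)
    rownames(tom) <- colnames(tom) <- rownames(m)
  } else {
    tom <- tom[rownames(m), rownames(m)]
  }
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cut <- stats::cutree(hc, h = cut_height)
  sizes <- table(cut)
  keep <- names(sizes)[sizes >= min_module_size]
  membership <- ifelse(cut %in% keep, as.character(cut), NA_character_)
  names(membership) <- rownames(m)

  samples <- colnames(m)
  modules <- function() split(names(membership)[!is.na(membership)],
                              membership[!is.na(membership)])
  mes <- function(mods) {
    vapply(mods, function(g) module_eigengene(m, g, samples), numeric(length(samples)))
  }
  mods <- modules()
  if (length(mods) > 1) {
    repeat {
      me <- mes(mods)
      cc <- stats::cor(me)
      diag(cc) <- -Inf
      top <- which(cc == max(cc), arr.ind = TRUE)[1, ]
      if (cc[top[1], top[2]] < merge_cor) break
      pair <- sort(colnames(cc)[top])
      membership[membership == pair[2]] <- pair[1]
      mods <- modules()
      if (length(mods) < 2) break
    }
  }
  # deterministic labels: by size desc, ties by smallest member gene id
  mods <- modules()
  ord_mod <- order(-lengths(mods), vapply(mods, min, character(1)))
  relabel <- stats::setNames(paste0("M", seq_along(mods)), names(mods)[ord_mod])
  membership <- ifelse(is.na(membership), "unassigned", relabel[membership])
  mods <- split(names(membership)[membership != "unassigned"],
                membership[membership != "unassigned"])
  me <- if (length(mods) > 0) mes(mods) else matrix(numeric(0), length(samples), 0)
  structure(list(
    assignment = tibble::tibble(gene_id = names(membership),
                                module = unname(membership)),
    eigengenes = dplyr::bind_cols(tibble::tibble(sample_id = samples),
                                  tibble::as_tibble(me)),
    params = list(min_module_size = min_module_size, cut_height = cut_height,
                  merge_cor = merge_cor)
  ), class = "tlr_modules")
}

#' Rank candidate regulators by DEG association of their network targets
#'
#' For each regulator gene, its targets are the genes of its own module with
#' TOM connection strength to the regulator in the top `1 - top_quantile`
#' fraction (default the top 10%), optionally restricted to a caller-supplied
#' prior edge list. Per condition, a hypergeometric test scores the overlap
#' between the targets and that condition's differentially expressed genes,
#' with the regulator's module as universe. Regulators are ranked within
#' condition by ascending p, ties by descending DE-target fraction then ID.
#'
#' @param modules A `tlr_modules` from [detect_modules()].
#' @param tom TOM matrix over the same genes.
#' @param regulators Character vector of candidate regulator gene IDs.
#' @param de_sets Named list: condition -> character vector of DE gene IDs.
#' @param top_quantile TOM quantile above which a module gene is a target
#'   (default 0.9).
#' @param edges Optional prior edge tibble (`from`, `to`); when given,
#'   targets are additionally restricted to the regulator's neighbors in it.
#' @return A `tlr_ranking` tibble: `condition`, `regulator`, `module`,
#'   `n_targets`, `n_de_targets`, `p_value`, `rank`.
#' @export
rank_regulators <- function(modules, tom, regulators, de_sets,
                            top_quantile = 0.9, edges = NULL) {
  asg <- modules$assignment
  known <- asg$gene_id[asg$module != "unassigned"]
  absent <- setdiff(regulators, known)
  if (length(absent) > 0) {
    warn(paste0("skipping regulators absent from assigned modules: ",
                paste(utils::head(absent, 5), collapse = ", ")))
  }
  regulators <- intersect(regulators, known)
  rows <- purrr::map_dfr(regulators, function(reg) {
    mod <- asg$module[asg$gene_id == reg]
    members <- setdiff(asg$gene_id[asg$module == mod], reg)
    w <- tom[reg, members]
    targets <- members[w >= stats::quantile(w, top_quantile)]
    if (!is.null(edges)) {
      nb <- union(edges$to[edges$from == reg], edges$from[edges$to == reg])
      targets <- intersect(targets, nb)
    }
    purrr::map_dfr(names(de_sets), function(cond) {
      de <- intersect(de_sets[[cond]], members)
      q <- length(intersect(targets, de))
      p <- stats::phyper(q - 1, length(de), length(members) - length(de),
                         length(targets), lower.tail = FALSE)
      tibble::tibble(condition = cond, regulator = reg, module = mod,
                     n_targets = length(targets), n_de_targets = q,
                     p_value = p)
    })
  })
  out <- rows %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::arrange(.data$p_value,
                   dplyr::desc(.data$n_de_targets / pmax(1, .data$n_targets)),
                   .data$regulator, .by_group = TRUE) %>%
    dplyr::mutate(rank = dplyr::row_number()) %>%
    dplyr::ungroup()
  new_result(out, "tlr_ranking", top_quantile = top_quantile)
}

#' Simulate module-structured expression
#'
#' Latent-factor generator for co-expression fixtures: each module has a
#' standard-normal factor per sample; a member gene is
#' `sqrt(w) * factor + sqrt(1 - w) * noise`, so any two genes of one module
#' correlate at `w = within_cor` and genes of different modules at
#' `within_cor * between_cor` (factors share correlation `between_cor`).
#' Optional `hub` genes load at `sqrt(hub_loading)` on their module's
#' factor. Power-law module sizes give an approximately scale-free
#' connectivity distribution.
#'
#' @param module_sizes Integer vector of module sizes.
#' @param n_samples Number of samples.
#' @param within_cor Within-module gene-gene correlation.
#' @param between_cor Factor correlation across modules (default 0).
#' @param n_noise Unstructured extra genes.
#' @param hubs Optional integer vector: number of hub genes per module.
#' @param hub_loading Squared factor loading for hubs (default 0.95).
#' @param seed Integer seed.
#' @return List: `expr` (tibble), `truth` (tibble `gene_id`, `module`,
#'   `is_hub`).
#' @export
simulate_module_expression <- function(module_sizes, n_samples = 20,
                                       within_cor = 0.9, between_cor = 0,
                                       n_noise = 0, hubs = NULL,
                                       hub_loading = 0.95, seed = 1) {
  stopifnot(within_cor >= 0, within_cor <= 1, between_cor >= -1, between_cor <= 1)
  withr::local_seed(seed)
  n_mod <- length(module_sizes)
  # factors with compound-symmetric correlation between_cor
  shared <- stats::rnorm(n_samples)
  factors <- vapply(seq_len(n_mod), function(i) {
    sqrt(abs(between_cor)) * shared + sqrt(1 - abs(between_cor)) * stats::rnorm(n_samples)
  }, numeric(n_samples))
  if (is.null(hubs)) hubs <- rep(0L, n_mod)
  rows <- list(); ids <- character(); mod_lab <- character(); hub_flag <- logical()
  gidx <- 0L
  for (mi in seq_len(n_mod)) {
    for (g in seq_len(module_sizes[mi])) {
      gidx <- gidx + 1L
      w <- if (g <= hubs[mi]) hub_loading else within_cor
      rows[[gidx]] <- sqrt(w) * factors[, mi] + sqrt(1 - w) * stats::rnorm(n_samples)
      ids[gidx] <- sprintf("g%04d", gidx)
      mod_lab[gidx] <- paste0("mod", mi)
      hub_flag[gidx] <- g <= hubs[mi]
    }
  }
  for (g in seq_len(n_noise)) {
    gidx <- gidx + 1L
    rows[[gidx]] <- stats::rnorm(n_samples)
    ids[gidx] <- sprintf("g%04d", gidx)
    mod_lab[gidx] <- "noise"
    hub_flag[gidx] <- FALSE
  }
  expr_m <- do.call(rbind, rows)
  colnames(expr_m) <- sprintf("s%02d", seq_len(n_samples))
  rownames(expr_m) <- ids
  list(expr = matrix_counts(expr_m),
       truth = tibble::tibble(gene_id = ids, module = mod_lab, is_hub = hub_flag))
}
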