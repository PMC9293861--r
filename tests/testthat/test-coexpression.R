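test_that("TOM formula is exact on the hand-computed 3-gene fixture", {
  # a12 = a13 = 1, a23 = 0
  a <- matrix(c(0, 1, 1,
                1, 0, 0,
                1, 0, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("g1", "g2", "g3"), c("g1", "g2", "g3")))
  tom <- tom_from_adjacency(a)
  expect_equal(tom["g1", "g2"], 1)        # (0 + 1) / (min(2, 1) + 1 - 1)
  expect_equal(tom["g2", "g3"], 0.5)      # (1 + 0) / (min(1, 1) + 1 - 0)
  expect_equal(diag(tom), c(g1 = 1, g2 = 1, g3 = 1))
})

test_that("TOM is symmetric, bounded, and all-ones for a complete graph", {
  withr::with_seed(41, {
    for (i in 1:20) {
      n <- sample(4:15, 1)
      a <- matrix(runif(n * n), n, n)
      a <- (a + t(a)) / 2
      tom <- tom_from_adjacency(a)
      expect_equal(tom, t(tom), tolerance = 1e-12)
      expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
    }
  })
  ones <- matrix(1, 5, 5)
  expect_equal(tom_from_adjacency(ones), matrix(1, 5, 5), tolerance = 1e-12)
  # identical expression for all genes -> complete graph -> all TOM = 1
  expr <- tibble::tibble(feature_id = c("g1", "g2", "g3"),
                         s1 = c(1, 2, 3), s2 = c(2, 4, 6), s3 = c(3, 6, 9),
                         s4 = c(1.5, 3, 4.5))
  expect_equal(unname(tom_matrix(expr, 6)), matrix(1, 3, 3), tolerance = 1e-9)
  expect_error(tom_matrix(dplyr::mutate(expr, s1 = 1, s2 = 1, s3 = 1, s4 = 1), 6),
               "constant")
})

test_that("soft power selection finds a scale-free fit and flags pure noise", {
  sim <- simulate_module_expression(
    module_sizes = c(60, 30, 20, 15, 12, 10, 8, 7, 6, 5),
    n_samples = 30, within_cor = 0.8, n_noise = 10, seed = 9
  )
  res <- pick_soft_power(sim$expr)
  expect_false(res$flagged)
  expect_gte(res$fit$r_squared[res$fit$power == res$power], 0.8)
  # determinism
  res2 <- pick_soft_power(sim$expr)
  expect_identical(res, res2)

  noise <- simulate_module_expression(module_sizes = integer(0), n_samples = 20,
                                      n_noise = 60, seed = 10)
  resn <- pick_soft_power(noise$expr)
  expect_true(resn$flagged)
})

test_that("module detection recovers planted blocks and honours size/merge rules", {
  sim <- simulate_module_expression(module_sizes = c(40, 40), n_samples = 30,
                                    within_cor = 0.9, between_cor = 0, seed = 2)
  mods <- detect_modules(sim$expr, power = 6, min_module_size = 30)
  asg <- dplyr::inner_join(mods$assignment, sim$truth, by = "gene_id")
  expect_equal(length(setdiff(unique(asg$module.x), "unassigned")), 2)
  expect_equal(adjusted_rand_index(asg$module.x, asg$module.y), 1)
  expect_equal(as.numeric(sort(table(asg$module.x))), c(40, 40))

  # a 10-gene block is below min_module_size -> unassigned
  sim2 <- simulate_module_expression(module_sizes = c(40, 10), n_samples = 30,
                                     within_cor = 0.9, seed = 2)
  mods2 <- detect_modules(sim2$expr, power = 6, min_module_size = 30)
  asg2 <- dplyr::inner_join(mods2$assignment, sim2$truth, by = "gene_id")
  small <- asg2$module.x[asg2$module.y == "mod2"]
  expect_true(all(small == "unassigned"))

  # two blocks with highly correlated factors merge into one module
  sim3 <- simulate_module_expression(module_sizes = c(40, 40), n_samples = 40,
                                     within_cor = 0.9, between_cor = 0.97, seed = 3)
  mods3 <- detect_modules(sim3$expr, power = 6, min_module_size = 30,
                          merge_cor = 0.85)
  expect_equal(glance(mods3)$n_modules, 1)
})

test_that("module recovery holds at moderate cross-block correlation", {
  sim <- simulate_module_expression(module_sizes = c(40, 40), n_samples = 40,
                                    within_cor = 0.9, between_cor = 0.2, seed = 12)
  mods <- detect_modules(sim$expr, power = 6, min_module_size = 30)
  asg <- dplyr::inner_join(mods$assignment, sim$truth, by = "gene_id")
  expect_gte(adjusted_rand_index(asg$module.x, asg$module.y), 0.9)
})

test_that("module labels are invariant to gene order", {
  sim <- simulate_module_expression(module_sizes = c(35, 45), n_samples = 25,
                                    within_cor = 0.85, seed = 6)
  mods <- detect_modules(sim$expr, power = 6)
  perm <- withr::with_seed(7, sample.int(nrow(sim$expr)))
  mods_p <- detect_modules(sim$expr[perm, ], power = 6)
  j <- dplyr::inner_join(mods$assignment, mods_p$assignment, by = "gene_id")
  expect_equal(j$module.x, j$module.y)
})

test_that("in-package ARI agrees with the mclust implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(17, {
    for (i in 1:25) {
      a <- sample(letters[1:4], 60, replace = TRUE)
      b <- sample(letters[1:3], 60, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                   tolerance = 1e-12)
    }
  })
})

test_that("regulator ranking rewards DE-enriched targets and handles extremes", {
  sim <- simulate_module_expression(module_sizes = c(60, 60), n_samples = 40,
                                    within_cor = 0.8, hubs = c(1, 1),
                                    hub_loading = 0.97, seed = 4)
  tom <- tom_matrix(sim$expr, 6)
  mods <- detect_modules(sim$expr, tom = tom, power = 6, min_module_size = 30)
  hub1 <- sim$truth$gene_id[sim$truth$is_hub][1]
  mod_of_hub <- mods$assignment$module[mods$assignment$gene_id == hub1]
  members <- mods$assignment$gene_id[mods$assignment$module == mod_of_hub]
  # DE genes concentrate in the hub's module; candidate regulators mostly sit
  # in the other (non-responsive) module, whose targets have no DE overlap
  de_sets <- list(CpG = setdiff(members, hub1)[1:45])
  assigned <- mods$assignment[mods$assignment$module != "unassigned", ]
  other <- assigned$gene_id[assigned$module != mod_of_hub]
  same <- setdiff(assigned$gene_id[assigned$module == mod_of_hub], hub1)
  regulators <- c(hub1, withr::with_seed(1, c(sample(same, 2), sample(other, 38))))
  rk <- rank_regulators(mods, tom, regulators, de_sets)
  expect_lte(rk$rank[rk$regulator == hub1], 5)

  # zero DE targets -> p = 1
  rk0 <- rank_regulators(mods, tom, hub1, list(none = character(0)))
  expect_equal(rk0$p_value, 1)
  # all targets DE -> minimal p for the margins, rank 1
  all_de <- list(allde = setdiff(members, hub1))
  rk1 <- rank_regulators(mods, tom, regulators, all_de)
  expect_equal(rk1$rank[rk1$regulator == hub1] <= 5, TRUE)
  expect_warning(rank_regulators(mods, tom, c(hub1, "ghost"), de_sets), "skipping")
})
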