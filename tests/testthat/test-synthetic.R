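no_effect_config <- function(...) {
  synthetic_config(effect_richness = 0, effect_dominance = 1,
                   effect_network = 1, ...)
}

test_that("generated counts respect depth, determinism and truth shape", {
  cfg <- synthetic_config(n_asv = 60, n_blocks = 4, block_size = 10,
                          months = 1:3, samples_per_group_month = 4,
                          depth = 2000, seed = 5)
  sim <- generate_counts(cfg)
  expect_true(all(colSums(sim$table$counts) == 2000))
  expect_equal(ncol(sim$table$counts), 2 * 3 * 4)
  expect_setequal(unique(sim$truth$block_membership), 0:4)
  expect_equal(length(sim$truth$effect_trajectory), 3)
  sim2 <- generate_counts(cfg)
  expect_identical(sim$table$counts, sim2$table$counts)
  cfg3 <- synthetic_config(n_asv = 60, n_blocks = 4, block_size = 10,
                           months = 1:3, samples_per_group_month = 4,
                           depth = 2000, seed = 6)
  expect_false(identical(sim$table$counts,
                         generate_counts(cfg3)$table$counts))
})

test_that("config invariants are enforced", {
  expect_error(synthetic_config(n_asv = 50, n_blocks = 10, block_size = 10),
               class = "menet_config_error")
  expect_error(synthetic_config(rho_within = 1), class = "menet_config_error")
  expect_error(synthetic_config(depth = 0), class = "menet_config_error")
  expect_error(synthetic_config(recovery_halflife = 0),
               class = "menet_config_error")
})

test_that("rho_within = 0 plants no block correlation signal", {
  cfg <- no_effect_config(n_asv = 60, n_blocks = 4, block_size = 10,
                          rho_within = 0, months = 1,
                          samples_per_group_month = 100, depth = 20000,
                          seed = 3)
  sim <- generate_counts(cfg)
  la <- log_transform(sim$table)
  r <- suppressWarnings(cor(t(la)))
  blocks <- sim$truth$block_membership
  same <- outer(blocks, blocks, "==") & outer(blocks, blocks,
                                              function(a, b) a > 0 & b > 0)
  off <- upper.tri(r)
  within <- mean(abs(r[off & same]), na.rm = TRUE)
  between <- mean(abs(r[off & !same]), na.rm = TRUE)
  expect_lt(abs(within - between), 0.05)
})

test_that("rho_within = 0.9 separates within- from between-block correlation", {
  cfg <- no_effect_config(n_asv = 60, n_blocks = 4, block_size = 10,
                          rho_within = 0.9, months = 1,
                          samples_per_group_month = 50, depth = 20000,
                          seed = 4)
  sim <- generate_counts(cfg)
  la <- log_transform(sim$table)
  r <- cor(t(la))
  blocks <- sim$truth$block_membership
  same <- outer(blocks, blocks, "==") & outer(blocks, blocks,
                                              function(a, b) a > 0 & b > 0)
  off <- upper.tri(r)
  expect_gte(mean(r[off & same]) - mean(r[off & !same]), 0.4)
})

test_that("null effects make groups exchangeable (PERMANOVA type-I)", {
  rejections <- 0L
  for (i in 1:200) {
    cfg <- no_effect_config(n_asv = 40, n_blocks = 2, block_size = 8,
                            months = 1, samples_per_group_month = 8,
                            depth = 1000, seed = 1000 + i)
    sim <- generate_counts(cfg)
    bc <- bray_curtis_matrix(sim$table)
    tr <- dissimilarity_test(bc, sim$table$metadata$group, "adonis",
                             n_perm = 99, seed = i)
    if (tr$p_value <= 0.05) rejections <- rejections + 1L
  }
  expect_gte(rejections / 200, 0.01)
  expect_lte(rejections / 200, 0.10)
})

test_that("group-A module weakening recovers monotonically in expectation", {
  cfg <- synthetic_config(months = c(1, 7, 14), seed = 9)
  sim <- generate_counts(cfg)
  expect_true(all(diff(sim$truth$effect_trajectory) < 0))
  md <- sim$table$metadata
  blocks <- sim$truth$block_membership
  within_r <- function(g, m) {
    ids <- md$sample_id[md$group == g & md$month == m]
    la <- log_transform(subset_samples(sim$table, samples = ids))
    r <- suppressWarnings(cor(t(la)))
    same <- outer(blocks, blocks, "==") &
      outer(blocks, blocks, function(a, b) a > 0 & b > 0)
    mean(r[upper.tri(r) & same], na.rm = TRUE)
  }
  deficit <- vapply(c(1, 14), function(m) within_r("C", m) - within_r("A", m),
                    numeric(1))
  expect_gt(deficit[1], deficit[2])
})

test_that("pathway generator plants one correlated block", {
  expect_error(generate_pathway_table(10, 0, 5, 0.9),
               class = "menet_config_error")
  expect_error(generate_pathway_table(10, 50, 11, 0.9),
               class = "menet_config_error")
  # null: near-empty functional network at default cutoffs
  pw0 <- generate_pathway_table(60, 100, 8, rho = 0, seed = 2)
  g0 <- build_pathway_network(pw0$table)
  expect_lte(igraph::ecount(g0) / choose(60, 2), 0.05)
  # planted: MCODE top cluster recovers the block
  pw <- generate_pathway_table(60, 100, 8, rho = 0.95, seed = 2)
  cl <- mcode_clusters(build_pathway_network(pw$table))
  expect_gte(length(intersect(cl[[1]]$members, pw$planted)), 7)
  # determinism
  pw2 <- generate_pathway_table(60, 100, 8, rho = 0.95, seed = 2)
  expect_identical(pw$table, pw2$table)
})
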