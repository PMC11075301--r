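test_that("alpha diversity follows the index formulas", {
  # uniform 4 species
  m <- matrix(c(5, 5, 5, 5), ncol = 1, dimnames = list(paste0("a", 1:4), "s"))
  a <- alpha_diversity(m)
  expect_equal(a$shannon, log(4))
  expect_equal(a$dominance, 0.25)
  expect_equal(a$chao1, 4)                       # no singletons: S_obs
  # S_obs = 10, F1 = 4, F2 = 2 -> chao1 = 10 + 4*3/(2*3) = 12
  x <- c(1, 1, 1, 1, 2, 2, 3, 4, 5, 6)
  m2 <- matrix(x, ncol = 1, dimnames = list(paste0("a", 1:10), "s"))
  expect_equal(alpha_diversity(m2)$chao1, 12)
  # all-zero sample reported missing
  m3 <- cbind(m, s0 = 0)
  expect_true(all(is.na(alpha_diversity(m3)[2, -1])))
})

test_that("alpha diversity agrees with vegan", {
  skip_if_not_installed("vegan")
  set.seed(21)
  m <- matrix(rpois(30 * 6, 3), 30, 6,
              dimnames = list(paste0("a", 1:30), paste0("s", 1:6)))
  a <- alpha_diversity(m)
  expect_equal(a$shannon, unname(vegan::diversity(t(m), "shannon")))
  expect_equal(a$dominance,
               unname(1 - vegan::diversity(t(m), "simpson")))
  expect_equal(a$chao1, unname(t(vegan::estimateR(t(m)))[, "S.chao1"]))
})

test_that("Bray-Curtis matches its definition and vegan", {
  x <- matrix(c(1, 1, 0, 0, 1, 1), ncol = 2,
              dimnames = list(paste0("a", 1:3), c("s1", "s2")))
  d <- bray_curtis_matrix(x)
  expect_equal(d["s1", "s2"], 0.5)
  ident <- cbind(x, s3 = x[, 1])
  expect_equal(bray_curtis_matrix(ident)["s1", "s3"], 0)
  disj <- matrix(c(2, 0, 0, 3), 2, dimnames = list(c("a", "b"),
                                                   c("s1", "s2")))
  expect_equal(bray_curtis_matrix(disj)["s1", "s2"], 1)
  set.seed(4)
  m <- matrix(rpois(20 * 8, 5), 20, 8,
              dimnames = list(paste0("a", 1:20), paste0("s", 1:8)))
  d2 <- bray_curtis_matrix(m)
  expect_true(isSymmetric(d2))
  expect_true(all(diag(d2) == 0))
  expect_true(all(d2 >= 0 & d2 <= 1))
  skip_if_not_installed("vegan")
  expect_equal(as.matrix(vegan::vegdist(t(m), "bray")), d2,
               ignore_attr = TRUE)
  zz <- m; zz[, 1:2] <- 0
  expect_error(bray_curtis_matrix(zz), class = "menet_config_error")
})

test_that("PCoA embeds Euclidean data exactly and matches cmdscale", {
  set.seed(8)
  pts <- matrix(rnorm(12 * 2), 12, 2,
                dimnames = list(paste0("s", 1:12), NULL))
  d <- as.matrix(dist(pts))
  ord <- pcoa(d, k = 2)
  dd <- as.matrix(dist(ord$coordinates))
  expect_lt(max(abs(dd - d)), 1e-8)
  # duplicate samples land on identical coordinates
  d2 <- as.matrix(dist(pts[c(1, 1, 2:12), ]))
  ord2 <- pcoa(d2, k = 2)
  expect_lt(max(abs(ord2$coordinates[1, ] - ord2$coordinates[2, ])), 1e-10)
  # eigenvalues match the classical-scaling oracle
  cm <- cmdscale(d, k = 2, eig = TRUE)
  expect_equal(ord$eigenvalues[1:2], cm$eig[1:2])
  expect_warning(pcoa(d, k = 12), "positive")
})

test_that("dissimilarity statistics agree with vegan on a fixture", {
  skip_if_not_installed("vegan")
  set.seed(13)
  m <- matrix(rpois(15 * 12, 6), 15, 12,
              dimnames = list(paste0("a", 1:15), paste0("s", 1:12)))
  m[, 1:6] <- m[, 1:6] + rpois(15 * 6, 2)
  d <- bray_curtis_matrix(m)
  labels <- rep(c("A", "C"), each = 6)
  an <- dissimilarity_test(d, labels, "anosim", n_perm = 99, seed = 1)
  van <- vegan::anosim(as.dist(d), labels, permutations = 9)
  expect_equal(an$statistic, unname(van$statistic), tolerance = 1e-12)
  ad <- dissimilarity_test(d, labels, "adonis", n_perm = 99, seed = 1)
  vad <- vegan::adonis2(as.dist(d) ~ g,
                        data = data.frame(g = labels), permutations = 9)
  expect_equal(ad$statistic, vad$F[1], tolerance = 1e-12)
  expect_equal(ad$r_squared, vad$R2[1], tolerance = 1e-12)
  mr <- dissimilarity_test(d, labels, "mrpp", n_perm = 99, seed = 1)
  vmr <- vegan::mrpp(as.dist(d), labels, permutations = 9)
  expect_equal(mr$statistic, vmr$delta, tolerance = 1e-12)
})

test_that("permutation tests detect separation and respect contracts", {
  set.seed(30)
  pts <- rbind(matrix(rnorm(24, 0, 0.01), 12),
               matrix(rnorm(24, 10, 0.01), 12))
  rownames(pts) <- paste0("s", 1:24)
  d <- as.matrix(dist(pts))
  labels <- rep(c("A", "B"), each = 12)
  an <- dissimilarity_test(d, labels, "anosim", n_perm = 999, seed = 2)
  expect_equal(an$statistic, 1)
  expect_equal(an$p_value, 1 / 1000)
  # label renaming leaves p unchanged
  an2 <- dissimilarity_test(d, c("x", "y")[match(labels, c("A", "B"))],
                            "anosim", n_perm = 999, seed = 2)
  expect_equal(an$p_value, an2$p_value)
  # one group split randomly in two: no structure, mrpp A ~ 0
  set.seed(31)
  m <- matrix(rnorm(40), 10)
  rownames(m) <- paste0("s", 1:10)
  mr <- dissimilarity_test(as.matrix(dist(m)), rep(c("A", "B"), 5), "mrpp",
                           n_perm = 499, seed = 3)
  expect_lt(abs(mr$A), 0.15)
  expect_error(dissimilarity_test(d, c("A", rep("B", 23)), "anosim"),
               class = "menet_config_error")
  expect_error(dissimilarity_test(d, rep("A", 24), "anosim"),
               class = "menet_config_error")
})

test_that("compare_groups picks the right branch", {
  # normal data: t-test branch in the large majority
  branches <- vapply(1:60, function(i) {
    menet:::with_seed(i, {
      a <- rnorm(20); b <- rnorm(20)
      compare_groups(a, b)$branch
    })
  }, character(1))
  expect_gte(mean(branches == "t-test"), 0.8)
  # heavily skewed data: Wilcoxon branch in the large majority
  branches2 <- vapply(1:60, function(i) {
    menet:::with_seed(1000 + i, {
      a <- rexp(30); b <- rexp(30)
      compare_groups(a, b)$branch
    })
  }, character(1))
  expect_gte(mean(branches2 == "wilcoxon"), 0.8)
  # constant input: fallback with warning
  expect_warning(res <- compare_groups(rep(1, 5), rep(1, 5)), "Wilcoxon")
  expect_equal(res$branch, "wilcoxon")
  expect_error(compare_groups(1:2, 1:5), class = "menet_config_error")
})
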