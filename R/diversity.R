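#' Per-sample alpha diversity
#'
#' Computes three indices per sample: bias-corrected chao1
#' `S_obs + F1 (F1 - 1) / (2 (F2 + 1))` (F1/F2 = singleton/doubleton counts),
#' Shannon entropy `-sum p_i log p_i` (natural log by default), and dominance
#' `sum p_i^2` (Simpson concentration). All-zero samples are reported as NA.
#'
#' @param table a [feature_table] or count matrix (ASV x sample).
#' @param shannon_base logarithm base for Shannon (default `exp(1)`).
#' @return data.frame with columns `sample_id`, `chao1`, `shannon`,
#'   `dominance`.
#' @export
alpha_diversity <- function(table, shannon_base = exp(1)) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  res <- t(apply(m, 2, function(x) {
    tot <- sum(x)
    if (tot == 0) return(c(chao1 = NA_real_, shannon = NA_real_,
                           dominance = NA_real_))
    s_obs <- sum(x > 0)
    f1 <- sum(x == 1); f2 <- sum(x == 2)
    chao1 <- s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
    p <- x[x > 0] / tot
    c(chao1 = chao1,
      shannon = -sum(p * log(p, base = shannon_base)),
      dominance = sum(p^2))
  }))
  data.frame(sample_id = colnames(m), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Bray-Curtis dissimilarity matrix
#'
#' `d(i, j) = sum_k |x_ik - x_jk| / sum_k (x_ik + x_jk)` over samples i, j.
#'
#' @param table a [feature_table] or count matrix (ASV x sample).
#' @return symmetric matrix with zero diagonal and values in \[0, 1\];
#'   a pair of all-zero samples is an error.
#' @export
bray_curtis_matrix <- function(table) {
  m <- if (inherits(table, "feature_table")) table$counts else as.matrix(table)
  n <- ncol(m)
  if (n < 2) stop_config("need >= 2 samples")
  d <- matrix(0, n, n, dimnames = list(colnames(m), colnames(m)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      denom <- sum(m[, i] + m[, j])
      if (denom == 0)
        stop_config("Bray-Curtis undefined for all-zero pair ",
                    colnames(m)[i], ", ", colnames(m)[j])
      d[i, j] <- d[j, i] <- sum(abs(m[, i] - m[, j])) / denom
    }
  }
  d
}

#' Principal coordinate analysis
#'
#' Classical metric scaling: eigendecomposition of the double-centered
#' squared-distance matrix `-0.5 J D^2 J`. Axes are ordered by eigenvalue;
#' variance explained is each positive eigenvalue over the sum of positive
#' eigenvalues (negative eigenvalues are dropped, no Lingoes correction).
#'
#' @param dist symmetric distance matrix with sample dimnames.
#' @param k number of axes to return (default 2); truncated with a warning if
#'   fewer positive eigenvalues exist.
#' @return list with `coordinates` (n x k matrix), `eigenvalues`, and
#'   `variance_explained` per returned axis.
#' @export
pcoa <- function(dist, k = 2) {
  d <- as.matrix(dist)
  n <- nrow(d)
  if (n < 2 || !isSymmetric(unname(d), tol = 1e-8))
    stop_config("dist must be a symmetric matrix with >= 2 samples")
  j <- diag(n) - 1 / n
  b <- -0.5 * j %*% (d^2) %*% j
  eig <- eigen((b + t(b)) / 2, symmetric = TRUE)
  pos <- eig$values > max(eig$values, 0) * 1e-10
  n_pos <- sum(pos)
  if (k > n_pos) {
    warning("only ", n_pos, " positive eigenvalues; truncating k")
    k <- n_pos
  }
  lam <- eig$values[seq_len(k)]
  coords <- eig$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(lam), nrow = k)
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("PCo", seq_len(k))
  list(coordinates = coords, eigenvalues = eig$values,
       variance_explained = lam / sum(eig$values[eig$values > 0]))
}

new_test_result <- function(method, statistic, p_value, n_perm = NA,
                            seed = NULL, extra = list()) {
  structure(c(list(method = method, statistic = statistic,
                   p_value = p_value, n_perm = n_perm, seed = seed), extra),
            class = "menet_test")
}

#' @export
print.menet_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$method, x$statistic,
              x$p_value))
  if (!is.na(x$n_perm)) cat(sprintf(" (%d permutations)", x$n_perm))
  cat("\n")
  invisible(x)
}

#' Permutation tests of group dissimilarity
#'
#' Three classical permutation tests on a distance matrix:
#' \describe{
#'   \item{anosim}{R = (mean between-group rank - mean within-group rank) /
#'     (M / 2) over the M = n(n-1)/2 pairwise distance ranks.}
#'   \item{adonis}{one-factor PERMANOVA pseudo-F from the partition of summed
#'     squared distances into between- and within-group components.}
#'   \item{mrpp}{observed delta = the group-size-weighted mean within-group
#'     distance, with chance-corrected A = 1 - delta / E(delta).}
#' }
#' p-values use `p = (1 + #permuted >= observed) / (n_perm + 1)` (<= for the
#' mrpp delta, which is small under structure).
#'
#' @param dist symmetric distance matrix.
#' @param labels group label per sample (>= 2 groups, each with >= 2 samples).
#' @param method one of "anosim", "adonis", "mrpp".
#' @param n_perm number of label permutations (default 999).
#' @param seed integer seed for the permutations.
#' @return a `menet_test` with the method's statistic (plus `A` for mrpp,
#'   `r_squared` for adonis).
#' @export
dissimilarity_test <- function(dist, labels,
                               method = c("anosim", "adonis", "mrpp"),
                               n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  d <- as.matrix(dist)
  labels <- as.character(labels)
  n <- nrow(d)
  stopifnot(length(labels) == n)
  tab <- table(labels)
  if (length(tab) < 2) stop_config("need >= 2 groups")
  if (any(tab < 2)) stop_config("singleton group: ",
                                names(tab)[tab < 2][1])
  lower <- which(lower.tri(d))
  dv <- d[lower]
  pair_i <- row(d)[lower]; pair_j <- col(d)[lower]

  stat_fun <- switch(method,
    anosim = {
      rk <- rank(dv)
      m_half <- length(dv) / 2
      function(lab) {
        within <- lab[pair_i] == lab[pair_j]
        (mean(rk[!within]) - mean(rk[within])) / m_half
      }
    },
    adonis = {
      dv2 <- dv^2
      ss_t <- sum(dv2) / n
      a <- length(tab)
      function(lab) {
        within <- lab[pair_i] == lab[pair_j]
        g <- lab[pair_i][within]
        ss_g <- tapply(dv2[within], g, sum)
        ng <- table(lab)
        ss_w <- sum(ss_g / as.numeric(ng[names(ss_g)]))
        ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
      }
    },
    mrpp = {
      function(lab) {
        within <- lab[pair_i] == lab[pair_j]
        ng <- table(lab)
        dg <- tapply(dv[within], lab[pair_i][within], mean)
        sum((ng[names(dg)] / n) * dg)
      }
    })

  obs <- stat_fun(labels)
  perm_stats <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i) stat_fun(sample(labels)),
           numeric(1))
  })
  if (method == "mrpp") {
    p <- (1 + sum(perm_stats <= obs)) / (n_perm + 1)
    extra <- list(A = 1 - obs / mean(perm_stats),
                  expected_delta = mean(perm_stats))
  } else {
    p <- (1 + sum(perm_stats >= obs)) / (n_perm + 1)
    extra <- if (method == "adonis") {
      a <- length(tab)
      list(r_squared = obs * (a - 1) / (obs * (a - 1) + (n - a)))
    } else list()
  }
  new_test_result(method, unname(obs), p, n_perm, seed, extra)
}

#' Normality-gated two-group comparison
#'
#' Mirrors the common reporting rule for longitudinal group contrasts: test
#' each group with Shapiro-Wilk; if both pass at `alpha` a two-sample t-test
#' is used (Student if an F-test finds the variances comparable, Welch
#' otherwise); if either fails, a two-sided Wilcoxon rank-sum test.
#' Degenerate (constant) inputs fall back to Wilcoxon with a warning.
#'
#' @param values_a numeric vector, group A (>= 3 values).
#' @param values_c numeric vector, group C (>= 3 values).
#' @param alpha significance level for the normality and variance gates
#'   (default 0.05).
#' @return a `menet_test` whose `method` records the branch ("t-test" or
#'   "wilcoxon"), with `branch` and Shapiro p-values attached.
#' @export
compare_groups <- function(values_a, values_c, alpha = 0.05) {
  values_a <- values_a[!is.na(values_a)]
  values_c <- values_c[!is.na(values_c)]
  if (length(values_a) < 3 || length(values_c) < 3)
    stop_config("each group needs >= 3 values")
  sw <- tryCatch(
    list(a = shapiro.test(values_a)$p.value,
         c = shapiro.test(values_c)$p.value),
    error = function(e) NULL)
  if (is.null(sw)) {
    warning("normality test undefined (constant input); using Wilcoxon")
    normal <- FALSE
    sw <- list(a = NA_real_, c = NA_real_)
  } else {
    normal <- sw$a > alpha && sw$c > alpha
  }
  if (normal) {
    equal_var <- var.test(values_a, values_c)$p.value > alpha
    tt <- t.test(values_a, values_c, var.equal = equal_var)
    new_test_result("t-test", unname(tt$statistic), tt$p.value,
                    extra = list(branch = "t-test", equal_var = equal_var,
                                 shapiro_p_a = sw$a, shapiro_p_c = sw$c))
  } else {
    wt <- suppressWarnings(wilcox.test(values_a, values_c))
    new_test_result("wilcoxon", unname(wt$statistic), wt$p.value,
                    extra = list(branch = "wilcoxon",
                                 shapiro_p_a = sw$a, shapiro_p_c = sw$c))
  }
}
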