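# Independent brute-force oracles. Everything here works from a plain
# edge list / adjacency list with hand-rolled BFS so the quantities are
# computed on a different route than the package (which goes through igraph).

# adjacency list from an igraph graph, by vertex index
oracle_adj <- function(g) {
  n <- igraph::vcount(g)
  el <- igraph::as_edgelist(g, names = FALSE)
  adj <- vector("list", n)
  for (r in seq_len(nrow(el))) {
    i <- el[r, 1]; j <- el[r, 2]
    if (i == j) next
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, unique)
}

bf_bfs <- function(adj, src) {
  n <- length(adj)
  d <- rep(Inf, n)
  d[src] <- 0
  q <- src
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (u in adj[[v]]) if (is.infinite(d[u])) {
      d[u] <- d[v] + 1
      q <- c(q, u)
    }
  }
  d
}

bf_distance_matrix <- function(adj) {
  t(vapply(seq_along(adj), function(s) bf_bfs(adj, s),
           numeric(length(adj))))
}

bf_topology <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  l <- sum(lengths(adj)) / 2
  # local clustering by direct triangle counting
  cc <- vapply(seq_len(n), function(v) {
    nb <- adj[[v]]
    k <- length(nb)
    if (k < 2) return(0)
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k)
      if (nb[b] %in% adj[[nb[a]]]) tri <- tri + 1
    2 * tri / (k * (k - 1))
  }, numeric(1))
  d <- bf_distance_matrix(adj)
  dv <- d[upper.tri(d)]
  reach <- is.finite(dv)
  list(nodes = n, links = l, avg_degree = 2 * l / n,
       avg_clustering = mean(cc),
       geodesic = if (any(reach)) mean(dv[reach]) else NA_real_,
       connectedness = mean(reach))
}

bf_efficiency <- function(g) {
  adj <- oracle_adj(g)
  n <- length(adj)
  d <- bf_distance_matrix(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (n * (n - 1))
}

bf_vulnerability <- function(g) {
  e0 <- bf_efficiency(g)
  n <- igraph::vcount(g)
  drops <- vapply(seq_len(n), function(i) {
    (e0 - bf_efficiency(igraph::delete_vertices(g, i))) / e0
  }, numeric(1))
  max(drops)
}

# modularity of a given partition, straight from the definition
bf_modularity <- function(g, membership) {
  el <- igraph::as_edgelist(g, names = FALSE)
  m <- nrow(el)
  deg <- tabulate(c(el[, 1], el[, 2]), nbins = igraph::vcount(g))
  q <- 0
  for (s in unique(membership)) {
    idx <- which(membership == s)
    e_ss <- sum(el[, 1] %in% idx & el[, 2] %in% idx)
    d_s <- sum(deg[idx])
    q <- q + e_ss / m - (d_s / (2 * m))^2
  }
  q
}

# best modularity over all partitions (Bell-number enumeration, n <= 8)
bf_best_modularity <- function(g) {
  n <- igraph::vcount(g)
  stopifnot(n <= 8)
  best <- -Inf
  memb <- integer(n)
  recurse <- function(i, k) {
    if (i > n) {
      best <<- max(best, bf_modularity(g, memb))
      return(invisible())
    }
    for (s in seq_len(k + 1)) {
      memb[i] <<- s
      recurse(i + 1, max(k, s))
    }
  }
  recurse(1, 0)
  best
}

adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

random_named_gnp <- function(n, p, seed) {
  g <- menet:::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- paste0("v", seq_len(n))
  g
}

# block-correlation matrix with a dense noisy background: |r| ~ 0.9 inside
# 20 blocks of 10, uniform noise up to 0.45 outside
planted_corr <- function(n_blocks = 20, block_size = 10, rho = 0.9,
                         noise_max = 0.45, jitter = 0.02, seed = 1) {
  menet:::with_seed(seed, {
    n <- n_blocks * block_size
    r <- matrix(0, n, n)
    r[lower.tri(r)] <- runif(n * (n - 1) / 2, -noise_max, noise_max)
    r <- r + t(r)
    for (b in seq_len(n_blocks)) {
      idx <- ((b - 1) * block_size + 1):(b * block_size)
      blk <- matrix(0, block_size, block_size)
      blk[lower.tri(blk)] <-
        rho + runif(block_size * (block_size - 1) / 2, -jitter, jitter)
      r[idx, idx] <- blk + t(blk)
    }
    diag(r) <- 1
    rownames(r) <- colnames(r) <- sprintf("a%03d", seq_len(n))
    r
  })
}

planted_blocks_truth <- function(n_blocks = 20, block_size = 10) {
  setNames(rep(seq_len(n_blocks), each = block_size),
           sprintf("a%03d", seq_len(n_blocks * block_size)))
}

toy_table <- function() {
  counts <- matrix(c(5, 0, 3, 1, 2, 9), nrow = 3, byrow = TRUE,
                   dimnames = list(c("asv1", "asv2", "asv3"),
                                   c("s1", "s2")))
  md <- data.frame(sample_id = c("s1", "s2"), group = c("A", "C"),
                   month = 1L, subject = c("m1", "m2"))
  feature_table(counts, md)
}
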