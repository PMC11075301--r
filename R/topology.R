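unsigned_skeleton <- function(g) {
  # structural indices ignore weights and signs
  g2 <- g
  if ("weight" %in% igraph::edge_attr_names(g2))
    g2 <- igraph::delete_edge_attr(g2, "weight")
  if ("sign" %in% igraph::edge_attr_names(g2))
    g2 <- igraph::delete_edge_attr(g2, "sign")
  igraph::simplify(g2)
}

#' Structural index panel of a network
#'
#' Computes the core topological descriptors on the unsigned skeleton:
#' number of nodes and links; average degree `avgK = 2L/n`; average
#' clustering coefficient `avgCC` (local transitivity, nodes of degree < 2
#' contribute 0); geodesic distance `GD` = mean shortest-path length over
#' reachable unordered pairs; connectedness `Con` = fraction of unordered
#' pairs that are reachable. Edge signs are used only for the
#' positive/negative link counts and their ratio (`NA` when there are no
#' negative links).
#'
#' @param men an igraph network from [build_network()] (nonempty).
#' @return named list: `nodes`, `links`, `avg_degree`, `avg_clustering`,
#'   `geodesic`, `connectedness`, `positive_links`, `negative_links`,
#'   `pn_ratio`.
#' @export
topology_indices <- function(men) {
  if (igraph::vcount(men) == 0) stop_config("empty network")
  g <- unsigned_skeleton(men)
  n <- igraph::vcount(g)
  l <- igraph::ecount(g)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.nan(cc)] <- 0
  d <- igraph::distances(g)
  dv <- d[upper.tri(d)]
  reachable <- is.finite(dv)
  signs <- if ("sign" %in% igraph::edge_attr_names(men))
    igraph::E(men)$sign else rep(1, igraph::ecount(men))
  pos <- sum(signs > 0); neg <- sum(signs < 0)
  list(nodes = n, links = l, avg_degree = 2 * l / n,
       avg_clustering = mean(cc),
       geodesic = if (any(reachable)) mean(dv[reachable]) else NA_real_,
       connectedness = mean(reachable),
       positive_links = pos, negative_links = neg,
       pn_ratio = if (neg > 0) pos / neg else NA_real_)
}

#' Scale-free fit of the degree distribution
#'
#' Ordinary least squares of `log10 P(k)` on `log10 k` over the observed
#' degrees (k >= 1). Networks with a power-law degree distribution give a
#' high R-squared and a negative slope.
#'
#' @param men an igraph network.
#' @return list with `slope` and `r_squared`; both NA (with a warning) when
#'   fewer than 3 distinct degrees are observed.
#' @export
scale_free_fit <- function(men) {
  k <- igraph::degree(unsigned_skeleton(men))
  k <- k[k >= 1]
  tab <- table(k)
  if (length(tab) < 3) {
    warning("fewer than 3 distinct degrees; scale-free fit undefined")
    return(list(slope = NA_real_, r_squared = NA_real_))
  }
  x <- log10(as.numeric(names(tab)))
  y <- log10(as.numeric(tab) / length(k))
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2]),
       r_squared = suppressWarnings(summary(fit))$r.squared)
}

#' Degree-preserving random null ensemble
#'
#' Generates `n_random` rewired copies of the network by Maslov-Sneppen
#' double-edge swaps (degree sequence preserved exactly), and summarizes
#' average clustering, geodesic distance, and fast-greedy modularity across
#' the ensemble with z-scores of the empirical values.
#'
#' @param men an igraph network with >= 2 edges.
#' @param n_random ensemble size (default 100).
#' @param n_swaps_per_edge swap attempts per edge per null (default 10).
#' @param seed integer seed.
#' @return a `null_ensemble`: `summary` data.frame (index, empirical, null
#'   mean/sd, z), plus the per-null `modularity` vector used for relative
#'   modularity.
#' @export
null_ensemble <- function(men, n_random = 100, n_swaps_per_edge = 10,
                          seed = NULL) {
  g <- unsigned_skeleton(men)
  if (igraph::ecount(g) < 2) stop_config("need >= 2 edges to rewire")
  emp <- topology_indices(men)
  emp_mod <- detect_modules(men)$modularity
  niter <- n_swaps_per_edge * igraph::ecount(g)
  stats <- with_seed(seed, {
    vapply(seq_len(n_random), function(i) {
      r <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
      ti <- topology_indices(r)
      cl <- igraph::cluster_fast_greedy(r)
      c(avg_clustering = ti$avg_clustering, geodesic = ti$geodesic,
        modularity = igraph::modularity(cl))
    }, numeric(3))
  })
  mu <- rowMeans(stats); s <- apply(stats, 1, sd)
  empv <- c(avg_clustering = emp$avg_clustering, geodesic = emp$geodesic,
            modularity = emp_mod)
  structure(list(
    summary = data.frame(index = names(mu), empirical = unname(empv[names(mu)]),
                         null_mean = unname(mu), null_sd = unname(s),
                         z = unname((empv[names(mu)] - mu) / s)),
    modularity = unname(stats["modularity", ]),
    n_random = n_random, seed = seed), class = "null_ensemble")
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("degree-preserving null ensemble (n = %d)\n", x$n_random))
  print(x$summary)
  invisible(x)
}
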