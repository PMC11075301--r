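#' Detect network modules by greedy modularity maximization
#'
#' Fast-greedy agglomerative modularity optimization on the unsigned,
#' unweighted skeleton. The algorithm is deterministic; `seed` is accepted
#' for interface symmetry with stochastic alternatives. Singleton components
#' form their own modules.
#'
#' @param men an igraph network (nonempty).
#' @param seed unused by the deterministic default algorithm.
#' @return a `module_partition`: `membership` (named integer vector),
#'   `sizes` (per-module node counts), `modularity`.
#' @export
detect_modules <- function(men, seed = NULL) {
  if (igraph::vcount(men) == 0) stop_config("empty network")
  g <- unsigned_skeleton(men)
  cl <- with_seed(seed, igraph::cluster_fast_greedy(g))
  memb <- igraph::membership(cl)
  # guard against floating-point tie artifacts in the greedy dendrogram cut:
  # never return a partition worse than one module per connected component
  comp <- igraph::components(g)$membership
  if (igraph::modularity(g, comp) > igraph::modularity(g, memb))
    memb <- comp
  structure(list(membership = setNames(as.integer(memb),
                                       igraph::V(g)$name %||% seq_along(memb)),
                 sizes = as.integer(table(as.integer(memb))),
                 modularity = igraph::modularity(g, memb)),
            class = "module_partition")
}

#' @export
print.module_partition <- function(x, ...) {
  cat(sprintf("module_partition: %d modules over %d nodes, M = %.4f\n",
              length(x$sizes), length(x$membership), x$modularity))
  invisible(x)
}

#' Relative modularity against a degree-preserving null
#'
#' `RM = (M - mean(M_null)) / mean(M_null)`, with M_null the fast-greedy
#' modularity of each rewired null graph. RM is comparable across networks of
#' different size and density, unlike raw M.
#'
#' @param men an igraph network.
#' @param partition a [detect_modules()] partition (default: computed).
#' @param null a [null_ensemble()] for `men`.
#' @return relative modularity (NA with a warning if the null mean is 0).
#' @export
relative_modularity <- function(men, partition = NULL, null) {
  partition <- partition %||% detect_modules(men)
  m_null <- mean(null$modularity)
  if (m_null == 0) {
    warning("null modularity mean is 0; relative modularity undefined")
    return(NA_real_)
  }
  (partition$modularity - m_null) / m_null
}

#' Module size summary
#'
#' Modules are small when they have fewer than `large_min` nodes and large at
#' `large_min` nodes or more (boundary at 5 by convention).
#'
#' @param partition a `module_partition`.
#' @param large_min minimum size of a large module (default 5).
#' @return list: `n_modules`, `n_small`, `n_large`, `nodes_in_large`.
#' @export
module_size_summary <- function(partition, large_min = 5) {
  sizes <- partition$sizes
  list(n_modules = length(sizes),
       n_small = sum(sizes < large_min),
       n_large = sum(sizes >= large_min),
       nodes_in_large = sum(sizes[sizes >= large_min]))
}

#' Zi-Pi node roles and keystone classification
#'
#' For each node, the within-module degree z-score
#' `Zi = (k_within - mean_within) / sd_within` (computed per module; a
#' zero-sd module gives Zi = 0) and the among-module participation
#' coefficient `Pi = 1 - sum_s (k_is / k_i)^2`. Roles: module hub
#' (`Zi > zi_cut`, `Pi <= pi_cut`), connector (`Pi > pi_cut`,
#' `Zi <= zi_cut`), network hub (both exceeded), else peripheral. Connectors,
#' module hubs and network hubs are the keystones.
#'
#' @param men an igraph network.
#' @param partition a [detect_modules()] partition covering the network.
#' @param zi_cut within-module degree cutoff (default 2.5).
#' @param pi_cut participation cutoff (default 0.62).
#' @return a `node_roles` data.frame: node, module, degree, zi, pi, role,
#'   keystone; with attribute `n_keystones`.
#' @export
zi_pi_roles <- function(men, partition, zi_cut = 2.5, pi_cut = 0.62) {
  g <- unsigned_skeleton(men)
  nodes <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  memb <- partition$membership[nodes]
  if (anyNA(memb)) stop_config("partition does not cover every network node")
  deg <- igraph::degree(g)
  if (any(deg == 0)) stop_config("isolated node in network: ",
                                 nodes[which(deg == 0)[1]])
  el <- igraph::as_edgelist(g, names = FALSE)
  mods <- sort(unique(memb))
  # k_is: links of node i into module s
  k_is <- matrix(0L, length(nodes), length(mods),
                 dimnames = list(nodes, mods))
  for (r in seq_len(nrow(el))) {
    i <- el[r, 1]; j <- el[r, 2]
    k_is[i, as.character(memb[j])] <- k_is[i, as.character(memb[j])] + 1L
    k_is[j, as.character(memb[i])] <- k_is[j, as.character(memb[i])] + 1L
  }
  k_within <- k_is[cbind(seq_along(nodes), match(memb, mods))]
  zi <- numeric(length(nodes))
  for (s in mods) {
    idx <- which(memb == s)
    mu <- mean(k_within[idx]); sdv <- sd(k_within[idx])
    zi[idx] <- if (is.na(sdv) || sdv == 0) 0 else (k_within[idx] - mu) / sdv
  }
  pi <- 1 - rowSums((k_is / deg)^2)
  role <- ifelse(zi > zi_cut & pi > pi_cut, "network_hub",
          ifelse(zi > zi_cut, "module_hub",
          ifelse(pi > pi_cut, "connector", "peripheral")))
  out <- data.frame(node = nodes, module = as.integer(memb),
                    degree = as.integer(deg), zi = zi, pi = pi, role = role,
                    keystone = role != "peripheral",
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n_keystones") <- sum(out$keystone)
  class(out) <- c("node_roles", "data.frame")
  out
}
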