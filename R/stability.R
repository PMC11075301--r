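#' Global network efficiency
#'
#' `E = (1 / (n (n - 1))) * sum_{i != j} 1 / d_ij`, with `1/Inf = 0` for
#' unreachable pairs. E = 1 for a complete graph and 0 for an edgeless one.
#'
#' @param men an igraph network with >= 2 nodes.
#' @return efficiency in \[0, 1\].
#' @export
global_efficiency <- function(men) {
  g <- unsigned_skeleton(men)
  n <- igraph::vcount(g)
  if (n < 2) stop_config("need >= 2 nodes")
  d <- igraph::distances(g)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (n * (n - 1))
}

#' Network vulnerability
#'
#' The maximum relative drop in global efficiency over all single-node
#' deletions: `V = max_i (E - E_minus_i) / E`. High vulnerability means one
#' node carries a disproportionate share of the network's shortest paths.
#'
#' @param men an igraph network with >= 3 nodes.
#' @return vulnerability (NA with a warning when E = 0).
#' @export
vulnerability <- function(men) {
  g <- unsigned_skeleton(men)
  n <- igraph::vcount(g)
  if (n < 3) stop_config("need >= 3 nodes")
  e0 <- global_efficiency(g)
  if (e0 == 0) {
    warning("zero efficiency; vulnerability undefined")
    return(NA_real_)
  }
  drops <- vapply(seq_len(n), function(i) {
    (e0 - global_efficiency(igraph::delete_vertices(g, i))) / e0
  }, numeric(1))
  max(drops)
}

#' Robustness to random or targeted node removal
#'
#' Random mode deletes `ceiling(fraction * n)` uniformly chosen nodes;
#' targeted mode deletes all module hubs (nodes whose role from
#' [zi_pi_roles()] is `module_hub` or `network_hub`). Survivors left without
#' any link are then pruned — a species with no remaining association is
#' counted as lost. Robustness is remaining nodes / original nodes; the
#' random mode is averaged over `n_reps` draws.
#'
#' @param men an igraph network.
#' @param mode "random" or "targeted".
#' @param fraction fraction of nodes removed in random mode, in (0, 1)
#'   (default 0.5).
#' @param roles a [zi_pi_roles()] table (required for targeted mode).
#' @param n_reps repetitions for random mode (default 100).
#' @param seed integer seed.
#' @param prune drop zero-link survivors (default TRUE; disable for
#'   sensitivity analysis).
#' @return list: `robustness` (mean fraction remaining), `sd` (random mode),
#'   `mode`, `n_reps`, `seed`.
#' @export
robustness <- function(men, mode = c("random", "targeted"), fraction = 0.5,
                       roles = NULL, n_reps = 100, seed = NULL,
                       prune = TRUE) {
  mode <- match.arg(mode)
  g <- unsigned_skeleton(men)
  n <- igraph::vcount(g)
  if (n == 0) stop_config("empty network")
  surviving_fraction <- function(remove_idx) {
    h <- igraph::delete_vertices(g, remove_idx)
    if (prune) h <- igraph::delete_vertices(h, which(igraph::degree(h) == 0))
    igraph::vcount(h) / n
  }
  if (mode == "random") {
    if (fraction <= 0 || fraction >= 1)
      stop_config("fraction must be in (0, 1)")
    n_remove <- ceiling(fraction * n)
    vals <- with_seed(seed, vapply(seq_len(n_reps), function(i) {
      surviving_fraction(sample(n, n_remove))
    }, numeric(1)))
    list(robustness = mean(vals), sd = sd(vals), mode = mode,
         n_reps = n_reps, seed = seed)
  } else {
    if (is.null(roles)) stop_config("targeted mode requires node roles")
    hubs <- roles$node[roles$role %in% c("module_hub", "network_hub")]
    nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
    list(robustness = surviving_fraction(which(nodes %in% hubs)),
         sd = NA_real_, mode = mode, n_reps = 1L, seed = seed)
  }
}
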