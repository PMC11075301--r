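#' Full per-network index panel
#'
#' Assembles the complete index record for one network: structural indices
#' ([topology_indices()]), modularity and relative modularity, module-size
#' summary, keystone count from Zi-Pi roles, robustness (random 50\% and
#' targeted module-hub removal), vulnerability, and the scale-free fit.
#'
#' @param men an igraph network (nonempty, with >= 2 edges for the null
#'   ensemble).
#' @param n_random null-ensemble size for relative modularity (default 50).
#' @param n_reps random-removal repetitions (default 100).
#' @param seed integer seed driving the null ensemble and removal draws.
#' @param zi_cut,pi_cut role cutoffs passed to [zi_pi_roles()].
#' @return one-row data.frame with columns nodes, links, avg_degree,
#'   avg_clustering, geodesic, connectedness, positive_links, negative_links,
#'   pn_ratio, modularity, relative_modularity, n_modules, n_small_modules,
#'   n_large_modules, nodes_in_large_modules, n_keystones, robustness_random,
#'   robustness_random_sd, robustness_targeted, vulnerability, scale_free_r2,
#'   scale_free_slope.
#' @export
network_indices <- function(men, n_random = 50, n_reps = 100, seed = NULL,
                            zi_cut = 2.5, pi_cut = 0.62) {
  ti <- topology_indices(men)
  part <- detect_modules(men)
  null <- null_ensemble(men, n_random = n_random,
                        seed = if (is.null(seed)) NULL
                               else derive_seed(seed, 1))
  rm_ <- relative_modularity(men, part, null)
  ms <- module_size_summary(part)
  roles <- zi_pi_roles(men, part, zi_cut = zi_cut, pi_cut = pi_cut)
  rob_r <- robustness(men, "random", fraction = 0.5, n_reps = n_reps,
                      seed = if (is.null(seed)) NULL
                             else derive_seed(seed, 2))
  rob_t <- robustness(men, "targeted", roles = roles)
  vul <- if (igraph::vcount(men) >= 3) vulnerability(men) else NA_real_
  sf <- suppressWarnings(scale_free_fit(men))
  data.frame(
    nodes = ti$nodes, links = ti$links, avg_degree = ti$avg_degree,
    avg_clustering = ti$avg_clustering, geodesic = ti$geodesic,
    connectedness = ti$connectedness, positive_links = ti$positive_links,
    negative_links = ti$negative_links, pn_ratio = ti$pn_ratio,
    modularity = part$modularity, relative_modularity = rm_,
    n_modules = ms$n_modules, n_small_modules = ms$n_small,
    n_large_modules = ms$n_large, nodes_in_large_modules = ms$nodes_in_large,
    n_keystones = attr(roles, "n_keystones"),
    robustness_random = rob_r$robustness,
    robustness_random_sd = rob_r$sd,
    robustness_targeted = rob_t$robustness,
    vulnerability = vul, scale_free_r2 = sf$r_squared,
    scale_free_slope = sf$slope)
}

#' Write a network as an edge-list TSV (and optionally GraphML)
#'
#' @param men an igraph network.
#' @param edge_path output TSV path (columns source, target, r, sign).
#' @param graphml_path optional GraphML output path.
#' @return invisibly, `edge_path`.
#' @export
write_network <- function(men, edge_path, graphml_path = NULL) {
  if (igraph::ecount(men) > 0) {
    el <- igraph::as_edgelist(men)
    df <- data.frame(source = el[, 1], target = el[, 2],
                     r = igraph::E(men)$weight,
                     sign = igraph::E(men)$sign)
  } else {
    df <- data.frame(source = character(), target = character(),
                     r = numeric(), sign = numeric())
  }
  write.table(df, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(graphml_path))
    igraph::write_graph(men, graphml_path, format = "graphml")
  invisible(edge_path)
}
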