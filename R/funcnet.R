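#' Build a pathway correlation network
#'
#' All-pairs Pearson correlation of pathway abundances with the usual
#' t-distributed two-sided p-value; an edge joins two pathways when
#' `|r| >= r_cut` and `p < p_cut`. Constant pathways are excluded with a
#' warning. The cutoffs are recorded as graph attributes.
#'
#' @param pathway_table pathway x sample abundance matrix (>= 2 pathways,
#'   >= 4 samples).
#' @param r_cut minimum absolute correlation (default 0.8).
#' @param p_cut maximum p-value (default 0.05).
#' @return igraph graph over all retained pathways (isolated nodes kept);
#'   edges carry `weight` (= r) and `p`.
#' @export
build_pathway_network <- function(pathway_table, r_cut = 0.8, p_cut = 0.05) {
  m <- as.matrix(pathway_table)
  if (nrow(m) < 2) stop_config("need >= 2 pathways")
  if (ncol(m) < 4) stop_config("need >= 4 samples")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    warning("excluding constant pathway(s): ",
            paste(rownames(m)[v == 0], collapse = ", "))
    m <- m[v > 0, , drop = FALSE]
  }
  n_s <- ncol(m)
  r <- cor(t(m))
  r[r > 1] <- 1; r[r < -1] <- -1
  tstat <- r * sqrt((n_s - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * pt(abs(tstat), df = n_s - 2, lower.tail = FALSE)
  keep <- abs(r) >= r_cut & p < p_cut
  diag(keep) <- FALSE
  a <- r * keep
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g, names = FALSE)
    igraph::E(g)$p <- p[cbind(el[, 1], el[, 2])]
  }
  igraph::graph_attr(g, "r_cut") <- r_cut
  igraph::graph_attr(g, "p_cut") <- p_cut
  g
}

mcode_vertex_weights <- function(g, degree_cutoff) {
  deg <- igraph::degree(g)
  vapply(seq_len(igraph::vcount(g)), function(v) {
    if (deg[v] < degree_cutoff) return(0)
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    h <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(h)
    kmax <- max(core)
    kv <- which(core == kmax)
    nk <- length(kv)
    if (nk < 2) return(0)
    hk <- igraph::induced_subgraph(h, kv)
    dens <- igraph::ecount(hk) / (nk * (nk - 1) / 2)
    kmax * dens
  }, numeric(1))
}

#' MCODE-style extraction of dense core subnetworks
#'
#' Bader-Hogue molecular-complex detection: each vertex is weighted by its
#' core-clustering coefficient (density of the highest k-core of its closed
#' neighbourhood) times that core's k. Clusters grow greedily from the
#' highest-weight unvisited seed, admitting unvisited neighbours whose weight
#' is at least `(1 - node_score_cutoff)` times the seed weight, up to
#' `max_depth` steps from the seed. Each cluster is then reduced to its
#' `k_core`-core (which subsumes the 2-core "haircut" when `k_core >= 2`),
#' scored by density x size, and ranked.
#'
#' @param net an igraph network (e.g. from [build_pathway_network()]).
#' @param degree_cutoff minimum vertex degree to seed or join (default 2).
#' @param k_core required core level of the final cluster (default 2).
#' @param node_score_cutoff admission slack relative to seed weight
#'   (default 0.2).
#' @param max_depth maximum expansion depth from the seed (default 100).
#' @param haircut remove singly-connected cluster members (default TRUE).
#' @return list of `core_cluster`s ordered by rank, each with `members`,
#'   `score`, `rank`, `size`, `density`.
#' @export
mcode_clusters <- function(net, degree_cutoff = 2, k_core = 2,
                           node_score_cutoff = 0.2, max_depth = 100,
                           haircut = TRUE) {
  g <- unsigned_skeleton(net)
  n <- igraph::vcount(g)
  if (n == 0 || igraph::ecount(g) == 0) return(list())
  nodes <- igraph::V(g)$name %||% as.character(seq_len(n))
  w <- mcode_vertex_weights(g, degree_cutoff)
  visited <- rep(FALSE, n)
  adj <- igraph::as_adj_list(g)
  clusters <- list()
  for (seed in order(w, decreasing = TRUE)) {
    if (visited[seed] || w[seed] <= 0) next
    thresh <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    visited[seed] <- TRUE
    frontier <- seed
    depth <- 0
    while (length(frontier) && depth < max_depth) {
      nxt <- unique(unlist(lapply(frontier, function(v) as.integer(adj[[v]]))))
      nxt <- nxt[!visited[nxt] & w[nxt] >= thresh]
      if (!length(nxt)) break
      visited[nxt] <- TRUE
      members <- c(members, nxt)
      frontier <- nxt
      depth <- depth + 1
    }
    if (length(members) < 2) next
    h <- igraph::induced_subgraph(g, members)
    core <- igraph::coreness(h)
    keep <- core >= k_core
    if (haircut) keep <- keep & igraph::degree(h) >= 2
    members <- members[keep]
    if (length(members) < 2) next
    h <- igraph::induced_subgraph(g, members)
    sz <- length(members)
    dens <- igraph::ecount(h) / (sz * (sz - 1) / 2)
    clusters[[length(clusters) + 1]] <-
      list(members = sort(nodes[members]), score = dens * sz,
           size = sz, density = dens)
  }
  if (!length(clusters)) return(list())
  ord <- order(vapply(clusters, `[[`, numeric(1), "score"),
               decreasing = TRUE)
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) {
    clusters[[i]]$rank <- i
    class(clusters[[i]]) <- "core_cluster"
  }
  clusters
}

#' Overlap matrix between two ranked cluster lists
#'
#' @param clusters_x,clusters_y ranked lists from [mcode_clusters()].
#' @param top_n number of top clusters from each side (default 3).
#' @return integer matrix of shared-member counts,
#'   rows = top clusters of x, columns = top clusters of y.
#' @export
cluster_overlap <- function(clusters_x, clusters_y, top_n = 3) {
  cx <- head(clusters_x, top_n)
  cy <- head(clusters_y, top_n)
  out <- matrix(0L, length(cx), length(cy),
                dimnames = list(paste0("x", seq_along(cx)),
                                paste0("y", seq_along(cy))))
  for (i in seq_along(cx)) for (j in seq_along(cy))
    out[i, j] <- length(intersect(cx[[i]]$members, cy[[j]]$members))
  out
}
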