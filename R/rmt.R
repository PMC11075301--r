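#' Pairwise Pearson correlation of log abundances
#'
#' @param log_abund numeric matrix, ASV x sample (typically from
#'   [log_transform()] after [prevalence_filter()]); needs >= 4 samples.
#' @return symmetric correlation matrix with unit diagonal; a zero-variance
#'   ASV is an error naming it (filter upstream).
#' @export
pearson_matrix <- function(log_abund) {
  m <- as.matrix(log_abund)
  if (ncol(m) < 4) stop_config("need >= 4 samples for correlation")
  v <- apply(m, 1, var)
  if (any(v == 0))
    stop_config("zero-variance ASV: ", rownames(m)[which(v == 0)[1]])
  r <- cor(t(m))
  r[r > 1] <- 1; r[r < -1] <- -1
  diag(r) <- 1
  r
}

#' Nearest-neighbour spacing distribution with a Poisson goodness-of-fit
#'
#' Implements the spectral test behind RMT thresholding. Eigenvalues are
#' de-duplicated (degenerate values removed), unfolded by a smoothing-spline
#' fit to the empirical cumulative spectral density (each eigenvalue mapped to
#' its fitted rank), and the nearest-neighbour spacings rescaled to mean 1. A
#' chi-squared goodness-of-fit against the Poisson law `P(d) = exp(-d)` uses
#' equal-probability exponential bins. Uncorrelated (Poisson) spectra conform;
#' Gaussian-orthogonal-ensemble spectra show level repulsion and are rejected.
#'
#' @param eigenvalues numeric vector of eigenvalues.
#' @param n_bins number of chi-squared bins; default `floor(sqrt(n_spacings))`.
#' @param min_eigs minimum unique eigenvalues required (default 100).
#' @param dedup_tol eigenvalues closer than this are treated as degenerate and
#'   collapsed (default 1e-8).
#' @param spline_df degrees of freedom of the unfolding spline (default 10).
#' @return list with `spacings` (mean-1), `chi_squared`, `df`, `p_value`,
#'   `n_bins`, `n_eigs` (after de-duplication).
#' @export
nnsd <- function(eigenvalues, n_bins = NULL, min_eigs = 100,
                 dedup_tol = 1e-8, spline_df = 10) {
  ev <- sort(eigenvalues)
  keep <- c(TRUE, diff(ev) > dedup_tol)
  ev <- ev[keep]
  n <- length(ev)
  if (n < min_eigs)
    stop_config("only ", n, " unique eigenvalues (need >= ", min_eigs,
                "); use a smaller threshold step or more ASVs")
  fit <- smooth.spline(ev, seq_len(n), df = min(spline_df, n - 1))
  unfolded <- sort(predict(fit, ev)$y)
  sp <- diff(unfolded)
  sp <- sp[sp > 0]
  sp <- sp / mean(sp)
  k <- n_bins %||% max(5L, floor(sqrt(length(sp))))
  gof <- function(breaks) {
    breaks[1] <- 0; breaks[k + 1] <- Inf
    obs <- table(cut(sp, breaks, include.lowest = TRUE))
    expd <- length(sp) / k
    sum((as.numeric(obs) - expd)^2 / expd)
  }
  q <- seq(0, 1, length.out = k + 1)
  chi2 <- gof(qexp(q))                       # Poisson: P(d) = exp(-d)
  chi2_wigner <- gof(sqrt(-4 / pi * log(1 - q)))  # Wigner surmise
  p <- pchisq(chi2, df = k - 1, lower.tail = FALSE)
  list(spacings = sp, chi_squared = chi2, chi_squared_wigner = chi2_wigner,
       df = k - 1, p_value = p, n_bins = k, n_eigs = n)
}

#' Scan correlation thresholds for the RMT Poisson transition
#'
#' For each candidate threshold s, entries with `|r| < s` are zeroed (unit
#' diagonal kept), the eigenvalues of the absolute thresholded matrix are
#' computed, and the spacing distribution is tested against Poisson with
#' [nnsd()]. The chosen threshold is the smallest s that conforms
#' (chi-squared p > `alpha`) and stays conforming at every larger scanned s
#' that still has enough eigenvalues — the point where the spectrum has
#' crossed from GOE-like (dense, correlated noise) to Poisson
#' (modular signal only).
#'
#' @param corr correlation matrix from [pearson_matrix()].
#' @param s_min,s_max,step scan grid (defaults 0.30, 0.99, 0.01).
#' @param alpha conformity level for the Poisson GOF (default 0.001).
#' @param min_eigs,dedup_tol,spline_df passed to [nnsd()].
#' @return a `threshold_scan`: data.frame `scan` (threshold, n_edges, n_eigs,
#'   chi_squared, p_value, conforming) plus `chosen_threshold`. If no
#'   threshold conforms an error carries the full scan in its `scan` field.
#' @export
scan_threshold <- function(corr, s_min = 0.30, s_max = 0.99, step = 0.01,
                           alpha = 0.001, min_eigs = 100, dedup_tol = 1e-8,
                           spline_df = 10) {
  stopifnot(isSymmetric(unname(corr), tol = 1e-8))
  grid <- seq(s_min, s_max, by = step)
  rows <- lapply(grid, function(s) {
    a <- corr
    a[abs(a) < s] <- 0
    diag(a) <- 1
    n_edges <- (sum(a != 0) - nrow(a)) / 2
    ev <- eigen(abs(a), symmetric = TRUE, only.values = TRUE)$values
    res <- tryCatch(
      nnsd(ev, min_eigs = min_eigs, dedup_tol = dedup_tol,
           spline_df = spline_df),
      menet_config_error = function(e) NULL)
    if (is.null(res)) {
      data.frame(threshold = s, n_edges = n_edges,
                 n_eigs = sum(c(TRUE, diff(sort(ev)) > dedup_tol)),
                 chi_squared = NA_real_, p_value = NA_real_,
                 conforming = NA, poisson_side = NA)
    } else {
      data.frame(threshold = s, n_edges = n_edges, n_eigs = res$n_eigs,
                 chi_squared = res$chi_squared, p_value = res$p_value,
                 conforming = res$p_value > alpha,
                 poisson_side = res$chi_squared < res$chi_squared_wigner)
    }
  })
  scan <- do.call(rbind, rows)
  testable <- !is.na(scan$conforming)
  chosen <- NA_real_
  # smallest conforming s; every larger testable s must at least remain on
  # the Poisson side of the two universal laws (near-empty matrices can
  # reject Poisson by level attraction without being GOE-like)
  for (i in seq_len(nrow(scan))) {
    if (!testable[i] || !scan$conforming[i]) next
    later <- testable & scan$threshold > scan$threshold[i]
    if (all(scan$poisson_side[later])) { chosen <- scan$threshold[i]; break }
  }
  if (is.na(chosen)) {
    cond <- errorCondition(
      "no threshold conforms to Poisson spacing statistics",
      scan = scan, class = c("menet_rmt_error", "error"))
    stop(cond)
  }
  structure(list(scan = scan, chosen_threshold = chosen),
            class = "threshold_scan")
}

#' @export
print.threshold_scan <- function(x, ...) {
  cat(sprintf("RMT threshold scan: %d thresholds, chosen = %.2f\n",
              nrow(x$scan), x$chosen_threshold))
  invisible(x)
}

#' Build a molecular ecological network at a correlation threshold
#'
#' Nodes are ASVs; an undirected edge joins i and j iff `|r_ij| >= threshold`.
#' Edges keep the signed correlation as their `weight` and a `sign`
#' attribute; nodes left without any edge are dropped. The threshold and any
#' provenance (group, month) are stored as graph attributes.
#'
#' @param corr correlation matrix.
#' @param threshold cutoff in (0, 1\].
#' @param provenance optional named list (e.g. `list(group = "A",
#'   month = 3)`) recorded on the graph.
#' @return an igraph graph (possibly empty, with a warning).
#' @export
build_network <- function(corr, threshold, provenance = NULL) {
  if (threshold <= 0 || threshold > 1)
    stop_config("threshold must be in (0, 1]")
  a <- corr
  diag(a) <- 0
  a[abs(a) < threshold] <- 0
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (igraph::ecount(g) == 0)
    warning("no correlations at |r| >= ", threshold, "; empty network")
  if (igraph::ecount(g) > 0)
    igraph::E(g)$sign <- sign(igraph::E(g)$weight)
  igraph::graph_attr(g, "threshold") <- threshold
  for (nm in names(provenance))
    igraph::graph_attr(g, nm) <- provenance[[nm]]
  g
}
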