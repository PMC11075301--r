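#' Configuration for the synthetic longitudinal community generator
#'
#' The generator emulates a two-arm longitudinal 16S experiment: groups A
#' (perturbed) and C (control) sampled monthly, hundreds of ASVs with
#' log-normal abundances, planted block-correlation modules, and a group-A
#' effect (reduced richness, increased dominance, weakened module
#' correlation) that decays exponentially with a configurable half-life.
#'
#' @param n_asv total number of ASVs (default 200).
#' @param n_blocks number of planted correlation blocks (default 12).
#' @param block_size ASVs per block (default 10).
#' @param rho_within exchangeable within-block latent correlation in \[0, 1)
#'   (default 0.9).
#' @param groups group labels, perturbed first (default c("A", "C")).
#' @param months sampled months (default 1:14).
#' @param samples_per_group_month subjects sampled per group and month
#'   (default 8).
#' @param depth sequencing reads per sample (default 10000).
#' @param effect_richness fraction of ASVs depleted in group A at month 1
#'   (default 0.3).
#' @param effect_dominance multiplicative abundance boost of the top taxa in
#'   group A at month 1 (default 3).
#' @param effect_network factor in \[0, 1\] scaling `rho_within` for group A at
#'   month 1 (default 0.3); 1 means no network effect.
#' @param recovery_halflife months for the group-A effect to halve
#'   (default 3).
#' @param latent_sd standard deviation of the per-ASV latent noise
#'   (default 1).
#' @param baseline_sd standard deviation of per-ASV baseline log-abundances,
#'   controlling community unevenness (default 1.5).
#' @param seed integer seed (default 1).
#' @return a `synthetic_config` list.
#' @export
synthetic_config <- function(n_asv = 200, n_blocks = 12, block_size = 10,
                             rho_within = 0.9, groups = c("A", "C"),
                             months = 1:14, samples_per_group_month = 8,
                             depth = 10000, effect_richness = 0.3,
                             effect_dominance = 3, effect_network = 0.3,
                             recovery_halflife = 3, latent_sd = 1,
                             baseline_sd = 1.5, seed = 1) {
  cfg <- list(n_asv = n_asv, n_blocks = n_blocks, block_size = block_size,
              rho_within = rho_within, groups = groups, months = months,
              samples_per_group_month = samples_per_group_month,
              depth = depth, effect_richness = effect_richness,
              effect_dominance = effect_dominance,
              effect_network = effect_network,
              recovery_halflife = recovery_halflife, latent_sd = latent_sd,
              baseline_sd = baseline_sd, seed = seed)
  if (n_blocks * block_size > n_asv)
    stop_config("n_blocks * block_size must be <= n_asv")
  if (rho_within < 0 || rho_within >= 1)
    stop_config("rho_within must be in [0, 1)")
  if (depth <= 0) stop_config("depth must be > 0")
  if (recovery_halflife <= 0) stop_config("recovery_halflife must be > 0")
  if (effect_network < 0 || effect_network > 1)
    stop_config("effect_network must be in [0, 1]")
  if (samples_per_group_month < 1) stop_config("need >= 1 sample per cell")
  class(cfg) <- "synthetic_config"
  cfg
}

#' Generate a synthetic longitudinal ASV count table
#'
#' Per-sample latent log-abundances are multivariate normal with a
#' block-diagonal exchangeable correlation structure (`rho_within` inside
#' planted blocks, 0 elsewhere), realized as
#' `z_i = mu_i + sd * (sqrt(rho) * g_block + sqrt(1 - rho) * e_i)`.
#' Counts are multinomial draws of size `depth` from the softmax of the
#' latents, i.e. a compositional log-normal community. Group-A effects at
#' month m are scaled by `w = 2^-((m - 1) / recovery_halflife)`: a fraction
#' `effect_richness` of ASVs is depleted, the top 5\% most abundant taxa are
#' boosted by `effect_dominance^w`, and within-block correlation becomes
#' `rho_within * (1 - (1 - effect_network) * w)`.
#'
#' @param config a [synthetic_config].
#' @return a list with `table` (a [feature_table]) and `truth` (a
#'   `synthetic_truth` list: `block_membership` with 0 for background ASVs,
#'   `effect_trajectory` of per-month weights, `depleted`/`dominant` ASV sets,
#'   and the per-sample latent matrix `latents`).
#' @export
generate_counts <- function(config) {
  if (!inherits(config, "synthetic_config"))
    config <- do.call(synthetic_config, config)
  cfg <- config
  with_seed(cfg$seed, {
    asv_ids <- sprintf("ASV_%04d", seq_len(cfg$n_asv))
    block <- integer(cfg$n_asv)
    in_blocks <- seq_len(cfg$n_blocks * cfg$block_size)
    block[in_blocks] <- rep(seq_len(cfg$n_blocks), each = cfg$block_size)
    mu <- rnorm(cfg$n_asv, 0, cfg$baseline_sd)
    depleted <- sample(cfg$n_asv, round(cfg$effect_richness * cfg$n_asv))
    dominant <- order(mu, decreasing = TRUE)[seq_len(max(1, ceiling(0.05 * cfg$n_asv)))]
    w_month <- 2^(-(cfg$months - 1) / cfg$recovery_halflife)

    n_cells <- length(cfg$groups) * length(cfg$months)
    n_samples <- n_cells * cfg$samples_per_group_month
    latents <- matrix(NA_real_, cfg$n_asv, n_samples)
    sample_id <- character(n_samples)
    md_group <- character(n_samples); md_month <- integer(n_samples)
    md_subject <- character(n_samples)
    col <- 0L
    for (g in cfg$groups) {
      perturbed <- g == cfg$groups[1]
      for (mi in seq_along(cfg$months)) {
        m <- cfg$months[mi]
        w <- if (perturbed) w_month[mi] else 0
        rho <- cfg$rho_within * (1 - (1 - cfg$effect_network) * w)
        for (j in seq_len(cfg$samples_per_group_month)) {
          col <- col + 1L
          gb <- rnorm(cfg$n_blocks)
          e <- rnorm(cfg$n_asv)
          shared <- ifelse(block > 0, gb[pmax(block, 1L)], 0)
          z <- mu + cfg$latent_sd *
            (sqrt(rho) * shared + sqrt(1 - ifelse(block > 0, rho, 0)) * e)
          if (w > 0) {
            z[depleted] <- z[depleted] - 6 * w
            z[dominant] <- z[dominant] + log(cfg$effect_dominance) * w
          }
          latents[, col] <- z
          sample_id[col] <- sprintf("%s_M%02d_S%d", g, m, j)
          md_group[col] <- g; md_month[col] <- m
          md_subject[col] <- sprintf("%s_subj%d", g, j)
        }
      }
    }
    counts <- vapply(seq_len(n_samples), function(i) {
      p <- exp(latents[, i] - max(latents[, i]))
      as.numeric(rmultinom(1, cfg$depth, p / sum(p)))
    }, numeric(cfg$n_asv))
    rownames(counts) <- asv_ids
    colnames(counts) <- sample_id
    rownames(latents) <- asv_ids
    colnames(latents) <- sample_id
    md <- data.frame(sample_id = sample_id, group = md_group,
                     month = md_month, subject = md_subject,
                     stringsAsFactors = FALSE)
    truth <- structure(list(
      block_membership = setNames(block, asv_ids),
      effect_trajectory = setNames(w_month, cfg$months),
      depleted = asv_ids[depleted],
      dominant = asv_ids[dominant],
      latents = latents,
      config = cfg), class = "synthetic_truth")
    list(table = feature_table(counts, md), truth = truth)
  })
}

#' Generate a synthetic pathway abundance table with one planted cluster
#'
#' Pathways are log-normal; the first `planted_clique_size` pathways share an
#' exchangeable latent correlation `rho` (the planted dense cluster), the rest
#' are independent background.
#'
#' @param n_pathways number of pathways.
#' @param n_samples number of samples (must be >= 1).
#' @param planted_clique_size size of the correlated block; must be
#'   <= `n_pathways`.
#' @param rho exchangeable correlation inside the planted block, in \[0, 1).
#' @param seed integer seed.
#' @return a list with `table` (pathway x sample abundance matrix) and
#'   `planted` (ids of the planted pathways).
#' @export
generate_pathway_table <- function(n_pathways, n_samples,
                                   planted_clique_size, rho, seed = 1) {
  if (planted_clique_size > n_pathways)
    stop_config("planted_clique_size must be <= n_pathways")
  if (n_samples < 1) stop_config("n_samples must be >= 1")
  if (rho < 0 || rho >= 1) stop_config("rho must be in [0, 1)")
  with_seed(seed, {
    ids <- sprintf("path_%03d", seq_len(n_pathways))
    planted <- seq_len(planted_clique_size)
    g <- rnorm(n_samples)
    z <- matrix(rnorm(n_pathways * n_samples), n_pathways, n_samples)
    z[planted, ] <- sqrt(rho) * rep(g, each = planted_clique_size) +
      sqrt(1 - rho) * z[planted, , drop = FALSE]
    ab <- exp(z + 3)
    rownames(ab) <- ids
    colnames(ab) <- sprintf("S%03d", seq_len(n_samples))
    list(table = ab, planted = ids[planted])
  })
}

#' Write the ground truth of a synthetic run to JSON
#'
#' @param truth a `synthetic_truth` object from [generate_counts()].
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(block_membership = as.list(truth$block_membership),
              effect_trajectory = as.list(truth$effect_trajectory),
              depleted = truth$depleted,
              dominant = truth$dominant,
              config = unclass(truth$config))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
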