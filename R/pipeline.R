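default_config <- function() {
  list(
    input = list(table = NULL, metadata = NULL, pathway_table = NULL),
    output_dir = "menet_results",
    seed = 1,
    stages = list(simulate = TRUE, filter = TRUE, diversity = TRUE,
                  network = TRUE, stability = TRUE, trends = TRUE,
                  funcnet = TRUE),
    simulate = list(),                       # synthetic_config overrides
    filter = list(min_total = 10, min_samples = 3),
    rarefy = list(enabled = FALSE, depth = 37800),
    diversity = list(n_perm = 999),
    network = list(min_fraction = 0.5, log_base = 10, pseudocount = 1,
                   threshold = 0.75,        # numeric, or "rmt" for the scan
                   rmt = list(s_min = 0.3, s_max = 0.99, step = 0.01,
                              alpha = 0.001, min_eigs = 100),
                   n_random = 30, zi_cut = 2.5, pi_cut = 0.62),
    stability = list(fraction = 0.5, n_reps = 100),
    trends = list(fc_base = 2, cor_method = "spearman", alpha = 0.05),
    funcnet = list(n_pathways = 60, planted_clique_size = 8, rho = 0.95,
                   r_cut = 0.8, p_cut = 0.05, degree_cutoff = 2,
                   k_core = 2, max_depth = 100, top_n = 3))
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' @param path YAML config path, or NULL for defaults.
#' @param overrides named list merged over the file values.
#' @return validated config list.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop_config("config file not found: ", path)
    cfg <- merge_config(cfg, yaml::read_yaml(path))
  }
  cfg <- merge_config(cfg, overrides)
  for (f in c("table", "metadata", "pathway_table")) {
    p <- cfg$input[[f]]
    if (!is.null(p) && !file.exists(p))
      stop_config("input file not found: ", p)
  }
  if (!is.null(cfg$input$table)) cfg$stages$simulate <- FALSE
  cfg
}

log_stage <- function(stage, ...) {
  message(sprintf("[menet:%s] %s", stage, paste0(...)))
}

tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the end-to-end analysis pipeline
#'
#' Stages, in the analysis order filtering -> diversity -> networks ->
#' stability -> trends -> functional networks, each writing TSV/GraphML
#' outputs under `output_dir` plus a JSON run manifest (package version,
#' config, config hash, seed). Networks are built per (group, month) cell
#' after half-prevalence filtering and log-transformation, at a fixed
#' correlation threshold or (with `network$threshold = "rmt"`) by the RMT
#' spacing-statistics scan with fallback to the fixed default when the scan
#' cannot run.
#'
#' @param config a config list from [load_config()], or a YAML path.
#' @param stages character vector of stages to run (default: those enabled in
#'   the config; `"all"` runs everything).
#' @return invisibly, the output directory.
#' @export
run_pipeline <- function(config = NULL, stages = NULL) {
  if (is.character(config)) config <- load_config(config)
  cfg <- config %||% load_config()
  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  enabled <- names(Filter(isTRUE, cfg$stages))
  if (!is.null(stages))
    enabled <- if (identical(stages, "all")) names(cfg$stages) else stages
  seed <- cfg$seed

  # --- simulate -------------------------------------------------------------
  if ("simulate" %in% enabled && is.null(cfg$input$table)) {
    log_stage("simulate", "generating synthetic community")
    sim_cfg <- do.call(synthetic_config,
                       merge_config(list(seed = derive_seed(seed, 10)),
                                    cfg$simulate))
    sim <- generate_counts(sim_cfg)
    write_feature_table(sim$table, file.path(out, "feature_table.tsv"),
                        file.path(out, "metadata.tsv"))
    write_truth_json(sim$truth, file.path(out, "truth.json"))
    cfg$input$table <- file.path(out, "feature_table.tsv")
    cfg$input$metadata <- file.path(out, "metadata.tsv")
  }
  ft <- read_feature_table(cfg$input$table, cfg$input$metadata)

  # --- filter ---------------------------------------------------------------
  if ("filter" %in% enabled) {
    log_stage("filter", "low-abundance filter")
    ft <- filter_low_abundance(ft, cfg$filter$min_total,
                               cfg$filter$min_samples)
    if (isTRUE(cfg$rarefy$enabled))
      ft <- rarefy(ft, cfg$rarefy$depth, seed = derive_seed(seed, 11))
    write_feature_table(ft, file.path(out, "filtered_table.tsv"))
  }

  md <- ft$metadata
  groups <- sort(unique(md$group))
  months <- sort(unique(md$month))

  # --- diversity ------------------------------------------------------------
  if ("diversity" %in% enabled) {
    log_stage("diversity", "alpha/beta diversity and permutation tests")
    alpha <- alpha_diversity(ft)
    tsv(merge(alpha, md, by = "sample_id"),
        file.path(out, "alpha_diversity.tsv"))
    bc <- bray_curtis_matrix(ft)
    tsv(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
        file.path(out, "bray_curtis.tsv"))
    ord <- pcoa(bc, k = 2)
    tsv(data.frame(sample_id = rownames(ord$coordinates),
                   ord$coordinates,
                   variance_explained_1 = ord$variance_explained[1],
                   variance_explained_2 = ord$variance_explained[2]),
        file.path(out, "pcoa.tsv"))
    tests <- lapply(c("anosim", "adonis", "mrpp"), function(m) {
      tr <- dissimilarity_test(bc, md$group, m, n_perm = cfg$diversity$n_perm,
                               seed = derive_seed(seed, 12))
      data.frame(method = m, statistic = tr$statistic, p = tr$p_value,
                 n_perm = tr$n_perm, seed = tr$seed)
    })
    tsv(do.call(rbind, tests), file.path(out, "dissimilarity_tests.tsv"))
  }

  # --- network (+ stability, merged into the indices panel) -----------------
  nets <- NULL
  if (any(c("network", "stability", "trends") %in% enabled)) {
    log_stage("network", "building per-(group, month) networks")
    ncfg <- cfg$network
    dir.create(file.path(out, "networks"), showWarnings = FALSE)
    rows <- list(); nets <- list()
    node_rows <- list()
    for (g in groups) for (m in months) {
      ids <- md$sample_id[md$group == g & md$month == m]
      if (length(ids) < 4) next
      sub <- prevalence_filter(subset_samples(ft, samples = ids),
                               ncfg$min_fraction)
      keep <- apply(sub$counts, 1, var) > 0
      sub$counts <- sub$counts[keep, , drop = FALSE]
      if (nrow(sub$counts) < 3) next
      la <- log_transform(sub, base = ncfg$log_base,
                          pseudocount = ncfg$pseudocount)
      corr <- pearson_matrix(la)
      thr <- ncfg$threshold
      if (identical(thr, "rmt")) {
        sc <- tryCatch(
          scan_threshold(corr, ncfg$rmt$s_min, ncfg$rmt$s_max,
                         ncfg$rmt$step, ncfg$rmt$alpha, ncfg$rmt$min_eigs),
          error = function(e) NULL)
        thr <- if (is.null(sc)) 0.75 else sc$chosen_threshold
      }
      men <- suppressWarnings(
        build_network(corr, thr, provenance = list(group = g, month = m)))
      if (igraph::ecount(men) < 2) next
      tag <- sprintf("%s_M%02d", g, m)
      write_network(men, file.path(out, "networks", paste0(tag, ".tsv")),
                    file.path(out, "networks", paste0(tag, ".graphml")))
      cell_seed <- derive_seed(seed, 100 + match(g, groups) * 50 + m)
      idx <- network_indices(men, n_random = ncfg$n_random,
                             n_reps = cfg$stability$n_reps,
                             seed = cell_seed, zi_cut = ncfg$zi_cut,
                             pi_cut = ncfg$pi_cut)
      rows[[tag]] <- cbind(data.frame(group = g, month = m,
                                      threshold = thr), idx)
      part <- detect_modules(men)
      roles <- zi_pi_roles(men, part, ncfg$zi_cut, ncfg$pi_cut)
      node_rows[[tag]] <- cbind(data.frame(group = g, month = m),
                                as.data.frame(roles))
      nets[[tag]] <- men
    }
    indices <- do.call(rbind, rows)
    rownames(indices) <- NULL
    tsv(indices, file.path(out, "network_indices.tsv"))
    tsv(do.call(rbind, node_rows), file.path(out, "node_roles.tsv"))

    if ("stability" %in% enabled) {
      stab <- indices[, c("group", "month", "robustness_random",
                          "robustness_random_sd", "robustness_targeted",
                          "vulnerability")]
      stab$n_reps <- cfg$stability$n_reps
      stab$seed <- seed
      tsv(stab, file.path(out, "stability.tsv"))
    }

    # --- trends -------------------------------------------------------------
    if ("trends" %in% enabled) {
      log_stage("trends", "time regressions, logFC, correlations")
      params <- setdiff(names(indices), c("group", "month", "threshold"))
      regs <- list()
      for (g in groups) for (p in params) {
        sub <- indices[indices$group == g, ]
        if (sum(!is.na(sub[[p]])) < 3) next
        r <- regress_vs_time(sub$month, sub[[p]])
        regs[[paste(g, p)]] <- data.frame(group = g, parameter = p,
                                          slope = r$slope,
                                          r_squared = r$r_squared,
                                          p_value = r$p_value, n = r$n)
      }
      tsv(do.call(rbind, regs), file.path(out, "regression_vs_time.tsv"))
      if (all(c("A", "C") %in% groups)) {
        fc <- lapply(params, function(p) {
          a <- setNames(indices[[p]][indices$group == "A"],
                        indices$month[indices$group == "A"])
          c_ <- setNames(indices[[p]][indices$group == "C"],
                         indices$month[indices$group == "C"])
          v <- suppressWarnings(tryCatch(log_fc(a, c_, cfg$trends$fc_base),
                                         error = function(e) NULL))
          if (is.null(v)) return(NULL)
          data.frame(parameter = p, month = as.integer(names(v)), log_fc = v)
        })
        tsv(do.call(rbind, fc), file.path(out, "log_fc.tsv"))
      }
      complexity <- c("nodes", "links", "avg_degree", "avg_clustering",
                      "modularity", "relative_modularity")
      stability_p <- c("robustness_random", "robustness_targeted",
                       "vulnerability")
      cors <- lapply(groups, function(g) {
        sub <- indices[indices$group == g, ]
        cbind(group = g,
              suppressWarnings(
                correlate_parameters(sub[complexity], sub[stability_p],
                                     method = cfg$trends$cor_method,
                                     alpha = cfg$trends$alpha)))
      })
      tsv(do.call(rbind, cors),
          file.path(out, "complexity_stability_correlations.tsv"))
    }
  }

  # --- funcnet --------------------------------------------------------------
  if ("funcnet" %in% enabled) {
    log_stage("funcnet", "pathway networks and MCODE clusters")
    fcfg <- cfg$funcnet
    clusters_by_group <- list()
    for (g in groups) {
      if (!is.null(cfg$input$pathway_table)) {
        pt <- as.matrix(read.delim(cfg$input$pathway_table, row.names = 1,
                                   check.names = FALSE))
      } else {
        ids <- md$sample_id[md$group == g]
        pt <- generate_pathway_table(
          fcfg$n_pathways, max(length(ids), 8), fcfg$planted_clique_size,
          fcfg$rho, seed = derive_seed(seed, 300 + match(g, groups)))$table
      }
      fn <- suppressWarnings(
        build_pathway_network(pt, fcfg$r_cut, fcfg$p_cut))
      write_network2 <- igraph::write_graph
      write_network2(fn, file.path(out, paste0("funcnet_", g, ".graphml")),
                     format = "graphml")
      cl <- mcode_clusters(fn, fcfg$degree_cutoff, fcfg$k_core,
                           max_depth = fcfg$max_depth)
      clusters_by_group[[g]] <- cl
      if (length(cl)) {
        df <- do.call(rbind, lapply(cl, function(x)
          data.frame(rank = x$rank, score = x$score, size = x$size,
                     members = paste(x$members, collapse = ","))))
        tsv(df, file.path(out, paste0("funcnet_clusters_", g, ".tsv")))
      }
    }
    if (length(clusters_by_group) >= 2) {
      ov <- cluster_overlap(clusters_by_group[[1]], clusters_by_group[[2]],
                            fcfg$top_n)
      tsv(data.frame(cluster = rownames(ov), ov, check.names = FALSE),
          file.path(out, "funcnet_cluster_overlap.tsv"))
    }
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "menet",
    version = as.character(utils::packageVersion("menet")),
    seed = seed,
    config = cfg,
    config_hash = digest::digest(cfg))
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out)
}

#' Command-line entry point
#'
#' Subcommands: `simulate`, `filter`, `diversity`, `network`, `stability`,
#' `trends`, `funcnet`, `all`. Flags: `--config <yaml>`, `--out <dir>`,
#' `--seed <int>`. Exit codes: 0 ok, 1 stage failure, 2 configuration error.
#'
#' @param args character vector (default: the command line).
#' @return exit status, invisibly. Called for its side effects.
#' @export
men_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0(
    "usage: menet <simulate|filter|diversity|network|stability|trends|",
    "funcnet|all> [--config FILE] [--out DIR] [--seed INT]")
  status <- tryCatch({
    if (!length(args)) stop_config(usage)
    cmd <- args[1]
    valid <- c("simulate", "filter", "diversity", "network", "stability",
               "trends", "funcnet", "all")
    if (!cmd %in% valid) stop_config("unknown subcommand '", cmd, "'\n",
                                     usage)
    opt <- list()
    i <- 2
    while (i <= length(args)) {
      key <- sub("^--", "", args[i])
      if (!key %in% c("config", "out", "seed") || i == length(args))
        stop_config("bad argument '", args[i], "'\n", usage)
      opt[[key]] <- args[i + 1]
      i <- i + 2
    }
    overrides <- list()
    if (!is.null(opt$out)) overrides$output_dir <- opt$out
    if (!is.null(opt$seed)) overrides$seed <- as.integer(opt$seed)
    cfg <- load_config(opt$config, overrides)
    stages <- if (cmd == "all") "all" else {
      # earlier stages a subcommand depends on are run implicitly
      deps <- list(simulate = "simulate",
                   filter = c("simulate", "filter"),
                   diversity = c("simulate", "filter", "diversity"),
                   network = c("simulate", "filter", "network"),
                   stability = c("simulate", "filter", "network",
                                 "stability"),
                   trends = c("simulate", "filter", "network", "trends"),
                   funcnet = c("simulate", "funcnet"))
      deps[[cmd]]
    }
    run_pipeline(cfg, stages = stages)
    0L
  },
  menet_config_error = function(e) { message("config error: ",
                                             conditionMessage(e)); 2L },
  error = function(e) { message("stage failure: ", conditionMessage(e)); 1L })
  invisible(status)
}
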