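#' Configuration for the end-to-end pipeline
#'
#' @param abundance,peaks,environment,tara Input CSV paths (see the
#'   \code{read_*} readers for their schemas).
#' @param out_dir Output directory for per-stage CSVs and the YAML report.
#' @param rho_min,alpha Edge-inference thresholds.
#' @param vif_limit VIF threshold for covariate screening.
#' @param salinity_tolerance Water-mass detection tolerance (PSU).
#' @param grouping_bounds Per-cell production bounds (fg/cell) separating
#'   low/medium/high producers; strictly increasing.
#' @param permutations ANOSIM permutation count.
#' @param reshuffles Null-network reshuffle count.
#' @param seed Master seed for every stochastic step.
#' @return A validated \code{pipeline_config} list.
#' @export
pipeline_config <- function(abundance, peaks, environment, tara,
                            out_dir = ".",
                            rho_min = 0.7, alpha = 0.05, vif_limit = 10,
                            salinity_tolerance = 0.15,
                            grouping_bounds = c(100, 300),
                            permutations = 9999L, reshuffles = 1000L,
                            seed = 1L) {
  config <- list(abundance = abundance, peaks = peaks,
                 environment = environment, tara = tara,
                 out_dir = out_dir, rho_min = rho_min, alpha = alpha,
                 vif_limit = vif_limit,
                 salinity_tolerance = salinity_tolerance,
                 grouping_bounds = grouping_bounds,
                 permutations = as.integer(permutations),
                 reshuffles = as.integer(reshuffles),
                 seed = as.integer(seed))
  if (any(c(rho_min, alpha, vif_limit, salinity_tolerance) <= 0)) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  if (length(grouping_bounds) != 2L || diff(grouping_bounds) <= 0) {
    stop("grouping_bounds must be two strictly increasing values",
         call. = FALSE)
  }
  class(config) <- "pipeline_config"
  config
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Chains every stage on the supplied input files: internal-standard
#' quantification and normalization; log-log density-dependence
#' regressions (per litre and per cell, with outlier exclusion);
#' production-class grouping with balanced ANOSIM (Bray-Curtis and
#' Jaccard), SIMPER and nMDS; the global transcript regression; and the
#' water-mass co-variation network with modules, LOFA-class edge
#' annotations and module-wise null tests. Per-stage CSVs and a YAML
#' report are written to \code{out_dir}; the same config and seed
#' reproduce the report byte for byte.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with every stage's result objects plus the
#'   \code{report} list written to YAML.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  if (!dir.exists(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE)
  }
  panel <- default_panel()

  abundance <- stage("abundance", read_abundance(config$abundance))
  peaks <- stage("peaks", read_peaks(config$peaks))
  env <- stage("environment", read_environment(config$environment))
  tara <- stage("tara", read_tara(config$tara))

  # -- quantification ------------------------------------------------------
  density <- colSums(abundance)
  profile <- stage("quantify",
                   lofa_profile(peaks, panel, diatom_density = density))
  utils::write.csv(profile, file.path(config$out_dir, "profile.csv"),
                   row.names = FALSE)

  # -- density-dependence regressions -------------------------------------
  regressions <- stage("regress", {
    # natural-log axes, the scale on which the density-law intercept is
    # defined (slopes are identical in any log base)
    logd <- log10_clean(profile$diatom_density) * log(10)
    log_ngl <- log10_clean(profile$ngL.total) * log(10)
    log_fgc <- log10_clean(profile$fgcell.total) * log(10)
    names(logd) <- profile$sample
    keep_l <- exclude_outliers(logd, log_ngl)
    keep_c <- exclude_outliers(logd, log_fgc)
    list(
      per_litre = fit_simple(logd[keep_l$keep], log_ngl[keep_l$keep],
                             excluded = keep_l$labels_dropped),
      per_cell = fit_simple(logd[keep_c$keep], log_fgc[keep_c$keep],
                            excluded = keep_c$labels_dropped))
  })

  # -- environmental covariate model --------------------------------------
  env_model <- stage("environment_model", {
    idx <- match(profile$sample, env$sample)
    covars <- env[idx, setdiff(names(env), c("sample", "week")),
                  drop = FALSE]
    covars$diatom_density <- log10_clean(profile$diatom_density)
    fit_environment(log10_clean(profile$fgcell.total), covars,
                    vif_limit = config$vif_limit)
  })

  # -- community composition across production classes --------------------
  multivar <- stage("multivar", {
    groups <- profile$production_class[match(colnames(abundance),
                                             profile$sample)]
    usable <- !is.na(groups)
    mat <- abundance[, usable, drop = FALSE]
    grp <- droplevels(groups[usable])
    sizes <- table(grp)
    grp_ok <- names(sizes)[sizes >= 2L]
    if (length(grp_ok) < 2L) {
      list(skipped = "fewer than 2 production classes with >= 2 samples")
    } else {
      sel <- grp %in% grp_ok
      mat <- mat[, sel, drop = FALSE]
      grp <- droplevels(grp[sel])
      bal <- balance_groups(mat, grp)
      bin <- (mat > 0) * 1
      bal_bin <- balance_groups(bin, grp)
      d_bray <- bray_curtis(bal$matrix)
      d_jac <- jaccard(bal_bin$matrix, binary = FALSE)
      list(
        anosim_bray = anosim_test(d_bray, bal$groups,
                                  permutations = config$permutations,
                                  seed = config$seed, pairwise = TRUE),
        anosim_jaccard = anosim_test(d_jac, bal_bin$groups,
                                     permutations = config$permutations,
                                     seed = config$seed + 1L,
                                     pairwise = TRUE),
        simper = simper_analysis(bal$matrix, bal$groups,
                                 exclude = bal$padded),
        nmds = nmds(d_bray, seed = config$seed + 2L))
    }
  })

  # -- global transcript regression ---------------------------------------
  tara_fit <- stage("tara_fit", fit_tara(tara))

  # -- co-variation network -----------------------------------------------
  network <- stage("network", {
    windows <- detect_water_masses(env,
                                   tolerance = config$salinity_tolerance)
    if (length(windows) == 0L) {
      list(skipped = "no water-mass windows detected")
    } else {
      edge_sets <- lapply(windows, function(w) {
        spearman_edges(abundance, w, rho_min = config$rho_min,
                       alpha = config$alpha)
      })
      edges <- do.call(rbind, edge_sets)
      net <- build_network(edges, taxa = rownames(abundance))
      net <- find_modules(net, seed = config$seed)
      net <- annotate_edges(net, profile, windows)
      nulls <- lapply(c("HTrA", "EPA", "DHA"), function(cl) {
        tryCatch(null_module_test(net, cl,
                                  reshuffles = config$reshuffles,
                                  seed = config$seed),
                 error = function(e) conditionMessage(e))
      })
      names(nulls) <- c("HTrA", "EPA", "DHA")
      export_network(net,
                     edge_csv = file.path(config$out_dir, "edges.csv"),
                     node_csv = file.path(config$out_dir, "nodes.csv"),
                     graphml = file.path(config$out_dir, "network.graphml"))
      list(windows = windows, network = net, null_tests = nulls)
    }
  })

  report <- list(
    seed = config$seed,
    thresholds = list(rho_min = config$rho_min, alpha = config$alpha,
                      vif_limit = config$vif_limit,
                      salinity_tolerance = config$salinity_tolerance,
                      grouping_bounds = config$grouping_bounds),
    quantification = list(
      n_samples = nrow(profile),
      total_ngL_range = range(profile$ngL.total)),
    regression = list(
      per_litre = summarize_regression(regressions$per_litre),
      per_cell = summarize_regression(regressions$per_cell)),
    environment_model = list(
      vif_dropped = env_model$vif_dropped,
      retained = setdiff(names(stats::coef(env_model$result$fit)),
                         "(Intercept)"),
      adj_r_squared = env_model$result$adj_r_squared),
    multivar = if (!is.null(multivar$skipped)) {
      list(skipped = multivar$skipped)
    } else {
      list(anosim_bray_R = multivar$anosim_bray$statistic,
           anosim_bray_p = multivar$anosim_bray$p_value,
           anosim_jaccard_R = multivar$anosim_jaccard$statistic,
           anosim_jaccard_p = multivar$anosim_jaccard$p_value,
           nmds_stress = multivar$nmds$stress)
    },
    tara = summarize_regression(tara_fit$pooled),
    network = if (!is.null(network$skipped)) {
      list(skipped = network$skipped)
    } else {
      list(n_windows = length(network$windows),
           n_nodes = nrow(network$network$nodes),
           n_connected = sum(network$network$nodes$degree > 0),
           n_edges = nrow(network$network$edges),
           n_modules = length(unique(stats::na.omit(
             network$network$nodes$module))),
           modularity = network$network$modularity)
    })
  yaml::write_yaml(report, file.path(config$out_dir, "report.yaml"))

  invisible(list(profile = profile, regressions = regressions,
                 env_model = env_model, multivar = multivar,
                 tara_fit = tara_fit, network = network,
                 report = report))
}

summarize_regression <- function(res) {
  list(slope = res$slope, intercept = res$intercept,
       adj_r_squared = res$adj_r_squared, f = res$f_statistic,
       df = res$df, p = res$p_value, n = res$n,
       excluded = res$excluded)
}
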