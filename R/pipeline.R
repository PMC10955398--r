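#' Run the full synthetic study pipeline
#'
#' Simulate a geo-phylogenetic dataset, reconstruct ancestral trait states,
#' quantify the genealogical bias of naive leaf regressions, run the
#' phylogeny-only co-evolution tests, build the node-pair table, fit the
#' diachronic causal model(s), and report Savage-Dickey Bayes factors and
#' ELPD model comparison.  Every artefact is written under `out_dir`
#' together with a run manifest (config echo, seeds, package version, file
#' digests, wall-clock per stage), so identical config + seed reproduce
#' identical outputs for the deterministic stages.
#'
#' @param config a list, or path to a YAML file.  Recognised top-level
#'   keys: `seed`, `sim` (arguments of [sim_config()]), `bias`
#'   (`n_datasets`, `alpha`), `tests` (`enabled`), `asr`
#'   (`use_reconstruction`, `bounds`), `fit` (`confounds`, `chains`,
#'   `iter`, `warmup`, `compare_no_humidity`, `geo_radius_km`,
#'   `phylo_radius`).  Unknown keys are an error.
#' @param out_dir output directory (created if needed).
#' @return a list of class `study_report` with the stage results and the
#'   manifest; also written as JSON.
#' @export
run_synthetic_study <- function(config = list(), out_dir = tempfile("study")) {
  config <- load_study_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config, package_version =
                     as.character(utils::packageVersion("geophylocausal")),
                   stages = list())
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(force(expr), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           "; completed stages: ",
           paste(names(manifest$stages), collapse = ", "), call. = FALSE))
    manifest$stages[[name]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    res
  }

  cfg <- do.call(sim_config, c(config$sim, list(seed = config$seed)))
  tree <- stage("simulate", simulate_geophylo(cfg))
  write_geophylo(tree, file.path(out_dir, "tree.nwk"),
                 file.path(out_dir, "nodes.csv"))

  rec <- stage("reconstruct", asr_brownian(
    tree, trait = "trait", root_fossil = cfg$trait$root,
    bounds = config$asr$bounds))
  utils::write.csv(rec, file.path(out_dir, "reconstruction.csv"),
                   row.names = FALSE)

  bias <- stage("bias", type1_error_study(
    tree, n_datasets = config$bias$n_datasets, alpha = config$bias$alpha,
    seed = config$seed + 100L, config = cfg))
  utils::write.csv(data.frame(slope = bias$slopes, p_value = bias$p_values),
                   file.path(out_dir, "bias_replicates.csv"),
                   row.names = FALSE)

  tests <- NULL
  if (isTRUE(config$tests$enabled)) {
    tests <- stage("tests", {
      leaves <- tree$nodes$is_leaf
      tb <- binarize(tree$nodes$trait[leaves],
                     mean(tree$nodes$trait[leaves]))
      hb <- binarize(tree$nodes$humidity[leaves],
                     mean(tree$nodes$humidity[leaves]))
      names(tb) <- names(hb) <- tree$nodes$id[leaves]
      list(discrete = pagel_discrete_test(
             tree, list(x = tb, y = hb), mode = "ml",
             n_starts = 3, seed = config$seed + 200L),
           continuous = brownian_correlation(
             tree, x = "trait", y = "humidity",
             root_fossil = list(x = cfg$trait$root)))
    })
  }

  pair <- stage("pair_table", build_node_pair_table(
    tree,
    reconstruction = if (isTRUE(config$asr$use_reconstruction)) rec else NULL,
    geo_radius_km = config$fit$geo_radius_km,
    phylo_radius = config$fit$phylo_radius,
    phylo_radius_mode = config$fit$phylo_radius_mode))
  utils::write.csv(pair, file.path(out_dir, "node_pairs.csv"),
                   row.names = FALSE)

  fits <- stage("fit", {
    out <- list(lin = fit_dcm(
      pair, variant = "lin", confounds = config$fit$confounds,
      reconstruction = rec,
      chains = config$fit$chains, iter = config$fit$iter,
      warmup = config$fit$warmup, seed = config$seed + 300L))
    if (isTRUE(config$fit$compare_no_humidity)) {
      # same model with the humidity coefficient pinned by a near-zero
      # prior would change the prior; instead drop H by zeroing the column
      pair0 <- pair; pair0$H <- 0
      out$lin_no_humidity <- fit_dcm(
        pair0, variant = "lin", confounds = config$fit$confounds,
        reconstruction = rec,
        chains = config$fit$chains, iter = config$fit$iter,
        warmup = config$fit$warmup, seed = config$seed + 301L)
    }
    out
  })

  report <- stage("report", {
    sd_eta <- savage_dickey(fits$lin, "eta")
    cmp <- if (length(fits) >= 2) elpd_compare(fits) else NULL
    list(bias_rate = bias$rate,
         bias_n_significant = sum(bias$significant),
         eta_mean = mean(fits$lin$draws[, "eta"]),
         eta_interval = unname(stats::quantile(
           fits$lin$draws[, "eta"], c(0.025, 0.975))),
         eta_bf10 = sd_eta$bf10,
         converged = all(fits$lin$diagnostics$rhat < 1.01),
         elpd = if (!is.null(cmp)) as.data.frame(cmp) else NULL,
         discrete_LR = if (!is.null(tests)) tests$discrete$LR else NULL,
         continuous_r = if (!is.null(tests)) tests$continuous$r else NULL)
  })

  manifest$files <- as.list(tools::md5sum(
    list.files(out_dir, full.names = TRUE, pattern = "\\.(csv|nwk)$")))
  out <- list(report = report, manifest = manifest,
              tree = tree, reconstruction = rec, bias = bias,
              tests = tests, pair_table = pair, fits = fits)
  jsonlite::write_json(list(report = report[setdiff(names(report), "elpd")],
                            manifest = manifest),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  class(out) <- "study_report"
  out
}

#' @export
print.study_report <- function(x, ...) {
  r <- x$report
  cat("Synthetic geo-phylo causal study\n")
  cat("  naive leaf OLS significant fraction:", format(r$bias_rate), "\n")
  cat("  diachronic model eta:", format(r$eta_mean, digits = 3),
      " 95% CI [", format(r$eta_interval[1], digits = 3), ",",
      format(r$eta_interval[2], digits = 3), "]  BF10:",
      format(r$eta_bf10, digits = 3), "\n")
  invisible(x)
}

#' Run the pipeline on a locally archived dataset
#'
#' Never downloads anything: `data_dir` must already contain
#' `tree.nwk` (Newick with labelled interior nodes), `nodes.csv` (node
#' table with `id,parent,age,lat,lon` plus trait columns, one of which is
#' the analysis trait), and `humidity_grid.csv`
#' (`year,lat,lon,humidity`) unless the node table already has a
#' `humidity` column.
#'
#' @param data_dir directory with the archived files.
#' @param config as in [run_synthetic_study()]; `sim` is ignored, `trait`
#'   (top-level) names the trait column, `root_fossil` optionally fixes
#'   the root state.
#' @param out_dir output directory.
#' @return a `study_report` list.
#' @export
run_archived_study <- function(data_dir, config = list(),
                               out_dir = tempfile("archived")) {
  config <- load_study_config(config, archived = TRUE)
  need <- c(tree = "tree.nwk", nodes = "nodes.csv")
  for (role in names(need)) {
    if (!file.exists(file.path(data_dir, need[[role]])))
      stop("archived data schema error: missing ", role, " file '",
           need[[role]], "'")
  }
  tree <- load_geophylo(file.path(data_dir, "tree.nwk"),
                        file.path(data_dir, "nodes.csv"))
  trait <- config$trait
  if (!trait %in% names(tree$nodes))
    stop("archived data schema error: node table has no trait column '",
         trait, "'")
  n_leaf_obs <- sum(!is.na(tree$nodes[[trait]][tree$nodes$is_leaf]))
  if (!"humidity" %in% names(tree$nodes)) {
    gridf <- file.path(data_dir, "humidity_grid.csv")
    if (!file.exists(gridf))
      stop("archived data schema error: missing humidity grid file ",
           "'humidity_grid.csv' (and node table has no humidity column)")
    field <- fit_humidity_field(utils::read.csv(gridf))
    tree <- gp_set_trait(tree, "humidity", humidity_at_nodes(field, tree))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  bias <- type1_error_study(tree, n_datasets = config$bias$n_datasets,
                            alpha = config$bias$alpha,
                            seed = config$seed + 100L)
  ci <- stats::binom.test(sum(bias$significant), bias$n_datasets)$conf.int
  rec <- asr_brownian(tree, trait = trait,
                      root_fossil = config$root_fossil,
                      bounds = config$asr$bounds)
  if (trait != "trait") {
    tree$nodes$trait <- tree$nodes[[trait]]
    attr(tree, "traits") <- union(attr(tree, "traits"), "trait")
  }
  lam <- pagels_lambda(tree, trait = trait)
  pair <- build_node_pair_table(tree, reconstruction = rec,
                                geo_radius_km = config$fit$geo_radius_km,
                                phylo_radius = config$fit$phylo_radius,
                                phylo_radius_mode = config$fit$phylo_radius_mode)
  fit <- fit_dcm(pair, variant = "lin", confounds = config$fit$confounds,
                 reconstruction = rec, chains = config$fit$chains,
                 iter = config$fit$iter, warmup = config$fit$warmup,
                 seed = config$seed + 300L)
  report <- list(n_leaves = sum(tree$nodes$is_leaf),
                 n_leaf_observations = n_leaf_obs,
                 bias_rate = bias$rate,
                 bias_n_significant = sum(bias$significant),
                 bias_binomial_ci = ci,
                 lambda_trait = lam$lambda_hat,
                 eta_mean = mean(fit$draws[, "eta"]),
                 eta_bf10 = savage_dickey(fit, "eta")$bf10)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  structure(list(report = report, tree = tree, bias = bias,
                 reconstruction = rec, pair_table = pair,
                 fits = list(lin = fit)),
            class = "study_report")
}

# validate and default-fill the study config; unknown keys are errors
load_study_config <- function(config, archived = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  allowed <- c("seed", "sim", "bias", "tests", "asr", "fit",
               if (archived) c("trait", "root_fossil"))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  defaults <- list(seed = 1L,
                   sim = list(),
                   bias = list(n_datasets = 100, alpha = 0.05),
                   tests = list(enabled = FALSE),
                   asr = list(use_reconstruction = TRUE, bounds = NULL),
                   fit = list(confounds = c("geo", "phylo"), chains = 2,
                              iter = 500, warmup = 500,
                              compare_no_humidity = FALSE,
                              geo_radius_km = 500, phylo_radius = 0.1,
                              phylo_radius_mode = "fraction_depth"))
  if (archived) {
    defaults$trait <- "trait"
    defaults$root_fossil <- NULL
  }
  for (k in names(defaults)) {
    if (k %in% names(config)) {
      if (is.list(defaults[[k]]) && length(defaults[[k]])) {
        sub_unknown <- setdiff(names(config[[k]]),
                               union(names(defaults[[k]]),
                                     names(formals(sim_config))))
        if (k != "sim") sub_unknown <- setdiff(names(config[[k]]),
                                               names(defaults[[k]]))
        if (length(sub_unknown))
          stop("unknown config key(s) under '", k, "': ",
               paste(sub_unknown, collapse = ", "))
        config[[k]] <- utils::modifyList(defaults[[k]], config[[k]])
      }
    } else config[[k]] <- defaults[[k]]
  }
  config$seed <- as.integer(config$seed)
  config
}
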