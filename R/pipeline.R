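# Config-driven orchestration: simulate (or load) a dataset, then run the
# requested analysis stages in dependency order, writing each stage's
# artifacts and a manifest to an output directory.

read_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config)) jsonlite::read_json(
      config, simplifyVector = TRUE) else yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  config
}

#' Validate a pipeline configuration
#'
#' Schema and cross-reference checks; returns findings rather than
#' erroring, so a driver can report all problems at once.
#'
#' @param config list, or path to a YAML/JSON file. Recognized blocks:
#'   `out_dir`, `seed`, `simulate` (scenario parameters) or `input` (paths
#'   to newick/TSV files), and per-stage blocks `tiprates`, `envbd`,
#'   `disparity`, `ou`, `dec`, `ppa` (presence of a block enables the
#'   stage).
#' @return character vector of problems (empty when valid).
#' @export
validate_config <- function(config) {
  problems <- character(0)
  config <- tryCatch(read_config(config), error = function(e) {
    return(NULL)
  })
  if (is.null(config)) return("config could not be read")
  if (is.null(config$simulate) && is.null(config$input))
    problems <- c(problems, "need either a `simulate` or an `input` block")
  if (!is.null(config$input)) {
    for (f in unlist(config$input))
      if (is.character(f) && !file.exists(f))
        problems <- c(problems, paste0("missing input file: ", f))
  }
  if (is.null(config$seed) && is.null(config$simulate$seed))
    problems <- c(problems, "a top-level `seed` is required")
  if (!is.null(config$ppa$model_set)) {
    ms <- tryCatch(load_model_set(config$ppa$model_set),
                   error = function(e) conditionMessage(e))
    if (is.character(ms))
      problems <- c(problems, paste0("model set invalid: ", ms))
  }
  problems
}

#' Load a causal-model set from a JSON file
#'
#' Format: a JSON object mapping model names to arrays of `"A->B"` edge
#' strings (an empty array is a disconnected model).
#'
#' @param path JSON file.
#' @return named list of [causal_model()]s.
#' @export
load_model_set <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  out <- lapply(names(spec), function(nm)
    causal_model(nm, as.character(unlist(spec[[nm]]))))
  stats::setNames(out, names(spec))
}

#' Run the full pipeline from a configuration
#'
#' Executes the requested stages in dependency order: dataset (simulated
#' scenario or loaded files) -> tip rates -> birth-death battery ->
#' disparity/DTT -> OU regime models -> DEC -> path analysis. Artifacts are
#' written as TSV/CSV/JSON under `out_dir` together with a manifest
#' (inputs, parameters, seeds, package version). A stage failure halts its
#' dependents but completed artifacts are kept.
#'
#' @param config see [validate_config()].
#' @return invisible list of stage results (`$manifest` holds the manifest).
#' @export
run_pipeline <- function(config) {
  config <- read_config(config)
  problems <- validate_config(config)
  if (length(problems)) stop("invalid config: ",
                             paste(problems, collapse = "; "))
  out_dir <- config$out_dir %||% tempfile("macroevo_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed)
  seeds <- spawn_seeds(seed, 8)
  results <- list()
  manifest <- list(seed = seed, stages = list(),
                   package_version = as.character(
                     utils::packageVersion("macroevopaths")))

  # --- stage: dataset ------------------------------------------------------
  if (!is.null(config$simulate)) {
    sc <- config$simulate
    sim <- simulate_rate_shift_tree(
      lambda0 = sc$lambda0 %||% 0.16, mu0 = sc$mu0 %||% 0.05,
      crown_age_ma = sc$crown_age_ma %||% 30,
      shift_age_ma = sc$shift_age_ma %||% 12,
      multiplier = sc$multiplier %||% 3,
      f = sc$f %||% 0.46, seed = seeds[1])
    tree <- sim$tree
    traits <- simulate_traits_bm(tree, sigma2 = sc$trait_sigma2 %||% 0.2,
                                 dims = sc$trait_dims %||% 3,
                                 seed = seeds[2])$traits
    results$dataset <- list(tree = tree, traits = traits,
                            truth = sim$truth)
    ape::write.tree(tree, file.path(out_dir, "tree.nwk"))
    utils::write.table(data.frame(species = rownames(traits), traits),
                       file.path(out_dir, "traits.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$stages$dataset <- list(kind = "simulated",
                                    n_tips = ape::Ntip(tree),
                                    seed = seeds[1],
                                    shift_tips = length(sim$truth$shift_tips))
  } else {
    inp <- config$input
    tree <- read_time_tree(file = inp$tree)
    traits <- NULL
    if (!is.null(inp$traits)) {
      tr <- utils::read.delim(inp$traits)
      rownames(tr) <- tr[[1]]; tr[[1]] <- NULL
      traits <- as.matrix(tr)
    }
    results$dataset <- list(tree = tree, traits = traits)
    manifest$stages$dataset <- list(kind = "loaded", n_tips = ape::Ntip(tree))
  }

  run_stage <- function(name, fun) {
    if (is.null(config[[name]])) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      manifest$stages[[name]] <<- list(status = "failed",
                                       error = conditionMessage(res))
      warning("stage '", name, "' failed: ", conditionMessage(res))
      return(invisible(NULL))
    }
    manifest$stages[[name]] <<- c(list(status = "ok"),
                                  attr(res, "manifest") %||% list())
    results[[name]] <<- res
    invisible(res)
  }

  run_stage("tiprates", function() {
    dr <- dr_statistic(tree)
    out <- data.frame(species = names(dr), DR = dr)
    if (!is.null(results$dataset$traits)) {
      rr <- ridge_rates(tree, results$dataset$traits)
      out$trait_rate <- rr$tip_rates[out$species]
    }
    utils::write.table(out, file.path(out_dir, "tiprates.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    out
  })

  run_stage("envbd", function() {
    eb <- config$envbd
    ca <- crown_age(tree)
    temp <- smooth_curve(make_paleo_curve("sinusoid",
      list(mean = 18, amplitude = 4, period = ca), span_ma = ca + 5),
      df = eb$df %||% 80)
    elev <- smooth_curve(make_paleo_curve("logistic_uplift",
      list(height = 4000, midpoint_ma = 12, scale_ma = 3), span_ma = ca + 5),
      df = eb$df %||% 80)
    bat <- battery_14(tree, temp, elev, f = eb$f %||% 0.46,
                      starts = eb$starts %||% 3, seed = seeds[3])
    utils::write.table(bat$table, file.path(out_dir, "envbd_fits.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    bat
  })

  run_stage("disparity", function() {
    if (is.null(results$dataset$traits)) stop("no traits available")
    ms <- ordinate(results$dataset$traits, "PCA")
    dp <- config$disparity
    dres <- dtt(tree, ms$scores, sims = dp$sims %||% 1000, seed = seeds[4])
    utils::write.csv(data.frame(age_ma = dres$ages, observed = dres$observed,
                                null_median = dres$null_median,
                                null_lower = dres$null_lower,
                                null_upper = dres$null_upper),
                     file.path(out_dir, "dtt.csv"), row.names = FALSE)
    jsonlite::write_json(list(mdi = dres$mdi, p = dres$p_value),
                         file.path(out_dir, "dtt.json"), auto_unbox = TRUE)
    list(morphospace = ms, dtt = dres)
  })

  run_stage("ou", function() {
    if (is.null(results$dataset$traits)) stop("no traits available")
    ms <- ordinate(results$dataset$traits, "PCA")
    y <- stats::setNames(ms$scores[, 1], rownames(ms$scores))
    shift_tips <- config$ou$shift_tips %||%
      results$dataset$truth$shift_tips
    if (is.null(shift_tips) || length(shift_tips) < 2)
      stop("no shift hypothesis available for OU stage")
    fits <- list(
      bm = fit_bm(tree, y),
      ou1 = fit_ou(tree, y, regime_painting(tree,
        rep("all", nrow(tree$edge)), "all")),
      shift = fit_ou(tree, y, paint_shift(tree, shift_tips)))
    tab <- compare_ou(fits, n = ape::Ntip(tree), edges = nrow(tree$edge))
    utils::write.table(tab, file.path(out_dir, "ou_models.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    list(fits = fits, table = tab)
  })

  run_stage("dec", function() {
    dc <- config$dec
    space <- range_state_space(dc$areas %||% c("A", "B", "C", "D"),
                               max_size = dc$max_size %||% 2)
    sim <- simulate_ranges_dec(tree, space,
                               dec_params(d = dc$d %||% 0.02,
                                          e = dc$e %||% 0.01),
                               root_range = dc$root_range %||%
                                 space$areas[1],
                               seed = seeds[5])
    fit <- fit_dec(tree, sim$tip_ranges, space, free = c("d", "e"),
                   seed = seeds[5])
    anc <- ancestral_ranges(tree, sim$tip_ranges, space, fit$params)
    utils::write.table(data.frame(node = rownames(anc), anc),
                       file.path(out_dir, "dec_ancestral.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    jsonlite::write_json(list(d = fit$params$d, e = fit$params$e,
                              logL = fit$logL),
                         file.path(out_dir, "dec_fit.json"),
                         auto_unbox = TRUE)
    list(fit = fit, ancestral = anc, sim = sim)
  })

  run_stage("ppa", function() {
    pp <- config$ppa
    models <- if (!is.null(pp$model_set)) load_model_set(pp$model_set) else
      default_model_set()
    dat <- if (!is.null(pp$simulate_chain) && isTRUE(pp$simulate_chain)) {
      make_ppa_dataset(tree, models[["m05_chain"]] %||% models[[5]],
                       coefs = c("BG->climR" = 0.8, "climR->SR" = 0.8),
                       seed = seeds[6])$data
    } else if (!is.null(results$tiprates) &&
               !is.null(results$dataset$truth$shift_tips)) {
      # biogeographic background = membership in the simulated shift clade;
      # trait-space rates from ridge regression; SR from DR
      tr <- results$tiprates
      trait_rate <- tr$trait_rate %||% tr$DR
      data.frame(row.names = tr$species,
                 BG = as.numeric(tr$species %in%
                                   results$dataset$truth$shift_tips),
                 climR = trait_rate, vegR = trait_rate, florR = trait_rate,
                 SR = tr$DR)
    } else stop("ppa stage needs tiprates on a simulated dataset, or simulate_chain")
    rk <- rank_and_average(models, dat, tree,
                           threshold = pp$threshold %||% 2)
    utils::write.table(rk$ranking, file.path(out_dir, "ppa_ranking.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(rk$averaged))
      utils::write.table(rk$averaged,
                         file.path(out_dir, "ppa_averaged.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    rk
  })

  results$manifest <- manifest
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  results$out_dir <- out_dir
  invisible(results)
}
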