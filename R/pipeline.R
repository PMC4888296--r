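#' Pipeline run configuration
#'
#' Either point the run at inputs on disk (`stops_csv`, `counts_csv`,
#' `rasters` = named list of per-year lists with `exurban`/`forest` ASCII
#' grid paths) or request the built-in synthetic scenario with
#' `preset = "study-scale"`. The global `seed` propagates to every stochastic
#' stage (simulation, MCMC, TITAN permutations and bootstrap).
#'
#' @param preset `NULL` or `"study-scale"`.
#' @param stops_csv,counts_csv,rasters input paths (ignored with a preset).
#' @param radii buffer radii in metres (default `c(400, 1000)`).
#' @param response_radius radius whose compactness drives TITAN and the GAMs
#'   (default 1000).
#' @param mspa an [mspa_config()].
#' @param titan a [titan_config()].
#' @param mcmc list: `chains`, `draws`, `warmup` (defaults 2, 2000, 1000).
#' @param out_dir output directory for report tables and provenance.
#' @param seed global seed.
#' @return object of class `run_config`.
#' @export
run_config <- function(preset = NULL, stops_csv = NULL, counts_csv = NULL,
                       rasters = NULL, radii = c(400, 1000),
                       response_radius = 1000, mspa = mspa_config(),
                       titan = titan_config(),
                       mcmc = list(chains = 2, draws = 2000, warmup = 1000),
                       out_dir = tempfile("exurbia_run_"), seed = 1) {
  if (is.null(preset)) {
    if (is.null(stops_csv) || is.null(counts_csv) || is.null(rasters))
      stop("without a preset, stops_csv, counts_csv and rasters are required")
    paths <- c(stops_csv, counts_csv,
               unlist(rasters, use.names = FALSE))
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("input file(s) not found: ", paste(missing, collapse = ", "))
  } else if (!identical(preset, "study-scale")) {
    stop("unknown preset: ", preset)
  }
  if (!response_radius %in% radii)
    stop("response_radius must be one of radii")
  mcmc <- utils::modifyList(list(chains = 2, draws = 2000, warmup = 1000),
                            mcmc)
  structure(list(preset = preset, stops_csv = stops_csv,
                 counts_csv = counts_csv, rasters = rasters, radii = radii,
                 response_radius = response_radius, mspa = mspa,
                 titan = titan, mcmc = mcmc, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, in dependency order: input simulation or loading, MSPA
#' classification, stop-level landscape metrics (composition table), MCMC
#' count adjustment per species, TITAN change-point analysis along the
#' compactness gradient, and GAM backward model selection against forest
#' loss/fragmentation predictors. Writes `table1.csv` (landscape
#' composition), `table2.csv` (TITAN results), `table3.csv` (GAM model
#' comparison), `adjusted_counts.csv`, `stop_metrics.csv`, `log.txt` and
#' `provenance.json` into `config$out_dir`. A stage failure halts the run
#' with the stage named; outputs of completed stages are retained.
#'
#' @param config a [run_config()].
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the output directory, the three report
#'   tables, adjusted counts, metrics, and per-species convergence
#'   diagnostics.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "log.txt")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   paste0(...))
    cat(msg, "\n", file = log_path, append = TRUE)
    if (!quiet) message(msg)
  }
  prov <- list(config = config[setdiff(names(config), "out_dir")],
               seed = config$seed, started = format(Sys.time()),
               stages = list())
  stage <- function(name, expr) {
    logf("stage ", name, " ...")
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    prov$stages[[name]] <<- list(seconds = round(
      proc.time()[["elapsed"]] - t0, 2))
    out
  }

  inputs <- stage("inputs", {
    if (identical(config$preset, "study-scale")) {
      b <- study_scale_scenario(seed = config$seed)
      list(stops = b$stops, counts = b$counts, rasters = b$rasters,
           truth = b$truth, metrics = b$metrics)
    } else {
      stops <- survey_stops(utils::read.csv(config$stops_csv))
      counts <- utils::read.csv(config$counts_csv)
      rasters <- lapply(config$rasters, function(r)
        list(exurban = read_ascii_grid(r$exurban),
             forest = read_ascii_grid(r$forest)))
      list(stops = stops, counts = counts, rasters = rasters, truth = NULL,
           metrics = NULL)
    }
  })

  metrics <- stage("metrics", {
    m <- if (!is.null(inputs$metrics)) inputs$metrics else
      stop_landscape_records(inputs$stops, inputs$rasters,
                             radii = config$radii, config = config$mspa)
    utils::write.csv(m, file.path(config$out_dir, "stop_metrics.csv"),
                     row.names = FALSE)
    m
  })

  table1 <- stage("table1", {
    t1 <- composition_table(metrics)
    utils::write.csv(t1, file.path(config$out_dir, "table1.csv"),
                     row.names = FALSE)
    t1
  })

  species <- sort(unique(inputs$counts$species))
  adj_list <- list()
  convergence <- list()
  stage("adjust", {
    for (sp in species) {
      spec <- build_model(inputs$counts[inputs$counts$species == sp, ])
      fit <- fit_mcmc(spec, chains = config$mcmc$chains,
                      draws = config$mcmc$draws,
                      warmup = config$mcmc$warmup,
                      seed = species_seed(config$seed, sp))
      adj <- adjusted_counts(fit, force = TRUE)
      convergence[[sp]] <- attr(adj, "max_rhat")
      adj$species <- sp
      adj_list[[sp]] <- adj
      logf("  adjusted ", sp, sprintf(" (max R-hat %.3f)",
                                      attr(adj, "max_rhat")))
    }
  })
  adjusted <- do.call(rbind, adj_list)
  rownames(adjusted) <- NULL
  utils::write.csv(adjusted,
                   file.path(config$out_dir, "adjusted_counts.csv"),
                   row.names = FALSE)

  table2 <- stage("titan", {
    m_r <- metrics[metrics$radius == config$response_radius, ]
    key_m <- paste(m_r$stop_id, m_r$year)
    cells <- unique(adjusted[, c("stop_id", "year")])
    env <- m_r$compactness[match(paste(cells$stop_id, cells$year), key_m)]
    abund <- sapply(species, function(sp) {
      a <- adjusted[adjusted$species == sp, ]
      a$adjusted[match(paste(cells$stop_id, cells$year),
                       paste(a$stop_id, a$year))]
    })
    cfg <- config$titan
    cfg$seed <- config$seed
    t2 <- run_titan(abund, env, cfg)
    utils::write.csv(t2, file.path(config$out_dir, "table2.csv"),
                     row.names = FALSE)
    t2
  })

  table3 <- stage("gam", {
    m_r <- metrics[metrics$radius == config$response_radius, ]
    rows <- list()
    for (sp in species) {
      a <- adjusted[adjusted$species == sp, ]
      d <- merge(a, m_r, by = c("stop_id", "year"))
      d$response <- d$adjusted
      terms <- c("compactness", "pct_exurban", "pct_forest",
                 "n_forest_patches", "forest_edge_m")
      sel <- tryCatch(
        backward_select(d[!is.na(d$compactness), ], terms),
        error = function(e) NULL)
      rows[[sp]] <- if (is.null(sel)) {
        data.frame(species = sp, model = "full", term = NA, edf = NA, p = NA,
                   deviance_explained = NA, gcv = NA, delta_aic = NA,
                   converged = FALSE)
      } else {
        do.call(rbind, lapply(c("full", "best"), function(which) {
          f <- sel[[which]]
          cbind(species = sp, model = which, f$terms,
                deviance_explained = f$deviance_explained, gcv = f$gcv,
                delta_aic = sel$table$delta_aic[sel$table$model == which],
                converged = f$converged)
        }))
      }
    }
    t3 <- do.call(rbind, rows)
    rownames(t3) <- NULL
    utils::write.csv(t3, file.path(config$out_dir, "table3.csv"),
                     row.names = FALSE)
    t3
  })

  prov$convergence <- convergence
  prov$finished <- format(Sys.time())
  prov$outputs <- list.files(config$out_dir)
  jsonlite::write_json(prov, file.path(config$out_dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  logf("done")
  invisible(list(out_dir = config$out_dir, table1 = table1, table2 = table2,
                 table3 = table3, adjusted = adjusted, metrics = metrics,
                 convergence = convergence, truth = inputs$truth))
}

#' Read a pipeline configuration from YAML
#'
#' The file may contain any [run_config()] argument; `mspa` and `titan`
#' sub-maps are passed to their constructors. Requires the `yaml` package.
#'
#' @param path YAML file path.
#' @return a `run_config`.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the 'yaml' package is required to read YAML configurations")
  y <- yaml::read_yaml(path)
  if (!is.null(y$mspa)) y$mspa <- do.call(mspa_config, y$mspa)
  if (!is.null(y$titan)) y$titan <- do.call(titan_config, y$titan)
  if (!is.null(y$rasters))
    y$rasters <- lapply(y$rasters, function(r) r)
  do.call(run_config, y)
}
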