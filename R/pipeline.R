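# End-to-end analysis pipeline: ingest (or simulate), cross-basis, the
# four pre-specified candidate fits, registry-clustered covariance, IRR
# surface, optional scenario, residual diagnostics, and a YAML fit bundle,
# with a plain-text log and content checksums for every table written.

#' Pipeline run configuration
#'
#' @param simulate if `TRUE`, data come from [simulate_study()] under
#'   `sim` + `seed`; otherwise `strata_file` and `panel_file` (CSV) are
#'   read.
#' @param strata_file,panel_file input CSVs (ignored when simulating).
#' @param schema optional column-mapping (list or YAML path) for
#'   [read_strata_table()].
#' @param sim a [sim_config()] or a list of overrides for one.
#' @param df_exposure,df_lag cross-basis spline df of the full model.
#' @param lag_max maximal lag (years).
#' @param lag_knot_scale lag-basis knot scale.
#' @param reference reference prevalence (%), in (0, 100).
#' @param exposure_grid,lag_grid prediction grids.
#' @param ci_level confidence level.
#' @param scenario optional list(new_prevalence=, horizon=).
#' @param n_sim residual simulation draws.
#' @param seed integer seed driving every stochastic stage.
#' @param outdir output directory.
#' @param plots write PNG figures?
#' @return list of class `"run_config"`.
#' @export
run_config <- function(simulate = TRUE, strata_file = NULL,
                       panel_file = NULL, schema = NULL, sim = list(),
                       df_exposure = 4L, df_lag = 4L, lag_max = 30L,
                       lag_knot_scale = "log-lag", reference = 50,
                       exposure_grid = 1:81, lag_grid = 0:lag_max,
                       ci_level = 0.95, scenario = NULL, n_sim = 250L,
                       seed = 1L, outdir = tempfile("smokelag_run_"),
                       plots = FALSE) {
  stopifnot(df_exposure >= 1L, df_lag >= 1L, lag_max >= 1L,
            reference > 0, reference < 100)
  structure(as.list(environment()), class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  args <- yaml::read_yaml(path)
  for (nm in c("exposure_grid", "lag_grid", "outcome_years")) {
    if (!is.null(args[[nm]])) args[[nm]] <- unlist(args[[nm]])
  }
  do.call(run_config, args)
}

file_checksum <- function(path) {
  h <- 17
  for (b in as.integer(readBin(path, "raw", file.info(path)$size))) {
    h <- (h * 31 + b) %% 2147483629
  }
  sprintf("%08x", as.integer(h))
}

#' Run the full analysis pipeline
#'
#' Stages: data (simulate or read), exposure histories, candidate model
#' set (full / no interaction / df-1 splines / both) with an AIC table,
#' registry-clustered sandwich covariance for the full model, IRR surface
#' and cumulative surface on the configured grids, optional scenario
#' table, scaled-residual diagnostics, fit bundle. Every table is written
#' as CSV under `config$outdir` and checksummed in `manifest.csv`; the run
#' is deterministic given the config (including its seed).
#'
#' @param config a [run_config()].
#' @return (invisibly) list with the in-memory artifacts: `strata`,
#'   `candidates`, `fit` (the full model), `robust`, `surface`,
#'   `residuals`, `scenario`, `aic_table`, `paths`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$outdir, "run.log")
  logf <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    cat(line, "\n", sep = "", file = log_path, append = TRUE)
    message(line)
  }
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$outdir, name)
    utils::write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
    logf("wrote %s (%d rows, checksum %s)", name, nrow(df), file_checksum(p))
    p
  }

  # ---- stage: data ----
  if (isTRUE(config$simulate)) {
    sim_args <- config$sim
    if (inherits(sim_args, "sim_config")) {
      scfg <- sim_args
    } else {
      sim_args$seed <- config$seed
      sim_args$lag_max <- config$lag_max
      sim_args$df_exposure <- config$df_exposure
      sim_args$df_lag <- config$df_lag
      sim_args$lag_knot_scale <- config$lag_knot_scale
      sim_args$reference <- config$reference
      scfg <- do.call(sim_config, sim_args)
    }
    sim <- simulate_study(scfg)
    strata <- sim$strata
    panel <- sim$panel
    logf("simulated %d strata (%d countries, seed %d)", nrow(strata),
         scfg$n_countries, scfg$seed)
    emit(as.data.frame(strata), "strata.csv")
    emit(as.data.frame(panel), "prevalence_panel.csv")
  } else {
    strata <- read_strata_table(config$strata_file, schema = config$schema)
    panel <- read_prevalence_panel(config$panel_file)
    logf("read %d strata, %d panel cells", nrow(strata), nrow(panel))
  }
  histories <- exposure_histories(panel, strata, config$lag_max)

  # ---- stage: candidate fits + AIC ----
  cand <- fit_candidate_set(strata, histories, df_full = config$df_exposure,
                            df_reduced = config$df_exposure - 1L,
                            lag_knot_scale = config$lag_knot_scale)
  emit(cand$aic_table, "aic_table.csv")
  fit <- cand$fits$full
  design <- cand$designs$full
  cb <- cand$cross_bases$full
  logf("full model: theta %.3f, AIC %.2f, converged %s", fit$theta, fit$aic,
       fit$converged)

  # ---- stage: robust covariance ----
  robust <- cluster_sandwich(fit, design)
  logf("sandwich covariance over %d registry clusters (%s)",
       robust$n_clusters, robust$correction)

  # ---- stage: prediction ----
  surface <- predict_surface(fit, cb, vcov = robust,
                             exposure_grid = config$exposure_grid,
                             lag_grid = config$lag_grid,
                             reference = config$reference,
                             level = config$ci_level)
  emit(as.data.frame(surface), "irr_surface.csv")

  scen <- NULL
  if (!is.null(config$scenario)) {
    scen <- scenario_irr_cum(fit, cb, reference = config$reference,
                             new_prevalence = config$scenario$new_prevalence,
                             horizon = config$scenario$horizon,
                             vcov = robust, level = config$ci_level)
    emit(scen, "scenario.csv")
  }

  # ---- stage: diagnostics ----
  resid <- simulate_scaled_residuals(fit, design, n_sim = config$n_sim,
                                     seed = config$seed)
  emit(residual_plot_data(resid), "residual_qq.csv")
  ks <- residual_ks_test(resid)
  logf("residual KS distance %.4f (p = %.3f)", ks$statistic, ks$p.value)

  # ---- stage: bundle + figures ----
  bundle_path <- file.path(config$outdir, "fit_bundle.yaml")
  write_fit_bundle(bundle_path, fit, cb, robust)
  paths[["fit_bundle.yaml"]] <- bundle_path
  logf("wrote fit_bundle.yaml (checksum %s)", file_checksum(bundle_path))
  if (isTRUE(config$plots)) {
    plot_paths <- write_figures(surface, resid, config$outdir)
    paths <- c(paths, plot_paths)
  }
  manifest <- data.frame(file = names(paths),
                         checksum = vapply(paths, file_checksum, ""))
  utils::write.csv(manifest, file.path(config$outdir, "manifest.csv"),
                   row.names = FALSE)
  invisible(list(strata = strata, histories = histories, candidates = cand,
                 fit = fit, design = design, cross_basis = cb,
                 robust = robust, surface = surface, residuals = resid,
                 scenario = scen, aic_table = cand$aic_table, paths = paths,
                 config = config))
}

write_figures <- function(surface, resid, outdir) {
  paths <- character(0)
  png_dev <- function(name) {
    p <- file.path(outdir, name)
    grDevices::png(p, width = 1000, height = 800, res = 120)
    paths[[name]] <<- p
    p
  }
  png_dev("surface_heatmap.png")
  graphics::image(surface$exposure_grid, surface$lag_grid, surface$log_irr,
                  col = grDevices::hcl.colors(64, "RdBu", rev = TRUE),
                  xlab = "smoking prevalence (%)", ylab = "lag (years)",
                  main = "log IRR surface")
  grDevices::dev.off()

  incr <- surface$exposure_grid[
    surface$exposure_grid %in% c(10, 30, 40, 60, 70, 80)]
  png_dev("lag_response.png")
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  for (x in incr) {
    i <- match(x, surface$exposure_grid)
    graphics::matplot(surface$lag_grid,
                      cbind(surface$irr[i, ], surface$irr_low[i, ],
                            surface$irr_high[i, ]),
                      type = "l", lty = c(1, 2, 2), col = 1,
                      xlab = "lag (years)", ylab = "IRR",
                      main = sprintf("prevalence %g%%", x))
    graphics::abline(h = 1, col = "grey")
  }
  grDevices::dev.off()

  png_dev("cumulative_response.png")
  graphics::par(mfrow = c(2, 3), mar = c(4, 4, 2, 1))
  for (x in incr) {
    i <- match(x, surface$exposure_grid)
    graphics::matplot(surface$lag_grid,
                      cbind(surface$irr_cum[i, ], surface$irr_cum_low[i, ],
                            surface$irr_cum_high[i, ]),
                      type = "l", lty = c(1, 2, 2), col = 1,
                      xlab = "lag (years)", ylab = "cumulative IRR",
                      main = sprintf("prevalence %g%%", x))
    graphics::abline(h = 1, col = "grey")
  }
  grDevices::dev.off()

  png_dev("residual_qq.png")
  qq <- residual_plot_data(resid)
  graphics::plot(qq$expected, qq$observed, pch = 20, cex = 0.4,
                 xlab = "expected uniform quantile",
                 ylab = "observed scaled residual")
  graphics::abline(0, 1, col = 2)
  grDevices::dev.off()
  paths
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write synthetic strata + panel CSVs), `fit`
#' (full pipeline), `predict` (surface from a saved fit bundle),
#' `scenario` (cumulative-IRR table from a saved bundle), `diagnose`
#' (alias of `fit` with diagnostics only in mind). A thin Rscript wrapper
#' lives in `inst/cli/smokelag`.
#'
#' @param args character vector, e.g. `commandArgs(trailingOnly = TRUE)`.
#' @return invisibly, whatever the subcommand produced.
#' @export
smokelag_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!requireNamespace("optparse", quietly = TRUE)) {
    stop("the CLI needs the optparse package", call. = FALSE)
  }
  usage <- "usage: smokelag <simulate|fit|predict|scenario|diagnose> [options]"
  if (!length(args)) stop(usage, call. = FALSE)
  cmd <- args[1]
  opts <- list(
    optparse::make_option("--config", type = "character", default = NULL,
                          help = "YAML run configuration"),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--outdir", type = "character",
                          default = "smokelag_out"),
    optparse::make_option("--bundle", type = "character", default = NULL,
                          help = "fit bundle YAML (predict/scenario)"),
    optparse::make_option("--reference", type = "double", default = 50),
    optparse::make_option("--lag-max", dest = "lag_max", type = "integer",
                          default = 30L),
    optparse::make_option("--df-exposure", dest = "df_exposure",
                          type = "integer", default = 4L),
    optparse::make_option("--df-lag", dest = "df_lag", type = "integer",
                          default = 4L),
    optparse::make_option("--ci-level", dest = "ci_level", type = "double",
                          default = 0.95),
    optparse::make_option("--new-prevalence", dest = "new_prevalence",
                          type = "double", default = 40),
    optparse::make_option("--horizon", type = "integer", default = 10L))
  parsed <- optparse::parse_args(
    optparse::OptionParser(option_list = opts), args = args[-1])
  base_cfg <- if (!is.null(parsed$config)) {
    read_run_config(parsed$config)
  } else {
    run_config()
  }
  for (nm in c("seed", "outdir", "reference", "lag_max", "df_exposure",
               "df_lag", "ci_level")) {
    base_cfg[[nm]] <- parsed[[nm]]
  }
  base_cfg$lag_grid <- 0:base_cfg$lag_max
  out <- switch(cmd,
    simulate = {
      dir.create(base_cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      sim <- simulate_study(sim_config(seed = base_cfg$seed,
                                       lag_max = base_cfg$lag_max))
      write_strata_table(sim$strata,
                         file.path(base_cfg$outdir, "strata.csv"))
      write_prevalence_panel(sim$panel,
                             file.path(base_cfg$outdir,
                                       "prevalence_panel.csv"))
      message("wrote strata.csv and prevalence_panel.csv to ",
              base_cfg$outdir)
      sim
    },
    fit = ,
    diagnose = run_pipeline(base_cfg),
    predict = {
      if (is.null(parsed$bundle)) stop("--bundle is required", call. = FALSE)
      b <- read_fit_bundle(parsed$bundle)
      surf <- predict_surface(b$fit, b$cb, vcov = b$robust,
                              reference = base_cfg$reference,
                              level = base_cfg$ci_level)
      dir.create(base_cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(as.data.frame(surf),
                       file.path(base_cfg$outdir, "irr_surface.csv"),
                       row.names = FALSE)
      surf
    },
    scenario = {
      if (is.null(parsed$bundle)) stop("--bundle is required", call. = FALSE)
      b <- read_fit_bundle(parsed$bundle)
      tab <- scenario_irr_cum(b$fit, b$cb, reference = base_cfg$reference,
                              new_prevalence = parsed$new_prevalence,
                              horizon = parsed$horizon, vcov = b$robust,
                              level = base_cfg$ci_level)
      dir.create(base_cfg$outdir, showWarnings = FALSE, recursive = TRUE)
      utils::write.csv(tab, file.path(base_cfg$outdir, "scenario.csv"),
                       row.names = FALSE)
      print(tab)
      tab
    },
    stop(usage, call. = FALSE))
  invisible(out)
}
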