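#' Run configuration
#'
#' All analyses are driven by one flat, human-readable YAML configuration
#' with optional sections \code{beam}, \code{pattern}, \code{noise},
#' \code{photons} and task-specific blocks (\code{map}, \code{efov},
#' \code{optimal_l}, \code{prior}, \code{simulation}). Lengths are in nm.
#' Missing fields take documented defaults (\code{w = 300}, \code{N = 100},
#' \code{raster_dim = 5}, \code{sbr_mode = "all_exposures"}), and every
#' output written by \code{\link{run_task}} embeds the fully resolved
#' configuration, including the SBR convention and raster dimension — the
#' two switches any reproduction must state.
#'
#' @param raw a nested list (e.g. from \code{yaml::read_yaml}) or \code{NULL}
#'   for an all-defaults configuration.
#' @return a validated \code{run_config} list.
#' @export
validate_config <- function(raw = NULL) {
  if (is.null(raw)) raw <- list()
  stopifnot(is.list(raw))
  grab <- function(block, field, default) {
    v <- raw[[block]][[field]]
    if (is.null(v)) default else v
  }
  cfg <- list(
    beam = list(
      l = as.integer(grab("beam", "l", 1L)),
      p = as.integer(grab("beam", "p", 0L)),
      w_nm = as.numeric(grab("beam", "w_nm", 300)),
      n = as.integer(grab("beam", "n", 1L))
    ),
    pattern = list(
      kind = as.character(grab("pattern", "kind", "four_point")),
      L_nm = as.numeric(grab("pattern", "L_nm", 50)),
      raster_dim = as.integer(grab("pattern", "raster_dim", 5L))
    ),
    noise = list(
      sbr = as.numeric(grab("noise", "sbr", Inf)),
      anchor_L_nm = as.numeric(grab("noise", "anchor_L_nm",
                                    grab("pattern", "L_nm", 50))),
      sbr_mode = as.character(grab("noise", "sbr_mode", "all_exposures"))
    ),
    photons = list(N = as.integer(grab("photons", "N", 100L))),
    map = list(
      roi_half_width_nm = as.numeric(grab("map", "roi_half_width_nm", 50)),
      grid_step_nm = as.numeric(grab("map", "grid_step_nm", 1))
    ),
    efov = list(
      threshold_nm = as.numeric(grab("efov", "threshold_nm", 4)),
      variant = as.character(grab("efov", "variant", "worst"))
    ),
    optimal_l = list(
      L_min_nm = as.numeric(grab("optimal_l", "L_min_nm", 10)),
      L_max_nm = as.numeric(grab("optimal_l", "L_max_nm", 100))
    ),
    prior = list(std_nm = as.numeric(grab("prior", "std_nm", 50))),
    simulation = list(
      trials = as.integer(grab("simulation", "trials", 2000L)),
      seed = as.integer(grab("simulation", "seed", 1L)),
      array_rows = as.integer(grab("simulation", "array_rows", 3L)),
      array_cols = as.integer(grab("simulation", "array_cols", 3L)),
      array_spacing_nm = as.numeric(grab("simulation", "array_spacing_nm", 5))
    )
  )
  with(cfg, {
    if (!pattern$kind %in% c("four_point", "raster"))
      stop("pattern$kind must be 'four_point' or 'raster'")
    if (!noise$sbr_mode %in% c("all_exposures", "signal_exposures"))
      stop("noise$sbr_mode must be 'all_exposures' or 'signal_exposures'")
    if (pattern$raster_dim < 2) stop("pattern$raster_dim must be >= 2")
    if (prior$std_nm <= 0) stop("prior$std_nm must be > 0")
    if (beam$w_nm <= 0) stop("beam$w_nm must be > 0")
    if (pattern$L_nm <= 0) stop("pattern$L_nm must be > 0")
    if (pattern$kind == "four_point") {
      if (abs(beam$l) < 1)
        stop("four-point MINFLUX requires a vortex beam (|l| >= 1)")
      if (pattern$L_nm^2 >= 2 * abs(beam$l) * beam$w_nm^2)
        stop("pattern$L_nm too large for this vortex order (needs L^2 < 2|l|w^2)")
    }
  })
  class(cfg) <- "run_config"
  cfg
}

#' @rdname validate_config
#' @param path path to a YAML configuration file.
#' @export
read_run_config <- function(path) {
  validate_config(yaml::read_yaml(path))
}

## Materialize the model described by a run_config.
config_model <- function(cfg) {
  beam <- vortex_beam(cfg$beam$l, cfg$beam$p, cfg$beam$w_nm, cfg$beam$n)
  pat <- if (cfg$pattern$kind == "four_point") four_point_tcp(cfg$pattern$L_nm)
         else raster_tcp(cfg$pattern$L_nm, cfg$pattern$raster_dim)
  photon_model(beam, pat, N = cfg$photons$N, sbr = cfg$noise$sbr,
               sbr_anchor_L = cfg$noise$anchor_L_nm,
               sbr_mode = cfg$noise$sbr_mode)
}

#' Run a named analysis task
#'
#' Dispatches a validated configuration to the corresponding analysis and
#' writes its outputs (\code{summary.json} always; \code{map.csv},
#' \code{curve.csv}, \code{trials.csv} as applicable) into \code{out_dir}.
#' The summary embeds the resolved configuration so a run can be reproduced
#' from its outputs alone.
#'
#' @param config a \code{run_config} (see \code{\link{validate_config}}).
#' @param task one of \code{"crb-center"}, \code{"crb-map"}, \code{"opt-L"},
#'   \code{"efov"}, \code{"bayes"}, \code{"simulate"}, \code{"sweep"}.
#' @param out_dir output directory (created if missing).
#' @param seed overrides \code{config$simulation$seed} when not \code{NULL}.
#' @return the summary list, invisibly.
#' @export
run_task <- function(config, task = c("crb-center", "crb-map", "opt-L",
                                      "efov", "bayes", "simulate", "sweep"),
                     out_dir = ".", seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  task <- match.arg(task)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  summary <- list(task = task, config = unclass(config))
  if (task %in% c("crb-center", "crb-map", "efov", "bayes", "simulate")) {
    model <- config_model(config)
  }
  if (task == "crb-center") {
    res <- crb_sigma(c(0, 0), model)
    summary$sigma_nm <- res$sigma
    if (config$pattern$kind == "four_point") {
      summary$sigma_closed_form_nm <- central_crb_closed_form(model)
    }
  } else if (task == "crb-map") {
    map <- crb_map(model, config$map$roi_half_width_nm,
                   config$map$grid_step_nm)
    map_to_csv(map, file.path(out_dir, "map.csv"))
    summary$sigma_center_nm <- crb_sigma(c(0, 0), model)$sigma
    summary$sigma_range_nm <- range(map$sigma_nm, na.rm = TRUE)
  } else if (task == "opt-L") {
    beam <- vortex_beam(config$beam$l, config$beam$p, config$beam$w_nm,
                        config$beam$n)
    res <- optimal_pattern_size(
      beam, config$pattern$kind, N = config$photons$N,
      sbr0 = config$noise$sbr, L0 = config$noise$anchor_L_nm,
      L_range = c(config$optimal_l$L_min_nm, config$optimal_l$L_max_nm),
      sbr_mode = config$noise$sbr_mode,
      raster_dim = config$pattern$raster_dim)
    utils::write.csv(res$curve, file.path(out_dir, "curve.csv"),
                     row.names = FALSE)
    summary$L_star_nm <- res$L_star
    summary$sigma_star_nm <- res$sigma_star
    summary$boundary_minimum <- res$boundary
  } else if (task == "efov") {
    summary$efov_diameter_nm <- efov_diameter(
      model, threshold = config$efov$threshold_nm,
      variant = config$efov$variant)
    summary$threshold_nm <- config$efov$threshold_nm
  } else if (task == "bayes") {
    summary$bayesian_crb_nm <- bayesian_crb(model, config$prior$std_nm)
    summary$prior_std_nm <- config$prior$std_nm
  } else if (task == "simulate") {
    sim_seed <- if (is.null(seed)) config$simulation$seed else seed
    arr <- make_grid_array(config$simulation$array_rows,
                           config$simulation$array_cols,
                           config$simulation$array_spacing_nm)
    sim <- run_experiment(arr, model, trials = config$simulation$trials,
                          master_seed = sim_seed, keep_estimates = TRUE)
    trials_to_csv(sim, file.path(out_dir, "trials.csv"))
    summary$average_error_nm <- sim$average_error
    summary$overall_rmse_nm <- sim$overall_rmse
    summary$overall_crb_nm <- sim$overall_crb
    summary$crb_ratio <- sim$crb_ratio
    summary$seed <- sim_seed
  } else if (task == "sweep") {
    rows <- list()
    for (l in 1:3) for (kind in c("four_point", "raster")) {
      cfg <- config
      cfg$beam$l <- l
      cfg$pattern$kind <- kind
      m <- config_model(cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        l = l, pattern = kind, L_nm = cfg$pattern$L_nm,
        sbr = cfg$noise$sbr, sbr_mode = cfg$noise$sbr_mode,
        raster_dim = cfg$pattern$raster_dim, N = cfg$photons$N,
        sigma_center_nm = crb_sigma(c(0, 0), m)$sigma)
    }
    sweep <- do.call(rbind, rows)
    utils::write.csv(sweep, file.path(out_dir, "curve.csv"), row.names = FALSE)
    summary$n_configurations <- nrow(sweep)
  }
  summary$elapsed_s <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  summary$r_version <- R.version.string
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(summary)
}
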