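# Orchestration: experiment drivers, synthetic fixtures and file I/O.

#' Read / write uniform time-series CSV
#'
#' Schema: columns `time_h`, `value`.
#'
#' @param path CSV path.
#' @return [read_timeseries_csv()]: a tibble `time_h`, `value`.
#' @export
read_timeseries_csv <- function(path) {
  as_timeseries(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_timeseries_csv
#' @param data Data frame with columns `time_h`, `value`.
#' @export
write_timeseries_csv <- function(data, path) {
  readr::write_csv(as_timeseries(data), path)
  invisible(path)
}

#' Experiment specification
#'
#' @param name Driver name: one of `"surrogate-compare"`,
#'   `"phase-jetlag-fit"`, `"dde-pulse-sweep"`, `"prc-sweep"`.
#' @param params Driver-specific parameter list (see [run_experiment()]).
#' @param out_dir Output directory (created if missing); `NULL` returns
#'   results without writing files.
#' @param seed Integer master seed, recorded in every output.
#' @return An `experiment_spec` list.
#' @export
experiment_spec <- function(name, params = list(), out_dir = NULL,
                            seed = 1L) {
  missing <- c()
  if (!is.character(name) || length(name) != 1) missing <- c(missing, "name")
  if (!is.list(params)) missing <- c(missing, "params")
  if (length(missing)) {
    abort(paste0("Invalid experiment spec; bad or missing fields: ",
                 paste(missing, collapse = ", ")))
  }
  structure(list(name = name, params = params, out_dir = out_dir,
                 seed = as.integer(seed)),
            class = "experiment_spec")
}

#' Run a named experiment driver
#'
#' Drivers:
#' * `"surrogate-compare"`: generates one surrogate movie per hypothesis at
#'   the same seed, computes pixel-wise period maps for both channels and
#'   the bivariate cluster count per hypothesis. Params: any
#'   [surrogate_config()] argument, plus `analysis` ([analysis_config()]).
#' * `"phase-jetlag-fit"`: [rss_fitness()] of the phase model against a
#'   reference shift table. Params: `reference` (data frame or CSV path),
#'   `k_values`, `z_values`, plus optional [rss_fitness()] arguments.
#' * `"dde-pulse-sweep"`: [simulate_light_pulse()] across `c_r_values`.
#' * `"prc-sweep"`: [phase_response_curve()] across `c_r_values` (variable
#'   `"P"`) or `b_p_values` (variable `"R"`).
#'
#' @param spec An [experiment_spec()].
#' @return Driver-specific result list, invisibly when files are written.
#'   Every result carries the resolved spec (with seed) under `$spec`.
#' @export
run_experiment <- function(spec) {
  stopifnot(inherits(spec, "experiment_spec"))
  result <- switch(
    spec$name,
    "surrogate-compare" = driver_surrogate_compare(spec),
    "phase-jetlag-fit" = driver_phase_jetlag_fit(spec),
    "dde-pulse-sweep" = driver_dde_pulse_sweep(spec),
    "prc-sweep" = driver_prc_sweep(spec),
    abort(sprintf("Unknown experiment driver `%s`.", spec$name))
  )
  result$spec <- list(name = spec$name, seed = spec$seed,
                      params = spec$params)
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, recursive = TRUE, showWarnings = FALSE)
    payload <- result
    payload$spec$params <- purrr::map(payload$spec$params, function(x) {
      if (is.data.frame(x) || inherits(x, "analysis_config")) NULL else x
    })
    jsonlite::write_json(
      purrr::keep(payload, ~ !is.data.frame(.x) || nrow(.x) <= 10000),
      file.path(spec$out_dir, paste0(spec$name, ".json")),
      auto_unbox = TRUE, digits = NA, dataframe = "columns", null = "null"
    )
    invisible(result)
  } else {
    result
  }
}

driver_surrogate_compare <- function(spec) {
  p <- spec$params
  analysis <- p$analysis %||% analysis_config()
  p$analysis <- NULL
  counts <- purrr::map(c(H0_1 = "H0_1", H0_2 = "H0_2"), function(h) {
    cfg <- do.call(surrogate_config,
                   modifyList(list(hypothesis = h, seed = spec$seed), p))
    sur <- generate_surrogate(cfg)
    map_b <- pixelwise_period_map(sur$bmal, analysis)
    map_p <- pixelwise_period_map(sur$per, analysis)
    as.integer(count_bivariate_clusters(map_b$period_h, map_p$period_h,
                                        analysis))
  })
  list(cluster_count_h01 = counts$H0_1, cluster_count_h02 = counts$H0_2)
}

driver_phase_jetlag_fit <- function(spec) {
  p <- spec$params
  ref <- p$reference
  if (is.character(ref)) ref <- readr::read_csv(ref, show_col_types = FALSE)
  args <- p[setdiff(names(p), "reference")]
  fit <- do.call(rss_fitness, c(list(reference = ref), args))
  list(landscape = fit, best = attr(fit, "best"))
}

driver_dde_pulse_sweep <- function(spec) {
  p <- spec$params
  c_r_values <- p$c_r_values %||% c(17.5, 35, 70)
  runs <- purrr::map(c_r_values, function(cr) {
    pars <- do.call(three_gene_params,
                    modifyList(list(c_r = cr),
                               p[setdiff(names(p), "c_r_values")]))
    simulate_light_pulse(pars)$shifts
  })
  list(c_r = c_r_values, shifts = runs)
}

driver_prc_sweep <- function(spec) {
  p <- spec$params
  c_r_values <- p$c_r_values %||% c(17.5, 35, 70)
  z <- p$z %||% 0.43
  n_phases <- p$n_phases %||% 8
  prcs <- purrr::map(c_r_values, function(cr) {
    phase_response_curve(three_gene_params(c_r = cr), variable = "P",
                         z = z, n_phases = n_phases)
  })
  list(c_r = c_r_values, prc = prcs)
}

#' Deterministic synthetic fixtures
#'
#' * `"jetlag_reference"`: per-loop jet-lag shift curves generated from the
#'   phase model at documented truth parameters (default `K = 0.05`,
#'   `z = 0.05`), sampled at days -1, 2, 3, 4 and 12 after a 6 h advance —
#'   a synthetic stand-in, in the same schema, for digitised experimental
#'   re-entrainment curves.
#' * `"toy_timeseries"`: a 12-day, 1-h-sampled cosine (truth period 23 h,
#'   amplitude 1) plus N(0, 0.25) noise.
#' * `"toy_movie"`: a small (32x32, 4 cells, 6-day) surrogate movie config
#'   and its rendered cell field summary.
#'
#' @param kind Fixture kind.
#' @param seed Integer seed (fixtures are deterministic given the seed).
#' @param dir Output directory; `NULL` returns the data without writing.
#' @param truth Optional named list overriding fixture truth parameters
#'   (`k`, `z`, `beta`, `delta_star`, `tau_star`, `jetlag_shift` for the
#'   jet-lag reference).
#' @return The fixture tibble (jetlag_reference, toy_timeseries) or config
#'   list (toy_movie); written as CSV/YAML when `dir` is given.
#' @export
make_fixture <- function(kind = c("jetlag_reference", "toy_movie",
                                  "toy_timeseries"),
                         seed = 1L, dir = NULL, truth = list()) {
  kind <- match.arg(kind)
  out <- switch(kind,
    jetlag_reference = {
      tr <- modifyList(list(k = 0.05, z = 0.05, beta = 0.7 * pi,
                            delta_star = -0.7 * pi, tau_star = 24.53,
                            jetlag_shift = 6, days = c(-1, 2, 3, 4, 12)),
                       truth)
      iso <- isocline(tr$delta_star, tr$beta, tr$tau_star, tr$k)
      pars <- phase_params(tau_p = iso$tau_p, tau_r = iso$tau_r, k = tr$k,
                           beta = tr$beta)
      prot <- zeitgeber("jetlag", z = tr$z, T = 24, jetlag_day = 25,
                        jetlag_shift = tr$jetlag_shift)
      sim <- simulate_jetlag(pars, prot, n_post = max(tr$days) + 3)
      tibble(
        day = tr$days,
        shift_per_h = approx(sim$day, sim$shift_per_h, xout = tr$days,
                             rule = 2)$y,
        shift_bmal_h = approx(sim$day, sim$shift_bmal_h, xout = tr$days,
                              rule = 2)$y
      )
    },
    toy_timeseries = {
      set.seed(child_seed(seed, "toy_timeseries"))
      t <- seq(0, 12 * 24, by = 1)
      tibble(time_h = t,
             value = cos(2 * pi * t / 23) + rnorm(length(t), 0, 0.5))
    },
    toy_movie = {
      surrogate_config(n_cells = 4, hypothesis = "H0_1", sigma_n = 0.2,
                       duration = 6, grid_shape = c(32L, 32L), seed = seed)
    }
  )
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    path <- file.path(dir, paste0(kind, ".csv"))
    if (kind == "toy_movie") {
      yaml::write_yaml(unclass(out), file.path(dir, "toy_movie.yml"))
    } else {
      readr::write_csv(out, path)
    }
  }
  out
}
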