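#' Experiment configuration
#'
#' A named, validated bundle of protocol, source geometry, bundle layout and
#' solver settings that round-trips losslessly through YAML.
#'
#' @param name Configuration name.
#' @param frequency_hz,amplitude_ma,width_ms,duration_s Pulse protocol.
#' @param source_height_um Distance from the point source to the (nearest)
#'   axon's central node.
#' @param sigma_S_m Extracellular conductivity.
#' @param n_axons,spacing_um Bundle layout (n_axons = 1 for a single axon).
#' @param fixed_ko Clamp peri-axonal [K+]o at 3 mM (control runs).
#' @param dt_ms Solver step.
#' @param morphology_overrides,channel_set_name Optional model variations.
#' @return Object of class \code{experiment_config}.
#' @export
experiment_config <- function(name, frequency_hz, amplitude_ma,
                              width_ms = 0.1, duration_s = 2,
                              source_height_um = 50, sigma_S_m = 0.286,
                              n_axons = 1, spacing_um = 10,
                              fixed_ko = FALSE, dt_ms = 0.005,
                              morphology_overrides = list(),
                              channel_set_name = "pyramidal_default") {
  cfg <- list(name = name, frequency_hz = frequency_hz,
              amplitude_ma = amplitude_ma, width_ms = width_ms,
              duration_s = duration_s, source_height_um = source_height_um,
              sigma_S_m = sigma_S_m, n_axons = n_axons,
              spacing_um = spacing_um, fixed_ko = fixed_ko, dt_ms = dt_ms,
              morphology_overrides = morphology_overrides,
              channel_set_name = channel_set_name)
  validate_config(cfg)
  class(cfg) <- "experiment_config"
  cfg
}

validate_config <- function(cfg) {
  # constructors of the component objects carry the real validation
  invisible(pulse_protocol(cfg$frequency_hz, cfg$amplitude_ma,
                           cfg$width_ms, cfg$duration_s))
  invisible(point_source(cfg$source_height_um, sigma_S_m = cfg$sigma_S_m))
  if (cfg$n_axons < 1 || cfg$spacing_um <= 0)
    stop("invalid bundle layout in config '", cfg$name, "'")
  invisible(cfg)
}

#' Write / read an experiment configuration (YAML)
#' @param cfg An \code{experiment_config}.
#' @param path File path.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(experiment_config, raw)
}

#' Packaged experiment configurations
#'
#' Named configurations reproducing the study's figures:
#' \describe{
#'   \item{fig2_single_axon}{130 Hz, -0.2 mA, source 50 um above the central
#'     node; peri-axonal K+ accumulation on; 2.5 s.}
#'   \item{fig3_fixed_ko}{Same stimulation with [K+]o clamped at 3 mM.}
#'   \item{fig4_bundle}{11-axon bundle, 10 um spacing, source 20 um above the
#'     nearest axon, 130 Hz, -0.2 mA (also yields the fig. 5
#'     synchronization series).}
#'   \item{fig6a_freq_<f>}{Bundle at 50/130/200 Hz, -0.3 mA.}
#'   \item{fig6b_amp_<a>}{Bundle at 130 Hz, -0.1/-0.3/-0.5 mA.}
#' }
#'
#' @param name Configuration name; NULL lists all names.
#' @return An \code{experiment_config}, or a character vector of names.
#' @export
packaged_config <- function(name = NULL) {
  mk <- function(...) experiment_config(...)
  reg <- list(
    fig2_single_axon = function() mk("fig2_single_axon", 130, -0.2,
                                     duration_s = 2.5,
                                     source_height_um = 50),
    fig3_fixed_ko = function() mk("fig3_fixed_ko", 130, -0.2,
                                  duration_s = 2, source_height_um = 50,
                                  fixed_ko = TRUE),
    fig4_bundle = function() mk("fig4_bundle", 130, -0.2, duration_s = 2,
                                source_height_um = 20, n_axons = 11),
    fig6a_freq_50 = function() mk("fig6a_freq_50", 50, -0.3,
                                  duration_s = 2, source_height_um = 20,
                                  n_axons = 11),
    fig6a_freq_130 = function() mk("fig6a_freq_130", 130, -0.3,
                                   duration_s = 2, source_height_um = 20,
                                   n_axons = 11),
    fig6a_freq_200 = function() mk("fig6a_freq_200", 200, -0.3,
                                   duration_s = 2, source_height_um = 20,
                                   n_axons = 11),
    fig6b_amp_0.1 = function() mk("fig6b_amp_0.1", 130, -0.1,
                                  duration_s = 2, source_height_um = 20,
                                  n_axons = 11),
    fig6b_amp_0.3 = function() mk("fig6b_amp_0.3", 130, -0.3,
                                  duration_s = 2, source_height_um = 20,
                                  n_axons = 11),
    fig6b_amp_0.5 = function() mk("fig6b_amp_0.5", 130, -0.5,
                                  duration_s = 2, source_height_um = 20,
                                  n_axons = 11)
  )
  if (is.null(name)) return(names(reg))
  if (!name %in% names(reg)) stop("unknown packaged config: ", name)
  reg[[name]]()
}

#' Run an experiment configuration end to end
#'
#' Simulates the configured axon or bundle, computes spike trains,
#' effectiveness flags, induction-ratio series (and, for bundles, the
#' synchronization-ratio series), and a steady-state summary.
#'
#' @param cfg An \code{experiment_config} or a packaged config name.
#' @param ci_mode If TRUE the duration is cut to 0.5 s (fast end-to-end
#'   checks; the steady-state window then covers the last 0.2 s).
#' @param steady_window_ms Steady-state averaging window; default from 1.5 s
#'   to the end of stimulation.
#' @param out_dir Optional directory: traces and metrics are written as tidy
#'   CSV and the summary as JSON.
#' @return List with \code{config}, \code{traces} (list of trace_set),
#'   \code{metrics} (per-axon), \code{sync} (bundle only), \code{summary}.
#' @export
run_experiment <- function(cfg, ci_mode = FALSE, steady_window_ms = NULL,
                           out_dir = NULL) {
  if (is.character(cfg)) cfg <- packaged_config(cfg)
  validate_config(cfg)
  if (ci_mode) cfg$duration_s <- min(cfg$duration_s, 0.5)
  proto <- pulse_protocol(cfg$frequency_hz, cfg$amplitude_ma, cfg$width_ms,
                          cfg$duration_s)
  solver <- solver_config(dt_ms = cfg$dt_ms, fixed_ko = cfg$fixed_ko)
  morph <- build_axon(cfg$morphology_overrides)
  cs <- channel_set(cfg$channel_set_name)
  end_ms <- proto$onset_ms + cfg$duration_s * 1000
  if (is.null(steady_window_ms))
    steady_window_ms <- if (ci_mode) c(end_ms - 200, end_ms) else
      c(1500, end_ms)

  if (cfg$n_axons == 1) {
    src <- point_source(cfg$source_height_um, sigma_S_m = cfg$sigma_S_m)
    traces <- list(simulate_axon(proto, src, morph, cs = cs,
                                 solver = solver))
  } else {
    traces <- simulate_bundle(proto, n_axons = cfg$n_axons,
                              spacing_um = cfg$spacing_um,
                              source_height_um = cfg$source_height_um,
                              sigma_S_m = cfg$sigma_S_m, morph = morph,
                              cs = cs, solver = solver)
  }
  metrics <- lapply(traces, axon_metrics)
  distances <- cfg$source_height_um + cfg$spacing_um *
    (seq_len(cfg$n_axons) - 1)

  summary <- list(
    name = cfg$name,
    steady_window_ms = steady_window_ms,
    distances_um = distances,
    induction_ratio_steady = vapply(metrics, function(m)
      tryCatch(steady_state_value(m$induction, steady_window_ms),
               error = function(e) NA_real_), numeric(1))
  )
  sync <- NULL
  if (cfg$n_axons > 1) {
    flags <- lapply(metrics, `[[`, "effective")
    sync <- synchronization_ratio(flags, traces[[1]]$pulse_times_ms)
    summary$synchronization_steady <-
      steady_state_value(sync, steady_window_ms, column = "smoothed")
  }
  res <- list(config = cfg, traces = traces, metrics = metrics,
              sync = sync, summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (k in seq_along(traces))
      traces_as_df(traces[[k]],
                   file.path(out_dir, sprintf("traces_axon%02d.csv", k)))
    if (!is.null(sync))
      utils::write.csv(sync, file.path(out_dir, "sync_ratio.csv"),
                       row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Synthetic fixtures for metric-level tests
#'
#' Deterministic fixtures with known ground-truth metrics so the metrics
#' module can be tested without any simulation.
#'
#' @param kind One of \code{"periodic_flags"} (effective every k-th pulse),
#'   \code{"checkerboard_flags"} (axons alternate all-on / all-off pulses),
#'   \code{"two_spike_trace"} (a Vm trace with two clean action potentials),
#'   \code{"artifact_trace"} (sub-threshold stimulus artifacts only).
#' @param n_pulses,period,n_axons,dt_ms Shape parameters.
#' @return A list whose elements depend on \code{kind}; always includes the
#'   ground truth under \code{truth}.
#' @export
make_fixtures <- function(kind = c("periodic_flags", "checkerboard_flags",
                                   "two_spike_trace", "artifact_trace"),
                          n_pulses = 40, period = 4, n_axons = 11,
                          dt_ms = 0.025) {
  kind <- match.arg(kind)
  switch(kind,
    periodic_flags = {
      flags <- seq_len(n_pulses) %% period == 1
      list(flags = flags, pulse_times_ms = seq_len(n_pulses) * 10,
           truth = list(induction_ratio = 100 / period))
    },
    checkerboard_flags = {
      on <- seq_len(n_pulses) %% 2 == 1
      flags <- matrix(rep(on, n_axons), ncol = n_axons)
      list(flags = flags, pulse_times_ms = seq_len(n_pulses) * 10,
           truth = list(raw = ifelse(on, 100, 0), smoothed = 50))
    },
    two_spike_trace = {
      t <- seq(0, 30, by = dt_ms)
      vm <- rep(-66, length(t))
      spike <- function(t0) 106 * exp(-((t - t0) / 0.4)^2)
      vm <- vm + spike(10) + spike(20)
      list(time = t, vm = vm, truth = list(n_spikes = 2,
                                           spike_times = c(10, 20)))
    },
    artifact_trace = {
      t <- seq(0, 30, by = dt_ms)
      vm <- rep(-66, length(t)) - 30 * (t %% 7.7 < 0.1)
      list(time = t, vm = vm, truth = list(n_spikes = 0))
    })
}
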