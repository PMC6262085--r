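#' Detect spikes by threshold crossing
#'
#' Upward crossings of the threshold separated by at least the refractory
#' window; the spike time is the crossing time by linear interpolation.
#' Overshooting action potentials make detection insensitive to the exact
#' threshold over roughly [-20, +10] mV.
#'
#' @param time Time stamps (ms), increasing.
#' @param vm Membrane potential trace (mV).
#' @param threshold_mV Detection threshold (default 0 mV).
#' @param refractory_ms Minimum inter-spike interval (default 1 ms).
#' @return Object of class \code{spike_train}: list with \code{times_ms},
#'   \code{threshold_mV}, \code{refractory_ms}.
#' @export
detect_spikes <- function(time, vm, threshold_mV = 0, refractory_ms = 1) {
  stopifnot(length(time) == length(vm), !is.unsorted(time))
  below <- vm < threshold_mV
  idx <- which(below[-length(vm)] & !below[-1])
  times <- numeric(0)
  for (i in idx) {
    tc <- time[i] + (threshold_mV - vm[i]) / (vm[i + 1] - vm[i]) *
      (time[i + 1] - time[i])
    if (!length(times) || tc - times[length(times)] >= refractory_ms)
      times <- c(times, tc)
  }
  structure(list(times_ms = times, threshold_mV = threshold_mV,
                 refractory_ms = refractory_ms),
            class = "spike_train")
}

#' Per-pulse effectiveness of evoked action potentials
#'
#' A pulse is effective iff a spike reaches BOTH end nodes within the
#' conduction window after the pulse and before the next pulse; each spike
#' is assigned to at most one pulse (greedy, in order).
#'
#' @param node1,node21 \code{spike_train}s at the two end nodes.
#' @param pulse_times_ms Pulse onset times (ms).
#' @param conduction_window_ms Maximum latency from pulse to end-node spike.
#' @return Logical vector, one flag per pulse.
#' @export
effective_aps <- function(node1, node21, pulse_times_ms,
                          conduction_window_ms = 5) {
  np <- length(pulse_times_ms)
  if (np < 1) stop("at least one pulse is required")
  nxt <- c(pulse_times_ms[-1], Inf)
  assign_train <- function(train) {
    used <- rep(FALSE, length(train$times_ms))
    hit <- logical(np)
    for (k in seq_len(np)) {
      lo <- pulse_times_ms[k]
      hi <- min(lo + conduction_window_ms, nxt[k])
      j <- which(!used & train$times_ms > lo & train$times_ms <= hi)
      if (length(j)) { hit[k] <- TRUE; used[j[1]] <- TRUE }
    }
    hit
  }
  assign_train(node1) & assign_train(node21)
}

#' Induction ratio of evoked action potentials
#'
#' The reciprocal (as a percentage) of the number of stimulation pulses
#' between two successive effective action potentials: an AP evoked by pulse
#' k followed by the next AP at pulse k+3 gives 100/3 = 33\%; every pulse
#' effective gives a constant 100\%.
#'
#' @param effective Logical per-pulse effectiveness flags.
#' @param pulse_times_ms Pulse onset times (for the series time stamps).
#' @return A \code{metric_series}: data.frame with \code{time_ms},
#'   \code{pulse} (index of the evoking pulse) and \code{value} (percent),
#'   one row per effective AP after the first.
#' @export
induction_ratio <- function(effective, pulse_times_ms = seq_along(effective)) {
  stopifnot(length(effective) == length(pulse_times_ms))
  eff <- which(effective)
  if (length(eff) < 2)
    return(structure(data.frame(time_ms = numeric(0), pulse = integer(0),
                                value = numeric(0)),
                     class = c("metric_series", "data.frame")))
  gaps <- diff(eff)
  structure(data.frame(time_ms = pulse_times_ms[eff[-1]],
                       pulse = eff[-1], value = 100 / gaps),
            class = c("metric_series", "data.frame"))
}

#' Synchronization ratio across a bundle
#'
#' Per pulse, the percentage of axons firing an effective action potential;
#' the smoothed series is the sliding average of every 10 consecutive
#' per-pulse values.
#'
#' @param flags Logical matrix, pulses x axons (or a list of per-axon flag
#'   vectors sharing the pulse grid).
#' @param pulse_times_ms Pulse onset times.
#' @param smooth_n Sliding-average window (pulses).
#' @return A \code{metric_series} data.frame with \code{time_ms},
#'   \code{pulse}, \code{value} (raw percent) and \code{smoothed} (right-
#'   aligned sliding mean, NA for the first \code{smooth_n - 1} pulses).
#' @export
synchronization_ratio <- function(flags, pulse_times_ms = NULL,
                                  smooth_n = 10) {
  if (is.list(flags) && !is.data.frame(flags)) {
    len <- lengths(flags)
    if (length(unique(len)) != 1)
      stop("axons do not share the pulse grid")
    flags <- do.call(cbind, flags)
  }
  flags <- as.matrix(flags)
  if (is.null(pulse_times_ms)) pulse_times_ms <- seq_len(nrow(flags))
  if (length(pulse_times_ms) != nrow(flags))
    stop("pulse grid mismatch between flags and pulse_times_ms")
  value <- 100 * rowMeans(flags)
  smoothed <- if (length(value) >= smooth_n)
    stats::filter(value, rep(1 / smooth_n, smooth_n), sides = 1)
  else rep(NA_real_, length(value))
  structure(data.frame(time_ms = pulse_times_ms,
                       pulse = seq_len(nrow(flags)),
                       value = value, smoothed = as.numeric(smoothed)),
            class = c("metric_series", "data.frame"))
}

#' Steady-state value of a metric series
#'
#' Arithmetic mean of series values whose time stamps fall inside the
#' window; the default window starts where the model reaches steady state
#' (about 1.5 s after stimulation onset).
#'
#' @param series A \code{metric_series} data.frame.
#' @param window_ms Numeric length-2 window \code{c(t_a, t_b)} in ms.
#' @param column Which column to average (\code{"value"} or
#'   \code{"smoothed"}).
#' @return Mean value (percent or series units).
#' @export
steady_state_value <- function(series, window_ms = c(1500, Inf),
                               column = "value") {
  if (length(window_ms) != 2 || window_ms[1] >= window_ms[2])
    stop("window must be an increasing length-2 vector")
  if (!nrow(series) || window_ms[1] > max(series$time_ms))
    stop("window lies outside the series span")
  sel <- series$time_ms >= window_ms[1] & series$time_ms <= window_ms[2]
  vals <- series[[column]][sel]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) stop("no values in the steady-state window")
  mean(vals)
}

#' Spike trains and metrics from a simulated trace set
#'
#' Convenience wrapper: detects spikes at both end nodes, computes per-pulse
#' effectiveness and the induction-ratio series.
#'
#' @param ts A \code{trace_set} from \code{\link{simulate_axon}}.
#' @param threshold_mV,refractory_ms,conduction_window_ms Detection settings.
#' @return List with \code{spikes_node1}, \code{spikes_node21},
#'   \code{effective}, \code{induction} (metric series).
#' @export
axon_metrics <- function(ts, threshold_mV = 0, refractory_ms = 1,
                         conduction_window_ms = 5) {
  s1 <- detect_spikes(ts$time, ts$vm$node_1, threshold_mV, refractory_ms)
  s21 <- detect_spikes(ts$time, ts$vm$node_21, threshold_mV, refractory_ms)
  eff <- effective_aps(s1, s21, ts$pulse_times_ms, conduction_window_ms)
  list(spikes_node1 = s1, spikes_node21 = s21, effective = eff,
       induction = induction_ratio(eff, ts$pulse_times_ms))
}
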