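#' Cathodic monophasic pulse train
#'
#' @param frequency_hz Pulse repetition rate (Hz).
#' @param amplitude_ma Pulse current (mA); negative values are cathodic.
#' @param width_ms Pulse width (ms); must be shorter than the period.
#' @param duration_s Train duration (s).
#' @param onset_ms Time of the first pulse (ms); the default leaves a settled
#'   pre-stimulus baseline.
#' @return Object of class \code{pulse_protocol}.
#' @export
pulse_protocol <- function(frequency_hz, amplitude_ma, width_ms = 0.1,
                           duration_s = 2, onset_ms = 5) {
  if (amplitude_ma == 0) stop("amplitude must be nonzero")
  if (frequency_hz <= 0) stop("frequency must be positive")
  if (width_ms <= 0 || width_ms >= 1000 / frequency_hz)
    stop("pulse width must be positive and shorter than the period")
  if (duration_s < 0) stop("duration must be nonnegative")
  structure(list(frequency_hz = frequency_hz, amplitude_ma = amplitude_ma,
                 width_ms = width_ms, duration_s = duration_s,
                 onset_ms = onset_ms),
            class = "pulse_protocol")
}

#' Pulse start times of a protocol
#'
#' @param p A \code{pulse_protocol}.
#' @return Times (ms) of every pulse onset; \code{floor(duration * frequency)}
#'   pulses spaced by the period.
#' @export
pulse_times <- function(p) {
  n <- floor(p$duration_s * p$frequency_hz)
  if (n < 1) return(numeric(0))
  p$onset_ms + (seq_len(n) - 1) * 1000 / p$frequency_hz
}

#' Pulse indicator function
#'
#' @param p A \code{pulse_protocol}.
#' @param t Time (ms), nonnegative; vectorized.
#' @return 1 while a pulse is on (t in [start, start + width)), else 0.
#' @export
pulse_indicator <- function(p, t) {
  if (any(t < 0)) stop("t must be nonnegative")
  starts <- pulse_times(p)
  if (!length(starts)) return(numeric(length(t)))
  period <- 1000 / p$frequency_hz
  tt <- t - p$onset_ms
  inside <- tt >= 0 & tt < length(starts) * period
  phase <- tt - floor(tt / period) * period
  as.numeric(inside & phase < p$width_ms)
}

#' Monopolar point source in a homogeneous medium
#'
#' @param height_um Perpendicular distance from the axon axis (um).
#' @param x_um Axial position of the source (um); \code{NULL} places it above
#'   the central node when a morphology is supplied to
#'   \code{\link{field_along_axon}}.
#' @param sigma_S_m Extracellular conductivity (S/m), positive.
#' @return Object of class \code{point_source}.
#' @export
point_source <- function(height_um, x_um = NULL, sigma_S_m = 0.286) {
  if (sigma_S_m <= 0) stop("sigma must be positive")
  if (height_um <= 0) stop("source height must be positive")
  structure(list(height_um = height_um, x_um = x_um, sigma_S_m = sigma_S_m),
            class = "point_source")
}

#' Extracellular potential of a monopolar point source
#'
#' phi = I / (4 pi sigma r), for an infinite homogeneous volume conductor.
#'
#' @param I_ma Source current (mA).
#' @param sigma_S_m Conductivity (S/m).
#' @param r_um Distance (um), strictly positive.
#' @return Potential in mV; linear in I, inversely proportional to r.
#' @examples
#' extracellular_potential(-0.2, 0.286, 50)  # ~ -1113 mV
#' @export
extracellular_potential <- function(I_ma, sigma_S_m, r_um) {
  if (any(r_um <= 0)) stop("r must be strictly positive")
  # mA/(S/m * um): 1e-3 A / (sigma * r * 1e-6 m) -> V = 1e3/(4 pi sigma r);
  # in mV: 1e6
  I_ma * 1e6 / (4 * pi * sigma_S_m * r_um)
}

#' Extracellular potential along every compartment of an axon
#'
#' The source sits at perpendicular distance \code{height_um} from the axon
#' axis (by default directly above the central node); the potential at each
#' compartment uses the Euclidean distance from the source to the
#' compartment centre.
#'
#' @param src A \code{point_source}.
#' @param morph An \code{axon_morphology}.
#' @param I_ma Source current (mA).
#' @return Numeric vector, phi (mV) per compartment; maximal magnitude at the
#'   compartment nearest the source.
#' @export
field_along_axon <- function(src, morph, I_ma) {
  comp <- morph$compartments
  x0 <- if (is.null(src$x_um)) {
    centers <- morph$node_centers
    centers[ceiling(length(centers) / 2)]
  } else src$x_um
  r <- sqrt((comp$x_center - x0)^2 + src$height_um^2)
  if (any(r == 0)) stop("source coincides with a compartment centre")
  if (I_ma == 0) return(numeric(nrow(comp)))
  extracellular_potential(I_ma, src$sigma_S_m, r)
}
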