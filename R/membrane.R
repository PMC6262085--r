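#' Passive electrical parameters of the axon
#'
#' Whole-sheath myelin values: the capacitance and conductance are effective
#' values for the complete 15-lamella sheath, not per lamella.
#'
#' @param overrides Named list replacing defaults.
#' @return Named list: \code{rho_a_ohm_cm} (axoplasmic resistivity),
#'   \code{c_m_uF_cm2}, \code{g_Lk_S_cm2}, \code{E_Lk_mV}, \code{c_my_uF_cm2},
#'   \code{g_my_S_cm2}, \code{V_rest_mV}, \code{E_Na_mV} (fixed),
#'   \code{E_K_init_mV}, and \code{rho_p_ohm_cm} (longitudinal resistivity of
#'   the peri-axonal pathway; defaults to the axoplasmic value).
#' @export
passive_params <- function(overrides = list()) {
  p <- list(
    rho_a_ohm_cm = 70,
    c_m_uF_cm2   = 1,
    g_Lk_S_cm2   = 0.0001,
    E_Lk_mV      = -66,
    c_my_uF_cm2  = 0.1,
    g_my_S_cm2   = 0.001,
    V_rest_mV    = -66,
    E_Na_mV      = 45,
    E_K_init_mV  = -95,
    rho_p_ohm_cm = 70
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown passive parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  for (nm in c("rho_a_ohm_cm", "c_m_uF_cm2", "g_Lk_S_cm2", "c_my_uF_cm2",
               "g_my_S_cm2", "rho_p_ohm_cm"))
    if (p[[nm]] <= 0) stop("passive parameter '", nm, "' must be positive")
  p
}

# Gate rate functions: every gate is first-order with
#   x_inf(V) = 1 / (1 + exp(-(V - vhalf)/slope))   (slope < 0: inactivation)
#   tau(V)   = tau_min + tau_amp / cosh((V - tau_vhalf)/tau_slope)
gate_inf <- function(g, V) 1 / (1 + exp(-(V - g$vhalf) / g$slope))
gate_tau <- function(g, V) g$tau_min + g$tau_amp / cosh((V - g$tau_vhalf) / g$tau_slope)

#' Voltage-gated channel set
#'
#' The three channel types of the model: transient sodium (Na_T, m^3 h) and
#' M-type potassium (K_M, single slow gate) on nodes of Ranvier, and a fast
#' rectifying potassium channel (K_f, n^4) on the juxtaparanode.  The rate
#' functions are a data-driven parameter set (sigmoid steady states,
#' bell-shaped time constants) in the Hodgkin-Huxley tradition for pyramidal
#' axons, calibrated so that (a) single cathodic pulses from rest always
#' elicit propagating spikes, (b) sustained baseline depolarization to about
#' -53 mV blocks spike initiation, and (c) with peri-axonal [K+]o clamped at
#' 3 mM, 130 Hz / 0.2 mA stimulation at 50 um elicits one spike per pulse.
#'
#' @param name Name of a built-in set (currently \code{"pyramidal_default"})
#'   or a path to a YAML file written by \code{\link{write_channel_set}}.
#' @return Object of class \code{channel_set}.
#' @export
channel_set <- function(name = "pyramidal_default") {
  if (file.exists(name)) return(read_channel_set(name))
  if (name != "pyramidal_default")
    stop("unknown channel set: ", name)
  # Calibrated default set.  The transient Na channel activates with a
  # ~0.13 ms time constant (so a 0.1 ms extracellular pulse primes but does
  # not exhaust it) and inactivates steeply around -62 mV, which makes
  # sustained depolarization above about -53 mV abolish spike initiation.
  # The juxtaparanodal rectifier uses a high-order (n^6) gate: strongly
  # activated once the fibre is depolarized into the -50s mV, nearly closed
  # at rest, so the quiescent axon releases almost no potassium while the
  # depolarized-block state is maintained by the elevated peri-axonal E_K.
  cs <- list(
    name = name,
    channels = list(
      Na_T = list(
        name = "Na_T", ion = "na", where = "NODE", gbar_S_cm2 = 2,
        gates = list(
          m = list(exponent = 3, vhalf = -40.5, slope = 4.5,
                   tau_min = 0.13, tau_amp = 0.05,
                   tau_vhalf = -40.5, tau_slope = 15),
          h = list(exponent = 1, vhalf = -62, slope = -3,
                   tau_min = 0.35, tau_amp = 4.5,
                   tau_vhalf = -57, tau_slope = 5)
        )
      ),
      K_M = list(
        name = "K_M", ion = "k", where = "NODE", gbar_S_cm2 = 0.003,
        gates = list(
          n = list(exponent = 1, vhalf = -40, slope = 5,
                   tau_min = 2, tau_amp = 2,
                   tau_vhalf = -40, tau_slope = 20)
        )
      ),
      K_f = list(
        name = "K_f", ion = "k", where = "JXP", gbar_S_cm2 = 0.03,
        gates = list(
          n = list(exponent = 6, vhalf = -60.5, slope = 12.2,
                   tau_min = 3.5, tau_amp = 0,
                   tau_vhalf = -55, tau_slope = 16)
        )
      )
    )
  )
  class(cs) <- "channel_set"
  cs
}

#' @export
print.channel_set <- function(x, ...) {
  cat("Channel set '", x$name, "'\n", sep = "")
  for (ch in x$channels)
    cat(sprintf("  %-4s on %-4s gbar %g S/cm2, gates: %s\n", ch$name,
                ch$where, ch$gbar_S_cm2, paste(names(ch$gates), collapse = ", ")))
  invisible(x)
}

#' Serialize a channel set to / from a YAML parameter file
#'
#' Alternative published kinetics can be dropped in without code changes.
#'
#' @param cs A \code{channel_set}.
#' @param path File path.
#' @export
write_channel_set <- function(cs, path) {
  yaml::write_yaml(list(name = cs$name, channels = cs$channels), path)
  invisible(path)
}

#' @rdname write_channel_set
#' @export
read_channel_set <- function(path) {
  raw <- yaml::read_yaml(path)
  cs <- list(name = raw$name, channels = raw$channels)
  class(cs) <- "channel_set"
  cs
}

#' Nernst equilibrium potential
#'
#' @param conc_in,conc_out Intracellular / extracellular concentrations (mM),
#'   both strictly positive.
#' @param valence Ionic valence (nonzero integer).
#' @param temperature_K Absolute temperature; default 310.15 K (37 C).
#' @return Potential in mV: (RT/zF) ln(out/in).
#' @examples
#' nernst(106, 3)    # ~ -95 mV, the initial potassium reversal potential
#' @export
nernst <- function(conc_in, conc_out, valence = 1L, temperature_K = 310.15) {
  if (any(conc_in <= 0) || any(conc_out <= 0))
    stop("concentrations must be strictly positive")
  if (any(valence == 0)) stop("valence must be nonzero")
  R <- 8.314462618; F <- 96485.33212
  1000 * R * temperature_K / (valence * F) * log(conc_out / conc_in)
}

#' Steady-state gating variables at a fixed voltage
#'
#' @param V Membrane potential (mV), finite scalar.
#' @param cs A \code{channel_set}.
#' @return Named numeric vector of gate fixed points in [0, 1], named
#'   \code{<channel>.<gate>}.
#' @export
steady_gates <- function(V, cs = channel_set()) {
  stopifnot(is.finite(V))
  out <- c()
  for (ch in cs$channels)
    for (gn in names(ch$gates))
      out[paste(ch$name, gn, sep = ".")] <- gate_inf(ch$gates[[gn]], V)
  pmin(pmax(out, 0), 1)
}

#' Advance gating variables over a time step (exact exponential update)
#'
#' Rush-Larsen update: each gate relaxes toward its steady state with its
#' voltage-dependent time constant; exact for constant V over dt.
#'
#' @param V Membrane potential (mV) held over the step.
#' @param gates Named vector as returned by \code{\link{steady_gates}}.
#' @param dt Time step (ms), positive.
#' @param cs A \code{channel_set}.
#' @return Updated named gate vector, clamped to [0, 1].
#' @export
advance_gates <- function(V, gates, dt, cs = channel_set()) {
  stopifnot(dt > 0)
  out <- gates
  for (ch in cs$channels)
    for (gn in names(ch$gates)) {
      g <- ch$gates[[gn]]
      key <- paste(ch$name, gn, sep = ".")
      xi <- gate_inf(g, V)
      out[key] <- xi + (gates[[key]] - xi) * exp(-dt / gate_tau(g, V))
    }
  pmin(pmax(out, 0), 1)
}

#' Per-channel ionic current densities
#'
#' Outward current is positive.  Channels absent from the given section kind
#' contribute zero; the non-specific leak is present on every axolemmal
#' compartment.
#'
#' @param V Membrane potential (mV).
#' @param gates Named gate vector (values in [0, 1]).
#' @param E_K Potassium reversal potential (mV) local to the compartment.
#' @param kind Section kind: "NODE", "PNJ", "JXP" or "IND".
#' @param cs A \code{channel_set}.
#' @param passive Passive parameter list (for leak and E_Na).
#' @return Named vector of current densities (uA/cm2): one entry per channel
#'   plus \code{Lk}.
#' @export
ionic_currents <- function(V, gates, E_K, kind, cs = channel_set(),
                           passive = passive_params()) {
  if (any(gates < 0 | gates > 1)) stop("gates must lie in [0, 1]")
  out <- c()
  for (ch in cs$channels) {
    if (ch$where != kind) { out[ch$name] <- 0; next }
    open <- 1
    for (gn in names(ch$gates)) {
      g <- ch$gates[[gn]]
      open <- open * gates[[paste(ch$name, gn, sep = ".")]]^g$exponent
    }
    E <- if (ch$ion == "na") passive$E_Na_mV else E_K
    # g (S/cm2) * V (mV) = 1e-3 W... -> 1e3 uA/cm2
    out[ch$name] <- ch$gbar_S_cm2 * open * (V - E) * 1e3
  }
  out["Lk"] <- passive$g_Lk_S_cm2 * (V - passive$E_Lk_mV) * 1e3
  out
}
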