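#' Solver configuration
#'
#' @param dt_ms Integration step (ms). The electrical subsystem is solved
#'   implicitly (a theta-scheme over the banded double-cable system;
#'   \code{theta = 0.5} is Crank-Nicolson), gates with the exact exponential
#'   update, and peri-axonal potassium with a semi-implicit tridiagonal
#'   solve, so the scheme is unconditionally stable; dt controls accuracy
#'   only. Steps land exactly on pulse edges.
#' @param theta Implicitness of the electrical solve, in [0.5, 1]:
#'   0.5 = Crank-Nicolson (default, second order), 1 = backward Euler.
#' @param record_dt_ms Sampling interval of recorded traces (>= dt).
#' @param fixed_ko If TRUE, peri-axonal [K+]o is clamped (control
#'   experiments): the potassium update is skipped and E_K stays at its
#'   initial value everywhere.
#' @param fixed_ko_mM Clamp concentration used when \code{fixed_ko} is TRUE.
#' @param settle_ms Unstimulated settling integration performed by
#'   \code{\link{initialize_axon}} before t = 0.
#' @return Object of class \code{solver_config}.
#' @export
solver_config <- function(dt_ms = 0.005, record_dt_ms = 0.025,
                          fixed_ko = FALSE, fixed_ko_mM = 3,
                          settle_ms = 200, theta = 0.5) {
  if (dt_ms <= 0) stop("dt must be positive")
  if (record_dt_ms < dt_ms) stop("record_dt must be >= dt")
  if (theta < 0.5 || theta > 1)
    stop("theta must lie in [0.5, 1]")
  structure(list(dt_ms = dt_ms, record_dt_ms = record_dt_ms,
                 fixed_ko = fixed_ko, fixed_ko_mM = fixed_ko_mM,
                 settle_ms = settle_ms, theta = theta),
            class = "solver_config")
}

# Flatten morphology + parameters into the plain arrays the compiled
# integrator consumes.  All electrical quantities are converted to
# mV/ms/nA/uS/nF; potassium geometry stays in um^2/um^3.
compile_model <- function(morph, passive, cs, kp, field_mV, solver) {
  comp <- morph$compartments
  n <- nrow(comp)
  kind_code <- c(NODE = 0L, PNJ = 1L, JXP = 2L, IND = 3L)[comp$kind]
  area_cm2 <- comp$area_um2 * 1e-8
  # myelin layer area uses the sheath outer diameter
  my_area_cm2 <- pi * morph$params$axon_outer_diam_um * comp$length * 1e-8
  is_my <- comp$kind != "NODE"

  chan <- list(na = cs$channels$Na_T, km = cs$channels$K_M,
               kf = cs$channels$K_f)

  gna <- ifelse(comp$kind == chan$na$where, chan$na$gbar_S_cm2, 0) *
    area_cm2 * 1e6
  gkm <- ifelse(comp$kind == chan$km$where, chan$km$gbar_S_cm2, 0) *
    area_cm2 * 1e6
  gkf <- ifelse(comp$kind == chan$kf$where, chan$kf$gbar_S_cm2, 0) *
    area_cm2 * 1e6

  # axial intracellular conductance between consecutive compartments:
  # series half-resistances, axoplasmic cross-sections pi d^2/4
  xsec_um2 <- pi * comp$diam^2 / 4
  halfR <- passive$rho_a_ohm_cm * (comp$length / 2) * 1e4 / xsec_um2  # Ohm
  g_ax <- 1e6 / (halfR[-n] + halfR[-1])                               # uS

  # peri-axonal longitudinal conductance: cross-section = axial diffusion
  # area of the section kind; links to a node ground at the node's phi_e
  pax_area <- c(NODE = NA,
                PNJ = morph$params$axial_area_pnj_um2,
                JXP = morph$params$axial_area_jxp_um2,
                IND = morph$params$axial_area_ind_um2)[comp$kind]
  halfRp <- passive$rho_p_ohm_cm * (comp$length / 2) * 1e4 / pax_area
  g_pax <- numeric(n - 1)
  for (i in seq_len(n - 1)) {
    a <- i; b <- i + 1
    if (is_my[a] && is_my[b]) g_pax[i] <- 1e6 / (halfRp[a] + halfRp[b])
    else if (is_my[a]) g_pax[i] <- 1e6 / halfRp[a]
    else if (is_my[b]) g_pax[i] <- 1e6 / halfRp[b]
  }

  links <- morph$diffusion_links
  ax_links <- links[links$b != 0L, ]
  stopifnot(all(ax_links$a == seq_len(n - 1)), all(ax_links$b == 2:n))
  g_diff <- kp$D_um2_ms * ax_links$area_um2 / ax_links$dx_um
  bath_links <- links[links$b == 0L, ]
  g_bath <- numeric(n)
  g_bath[bath_links$a] <- kp$D_um2_ms * bath_links$area_um2 /
    bath_links$dx_um

  g <- cs$channels
  gates <- list(
    m = g$Na_T$gates$m, h = g$Na_T$gates$h,
    nkm = g$K_M$gates$n, nkf = g$K_f$gates$n
  )

  list(
    n = n, kind = kind_code,
    cm_ax = passive$c_m_uF_cm2 * area_cm2 * 1e3,
    cm_my = ifelse(is_my, passive$c_my_uF_cm2 * my_area_cm2 * 1e3, 0),
    g_my = ifelse(is_my, passive$g_my_S_cm2 * my_area_cm2 * 1e6, 0),
    g_lk = passive$g_Lk_S_cm2 * area_cm2 * 1e6,
    gna = gna, gkm = gkm, gkf = gkf,
    area_um2 = comp$area_um2, vol_um3 = comp$volume_um3,
    g_ax = g_ax, g_pax = g_pax, g_diff = g_diff, g_bath = g_bath,
    phi_unit = field_mV,
    ibal = numeric(n),
    gates = gates,
    ELk = passive$E_Lk_mV, ENa = passive$E_Na_mV,
    inakmax = kp$I_NaKmax_uA_cm2, kmk = kp$KmK_mM, kmna = kp$KmNa_mM,
    nai = kp$nai_mM, ki = kp$ki_mM, bath = kp$bath_mM,
    RTF = nernst(1, exp(1)),  # RT/F in mV at the model temperature
    theta = if (is.null(solver$theta)) 1 else solver$theta,
    fixed_ko = isTRUE(solver$fixed_ko)
  )
}

# Analytic quiescent state: V_rest everywhere, gates at steady state,
# [K+]o at its initial value.  A per-compartment constant balancing current
# cancels the residual membrane current (channel tails + electrogenic pump)
# at that point, so the quiescent state is an exact fixed point of the
# electrical subsystem.
rest_state <- function(model, cs, passive, ko0) {
  n <- model$n
  V <- passive$V_rest_mV
  sg <- steady_gates(V, cs)
  EK <- model$RTF * log(ko0 / model$ki)
  st <- list(
    Vm = rep(V, n), Vp = rep(0, n),
    m = rep(sg[["Na_T.m"]], n), h = rep(sg[["Na_T.h"]], n),
    nkm = rep(sg[["K_M.n"]], n), nkf = rep(sg[["K_f.n"]], n),
    ko = rep(ko0, n), EK = rep(EK, n), t = 0
  )
  gna_eff <- model$gna * st$m^cs$channels$Na_T$gates$m$exponent *
    st$h^cs$channels$Na_T$gates$h$exponent
  gkm_eff <- model$gkm * st$nkm^cs$channels$K_M$gates$n$exponent
  gkf_eff <- model$gkf * st$nkf^cs$channels$K_f$gates$n$exponent
  ipump_nA <- nak_pump_current(ko0, model$nai, V,
                               kdyn_params(list(I_NaKmax_uA_cm2 = model$inakmax,
                                                KmK_mM = model$kmk,
                                                KmNa_mM = model$kmna))) *
    model$area_um2 * 1e-5
  resid <- model$g_lk * (V - model$ELk) + gna_eff * (V - model$ENa) +
    (gkm_eff + gkf_eff) * (V - EK) + ipump_nA
  model$ibal <- resid
  list(model = model, state = st)
}

#' Initialize a quiescent axon state
#'
#' Builds the compiled model, places it at the analytic resting point
#' (V = V_rest, gates at steady state, [K+]o = 3 mM with a balancing current
#' cancelling the residual rest current), then integrates without stimulation
#' for \code{solver$settle_ms} so the potassium subsystem reaches its own
#' pump-diffusion equilibrium.  Errors if the membrane drifts by 0.5 mV or
#' more during settling (an unstable parameter set).
#'
#' @param morph \code{\link{build_axon}} result.
#' @param passive \code{\link{passive_params}}.
#' @param cs \code{\link{channel_set}}.
#' @param kp \code{\link{kdyn_params}}.
#' @param solver \code{\link{solver_config}}.
#' @return List with \code{model} (compiled arrays) and \code{state}.
#' @export
initialize_axon <- function(morph, passive = passive_params(),
                            cs = channel_set(), kp = kdyn_params(),
                            solver = solver_config()) {
  model <- compile_model(morph, passive, cs, kp,
                         field_mV = numeric(nrow(morph$compartments)),
                         solver = solver)
  ko0 <- if (isTRUE(solver$fixed_ko)) solver$fixed_ko_mM else kp$bath_mM
  rs <- rest_state(model, cs, passive, ko0)
  if (solver$settle_ms > 0) {
    out <- .engine_run(rs$model, rs$state, numeric(0), 0,
                       solver$settle_ms, solver$dt_ms,
                       solver$settle_ms, 1L, 1L)
    drift <- max(abs(out$state$Vm - passive$V_rest_mV))
    if (drift >= 0.5)
      stop("calibration error: membrane drifted ", round(drift, 2),
           " mV from rest during settling; the channel set and passive ",
           "parameters are not mutually consistent at V_rest")
    st <- out$state
    st$t <- 0
    rs$state <- st
  }
  rs
}

#' Simulate one axon under a pulse protocol
#'
#' Runs the double-cable model with peri-axonal potassium accumulation (or
#' clamped [K+]o) under extracellular stimulation from a monopolar point
#' source, recording membrane potential at the two end nodes and the central
#' node, and [K+]o in the node shell of the central node and its neighbouring
#' juxtaparanodal peri-axonal compartment.
#'
#' @param morph,passive,cs,kp,solver Model components (defaults throughout).
#' @param protocol A \code{\link{pulse_protocol}}.
#' @param source A \code{\link{point_source}}.
#' @param init Optional pre-settled state from \code{\link{initialize_axon}}
#'   (re-used across bundle axons; computed if NULL).
#' @return A \code{trace_set}: list with \code{time} (ms), \code{vm}
#'   (data.frame of traces at node_1, node_11, node_21), \code{ko}
#'   (node_11 shell and adjacent JXP), \code{pulse_times_ms}, \code{protocol},
#'   \code{source}, \code{solver}, \code{nsteps}.
#' @export
simulate_axon <- function(protocol, source, morph = build_axon(),
                          passive = passive_params(), cs = channel_set(),
                          kp = kdyn_params(), solver = solver_config(),
                          init = NULL) {
  if (is.null(init))
    init <- initialize_axon(morph, passive, cs, kp, solver)
  model <- init$model
  model$phi_unit <- field_along_axon(source, morph, protocol$amplitude_ma)
  comp <- morph$compartments
  nodes <- which(comp$kind == "NODE")
  n_nodes <- length(nodes)
  central <- nodes[ceiling(n_nodes / 2)]
  # JXP compartment adjacent to the central node (left side)
  jxp_left <- max(which(comp$kind == "JXP" & comp$comp < central))
  rec_v <- c(node_1 = nodes[1], node_11 = central, node_21 = nodes[n_nodes])
  rec_ko <- c(node_11_shell = central, jxp_node_11 = jxp_left)

  starts <- pulse_times(protocol)
  t_end <- protocol$duration_s * 1000 + protocol$onset_ms
  out <- .engine_run(model, init$state, starts, protocol$width_ms,
                     t_end, solver$dt_ms, solver$record_dt_ms,
                     as.integer(rec_v), as.integer(rec_ko))
  vm <- as.data.frame(out$v); names(vm) <- names(rec_v)
  ko <- as.data.frame(out$ko); names(ko) <- names(rec_ko)
  structure(list(time = out$time, vm = vm, ko = ko,
                 pulse_times_ms = starts,
                 protocol = protocol, source = source, solver = solver,
                 final_state = out$state, nsteps = out$nsteps),
            class = "trace_set")
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf("trace_set: %d samples over %.1f ms, %d pulses (%g Hz, %g mA)\n",
              length(x$time), max(x$time), length(x$pulse_times_ms),
              x$protocol$frequency_hz, x$protocol$amplitude_ma))
  invisible(x)
}

#' Export a trace set as a tidy data.frame / CSV
#'
#' @param ts A \code{trace_set}.
#' @param path Optional CSV path; written with \code{write.csv} when given.
#' @return data.frame with columns time_ms, quantity, compartment, value.
#' @export
traces_as_df <- function(ts, path = NULL) {
  vm <- do.call(rbind, lapply(names(ts$vm), function(nm)
    data.frame(time_ms = ts$time, quantity = "Vm", compartment = nm,
               value = ts$vm[[nm]])))
  ko <- do.call(rbind, lapply(names(ts$ko), function(nm)
    data.frame(time_ms = ts$time, quantity = "ko", compartment = nm,
               value = ts$ko[[nm]])))
  df <- rbind(vm, ko)
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Simulate a parallel bundle of identical axons
#'
#' Axons are electrically independent (no ephaptic coupling) and identical;
#' they differ only in distance to the stimulation point, which sits in the
#' bundle plane above the central node of the nearest axon.  Axon k's
#' distance is \code{source_height_um + spacing_um * (k - 1)}.
#'
#' @param n_axons Number of axons (default 11).
#' @param spacing_um Axon spacing (default 10 um).
#' @param source_height_um Distance from the source to the nearest axon.
#' @param protocol,morph,passive,cs,kp,solver As in
#'   \code{\link{simulate_axon}}.
#' @param sigma_S_m Extracellular conductivity.
#' @return List of \code{trace_set}, one per axon, nearest first; the
#'   settled initial state is computed once and shared.
#' @export
simulate_bundle <- function(protocol, n_axons = 11, spacing_um = 10,
                            source_height_um = 20, sigma_S_m = 0.286,
                            morph = build_axon(),
                            passive = passive_params(), cs = channel_set(),
                            kp = kdyn_params(), solver = solver_config()) {
  if (n_axons < 1) stop("n_axons must be >= 1")
  if (spacing_um <= 0) stop("spacing must be positive")
  init <- initialize_axon(morph, passive, cs, kp, solver)
  lapply(seq_len(n_axons), function(k) {
    src <- point_source(source_height_um + spacing_um * (k - 1),
                        sigma_S_m = sigma_S_m)
    simulate_axon(protocol, src, morph, passive, cs, kp, solver,
                  init = init)
  })
}
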