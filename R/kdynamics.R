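FARADAY <- 96485.33212  # C/mol

#' Parameters of peri-axonal potassium dynamics
#'
#' @param overrides Named list replacing defaults.
#' @return Named list: \code{ki_mM} (intracellular K+, constant),
#'   \code{nai_mM} (intracellular Na+, constant), \code{bath_mM} (bath K+),
#'   \code{D_um2_ms} (diffusion coefficient), \code{I_NaKmax_uA_cm2},
#'   \code{KmK_mM}, \code{KmNa_mM}.
#' @export
kdyn_params <- function(overrides = list()) {
  p <- list(
    ki_mM = 106, nai_mM = 10, bath_mM = 3,
    D_um2_ms = 1.85,
    I_NaKmax_uA_cm2 = 2.46, KmK_mM = 5.3, KmNa_mM = 27.9
  )
  if (length(overrides)) {
    bad <- setdiff(names(overrides), names(p))
    if (length(bad))
      stop("unknown K-dynamics parameter(s): ", paste(bad, collapse = ", "))
    p[names(overrides)] <- overrides
  }
  p
}

#' Na/K pump current density
#'
#' Michaelis-type saturation in extracellular K+ and intracellular Na+
#' (exponent 1.5) with a mild voltage dependence.  The pump is electrogenic:
#' 3 Na+ out, 2 K+ in per cycle, one net elementary charge.
#'
#' @param ko Extracellular K+ (mM), nonnegative.
#' @param nai Intracellular Na+ (mM).
#' @param V Membrane potential (mV), must exceed -200 mV.
#' @param p Parameter list from \code{\link{kdyn_params}}.
#' @return Current density (uA/cm2), outward positive; zero at \code{ko = 0},
#'   saturating at \code{I_NaKmax} times the Na and voltage factors.
#' @examples
#' nak_pump_current(3, 10, -66)   # ~0.0985 uA/cm2
#' @export
nak_pump_current <- function(ko, nai, V, p = kdyn_params()) {
  if (any(ko < 0)) stop("ko must be nonnegative")
  if (any(V <= -200)) stop("V must exceed -200 mV (voltage-factor pole)")
  na32 <- nai^1.5
  p$I_NaKmax_uA_cm2 * (ko / (ko + p$KmK_mM)) *
    (na32 / (na32 + p$KmNa_mM^1.5)) * ((V + 150) / (V + 200))
}

#' Fickian diffusion flux between two compartments
#'
#' @param D Diffusion coefficient (um2/ms).
#' @param A Cross-section area of the diffusion zone (um2), positive.
#' @param ko_a,ko_b Concentrations (mM) in compartments a and b.
#' @param dx Diffusion distance (um), positive.
#' @return Mol-equivalent flux (mM um3/ms), signed from a to b; antisymmetric
#'   under swapping a and b.
#' @export
diffusion_flux <- function(D, A, ko_a, ko_b, dx) {
  if (any(A <= 0) || any(dx <= 0)) stop("A and dx must be positive")
  D * A * (ko_a - ko_b) / dx
}

#' Rate of change of extracellular K+ from membrane currents
#'
#' Outward channel K+ current adds K+ to the adjacent extracellular
#' compartment; the pump removes 2 K+ per net elementary charge of its
#' current (3 Na+ out / 2 K+ in per cycle).
#'
#' @param I_K_channels K+ channel current density (uA/cm2, outward positive).
#' @param I_pump Pump current density (uA/cm2).
#' @param membrane_area_um2 Membrane area feeding the compartment (um2).
#' @param volume_um3 Compartment volume (um3), positive.
#' @return d[K+]o/dt in mM/ms.
#' @export
k_source_from_currents <- function(I_K_channels, I_pump, membrane_area_um2,
                                   volume_um3) {
  if (any(volume_um3 <= 0)) stop("volume must be positive")
  # uA/cm2 * um2 -> mol/ms -> mM/ms:  factor 10 / F per um3
  10 * (I_K_channels - 2 * I_pump) * membrane_area_um2 /
    (FARADAY * volume_um3)
}

#' Create a potassium state for a diffusion network
#'
#' @param ko Initial concentrations (mM), one per tracked compartment.
#' @param volumes_um3 Compartment volumes (um3).
#' @param p \code{\link{kdyn_params}}.
#' @return Object of class \code{k_state} with fields \code{ko},
#'   \code{volumes_um3}, \code{E_K_mV} (Nernst, recomputed on every step) and
#'   the constant concentrations.
#' @export
k_state <- function(ko, volumes_um3, p = kdyn_params()) {
  if (length(ko) != length(volumes_um3))
    stop("ko and volumes must have the same length")
  if (any(ko <= 0)) stop("ko must be positive")
  structure(list(ko = ko, volumes_um3 = volumes_um3, params = p,
                 E_K_mV = nernst(p$ki_mM, ko)),
            class = "k_state")
}

#' Advance a potassium state by one time step
#'
#' Semi-implicit (backward Euler) update of the linear diffusion network with
#' explicit channel/pump source terms: unconditionally stable and
#' mass-conserving, and positivity-preserving for nonnegative sources.  If a
#' negative source would still drive a concentration nonpositive the step is
#' recursively halved; failure after maximal reduction is an error naming the
#' compartment.
#'
#' This is the reference implementation used for standalone K-network
#' studies and as an oracle for the compiled engine, which performs the same
#' update inside its integration loop.
#'
#' @param ks A \code{k_state}.
#' @param sources d[K+]o/dt (mM/ms) per compartment (e.g. from
#'   \code{\link{k_source_from_currents}}); held constant over the step.
#' @param links data.frame of diffusion links (columns \code{a}, \code{b},
#'   \code{area_um2}, \code{dx_um}; \code{b = 0} is the bath reservoir).
#' @param dt Time step (ms), positive.
#' @param max_halvings Maximum number of step halvings for positivity.
#' @return Updated \code{k_state}.
#' @export
step_kstate <- function(ks, sources, links, dt, max_halvings = 12L) {
  stopifnot(dt > 0, length(sources) == length(ks$ko))
  p <- ks$params
  n <- length(ks$ko)
  g <- p$D_um2_ms * links$area_um2 / links$dx_um  # um3/ms
  interior <- links$b != 0L
  M <- diag(ks$volumes_um3 / dt, n)
  rhs <- ks$volumes_um3 / dt * ks$ko + sources * ks$volumes_um3
  for (i in which(interior)) {
    a <- links$a[i]; b <- links$b[i]
    M[a, a] <- M[a, a] + g[i]; M[b, b] <- M[b, b] + g[i]
    M[a, b] <- M[a, b] - g[i]; M[b, a] <- M[b, a] - g[i]
  }
  for (i in which(!interior)) {
    a <- links$a[i]
    M[a, a] <- M[a, a] + g[i]
    rhs[a] <- rhs[a] + g[i] * p$bath_mM
  }
  ko_new <- solve(M, rhs)
  if (any(ko_new <= 0)) {
    if (max_halvings == 0L)
      stop("potassium positivity failure at compartment ",
           which.min(ko_new), " after maximal step reduction")
    half <- step_kstate(ks, sources, links, dt / 2, max_halvings - 1L)
    return(step_kstate(half, sources, links, dt / 2, max_halvings - 1L))
  }
  ks$ko <- ko_new
  ks$E_K_mV <- nernst(p$ki_mM, ko_new)
  ks
}
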