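test_that("pump current follows the saturating product form", {
  expect_equal(nak_pump_current(0, 10, -66), 0)
  # frozen from independent arithmetic on the product form with defaults
  expect_equal(nak_pump_current(3, 10, -66), 0.098474, tolerance = 1e-4)
  # monotone increasing and saturating in ko
  ko <- c(0.5, 1, 3, 10, 30, 100, 1000)
  iv <- nak_pump_current(ko, 10, -66)
  expect_true(all(diff(iv) > 0))
  p <- kdyn_params()
  cap <- p$I_NaKmax_uA_cm2 * (10^1.5 / (10^1.5 + p$KmNa_mM^1.5)) *
    ((-66 + 150) / (-66 + 200))
  expect_lt(iv[length(iv)], cap)
  expect_equal(nak_pump_current(1e9, 10, -66), cap, tolerance = 1e-6)
  expect_error(nak_pump_current(3, 10, -250), "-200")
  expect_error(nak_pump_current(-1, 10, -66), "nonnegative")
})

test_that("diffusion flux is Fickian and antisymmetric", {
  expect_equal(diffusion_flux(1.85, 2.2, 3, 3, 1), 0)
  # frozen: paranodal bottleneck area, elevated juxtaparanodal K+
  expect_equal(diffusion_flux(1.85, 0.004, 16.5, 3, 2.0), 0.04995)
  a <- diffusion_flux(1.85, 2.2, 3.001, 3, 0.5)
  b <- diffusion_flux(1.85, 2.2, 3, 3.001, 0.5)
  expect_equal(a, -b)
  expect_error(diffusion_flux(1.85, 0, 3, 3, 1), "positive")
  expect_error(diffusion_flux(1.85, 2.2, 3, 3, 0), "positive")
})

test_that("current-to-concentration conversion has the right scaling", {
  expect_equal(k_source_from_currents(0, 0, 12.57, 0.1), 0)
  r1 <- k_source_from_currents(10, 0.1, 12.57, 0.1)
  # doubling the volume halves the rate; doubling area doubles it
  expect_equal(k_source_from_currents(10, 0.1, 12.57, 0.2), r1 / 2)
  expect_equal(k_source_from_currents(10, 0.1, 2 * 12.57, 0.1), 2 * r1)
  # the pump removes two K+ per unit charge: with I_K = 2 I_pump the
  # net source is exactly zero
  expect_equal(k_source_from_currents(0.2, 0.1, 12.57, 0.1), 0)
  # unit check against first principles: 1 uA/cm2 over 1 um2 into 1 um3
  # is 1e-14 A / 96485 C/mol / 1e-15 L = 1.0364e-1 mM/ms
  expect_equal(k_source_from_currents(1, 0, 1, 1),
               10 / 96485.33212, tolerance = 1e-9)
})

toy_network <- function() {
  # three compartments in a chain, last one linked to the bath
  data.frame(a = c(1L, 2L, 3L), b = c(2L, 3L, 0L),
             area_um2 = c(0.02, 0.004, 2.2), dx_um = c(10, 2, 0.015))
}

test_that("closed potassium networks conserve mass exactly", {
  links <- toy_network()
  closed <- links[links$b != 0L, ]
  ks <- k_state(c(20, 5, 3), c(0.4, 0.1, 0.05))
  total0 <- sum(ks$ko * ks$volumes_um3)
  for (i in 1:2000) ks <- step_kstate(ks, c(0, 0, 0), closed, dt = 0.5)
  expect_equal(sum(ks$ko * ks$volumes_um3), total0, tolerance = 1e-9)
  # concentrations equilibrate to the mass-weighted mean
  expect_equal(unname(diff(range(ks$ko))), 0, tolerance = 1e-6)
})

test_that("an elevated compartment relaxes monotonically to the bath", {
  links <- toy_network()
  ks <- k_state(c(20, 3, 3), c(0.4, 0.1, 0.05))
  traj <- numeric(6000)   # ~14 relaxation times of the slowest mode
  for (i in seq_along(traj)) {
    ks <- step_kstate(ks, c(0, 0, 0), links, dt = 0.5)
    traj[i] <- ks$ko[1]
  }
  expect_true(all(diff(traj) < 0))
  expect_equal(traj[length(traj)], 3, tolerance = 1e-3)
  expect_true(all(ks$ko > 0))
  # E_K is recomputed from the new concentrations at every step
  expect_equal(ks$E_K_mV, nernst(106, ks$ko))
})

test_that("the semi-implicit K step matches a dense ODE oracle", {
  skip_if_not_installed("deSolve")
  links <- toy_network()
  vols <- c(0.4, 0.1, 0.05)
  src <- c(0.05, 0.2, 0)   # constant channel-like sources, mM/ms
  p <- kdyn_params()
  g <- p$D_um2_ms * links$area_um2 / links$dx_um
  rhs <- function(t, ko, parms) {
    f12 <- g[1] * (ko[1] - ko[2]); f23 <- g[2] * (ko[2] - ko[3])
    fb <- g[3] * (ko[3] - p$bath_mM)
    list(c(src[1] - f12 / vols[1],
           src[2] + (f12 - f23) / vols[2],
           (f23 - fb) / vols[3]))
  }
  oracle <- deSolve::lsoda(c(5, 8, 3), seq(0, 100, by = 1), rhs, NULL,
                           rtol = 1e-10, atol = 1e-12)
  ks <- k_state(c(5, 8, 3), vols)
  for (i in 1:(100 / 0.005)) ks <- step_kstate(ks, src, links, dt = 0.005)
  expect_equal(ks$ko, unname(oracle[nrow(oracle), 2:4]),
               tolerance = 1e-3)
})

test_that("positivity is protected by step halving with a clear error", {
  links <- toy_network()
  ks <- k_state(c(3, 3, 3), c(0.4, 0.1, 0.05))
  # a violent sink: halving cannot rescue it forever
  expect_error(step_kstate(ks, c(0, -1e7, 0), links, dt = 1),
               "compartment 2")
  # a mild sink is absorbed by halving
  ks2 <- step_kstate(ks, c(0, -50, 0), links, dt = 0.05)
  expect_true(all(ks2$ko > 0))
})
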