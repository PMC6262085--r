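test_that("Nernst potential matches the closed form", {
  # initial potassium reversal: 106 mM in / 3 mM out at 37 C
  expect_equal(nernst(106, 3), -95, tolerance = 0.5 / 95)
  # equal concentrations give zero for any valence and temperature
  expect_equal(nernst(7.5, 7.5, valence = 2L, temperature_K = 290), 0)
  # elevated peri-axonal K+ (frozen from direct evaluation of the formula)
  expect_equal(nernst(106, 16.5), -49.70, tolerance = 1e-3)
  # strictly increasing in the outside concentration
  ko <- seq(1, 40, by = 0.5)
  expect_true(all(diff(nernst(106, ko)) > 0))
  expect_error(nernst(0, 3), "positive")
  expect_error(nernst(106, -1), "positive")
  expect_error(nernst(106, 3, valence = 0L), "valence")
})

test_that("steady-state gates are fixed points with correct limits", {
  cs <- channel_set()
  g <- steady_gates(-66, cs)
  expect_true(all(g >= 0 & g <= 1))
  # repeated application of the exponential update leaves them unchanged
  g2 <- advance_gates(-66, g, dt = 5, cs)
  expect_equal(g2, g, tolerance = 1e-12)
  # depolarized limit: activation gates open, inactivation gate shut
  ghi <- steady_gates(200, cs)
  expect_gt(ghi[["Na_T.m"]], 0.999)
  expect_gt(ghi[["K_f.n"]], 0.999)
  expect_lt(ghi[["Na_T.h"]], 1e-6)
  # sustained depolarization to the block boundary strips Na availability
  expect_lt(steady_gates(-53.4, cs)[["Na_T.h"]],
            0.25 * steady_gates(-66, cs)[["Na_T.h"]])
})

test_that("the exponential gate update is exact for constant voltage", {
  cs <- channel_set()
  g0 <- steady_gates(-66, cs)
  V <- -40
  full <- advance_gates(V, g0, dt = 0.8, cs)
  half <- advance_gates(V, advance_gates(V, g0, dt = 0.4, cs), dt = 0.4, cs)
  expect_equal(half, full, tolerance = 1e-12)
  # dt -> 0 leaves the state unchanged to first order
  tiny <- advance_gates(V, g0, dt = 1e-9, cs)
  expect_equal(tiny, g0, tolerance = 1e-6)
})

test_that("ionic currents vanish at reversal and respect channel placement", {
  cs <- channel_set()
  pas <- passive_params()
  g <- steady_gates(-20, cs)
  at_ena <- ionic_currents(pas$E_Na_mV, g, E_K = -95, kind = "NODE", cs, pas)
  expect_equal(at_ena[["Na_T"]], 0)
  at_ek <- ionic_currents(-95, g, E_K = -95, kind = "NODE", cs, pas)
  expect_equal(at_ek[["K_M"]], 0)
  at_ek_j <- ionic_currents(-95, g, E_K = -95, kind = "JXP", cs, pas)
  expect_equal(at_ek_j[["K_f"]], 0)
  # internode and paranode carry no voltage-gated current at any V
  for (kind in c("IND", "PNJ")) {
    cur <- ionic_currents(0, g, E_K = -50, kind = kind, cs, pas)
    expect_equal(unname(cur[c("Na_T", "K_M", "K_f")]), c(0, 0, 0))
  }
  # Na_T and K_M only on nodes, K_f only on juxtaparanodes
  node <- ionic_currents(0, g, E_K = -50, kind = "NODE", cs, pas)
  expect_gt(abs(node[["Na_T"]]), 0)
  expect_equal(node[["K_f"]], 0)
  jxp <- ionic_currents(0, g, E_K = -50, kind = "JXP", cs, pas)
  expect_gt(abs(jxp[["K_f"]]), 0)
  expect_equal(jxp[["Na_T"]], 0)
  expect_error(ionic_currents(0, pmax(g, 2), -95, "NODE", cs, pas), "0, 1")
})

test_that("channel sets round-trip through their YAML serialization", {
  cs <- channel_set()
  path <- withr::local_tempfile(fileext = ".yml")
  write_channel_set(cs, path)
  cs2 <- read_channel_set(path)
  expect_equal(cs2$channels, cs$channels, tolerance = 1e-12)
  expect_error(channel_set("no_such_set"), "unknown")
})

test_that("passive parameters validate and default to the published table", {
  p <- passive_params()
  expect_equal(p$rho_a_ohm_cm, 70)
  expect_equal(p$g_Lk_S_cm2, 1e-4)
  expect_equal(p$c_my_uF_cm2, 0.1)
  expect_equal(p$V_rest_mV, -66)
  expect_error(passive_params(list(c_m_uF_cm2 = 0)), "positive")
  expect_error(passive_params(list(bogus = 1)), "unknown")
})
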