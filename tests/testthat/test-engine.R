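test_that("the initialized axon is quiescent for a second of simulated time", {
  init <- settled_init()
  expect_true(all(abs(init$state$Vm - (-66)) < 0.5))
  # integrate one further second without stimulation: membrane stays
  # within 1 mV of rest and [K+]o near the bath value
  out <- periaxon:::.engine_run(init$model, init$state, numeric(0), 0,
                                1000, 0.005, 1000, 1L, 1L)
  expect_true(all(abs(out$state$Vm - (-66)) < 1))
  # quiescent [K+]o sits near bath: slightly below in the internode
  # (pump uptake), slightly above at the juxtaparanode (rectifier tail)
  expect_true(all(out$state$ko > 2.2 & out$state$ko < 4.2))
})

test_that("initialization fails loudly for unstable parameter sets", {
  cs <- channel_set()
  cs$channels$Na_T$gates$m$vhalf <- -70   # Na on at rest
  expect_error(initialize_axon(default_axon(), cs = cs),
               "calibration error")
})

test_that("a single suprathreshold pulse elicits one symmetric spike", {
  proto <- pulse_protocol(130, -0.2, duration_s = 0.0077)  # one pulse
  ts <- simulate_axon(proto, point_source(50), default_axon(),
                      init = settled_init())
  m <- axon_metrics(ts)
  expect_length(m$spikes_node1$times_ms, 1)
  expect_length(m$spikes_node21$times_ms, 1)
  expect_true(m$effective[1])
  # equal conduction latency to both ends for a centred source
  expect_lt(abs(m$spikes_node1$times_ms - m$spikes_node21$times_ms), 0.01)
  # the spike overshoots zero at the central node
  expect_gt(max(ts$vm$node_11), 0)
})

test_that("simulations are deterministic and bit-reproducible", {
  proto <- pulse_protocol(130, -0.2, duration_s = 0.03)
  run <- function() {
    simulate_axon(proto, point_source(50), default_axon(),
                  init = settled_init())
  }
  a <- run(); b <- run()
  expect_identical(a$vm, b$vm)
  expect_identical(a$ko, b$ko)
})

test_that("halving the time step leaves spike times essentially unchanged", {
  ax <- default_axon()
  proto <- pulse_protocol(130, -0.2, duration_s = 0.1)
  spikes <- lapply(c(0.0025, 0.00125), function(dt) {
    sv <- solver_config(dt_ms = dt, record_dt_ms = 0.025)
    ts <- simulate_axon(proto, point_source(50), ax, solver = sv,
                        init = initialize_axon(ax, solver = sv))
    axon_metrics(ts)$spikes_node1$times_ms
  })
  expect_equal(length(spikes[[1]]), length(spikes[[2]]))
  expect_lt(max(abs(spikes[[1]] - spikes[[2]])), 0.01)
})

test_that("clamped [K+]o gives a response periodic with the stimulus", {
  sv <- solver_config(fixed_ko = TRUE)
  ax <- default_axon()
  proto <- pulse_protocol(130, -0.2, duration_s = 0.4)
  ts <- simulate_axon(proto, point_source(50), ax, solver = sv,
                      init = initialize_axon(ax, solver = sv))
  m <- axon_metrics(ts)
  expect_true(all(m$effective))
  # [K+]o untouched; E_K pinned
  expect_equal(unique(round(ts$ko$jxp_node_11, 9)), 3)
  # late inter-spike intervals equal the pulse period
  isi <- diff(m$spikes_node1$times_ms)
  late <- tail(isi, 10)
  expect_equal(late, rep(1000 / 130, 10), tolerance = 1e-3)
})

test_that("a bundle of one axon reproduces the single-axon run", {
  proto <- pulse_protocol(130, -0.2, duration_s = 0.03)
  b <- simulate_bundle(proto, n_axons = 1, source_height_um = 50)
  s <- simulate_axon(proto, point_source(50), build_axon())
  expect_equal(b[[1]]$vm, s$vm, tolerance = 1e-12)
  expect_equal(b[[1]]$ko, s$ko, tolerance = 1e-12)
})

test_that("bundle axons see the documented source distances", {
  proto <- pulse_protocol(130, -0.2, duration_s = 0.02)
  b <- simulate_bundle(proto, n_axons = 3, spacing_um = 10,
                       source_height_um = 20)
  hts <- vapply(b, function(ts) ts$source$height_um, numeric(1))
  expect_equal(hts, c(20, 30, 40))
})

test_that("trace sets export to tidy CSV and echo their protocol", {
  ts <- short_run()
  df <- traces_as_df(ts)
  expect_setequal(unique(df$quantity), c("Vm", "ko"))
  expect_setequal(unique(df$compartment),
                  c("node_1", "node_11", "node_21",
                    "node_11_shell", "jxp_node_11"))
  path <- withr::local_tempfile(fileext = ".csv")
  traces_as_df(ts, path)
  back <- read.csv(path)
  expect_equal(nrow(back), nrow(df))
  expect_equal(ts$protocol$frequency_hz, 130)
})
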