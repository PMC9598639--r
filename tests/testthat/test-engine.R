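# Population engine: determinism, partition equivalence, causality of the
# recorded activity and single-spike responses routed through a real network.

test_that("simulation runs are reproducible and spikes are conserved", {
  net <- tiny_network()
  prot <- tiny_prot1_trains(tfin = 300)
  s1 <- run_simulation(net, prot$trains, tfin = 300)
  s2 <- run_simulation(net, prot$trains, tfin = 300)
  expect_identical(s1$raster, s2$raster)
  expect_gt(nrow(s1$raster), 0)
  expect_true(!is.unsorted(s1$raster$time_ms))
  for (acct in s1$queues)
    expect_identical(acct$consumed + acct$pending, acct$scheduled)
})

test_that("partitioned updates reproduce the monolithic run exactly", {
  net <- tiny_network()
  prot <- tiny_prot1_trains(tfin = 300)
  ref <- run_simulation(net, prot$trains, tfin = 300,
                        record = list(goc = 1L, grc = c(1L, 7L)))
  for (n_parts in c(2L, 4L)) {
    part <- run_simulation_partitioned(net, prot$trains, tfin = 300,
                                       n_parts = n_parts,
                                       record = list(goc = 1L, grc = c(1L, 7L)))
    expect_identical(part$raster, ref$raster)
    expect_identical(part$traces, ref$traces)
  }
  expect_error(run_simulation(net, prot$trains, 300, n_parts = 10),
               "population size")
})

test_that("recorded membrane potentials never exceed threshold", {
  net <- tiny_network()
  prot <- tiny_prot1_trains(tfin = 300)
  sim <- run_simulation(net, prot$trains, tfin = 300,
                        record = list(goc = seq_len(net$counts$n_goc),
                                      grc = 1:20))
  expect_true(all(sim$traces$goc <= goc_params()$VTH))
  expect_true(all(sim$traces$grc <= grc_params()$VTH))
  expect_identical(nrow(sim$traces$goc), 3000L)  # one row per step
})

test_that("a zero-length run yields an empty raster", {
  net <- tiny_network()
  sim <- run_simulation(net, replicate(net$counts$n_mf, numeric(0),
                                       simplify = FALSE), tfin = 0)
  expect_identical(nrow(sim$raster), 0L)
})

test_that("Golgi cells pace while granule cells stay quiet between inputs", {
  net <- tiny_network()
  prot <- tiny_prot1_trains(tfin = 1000)
  sim <- run_simulation(net, prot$trains, tfin = 1000)
  # pacemaker floor is ~10 Hz; network excitation can only raise it
  expect_gte(sim$summary[["goc_rate_hz"]], 5)
  # sparse 1 Hz mossy-fiber background keeps granule cells nearly silent
  expect_lt(sim$summary[["grc_rate_hz"]], 5)
  rate <- firing_rate(sim$raster, "goc", c(0, 1000), net$counts$n_goc)
  expect_equal(rate$mean, sim$summary[["goc_rate_hz"]], tolerance = 1e-9)
})

test_that("one mossy-fiber spike elicits a granule spike; Golgi inhibition dips Vm", {
  net <- tiny_network()
  n_mf <- net$counts$n_mf
  # a single MF spike at 50 ms, nothing else
  trains <- replicate(n_mf, numeric(0), simplify = FALSE)
  trains[[1]] <- 50
  # pick a granule cell driven by a glomerulus of fiber 1
  glo1 <- which(net$glo_to_mf == 1L)
  hit <- net$edges_grc_glo$grc[net$edges_grc_glo$glo %in% glo1]
  sim <- run_simulation(net, trains, tfin = 70)
  g_spk <- sim$raster[sim$raster$population == "grc", ]
  expect_gt(nrow(g_spk), 0)
  expect_true(all(g_spk$neuron_id %in% hit))
  expect_true(all(g_spk$time_ms >= 50 & g_spk$time_ms <= 52))  # within 2 ms
  # inhibitory arrival: drive one granule cell's inhibitory slot directly
  arr <- vector("list", 8)
  arr[[5]] <- 100
  r <- simulate_neuron(grc_params(), default_receptors("grc"), arr,
                       tfin = 200, h = 0.1)
  i_on <- 1001  # step that receives the arrival
  expect_lt(r$Vm[i_on + 1], r$Vm[i_on - 1])    # instantaneous dip
  expect_gt(min(r$Vm), -85)                    # bounded by the reversal
  expect_equal(tail(r$Vm, 1), grc_params()$EL, tolerance = 0.2)  # recovers
})

test_that("per-event delay resampling is seed-reproducible and seed-sensitive", {
  net <- tiny_network()
  # known mossy-fiber spikes so granule responses are guaranteed
  trains <- replicate(net$counts$n_mf, numeric(0), simplify = FALSE)
  trains[[1]] <- c(50, 120)
  trains[[2]] <- 80
  a <- run_simulation(net, trains, 200, delay_mode = "per_event", seed = 5)
  b <- run_simulation(net, trains, 200, delay_mode = "per_event", seed = 5)
  expect_identical(a$raster, b$raster)
  expect_gt(nrow(a$raster), 0)
  c <- run_simulation(net, trains, 200, delay_mode = "per_event", seed = 6)
  expect_false(identical(a$raster, c$raster))
})
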