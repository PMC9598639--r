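# Single-neuron dynamics: one-step updates against closed-form oracles,
# synapse laws, threshold/reset/refractory mechanics.

test_that("implicit one-step membrane update matches the closed-form solution of the linear update", {
  p <- goc_params()
  h <- 0.1
  st <- neuron_state(p, list(), Vm = -75)
  got <- membrane_update(st, p, I_inj = 0, h = h)
  # independent oracle: solve V' = V + (h/Cm) (IE + gL EL - gL V') for V'
  oracle <- (-75 + (h / p$Cm) * (p$IE + p$gL * p$EL)) / (1 + h * p$gL / p$Cm)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, -74.9048, tolerance = 1e-4)
})

test_that("Vm = EL is a fixed point when IE = 0 and no receptors are active", {
  p <- grc_params()  # IE = 0
  st <- neuron_state(p, list(), Vm = p$EL)
  for (h in c(0.01, 0.1, 1, 10)) {
    expect_equal(membrane_update(st, p, 0, h, scheme = "implicit"), p$EL)
    expect_equal(membrane_update(st, p, 0, h, scheme = "explicit"), p$EL)
  }
})

test_that("passive relaxation is monotone toward EL and bracketed by the exact exponential", {
  p <- grc_params()
  st <- neuron_state(p, list(), Vm = -84)
  v <- membrane_update(st, p, 0, 0.1)
  expect_gt(v, -84)
  expect_lt(v, -74)
  # iterated update converges monotonically to V_inf = EL
  vm <- -84
  gap <- abs(vm - p$EL)
  for (i in 1:200) {
    st$Vm <- vm
    vm <- membrane_update(st, p, 0, 0.1)
    expect_lt(abs(vm - p$EL), gap)
    gap <- abs(vm - p$EL)
  }
})

test_that("n-step integration error against the exact solution shrinks linearly in h", {
  p <- goc_params()
  t_end <- 20
  truth <- exact_passive_vm(p, V0 = -75, t = t_end)
  err <- function(h, scheme) {
    st <- neuron_state(p, list(), Vm = -75)
    vm <- -75
    for (i in seq_len(round(t_end / h))) {
      st$Vm <- vm
      vm <- membrane_update(st, p, 0, h, scheme = scheme)
    }
    abs(vm - truth)
  }
  for (scheme in c("implicit", "explicit")) {
    e <- vapply(c(0.2, 0.1, 0.05), err, numeric(1), scheme = scheme)
    expect_true(all(diff(e) < 0))           # error decreases with h
    ratio <- e[-length(e)] / e[-1]
    expect_true(all(ratio > 1.6 & ratio < 2.4))  # halving h halves the error
  }
})

test_that("membrane_update rejects corrupted or invalid input", {
  p <- grc_params()
  st <- neuron_state(p, list(), Vm = NaN)
  expect_error(membrane_update(st, p, 0, 0.1), "non-finite")
  st <- neuron_state(p, list(), Vm = -70)
  expect_error(membrane_update(st, p, 0, h = 0), "h must be > 0")
  st$refractory_remaining <- 1
  expect_error(membrane_update(st, p, 0, 0.1), "refractory")
})

test_that("synaptic decay follows g exp(-h/tau) with the semigroup property", {
  expect_equal(synaptic_decay(20, tau = 0.5, h = 0.5), 20 * exp(-1),
               tolerance = 1e-12)
  expect_equal(synaptic_decay(20, tau = 0.5, h = 0.5), 7.3576, tolerance = 1e-4)
  expect_identical(synaptic_decay(0, 10, 123), 0)
  # composing n steps of h equals one decay over n h
  g <- 13.7
  g_steps <- g
  for (i in 1:7) g_steps <- synaptic_decay(g_steps, tau = 3, h = 0.4)
  expect_equal(g_steps, synaptic_decay(g, tau = 3, h = 7 * 0.4),
               tolerance = 1e-12)
  expect_error(synaptic_decay(1, tau = 0, h = 1), "tau")
})

test_that("spike arrivals increment conductance by |w|, additively", {
  expect_equal(apply_spike(0, 20), 20)
  expect_equal(apply_spike(0, -10), 10)    # inhibitory magnitude stored
  expect_equal(apply_spike(5, 20, n = 2), 45)
  set.seed(11)
  for (i in 1:50) {
    g <- stats::runif(1, 0, 50)
    w <- stats::runif(1, -30, 30)
    expect_gte(apply_spike(g, w), g)               # never decreases g
    expect_lte(synaptic_decay(g, stats::runif(1, 0.1, 20),
                              stats::runif(1, 0, 5)), g)  # never increases g
  }
})

test_that("threshold crossing resets to Vinit and arms the refractory clamp", {
  p <- goc_params()
  st <- neuron_state(p, list())
  out <- threshold_and_reset(-54, st, p, h = 0.1)   # VTH = -55
  expect_true(out$spiked)
  expect_equal(out$state$Vm, -75)
  expect_equal(out$state$refractory_remaining, p$tref)
  out2 <- threshold_and_reset(-60, st, p, h = 0.1)
  expect_false(out2$spiked)
  expect_equal(out2$state$Vm, -60)
  # during the clamp any candidate is ignored and the clamp counts down
  stref <- out$state
  out3 <- threshold_and_reset(0, stref, p, h = 0.1)
  expect_false(out3$spiked)
  expect_equal(out3$state$Vm, p$Vinit)
  expect_equal(out3$state$refractory_remaining, p$tref - 0.1)
})

test_that("synaptic current sums |g| (Vm - Vrev) over receptors", {
  p <- grc_params()
  recs <- default_receptors("grc")
  st <- neuron_state(p, recs)
  st$receptor_g[1] <- 20
  expect_equal(synaptic_current(st, recs, Vm = -84), 20 * (-84 - 0))  # -1680 pA
  st$receptor_g[] <- 0
  expect_equal(synaptic_current(st, recs, Vm = -60), 0)
  st$receptor_g[5] <- 10  # inhibitory slot, Vrev = -85
  expect_equal(synaptic_current(st, recs, Vm = -85), 0)  # at reversal
  expect_error(synaptic_current(st, recs[1:3], Vm = -70), "one conductance slot")
})

test_that("Golgi pacemaking ISI tracks the closed-form oracle with error decreasing in h", {
  p <- goc_params()
  isi_ref <- isi_closed_form(p)
  expect_equal(isi_ref, p$tref + (p$Cm / p$gL) *
                 log((p$Vinit - (p$EL + p$IE / p$gL)) /
                       (p$VTH - (p$EL + p$IE / p$gL))))
  errs <- vapply(c(0.1, 0.05, 0.025), function(h) {
    r <- simulate_neuron(p, default_receptors("goc"), NULL, tfin = 600, h = h)
    abs(mean(diff(r$spikes)) - isi_ref)
  }, numeric(1))
  expect_true(all(errs < 0.005 * isi_ref))  # within 0.5% of ~98.6 ms
  expect_true(all(diff(errs) < 0))
})

test_that("a granule cell with no input never spikes and relaxes to EL", {
  r <- simulate_neuron(grc_params(), default_receptors("grc"), NULL,
                       tfin = 1000, h = 0.1)
  expect_length(r$spikes, 0)
  expect_equal(tail(r$Vm, 1), grc_params()$EL, tolerance = 1e-6)
})
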