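# Mossy-fiber stimulation: Poisson statistics and protocol composition.

test_that("poisson_train respects bounds, order and the zero-rate edge case", {
  expect_identical(poisson_train(0, 0, 60000, seed = 1), numeric(0))
  tr <- poisson_train(50, 100, 400, seed = 2)
  expect_true(all(tr >= 100 & tr < 400))
  expect_true(all(diff(tr) > 0))
  expect_identical(poisson_train(5, 0, 1000, seed = 3),
                   poisson_train(5, 0, 1000, seed = 3))
})

test_that("Poisson counts match their expectation across many seeds", {
  n_rep <- 1000
  set.seed(123)
  c1 <- vapply(seq_len(n_rep), function(i) length(poisson_train(1, 0, 60000)),
               numeric(1))  # 1 Hz over 60 s -> mean 60
  se <- sqrt(60 / n_rep)
  expect_lt(abs(mean(c1) - 60), 3 * se)
  c2 <- vapply(seq_len(n_rep), function(i) length(poisson_train(100, 0, 50)),
               numeric(1))  # 100 Hz over 50 ms -> mean 5
  se2 <- sqrt(5 / n_rep)
  expect_lt(abs(mean(c2) - 5), 3 * se2)
})

test_that("protocols select the specified bursting fractions", {
  p2 <- make_protocol("prot2", n_mf = 100, tfin = 1000, seed = 1)
  expect_length(p2$bursting, 10)        # 10% of the fibers
  p4 <- make_protocol("prot4", n_mf = 100, tfin = 1000, seed = 1)
  expect_length(p4$bursting, 1)         # 1%, floored at one fiber
  p1 <- make_protocol("prot1", n_mf = 100, tfin = 1000, seed = 1)
  expect_length(p1$bursting, 0)
  p3 <- make_protocol("prot3", n_mf = 20, tfin = 1000, seed = 1)
  expect_identical(p3$bursting, 1:20)   # every fiber bursts
  # the floor also applies to tiny populations
  p4b <- make_protocol("prot4", n_mf = 7, tfin = 1000, seed = 1)
  expect_length(p4b$bursting, 1)
  expect_error(protocol_preset("prot9"))
})

test_that("burst-only fibers are silent outside the burst window", {
  p2 <- make_protocol("prot2", n_mf = 50, tfin = 2000, seed = 4)
  on <- p2$spec$burst_onset
  off <- on + p2$spec$burst_duration
  for (m in seq_len(50)) {
    tr <- p2$trains[[m]]
    if (m %in% p2$bursting) {
      expect_true(all(tr >= on & tr <= off + 1e-3))
    } else {
      expect_length(tr, 0)
    }
  }
})

test_that("merged trains are strictly ascending and truncated to the run", {
  p3 <- make_protocol("prot3", n_mf = 200, tfin = 1000, seed = 9)
  for (tr in p3$trains) {
    if (length(tr) > 1) expect_true(all(diff(tr) > 0))
    expect_true(all(tr >= 0 & tr < 1000))
  }
})

test_that("background rate is recovered empirically within 5%", {
  p1 <- make_protocol("prot1", n_mf = 1000, tfin = 100000, seed = 11)
  rate <- mean(lengths(p1$trains)) / 100  # spikes per fiber per 100 s -> Hz
  expect_lt(abs(rate - 1), 0.05)
  # trains differ across fibers even at equal rate
  expect_false(identical(p1$trains[[1]], p1$trains[[2]]))
  # and the whole set is seed-reproducible
  p1b <- make_protocol("prot1", n_mf = 1000, tfin = 100000, seed = 11)
  expect_identical(p1$trains, p1b$trains)
})
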