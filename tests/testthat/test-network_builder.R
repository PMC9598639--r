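# Network reconstruction: counts, placement, and every wiring rule on the
# small test geometry plus forced micro-scenarios.

test_that("population counts reproduce the reference geometries", {
  d <- density_config()
  n1 <- sample_counts(volume_spec(300, 75, 1200), d)
  expect_identical(n1$n_grc, 108000L)
  expect_identical(n1$n_goc, 243L)
  expect_identical(n1$n_glo, 8100L)
  n2 <- sample_counts(volume_spec(600, 150, 1200), d)
  expect_identical(n2$n_goc, 972L)
  expect_identical(n2$n_grc, 432000L)
  tiny <- sample_counts(volume_spec(60, 60, 120), d)
  expect_identical(unlist(tiny, use.names = FALSE), c(4L, 1728L, 130L, 7L))
  expect_error(sample_counts(volume_spec(5, 5, 5), d), "larger volume")
})

test_that("placement is uniform in the box, seed-reproducible and seed-sensitive", {
  vol <- volume_spec(60, 60, 120)
  cn <- sample_counts(vol)
  p1 <- place_cells(cn, vol, seed = 3)
  for (pop in names(p1)) {
    expect_true(all(p1[[pop]][, 1] >= 0 & p1[[pop]][, 1] <= vol$x))
    expect_true(all(p1[[pop]][, 2] >= 0 & p1[[pop]][, 2] <= vol$y))
    expect_true(all(p1[[pop]][, 3] >= 0 & p1[[pop]][, 3] <= vol$z))
  }
  p2 <- place_cells(cn, vol, seed = 3)
  expect_identical(p1, p2)
  p3 <- place_cells(cn, vol, seed = 4)
  expect_false(identical(p1$grc, p3$grc))
})

test_that("mossy-fiber assignment is a balanced total partition", {
  mf <- assign_mfs(130, ratio = 20, seed = 5)
  expect_length(mf, 130)
  expect_false(anyNA(mf))
  loads <- tabulate(mf)
  expect_length(loads, 7)
  expect_true(all(loads %in% 18:19))
  # ratio 1: one glomerulus per fiber
  mf1 <- assign_mfs(9, ratio = 1, seed = 5)
  expect_identical(sort(unique(mf1)), 1:9)
  expect_true(all(tabulate(mf1) == 1))
})

test_that("a granule cell with exactly four in-range glomeruli connects to all of them", {
  pos <- manual_positions(
    grc = c(50, 50, 50),
    glo = rbind(c(50, 50, 60), c(50, 60, 50), c(60, 50, 50), c(40, 50, 50))
  )
  out <- connect_grc_dendrites(pos, rule_config(), volume_spec(100, 100, 100),
                               seed = 1)
  expect_identical(sort(out$edges$glo), 1:4)
  expect_identical(sort(out$edges$slot), 1:4)
})

test_that("an unreachable granule cell errors when relaxation is disabled", {
  pos <- manual_positions(
    grc = c(0, 0, 0),
    glo = rbind(c(500, 500, 500), c(500, 500, 510), c(510, 500, 500),
                c(500, 510, 500))
  )
  expect_error(
    connect_grc_dendrites(pos, rule_config(relax_step = 0),
                          volume_spec(600, 600, 600), seed = 1),
    "relaxation is disabled")
  # with relaxation enabled the distance bound widens until targets are found
  ok <- connect_grc_dendrites(pos, rule_config(), volume_spec(600, 600, 600),
                              seed = 1)
  expect_identical(nrow(ok$edges), 4L)
  expect_identical(ok$log$n_relaxed, 1L)
  expect_gt(ok$log$max_radius_used, 40)
})

test_that("the tiny network satisfies every hard wiring invariant", {
  net <- tiny_network()
  r <- net$rules
  e <- net$edges_grc_glo
  per_grc <- tabulate(e$grc, net$counts$n_grc)
  expect_true(all(per_grc == 4L))                      # exactly-4 rule
  expect_identical(anyDuplicated(e[c("grc", "glo")]), 0L)
  inh <- net$edges_goc_grc_inh
  expect_identical(anyDuplicated(inh[c("goc", "grc")]), 0L)
  per_axon <- tabulate(net$edges_goc_glo_axon$goc, net$counts$n_goc)
  expect_true(all(per_axon <= r$goc_axon_max_glo))
  per_goc_dend <- tabulate(net$edges_glo_goc_dend$goc, net$counts$n_goc)
  expect_true(all(per_goc_dend == r$glo_per_goc_dendrite))
  gg <- net$edges_grc_goc_exc
  expect_identical(anyDuplicated(gg[c("goc", "grc", "pathway")]), 0L)
  aa_n <- tabulate(gg$goc[gg$pathway == "aa"], net$counts$n_goc)
  pf_n <- tabulate(gg$goc[gg$pathway == "pf"], net$counts$n_goc)
  expect_true(all(aa_n == r$aa_per_goc))
  expect_true(all(pf_n == r$pf_per_goc))
  # dendrite distances respect the (possibly relaxed, logged) radius
  d <- sqrt(rowSums((net$positions$grc[e$grc, ] - net$positions$glo[e$glo, ])^2))
  expect_true(all(d <= net$audit$max_dendrite_radius + 1e-9))
  expect_true(net$audit$max_dendrite_radius == r$grc_dendrite_max_dist ||
                net$audit$n_grc_relaxed > 0)           # relaxations are logged
  # inhibitory slots pair with the dendrite slots (5..8)
  expect_true(all(inh$slot %in% 5:8))
  expect_silent(validate_network(net))
})

test_that("delays are drawn once per connection inside the configured range", {
  net <- tiny_network()
  dl <- c(net$edges_grc_glo$delay_ms, net$edges_glo_goc_dend$delay_ms,
          net$edges_goc_grc_inh$delay_ms, net$edges_grc_goc_exc$delay_ms)
  expect_true(all(dl >= net$rules$delay_range[1] &
                    dl <= net$rules$delay_range[2]))
})

test_that("builds are deterministic per seed and differ across seeds", {
  a <- build_network("tiny", seed = 99)
  b <- build_network("tiny", seed = 99)
  expect_identical(a$edges_grc_glo, b$edges_grc_glo)
  expect_identical(a$edges_goc_grc_inh, b$edges_goc_grc_inh)
  expect_identical(a$edges_grc_goc_exc, b$edges_grc_goc_exc)
  expect_identical(a$positions, b$positions)
  c <- build_network("tiny", seed = 100)
  expect_false(identical(a$edges_grc_glo, c$edges_grc_glo))
})

test_that("mean dendrites per glomerulus depends on densities, not volume", {
  m1 <- tiny_network()$audit$mean_dendrites_per_glo
  net2 <- build_network(volume_spec(120, 60, 120), seed = 2)
  m2 <- net2$audit$mean_dendrites_per_glo
  expect_lt(abs(m1 - m2), 1)
  # density arithmetic: 4 rho_grc / rho_glo = 53.3
  d <- density_config()
  expect_equal(4 * d$rho_grc / d$rho_glo, 53.33, tolerance = 1e-3)
})

test_that("Golgi axon targeting is capped, deduplicated and tolerant of empty reach", {
  net <- tiny_network()
  # a GOC whose axon hits two glomeruli shared by one GRC inhibits it once:
  # engineered directly
  pos <- manual_positions(grc = c(10, 10, 10),
                          glo = rbind(c(10, 10, 20), c(10, 20, 10)),
                          goc = c(15, 15, 15))
  dd <- connect_grc_dendrites(pos, rule_config(grc_dendrites = 2L),
                              volume_spec(50, 50, 50), seed = 1)
  ax <- connect_goc_axon(pos, dd$edges, rule_config(grc_dendrites = 2L), seed = 1)
  expect_identical(nrow(ax$edges_axon), 2L)     # both glomeruli reached
  expect_identical(nrow(ax$edges_inh), 1L)      # but the GRC inhibited once
  # out-of-reach axon: zero edges, no error
  pos2 <- manual_positions(grc = c(0, 0, 5), glo = c(0, 0, 0),
                           goc = c(1000, 1000, 1000))
  dd2 <- connect_grc_dendrites(pos2, rule_config(grc_dendrites = 1L),
                               volume_spec(1100, 1100, 1100), seed = 1)
  ax2 <- connect_goc_axon(pos2, dd2$edges, rule_config(grc_dendrites = 1L),
                          seed = 1)
  expect_identical(nrow(ax2$edges_axon), 0L)
  expect_identical(nrow(ax2$edges_inh), 0L)
})

test_that("granule-to-Golgi convergence is clipped to the eligible pool with a warning", {
  set.seed(2)
  pos <- manual_positions(grc = matrix(stats::runif(30, 0, 50), 10, 3),
                          glo = matrix(stats::runif(30, 0, 50), 10, 3),
                          goc = c(25, 25, 25))
  expect_warning(out <- connect_grc_to_goc(pos, rule_config(), seed = 1),
                 "clipped")
  expect_lte(sum(out$edges$pathway == "aa"), 10)
  expect_identical(sum(out$edges$pathway == "pf"), 10L)
  expect_identical(anyDuplicated(out$edges[c("goc", "grc", "pathway")]), 0L)
})
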