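# Clock-driven population engine. Each step follows the serial/parallel
# flowcharts of the simulator design: (1) collect the Golgi flag array from
# the mossy-fiber and granule-driven excitatory queues and batch-update all
# Golgi cells; (2) route Golgi spikes into granule inhibitory queues at
# t + delay; (3) collect the granule flag array (mossy-fiber excitation via
# the glomerular mapping plus inhibitory queues) and batch-update all granule
# cells; (4) route granule spikes into Golgi excitatory queues. The two batch
# updates may be split across partitions; spike routing happens at a serial
# barrier in (population, neuron id) order, which is what makes partitioned
# and monolithic runs bit-identical.

pop_receptor_constants <- function(cell_type, h) {
  recs <- default_receptors(cell_type)
  tau <- vapply(recs, function(r) r$tau, numeric(1))
  list(k = length(recs),
       w = abs(vapply(recs, function(r) r$w, numeric(1))),
       vrev = vapply(recs, function(r) r$Vrev, numeric(1)),
       g0 = vapply(recs, function(r) r$g0, numeric(1)),
       decay = exp(-h / tau))
}

block_ranges <- function(n, n_parts) {
  if (n_parts < 1) stop("n_parts must be >= 1")
  if (n_parts > n) stop("n_parts exceeds the population size (", n, ")")
  sizes <- rep(n %/% n_parts, n_parts)
  sizes[seq_len(n %% n_parts)] <- sizes[seq_len(n %% n_parts)] + 1L
  hi <- cumsum(sizes)
  lo <- hi - sizes + 1L
  Map(function(a, b) seq.int(a, b), lo, hi)
}

#' Initialize a simulation state
#'
#' Allocates membrane/conductance arrays (Vm at `Vinit`, conductances at their
#' initial value), builds the per-population spike-queue sets, pre-loads the
#' mossy-fiber trains into the glomerulus-mapped excitatory queues (each
#' arrival delayed by its edge's propagation delay), and compiles per-neuron
#' routing tables for spike delivery.
#'
#' @param network a `gl_network` from [build_network()].
#' @param trains list of mossy-fiber spike trains (ms), one per fiber, e.g.
#'   `make_protocol(...)$trains`.
#' @param tfin simulated duration (ms), > 0.
#' @param h integration step (ms), default 0.1.
#' @param scheme integration scheme, `"implicit"` (default) or `"explicit"`.
#' @param record list with integer vectors `goc` and/or `grc`: neurons whose
#'   membrane traces are recorded.
#' @param n_parts number of partitions for the batch updates (>= 1).
#' @param delay_mode `"per_connection"` (default: the delays fixed at build
#'   time) or `"per_event"` (a fresh delay drawn for every spike event).
#' @param seed optional seed; only consumed by `"per_event"` delays.
#' @return An environment of class `gl_sim_state`.
#' @export
init_sim_state <- function(network, trains, tfin, h = 0.1,
                           scheme = c("implicit", "explicit"),
                           record = list(), n_parts = 1,
                           delay_mode = c("per_connection", "per_event"),
                           seed = NULL) {
  stopifnot(inherits(network, "gl_network"))
  scheme <- match.arg(scheme)
  delay_mode <- match.arg(delay_mode)
  if (tfin <= 0 && tfin != 0) stop("init_sim_state: tfin must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$h <- h
  st$tfin <- tfin
  st$scheme <- scheme
  st$step_i <- 0L
  st$n_steps <- as.integer(ceiling(tfin / h - 1e-9))
  st$delay_mode <- delay_mode
  st$delay_range <- network$rules$delay_range
  n_goc <- network$counts$n_goc
  n_grc <- network$counts$n_grc
  st$n_goc <- n_goc
  st$n_grc <- n_grc
  st$p_goc <- goc_params()
  st$p_grc <- grc_params()
  st$rc_goc <- pop_receptor_constants("goc", h)
  st$rc_grc <- pop_receptor_constants("grc", h)
  st$V_goc <- rep(st$p_goc$Vinit, n_goc)
  st$V_grc <- rep(st$p_grc$Vinit, n_grc)
  st$refr_goc <- numeric(n_goc)
  st$refr_grc <- numeric(n_grc)
  st$G_goc <- matrix(rep(st$rc_goc$g0, each = n_goc), n_goc, st$rc_goc$k)
  st$G_grc <- matrix(rep(st$rc_grc$g0, each = n_grc), n_grc, st$rc_grc$k)
  st$decayM_goc <- matrix(rep(st$rc_goc$decay, each = n_goc), n_goc, st$rc_goc$k)
  st$decayM_grc <- matrix(rep(st$rc_grc$decay, each = n_grc), n_grc, st$rc_grc$k)
  st$blocks_goc <- block_ranges(n_goc, n_parts)
  st$blocks_grc <- block_ranges(n_grc, n_parts)
  st$n_parts <- n_parts
  horizon <- max(tfin, h)
  st$qs_goc <- spike_queue_set(n_goc, st$rc_goc$k, h, horizon)
  st$qs_grc <- spike_queue_set(n_grc, st$rc_grc$k, h, horizon)

  # routing tables: flat (column-major) target slot ids + per-edge delays
  inh <- network$edges_goc_grc_inh
  st$goc_out_flat <- split((inh$slot - 1L) * n_grc + inh$grc, factor(inh$goc, levels = seq_len(n_goc)))
  st$goc_out_delay <- split(inh$delay_ms, factor(inh$goc, levels = seq_len(n_goc)))
  exc <- network$edges_grc_goc_exc
  st$grc_out_flat <- split((exc$slot - 1L) * n_goc + exc$goc, factor(exc$grc, levels = seq_len(n_grc)))
  st$grc_out_delay <- split(exc$delay_ms, factor(exc$grc, levels = seq_len(n_grc)))

  # pre-load mossy-fiber arrivals through the glomerular mapping
  e <- network$edges_grc_glo
  mf_of_grc_edge <- network$glo_to_mf[e$glo]
  grc_flat <- (e$slot - 1L) * n_grc + e$grc
  gd <- network$edges_glo_goc_dend
  mf_of_goc_edge <- network$glo_to_mf[gd$glo]
  goc_flat <- (gd$slot - 1L) * n_goc + gd$goc
  n_mf <- network$counts$n_mf
  by_mf_grc <- split(seq_along(grc_flat), factor(mf_of_grc_edge, levels = seq_len(n_mf)))
  by_mf_goc <- split(seq_along(goc_flat), factor(mf_of_goc_edge, levels = seq_len(n_mf)))
  if (length(trains) < n_mf)
    stop("init_sim_state: need one spike train per mossy fiber (", n_mf, ")")
  for (m in seq_len(n_mf)) {
    tm <- trains[[m]]
    tm <- tm[tm >= 0 & tm < tfin]
    if (!length(tm)) next
    rg <- by_mf_grc[[m]]
    if (length(rg)) {
      dl <- if (delay_mode == "per_event")
        stats::runif(length(rg) * length(tm), st$delay_range[1], st$delay_range[2])
      else rep(e$delay_ms[rg], times = length(tm))
      qs_schedule_flat(st$qs_grc, rep(grc_flat[rg], times = length(tm)),
                       rep(tm, each = length(rg)) + dl)
    }
    gg <- by_mf_goc[[m]]
    if (length(gg)) {
      dl <- if (delay_mode == "per_event")
        stats::runif(length(gg) * length(tm), st$delay_range[1], st$delay_range[2])
      else rep(gd$delay_ms[gg], times = length(tm))
      qs_schedule_flat(st$qs_goc, rep(goc_flat[gg], times = length(tm)),
                       rep(tm, each = length(gg)) + dl)
    }
  }

  st$record_goc <- as.integer(record$goc %||% integer(0))
  st$record_grc <- as.integer(record$grc %||% integer(0))
  st$trace_goc <- matrix(NA_real_, st$n_steps, length(st$record_goc))
  st$trace_grc <- matrix(NA_real_, st$n_steps, length(st$record_grc))
  st$spk_t <- vector("list", st$n_steps)
  st$spk_pop <- vector("list", st$n_steps)
  st$spk_id <- vector("list", st$n_steps)
  class(st) <- "gl_sim_state"
  st
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# batch LIF update of one population over the given index blocks;
# returns ascending ids of neurons that spiked this step
update_population <- function(Vm, refr, G, params, rc, blocks, h, scheme) {
  spiked_all <- logical(length(Vm))
  for (idx in blocks) {
    g <- G[idx, , drop = FALSE]
    gsum <- rowSums(g)
    gvrev <- as.numeric(g %*% rc$vrev)
    v_cand <- vm_step(Vm[idx], h, params, 0, gsum, gvrev, scheme)
    in_ref <- refr[idx] > 1e-9
    spiked <- !in_ref & v_cand >= params$VTH
    v_new <- v_cand
    v_new[in_ref | spiked] <- params$Vinit
    Vm[idx] <- v_new
    r <- refr[idx]
    r[in_ref] <- pmax(0, r[in_ref] - h)
    r[spiked] <- params$tref
    refr[idx] <- r
    spiked_all[idx] <- spiked
  }
  list(Vm = Vm, refr = refr, spiked = which(spiked_all))
}

#' Advance the simulation by one step
#'
#' Executes one iteration of the main loop: Golgi flags + batch update, Golgi
#' spike routing (serial barrier), granule flags + batch update, granule spike
#' routing, then conductance decay and recording. Spikes scheduled in this
#' step can only arrive in later steps because the minimum propagation delay
#' is at least one integration step.
#'
#' @param st a `gl_sim_state` from [init_sim_state()].
#' @return List with `t` (step time, ms), `goc_spikes` and `grc_spikes`
#'   (ascending neuron ids); `NULL` once the final time is reached.
#' @export
sim_step <- function(st) {
  if (st$step_i >= st$n_steps) return(NULL)
  st$step_i <- st$step_i + 1L
  i <- st$step_i
  t <- (i - 1L) * st$h

  # (1) Golgi flags and batch update
  fl <- collect_flags(st$qs_goc, t)
  if (length(fl$flat))
    st$G_goc[fl$flat] <- st$G_goc[fl$flat] + fl$count * st$rc_goc$w[fl$slot]
  up <- update_population(st$V_goc, st$refr_goc, st$G_goc, st$p_goc,
                          st$rc_goc, st$blocks_goc, st$h, st$scheme)
  st$V_goc <- up$Vm; st$refr_goc <- up$refr
  goc_spikes <- up$spiked

  # (2) route Golgi spikes to granule inhibitory queues (serial barrier,
  # ascending id order)
  if (length(goc_spikes)) {
    flat <- unlist(st$goc_out_flat[goc_spikes], use.names = FALSE)
    if (length(flat)) {
      dl <- if (st$delay_mode == "per_event")
        stats::runif(length(flat), st$delay_range[1], st$delay_range[2])
      else unlist(st$goc_out_delay[goc_spikes], use.names = FALSE)
      qs_schedule_flat(st$qs_grc, flat, t + dl, t)
    }
  }

  # (3) granule flags and batch update
  fl <- collect_flags(st$qs_grc, t)
  if (length(fl$flat))
    st$G_grc[fl$flat] <- st$G_grc[fl$flat] + fl$count * st$rc_grc$w[fl$slot]
  up <- update_population(st$V_grc, st$refr_grc, st$G_grc, st$p_grc,
                          st$rc_grc, st$blocks_grc, st$h, st$scheme)
  st$V_grc <- up$Vm; st$refr_grc <- up$refr
  grc_spikes <- up$spiked

  # (4) route granule spikes to Golgi excitatory queues
  if (length(grc_spikes)) {
    flat <- unlist(st$grc_out_flat[grc_spikes], use.names = FALSE)
    if (length(flat)) {
      dl <- if (st$delay_mode == "per_event")
        stats::runif(length(flat), st$delay_range[1], st$delay_range[2])
      else unlist(st$grc_out_delay[grc_spikes], use.names = FALSE)
      qs_schedule_flat(st$qs_goc, flat, t + dl, t)
    }
  }

  # conductance decay and recording
  st$G_goc <- st$G_goc * st$decayM_goc
  st$G_grc <- st$G_grc * st$decayM_grc
  if (length(st$record_goc)) st$trace_goc[i, ] <- st$V_goc[st$record_goc]
  if (length(st$record_grc)) st$trace_grc[i, ] <- st$V_grc[st$record_grc]
  n_ev <- length(goc_spikes) + length(grc_spikes)
  if (n_ev) {
    st$spk_t[[i]] <- rep.int(t, n_ev)
    st$spk_pop[[i]] <- rep(c("goc", "grc"),
                           c(length(goc_spikes), length(grc_spikes)))
    st$spk_id[[i]] <- c(goc_spikes, grc_spikes)
  }
  list(t = t, goc_spikes = goc_spikes, grc_spikes = grc_spikes)
}

#' Run a granular-layer network simulation
#'
#' Initializes the state (membrane potentials at `Vinit`, conductances at
#' their initial values), loads the mossy-fiber trains into the
#' glomerulus-mapped excitatory queues and iterates [sim_step()] until the
#' final time. Fully reproducible: the same network, trains and arguments give
#' an identical result.
#'
#' @inheritParams init_sim_state
#' @return Object of class `gl_sim`: `raster` (data.frame `time_ms`,
#'   `population`, `neuron_id`, ascending in time), `traces` (list of
#'   matrices, one column per recorded neuron, one row per step), `summary`
#'   (per-population mean firing rate, Hz), `queues` (spike-conservation
#'   accounting) and `meta`.
#' @export
run_simulation <- function(network, trains, tfin, h = 0.1,
                           scheme = c("implicit", "explicit"),
                           record = list(), n_parts = 1,
                           delay_mode = c("per_connection", "per_event"),
                           seed = NULL) {
  st <- init_sim_state(network, trains, tfin, h, scheme, record, n_parts,
                       delay_mode, seed)
  while (!is.null(sim_step(st))) {}
  raster <- data.frame(
    time_ms = unlist(st$spk_t, use.names = FALSE) %||% numeric(0),
    population = unlist(st$spk_pop, use.names = FALSE) %||% character(0),
    neuron_id = unlist(st$spk_id, use.names = FALSE) %||% integer(0)
  )
  dur_s <- tfin / 1000
  summary <- c(
    goc_rate_hz = if (dur_s > 0) sum(raster$population == "goc") / st$n_goc / dur_s else 0,
    grc_rate_hz = if (dur_s > 0) sum(raster$population == "grc") / st$n_grc / dur_s else 0
  )
  times <- (seq_len(st$n_steps) - 1) * h
  traces <- list()
  if (length(st$record_goc))
    traces$goc <- structure(st$trace_goc, dimnames = list(NULL, st$record_goc),
                            time_ms = times)
  if (length(st$record_grc))
    traces$grc <- structure(st$trace_grc, dimnames = list(NULL, st$record_grc),
                            time_ms = times)
  structure(list(
    raster = raster,
    traces = traces,
    summary = summary,
    queues = list(goc = queue_accounting(st$qs_goc),
                  grc = queue_accounting(st$qs_grc)),
    meta = list(tfin = tfin, h = h, scheme = st$scheme, n_parts = n_parts,
                n_goc = st$n_goc, n_grc = st$n_grc,
                delay_mode = st$delay_mode, seed = seed)
  ), class = "gl_sim")
}

#' Partitioned simulation run
#'
#' Splits each population into `n_parts` contiguous blocks that are updated
#' independently within a step; spike events merge at the serial routing
#' barrier in (population, neuron id) order. The result is bit-identical to
#' the monolithic [run_simulation()].
#'
#' @inheritParams run_simulation
#' @param n_parts number of partitions, >= 1 and at most the size of the
#'   smaller population.
#' @return A `gl_sim`, identical to the `n_parts = 1` run.
#' @export
run_simulation_partitioned <- function(network, trains, tfin, h = 0.1,
                                       n_parts, ...) {
  out <- run_simulation(network, trains, tfin, h, n_parts = n_parts, ...)
  out$meta$n_parts <- n_parts
  out
}

#' @export
print.gl_sim <- function(x, ...) {
  cat(sprintf("gl_sim: %g ms at h = %g ms (%s Euler, %d partition%s)\n",
              x$meta$tfin, x$meta$h, x$meta$scheme, x$meta$n_parts,
              if (x$meta$n_parts > 1) "s" else ""))
  cat(sprintf("  spikes: %d (GOC %.3g Hz, GRC %.3g Hz)\n", nrow(x$raster),
              x$summary[["goc_rate_hz"]], x$summary[["grc_rate_hz"]]))
  invisible(x)
}
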