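# Per-receptor spike queues. Every (neuron, receptor slot) pair owns an
# ascending queue of pending arrival times. Internally arrivals are bucketed
# by integration-step bin of width h, which makes per-step collection O(events)
# while preserving the per-slot ascending-queue semantics exposed by
# queue_times(). Flat slot ids are column-major, (slot - 1) * n_neurons +
# neuron, so they index the engine's n x k conductance matrices directly.

#' Create a spike-queue set
#'
#' One ascending queue of pending spike-arrival times per (neuron, receptor
#' slot) pair, binned on the integration grid of width `h` over `[0, t_max)`.
#' Arrivals at or beyond `t_max` are retained in an overflow store (pending at
#' the end of the simulation) rather than dropped, so spike conservation can
#' be audited.
#'
#' @param n_neurons number of neurons.
#' @param n_slots receptor slots per neuron.
#' @param h bin width = integration step (ms), > 0.
#' @param t_max time horizon (ms): arrivals in `[0, t_max)` are deliverable.
#' @return An environment of class `spike_queue_set`.
#' @export
spike_queue_set <- function(n_neurons, n_slots, h, t_max) {
  stopifnot(n_neurons >= 1, n_slots >= 1, h > 0, t_max > 0)
  qs <- new.env(parent = emptyenv())
  qs$n <- as.integer(n_neurons)
  qs$k <- as.integer(n_slots)
  qs$h <- h
  qs$t_max <- t_max
  qs$n_bins <- as.integer(ceiling(t_max / h - 1e-9))
  qs$slots <- vector("list", qs$n_bins)
  qs$times <- vector("list", qs$n_bins)
  qs$consumed_bin <- logical(qs$n_bins)
  qs$over_slots <- integer(0)
  qs$over_times <- numeric(0)
  qs$n_scheduled <- 0L
  qs$n_consumed <- 0L
  class(qs) <- "spike_queue_set"
  qs
}

qs_flat <- function(qs, neuron, slot) {
  stopifnot(all(neuron >= 1L & neuron <= qs$n), all(slot >= 1L & slot <= qs$k))
  (as.integer(slot) - 1L) * qs$n + as.integer(neuron)
}

qs_bin <- function(qs, t) as.integer(floor(t / qs$h + 1e-9)) + 1L

# bulk insert of flat slot ids at given times
qs_schedule_flat <- function(qs, flat, t_arrival, t_now = 0) {
  if (!length(flat)) return(invisible(qs))
  if (any(t_arrival < t_now - 1e-9))
    stop("schedule_spike: arrival time precedes current time (causality violation)")
  b <- qs_bin(qs, t_arrival)
  over <- b > qs$n_bins
  if (any(over)) {
    qs$over_slots <- c(qs$over_slots, flat[over])
    qs$over_times <- c(qs$over_times, t_arrival[over])
    flat <- flat[!over]
    t_arrival <- t_arrival[!over]
    b <- b[!over]
  }
  if (length(flat)) {
    if (any(qs$consumed_bin[b]))
      stop("schedule_spike: arrival scheduled into an already-processed step")
    for (bb in unique(b)) {
      sel <- b == bb
      qs$slots[[bb]] <- c(qs$slots[[bb]], flat[sel])
      qs$times[[bb]] <- c(qs$times[[bb]], t_arrival[sel])
    }
  }
  qs$n_scheduled <- qs$n_scheduled + length(flat) + sum(over)
  invisible(qs)
}

#' Schedule spike arrivals
#'
#' Inserts arrival times into the queue of one or more (neuron, slot) pairs,
#' preserving ascending order within each queue. Arguments are recycled to a
#' common length. Arrivals earlier than `t_now` raise a causality error.
#'
#' @param qs a [spike_queue_set()].
#' @param neuron,slot target neuron index and receptor slot (1-based).
#' @param t_arrival arrival time(s), ms.
#' @param t_now current simulation time (ms); arrivals must not precede it.
#' @return The queue set, invisibly (modified in place).
#' @export
schedule_spike <- function(qs, neuron, slot, t_arrival, t_now = 0) {
  nn <- max(length(neuron), length(slot), length(t_arrival))
  neuron <- rep_len(neuron, nn)
  slot <- rep_len(slot, nn)
  t_arrival <- rep_len(t_arrival, nn)
  qs_schedule_flat(qs, qs_flat(qs, neuron, slot), t_arrival, t_now)
}

#' Collect and consume the arrivals of one step
#'
#' A slot is flagged iff the head of its queue lies in the half-open window
#' `[t, t + h)`; all arrivals in the window are consumed, and simultaneous
#' arrivals accumulate into a per-slot count (each contributing one
#' conductance increment). `t` must lie on the integration grid.
#'
#' @param qs a [spike_queue_set()].
#' @param t window start (ms), a multiple of `qs$h`.
#' @return List with integer vectors `flat` (column-major slot ids), `neuron`,
#'   `slot`, and `count`; zero-length when no arrivals fall in the window.
#' @export
collect_flags <- function(qs, t) {
  b <- qs_bin(qs, t)
  if (abs(t - (b - 1L) * qs$h) > qs$h * 1e-6)
    stop("collect_flags: t must lie on the integration grid")
  empty <- list(flat = integer(0), neuron = integer(0),
                slot = integer(0), count = integer(0))
  if (b < 1L || b > qs$n_bins) return(empty)
  if (qs$consumed_bin[b]) return(empty)
  qs$consumed_bin[b] <- TRUE
  s <- qs$slots[[b]]
  if (is.null(s) || !length(s)) return(empty)
  qs$slots[b] <- list(NULL)
  qs$times[b] <- list(NULL)
  qs$n_consumed <- qs$n_consumed + length(s)
  u <- sort(unique(s))
  cnt <- tabulate(match(s, u), nbins = length(u))
  list(flat = u,
       neuron = (u - 1L) %% qs$n + 1L,
       slot = (u - 1L) %/% qs$n + 1L,
       count = cnt)
}

#' Pending arrival times of one queue
#'
#' @param qs a [spike_queue_set()].
#' @param neuron,slot queue address (1-based).
#' @return Ascending numeric vector of pending arrival times (ms), including
#'   any arrivals beyond the horizon.
#' @export
queue_times <- function(qs, neuron, slot) {
  f <- qs_flat(qs, neuron, slot)
  out <- numeric(0)
  for (b in which(!vapply(qs$slots, is.null, logical(1)))) {
    sel <- qs$slots[[b]] == f
    if (any(sel)) out <- c(out, qs$times[[b]][sel])
  }
  if (length(qs$over_slots)) out <- c(out, qs$over_times[qs$over_slots == f])
  sort(out)
}

#' Spike-conservation accounting of a queue set
#'
#' @param qs a [spike_queue_set()].
#' @return List with `scheduled`, `consumed` and `pending` counts; every
#'   scheduled arrival is either consumed exactly once or still pending.
#' @export
queue_accounting <- function(qs) {
  pending <- sum(lengths(qs$slots)) + length(qs$over_slots)
  list(scheduled = qs$n_scheduled, consumed = qs$n_consumed, pending = pending)
}
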