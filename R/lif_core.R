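# Single-neuron LIF and synapse dynamics. All functions are vectorized over
# neurons so the population engine can call them on whole arrays; the
# documented interfaces operate on one neuron_state at a time.

# One integration step of Cm dV/dt = IE + I_inj - gL (V - EL) - sum g_k (V - Vrev_k).
# `gsum` = sum of conductance magnitudes, `gvrev` = sum g_k * Vrev_k; both may
# be vectors aligned with Vm. Implicit scheme solves the linear update for
# V(t+h) with conductances frozen at their start-of-step values; explicit
# evaluates every term at time t.
vm_step <- function(Vm, h, params, I_inj = 0, gsum = 0, gvrev = 0,
                    scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  a <- h / params$Cm
  if (scheme == "implicit") {
    (Vm + a * (params$IE + I_inj + params$gL * params$EL + gvrev)) /
      (1 + a * (params$gL + gsum))
  } else {
    Vm + a * (params$IE + I_inj - params$gL * (Vm - params$EL) -
                (gsum * Vm - gvrev))
  }
}

#' Advance the membrane potential by one step
#'
#' Integrates the LIF membrane equation
#' `Cm dVm/dt = IE + I_inj - gL (Vm - EL) - sum_k g_k (Vm - Vrev_k)`
#' over one step of length `h`. The default scheme is implicit Euler (all
#' terms linear in `Vm` are evaluated at `t + h`, conductances held at their
#' start-of-step values); `"explicit"` selects forward Euler.
#'
#' @param state a [neuron_state()]; must not be inside the refractory clamp
#'   (see [threshold_and_reset()], which owns the clamp).
#' @param params [cell_params()].
#' @param I_inj externally injected current (pA).
#' @param h integration step (ms), > 0.
#' @param receptors list of [receptor_params()] matching `state$receptor_g`;
#'   `NULL` means no synaptic input.
#' @param scheme `"implicit"` (default) or `"explicit"`.
#' @return The membrane potential one step ahead (mV), before any threshold
#'   test.
#' @export
membrane_update <- function(state, params, I_inj = 0, h,
                            receptors = NULL,
                            scheme = c("implicit", "explicit")) {
  if (!is.numeric(h) || h <= 0) stop("membrane_update: h must be > 0")
  if (!is.finite(state$Vm) || !is.finite(I_inj) ||
      !all(is.finite(state$receptor_g)))
    stop("membrane_update: non-finite state; simulation state is corrupted")
  if (state$refractory_remaining > 1e-9)
    stop("membrane_update: neuron is inside the refractory clamp")
  gsum <- 0
  gvrev <- 0
  if (!is.null(receptors) && length(receptors)) {
    g <- abs(state$receptor_g)
    vrev <- vapply(receptors, function(r) r$Vrev, numeric(1))
    gsum <- sum(g)
    gvrev <- sum(g * vrev)
  }
  vm_step(state$Vm, h, params, I_inj, gsum, gvrev, match.arg(scheme))
}

#' Exponential decay of a synaptic conductance
#'
#' `g(t + h) = g(t) exp(-h / tau)`: the per-step form of the exponential
#' conductance decay. Composing `n` steps of size `h` equals a single decay
#' over `n h`.
#'
#' @param g conductance (nS); vectorized.
#' @param tau decay time constant (ms), > 0.
#' @param h elapsed time (ms), >= 0.
#' @return Decayed conductance (nS).
#' @export
synaptic_decay <- function(g, tau, h) {
  if (any(tau <= 0)) stop("synaptic_decay: tau must be > 0")
  if (any(h < 0)) stop("synaptic_decay: h must be >= 0")
  g * exp(-h / tau)
}

#' Conductance increment on spike arrival
#'
#' Each arriving spike increments the receptor conductance by the magnitude
#' `|w|`; the sign printed for inhibitory synapses encodes polarity, which is
#' carried by the receptor's reversal potential, not by the conductance.
#'
#' @param g current conductance (nS).
#' @param w per-spike increment (nS); absolute value is used.
#' @param n number of simultaneous arrivals (default 1).
#' @return `g + n |w|` (nS).
#' @export
apply_spike <- function(g, w, n = 1) g + n * abs(w)

#' Total synaptic current
#'
#' `Isyn = sum_k |g_k| (Vm - Vrev_k)` in pA (nS times mV). This quantity
#' enters the membrane equation with a leading minus sign, so an excitatory
#' receptor (Vrev = 0 mV) at a hyperpolarized Vm yields a negative `Isyn`,
#' i.e. a depolarizing contribution.
#'
#' @param state a [neuron_state()].
#' @param receptors list of [receptor_params()], one per conductance slot.
#' @param Vm membrane potential (mV) at which to evaluate the current.
#' @return Total synaptic current (pA).
#' @export
synaptic_current <- function(state, receptors, Vm) {
  if (length(receptors) != length(state$receptor_g))
    stop("synaptic_current: one conductance slot per receptor required")
  if (!length(receptors)) return(0)
  vrev <- vapply(receptors, function(r) r$Vrev, numeric(1))
  sum(abs(state$receptor_g) * (Vm - vrev))
}

#' Threshold test, reset and refractory clamp
#'
#' Implements the spike mechanism: while the refractory clamp is active the
#' potential stays at `Vinit` and the remaining clamp time is decremented by
#' `h`; otherwise a candidate potential at or above `VTH` fires a spike, the
#' potential resets to `Vinit` and the clamp is armed for `tref`.
#'
#' @param Vm_candidate candidate membrane potential (mV), typically the output
#'   of [membrane_update()].
#' @param state a [neuron_state()].
#' @param params [cell_params()].
#' @param h step length (ms), > 0.
#' @return List with `state` (updated [neuron_state()]) and `spiked` (logical).
#' @export
threshold_and_reset <- function(Vm_candidate, state, params, h) {
  if (h <= 0) stop("threshold_and_reset: h must be > 0")
  if (state$refractory_remaining > 1e-9) {
    state$Vm <- params$Vinit
    state$refractory_remaining <- max(0, state$refractory_remaining - h)
    return(list(state = state, spiked = FALSE))
  }
  if (Vm_candidate >= params$VTH) {
    state$Vm <- params$Vinit
    state$refractory_remaining <- params$tref
    return(list(state = state, spiked = TRUE))
  }
  state$Vm <- Vm_candidate
  list(state = state, spiked = FALSE)
}

#' Simulate a single neuron with prescribed spike arrivals
#'
#' Clock-driven single-cell run used for model validation: arrivals listed per
#' receptor slot bump the conductances, the membrane is advanced with
#' [membrane_update()]'s scheme, threshold/reset/refractory follow
#' [threshold_and_reset()], and conductances decay at the end of each step
#' (conductances keep decaying, and arrivals keep accumulating, during the
#' refractory clamp; only `Vm` is frozen).
#'
#' @param params [cell_params()].
#' @param receptors list of [receptor_params()]; `default_receptors()` of the
#'   cell type in typical use.
#' @param arrivals list of numeric vectors, one per receptor slot: spike
#'   arrival times (ms). Use `list()` or `NULL` for no input.
#' @param tfin simulated duration (ms).
#' @param h integration step (ms), default 0.1.
#' @param I_inj constant injected current (pA).
#' @param scheme integration scheme, as in [membrane_update()].
#' @return List with `time` (ms), `Vm` (mV trace, one value per step, taken
#'   after threshold/reset), and `spikes` (spike times, ms).
#' @export
simulate_neuron <- function(params, receptors, arrivals = NULL, tfin,
                            h = 0.1, I_inj = 0,
                            scheme = c("implicit", "explicit")) {
  scheme <- match.arg(scheme)
  k <- length(receptors)
  g <- vapply(receptors, function(r) r$g0, numeric(1))
  w <- abs(vapply(receptors, function(r) r$w, numeric(1)))
  vrev <- vapply(receptors, function(r) r$Vrev, numeric(1))
  decay <- exp(-h / vapply(receptors, function(r) r$tau, numeric(1)))
  n_steps <- ceiling(tfin / h - 1e-9)
  # pre-bin arrivals: counts per (step, slot)
  bins <- vector("list", k)
  if (k > 0 && !is.null(arrivals)) {
    for (s in seq_len(k)) {
      ts <- if (s <= length(arrivals)) arrivals[[s]] else numeric(0)
      if (length(ts)) {
        idx <- floor(ts / h + 1e-9) + 1L
        idx <- idx[idx >= 1L & idx <= n_steps]  # arrivals beyond tfin stay pending
        if (length(idx)) bins[[s]] <- tabulate(idx, nbins = n_steps)
      }
    }
  }
  Vm <- params$Vinit
  refr <- 0
  trace <- numeric(n_steps)
  times <- (seq_len(n_steps) - 1) * h
  spikes <- numeric(0)
  for (i in seq_len(n_steps)) {
    for (s in seq_len(k)) {
      cnt <- if (is.null(bins[[s]])) 0L else bins[[s]][i]
      if (cnt > 0) g[s] <- apply_spike(g[s], w[s], cnt)
    }
    if (refr > 1e-9) {
      Vm <- params$Vinit
      refr <- max(0, refr - h)
    } else {
      gs <- sum(g)
      gv <- sum(g * vrev)
      v_cand <- vm_step(Vm, h, params, I_inj, gs, gv, scheme)
      if (v_cand >= params$VTH) {
        Vm <- params$Vinit
        refr <- params$tref
        spikes <- c(spikes, times[i])
      } else {
        Vm <- v_cand
      }
    }
    trace[i] <- Vm
    g <- g * decay
  }
  list(time = times, Vm = trace, spikes = spikes)
}
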