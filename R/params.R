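#' Leaky integrate-and-fire cell parameters
#'
#' Bundles the seven constants of a single-compartment LIF neuron:
#' subthreshold dynamics follow `Cm dVm/dt = IE - gL (Vm - EL)` plus synaptic
#' input, with threshold `VTH`, reset potential `Vinit` and an absolute
#' refractory period `tref` during which `Vm` is clamped at `Vinit`.
#'
#' @param gL leak conductance (nS), > 0.
#' @param EL leak reversal potential (mV).
#' @param IE constant intrinsic current (pA); a positive value makes the cell
#'   an intrinsic pacemaker.
#' @param Cm membrane capacitance (pF), > 0.
#' @param VTH spike threshold (mV).
#' @param Vinit reset and initial potential (mV), must lie below `VTH`.
#' @param tref absolute refractory period (ms), >= 0.
#' @return An object of class `cell_params`.
#' @seealso [grc_params()], [goc_params()] for the granular-layer defaults.
#' @export
cell_params <- function(gL, EL, IE, Cm, VTH, Vinit, tref) {
  vals <- c(gL = gL, EL = EL, IE = IE, Cm = Cm, VTH = VTH,
            Vinit = Vinit, tref = tref)
  if (!all(is.finite(vals)))
    stop("cell_params: all parameters must be finite numbers")
  if (Cm <= 0) stop("cell_params: Cm must be > 0")
  if (gL <= 0) stop("cell_params: gL must be > 0")
  if (tref < 0) stop("cell_params: tref must be >= 0")
  if (Vinit >= VTH) stop("cell_params: Vinit must be < VTH")
  structure(as.list(vals), class = "cell_params")
}

#' Granule-cell LIF parameters
#'
#' Defaults for the cerebellar granule cell (GRC): a small, passive cell
#' (IE = 0 pA) that never fires without synaptic input.
#'
#' @return A [cell_params()] object.
#' @export
grc_params <- function() {
  cell_params(gL = 1.5, EL = -74, IE = 0, Cm = 3,
              VTH = -42, Vinit = -84, tref = 1.5)
}

#' Golgi-cell LIF parameters
#'
#' Defaults for the cerebellar Golgi cell (GOC). The positive intrinsic
#' current (IE = 36.75 pA) drives spontaneous pacemaking at roughly 10 Hz.
#'
#' @return A [cell_params()] object.
#' @export
goc_params <- function() {
  cell_params(gL = 3.6, EL = -65, IE = 36.75, Cm = 76,
              VTH = -55, Vinit = -75, tref = 2)
}

#' Synaptic receptor parameters
#'
#' An exponential conductance-based synapse: each arriving spike increments
#' the conductance by `|w|` and the conductance then decays as
#' `g(t + h) = g(t) exp(-h / tau)`. The polarity of the synapse is carried by
#' the reversal potential `Vrev` (0 mV excitatory, -85 mV inhibitory), so the
#' conductance itself is always stored as a magnitude; a negative `w` (the
#' printed convention for inhibition) is accepted and its absolute value used.
#'
#' @param Vrev synaptic reversal potential (mV).
#' @param tau decay time constant (ms), > 0.
#' @param w conductance increment per spike (nS); sign is ignored, polarity
#'   lives in `Vrev`.
#' @param g0 initial conductance (nS), >= 0.
#' @return An object of class `receptor_params`.
#' @export
receptor_params <- function(Vrev, tau, w, g0 = 0) {
  if (!all(is.finite(c(Vrev, tau, w, g0))))
    stop("receptor_params: all parameters must be finite")
  if (tau <= 0) stop("receptor_params: tau must be > 0")
  if (g0 < 0) stop("receptor_params: g0 must be >= 0")
  structure(list(Vrev = Vrev, tau = tau, w = w, g0 = g0),
            class = "receptor_params")
}

#' @rdname receptor_params
#' @export
excitatory_receptor <- function() receptor_params(Vrev = 0, tau = 0.5, w = 20)

#' @rdname receptor_params
#' @export
inhibitory_receptor <- function() receptor_params(Vrev = -85, tau = 10, w = -10)

#' Receptor layout of a cell type
#'
#' Number of excitatory and inhibitory receptor slots per cell: granule cells
#' carry four excitatory (one per dendrite) and four inhibitory receptors;
#' Golgi cells carry two excitatory (slot 1: mossy-fiber input through the
#' glomeruli, slot 2: granule-cell input via ascending axon and parallel
#' fibers) and one inhibitory receptor (left unconnected by the default
#' wiring).
#'
#' @param cell_type `"grc"` or `"goc"`.
#' @return Integer vector `c(n_excitatory = , n_inhibitory = )`.
#' @export
receptor_layout <- function(cell_type) {
  switch(match.arg(cell_type, c("grc", "goc")),
         grc = c(n_excitatory = 4L, n_inhibitory = 4L),
         goc = c(n_excitatory = 2L, n_inhibitory = 1L))
}

#' Default receptor set of a cell type
#'
#' One [receptor_params()] per slot, excitatory slots first.
#'
#' @inheritParams receptor_layout
#' @return List of `receptor_params`, length 8 (grc) or 3 (goc).
#' @export
default_receptors <- function(cell_type) {
  lay <- receptor_layout(cell_type)
  c(replicate(lay[["n_excitatory"]], excitatory_receptor(), simplify = FALSE),
    replicate(lay[["n_inhibitory"]], inhibitory_receptor(), simplify = FALSE))
}

#' Instantaneous state of one neuron
#'
#' @param params [cell_params()] of the cell.
#' @param receptors list of [receptor_params()], one per slot.
#' @param Vm starting membrane potential (mV); defaults to `params$Vinit`.
#' @return An object of class `neuron_state` with fields `Vm`,
#'   `refractory_remaining` (ms) and `receptor_g` (nS per slot).
#' @export
neuron_state <- function(params, receptors, Vm = params$Vinit) {
  stopifnot(inherits(params, "cell_params"))
  g <- vapply(receptors, function(r) r$g0, numeric(1))
  structure(list(Vm = Vm, refractory_remaining = 0, receptor_g = g),
            class = "neuron_state")
}
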