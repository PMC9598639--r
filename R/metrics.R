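# Memory-footprint model, firing statistics and the closed-form single-cell
# oracle used throughout validation.

#' Per-cell memory footprint
#'
#' Each cell carries seven cellular parameters plus four per synaptic
#' receptor, stored as IEEE754 single-precision values (4 B), and one 4 B flag
#' per receptor: a granule cell (8 receptors) needs 156 B of parameters plus
#' 32 B of flags = 188 B; a Golgi cell (3 receptors) needs 76 B + 12 B = 88 B.
#'
#' @param cell_type `"grc"` or `"goc"`.
#' @return Named numeric vector `c(params = , flags = , total = )` in bytes.
#' @export
per_cell_bytes <- function(cell_type) {
  lay <- receptor_layout(cell_type)  # errors on unknown type
  n_rec <- sum(lay)
  bytes_per_value <- 4
  params <- (7 + 4 * n_rec) * bytes_per_value
  flags <- n_rec * 4
  c(params = params, flags = flags, total = params + flags)
}

#' Memory required to simulate a network
#'
#' `bytes = 88 n_goc + 188 n_grc`. The headline `mib` figure uses 2^20 bytes
#' per MiB with the third decimal truncated — the convention that reproduces
#' the reference footprints of the large preset networks exactly (77.53 and
#' 310.14 MiB); `mib_exact` carries the untruncated value.
#'
#' @param n_goc,n_grc population counts, >= 0.
#' @return List with `bytes`, `mib` (2 decimals, truncated) and `mib_exact`.
#' @export
memory_estimate <- function(n_goc, n_grc) {
  if (n_goc < 0 || n_grc < 0) stop("memory_estimate: counts must be >= 0")
  b_goc <- per_cell_bytes("goc")[["total"]]
  b_grc <- per_cell_bytes("grc")[["total"]]
  bytes <- b_goc * n_goc + b_grc * n_grc
  mib_exact <- bytes / 2^20
  list(bytes = bytes, mib = floor(mib_exact * 100) / 100, mib_exact = mib_exact)
}

#' Firing rates from a spike raster
#'
#' @param raster data.frame with columns `time_ms`, `population`, `neuron_id`
#'   (as produced by [run_simulation()]).
#' @param population population label to select (`"goc"` or `"grc"`).
#' @param window two-element numeric `c(t0, t1)` in ms; only spikes in
#'   `[t0, t1)` are counted and rates are per `t1 - t0`.
#' @param n_neurons population size (silent neurons count as 0 Hz).
#' @return List with `per_neuron` (Hz, length `n_neurons`) and `mean` (Hz).
#' @export
firing_rate <- function(raster, population, window, n_neurons) {
  if (diff(window) <= 0) stop("firing_rate: window length must be > 0")
  sel <- raster$population == population &
    raster$time_ms >= window[1] & raster$time_ms < window[2]
  counts <- tabulate(raster$neuron_id[sel], n_neurons)
  per <- counts / (diff(window) / 1000)
  list(per_neuron = per, mean = mean(per))
}

#' Closed-form inter-spike interval of a LIF pacemaker
#'
#' For constant input the membrane relaxes toward `Vinf = EL + IE / gL` with
#' time constant `Cm / gL`. If `Vinf <= VTH` the cell never reaches threshold
#' and `Inf` is returned ("no spiking"); otherwise the exact interval is
#' `tref + (Cm / gL) log((Vinit - Vinf) / (VTH - Vinf))`. This is the
#' continuous-time oracle against which the discretized engine is validated.
#'
#' @param params [cell_params()].
#' @param I_extra additional constant current (pA) added to `IE`.
#' @return Inter-spike interval (ms), or `Inf` when the cell does not spike.
#' @export
isi_closed_form <- function(params, I_extra = 0) {
  vinf <- params$EL + (params$IE + I_extra) / params$gL
  if (vinf <= params$VTH) return(Inf)
  params$tref + (params$Cm / params$gL) *
    log((params$Vinit - vinf) / (params$VTH - vinf))
}
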