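# shared fixtures: networks are built once per test run and memoised
.fixtures <- new.env(parent = emptyenv())

tiny_network <- function(seed = 1) {
  key <- paste0("tiny_", seed)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- build_network("tiny", seed = seed)
  .fixtures[[key]]
}

tiny_prot1_trains <- function(seed = 7, tfin = 1000) {
  key <- paste0("prot1_", seed, "_", tfin)
  if (is.null(.fixtures[[key]]))
    .fixtures[[key]] <- make_protocol("prot1", tiny_network()$counts$n_mf,
                                      tfin, seed = seed)
  .fixtures[[key]]
}

# exact solution of Cm dV/dt = IE - gL (V - EL) from V0 over time t (passive,
# no synapses): the continuous-time oracle for the Euler schemes
exact_passive_vm <- function(params, V0, t, I_extra = 0) {
  vinf <- params$EL + (params$IE + I_extra) / params$gL
  tau <- params$Cm / params$gL
  vinf + (V0 - vinf) * exp(-t / tau)
}

# hand-made placement set for forced wiring scenarios
manual_positions <- function(grc, glo, goc = matrix(numeric(0), 0, 3)) {
  fix <- function(m) {
    m <- matrix(m, ncol = 3)
    dimnames(m) <- list(NULL, c("x", "y", "z"))
    m
  }
  list(goc = fix(goc), grc = fix(grc), glo = fix(glo))
}
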