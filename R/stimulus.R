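# Mossy-fiber stimulation protocols: homogeneous Poisson background and burst
# trains, combined per protocol. Each mossy fiber gets its own RNG substream
# (spawned from the root seed), so trains differ across fibers even at equal
# rates and any fiber's train is reproducible in isolation.

#' Stimulation protocol specification
#'
#' The four standard mossy-fiber protocols: a 1 Hz Poisson background to all
#' fibers (prot1); a 100 Hz, 50 ms burst to 10% of the fibers (prot2);
#' background plus burst to every fiber (prot3, a stress test); background to
#' all plus burst to 1% (prot4).
#'
#' @param protocol_id one of `"prot1"`..`"prot4"`, or `"custom"`.
#' @param background_rate background Poisson rate (Hz), >= 0.
#' @param burst_rate burst Poisson rate (Hz), >= 0.
#' @param burst_duration burst length (ms), >= 0.
#' @param burst_fraction fraction of mossy fibers receiving the burst, in
#'   `[0, 1]`.
#' @param burst_onset burst start time (ms); default 200 ms.
#' @param burst_regular if `TRUE` the burst is a regular train at
#'   `burst_rate` instead of a Poisson process.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(protocol_id = "custom",
                          background_rate = 1,
                          burst_rate = 100,
                          burst_duration = 50,
                          burst_fraction = 0,
                          burst_onset = 200,
                          burst_regular = FALSE) {
  if (background_rate < 0 || burst_rate < 0)
    stop("protocol_spec: rates must be >= 0")
  if (burst_fraction < 0 || burst_fraction > 1)
    stop("protocol_spec: burst_fraction must lie in [0, 1]")
  if (burst_duration < 0)
    stop("protocol_spec: burst_duration must be >= 0")
  structure(list(protocol_id = protocol_id,
                 background_rate = background_rate,
                 burst_rate = burst_rate,
                 burst_duration = burst_duration,
                 burst_fraction = burst_fraction,
                 burst_onset = burst_onset,
                 burst_regular = isTRUE(burst_regular)),
            class = "protocol_spec")
}

#' Named stimulation protocol presets
#'
#' @param name `"prot1"`, `"prot2"`, `"prot3"` or `"prot4"`.
#' @return A [protocol_spec()].
#' @export
protocol_preset <- function(name) {
  switch(match.arg(tolower(name), c("prot1", "prot2", "prot3", "prot4")),
         prot1 = protocol_spec("prot1", background_rate = 1, burst_fraction = 0),
         prot2 = protocol_spec("prot2", background_rate = 0, burst_fraction = 0.10),
         prot3 = protocol_spec("prot3", background_rate = 1, burst_fraction = 1),
         prot4 = protocol_spec("prot4", background_rate = 1, burst_fraction = 0.01))
}

#' Homogeneous Poisson spike train
#'
#' Draws a homogeneous Poisson process of the given rate on `[t0, t1)`:
#' a Poisson-distributed count, with spike times uniform on the window, sorted
#' ascending.
#'
#' @param rate firing rate (Hz), >= 0.
#' @param t0,t1 window bounds (ms), `t1 >= t0`.
#' @param seed optional integer seed for reproducibility.
#' @return Ascending numeric vector of spike times (ms).
#' @export
poisson_train <- function(rate, t0 = 0, t1, seed = NULL) {
  if (rate < 0) stop("poisson_train: rate must be >= 0")
  if (t1 < t0) stop("poisson_train: t1 must be >= t0")
  if (!is.null(seed)) set.seed(seed)
  if (rate == 0 || t1 == t0) return(numeric(0))
  n <- stats::rpois(1, rate * (t1 - t0) / 1000)
  sort(stats::runif(n, t0, t1))
}

# merge two ascending trains; exact duplicates are perturbed forward by eps
# (deterministically) so the result is strictly ascending
merge_trains <- function(a, b, eps = 1e-4) {
  out <- sort(c(a, b))
  if (length(out) > 1) {
    for (i in seq_along(out)[-1]) {
      if (out[i] <= out[i - 1]) out[i] <- out[i - 1] + eps
    }
  }
  out
}

#' Generate mossy-fiber spike trains for a protocol
#'
#' Builds one spike train per mossy fiber: a Poisson background (if the
#' protocol has one) plus a Poisson (or regular) burst for the bursting subset
#' of fibers. The bursting subset is sampled uniformly without replacement;
#' its size is `burst_fraction` rounded to the nearest integer with a floor of
#' one fiber whenever the fraction is positive. Per-fiber RNG substreams are
#' spawned from `seed`, so trains are independent across fibers and the same
#' seed reproduces the full set. Merged trains are strictly ascending and
#' truncated to `[0, tfin)`.
#'
#' @param spec a [protocol_spec()] (or preset name accepted by
#'   [protocol_preset()]).
#' @param n_mf number of mossy fibers, >= 1.
#' @param tfin simulated duration (ms).
#' @param seed integer root seed.
#' @param dedup_eps forward perturbation applied to coincident merged spike
#'   times (ms).
#' @return List with `trains` (list of ascending numeric vectors, one per
#'   fiber), `bursting` (integer ids of bursting fibers) and `spec`.
#' @export
make_protocol <- function(spec, n_mf, tfin, seed = NULL, dedup_eps = 1e-4) {
  if (is.character(spec)) spec <- protocol_preset(spec)
  stopifnot(inherits(spec, "protocol_spec"))
  if (n_mf < 1) stop("make_protocol: n_mf must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  mf_seeds <- sample.int(.Machine$integer.max - 1L, 2L * n_mf)
  bursting <- integer(0)
  if (spec$burst_fraction > 0 && spec$burst_rate > 0 && spec$burst_duration > 0) {
    n_burst <- max(1L, as.integer(round(spec$burst_fraction * n_mf)))
    n_burst <- min(n_burst, n_mf)
    bursting <- sort(sample.int(n_mf, n_burst))
  }
  t_b0 <- spec$burst_onset
  t_b1 <- min(spec$burst_onset + spec$burst_duration, tfin)
  trains <- vector("list", n_mf)
  for (m in seq_len(n_mf)) {
    bg <- if (spec$background_rate > 0)
      poisson_train(spec$background_rate, 0, tfin, seed = mf_seeds[m])
    else numeric(0)
    bu <- numeric(0)
    if (m %in% bursting && t_b1 > t_b0) {
      bu <- if (spec$burst_regular) {
        seq(t_b0, t_b1, by = 1000 / spec$burst_rate)
      } else {
        poisson_train(spec$burst_rate, t_b0, t_b1, seed = mf_seeds[n_mf + m])
      }
    }
    tr <- merge_trains(bg, bu, eps = dedup_eps)
    trains[[m]] <- tr[tr < tfin]
  }
  list(trains = trains, bursting = bursting, spec = spec)
}
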