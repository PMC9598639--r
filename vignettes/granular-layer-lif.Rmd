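---
title: "Modeling the cerebellar granular layer with granlif"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the cerebellar granular layer with granlif}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

granlif reconstructs the cerebellar granular layer — granule cells (GRC),
Golgi cells (GOC), glomeruli (GLO) and mossy fibers (MF) — in a
three-dimensional volume from anatomical convergence/divergence rules, and
simulates the resulting circuit with conductance-based leaky
integrate-and-fire (LIF) neurons. This vignette documents the model, the
parameters that matter, the numerical choices, and what the package's
synthetic networks do and do not say about real tissue.

## The neuron model

Each cell is a single-compartment LIF neuron,

$$C_m \frac{dV_m}{dt} = I_E - g_L\,(V_m - E_L) - \sum_k g_k(t)\,(V_m - V^{rev}_k),$$

with a threshold mechanism: when $V_m \ge V_{TH}$ the cell emits a spike,
$V_m$ resets to $V_{init}$, and stays clamped there for the refractory period
$t_{ref}$. The two cell types differ only in their constants:

| parameter | GRC | GOC | meaning |
|---|---|---|---|
| $g_L$     | 1.5 nS | 3.6 nS | leak conductance |
| $E_L$     | −74 mV | −65 mV | leak reversal |
| $I_E$     | 0 pA | 36.75 pA | intrinsic current |
| $C_m$     | 3 pF | 76 pF | membrane capacitance |
| $V_{TH}$  | −42 mV | −55 mV | spike threshold |
| $V_{init}$| −84 mV | −75 mV | reset / initial potential |
| $t_{ref}$ | 1.5 ms | 2 ms | refractory period |

The positive $I_E$ of the Golgi cell makes it an intrinsic pacemaker: its
equilibrium potential $V_\infty = E_L + I_E/g_L \approx -54.79$ mV lies just
above threshold, so the cell fires periodically. `isi_closed_form()` gives
the exact interval,
$t_{ref} + \tau_m \ln\big[(V_{init}-V_\infty)/(V_{TH}-V_\infty)\big]
\approx 98.58$ ms with $\tau_m = C_m/g_L \approx 21.1$ ms, i.e. roughly a
10 Hz pacemaker. The granule cell has $I_E = 0$ and $V_\infty = E_L = -74$ mV,
far below its −42 mV threshold: it never fires without synaptic input. Note
that the granule cell therefore *relaxes to $E_L$*, not to its initial
potential $V_{init} = -84$ mV; with these constants a resting granule cell
sits at −74 mV and every simulation reflects that.

Synapses are exponential conductances. An arriving spike increments the
receptor conductance by a fixed quantity $|w|$ and the conductance then
decays per step, $g(t+h) = g(t)\,e^{-h/\tau}$:

| parameter | excitatory | inhibitory |
|---|---|---|
| $V^{rev}$ | 0 mV | −85 mV |
| $\tau$    | 0.5 ms | 10 ms |
| $w$       | 20 nS | −10 nS |
| $g(0)$    | 0 nS | 0 nS |

Two conventions deserve a note. First, the printed inhibitory increment is
negative; a signed conductance in
$I_{syn} = g_{syn}(V_m - V^{rev}_{syn})$ would not self-consistently
hyperpolarize, so granlif stores conductance magnitudes and keeps polarity in
the reversal potential — excitation (reversal 0 mV) depolarizes, inhibition
(−85 mV) pulls $V_m$ down toward the reversal. This reproduces the expected
single-cell traces: a burst of spikes on an excitatory arrival, an
instantaneous hyperpolarizing dip on an inhibitory one (`simulate_neuron()`,
`exec/granlif validate-cell`). Second, the decay law is applied per elapsed
step ($e^{-h/\tau}$), so decay depends on elapsed time, not absolute time,
and composing $n$ steps of size $h$ equals one decay over $nh$.

Receptor slots follow the granular-layer wiring: a granule cell has 4
excitatory receptors (one per dendrite, fed by its glomeruli) and 4
inhibitory receptors (paired with the dendrites, fed by Golgi axons); a Golgi
cell has 2 excitatory receptors (slot 1: mossy-fiber input through its
dendritic glomeruli; slot 2: granule input via ascending axons and parallel
fibers) and one inhibitory receptor, which the default wiring leaves
unconnected because no source of Golgi inhibition is part of this circuit.

## Numerical integration

The subthreshold equation is linear, and granlif integrates it with implicit
(backward) Euler by default: all terms linear in $V$ are evaluated at $t+h$
with conductances frozen at their start-of-step values,

$$V(t+h) = \frac{V(t) + \frac{h}{C_m}\big(I_E + I_{inj} + g_L E_L + \sum_k g_k V^{rev}_k\big)}
{1 + \frac{h}{C_m}\big(g_L + \sum_k g_k\big)}.$$

Implicit Euler is unconditionally stable, which matters for the granule cell:
an excitatory arrival sets $g = 20$ nS against $g_L = 1.5$ nS and
$C_m = 3$ pF, giving an effective time constant of
$C_m/(g_L+g) \approx 0.14$ ms — close to the default step. A forward-Euler
variant (`scheme = "explicit"`) is available for comparison; both are first
order, and the test suite verifies that halving $h$ halves the error against
the exact exponential solution.

The default step is $h = 0.1$ ms (configurable). It resolves the fastest
synaptic time constant (0.5 ms) and makes the refractory periods exact
multiples of the step. One accuracy limit is worth knowing: the Golgi
pacemaker approaches threshold almost tangentially
($V_\infty - V_{TH} \approx 0.21$ mV), which amplifies the $O(h)$
integration bias in the *crossing time* to roughly $3h$ (≈0.32 ms at
$h = 0.1$ ms against the 98.58 ms closed form, shrinking linearly with $h$).
Simulated pacemaking is therefore accurate to a fraction of a percent in
rate, but not to within a single step in spike timing; the acceptance suite
records this measured bias explicitly rather than hiding it.

Threshold uses $V \ge V_{TH}$ exactly. During the refractory clamp only the
potential is frozen at $V_{init}$: conductances keep decaying and incoming
spikes still increment them, so stimuli arriving during the clamp shape the
potential immediately after it ends. The clamp countdown treats remaining
times below $10^{-9}$ ms as zero so that $t_{ref}$ equal to an exact multiple
of $h$ lasts exactly that many steps.

## Network reconstruction

Cells are placed uniformly at random in the box (more realistic placement
with soma exclusion is out of scope) and wired by rule:

1. every GRC sends exactly 4 dendrites to 4 distinct GLOs within 40 µm, at
   most one dendrite per GLO;
2. GLO→GRC divergence targets 1:53, enforced as a per-GLO capacity while
   feasible (see below);
3. every GOC dendritic tree samples 50 distinct GLOs within 100 µm;
4. every GOC axon inhibits at most 40 distinct GLOs within 150 µm, and a GRC
   is never inhibited twice by the same GOC (the axonal edge expands to the
   granule cells of each targeted glomerulus, on the inhibitory receptor slot
   paired with the dendrite, first occurrence kept);
5. every GOC receives 400 ascending-axon inputs from GRCs in a vertical
   column (lateral x–z distance ≤ 50 µm) and 1000 parallel-fiber inputs
   sampled from the whole volume.

Default densities are reverse-derived from the reference geometries
(counts ÷ volume): $4.0\times10^{-3}$ GRC/µm³, $9.0\times10^{-6}$ GOC/µm³,
$3.0\times10^{-4}$ GLO/µm³, and 20 glomeruli per mossy fiber. With them the
300×75×1200 µm³ preset yields 108,000 GRCs, 243 GOCs and 8100 GLOs
(`round(ρV)` puts the GLO count within one of the reference tabulation, which
prints 8099). The Golgi dendritic/axonal radii (100/150 µm) and the
ascending-axon column radius (50 µm) are configuration defaults chosen at
plausible anatomical scales; they are not derived quantities.

**Capacity saturation.** At the default densities the exactly-4 rule demands
$4\rho_{GRC}/\rho_{GLO} = 53.3$ dendrites per glomerulus on average — above
the 1:53 divergence treated as a hard capacity. The two rules are therefore
jointly infeasible by about 0.6%, and granlif resolves the conflict in favor
of the anatomically explicit exactly-4 rule: a granule cell that finds fewer
than 4 unsaturated glomeruli widens its search radius in 10 µm increments
(logged), and once every glomerulus within 80 µm is full it takes the
least-loaded in-range glomeruli (ties broken by index). The audit reports the
overflow count and the maximum load (54–55 in practice, i.e. ≤4% above
capacity); `allow_overflow = FALSE` turns saturation into an error instead.

Every connection carries a propagation delay drawn once at build time from
Uniform(0.1, 1) ms. The lower bound equals the default step, which guarantees
no spike can influence its own step (no same-step causality loops). A
per-event resampling mode exists for sensitivity checks; per-connection is
the default because fixed conduction delays are the physical interpretation.

Builds are deterministic: one seed drives placement, wiring and delays, and
identical (configuration, seed) pairs give byte-identical edge files.

## Stimulation protocols

Mossy fibers are the network's only input. Four standard protocols are
provided: `prot1` — 1 Hz Poisson background to every fiber; `prot2` — a
100 Hz, 50 ms Poisson burst to 10% of the fibers; `prot3` — background plus
burst to every fiber (a stress test); `prot4` — background to all plus burst
to 1%. Percentages round to the nearest fiber with a floor of one. The burst
is itself a Poisson process (≈5 spikes per 50 ms window on average, matching
the expected count at 100 Hz); a regular-train mode is available. Burst onset
is not part of the protocol definitions and defaults to 200 ms. Each fiber
gets an independent RNG substream spawned from the root seed, so spike times
differ across fibers even at equal rates and any train is reproducible in
isolation.

## The engine

Simulation is clock-driven. Pending spike arrivals live in per-(neuron,
receptor) queues, internally bucketed by integration step, and a step
consumes the half-open window $[t, t+h)$: coincident arrivals accumulate into
a count and bump the conductance by count × $|w|$. Each iteration follows the
two-population flow: collect Golgi flags → batch-update all GOCs → route GOC
spikes into granule inhibitory queues at $t + delay$ → collect granule flags
→ batch-update all GRCs → route GRC spikes into Golgi excitatory queues.
Mossy-fiber trains are expanded through the glomerular mapping and
pre-loaded into the excitatory queues at initialization, each arrival delayed
by its edge's propagation delay.

The batch updates can be split into `n_parts` contiguous blocks, mirroring a
multi-device decomposition in one address space. Because the per-neuron
update is elementwise and spike routing happens at a serial barrier in
(population, neuron id) order, the partitioned run is bit-identical to the
monolithic one — the test suite asserts raster equality for 1, 2 and 4
partitions. Queue accounting (scheduled = consumed + pending) is carried
through every run so spike conservation is checkable after the fact.

## Memory footprint

Each cell stores 7 cellular parameters plus 4 per receptor in single
precision (4 B), plus one 4 B flag per receptor: 156 + 32 = 188 B per granule
cell and 76 + 12 = 88 B per Golgi cell, hence
$\mathrm{RAM} = 88\,N_{GOC} + 188\,N_{GRC}$ bytes. `memory_estimate()`
reports MiB ($2^{20}$ B) with the third decimal truncated — the convention
that reproduces the reference footprints of the two larger presets exactly
(77.53 and 310.14 MiB). The reference figure for the smallest preset
(19.77 MB) is not consistent with the formula under any byte convention
(which yields 19.38 MiB); granlif reports the formula's value.

## What the synthetic networks do and do not show

The generator emulates the densities, convergence/divergence statistics and
spatial reach of granular-layer wiring, and the input statistics of standard
background/burst stimulation. It does not emulate somatic exclusion volumes,
anisotropic dendritic fields, glomerular clustering along mossy-fiber
rosettes, synaptic weight heterogeneity, or short-term plasticity. Passing
tests therefore demonstrate that the implementation obeys its stated rules
and dynamics — not that the emergent firing statistics quantitatively match
recordings from real tissue.

## Problem sizes and performance

The package is pure R with vectorized population updates. Reference points
on one CPU core: the full 300×75×1200 µm³ build (108k GRCs, ~2 million
edges) takes ~10 s; the 60×60×120 µm³ test geometry (1728 GRCs) builds in
under 0.1 s and simulates at roughly 6 s per simulated second at
$h = 0.1$ ms. The test suite runs its dynamical checks on the test geometry
(0.3–1 s of activity) and builds the full geometry once for connectivity
checks; those sizes are a deliberate choice to keep the suite fast while
still exercising every rule at scale.

## Known limitations

- Wall-clock performance of the original multi-GPU implementation is out of
  scope; the partitioned mode reproduces its decomposition semantics, not its
  speed.
- The Golgi inhibitory receptor is present in the memory model but never
  wired, because the circuit defines no source for it.
- Spike times are reported on the integration grid (the step in which the
  threshold crossing is detected).
- Capacity overflow (above) means per-glomerulus load can exceed 53 by a few
  dendrites at the default densities; the audit quantifies it per build.
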