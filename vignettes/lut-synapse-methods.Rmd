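---
title: "Look-up-table synapse models: methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Look-up-table synapse models: methods and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(synlut)
```

## The model

Glutamatergic receptor currents (AMPAr, NMDAr) are classically simulated by
integrating a Markov kinetic scheme: a state vector $P(t)$ over receptor
conformations obeying the master equation

$$\frac{dP}{dt} = G(L(t))\,P, \qquad G = G_b + L(t)\,G_l,$$

where $G_b$ collects ligand-independent transition rates, $G_l$ the
ligand-dependent ones, and $L(t)$ is the glutamate concentration in the
cleft. This is accurate but expensive: every synapse requires an ODE solve
at every time step of a network simulation.

The look-up-table (LUT) approach replaces the online ODE solve with a
precomputed table of *isolated pulse-response amplitudes*. The key
observations are:

1. The glutamate transient of a single vesicle release is stereotyped, so
   the response to a pulse depends only on the receptor's recent history of
   pulses, not on absolute time.
2. History older than a memory window $M$ (ms) is negligible: a receptor
   recovers to within a tolerance of its resting response.
3. Within the window, interpulse intervals can be quantized at a
   granularity $\delta$ (ms) with little loss, giving $R = M/\delta$
   discrete interval bins.

A model of order $N$ conditions each pulse's amplitude on up to $N - 1$
preceding pulses inside the window. The amplitude of an event preceded by
intervals $(\tau_1 < \dots < \tau_{N-1})$ is obtained at generation time by
simulating the full kinetic scheme for the $N$-pulse train and for the
$(N-1)$-pulse train without the newest pulse, subtracting, and taking the
peak of the difference after the last pulse (the *isolated* response). At
runtime the synapse replays that stored amplitude as a scale factor on a
fixed basis waveform, and output traces are the plain sum of the scaled
waveforms — superposition is linear once amplitudes are fixed.

### Indexing

Quantized intervals form strictly increasing 0-based bins
$t_n = \mathrm{round}_{half-up}(\tau_n/\delta) - 1 \in \{0, \dots, R-1\}$.
Each increasing tuple maps to a dense flat index by the combinatorial
number system:

$$\mathrm{index}(t_1, \dots, t_k) = \sum_{n=1}^{k} \binom{t_n}{n},$$

a bijection onto $[0, \binom{R}{k})$. An order-$N$ model stores one
sub-table per order $1 \dots N$; the dominant cost is the order-$N$
sub-table with $\binom{R}{N-1}$ doubles. For example
`table_size(300, 4)` is 4,455,100 entries (35.6 MB) and
`table_size(200, 5)` is 64,684,950 entries (517 MB) — the memory/accuracy
trade-off is explicit and computable in advance.

When two intervals round to the same bin, the later (older) one is bumped
to the next bin; if bumping runs past bin $R-1$ the oldest interval is
dropped. This keeps every runtime pattern inside the table's domain.

### Basis waveform

Stored amplitudes scale a normalized triple exponential

$$y(t) = F_{norm}\left(w\,e^{-t/T_{c2}} + (1-w)\,e^{-t/T_{c3}} -
e^{-t/T_{c1}}\right),$$

with rise constant $T_{c1}$ and a weighted pair of decay constants.
$F_{norm}$ normalizes the peak to exactly 1 and is computed at
construction by a 512-point coarse scan over $[0, 5\max(T_{c2}, T_{c3})]$
refined with bounded scalar optimization (`optimize`, tol $10^{-12}$). The
weighting factor defaults to $w = 0.963$.

Per-order time constants are fitted by exhaustive grid search minimizing

$$f(T_c) = \frac{|\gamma - \hat{\gamma}|}{\gamma} + \mathrm{NRMSE},$$

the equally weighted sum of the relative error in full duration at half
maximum (FDHM, $\gamma$) and the normalized root-mean-square error against
an average isolated waveform per order. Target waveforms for the fit are
obtained by `isolate_and_average()`: a Poisson train is simulated through
the kinetic scheme, each pulse's isolated contribution is extracted by
prefix subtraction, assigned an order (1 + in-window predecessors, capped
at $N$), and averaged within order.

## Parameters and defaults

| Parameter | Default | Units | Role |
|---|---|---|---|
| glutamate rise / decay | 0.1 / 1.2 | ms | biexponential transient shape |
| glutamate peak | 1 | mM | transient amplitude |
| `dt` | 0.1 | ms | simulation / trace step |
| memory window `M` | calibrated | ms | history horizon |
| granularity `delta` | user | ms | interval bin width |
| window tolerance | 0.02 | – | two-pulse recovery criterion |
| `w` | 0.963 | – | decay weighting |
| NMDAr `g1`, `g2` | 40, 247 | pS | conductance sigmoid bounds |
| NMDAr `alpha` | 0.1 | /mV | conductance sigmoid slope |
| `Mg_o` | 1 | mM | extracellular magnesium |
| `K0` | 3.57 | mM | Mg block IC50 scale |
| voltage slope | 0.062 | /mV | Mg block voltage dependence |
| `tau_vr` | 10 | ms | van Rossum kernel |
| LIF: C, g_leak | 100 pF, 10 nS | | point-neuron membrane |
| LIF: E_leak, V_thresh | −65, −50 | mV | rest and threshold |

The memory window is calibrated by `calibrate_memory_window()`: the
smallest $M$ such that a second pulse $M$ after the first has an isolated
amplitude within 2% of the unconditioned single-pulse amplitude, located
by a grid scan refined with bisection.

NMDAr conductance combines a voltage sigmoid
$g_0 = g_1 + (g_2 - g_1)/(1 + e^{\alpha V})$ with the divisive magnesium
block $g = g_0 / (1 + (\mathrm{Mg}_o / K_0)\,e^{-0.062 V})$; an additive
variant of the block denominator is available as
`receptor_params(mg_block = "literal")` for sensitivity analysis. Current
is $I = n_b (V - V_{rev})\, g \times 10^{-3}$ pA for $n_b$ channels.

## Synthetic generator realism

The package ships three synthetic kinetic schemes
(`synthetic_scheme()`) used as ground truth throughout the tests:

- **linear**: 2-state C↔O with low occupancy (`kon` 0.02/mM/ms), so
  responses superpose almost exactly — the null case where the LUT and a
  plain exponential synapse should coincide;
- **saturating**: 2-state with high binding (`kon` 5/mM/ms) and slow
  recovery, producing strong paired-pulse depression — the case the LUT is
  built for;
- **desensitizing**: 3-state C–O–D adding a slow desensitized state.

These are minimal schemes, not fitted receptor models: they reproduce the
qualitative nonlinearities (saturation, use-dependent depression, slow
recovery) that make table conditioning necessary, at a size where every
table entry can be verified against a direct ODE solve in the test suite.
Real AMPAr/NMDAr schemes have 7+ states; the machinery is identical, only
the YAML scheme definition changes. Note that even the "linear" scheme has
~0.1% paired-pulse depression at 5 ms intervals from residual occupancy.

Validation inputs are Poisson trains drawn as independent Bernoulli bins
($p = \mathrm{rate} \cdot dt \cdot 10^{-3}$), seeded without disturbing the
global RNG stream; defaults (rates 2–14 Hz, 20 s duration) reflect
physiological cortical rates where interpulse intervals regularly fall
inside the memory window.

## Numerical choices

- **ODE integration**: `deSolve::lsoda` with an analytic Jacobian,
  `rtol = 1e-9`, `atol = 1e-11`. Halving the output step changes the
  output trace by under 1% NRMSE (dominated by output-grid alignment, not
  solver error).
- **Table generation** simulates full pulse trains per entry rather than
  reusing sub-train results; slower but each entry is independently
  correct, which the test suite exploits by checking every entry of a
  small table against a from-scratch simulation.
- **Quantization** uses round-half-up (not banker's rounding) so bin
  boundaries are deterministic and platform-independent.
- **Grid search** is exhaustive and deterministic with lexicographic
  tie-breaking, so fitted banks are bit-reproducible. The default
  `tc_grid()` is large (~20M triplets); realistic fits should pass a
  narrowed grid. The test suite uses small explicit grids.
- **Storage** is a flat little-endian double payload plus a JSON sidecar
  carrying the structural header and an MD5 checksum; loading validates
  the checksum, counts and the integrality of $R = M/\delta$.
- **Problem sizes in the test suite** ($R = 10$, $N \le 3$, 2-state
  schemes) are chosen so the whole suite, including entry-by-entry table
  verification and a 7-rate × 20 s validation sweep, runs in minutes.

## Limitations

- Amplitude conditioning captures history effects on *peak* response;
  waveform *shape* changes with history are only captured per order via
  the basis bank, not per interval pattern.
- Additive superposition of scaled waveforms ignores driving-force
  interactions between temporally overlapping responses (conductance, not
  current, is tabulated — the driving force is applied afterwards).
- The stereotyped transient assumption excludes multivesicular release and
  spillover.
- Table memory grows as $\binom{R}{N-1}$: fine granularity and high order
  quickly become storage-bound, which is the central trade-off the
  `table_size()` / `table_bytes()` accounting exposes.
- The bundled schemes are deliberately small; quantitative conclusions
  about real receptors require user-supplied kinetic schemes.
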