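---
title: "Modelling ictal wavefront propagation: potassium diffusion versus synaptic spread"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling ictal wavefront propagation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`ictalwave` simulates epileptic ictal discharges (IDs) on a two-dimensional
sheet of cortical tissue with a spatially extended variant of the
Epileptor-2 neural-mass model. Five fields live on a regular grid: the
extracellular potassium concentration $[K]_o$, the intracellular sodium
concentration $[Na]_i$, the population membrane-potential deflection $V$,
the Tsodyks–Markram synaptic resource $x^D$, and the presynaptic firing
rate $\varphi$.

$$
\frac{\partial [K]_o}{\partial t}
  = D_K \nabla^2 [K]_o
  + \frac{[K]_{bath} - [K]_o}{\tau_K}
  - 2\gamma\, I_{pump} + \delta_K\, \theta(t)
$$
$$
\frac{d [Na]_i}{dt}
  = \frac{[Na]_{i0} - [Na]_i}{\tau_{Na}} - 3 I_{pump} + \delta_{Na}\,\theta(t),
\qquad
\tau_m \frac{dV}{dt} = -V + u(t)
$$
$$
\frac{d x^D}{dt} = \frac{1 - x^D}{\tau_D} - \delta_x\, x^D \varphi,
\qquad
\lambda^2 \nabla^2 \varphi = \varphi - \nu
$$

with the closures: a rectified sigmoidal rate
$\nu = \nu_{max}\,[2/(1+e^{-2(V - V_{th})/k_\nu}) - 1]_+$; the input current
(per leak conductance, in mV)
$u = g_{K,leak}(V_K - V_{K0}) + G_{syn}\varphi\,(x^D - c_{IE}) + \sigma\xi$;
the Nernst potential $V_K = 26.6\,\mathrm{mV}\,\ln([K]_o/130\,\mathrm{mM})$;
and the Na/K pump
$I_{pump} = \rho\,/\,[(1+e^{3.5-[K]_o})(1+e^{(25-[Na]_i)/3})]$.

Two propagation mechanisms compete. In the **diffusion model** (variant 1)
the only spatial coupling is lateral potassium diffusion; the rate driving
the ion balances is the local somatic rate ($\theta = \nu$, and $\varphi$
reduces to $\nu$ pointwise since the connectivity equation is switched
off). In the **synaptic model** (variant 2) the diffusion term is dropped
and the coupling is purely axo-dendritic: the screened-Poisson equation
turns the somatic rate into a presynaptic rate, equivalent to convolving
$\nu$ with the exponential connectivity kernel $e^{-r/\lambda}$, and
$\theta = \varphi$. The **combined model** (variant 3) keeps both.

The slow variables $([K]_o, [Na]_i)$ gate the fast subsystem $(V, x^D)$:
potassium creeps up toward the elevated bath value until, near 4 mM, the
potassium depolarisation lets noise-triggered bursts regenerate through
the depressing synaptic loop — an ID, a cluster of interictal-like bursts.
Sodium loading activates the pump, which terminates the event and drives
$[K]_o$ below baseline; the cycle then repeats. An adaptive quadratic
integrate-and-fire neuron-observer (`integrate_neuron()`) converts a
recorded input-current trace into a spiking membrane-potential trace.

## Numerics

* **Units.** Internally everything is in s, mm, mV, mM, Hz. `tau_m` is
  entered in ms and `D_K` in cm²/s (the conventional units) and converted
  at construction.
* **Grid.** Cell-centred, `dx = width/nx` (default 6 mm / 80 = 0.075 mm);
  5-point Laplacian with mirror (zero-flux) boundaries, which conserves
  total potassium exactly in pure-diffusion mode. The explicit stability
  bound `D_K dt/dx² < 1/4` is checked at configuration time.
* **Time stepping.** Explicit Euler–Maruyama with `dt = 1` ms. The noise
  term is one fresh N(0,1) draw per step entering `u` directly with
  amplitude `sigma_over_gL` (25 mV); this per-step convention at the
  reference `dt` gives a stationary voltage-noise SD of
  $\sigma\sqrt{dt/2\tau_m} \approx 5.6$ mV, which is what produces the
  observed burst statistics. A `sqrt_dt` scaling mode makes the statistics
  `dt`-invariant (it coincides with per-step at 1 ms). Spatially
  homogeneous noise (one draw shared by all cells) is the default;
  inhomogeneous noise draws independently per cell.
* **Elliptic solve.** The connectivity equation is linear with a
  time-independent operator, so the engine solves it exactly in the
  eigenbasis of the discrete Neumann Laplacian (a DCT-II basis;
  two small dense matrix products per step) instead of iterating Jacobi
  to tolerance at every step — the solutions agree with a dense direct
  solve to below 1e−8 relative error, and the classical Jacobi iteration
  is retained in `solve_presynaptic_rate(method = "jacobi")` as a
  reference path. A complete vertical cut splits the sheet into
  independent rectangles which are again separable (mixed
  Neumann/Dirichlet or Neumann/Neumann 1D bases, eigendecomposed
  numerically); only partial-segment lesions need the warm-started
  conjugate-gradient path (relative residual ≤ 1e−8).
* **Degenerate inputs.** `x^D` is clamped to [0, 1] after each step;
  non-finite fields abort the run with a diagnostic; a zero-duration run
  returns the initial state, with $\varphi$ solved from the initial rate
  field (the equation is algebraic in time, so no independent initial
  condition exists).

## Lesions

A lesion interrupts the axo-dendritic coupling. Partial segments follow
the literal prescription $\varphi = 0$ on the rasterised cells (Dirichlet
rows in the elliptic system). For a *complete* transection two styles are
available: `"cells"` (a deadened cell column, as for segments) and
`"edges"` (a blade cut: the coupling across one inter-column interface is
severed while the tissue on both sides stays alive — no-flux faces in the
elliptic operator, and, when `blocks_diffusion = TRUE`, in the potassium
Laplacian too). The bundled `complete_lesion` preset uses the blade-cut
style: with a dead column in between, the potassium that crosses the cut
is diluted by a strip of tissue that cannot fire, and the recruitment of
the far side — the phenomenon the setup exists to show — depends
sensitively on that extra half-kernel of separation.

The `complete_lesion` preset also sets `K_o0 = 4` mM: in the zoned-bath
setup the dish perfuses the tissue at 4 mM and only the central zone's
effective bath is elevated to 7 mM, so both the initial condition and the
reference potential `V_K0` of the potassium depolarising term belong at
4 mM. Referencing them at the standard 3 mM would impose a permanent
~18 mV depolarisation on the whole periphery (`g_{K,leak}/g_L = 3` in
this preset) and make the far territory self-ignite, which is not the
intended physics of the lesion experiment. A related option
(`domain$init_K = "bath"`) initialises every cell at its local bath value
with a per-cell reference potential.

## Measurements

* `detect_discharges()` scores IDs on a potassium trace: onset at an
  upward 4 mM crossing, offset below 3.5 mM (0.5 mM hysteresis), events
  closer than 5 s merged. The 4 mM default is the model's own ignition
  threshold; the hysteresis guards against burst-scale chatter.
* `rate_onsets()` detects ignition independently of the potassium
  threshold: sustained elevation of the 2-s-smoothed firing rate above
  10 Hz for at least 5 s, with the onset taken at the first raw burst
  inside the episode (centred smoothing would otherwise advance the edge
  by up to half a window). The potassium value at those onsets is the
  measured ignition threshold.
* `front_arrival_times()` thresholds snapshot stacks along a ray from
  the excitation centre, interpolating linearly between snapshots, and
  requires a *fresh* upward crossing inside the per-wave window so that
  residual elevation from the previous wave is never scored as an
  arrival. `wavefront_speed()` fits distance against arrival time over
  0.5–2.5 mm by default — past the initiation disk, clear of the
  boundary, in the constant-profile regime of the travelling pulse.
* `envelope_arrival_times()` measures the *slow* wave: the time-averaged
  firing rate between snapshots (recorded alias-free by the engine as
  `nu_env`), smoothed over 3 snapshots and thresholded at 5 Hz.
  Individual bursts invade the penumbra almost instantaneously — that is
  precisely the core/penumbra physics — so an instantaneous-rate
  threshold would see a near-infinite speed; sustained mean rate marks
  actual recruitment, and its front tracks the potassium wave.
* `space_time_pattern()` / `burst_inclination()` quantify the y–t burst
  diagram of a fine-cadence strip capture: the inclination (s/mm) of a
  burst stripe is the reciprocal of its propagation speed, ~0 for the
  near-synchronous intra-ID bursts, against seconds-per-mm for the ictal
  front itself. `burst_synchrony()` makes the same point from probe
  pairs: sub-second matched burst delays against multi-second ID-onset
  delays.

## What the simulations show, and problem sizes

On the standard domain the diffusion model produces thin, slow potassium
waves (~0.02 mm/s at the physiological `D_K = 4e-6` cm²/s in this
implementation, scaling as $\sqrt{D_K}$), with ~17 s discharges roughly
every two minutes; the synaptic model produces broad waves an order of
magnitude faster (~0.09–0.10 mm/s at `lambda = 0.385` mm), ~40 s
discharges every ~210 s, and a slow envelope wave slightly faster than
the potassium front. Adding diffusion on top of the synaptic mechanism
(variant 3) changes the speed by less than the seed-to-seed spread —
potassium diffusion does not set the ictal wavefront speed. Disinhibition
(`c_IE` from 0.7 to 0.3 on the narrow strip) accelerates the front more
than twentyfold. Wavefront speed is *noise-mediated* in both mechanisms:
with `sigma_over_gL = 0` a front does not propagate at all, because the
deterministic potassium depolarisation alone never crosses the firing
threshold; quantitative speeds therefore inherit the stochastic
convention above.

These behaviours are exercised by the test-suite at the following sizes,
chosen to keep the full suite within minutes while leaving every
phenomenon measurable: full 80×80 runs of 380 s (diffusion model) and
550 s (synaptic model) for the headline statistics; 80×8 narrow-strip
runs of 160–300 s for parameter sweeps (the strip preserves `dx` and the
disk size, and quasi-1D confinement raises absolute speeds roughly
twofold, which is why sweeps compare like with like on the strip);
20×20 grids for operator oracles. `scripts/acceptance.R` re-runs the full
measurements from scratch (three seeds for the wave speeds) and writes
them as JSON.

The synthetic-data side of testing uses constructed fields — translating
tanh fronts, square pulses, shifted burst trains — with known ground
truth; estimator accuracy (2% on front speeds across 0.01–10 mm/s) is
established there. What passing tests on synthetic and simulated data do
*not* show is fidelity to real cortical tissue: the model has a single
implicit inhibitory population, no chloride dynamics, a phenomenological
potassium source term, and isotropic local connectivity.

## Known limitations

* Quantitative wavefront speeds in the diffusion model sit around half
  the values usually quoted for comparable settings; they depend on the
  noise-ignition rate at the front (see above), which is the least
  constrained ingredient of the model. Orderings and scalings
  ($\sqrt{D_K}$, $\propto\lambda$, anti-monotone in $c_{IE}$) are robust.
* The representative neuron's drive gain (pA per mV of population `u`)
  is a free coupling; the default 10 pA/mV is chosen so that an ID
  elicits burst-clustered spiking, and is overridable.
* Event detectors assume uniformly sampled traces; probes record every
  step by default.
* No axonal conduction delays (negligible against the membrane time
  constant) and no electrodiffusion of potassium —
  `electrodiffusion_speed()` reproduces the order-of-magnitude argument
  (µm/s) for why the latter is omitted.
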