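---
title: "Equation-free macroscopic analysis of a striatal network model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equation-free macroscopic analysis of a striatal network model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`striatnet` simulates a spatially embedded network of striatal neurons and
analyses its collective dynamics without ever deriving closed macroscopic
equations. The microscopic model has three layers.

**Membrane dynamics.** Each neuron obeys a current-balance equation

$$C\,\dot V_i = -I_{leak} - I_{K} - I_{Na} - I_{M/D} - I_{syn} + I_{app},$$

with conductance-based currents in the Hodgkin-Huxley formalism:
$I_{Na} = g_{Na} m_{Na}^3 h_{Na}(V - E_{Na})$,
$I_K = g_K m_K^4 (V - E_K)$, $I_{leak} = g_{leak}(V - E_{leak})$. Medium
spiny neurons (MSN, the striatal projection class) carry a non-inactivating
M-type potassium current $I_M = g_M m_M (V - E_K)$; fast-spiking
interneurons (FS) carry a D-type current $I_D = g_D m_D^3 h_D (V - E_D)$
that delays firing on depolarisation. Gating variables relax as
$\dot x = a_x(V)(1 - x) - b_x(V)x$ with the standard rational/exponential
rate functions; the removable singularities of the $a$ functions (e.g. at
$V = -54$ mV for $m_{Na}$) are evaluated by their analytic limits. The
applied current $I_{app} = I_0 + I_{DBS}$ combines a constant network
activation current $I_0$ — the proxy for cortico-striatal drive and the
bifurcation parameter of the whole analysis — and an optional stimulation
current.

Two deliberate modelling choices deserve flagging. First, the M-gate rate
functions are taken identical to the delayed-rectifier rates, exactly as in
the source model specification; this makes the M-current fast rather than
slow, and is kept for fidelity (the conventional slow M-current kinetics
can be substituted through `membrane_params()`). Second, the D-gate
kinetics are not specified anywhere in the source material; we use
first-order relaxation to sigmoid steady states
($m_D$: half-activation $-50$ mV, slope 20 mV, $\tau = 2$ ms; $h_D$:
half-inactivation $-70$ mV, slope $-6$ mV, $\tau = 150$ ms), which
reproduces the fast-activating, slowly-inactivating phenotype. These
constants live in one config block and are explicitly not ground truth.
The membrane capacitance is not stated in the source and defaults to the
standard $C = 1\,\mu F/cm^2$.

**Synapses.** All coupling is GABAergic and inhibitory
($E_{GABA} = -80$ mV). Each neuron carries one presynaptic activation
$s_i \in [0,1]$ with
$\dot s_i = \alpha_X (1 - s_i) H_X(V_i) - \beta_X s_i$, where the release
sigmoid is $H_M(V) = 1 + \tanh(V/4)$ for MSN and $H_F(V) = 1 + \tanh(V/10)$
for FS terminals. $H$ ranges over $[0,2]$ as printed in the source model —
it is deliberately not normalised to $[0,1]$, so the saturated activation
is $2\alpha/(2\alpha + \beta)$ rather than $\alpha/(\alpha+\beta)$.
Postsynaptic currents sum presynaptic activations over incoming edges,
$I_{syn,i} = \sum_Y g_{XY}(V_i - E_{GABA})\sum_{j \in Y} A_{ij} s_j$, with
$g_{MM} = g_{MF} = 0.02$ and $g_{FF} = g_{FM} = 0.005$ (treated as
mS/cm², the reading consistent with the other units).

**Connectivity.** 1995 neurons (1856 MSN + 139 FS by default — the stated
explicit counts; the nominal "95%/5%" split is inconsistent with them and
both are configurable) are placed uniformly in an ellipsoidal volume. Each
MSN sends edges to its 20 nearest neighbours within a local neighbourhood
of 5 mm diameter; each FS to its 100 nearest (the five-fold higher
interneuron connectivity). Each local edge spawns, with probability
$p = 0.05$, an additional edge to a uniformly chosen remote neuron — the
small-world shortcut; the local edge is kept. Directionality follows
$A_{ij} = 1$ for an edge $j \to i$; $k$ counts outgoing edges. Ties in
nearest-neighbour distance break toward the lower index.

## The synthetic volume

The anatomical geometry (an atlas-derived striatum surface) is out of
scope; `generate_positions()` replaces it with uniform sampling in an
ellipsoid, and `read_positions()` imports arbitrary 3-D coordinates for
users who do have anatomical data. The default semi-axes (6, 4, 3) mm were
chosen once so that the volume is compact and striatum-like while dense
enough that every neuron — including every FS with $k = 100$ — finds its
full complement of neighbours inside the 5 mm neighbourhood; in a sparser
volume the builder degrades gracefully (connect to all available,
warn). What the synthetic volume does *not* emulate: the elongated
caudate/putamen geometry, anatomical gradients in cell density, and any
correspondence between coordinates and real anatomical space. Tests passing
on this geometry therefore validate the algorithms, not anatomical claims;
electrode positions in particular are meaningful only relative to the
chosen volume, which is why the default electrode sits at (2, 1, 1) mm
inside the default ellipsoid.

## The equation-free layer

The macroscopic variable is the mean synaptic activity of the MSNs,
$S_t = \frac{1}{N_{MSN}}\sum_{i \in MSN} s_i(t)$ (`restrict_state()`), a
quantity akin to a local field potential. The divisor is the number of
MSNs — the natural reading for a variable bounded in $[0,1]$; dividing by
the total count is available as an option.

The coarse timestepper composes lift, evolve, restrict:

1. **Reference microstates.** For each $I_0$ the network is integrated for
   a 20 ms settling period from a seeded random initial condition and the
   terminal microstate recorded (`make_reference_state()`).
2. **Lifting.** `lift_state()` copies a reference and overwrites every
   MSN's $s_i$ with $S + 0.05\,Z_i$, $Z_i \sim N(0,1)$, clipped to
   $[0,1]$; membrane potentials, gating variables and FS synapses are left
   untouched. Clipping is a choice: values outside $[0,1]$ are dynamically
   meaningless and the kinetics would expel them anyway. The resulting
   boundary bias is exactly the truncated-normal mean
   ($\approx 0.05\,\varphi(0) = 0.0199$ at $S = 0$) and is measured by the
   tests; away from the boundaries $E[R(L(S))] = S$ to within
   $0.05/\sqrt{N_{MSN}}$.
3. **Ensembles.** Each mesh point is evaluated with 20 independent
   realizations. Each realization uses its *own* reference microstate
   (a seeded pool of references per $I_0$), so the ensemble spread reflects
   genuine microstate variability rather than lifting noise alone — with a
   single shared reference the relative standard error collapses to a few
   hundredths of a percent and overstates the estimator's precision. With
   per-member references the relative ensemble error at a mid-mesh state is
   a fraction of a percent, which is what the acceptance checks measure.

The drift is the finite difference $f(S, I_0) \approx (F_T(S) - S)/T$ over
a coarse horizon of $T = 5$ ms (`estimate_f()`). $T$ is a compromise: long
enough for the fast degrees of freedom to become enslaved to $S$, short
enough that $S$ itself moves little (the chord $(F_T(S)-S)/T$ estimates
the drift with an $O(T)$ bias proportional to $f f'$); no separate healing
interval is used. `horizon_diagnostic()` makes the choice auditable: it
reconstructs $f$ at $T$ and $2T$ and flags mesh points where the two
disagree beyond their combined error bars. For this network at $T = 5$ ms
the diagnostic does reveal residual horizon sensitivity, visible also as a
small systematic offset ($\approx 0.05$ in $S$) between the drift zero and
the long-run attractor of direct simulations: lifting replaces the
heterogeneous per-neuron activation pattern of the true attractor with a
homogeneous cloud, and the 20 ms reference settling leaves the slowest
gating variables (FS D-inactivation, $\tau = 150$ ms) short of
equilibrium. Both are intrinsic to the explicit lift-evolve-restrict
protocol at these settings and are reported, not hidden. Fixed points are zeros of $f$ located by sign changes on
the mesh and refined on a monotone cubic interpolant (`splinefun`,
monoH.FC) by bisection to $10^{-3}$; the interpolant slope at the zero
gives macroscopic stability (stable iff negative). Zeros whose
neighbourhood satisfies $|f| < 2\times$ the local standard error are
flagged *marginal* — indistinguishable from a tangency at the available
ensemble resolution — instead of being split into spurious pairs.
`bifurcation_scan()` repeats this over an $I_0$ grid, brackets the
parameter where the fixed-point count drops from two-or-more to zero, and
bisects the bracket; inconsistent count patterns along the grid (e.g.
2, 1, 2) are flagged and the bracket widened.

All of this machinery is exercised against an independent oracle: a
`drift_stepper()` whose "microscopic" system is a particle cloud evolving
under an exactly known scalar ODE $S' = \mu - (S - 0.5)^2$. The
reconstruction must recover that drift within its error bars and the scan
must locate the saddle-node at $\mu^* = 0$; this separates the correctness
of the equation-free layer from the physics of the network beneath it.

## What the default constants actually produce

Run at the default microscopic constants, the package's own analysis finds
a *single* stable macroscopic branch: $S^*(I_0)$ rises smoothly from
quiescence (below $I_0 \approx 5$) through $S^* \approx 0.40$ at
$I_0 = 10$ to $\approx 0.75$ at $I_0 = 20$, with no unstable low-activation
state and no saddle-node — the census of drift zeros at
$I_0 = (8, 10, 12, 13.5)$ is $(1, 1, 1, 1)$. The reason is quantitative
and worth recording. A bistable regime of the kind expected from a strong
feed-forward interneuron loop requires the FS population to hold the MSNs
quiescent at drives well above the single-MSN rheobase
($\approx 3$–$4\,\mu A/cm^2$ here). The aggregate FS$\to$MSN conductance
available per MSN is bounded by
$k_{FS}\cdot n_{FS}/n \cdot g_{MF} \approx 100 \cdot 0.07 \cdot 0.02
\approx 0.14$ mS/cm² — about 3–4 µA/cm² of inhibitory current at
physiological driving force, several-fold short of what state-dependent
silencing at $I_0 \approx 10$–13 would require. We verified that none of
the ambiguous-connectivity readings (outgoing vs. incoming vs. symmetrised
interneuron links, restricting $I_0$ to MSNs) closes this gap. The levers
that would (larger $g_{MF}$, more interneurons, larger FS out-degree) are
all exposed in the configuration, so the bistable regime is reachable for
users who wish to explore it — but the defaults stay faithful to the
stated constants, and the package reports what they produce.

The activated state does carry a robust population rhythm: the spectrum of
the mean membrane potential at $I_0 = 10$ peaks far above the 30 Hz gamma
floor (at the population firing frequency, $\sim$130–140 Hz under the
defaults).

## Deep-brain stimulation and closed-loop control

The stimulation current is a pulse train with Gaussian spatial decay,
$I_{DBS,i} = A\,e^{-\|x_i - x_E\|^2/\sigma^2}
H(\sin\omega t)\bigl(1 - H(\sin(\omega t + \delta))\bigr)$, $H$ the
Heaviside step. The pulse is on for a fraction $\delta/2\pi$ of each
period; the default $\delta = 0.2\pi$ gives 10% duty — short periodic
pulses rather than a plain harmonic. The decay length $\sigma$ is not
specified in the source; the default 2 mm confines the field to a few
millimetres, consistent with near-electrode stimulation. Frequency is
specified via the period in ms ($\omega = 2\pi/T_{DBS}$), with clinical
presets at 130 Hz and 200 Hz and a literal preset $T_{DBS} = 130$ ms for
users wanting the verbatim low-frequency variant of the published formula
(the source is internally inconsistent about these units).

Closed-loop control treats the amplitude as a state variable,
$\dot A = -K_p (S(t) - S^{*})$, co-integrated with the network (same RK4
step), clamped to actuator bounds, and activated at $t_{on}$ (150 ms by
default) after an open-loop epoch. $S(t)$ is measured every integration
step without sensor noise or delay. Under the defaults, open-loop
stimulation at $A = 200$ raises mean synaptic activity and induces strong
near-electrode synchrony (index $\approx 0.6$); switching the feedback on
drives the amplitude down, lowers time-averaged $S$ and destroys the
stimulus-locked synchrony (index $\approx 0.01$) — the qualitative
closed-loop contract the tests assert.

## Numerical choices

* **Integrator:** fixed-step classical RK4, $dt = 0.025$ ms, compiled
  (Rcpp). The scheme and step are configurable; halving $dt$ changes the
  terminal state at fourth order on smooth intervals (asserted by the
  tests). Non-finite states abort with the offending time and neuron.
* **Observables** are recorded every 0.5 ms to bound memory; spikes
  (upward crossings of $-15$ mV with a below-threshold reset guard) are
  detected on the full-resolution trace inside the integrator. Running
  minima/maxima of every bounded variable are tracked at every step so
  invariant checks cover the whole trajectory, not just snapshots.
* **Determinism:** every stochastic ingredient (positions, labels,
  rewiring, initial conditions, lifting noise) draws from substreams
  derived deterministically from a master seed; mesh-point substreams are
  keyed by the mesh *value*, so results are independent of mesh ordering
  and repeated points reproduce exactly. Identical configuration and seed
  give bit-identical trajectories and edge lists.
* **Problem sizes in the shipped checks:** the drift curve at the primary
  operating point uses the full 1995-neuron network, 21 mesh points and 20
  realizations; census and scan curves use an 11-point mesh; the
  scaled-down `mini_striatum` fixture (200 neurons, degrees 8/40, same
  MSN fraction) carries the cheap structural tests. These sizes are the
  package's chosen defaults for its own validation runs.

## Known limitations

* No synaptic plasticity, transmission delays, channel noise or
  multi-compartment morphology; stochasticity enters only through initial
  conditions, network realization and lifting.
* The macroscopic description is one-dimensional by construction; no
  data-driven coordinate discovery is attempted, and regimes where one
  scalar is insufficient (e.g. strongly synchronised states, where $S$
  oscillates) are summarised only through their time averages.
* The saddle-node machinery assumes the two-to-zero fixed-point pattern;
  richer bifurcation structures are flagged but not continued.
* The D-current kinetics and the membrane capacitance are conventional
  defaults, not fitted constants; conclusions sensitive to FS spike timing
  should be checked against their configuration block.
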