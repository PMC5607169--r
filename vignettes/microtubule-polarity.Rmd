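---
title: "Microtubule-based spontaneous cell polarity: model, theory and simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microtubule-based spontaneous cell polarity: model, theory and simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`mtpolarity` implements a minimal activator-depletion mechanism for
spontaneous cell polarity in which the "activator" transport route is
mediated by dynamic microtubules rather than by diffusion. A circular
(simulation) or spherical (theory) cell of radius $R$ contains a central
point-like centrosome with $M$ nucleation sites, each supporting at most one
microtubule (MT). An empty site fires with rate $r_n$; an MT then follows
two-state dynamic instability with growth speed $v_+$, shrink speed $v_-$,
catastrophe rate $r_+$ and rescue rate $r_-$. When a growing tip reaches the
cell boundary it stalls ("paused"), and resumes shrinking with a release
rate that depends on the local membrane density $c_b$ of a single conserved
molecular species, the polarity factor (PF):

$$ r_u(c_b) = (r_u(0) - r_u(\infty))\,\sigma(c_b/c_*) + r_u(\infty),
   \qquad \sigma(\gamma) = \frac{1}{1+\gamma^p},\; p > 1 . $$

PFs in the interior bind the MT arbor in fast equilibrium (bound fraction
$l_{tot}/(l_{1/2} + l_{tot})$ of the interior pool, where $l_{tot}$ is the
total MT length and $l_{1/2}$ an affinity half-length), ride towards plus
ends at speed $v_m$, and are deposited into the membrane wherever an MT is
stalled — or simply fall off at an interior tip. Membrane PFs diffuse along
the boundary with angular diffusion constant $D$ and unbind (recycle) with
rate $k_u$. The total number $C$ of PFs is strictly conserved.

High local PF density stabilises stalled MTs, which deliver more PFs there:
a positive feedback. The conserved pool provides the global inhibition: a
growing patch depletes the supply available elsewhere. Polarity can
therefore emerge spontaneously, but only in an intermediate range of PF
abundance — too few PFs cannot activate a patch, too many saturate the
stabilisation everywhere (reentrance).

### Parameters

| symbol | code | default | units | meaning |
|---|---|---|---|---|
| $R$ | `R` | 3 | um | cell radius |
| $v_+$ | `v_plus` | 0.018 (alt 0.013) | um/s | growth speed |
| $v_-$ | `v_minus` | 0.045 (alt 0.040) | um/s | shrink speed |
| $r_+$ | `r_cat` | 0.0078 | 1/s | catastrophe rate |
| $r_-$ | `r_res` | 0.0016 | 1/s | rescue rate |
| $r_n$ | `r_nuc` | 0.05 | 1/s | nucleation firing rate |
| $M$ | `M` | 1000 | — | nucleation sites / membrane segments |
| $v_m$ | `v_m` | 0.81 | um/s | PF transport speed |
| $k_u$ | `k_u` | 0.07 | 1/s | membrane unbinding rate |
| $D$ | `D_ang` | 0.02 | rad^2/s | angular membrane diffusion |
| $l_{1/2}$ | `l_half` | 150 | um | binding affinity half-length |
| $2\pi c_*$ | `c_star` ($\times 2\pi$) | 20000 | PF | feedback density scale |
| $C$ | `C_total` | scanned | PF | conserved total |
| $p$ | `p` | 5 | — | Hill coefficient |

The diffusion entry is interpreted as an *angular* constant so that the
composite displacement parameter is $\delta = D/k_u = 0.286$ directly; a
translational reading ($D_b/R^2$) is available through the
`d_is_angular: false` configuration flag.

The boundary-release rates $r_u(0), r_u(\infty)$ are not fixed by any
measured quantity; only the dimensionless combinations below matter. The
package calibrates them via `calibrate_feedback()`: given a target
competition parameter $\eta$ (default 0.322) and a ratio
$\rho = r_u(\infty)/r_u(0)$, it solves the closed form of $\eta$ for
$r_u(0)$. The default $\rho = 0.1$ (giving $r_u(0) \approx 0.0102$/s) was
chosen because the resulting isotropic self-consistency map reproduces the
reference abundance-to-density pairs
$C = 30000, 37000, 50000 \mapsto \bar\gamma = 0.923, 1.288, 1.853$ to about
0.1%, which pins the remaining degree of freedom; $\rho = 0.2$, for
comparison, misses these pairs by 25–50%.

## Mean-field theory

### Steady state of the MT population

For one site at fixed reduced density $\gamma$, the stationary length
densities of growing and shrinking MTs obey a two-state transport balance.
Because nucleation injects at the centre and pausing returns MTs at the
boundary, the net radial flux vanishes identically, forcing
$v_+ m_+(r) = v_- m_-(r)$ and
$m_\pm(r) \propto e^{-\lambda r}$ with
$\lambda = r_+/v_+ - r_-/v_-$. Bounded growth requires $\lambda > 0$, and
the unconfined mean length is $1/\lambda$ (1.79 um and 2.51 um for the two
default speed pairs). Normalising yields the state probabilities in closed
form, parameterised by

$$ \mu_b = e^{-\lambda R}, \qquad
   \mu_i = r_n\left(\tfrac1{v_+}+\tfrac1{v_-}\right)
           \frac{1-e^{-\lambda R}}{\lambda}, $$

the probability that a nucleated MT reaches the boundary and the mean
interior dwell per firing, respectively. The paused probability is
$P_{b}(\gamma) = r_n \mu_b / (r_u(\gamma)(1+\mu_i) + r_n\mu_b)$, and the
expected arbor length follows from the first moments (`mt_meanfield()`).
`lambda <= 0` raises an error in this layer; the simulator still accepts it
because the boundary caps all lengths.

### Isotropic state and linear stability

The membrane balance
$D\Delta c_b - k_u c_b + v_m c_m m_b(\gamma) = 0$, with
$c_m = C_m/l_{tot}$ the bound-PF line density and $m_b = \tfrac{M}{2\pi}P_b$
the boundary MT density, always admits an isotropic solution: a scalar
fixed point in the membrane total $C_b$ solved by sign-change scan plus
bisection (`isotropic_solution()`), with local stability read off the flux
derivative. Starting from an empty membrane the simulation relaxes to the
first root, which defines the mapping $C \mapsto \bar\gamma$ used to label
abundances (`gamma_from_C()`); it is non-decreasing in $C$.

Linearising around the isotropic state in an angular mode $n \ge 1$ (whose
perturbations of all global pools vanish by symmetry) gives a Helmholtz
problem whose squared wavenumber works out to

$$ \Omega^2(\gamma) = \gamma\,\frac{d\ln m_b}{d\gamma} - 1
 = \frac{p\,\gamma^p}{(1+\gamma^p)\,\bigl(1+\eta\,(1+\gamma^p)\bigr)} - 1,
 \qquad
 \eta = \frac{\rho + \mu_b r_n /\bigl((1+\mu_i) r_u(0)\bigr)}{1-\rho}. $$

The mode is unstable — the cell polarises — when
$\Omega^2 > L\,\delta$ with Laplacian eigenvalue $L = n^2$ on the circle
and $n(n+1)$ on the sphere; dimensionality enters only through $L$.
Closed-form consequences implemented in `polarization_criteria()`:
$\eta < (p-1)^2/(4p)$, $\gamma > (p-1)^{-1/p}$, $p > 1$, and for the
spherical unipolar mode at $\eta \to 0$, $\delta < (p-1)/2$.
`phase_boundary()` returns the 0, 1 or 2 roots of
$\Omega^2(\gamma) = L\delta$; two roots delimit the reentrant window (for
the reference values $p=5$, $\eta=0.322$, $\delta=0.286$, $n=1$ on the
circle: $\gamma \in (0.917,\,1.446)$).

Because the algebra above was derived here rather than copied, it is
anchored by two independent cross-checks in the test suite: the printed
closed-form limits, and `omega_squared_numeric()`, which re-derives
$\Omega^2$ by centred finite differences of the fully discretised membrane
balance (all global pools recomputed from the perturbed field) and agrees
to $10^{-6}$.

## The stochastic simulator

`run_simulation()` advances all particles with a fixed time step:

1. **MT update** (per site): the state transition is sampled first with
   exact per-step probability $1-e^{-r\,\Delta t}$, then the length moves
   under the new state; growth caps at $R$ (paused), shrinkage floors at 0
   (empty). Ties (catastrophe sampled in the step that would have reached
   the boundary) resolve in favour of the sampled transition; the effect
   vanishes as $\Delta t \to 0$ and is covered by a step-halving test.
2. **Binding equilibrium**: the bound count is reset to
   $\mathrm{round}(C_{int}\, l_{tot}/(l_{1/2}+l_{tot}))$.
3. **Transport and delivery**: bound PFs advance by $v_m \Delta t$;
   those passing a stalled tip enter the membrane segment of that site,
   those passing an interior tip return to the free pool.
4. **Membrane step**: each membrane PF independently unbinds with
   probability $k_u \Delta t$ or moves by a displacement drawn from the
   exact circle-diffusion law.
5. **Recording** of the order parameter
   $S_1 = |\langle e^{i\theta}\rangle|$, pool sizes, histogram.

Exact integer conservation of $C$ is asserted at every step. A run is a
deterministic function of the configuration and the integer seed (the
engine uses a dedicated xoshiro256+ stream seeded from it).

### Transport modes

Two interpretations of "fast binding equilibrium plus directed transport"
are provided. The default, `transport = "refresh"`, redraws every bound
PF's position from the equilibrium distribution (uniform on the arbor) each
step: in the fast-exchange limit a bound particle unbinds and rebinds many
times per step, so positions decorrelate, and the realised delivery flux
equals the mean-field kernel $v_m c_m m_b$ exactly (verified to within
Monte-Carlo error by the flux counters). The alternative,
`transport = "track"`, preserves in-transit positions; uniform injection
plus advection then accumulates particles towards the tips (line density
rising roughly linearly toward the plus end), inflating delivery by a
factor up to ~2 and shifting the isotropic membrane level ~15% above the
mean-field fixed point. Because the package's theory layer — like the
mean-field treatment it implements — assumes the equilibrium kernel, and
because only the refresh mode reproduces the reference
abundance-to-density mapping, refresh is the default; track mode remains
available for studying the slow-exchange regime.

### Membrane diffusion at segment resolution

All couplings go through per-segment densities (the local density is the
3-segment cyclic average $c^m = (C_b^{m-1}+C_b^m+C_b^{m+1})/(3\Delta\theta)$,
which integrates back to the membrane total exactly), so PF angular
positions are kept at segment resolution. One diffusion update therefore
moves a particle by a whole number of segments, with *exact* probabilities
obtained by integrating the circle heat-kernel CDF

$$ P(\delta\theta) = \frac{\delta\theta}{2\pi} + \frac1\pi \sum_{n\ge1}
   \frac{e^{-n^2 D\Delta t}}{n}\,\sin(n\,\delta\theta) $$

over the segment bins (`segment_offset_probs()`), sampled through a Walker
alias table. The series is truncated once $e^{-n^2 D\Delta t} < 10^{-16}$;
the inverse-CDF sampler (`sample_wrapped_displacement()`) bisects to
$10^{-10}$ and is validated by Kolmogorov–Smirnov tests against the dual
(Gaussian-image) representation of the same kernel at
$D\Delta t \in \{10^{-3}, 0.1, 10\}$.

### Controls and observables

Two no-polarization controls are implemented:

* `mode = "homogenized"` redistributes the membrane pool uniformly
  (multinomially) over the segments after every step, preserving its
  total. The recorded $S_1$ is then the pure finite-number counting floor,
  $E[S_1] \approx \sqrt{\pi/(4 C_b)}$.
* `mode = "feedback_cut"` lets the membrane field evolve freely but shows
  every MT the spatially uniform mean density, severing the feedback loop
  while retaining the dominant small-$M$ noise source: stalled MTs deliver
  in long bursts (residence $1/r_u \sim 10^2$–$10^3$ s) at discrete
  angles, producing transient density bumps. This baseline is what
  polarization must exceed at small $M$, and subtracting it (plain
  subtraction of mean curves, via `scan_abundance()`) is what makes
  order-parameter curves comparable across different $M$.

`drift_correct()` re-phases boundary histograms by the argument of their
first circular Fourier mode before averaging, since a polarized patch
performs a slow angular random walk. `ensemble_stats()` aggregates
per-run time averages into mean ± SEM over seeds.

## Numerical choices and degenerate inputs

* Step size: the engine enforces
  $\Delta t \cdot \max(r_n, r_+, r_-, r_u(0)) < 0.1$ and
  $k_u \Delta t < 1$. The fine default is $\Delta t = 0.05$ s; the
  package's own scans use $\Delta t = 1$ s, validated by a step-halving
  comparison of stationary pools (the slowest rates in the reference set
  are $\sim 10^{-2}$/s, so even 1 s resolves every process).
* Equilibration: runs start from the empty state (no MTs, all PFs free)
  and discard the first half by default; summaries carry an
  `equilibration_suspect` flag raised when the first and second halves of
  the measurement window disagree by more than three naive standard
  errors (a heuristic — the order parameter is autocorrelated — backed by
  the full recorded time series).
* Root finding: bisection/`uniroot` to relative $10^{-10}$ on the
  log-density axis for `phase_boundary()`, on the pool axis for
  `isotropic_solution()` (512-point bracketing scan; all fixed points are
  reported with stability flags, and the label uses the first root, the
  one reached from an empty membrane).
* Degenerate inputs: $C = 0$ gives an undefined order parameter (`NA`)
  and an exactly empty membrane; $v_m \to 0$ collapses the isotropic root
  to zero; $\lambda \le 0$ warns at construction and errors in the theory
  layer; an all-zero histogram frame is skipped by drift correction with
  a warning.
* Rounding: the binding target is rounded to the nearest integer
  (deterministically) so pools remain integers; surplus unbinding picks
  particles uniformly.

## What the validation runs do and do not show

The test suite validates: the closed-form layer against its printed
limits and against an independent discretised linearization; the
stochastic MT engine against the mean-field occupancies and fluxes
(3-SE equivalence at clamped densities, both speed pairs); the sampler
against the dual heat-kernel representation; exact conservation; bitwise
reproducibility; and the reentrant phenomenology on scaled-down study
conditions — $M = 200$, $l_{1/2} = 30$ um (and the $M=1000/100$
compensation pair at $l_{1/2} = 150/15$ um) with runs of $8000$ s at
$\Delta t = 1$ s and 2–6 seeds per point. These sizes were chosen so the
full suite runs on a desktop; they are *not* the sizes one would use for
publication-quality curves (many seeds, $M = 10^3$, longer averaging).

Two finite-size caveats matter when interpreting scaled-down runs. First,
fluctuation-induced stabilisation (Jensen effects in the convex release
law) shifts the *operating* density at small $M$ slightly above the
mean-field label. Second, near the activation edge of the window
($\gamma \approx 0.92$, which theory places essentially on the marginal
contour $\Omega^2 = \delta$), near-critical fluctuations make the raw
order parameter at $M \le 200$ almost as large as in the polarized
regime; the saturated edge ($\gamma \approx 1.85$) is far from marginal
and separates cleanly at every scale. At $M = 1000$ the full
low/high/low sequence across $\gamma \approx 0.93/1.29/1.85$ is already
visible in the raw averages (the compensation scan in the acceptance
suite exercises exactly this grid). The synthetic model also idealises
real cells in
ways the tests cannot probe: a point centrosome, a single PF species, no
interior diffusion limitation (well-mixed pool), no MT-MT interactions,
no cell growth or shape change, and delivery only at stalled tips.

## Known limitations

* The 2D particle simulation validates the circle mode $n = 1$; spherical
  modes enter the theory only through the Laplacian eigenvalue.
* The finite-tubulin-pool variant (shorter MTs under depletion) is not
  implemented; the parameter bundle is the natural extension point.
* Only the Hill dose-response is built in, though any monotone
  alternative could be swapped behind `release_rate()`.
* At $M \lesssim 200$ the activation boundary of the window cannot be
  localised from raw order parameters; use the feedback-cut control and
  noise subtraction, and expect only the saturated boundary to be sharp.
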