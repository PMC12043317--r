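---
title: "Gain and stability in E-PV-SOM rate circuits: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gain and stability in E-PV-SOM rate circuits: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(epvsom)
```

## The model

`epvsom` analyses a recurrent firing-rate circuit of three cortical
populations: excitatory pyramidal neurons (E), parvalbumin-expressing
interneurons (PV) and somatostatin-expressing interneurons (SOM).  Each
population obeys

$$\tau_X \frac{dr_X}{dt} = -r_X + f_X(q_X), \qquad
  q_X = \Big[\textstyle\sum_Y (\pm) w_{XY}\, r_Y + I_X\Big]_+ ,$$

with a rectified power-law transfer $f(q) = \alpha\,[q]_+^{\beta}$.  The sign
of each coupling follows the presynaptic identity: the E column of the
connectivity matrix is positive, the PV and SOM columns negative.  Defaults
are $\alpha = 1/4$, $\beta = 2$ and $\tau_X = 10$ ms for every population;
all of these may be set per population.  With these defaults the *cellular
gain* — the slope $b_X = f'(q_X)$ at an operating point — takes the closed
form $b_X = \sqrt{r_X}$, so a population's local sensitivity grows with its
rate.  This single fact drives most of the state dependence below.

Two inhibitory motifs compete in this circuit: the direct *inhibitory
pathway* SOM → E and the *disinhibitory pathway* SOM → PV → E.  The package
exists to quantify how a small modulatory input to SOM shifts E-population
stimulus gain and network stability, depending on connectivity and on the
operating point.

## Operating points

All analyses linearise around a self-consistent state $r = f(Wr + I)$.  Two
constructors exist:

* `inputs_for_rates(rates, circ)` — the closed-form inverse
  $I = f^{-1}(r) - W r$.  Rate grids are parameterised this way, so every
  grid cell is a fixed point by construction and the linearisation is
  available even where the dynamics are unstable (the heatmaps deliberately
  extend beyond the stability boundary).  External inputs may come out
  negative (net hyperpolarising drive); the net currents $q = f^{-1}(r)$ are
  nonnegative by construction.
* `fixed_point(I, circ)` — solves for the rates at given inputs.  A damped
  Newton iteration on $f(Wr+I) - r$ is used first, with a damped Picard
  iteration (damping 0.5) and simulation-to-convergence as fallbacks, all at
  residual tolerance $10^{-10}$.  Newton was preferred over pure Picard
  because grid pipelines solve thousands of fixed points and Picard stalls
  near marginal stability; the fallbacks retain its robustness.  Regimes
  with no attracting state (e.g. runaway E self-excitation) are reported
  via a `converged = FALSE` flag, never silently.

If any net current is non-positive the transfer sits on its rectified
branch, the derivative is undefined, and `linear_response()` refuses to
linearise, naming the silenced population.

## Linear response and its pathway expansion

Around a stable operating point, steady-state rate changes follow
$\delta r = L\, \delta I$ with the response matrix

$$L = (B^{-1} - W)^{-1} = (1 - BW)^{-1} B = (-J)^{-1}, \qquad
  J = W - B^{-1},$$

where $B = \mathrm{diag}(b_X)$.  Both factorisations are computed and
cross-checked at $10^{-8}$; the test suite additionally checks $L$ against a
Richardson-extrapolated finite difference of the nonlinear fixed-point map.
When the spectral radius of $BW$ is below one, $L = \sum_i (BW)^i B$: the
`pathway_expansion()` terms collect all synaptic pathways of length $i$, and
the first-order (E, S) term is the monosynaptic contribution
$-b_E w_{ES} b_S$.

The SOM-to-E element factorises (`som_to_E_transfer()`) as

$$L_{ES} = \psi_{ES}\left(\frac{w_{EP} w_{PS}}{b_P^{-1} + w_{PP}} -
  w_{ES}\right), \qquad
  \psi_{ES} = \frac{b_P^{-1} + w_{PP}}{\det(B^{-1} - W)} > 0
  \text{ when stable},$$

so the bracket alone sets the sign of the E-rate response to SOM
modulation: disinhibition ($w_{EP}w_{PS}$, tempered by PV self-inhibition
and PV gain) against direct inhibition ($w_{ES}$).  Because $b_P$ grows with
the PV rate, the same wiring can flip from net-inhibitory to
net-disinhibitory as PV activity rises.  (A published form of this
prefactor carries an extra $b_E^{-1}$ factor; direct inversion of
$B^{-1} - W$ shows the factor cannot be present if
$\psi_{ES} \times \mathrm{bracket}$ is to equal the matrix element, and the
package implements the matrix-consistent form.  The positivity guarantee is
unaffected.)

The PV response to SOM modulation (`pv_response_to_som()`) is
$L_{PS} = ((w_{EE} - b_E^{-1}) w_{PS} - w_{ES} w_{PE}) / \det$.  With
$w_{ES} = 0$ its sign flips exactly at $w_{EE} = 1/b_E$, the
inhibition-stabilised-network (ISN) boundary: in the ISN regime PV rates
*rise* when SOM inhibition to PV increases — the paradoxical response.

## Network gain and stability

Sensory stimuli are modelled as drive to E and PV,
$\delta I^{stim} = (\delta I_E, \delta I_P, 0)$, and the network gain of the
E population is $g_E = L_{EE}\,\delta I_E + L_{EP}\,\delta I_P$
(`network_gain()`), with the equivalent expanded form checked when
$w_{SS}=0$.  The default stimulus is equal unit drive $(1, 1)$; under the
catalogued connectivity ($w_{EP} = 0.5$, $w_{PP} = 0.6$) the gain is then
positive over the whole rate grid, matching the reference heatmaps.

Stability is measured by $\lambda_{max}$, the largest real part of the
eigenvalues of $J = W - B^{-1}$ (`stability()`).  This convention omits the
$1/\tau$ prefactor of the dynamics; with equal time constants the sign
structure is unchanged and the printed stability changes stay on the
familiar scale.  A `jacobian = "dynamical"` flag provides
$T^{-1}(BW - 1)$ for unequal time constants.  The measure ignores imaginary
parts, but the oscillatory flag is always attached because switches between
real and complex leading eigenvalues produce genuine discontinuities in
$\lambda_{max}$ along rate or weight sweeps.

A SOM modulation experiment (`modulation_deltas()`) compares two operating
points — before and after an input step $\delta I_S^{mod}$ onto SOM — and
reports $\Delta g = g_E^{mod} - g_E$ and
$\Delta\lambda = \lambda_{max} - \lambda_{max}^{mod}$, so positive
$\Delta\lambda$ means the modulation stabilised the circuit.  The modulated
state is found by a nonlinear re-solve by default (matching simulations);
a linear mode ($\delta r = L\,(0,0,\delta I_S^{mod})^T$) is available and
agrees to $O(\delta I^2)$.

## Grid scans, vector fields, sweeps

`rate_grid_scan()` evaluates gain and $\lambda_{max}$ on an $(r_E, r_P)$
grid at fixed SOM rate (default $[0.5, 10]$ Hz, $50 \times 50$, the
figure convention).  Normalisation was unspecified in the source material;
the package divides the gain by its largest finite absolute value on the
grid and $\lambda_{max}$ by $|\min \lambda_{max}|$, so contours can be drawn
in steps of 0.2 on both maps.  `modulation_vector_field()` adds, per stable
cell, the direction the fixed point moves under a SOM step (arrows are
unit-normalised; only direction is meaningful) plus unnormalised
$(\Delta g, \Delta\lambda)$.  Cells whose unmodulated state is unstable, or
whose modulated state fails to converge or lands on the rectified branch,
are masked rather than extrapolated.  `quadrant_statistics()` bins the
$(\Delta g, \Delta\lambda)$ pairs by sign after excluding magnitudes below
$|\Delta g| \le 0.1$, $|\Delta\lambda| \le 0.01$ (the reference thresholds);
the Q1–Q4 labels follow Q1 = both up, Q2 = gain down/stability up,
Q3 = both down, Q4 = gain up/stability down — the descriptive names are
authoritative since the source never defines the ordering.

For feedforward SOM wiring the $(r_E, r_P)$ heatmaps cannot depend on *how*
SOM projects into the E–PV circuit, so any modulation merely moves the
state along maps whose gain and stability gradients oppose each other:
gain and stability trade off.  Feedback onto SOM (E → SOM or PV → SOM)
makes the maps themselves depend on the SOM rate, and modulations can then
increase both.  In the catalogued E-feedback circuit the fraction of grid
cells whose gain and stability rise together under positive modulation is
already above 80% at $r_S = 1$ Hz and grows with the SOM rate, saturating
between $r_S = 2$ and 3 Hz on the default grid (at the grid ceiling the
comparison of $r_S = 2$ versus 3 reverses by about 1% of cells; with an
E-biased stimulus the growth is strictly monotone).

`weight_sweep()` varies one coupling magnitude at a time while re-deriving
the inputs that pin the rates at a fixed target (default
$(3, 5, 0.5)$ Hz), isolating pure connectivity effects: the cellular gains
never change along a sweep.  The default axis spans $[0, 1.5]$ in 61 steps
(the reference colour bars print no range).  PV self-inhibition shows an
interior stability optimum; SOM self-inhibition is the least effective
weight on both measures.

## Stochastically forced circuits

To check conclusions beyond linearisation, `frozen_noise_experiment()`
drives E and PV with a temporally smoothed noisy input
$\tau_\xi \dot\xi = -\xi + I + \sigma\zeta$ ($\tau_\xi = 50$ ms,
$\sigma = 6$, zero on SOM) for 1000 s.  The integrator (compiled, Euler at
$dt = 10^{-4}$ s) applies one unit-variance draw per step; the stationary
input variance is then $\sigma^2 a/(2-a)$ with $a = dt/\tau_\xi$, which the
tests verify against the simulated process.  The raw timestep `0.01` of the
reference implementation is dimensionless; reading it in units of the 10 ms
time constant ($dt = 0.1$ ms) reproduces E-rate variances of order 1 Hz²,
whereas reading it as 0.01 s yields variances two orders of magnitude
larger, so the former is used.  An Euler–Maruyama mode
($\zeta/\sqrt{dt}$ scaling, $dt$-independent limit) is available behind the
`mode` flag.

Gain without linearisation uses *frozen noise*: the four conditions
(± SOM modulation × ± stimulus) reuse the identical noise realisation, so
the per-timestep difference of E rates between stimulated and unstimulated
runs isolates the stimulus effect and yields a distribution of network
gains.  Stability is proxied by the mean and variance of the E rate: a more
stable circuit quenches input fluctuations.  Rates are hard-rectified at
zero inside the integrator, and runs are bit-reproducible from the seed.

## Tuned stimuli and modulation arithmetic

`tuning_experiment()` drives E and PV with a Gaussian orientation profile
$I^{stim}(\theta) = w_{ff}\, e^{-(\theta - \theta_p)^2/\sigma_\theta^2}
(1, 1, 0)^T$ ($w_{ff} = 2$, $\theta_p = 90^\circ$, $\sigma_\theta = 20$)
on top of a background $(1, 1, 1.5)$, solving the fixed point at every
angle (default $0$–$180^\circ$ in $1^\circ$ steps — fine enough that the
regression below is grid-insensitive) with and without a SOM input step.
SOM receives no tuned input but inherits tuning whenever E → SOM feedback
exists.  `decompose_tuning()` regresses modulated on unmodulated rates by
OLS: slope > 1 is multiplicative, < 1 divisive; intercept > 0 additive,
< 0 subtractive.  The additive component is normalised by the maximum of
the *unmodulated* curve (the reference is ambiguous between pre and post;
pre is the stable choice since it is shared across modulations).  The
modulation amplitude is only described as "small negative"; the default is
$-0.1$.

## Reconstructed quantities

The connectivity table rows and the constants above are taken from the
source material.  Several inputs are *not* printed anywhere and were
reconstructed, then frozen in the fixture catalogue
(`load_fixture()`, provenance field `"reconstructed"`):

* the operating points and modulation amplitudes behind the deterministic
  gain/stability-change examples (rates $(1, 2.75, 1.5)$ Hz with
  $\delta I_S^{mod} = +0.2$ for the disinhibitory circuit; $(5.75, 3, 1)$ Hz
  with $-0.2$ for the PV→SOM-feedback circuit);
* the mean inputs and amplitudes of the stochastic runs;
* the collapsed blank cells of the printed weight table, resolved by row
  inheritance together with each figure's described motif (one row admits
  no assignment consistent with the described motif; the package follows
  the motif description and flags that fixture as reconstructed);
* sweep axes and scan normalisations, as described above.

Reconstruction searched round-valued operating points until the package's
own pipelines reproduced the printed caption values; the values were then
frozen and are never re-fit at run time.

## What the synthetic experiments do and do not show

All tests run on synthetic circuits: the catalogued connectivity variants
plus randomly drawn stable circuits (couplings uniform on $[0, 1.2]$,
rates on $[0.5, 8]$ Hz, filtered for stability and pathway convergence).
They verify internal consistency (oracle identities, invariances,
reproductions) under the model's assumptions — three homogeneous
populations, instantaneous power-law transfer, no synaptic dynamics, no
transmission delays, Gaussian input noise.  Passing them says nothing about
heterogeneous real cortex, spiking dynamics, conductance effects, VIP
neurons or short-term plasticity, all of which are outside the model class.

## Problem sizes used by the test suite

Structural grid claims are checked on $15$–$21$ point axes (values are
pointwise, so resolution only affects coverage, and a dedicated test proves
grid-refinement invariance); vector fields on $12$–$15$ point axes;
stochastic reproduction runs use the full 1000 s protocol; tuning runs the
full $1^\circ$ axis in the acceptance test and coarser axes elsewhere.
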