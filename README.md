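# epvsom

Gain and stability analysis of recurrent cortical circuits with two
inhibitory interneuron classes.

## The problem

Cortical inhibition has to do two jobs at once: keep recurrent excitation
from running away (network stability) and set how strongly excitatory (E)
neurons respond to a stimulus (network gain).  In circuits with a single
inhibitory population these two jobs oppose each other — states with high
gain sit close to instability.  Real cortex, however, splits inhibition
over distinct cell classes, at a minimum parvalbumin- (PV) and
somatostatin-expressing (SOM) interneurons, wired differently into the
circuit: PV cells receive stimulus drive and inhibit each other; SOM cells
receive modulatory drive, inhibit E and PV, and have no self-coupling.

`epvsom` implements the three-population firing-rate model of this E-PV-SOM
circuit and the analysis machinery to ask: when a modulatory input shifts
SOM activity, what happens to E rates, to stimulus gain, and to stability —
and how does the answer depend on connectivity and on the network state?

## The model in brief

Rates follow `tau * dr/dt = -r + f(W r + I)` with a rectified power-law
transfer `f(q) = alpha * [q]+^beta` (defaults `alpha = 1/4`, `beta = 2`,
`tau = 10 ms`).  Around a self-consistent state with cellular gains
`B = diag(f'(q))`, small input changes map to rate changes through the
response matrix

    L = (B^-1 - W)^-1 = (-J)^-1,     J = W - B^-1 .

Key derived quantities:

* **SOM-to-E transfer** `L_ES = psi * (wEP*wPS/(bP^-1 + wPP) - wES)` — the
  bracket pits the disinhibitory pathway SOM→PV→E against direct SOM→E
  inhibition and alone decides whether SOM modulation boosts or suppresses
  E activity (`som_to_E_transfer()`).
* **Network gain** `gE = L_EE dI_E + L_EP dI_P` for a stimulus onto E and
  PV (`network_gain()`).
* **Stability** `lambda_max`, the largest real part of the eigenvalues of
  `J` (`stability()`); the paradoxical PV response appears exactly when
  `wEE > 1/bE` (`pv_response_to_som()`).
* **Modulation effects** `delta_g` and `delta_lambda` between the states
  before and after a SOM input step (`modulation_deltas()`), plus rate-grid
  scans, modulation vector fields, weight sweeps, stochastically forced
  simulations with frozen-noise gain estimates, and additive/multiplicative
  decomposition of tuning-curve changes.

## Worked example

Hold the disinhibitory reference circuit (SOM inhibits PV only) at rates
(rE, rP, rS) = (1, 2.75, 1.5) Hz and apply a positive SOM input step:

```r
library(epvsom)

circ <- config_circuit(load_fixture("fig2a"))   # wEE=0.8 wEP=0.5 wPE=1 wPP=0.6 wPS=0.8
op <- inputs_for_rates(c(1, 2.75, 1.5), circ)
op
#> Operating point of E-PV-SOM circuit
#>             E     P     S
#> rate    1.000 2.750 1.500
#> input   2.575 5.167 2.449
#> current 2.000 3.317 2.449
#> gain    1.000 1.658 1.225

modulation_deltas(op, dI_som = 0.2)
#> SOM modulation dI_som = 0.2 ( nonlinear )
#>   delta r: E +0.1456, PV -0.04836, SOM +0.2549 Hz
#>   network gain: 0.9493 -> 1.07 (delta_g = +0.1204)
#>   lambda_max:   -0.7015 -> -0.6713 (delta_lambda = -0.03018)
```

Reading the output: raising SOM activity suppresses PV, which releases E
(disinhibition, `delta r: E` positive).  The network gain rises by 0.12 —
but `lambda_max` moves toward zero, i.e. the circuit becomes *less* stable:
the classic gain-stability tradeoff.  Running the same experiment on the
variant with PV→SOM feedback (`load_fixture("fig2c")`, negative modulation)
yields `delta_g = +0.35` together with `delta_lambda = +0.04` — feedback
onto SOM lets gain and stability improve together.

The same machinery scales to whole rate grids:

```r
sc <- rate_grid_scan(circ, rS = 2)        # 50 x 50 (rE, rP) grid
plot(sc, "gain_norm")                     # normalised gain heatmap
vf <- modulation_vector_field(circ, dI_som = 0.1, rS = 2)
quadrant_statistics(vf)$percent           # where do (dg, dlambda) fall?
```

A thin command-line wrapper (`inst/cli/epvsom`) exposes the same pipelines
as `simulate`, `scan`, `vectorfield`, `sweep`, `noisy` and `tuning`
subcommands over fixture names or YAML/JSON config files, writing tidy CSV
and JSON artifacts.

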