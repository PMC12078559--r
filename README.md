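# photoswim

Simulation and trajectory analysis of light-driven DNA condensate
swimming.

DNA condensates assembled from branched motifs with azobenzene-modified
sticky ends are photoswitchable: visible light (trans isomer) stabilizes
sticky-end binding, UV light (cis) melts it. Switching the light inside a
region smaller than the condensate alternately discharges a dissolved DNA
microflow and pulls it back, and the condensate swims — away from the
irradiated region at low switching frequency ("push-swimming"), toward it
at intermediate frequency ("pull-swimming"). photoswim provides the
computational toolkit for this system, aimed at people modelling or
quantifying condensate microflow experiments:

* **Two-state swimming model** — a deterministic mass/momentum-exchange
  model of the liquid and dissociated domains under alternating UV/Vis
  intervals of length *T* (switching frequency *f* = 1/2*T*). Mass
  transfer follows
  ṁ<sub>L</sub> = −A(t′) m<sub>L</sub>,
  ṁ<sub>D</sub> = (1 − λ(t′)) A(t′) m<sub>L</sub> in UV-to-Vis intervals
  and ṁ<sub>D</sub> = −B m<sub>D</sub>,
  ṁ<sub>L</sub> = (1 − κ) B m<sub>D</sub> in Vis-to-UV intervals, with
  saturating diffusion-limited ratios A(t′), λ(t′) on the characteristic
  time τ\*. The 1D velocity gains a recoil term from ejected mass, a
  momentum-exchange term from returning mass, and viscous drag; the
  Vis-to-UV exchange can be ablated to show it causes the push/pull sign
  inversion. Forward-Euler integration, exact mass ledger, frequency
  sweeps (`simulate_condensate()`, `frequency_sweep()`,
  `ablation_compare()`).
* **MSD analysis** — time-averaged MSD of 2D tracks by the FFT
  (Wiener–Khinchin) algorithm with a naive O(N²) oracle, the
  truncate-then-fit protocol giving D′ = slope/4, automatic
  inward/outward direction calls, and the signed mobility
  D\* = ±D′ (negative for inward flow) with top-*k* selection
  (`compute_msd_fft()`, `fit_diffusion()`, `signed_estimates()`).
* **Swimming kinematics** — per-switch displacement vectors Δr<sub>i</sub>,
  net displacement L(t) = |Σ Δr<sub>i</sub>| and L<sub>max</sub>, plus the
  characteristic cycle time τ<sub>c</sub> = a²/4D<sub>S</sub> +
  a²/4D<sub>R</sub> and threshold frequency f<sub>c</sub> = 1/τ<sub>c</sub>
  separating push from pull (`displacement_series()`, `cycle_estimate()`,
  `swim_regime()`).
* **Flow-mode classifier** — gel/liquid/dissociated phase states per
  isomer from per-variant transition temperatures, mapped to the observed
  flow modes (spread, collapse, spread-and-collect) over temperature grids
  (`flow_mode()`, `mode_table()`, `variant_fixtures()`).
* **Synthetic ground truth** — Brownian, ballistic, radial
  spread/collapse and push/pull interface-walk generators with known
  parameters and recorded seeds, used throughout the test suite
  (`gen_brownian()`, `gen_radial()`, `gen_interface_walk()`).

## Worked example

The default three-frequency sweep, with the shipped calibration:

```r
library(photoswim)
d  <- default_model_params()
sw <- frequency_sweep(d$params, d$frequencies, d$horizon, m_L0 = d$m_L0)
print(sw, digits = 3)
#>        f lifetime net_displacement peak_speed positive_fraction
#> 1 0.0125     14.7            21.03     2.1185           0.52028
#> 2 0.1250      Inf           -26.47     0.1317           0.01643
#> 3 0.6250      Inf            -1.27     0.0049           0.00793
```

At the low frequency the condensate is short-lived (its liquid mass drops
below 10% of the start value at t = 14.7) and migrates away from the
irradiated region (net displacement +21, velocity predominantly positive);
at the intermediate frequency it lives past the horizon and is pulled the
other way, further (−26.5) but with smaller velocity peaks; at the high
frequency almost nothing moves. Disabling the momentum exchange
(`ablation_compare()`) removes the negative displacements entirely.

The threshold-frequency estimate for a 20 µm condensate whose spreading
and reversing microflows have effective diffusion coefficients 20 and
10 µm²/s:

```r
est <- cycle_estimate(a = 20, D_S = 20, D_R = 10)
print(est)
#> Characteristic cycle time for a = 20 um (D_S = 20, D_R = 10 um^2/s)
#>   tau_UV = 5 s, tau_Vis = 10 s, tau_c = 15 s
#>   threshold switching frequency f_c = 0.07 /s (0.0666667 full precision)
swim_regime(0.12, est)
#> [1] "exchange_dominant_pull"
```

A switching frequency of 0.12 s⁻¹ lies above f<sub>c</sub> ≈ 0.07 s⁻¹, in
the pull-swimming regime; 0.02 s⁻¹ would fall below it, in the
push-swimming regime.

A minimal command-line binding ships in `inst/cli/photoswim.R`
(subcommands `simulate`, `sweep`, `ablate`, `msd`, `swim`, `cycle`,
`modes`, `synth`), e.g.
`Rscript inst/cli/photoswim.R cycle --a 20 --ds 20 --dr 10`.

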