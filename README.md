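# istdpsim

Simulation toolkit for **heterosynaptic, anti-Hebbian input-spike-timing
dependent plasticity (iSTDP)** at vestibular afferent synapses, and for the
transfer of vestibulo-ocular reflex (VOR) gain from cerebellar cortex to the
brainstem that this plasticity supports.

Neurons of the medial vestibular nucleus (MVN) combine excitatory
vestibular-afferent input (weight *w*) with inhibitory Purkinje-cell input.
The covariance learning rule for consolidating a cortically learnt VOR gain
into *w* is anti-Hebbian in the two *inputs*,

    dw = -beta * < c(t) * v(t) >,

independent of postsynaptic firing. At spike level each input pair separated
by tau = t_v - t_c contributes beta * P(tau), where the iSTDP profile P has
a narrow LTD dip at coincidence balanced by broad shallow LTP lobes. For
sinusoidal inputs at frequency f the effective learning rate is
lambda(f) = Re F[-P](2*pi*f): a balanced profile is a bandpass filter on
input correlations, with the dip width setting the upper band edge.

The package provides, as composable R functions:

* **Kernels** — difference-of-Gaussians / difference-of-exponentials
  profiles with exact LTP/LTD area control and imbalance, closed-form and
  numeric learning-rate functions, bandpass calibration, dip-width
  measurement (`make_dog_profile`, `calibrate_bandpass`, `dip_halfwidth`,
  `learning_rate_function`).
* **Plasticity rules** — spike-pair rule (direct and FFT cross-correlogram
  paths), firing-rate rule, inter-spike-interval histograms
  (`pairwise_weight_change`, `pairwise_weight_change_fft`,
  `rate_weight_change`, `isi_histogram`).
* **Protocols** — in-vitro induction schedules: single-pairing timing sweep
  and the pause-rebound family PR-0..3 (`build_ist_protocol`,
  `build_pr_protocol`, `protocol_to_rates`).
* **Synthetic inputs** — seeded sinusoidally modulated Poisson spike trains
  (`modulation_spec`, `poisson_encode`, `make_correlated_pair`).
* **Simulations** — protocol weight trajectories with soft saturation,
  stochastic sinusoidal learning, empirical learning-rate curves, and
  closed-loop gain transfer with LTP/LTD imbalance
  (`simulate_protocol`, `simulate_sinusoidal_learning`,
  `estimate_learning_rate`, `simulate_closed_loop`,
  `analytic_closed_loop_error`).
* **Interface** — validated JSON/YAML run configs, reproducible run
  manifests, CSV I/O for every domain type (`load_config`,
  `write_run_manifest`).

## Worked example

```r
library(istdpsim)

## profile calibrated to the VOR-adaptation band: learning rate falls to
## 20% of its peak at 0.3 and 10 Hz
vor <- vor_calibrated_profile()
vor
#> iSTDP profile (dog)
#>   LTD: amp -1.091, sigma 28.92 ms | LTP: amp 0.09071, sigma 347.8 ms
#>   imbalance: 0 | grid 1 ms | support +/- 2.43 s
1000 * dip_halfwidth(vor, 0.2)   # LTD dip half-width at 20% depth, in ms
#> [1] 47.08184

## pause-rebound induction protocols, firing-rate form of the rule
sapply(c("PR0", "PR1", "PR2", "PR3"), function(v)
  tail(simulate_protocol(build_pr_protocol(v), vor)$weights, 1))
#>       PR0       PR1       PR2       PR3
#> -1679.224    63.627   -16.828  1679.224
```

The strong LTD of PR-0 (hyperpolarisation paired with the afferent train),
the near-cancellation of PR-1/PR-2 (depolarisation of equal area appended),
and the mirrored LTP of PR-3 are the linear-model predictions for the
pause-rebound experiments; values are relative weight change per unit
learning-rate scale.

```r
## closed-loop gain transfer with a +10% LTP area excess
prof <- constrained_profile(imbalance = 0.10)
cl <- simulate_closed_loop(
  closed_loop_config(tonic_v = 50, tonic_c = 50, depth_v = 40, depth_c = 40,
                     freq = 3, imbalance = 0.10, seed = 7001),
  prof)
cl$metadata$final_gain_error     # percent weight error vs the balanced case
#> [1] 31.40815
analytic_closed_loop_error(closed_loop_config(imbalance = 0.10), prof)
#> [1] 32.00704
```

A ±10% imbalance between LTP and LTD areas corrupts the transferred gain by
roughly ±30%, so stable consolidation requires nearly balanced plasticity.

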