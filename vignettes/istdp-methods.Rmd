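---
title: "Heterosynaptic iSTDP and vestibular gain transfer: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heterosynaptic iSTDP and vestibular gain transfer: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(istdpsim)
```

## The model

Second-order neurons of the medial vestibular nucleus (MVN) receive
excitatory vestibular-afferent input with synaptic weight $w$ and inhibitory
input from cerebellar (floccular) Purkinje cells. The gain of the
vestibulo-ocular reflex (VOR) can be adapted quickly in cerebellar cortex,
but consolidating that gain into the brainstem requires a rule by which
Purkinje-cell activity sculpts the vestibular synapse. The covariance form
of that rule is anti-Hebbian,

$$\delta w = -\beta \,\langle c(t)\, v(t) \rangle,$$

with $v$ and $c$ the deviations of vestibular and cerebellar firing rates
from their tonic levels and $\beta > 0$ the learning-rate scale: in-phase
(positively correlated) inputs depress the vestibular synapse, anti-phase
inputs potentiate it. Expressed at the level of single input spikes this
becomes input-spike-timing dependent plasticity (iSTDP): each pair of
vestibular and cerebellar input spikes separated by
$\tau = t_v - t_c$ changes the weight by $\beta P(\tau)$, independently of
postsynaptic firing. The profile $P$ has a narrow LTD dip at coincidence
balanced by broad shallow LTP lobes; the balance (zero total area) ensures
tonic uncorrelated firing causes no drift.

For sinusoidally modulated inputs at frequency $f$ the effective learning
rate is the real part of the Fourier transform of the convolution kernel
$k(\tau) = -P(\tau)$:

$$\lambda(f) = \mathrm{Re}\, \hat{k}(2\pi f).$$

A balanced profile has $\lambda(0) = 0$ and acts as a bandpass filter on
input correlations: the dip width sets the upper band edge, the lobe width
the lower one.

## Profile families and their parameters

Two parametric families are provided.

* **Difference of Gaussians** (`make_dog_profile`): dip
  $a_D e^{-\tau^2/2\sigma_D^2}$ ($a_D < 0$) plus lobes
  $a_P e^{-\tau^2/2\sigma_P^2}$. The LTP amplitude is always solved from
  the area condition $a_P \sigma_P = (1+\varepsilon)\,|a_D|\,\sigma_D$,
  where $\varepsilon$ is the *imbalance*: the relative excess of the
  positive component's area over the negative component's. We define
  $\varepsilon$ on the component areas (the positive and negative
  Gaussians), not on the positive and negative parts of $P$; the two
  definitions coincide when balanced and differ only through the overlap
  of the components otherwise.
* **Difference of exponentials** (`make_doe_profile`): the same
  construction with $e^{-|\tau|/\tau_D}$ branches, either even
  (two-sided) or, with `antisymmetric = TRUE`, one-sided LTD for
  $\tau > 0$ and LTP for $\tau < 0$, resembling classical causal STDP
  windows.

All internal times are seconds; printed summaries use ms. The default
tabulation step is 1 ms. The tabulation support is chosen adaptively —
$7\sigma_P$ for Gaussian lobes, $25\tau_P$ for exponential lobes, at least
1 s — so that the truncated tail area is negligible against the balance
condition; a fixed short window would clip several tenths of a percent of
the LTP area of the wider calibrated profiles and masquerade as imbalance.

Two standard profiles recur throughout:

```{r profiles}
vor <- vor_calibrated_profile()   # passband 0.3-10 Hz at 20% of peak
vor
1000 * dip_halfwidth(vor, 0.2)    # dip half-width at 20% depth, ms

con <- constrained_profile()      # 20 ms dip, lobes as in the VOR profile
con
```

The **VOR-calibrated profile** is the balanced DoG whose learning rate
falls to 20% of maximum at 0.3 and 10 Hz, the band over which behavioural
VOR adaptation transfers to the brainstem. These two constraints pin both
widths uniquely ($\sigma_D = 28.9$ ms, $\sigma_P = 347.8$ ms); the solver
is a damped Newton iteration on $(\log\sigma_D, \log\sigma_P)$ using the
closed-form transform, converging to residuals below $10^{-10}$ in a few
milliseconds. Amplitudes are normalised so $\min P = -1$; absolute
magnitude is carried by $\beta$.

"Half-width at 20% of maximum" we read as half of the full width of the
region where the dip reaches at least 20% of its maximum depth, with depth
measured from zero. Under this reading the calibrated profile's half-width
is 47.1 ms; measuring depth from the LTP plateau instead gives 51.7 ms.
Both readings are implemented by `dip_halfwidth` (the zero-referenced one
is the default and the closer of the two to the nominal 49 ms figure for
this passband); no parameter choice can move the value while the two
band-edge constraints hold, since they determine the profile's shape
completely.

The **experimentally constrained profile** encodes what the in-vitro
timing sweep implies: LTD confined to a ~20 ms window around coincidence,
i.e. better high-frequency learning than the behavioural band requires.
The slice data constrain only the dip, so we keep $\sigma_P$ at its
VOR-calibrated value (unchanged low-frequency edge) and solve $\sigma_D$
so the dip half-width at 20% depth is exactly 20 ms. With broad lobes the
profile also reproduces the pause-rebound protocol predictions cleanly
(below); lobes much narrower than the 550 ms stimulus train would break
the per-presentation LTD/LTP cancellation that the linear model predicts.

## Applying the rule to spike trains and rates

`pairwise_weight_change` is the literal double sum
$\beta \sum_{i,j} P(t_{v,i} - t_{c,j})$ over pairs within the pair window
(the profile support by default). `pairwise_weight_change_fft` bins both
trains at 1 ms, forms the cross-correlogram by FFT, and weights it by the
tabulated profile; the discrepancy against the direct sum is first order
in the bin width and bounded by (max slope of $P$) x (bin width) x (number
of in-window pairs). The binning path refuses grids coarser than a fifth
of the dip width.

`rate_weight_change` implements the rate form
$\beta \int\!\!\int v(t)\,c(s)\,P(t-s)\,dt\,ds$ by discrete convolution.
The sign and scale conventions are fixed against the sinusoidal closed
form: in-phase unit-amplitude sinusoids at frequency $f$ produce a
weight-change *rate* of exactly $-\beta\,\lambda(f)/2$ (the factor 1/2 is
$\langle \sin^2 \rangle$), which the tests assert to $10^{-4}$ relative.
Boundary handling is zero-padded for isolated presentations and periodic
for steady-state sinusoids.

## Synthetic inputs

In vivo inputs are emulated as sinusoidally modulated inhomogeneous
Poisson trains (`modulation_spec`, `sinusoidal_rate`, `poisson_encode`):
rate $r(t) = r_0 + m \sin(2\pi f t + \phi)$, encoded by per-bin Bernoulli
draws with $p = r\,\Delta t$, the grid refined automatically so
$p \le 0.1$. Negative instantaneous rates are clipped to zero and the
clipped fraction reported; clipping never occurs when $m \le r_0$, which
holds for every standard setting used here (30±20, 60±40, 50±40 sp/s).
The generator takes a seed and derives independent substreams per train,
so every stochastic result in the package is replayable. This emulates
rate-coded asynchronous firing only: no refractoriness, bursting, or
non-Poisson interval statistics, and perfectly sinusoidal modulation. A
passing simulation therefore demonstrates that the rule needs no precise
spike timing, not that it survives every firing-statistics deviation
found in real afferents.

## Induction protocols

`build_ist_protocol` encodes the single-pairing experiment: a 20 ms
hyperpolarising pulse (unit amplitude) with one afferent stimulus at
relative time $T_s$, default 1000 presentations at 0.5 s. The pulse is
placed mid-window so negative $T_s$ remains inside the presentation.
`build_pr_protocol` encodes the pause-rebound family: a 130 Hz, 550 ms
train (72 stimuli) with a 250 ms hyperpolarisation (PR-0), followed by an
equal-area depolarisation (PR-1: 250 ms x 1, PR-2: 125 ms x 2), or a
depolarisation alone (PR-3); 30 presentations at 5 s. We use 130 Hz
throughout (one figure caption elsewhere says 133 Hz; at this granularity
the results are insensitive to the difference).

For simulation the pulses are mapped to proportional cerebellar rate
deviations (hyperpolarisation, i.e. stronger inhibition, positive) and the
stimuli to unit-area vestibular rate impulses. The proportionality
constants (50 sp/s per pulse unit, 1 spike per event) are not measured
quantities; relative weight changes across protocol variants are invariant
to both up to the overall $\beta$ scale, which is why results are reported
relative to PR-0 or to the saturation bound. Presentations are treated as
independent — at 0.5–5 s periods the cross-presentation pair mass is
negligible — making the unsaturated trajectory exactly periodic.

In the spiking representation of a protocol (`protocol_spike_trains`) the
cerebellar channel needs a tonic rate to express depolarisations as rate
decreases. Tonic inhibitory firing does not stop between presentations,
so the cerebellar window is padded by the profile support on both sides;
without the padding, events near the window edges lose far-lag LTP
partners from the tonic stream and a spurious LTD bias of order the LTP
lobe area appears.

```{r pr}
dw <- sapply(c("PR0", "PR1", "PR2", "PR3"), function(v)
  tail(simulate_protocol(build_pr_protocol(v), vor)$weights, 1))
round(dw, 1)
```

PR-0 accumulates strong LTD; PR-1 and PR-2 nearly cancel (their
depolarisations pair the same stimuli with opposite-sign input); PR-3
mirrors PR-0 into LTP. `soft_saturate` adds the standard soft-bounds
model ($dw \cdot (1 - w/w_{max})$ for LTP, $dw \cdot w/w_{max}$ for LTD),
and `calibrate_pr0_beta` picks $\beta$ so PR-0 drives the weight from 95%
to 50% of its maximum, the operating point at which implicit LTP becomes
observable only after prior LTD.

## Learning-rate estimation

`estimate_learning_rate` recovers $\lambda(f)$ empirically: for each
frequency it draws in-phase Poisson segment pairs (50 s by default),
applies the spike-pair rule, and converts the mean weight change to a rate
via $\hat\lambda = -2\,\Delta w/(\beta T)$, whose expectation is
$m_v m_c \lambda(f)$. Two numerical choices matter:

* **Edge correction.** In a finite segment the number of pairs at lag
  $\tau$ scales as $T - |\tau|$, so lobe contributions are slightly
  undercounted and $\hat\lambda$ is biased upward where $\lambda$ is
  small (band edges). The estimator reweights the cross-correlogram by
  $T/(T - |\tau|)$ — the standard correlogram edge correction — making it
  unbiased for the infinite-duration rate. The learning *rule* itself
  never applies this; it is purely an estimator refinement.
* **Common random numbers.** When two modulation settings are compared
  (e.g. 60±40 versus 30±20 sp/s), passing the same master seed reuses the
  same uniform draws for both, which cancels most of the shared sampling
  noise in the peak ratio: the ratio then concentrates tightly around the
  product of modulation depths, here
  $(20 \times 20)/(40 \times 40) = 25\%$.

Because the peak rate is proportional to the product of the two modulation
depths and independent of the tonic rates, halving both depths quarters
the peak while leaving the curve's shape (and the irrelevance of tonic
rate) intact — both properties are asserted in the test suite at the
3-standard-error level.

## Closed-loop gain transfer and imbalance

The consolidation loop is simulated under the fast-cortex shortcut:
cerebellar learning is assumed accurate and fast relative to brainstem
learning, so at every step the cerebellar input is the optimal corrective
signal for the current weight, $c \propto (w - w^*)\,x(t)$ for target
gain $w^*$ and head-velocity signal $x$. We encode the *fractional* gain
error $(w - w^*)/w^*$ at `depth_c` spikes/s per unit, which makes the
equilibrium error scale-free in $w^*$; corrective amplitudes beyond the
clipping limit are clipped with a warning. Both channels are Poisson
rate-coded (defaults: tonic 50 sp/s, depth 40 sp/s, 3 Hz, 50 s segments,
150 steps, target gain 0.5). The default $\beta$ is set so the balanced
loop reaches 95% of its asymptote within half the default run — brainstem
learning slower than cortical learning is a stability requirement of the
two-site architecture, and the separation keeps the per-step weight noise
small. The reported error averages the final third of the trajectory.

With a balanced profile the loop converges to $w = w^*$. An imbalance
$\varepsilon$ adds a constant drift from the tonic rates; equating that
drift against the corrective-modulation term gives the equilibrium

$$\frac{w_\infty - w^*}{w^*}
  = \frac{2\, r_{0v}\, r_{0c}\, \int P}
         {m_v\, m_c\, \lambda(f)},$$

implemented in `analytic_closed_loop_error`. For the idealised all-pass
profile $\int P / \lambda = \varepsilon$ and the error reduces to
$200\,\varepsilon\, r_{0v} r_{0c}/(m_v m_c)$ percent: with
$\varepsilon = 0.1$ and the default rates, 31.25% — a ±10% imbalance
maps to roughly ±30% gain error, which is why accurate gain transfer
demands nearly balanced LTP and LTD. The stochastic simulation lands
slightly below the analytic value (30.0% versus 32.0% with the
constrained profile) because finite 50 s segments truncate a small part
of the tonic drift term; the analytic form assumes infinite segments.

## Problem sizes and degenerate inputs

Simulations default to the scales above (20 seeds or segment pairs, 50 s
segments, 150 closed-loop steps); the test suite uses the same or smaller
sizes, chosen so the full stochastic battery completes in a few minutes
while every stochastic assertion retains a >=3-standard-error margin.
Degenerate inputs are defined rather than rejected wherever the physics
is clear: empty spike trains contribute zero weight change, zero
modulation depth yields no systematic drift, and `depth_fraction = 1`
gives a zero dip half-width. Genuine contract violations — unordered
spike times, mismatched sampling, widths out of order, a pair window
beyond the profile support, a grid too coarse for the dip or the
requested frequency — raise errors naming the violated condition.

## Known limitations

* The optimal-cerebellum shortcut replaces the cortical adaptive filter;
  dynamics of cortical learning (and its errors) are outside scope.
* The pulse-to-rate mapping is the model's stated abstraction; no
  membrane or conductance model stands behind it, so absolute weight
  changes are not comparable to measured EPSC amplitudes.
* Poisson rate coding omits refractoriness and regularity of real
  vestibular afferents; the robustness results say learning tolerates
  asynchronous coding, not arbitrary spike statistics.
* The imbalance analysis treats $\varepsilon$ as fixed; homeostatic
  mechanisms that would actively rebalance LTP/LTD over long timescales
  are not modelled.
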