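---
title: "Modeling CA1 place-field formation and stabilization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling CA1 place-field formation and stabilization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(ca1place)
```

## The model

`ca1place` simulates a hippocampal CA1 pyramidal neuron as a
two-compartment rate unit on an annular track. The dendritic
compartment integrates place-tuned excitatory input; the perisomatic
compartment receives a constant drive, somatic inhibition, and —
through an all-or-nothing gate — the dendritic activity.

The dendritic rate obeys

$$\tau_0\,\dot r_{dend} = -r_{dend} + g_{dend}(p_{dend}),
  \qquad p_{dend} = \sum_j w_j R_j - I_{dend} + I^{ext}_{dend},$$

with a static nonlinearity combining a rectified saturating gain and a
sigmoidal dendritic-spike term,

$$g_{dend}(I) = \alpha_1\left[\tanh(I/I_0)\right]_+ +
  \alpha_2\,\tfrac12\!\left(\tanh(2(I-I_0)) + 1\right).$$

Inputs above $I_0$ recruit a step-like activity increment — the rate
analogue of a dendritic spike. The somatic rate obeys

$$\tau_0\,\dot r_{soma} = -r_{soma} +
  \left[g_{prop}(V_{soma})\,r_{dend} + E_{soma} - I_{soma} -
  N_{th}\right]_+,$$

where $V_{soma} = E_{soma} - I_{soma}$ and the propagation gate
$g_{prop}$ is 1 when $V_{soma} \ge \theta_{prop}$ and 0 otherwise.
Both equations advance by explicit synchronous Euler steps
($dt = 1$ ms $\ll \tau_0 = 5$ ms); all drives and the plasticity
increment are evaluated on the start-of-step state and applied
together, and rates are clamped at zero.

Ten presynaptic neurons carry Gaussian spatial tuning curves of common
amplitude $A_{pre} = 2.2$ and width $\sigma_{pre} = 5$ on a track of
length 50, with centers at the track midpoints (no center on the 0/50
seam). The animal runs unidirectionally at $10^{-2}$ track units per
ms, so one lap lasts 5 s.

### Novelty-scheduled inhibition

Dendrite-targeting (SST-like) and soma-targeting (PV-like)
interneurons are modeled as scheduled scalar inhibition. A novelty
signal $n(t) = e^{-t/\tau_n}$ ($\tau_n$ = 100 s, i.e. 20 laps per
e-fold) interpolates each level between its novel-environment value
($n = 1$) and its familiar-environment value ($n \to 0$):

$$I_{dend/soma}(t) = I^{\infty}_{dend/soma} -
  (I^{\infty}_{dend/soma} - I^{0}_{dend/soma})\,n(t).$$

Dendritic inhibition rises (0.8 to 7.5 or 8.5 depending on the
scenario) while somatic inhibition falls (1.2 to 0). When the novelty
schedule is *disabled*, the package holds $n \equiv 1$, i.e. both
levels stay at their initial, novel-environment values. This choice is
deliberate: holding the familiar values instead would silence the
dendrite outright for any weak weight profile (the asymptotic
dendritic inhibition exceeds the largest drive such profiles can
produce), whereas the published behavior of the no-novelty control is
activity that rises within a few laps and does not return to baseline
— which the $n \equiv 1$ convention reproduces.

### Plasticity

Synaptic weights follow a Hebbian term gated by dendritic activity
plus a subtractive homeostatic term driving the summed weight toward
$\theta_{homeo}$:

$$\dot w_j = \eta_{ex}\, r_{dend} R_j -
  \eta_{homeo}\Bigl(\sum_k w_k - \theta_{homeo}\Bigr).$$

Two bounding choices matter and are documented here because the bare
rule is not self-stabilizing over a 100-lap session:

* **Weights are not clipped at zero by default.** With the printed
  learning rates the homeostatic time constant
  $1/(N_{pre}\eta_{homeo})$ is 500 ms, so the weight *sum* is pinned
  near $\theta_{homeo}$ throughout. A familiar-environment place field
  needs an in-field drive above $I^{\infty}_{dend} = 8.5$, which with
  non-negative weights would require a sum of at least
  $8.5/A_{pre} \approx 3.9 > \theta_{homeo}$ — impossible. Letting the
  subtractive term drive out-of-field weights negative is what makes a
  tuned profile compatible with the sum constraint. Clipping remains
  available (`clip_weights = TRUE`); with it the familiar field
  provably dies.
* **Each weight is bounded above by `w_max`** (bounded Hebbian
  potentiation). Without a bound the winner synapses drift without
  limit (the homeostatic term only constrains the sum, and tuning
  overlap keeps every near neighbor's Hebbian gain above the uniform
  homeostatic share), saturating the dendrite across most of the
  track. The bound is calibrated once per scenario so that the
  familiar-environment field matches the first-lap field: 1.7 for the
  $\theta_{homeo} = 3$ scenarios and 1.8 for the induction scenario
  ($\theta_{homeo} = 2$).

The gate opens at equality ($V_{soma} \ge \theta_{prop}$) by default:
with $I^{0}_{soma} = 1.2$ and $\theta_{prop} = -0.2$ this places the
silent-to-place transition of the current-injection experiment exactly
at $I^{ext}_{soma} = 1.0$, one of the amplitudes the experiment
probes. `gate_strict = TRUE` restores the strict inequality.

## Scenario presets

`preset_protocol()` bundles the five packaged experiments. Initial
weight profiles are the scenario conditions; where only qualitative
descriptions exist, the generator defaults below are the package's
choices.

| preset | inhibition | $\theta_{homeo}$ | $E^{int}_{soma}$ | initial weights |
|---|---|---|---|---|
| `familiar_injection` | constant (0.8, 1.2) | — (plasticity off) | 0 | bump (0.64) on a strong uniform background |
| `novel_silent` | scheduled, $I^\infty_{dend}$ = 7.5 | 3 | 0.5 | single bump, $\Delta$ = 0.3 |
| `novel_active` | scheduled, $I^\infty_{dend}$ = 8.5 | 3 | 1.0 | single bump, $\Delta$ = 1.2 |
| `novel_induction` | scheduled, $I^\infty_{dend}$ = 8.5 | 2 | 1.0 | single bump, $\Delta$ = 0.5 |
| `nonlinearity_control` | constant (0.8, 1.2) | 3 | 1.0 | jittered uniform + per-lap input noise |

The injection preset's background level (0.617 per synapse) is chosen
so that the out-of-field dendritic rate exceeds the somatic threshold
once the gate opens; this keeps the place-field *amplitude*
(peak − baseline) independent of the injected current, because the
current then shifts peak and baseline equally. The induction bump
$\Delta = 0.5$ is the value at which four induction laps suffice to
shift the field in a novel environment while the familiar-environment
removal counts match the small/large-region asymmetry.

```{r example}
sess <- run_session(preset_protocol("novel_active"))
summary(sess)
```

```{r plot, fig.height = 6}
plot(sess)
```

## The induction experiments

`min_induction_laps()` sweeps the number of consecutive laps on which
a constant current (default 25 a.u.) is injected into the dendrite
while the animal traverses a region covering 15% or 45% of the track,
centered at the antipode of the pre-induction field peak. The default
amplitude guarantees a supra-threshold dendritic potential across the
region even against familiar-environment inhibition and negative
out-of-field weights (10 a.u. would leave the region subthreshold).
Outcomes are classified on the final 20 laps of a 30-lap
post-induction window: *removed* means no lap of that window carries a
place field (so transient removals that re-emerge do not count), and
*shifted* means every lap carries a field whose peak lies inside the
region.

## Stability probing

`stability_protocol()` freezes a network snapshot (weights, rates, and
the scheduled inhibition at that instant), simulates one plasticity-free
lap, rescales the somatic map to unit peak, and measures the mean
absolute distance to the same map after one of three perturbations:
multiplicative Gaussian gains on the input place fields, rectified
additive input-rate offsets, or additive Gaussian weight noise. Draws
are made once per probe lap and are reproducible from `(seed, draw)`.
Default $N_{noise}$ is 100 samples. Because inhibition changes by less
than 5% of its dynamic range over one 5-s lap, the probe holds it
constant at the snapshot values.

The noise amplitudes worth probing are those where out-of-field noise
excursions can cross the somatic threshold (roughly $N \ge 0.3$);
below that, the unit-peak rescaling removes most of what the noise
does.

## Numerical choices

* 50 spatial bins (1 track unit each); at the default speed and step
  every bin collects 100 samples per lap, and halving $dt$ changes a
  100-lap session's final map by well under 1% per bin.
* Place-field criterion: amplitude (peak minus the mean of the lowest
  decile of bins) above 0.1 a.u. The model's silent cells sit at
  exactly zero, so any small positive threshold separates the regimes;
  the decile baseline makes the amplitude exactly invariant to common
  offsets.
* Zero-peak maps cannot be unit-rescaled; `field_change()` treats them
  as all-zero and flags the result.
* The compensated state manipulations (weight scaling with dendritic
  disinhibition, or dendritic disinhibition with added somatic
  inhibition, each preserving the baseline field amplitude) solve for
  the compensating level by a bracketed scalar root search (tolerance
  $10^{-3}$), rejecting sign changes caused by the propagation-gate
  discontinuity.
* The compiled inner loop is mirrored by a pure-R engine
  (`engine = "r"`) assembled from the exported single-step primitives;
  the test suite checks the two against each other to $10^{-12}$.

## What the generator does and does not emulate

The synthetic environment captures single-peaked, translation-
symmetric spatial tuning, constant running speed, spatially uniform
inhibition, and deterministic lap structure. It does not emulate
multi-peaked or grid-like inputs, variable speed or direction changes,
theta-band dynamics, spiking variability, or feedback inhibition —
passing tests therefore speak to the rate-model mechanism, not to
quantitative properties of in-vivo recordings.

## Known limitations

With the bounded-Hebbian stabilizer, the winning synapse group in a
familiar environment is always several synapses wide: a neighbor whose
tuning overlaps the winner at 0.84 always outgains the uniform
homeostatic share, so competition cannot concentrate the profile onto
a single synapse. Three consequences are documented here because they
bound what the package reproduces:

* A field relocated by dendritic induction into a 15% region (which
  contains only two input centers) cannot reach a self-sustaining
  group in a familiar environment within 15 induction laps; shifting
  there first succeeds near 25 laps.
* Under multiplicative place-field noise the familiar state's wide
  plateau wiggles in shape more than the novel state's single-synapse
  field, so for that noise kind the stability ordering between novel
  and familiar states is inverted; the ordering holds for rate and
  weight noise at amplitudes $\ge 0.5$–1.
* Linear-dendrite controls develop (some) stable field about as often
  as nonlinear ones — the cap, not the dendritic spike, ultimately
  locks the winner — although their final-block spatial correlation is
  consistently lower.
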