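---
title: "A dual-transmitter plasticity model of mushroom-body learning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A dual-transmitter plasticity model of mushroom-body learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mbplast)
```

## The model

In the *Drosophila* mushroom body, an odor is represented by sparse activity
across Kenyon cells (KCs), and the learned value of that odor is stored in
the weights of KC synapses onto a mushroom-body output neuron (MBON).
A compartment's dopaminergic neuron (DAN) acts as the teaching signal, but
the DAN releases two transmitters with opposing consequences: dopamine
depresses the synapses of coactive KCs, while nitric oxide (NO), acting
through an independent pathway, facilitates them. `mbplast` implements a
minimal kinetic model of these two antagonistic pathways for the
γ1pedc compartment and everything needed to use it: protocol simulation, a
behavioral readout, grid-search parameter inference and a synthetic assay
generator.

Each synapse class (the synapses driven by one odor) carries two *fast
eligibility* variables, `d` and `n`, one per pathway, both confined to
[0, 1]. While the DAN and the KCs are coactive, each relaxes exponentially
towards 1 at its pairing rate (`a_d`, `a_n`, in min^-1); while the DAN is
active but the KCs silent, each decays towards 0 at its unpaired rate
(`b_d`, `b_n`); spontaneous background DAN activity after training decays
them at much smaller rates (`b_d_bg`, `b_n_bg`); and with the DAN silent
they do not change at all. The behaviorally expressed variables `D` and `N`
low-pass filter the fast ones with time constants `tau_d_s` = 30 s and
`tau_n_s` = 600 s:

    tau * dY/dt = y(t) - Y(t)

The tenfold-plus difference between the two expression time constants is
the heart of the model: dopaminergic depression is expressed within tens of
seconds, while the NO effect takes minutes to appear and, once present,
takes equally long to leave — which is why NO-dependent memory is invisible
one minute after training, grows for tens of minutes, and outlasts the
dopamine trace.

The normalized synaptic weight combines the two expressed effects. Four
rules are implemented: `da_only` (`w = 1 - D`), `no_only` (`w = 1 + N`),
`additive` (`w = 1 + N - D`) and `multiplicative`
(`w = (1 - D)(1 + N)`). The additive rule is anchored so that the naive
state (D = N = 0) has weight 1 under every rule; only the relative offset
matters behaviorally, and this choice keeps the naive weight meaningful.
The two single-pathway rules describe the genotype conditions used for
fitting: blocking NO synthesis (`no_null`) leaves a DA-only animal;
removing dopamine (`da_null`, the TH-mutant condition) leaves an NO-only
animal whose learned preference has the opposite valence.

Behavior is read out through the MBON activation
`r = (1/N_KC) * sum_i w_i s_i`, which under the default mean-field coding
(disjoint 10% KC ensembles per odor, infinite-population limit) reduces to
`r = 0.1 * w_class(odor)`. The probability of choosing odor A is a softmax
with gain `g`, and the performance index is its expectation:

    PI = 2 P(A) - 1 = tanh(g * (r_A - r_B) / 2)

The modeled MBON drives approach, so dopaminergic depression of the trained
odor's synapses yields negative PI and NO facilitation positive PI.

## Piecewise-constant propagation

Protocols are ordered lists of segments, each holding its drive constant,
so within a segment the dynamics are linear with constant coefficients and
are propagated in closed form: the fast variable relaxes as
`x(t) = x_inf + (x_0 - x_inf) e^(-rho t)`, and the filtered variable has
the matching biexponential solution. When `rho * tau = 1` the two
exponentials degenerate and the solution acquires a `t e^(-t/tau)` term;
the implementation switches to this analytic limit when `|1 - rho tau|`
falls below 1e-9, avoiding catastrophic cancellation near the resonance.
A fixed-step RK4 integrator (`propagate_numeric()`) is kept alongside as a
reference; the test suite checks agreement to better than 1e-6 per
component on a thousand randomized segments, including near-resonant ones,
and checks both against an independent adaptive ODE solver.

Rates are stored in min^-1 (the convention in which the fitted values are
quoted) and durations in seconds; the single conversion happens inside the
propagator, and an exactness test pins it down. One design point worth
making explicit: odor exposure with the DAN silent changes nothing — the
fast variables are frozen bitwise. The slow variables always relax towards
the fast ones, so PI is not frozen in wall-clock time after training; the
invariance the model predicts (and the tests assert) is that a schedule
with odor-only exposures is state-for-state identical to the same schedule
with the odors removed.

## Protocols

`acquisition_protocol()` builds the standard conditioning bout — 60 s of
CS+ odor paired with DAN activation, 60 s of nothing, 60 s of the control
odor alone — repeated back-to-back for multi-trial training (an optional
inter-trial interval is available; the repeated-bout spacing is not pinned
down by the assay description, and back-to-back repetition is the
default). The one-minute pairing is modeled as continuous co-activation
even though the optogenetic drive is pulsed at 1 Hz; the fitted rates
absorb the duty cycle. The standard suite is 1×10 s, 1×1 min, 3×1 min and
10×1 min.

`retention_protocol()` appends background-DAN segments and reads PI at
given delays; `reversal_protocol()` retrains with the odor roles swapped
(PI stays in the original CS+ frame, so successful reversal is a sign
flip); `dan_only_protocol()` activates the DAN without odor (both classes
experience the unpaired rule; the 60 s default activation length mirrors
one pairing slot); `odor_only_protocol()` presents odors without the DAN.
Tests are instantaneous reads of the model PI at the scheduled test times;
the two-minute arena test and its 30 s scoring window are treated as a
measurement detail and live in the synthetic-assay noise model instead.

## Inference

All parameters are estimated by exhaustive grid search minimizing the mean
squared difference between model and observed PI, in the staged order the
data dictate: pairing rates and gains from the single-pathway acquisition
data (`fit_acquisition()`, freeing `a_d, g` or `a_n, g`); the wild-type
gain refit under the chosen combination rule with the rates held fixed
(`refit_gain()`); background decay rates from retention data
(`fit_background_decay()`); unpaired decay rates from DAN-activation data
(`fit_unpaired()`). Reversal dynamics are then predictions with no free
parameters. `staged_fit()` runs the whole pipeline.

The search grids are a design choice of this package: rates on a log grid
over [1e-4, 1e2] min^-1 with 61 points, the gain on a linear grid over
[0, 50] with 101 points, and two refinement stages that each shrink the
span tenfold around the incumbent (clipped to the original box), giving a
final resolution of ~0.23% on rates and 0.005 on the gain at a few hundred
thousand model evaluations per fit — a second or so of compute, since the
propagator is vectorized across grid rows. Ties are broken by the first
point in scan order (documented per fit), which makes degenerate fits
deterministic: a dataset of all-zero PIs, for which `g = 0` fits exactly at
any rate, lands on the smallest grid values. Flat loss directions (e.g.
the unpaired rates when a dataset contains no DAN activations) are
detected and flagged in the `fit_result`.

Two properties of staged grid inference deserve a note. First, the
"recover within one final grid step" guarantee applies when each stage sees
exact upstream values; because each stage inherits the previous stage's
*discretized* estimates, coarser refinement than the default propagates
discretization error into correlated downstream valleys (visibly so for
the `b_d`/`b_n` pair under the multiplicative rule). Second, gains are
fitted per condition and kept per condition — the package never implicitly
averages the NO-null and DA-null gains even though they come out similar.

Fitting always uses the deterministic mean-field readout. The sampled
coding mode draws each odor's 10% KC ensemble independently, so ensembles
overlap in ~1% of KCs; those dual-responsive synapses are tracked as a
third class driven by the union of the two odors' schedules. The overlap
biases the control odor's activation by O(f^2) relative to the disjoint
mean field — a real feature of independent sampling, not sampling noise —
so the convergence test compares the sampled mean against the
overlap-aware infinite-population limit and checks the disjoint mean field
only to an O(f) tolerance.

## The synthetic assay generator

The generator stands in for the optogenetic arena: groups of 20 flies
choosing between two odor quadrant pairs, `PI = (n_A - n_B) / n`. Flies
are independent Bernoulli choosers with `p = (PI_model + 1)/2`; the
within-test dynamics are collapsed into that single draw, which makes the
synthetic counts exactly binomial — real arena counts are plausibly
overdispersed (flies interact), and no dispersion estimate is available,
so binomial is the documented default. Each replicate is a reciprocal pair
(a second group trained with the odor identities swapped), and the
pair average cancels any fixed odor-identity bias; the generator exposes a
bias knob solely so tests can demonstrate that cancellation. Defaults are
12 replicate pairs per condition (the middle of the 8–16 range typical for
these assays) and 20 flies per group.

What passing recovery tests on these data do and do not show: they
establish that the estimation machinery is self-consistent (noiseless data
generated at the quoted parameter values are refit to within one final
grid step) and they quantify the sampling precision of the assay design.
They do not validate the model against real behavior — the real PIs exist
only as figure summaries, so real-data refits are out of scope. The
stochastic recovery study is informative in itself: at 12 pairs × 20
flies, the DA pairing rate is recovered within 25% in roughly four seeds
out of five (the 1×10 s protocol is the only one that constrains `a_d`
before the DA effect saturates), and the NO pairing rate spreads wider
still because, at immediate test times, `a_n` and `g` act almost
collinearly on the small expressed NO effect.

## Model phenomena the tests assert

* NO-only (DA-null) memory after a single 1 min pairing is a slow riser:
  under half its 60-minute value at one minute post-training, and still
  above half its 0–24 h peak six hours after training once the fitted
  background decay is included.
* Under the additive rule (refit gain 24.6), ten pairings predict a
  *weaker* memory than three, because `N` keeps growing toward `D ≈ 1` and
  the difference shrinks; the multiplicative rule (gain 14.3) saturates
  instead, keeping |PI| non-decreasing across the acquisition suite. This
  contrast is the main qualitative argument for the multiplicative
  interaction.
* Reversal training flips the sign of the full multiplicative model's PI
  after a single reversal bout, while odor exposure alone changes nothing.
  One related claim is *not* borne out by the fitted parameters and the
  corresponding acceptance check is left failing by design: the DA-only
  model also flips after the first reversal bout when tested at the end of
  the bout, because the new trace forms at `a_d` = 4.3 min^-1 while the
  old one decays at only `b_d` = 0.26 min^-1, and expression (30 s) is
  fast on the bout timescale. The NO contribution shows up instead as a
  larger PI change per bout and an earlier within-bout crossover, not as a
  difference in bout counts.

## Limitations

The model is a compartment-level abstraction: no receptor-level
biochemistry, no spiking, no multi-MBON integration, and no arena
geometry. It deliberately does not model long-term consolidation — the
enhanced persistence seen after 10× spaced training in single-pathway
conditions needs mechanisms beyond these two traces — nor
timing-dependent valence inversion (relief learning), which involves a
different receptor pathway. Background DAN activity is applied only in
segments explicitly marked as such (after training); whether it also
operates during training is not determined by the data the model was built
on, and including it would be a one-line protocol change.

## Reproducing the numbers

```{r, eval = FALSE}
suite <- protocol_library()[c("acq_1x10s", "acq_1x1min",
                              "acq_3x1min", "acq_10x1min")]
ds <- generate_dataset(suite, plasticity_params(),
                       fitted_readouts()["no_null"],
                       assay_config(noise = "none"))
fit_acquisition(ds, "no_null")
```

recovers `a_d` ≈ 4.3 min^-1 and `g` = 14.8 from its own noiseless output;
`scripts/acceptance.R` packages this and the multiplicative gain refit
(`g` = 14.3) as a reproducible report.
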