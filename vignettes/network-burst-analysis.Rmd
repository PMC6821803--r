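---
title: "Network burst analysis of multi-well MEA recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network burst analysis of multi-well MEA recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netburst)
```

## The problem

Neuronal cultures grown on multi-well microelectrode arrays (MEAs) develop
spontaneous population activity over a few weeks in vitro.  In mature
excitatory networks that activity organizes into *network bursts*: short
episodes in which most electrodes of a well fire densely and almost
simultaneously, separated by quieter intervals.  Disease models derived from
patient iPS cells often leave single-cell properties untouched while shifting
the *statistics* of this population rhythm — the rate, duration and
regularity of network bursts, and how much spiking happens between them.
`netburst` implements the full analysis chain from raw extracellular voltage
to a well-level phenotype vector, plus the companion single-cell
(patch-clamp) and molecular (qPCR) quantifications used alongside MEA
phenotyping, and a synthetic-data generator so that every stage can be
validated against known ground truth.

## From voltage to spikes

Raw electrode signals (10 kHz in the reference acquisition setup) are
high-pass filtered with a Butterworth filter (100 Hz cutoff, order 2) applied
forward and backward, so the filter is zero-phase and spike times are not
shifted by the filter's group delay.  The trace is demeaned before filtering;
this rejects the DC component exactly and avoids start-up transients in the
forward–backward pass.

Spikes are detected where the filtered signal exceeds ±`threshold_k` times
the noise standard deviation (default 4.5).  The noise SD is estimated with
the scaled median absolute deviation (MAD/0.6745) rather than the raw SD:
the spikes themselves inflate the raw SD, while the MAD tracks the Gaussian
noise floor as long as spikes occupy a small fraction of samples
(`noise_method = "sd"` restores the plain estimator).  Each crossing is
timestamped at the extremum within 1 ms, and crossings within a 1.5 ms dead
time of an accepted spike are suppressed.  The dead time and extremum rule
are conventional choices for multi-unit MEA data and are exposed as
parameters; no spike sorting is attempted — each electrode is treated as one
multi-unit channel.

## Single-channel bursts: the logISI method

Bursts on one channel are detected from the histogram of
log10(inter-spike interval), with 10 bins per decade and a centered 3-bin
moving average.  In a bursting channel this histogram is bimodal: a fast
intra-burst mode and a slow inter-burst mode.  The intra-burst peak is taken
to be the histogram's *dominant* (global maximum) smoothed peak, and it must
lie below the 100 ms cap.  Requiring dominance makes the procedure
deterministic on non-bursting channels: a stationary Poisson train has its
ISI mode at its mean, so a handful of chance short intervals can never
masquerade as an intra-burst regime.  Candidate separation points are then
scored by the void parameter

\[ v = 1 - \frac{h_{min}}{\sqrt{h_{p1} h_{p2}}} \]

between the intra-burst peak and each later peak; the threshold is the ISI at
the deepest minimum before the first peak with \(v \ge 0.7\), capped at
100 ms.  If no intra-burst peak or no sufficiently void valley exists the cap
itself is used (flagged as a fallback).  Bursts are maximal runs of spikes
whose ISIs all stay at or below the threshold, with at least 5 spikes per
burst; a channel is classified as *bursting* when its burst rate reaches
0.4 bursts/s (inclusive boundary — the boundary convention is documented
because the defining description leaves it open, and it is configurable).

The 100 ms figure is interpreted as a cap on the intra-burst ISI threshold
(the maximum allowed within-burst interval).  A literal reading — spikes at
least 100 ms apart forming a burst — would preclude bursts entirely and is
rejected.

## Network bursts and the phenotype vector

An electrode is *active* when its overall rate is at least 0.1 Hz (no
canonical numeric definition exists; the threshold is exposed as
`min_rate`).  Single-channel bursts on active electrodes are pooled, and
bursts whose intervals overlap or fall within a 100 ms merge gap are chained
into candidate events (transitive closure).  A candidate is a network burst
iff its distinct channels exceed 80% of the active channels — strictly: with
10 active channels, 9 participating channels qualify and 8 do not.  The
merge gap mirrors the intra-burst ISI cap, tying "closely spaced" at the
network level to the same timescale as within-channel bursting.

Per well, the package reports:

* **MFR** — mean firing rate over active electrodes (Hz);
* **NB rate** — network bursts per minute;
* **NBD** — mean network burst duration (s);
* **NIBI** — mean network inter-burst interval (s), measured from the *end*
  of one network burst to the *start* of the next (the defining phrase
  "interval between consecutive network bursts" is ambiguous; end-to-start
  is used and documented, onset-to-onset differs by one mean NBD);
* **CV of NIBI** — population SD over mean of the NIBI distribution, the
  irregularity measure (population rather than sample SD because the CV is
  used descriptively; at the typical 50+ intervals per recording the
  difference is negligible);
* **% spikes outside** — percentage of active-electrode spikes falling
  outside every network-burst window.  Spikes inside plus outside equal the
  total exactly, by construction.

Undefined quantities (no active electrodes, fewer than two network bursts)
propagate as `NA` sentinels, never as zeros.

## The synthetic generator

`simulate_well()` emulates the structure of a mature bursting culture: a
network-burst skeleton, per-channel participation, dense intra-burst firing
and sparse background spiking.  The skeleton alternates gamma-distributed
inter-burst gaps (mean `mean_nibi`, CV `cv_nibi`; shape \(1/cv^2\), scale
\(mean \cdot cv^2\)) with gamma-distributed durations (mean `mean_nbd`, CV
`nbd_cv`).  Alternating gaps and durations — rather than drawing
onset-to-onset intervals — makes the generated end-to-start NIBI *exactly*
the parameterized quantity, so its sample mean and CV converge to the
configured values and parameter-recovery tests are meaningful.  Within each
burst every active channel joins with probability `participation_p` and
fires a homogeneous Poisson train at `intra_burst_rate`; background activity
is homogeneous Poisson at `background_rate` over the whole recording.
Everything descends from one integer seed.

Two presets encode the qualitative group phenotypes studied with this kind
of pipeline.  They differ **only** along the phenotype axes:

| parameter | `control_preset()` | `ks_preset()` |
|---|---|---|
| mean NIBI (s) | 15 | 40 |
| CV of NIBI | 0.3 | 0.7 |
| mean NBD (s) | 1 | 3 |
| background rate (Hz) | 1 | 0.3 |

so the KS-like preset has fewer, longer, more irregular network bursts and a
smaller percentage of spikes outside bursts.  No published per-well
generative parameters exist for these cultures; the preset values are
repository choices that reproduce the qualitative ordering of the group
phenotypes at realistic magnitudes (tens of seconds between bursts,
second-scale bursts, 20-min recordings, 12 electrodes/well).  The default
recording length (1200 s), well geometry and intra-burst rate (60 Hz per
channel) are likewise chosen to resemble mature iNeuron cultures on
24-well MEA plates.

What the generator does *not* emulate: developmental drift within a
recording (all processes are stationary), electrode cross-talk, bursts with
internal rate structure (onset jitter per channel, rate ramps), or
non-Poisson background such as isolated minor bursts.  Tests that pass on
synthetic data therefore certify the *analysis* chain — detection, merging,
counting, statistics — under a faithful generative model of the burst
skeleton, not the biological realism of any particular culture.

```{r phenotype}
ctl <- summarize_plate(simulate_plate(control_preset(), 4, "control",
                                      seed = 1)$plate)
ks  <- summarize_plate(simulate_plate(ks_preset(), 4, "KS", seed = 11)$plate)
round(rbind(control = colMeans(ctl[, 4:9]), KS = colMeans(ks[, 4:9])), 2)
```

## Pharmacology normalization

Treatment experiments (AMPAR/NMDAR antagonists, chronic NMDAR blockade) are
expressed per well relative to its own non-treated (NT) baseline:
`normalize_to_baseline()` maps the NT segment to exactly 1, full suppression
to 0, and is invariant to rescaling the raw metric.  `recovery_fraction()`
interpolates the normalized trajectory piecewise-linearly between recorded
segments — recordings sample the washout at discrete times, and no
parametric recovery model is assumed.  Group tables report mean ± SEM only;
hypothesis testing is deliberately out of scope.

## Phenotype classification

`fit_discriminant()` implements canonical discriminant functions: features
are standardized internally, the pooled within-group covariance \(W\) gets a
ridge of \(10^{-8}\,\mathrm{tr}(W)\) on the diagonal (guarding near-singular
feature sets while leaving well-conditioned problems untouched), and the
canonical axes solve the between/within eigenproblem, scaled to unit pooled
within-group variance.  There are `min(groups − 1, features)` canonical
functions.  Reclassification assigns each well to the nearest group centroid
in canonical space with equal priors by default (proportional priors
optional); the reported accuracy is resubstitution accuracy, matching the
reclassification-of-group-membership convention of classical statistical
packages, with a leave-one-out mode (`method = "loo"`) for honest error
estimates.  Group envelopes are 95% chi-square ellipses (2 df) of the
canonical scores, centered on the group centroids; one-function models are
padded with a zero second dimension for plotting.

The default feature set is the five-metric network vector (MFR, NB rate,
NBD, % spikes outside, CV of NIBI).

```{r lda}
tab <- rbind(ctl, ks)
model <- fit_discriminant(tab, tab$group_label)
reclassify(model, tab, tab$group_label)$percent_correct
```

## Patch-clamp quantification

* **sEPSC bursts** use the same run-scan as channel bursts with a fixed
  100 ms inter-event threshold and 5-event minimum (no adaptive logISI step:
  event trains are far sparser than MEA channels).
* **NMDA/AMPA ratio**: sweeps at −70 mV and +40 mV are baseline-subtracted
  (mean of the 50 ms pre-stimulus window).  The AMPA amplitude is the most
  negative deflection in a 2–50 ms post-stimulus window (the first 2 ms are
  blanked against the stimulus artifact; the defining rule gives no search
  window, so both bounds are parameters); the NMDA amplitude is the mean
  over 65–70 ms post-stimulus, late enough that the fast AMPA component has
  decayed.  The window anchor is the stimulus onset (for the slice protocol
  the anchor could also be read as the end of the stimulus artifact; onset
  is used, switchable via the window arguments).  Pairs whose AMPA amplitude
  falls below 25 pA are flagged as failing QC.
* **Decay constant**: single-exponential least-squares fit from the point
  where the current drops to 90% of its peak, down to 2% of peak or sweep
  end; nonlinear least squares with a log-slope-derived starting value.
* **Passive properties** from a 0.5 s, −25 pA step: input resistance by
  Ohm's law on the late-plateau deflection (last 20% of the step, with a
  drift check), membrane tau from an exponential fit of the charging
  transient.
* **AP features** at rheobase: threshold at the sample preceding the first
  dV/dt ≥ 20 V/s crossing (a standard convention), amplitude peak-minus-
  threshold, half-width at half amplitude with sub-sample interpolation, and
  decay time from peak to the falling half-amplitude crossing.  Rheobase is
  the smallest ladder current eliciting an AP.

mEPSC event *detection* is out of scope; the module consumes event times.

## Molecular quantification

ChIP-qPCR enrichment is `100 × 2^−ΔCt` with
`ΔCt = Ct[ChIP] − (Ct[input] − log2(dilution factor))`; relative expression
is the plain `2^−ΔΔCt` model with no amplification-efficiency correction.
Technical duplicates are averaged **on the Ct scale** before any
exponentiation; biological replicates are summarized as mean ± SEM on the
computed scale.  Both formulas are exact closed forms and are tested to
1e-12 against independent log-space recomputation.

```{r qpcr}
percent_input(25, 20, dilution_factor = 100)
ddct_fold_change(20, 18, 22, 18)
```

## Numerical and design notes

* All times are seconds from recording start; rates are Hz internally, with
  network-burst rate reported per minute at the reporting layer.
* Missing electrodes are absent; an electrode with zero spikes is an
  explicit empty train.  Spike tables store times at 0.1 µs resolution;
  rows coinciding at that resolution collapse to one spike on read.
* Raw traces and sweeps use an annotated plain-text container (attribute
  lines plus one sample line per trace at 17 significant digits), so
  write/read round trips are bit-exact and fixtures stay diffable.
* Burst *count* is not monotone in the ISI threshold (a larger threshold
  merges adjacent bursts); the monotone quantity, verified by the property
  tests, is the number of spikes covered by bursts.
* Test problem sizes: the burst-scan equivalence runs 1,000 random 20-min
  Poisson trains against a literal brute-force scanner; phenotype separation
  uses 10 wells per preset; detection and ratio-recovery checks use 100
  seeded replicates each.  These sizes put Monte-Carlo standard errors well
  inside the asserted tolerances.

## Known limitations

* The logISI internals (bin count, smoothing, void threshold, peak rule) are
  parameterized reconstructions of common practice; vendor implementations
  differ in unpublished details, so absolute burst counts may differ between
  tools even when the phenotype ordering is preserved.
* The discriminant module is linear by design; no feature selection or
  nonlinear classifier is provided.
* No liquid-junction-potential or series-resistance corrections are applied
  to patch-clamp sweeps.
* Published group-level values from patient-derived recordings cannot be
  reproduced from this package alone: the underlying recordings are not
  publicly deposited, which is precisely why the validation strategy is
  simulation- and property-based.
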