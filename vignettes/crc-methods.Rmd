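---
title: "Quantifying cardiorespiratory coupling around neonatal bradycardia: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying cardiorespiratory coupling around neonatal bradycardia: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crcoupling)
```

## The question and the measurement model

Preterm infants commonly suffer bradycardia — the heart rate dropping below
100 bpm, equivalently the R-R interval exceeding 0.6 s — often in the context
of apnea of prematurity. The cardiac and respiratory rhythms of a healthy
infant are not independent: vagally mediated cardiorespiratory coupling (CRC)
ties the heart period to the respiratory cycle. This package quantifies
whether that interdependence differs between bradycardic (B) and
non-bradycardic (NB) periods.

The measurement model is deliberately simple. Two event series per subject —
heartbeat times and breath times — are reduced to interval series: the R-R
tachogram and the inter-breath-interval (IBI) series, in seconds. After
artifact handling, both are resampled on one shared 4 Hz grid so that each
grid sample pairs an instantaneous R-R value with an instantaneous IBI value.
Grid samples are labeled B or NB by the bradycardia rule, the majority (NB)
class is undersampled to the minority size, and the paired values of each
condition are binned into histograms. All comparisons then operate on four
histogram functionals, in bits:

* Shannon entropy of each marginal, $H(X) = -\sum_i p(x_i) \log_2 p(x_i)$,
  the irregularity of each rhythm;
* cross-entropy in both directions, $cH(X,Y) = -\sum_i p(x_i) \log_2 p(y_i)$,
  a by-bin-index divergence of the two marginals;
* mutual information, $MI(X,Y) = H(X) + H(Y) - H(X,Y)$ from the joint
  histogram, the coupling measure proper.

Because the histograms are order-invariant, MI here measures *static*
value-vs-value dependence between the instantaneous R-R and IBI values, not
phase synchronization — an important point for interpreting both real and
synthetic results (see the generator section).

Per subject, the stochastic stages (outlier replacement and undersampling)
are repeated over many trials; each subject is summarized by the median of
each metric over trials; the cohort comparison is an exact Wilcoxon
matched-pairs signed-rank test of the per-subject B medians against the NB
medians. `crc_study()` runs this whole protocol and returns a classed object
with `print`, `summary` and `plot` methods.

## Preprocessing

**Recognition errors.** Intervals that cannot be physiological are deleted
outright before anything else: non-positive values and values outside
plausibility bounds (defaults: R-R in [0.2, 2.0] s, IBI in [0.3, 15] s).
Removing over 20% of a series raises a quality warning.

**Adaptive replacement filter.** The remaining artifacts — missed or spurious
beats producing isolated doubled or halved intervals — are handled by a
streaming filter maintaining an adaptive mean $\mu_a$ and standard deviation
$\sigma_a$, updated exponentially (`adapt_coeff` $c = 0.05$) with every
incoming sample. A sample is an outlier if it jumps more than `percent_limit`
relative to its predecessor, or deviates from $\mu_a$ by more than
`sigma_mult` $\sigma_a$ (default 3). Outliers are replaced by uniform draws
from $[\mu_a - 0.5\sigma_a,\, \mu_a + 0.5\sigma_a]$ — the protocol's source of
trial-to-trial variability.

Two design points deserve emphasis:

* *The adaptive statistics absorb every sample, accepted or not.* If the
  statistics froze on rejected samples, $\sigma_a$ could never widen to admit
  a sustained physiological shift, and the controlling filter would reject a
  bradycardic deceleration beat after beat until the episode was erased — the
  very signal the study needs. Updating on all samples lets the filter track
  genuine nonstationarity at the cost of brief blindness after a gross
  artifact (the inflated $\sigma_a$ decays at rate $c$). A side benefit is
  that outlier *decisions* depend only on the input, so two trials differ
  only in the replacement values, never in which samples are replaced.
* *`percent_limit` defaults to 0.5*, not the 10–20% sometimes used for adult
  records. Neonatal respiratory modulation at the depths this analysis
  studies produces legitimate beat-to-beat R-R changes of tens of percent; a
  10% limit would classify physiological modulation as artifact and replace
  most of the record with noise. At 0.5 the filter still catches the
  missed-beat signature (a doubled interval), while the controlling filter
  covers smaller but statistically extreme deviations.

**Resampling.** Both interval series are interpolated at 4 Hz over the
intersection of their time spans, so the two grids are identical and samples
are paired. The interpolant is the Fritsch–Carlson shape-preserving piecewise
cubic (`stats::splinefun(method = "monoH.FC")`): unlike a natural cubic
spline it cannot overshoot, which matters near bradycardia steps where
overshoot would manufacture spurious R-R values below the data range. Linear
interpolation is available as a config alternative. No further smoothing is
applied; the anti-aliasing effect of interpolation onto a 4 Hz grid is the
only high-frequency attenuation.

## Segmentation

Bradycardia is flagged on the *beat-wise* filtered R-R series — "lasts at
least two beats" is a beat-domain statement — and transferred to the grid as
time spans. An interval of at least `rr_threshold` = 0.6 s is bradycardic if
together with at least one neighbouring interval it spans `pair_sum` = 1.2 s;
the first interval of a series can only pair with its successor and the last
only with its predecessor. This neighbour-either reading implements
"sustained for two beats": every interval of a $\geq$ 2-beat run of slow
beats is flagged, an isolated slow beat is not, and no interval under 0.6 s
is ever flagged (a hard invariant, property-tested). Equality is included at
both thresholds.

Each maximal run of flagged intervals becomes a span from the start of its
first interval (end-anchored timestamps minus the value) to the end of its
last. Grid samples are labeled B if their time falls in a span, closed on the
left and open on the right. A subject-trial needs at least `min_b_samples` =
8 bradycardic grid samples (2 s at 4 Hz) to be usable; below that the trial
is recorded as failed, and a subject with no completed trials is excluded
from the cohort comparison.

Random undersampling draws individual paired grid samples (not contiguous
blocks) uniformly without replacement from the NB majority, because the
histogram measures are order-invariant and per-sample draws give the least
variance for a fixed sample count.

## Binning and estimation choices

Histograms use `n_bins` = 16 equal-width bins per variable (and 16 x 16 for
the joint), with edges spanning the pooled B + NB range of that subject-trial,
rightmost edge inclusive. A fixed bin count keeps entropies comparable across
subjects, trials and conditions and bounds every marginal entropy by 4 bits;
shared pooled edges mean condition differences reflect distribution *shape*,
not support. Degenerate (zero-width) ranges raise an error rather than
producing silent one-bin histograms.

Cross-entropy is infinite if the reference distribution has an empty bin
where the source has mass. Only in that case the reference is smoothed with
Jeffreys pseudo-counts (add 0.5 per bin, renormalize); otherwise it is used
untouched, so `cross_entropy(p, p)` equals `shannon_entropy(p)` whenever `p`
has no empty bins.

MI is the plug-in estimator, exactly $H(X) + H(Y) - H(X,Y)$, with no bias
correction. Its finite-sample bias is positive and grows with the number of
occupied cells over the sample count; balancing the conditions to equal
sample counts makes the bias comparable between B and NB but not identical
(see limitations).

The exact Wilcoxon signed-rank test drops zero differences, average-ranks
ties, uses $W = \min(W^+, W^-)$, and computes the two-sided p-value as the
null probability over all $2^n$ sign assignments that $\min(W^+, W^-)$ is at
most the observed value — evaluated by an exact convolution over the
(doubled, tie-averaged) ranks, which is algebraically the full enumeration.
At the cohort sizes involved ($n \le 10$) a normal approximation would be
inaccurate and is not offered.

## The synthetic cohort generator

The generator exists so the entire pipeline can run, and be tested, with no
clinical recordings. It emulates the statistical structure the analysis
assumes, not waveforms.

Breath intervals follow a stationary AR(1) process around `mean_ibi` = 1.5 s
(40 breaths/min) with coefficient of variation `ibi_cv` = 0.2 and lag-1
autocorrelation `ibi_ar1` = 0.9 — breath durations wander slowly with
autonomic state rather than jumping independently. Beats are generated
sequentially: the next R-R interval is

$$RR = \overline{RR} \cdot f \cdot \big(1 + m\,[\,a_{rsa}\, w \sin(2\pi\phi)
 + a_{tone} (w - 1)\,]\big)\cdot(1 + \varepsilon)$$

with $\phi$ the fractional phase of the current breath, $w$ the current
breath's duration relative to the mean (clipped to [0.6, 1.4]),
$\varepsilon$ Gaussian noise (cv 0.03), and $f$ the bradycardia elongation
factor. The coupling depth $m$ (0.3 outside episodes, 0.05 inside, by
default) scales two channels: phase-locked respiratory sinus modulation whose
amplitude grows with breath duration ($a_{rsa} = 0.5$), and a shared-drive
"tone" channel that lengthens the heart period when breathing slows
($a_{tone} = 1.5$). The second channel is essential: a phase-locked
modulation of fixed amplitude leaves the *value-vs-value* joint distribution
of R-R and IBI essentially independent, so histogram MI would not respond to
$m$ at all. With both channels, pipeline MI rises monotonically in $m$
(property-tested) and the NB-condition grid correlation sits near 0.6 at
$m = 0.3$.

Bradycardia episodes start at thinned Poisson times (`brady_rate` = 40/h),
ramp geometrically over 4 beats to a plateau of `brady_depth` = 2.0 times the
baseline for `brady_beats` = 12 beats, and ramp back down — a 10–15 s
deceleration-plateau-recovery profile typical of apnea-associated events. The
ramp is not cosmetic: a single-beat step is statistically indistinguishable
from a gross artifact and would be removed by any defensible outlier filter,
whereas a graded deceleration (about 15% per beat) passes the percent filter
and lets $\sigma_a$ widen before the plateau arrives. Depth 2.0 keeps the
plateau above 0.6 s under episode-level modulation for every subject, so each
episode yields one contiguous run of bradycardic intervals; ground truth
spans are recorded from the emitted intervals and, on noiseless fixtures, are
recovered *exactly* by the segmentation (tested).

Per-subject mean R-R is drawn from [0.36, 0.42] s, giving mean heart rates
within the 131–167 bpm band reported for preterm cohorts while keeping
headroom below the 0.6 s threshold: at 0.42 s baseline even the deepest
default modulation peaks near 0.59 s, so non-episode beats cannot trip the
bradycardia rule.

Record duration defaults to 2 h per subject. This was a measured choice, not
convenience: with 30-minute records a subject has only ~10 episodes, the B
condition's samples are serially clustered in those few events, and the
plug-in MI of the B condition carries a systematic offset against NB of
order +0.1 bits purely from clustering. At 2 h (~80 episodes) the measured
offset falls to below 0.01 bits. Shorter records remain available through
`duration` and are used deliberately in some tests.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: ECG or respiration waveforms and their
annotation errors (beyond isolated spikes), apnea (breathing never pauses),
periodic breathing, sleep-state transitions, the co-occurrence of apnea and
bradycardia, drift over the 20–70 h of a real NICU recording, and any
respiratory change *during* episodes (IBI statistics are identical in B and
NB by construction, so a real difference in respiratory irregularity during
bradycardia is outside the synthetic model).

## Protocol sizes and numerical conventions

The package's own studies use: 10 subjects, 100 trials per subject (the full
protocol; the per-subject trial medians feed the cohort test), trial seeds
`base_seed + 7919 i + k` so every draw is traceable to one master seed, and
16-bin histograms. The test suite scales some simulations down — 20-trial
studies for replicate power checks, 2-trial studies inside a 200-replicate
null calibration — and states the sizes in each test. Determinism is end to
end: a configuration plus seed reproduces every output bit-for-bit, and the
synthetic fixtures regenerate byte-identically.

Conventions worth knowing: $0 \log 0 = 0$ throughout; histogram bins are
left-closed right-open with the last bin closed; probability vectors must sum
to 1 within $10^{-12}$; MI may be a rounding hair below zero and is not
clamped; grid labeling is closed-left open-right; equality counts as
exceeding both bradycardia thresholds.

## Known limitations

* **The B/NB comparison is conditioned on the segmentation.** Bradycardic
  samples differ from NB samples by construction — that is what makes them
  bradycardic — so *every* metric, not only MI, mixes coupling differences
  with episode-morphology differences. Even with identical coupling depth in
  and out of episodes, the episode waveform adds R-R variance unrelated to
  respiration (deflating B-condition MI) while the serial clustering of
  episode samples inflates the B-condition plug-in MI; the net offset
  depends on episode rate, length and record duration. At the default
  conditions the residual offset is small but not exactly zero, so the
  false-positive rate of the MI comparison under an equal-coupling null sits
  near, and possibly above, the nominal 5%. Interpreting a B-vs-NB MI
  difference as a pure coupling change therefore requires the same caution
  with real recordings as with synthetic ones.
* **Plug-in estimators are biased.** No Miller–Madow or shrinkage correction
  is applied, matching the plain definitions; balanced sample counts make the
  bias comparable, not equal, across conditions.
* **The 16-bin alphabet is a convention.** Entropy magnitudes scale with the
  bin count; only within-study comparisons are meaningful.
* **Cross-entropy pairs bins by index** across two physically different
  supports (R-R vs IBI seconds); it is a divergence of histogram shapes, not
  of physical quantities, and is reported for completeness.
* **The exact test's p-values are discrete**: with 10 subjects the smallest
  attainable two-sided p is about 0.002, and nominal levels are reached only
  approximately.
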