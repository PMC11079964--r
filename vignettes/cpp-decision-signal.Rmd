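---
title: "Decision-locked analysis of the centro-parietal positivity"
author: "cppErp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decision-locked analysis of the centro-parietal positivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cppErp)
```

## The scientific problem

The centro-parietal positivity (CPP) is a slow positive EEG potential over
central-parietal scalp whose build-up rate tracks the formation of a
decision: its amplitude peaks around the moment of commitment, and under an
accumulation-to-bound account the potential climbs to a roughly fixed bound,
so faster decisions show steeper ramps. This package implements the complete
analysis chain used to test whether such a signal accompanies decisions made
about *internal* content — selecting and reporting an item held in visual
working memory after a symbolic retro-cue — together with a synthetic-data
generator that produces continuous EEG with a ground-truth
accumulation-to-bound component, so that every stage of the chain can be
validated against known truth without any data download.

The two signatures the chain quantifies are:

1. **Decision-time scaling.** Trials are binned by decision time (the
   interval from cue onset to report onset). Under bound-fixed accumulation,
   the pre-decision slope of the response-locked CPP falls with decision
   time; the analysis quantifies this as a per-participant Pearson
   correlation between bin number and slope, tested against zero across
   participants.
2. **Selection demand.** When the relevant memory item still has to be
   selected among alternatives after the cue, the CPP is larger and decisions
   are slower than when the item was pre-selected at encoding; the analysis
   detects this with paired cluster-based permutation tests along the time
   axis.

## The generative model

For trial $i$ with decision time $DT_i$ (ms after cue) and condition $c$, the
noiseless component at channel $k$ and time $t$ after the cue is

$$s_{ik}(t) = w_k \, A_c \cdot \max\!\left(0, \frac{t - t_0}{DT_i - t_0}\right),
\qquad t \le DT_i,$$

decaying as $A_c\,e^{-(t - DT_i)/\tau}$ afterwards. The component reaches the
bound $A_c$ exactly at the response sample, so its ramp slope is
$A_c/(DT_i - t_0)$ — the quantity `expectedSlope()` returns and the
parameter-recovery tests check. The spatial profile $w_k$ is an isotropic 2-D
Gaussian over flattened 10-10 coordinates centred between Pz and CPz
(SD 0.3 head radii), which concentrates the component on the a priori
analysis cluster ("Pz", "CPz", "POz", "P1", "P2").

Decision times follow a shifted lognormal,
$DT = \delta + \mathrm{LogNormal}(\mu, \sigma)$, chosen for its realistic
right skew. The defaults $\delta = 200$ ms, $\mu = 6.17$, $\sigma = 0.55$
give a cohort mean of $200 + e^{6.17 + 0.55^2/2} = 756.6$ ms. Draws are not
truncated to the 200–2000 ms analysis bounds, so the downstream exclusion
filter is genuinely exercised (about 0.8% of default draws exceed 2000 ms).

Noise has four components, each with configurable RMS: 1/f ("pink") noise
synthesized in the frequency domain with power spectral density
$\propto 1/f$ (log-log slope $-1$, the dominant EEG background), white
sensor noise, a 10 Hz alpha oscillation with random phase per channel, and a
slow common-mode drift shared by all channels, which mastoid-average
rereferencing removes (this is what makes the rereferencing step testable).
Defaults are 10, 5, 4 and 2 µV RMS — single-trial broadband noise an order
of magnitude above the 10 µV component bound, as in real recordings.

A brief cue-evoked transient (Gaussian envelope, SD 40 ms, peak ~60 ms after
cue, default 3 µV) models the visual response to the fixation-cross color
change. Because the cue is a small foveal stimulus, the transient is given
an occipital locus ((0, −0.75), SD 0.45). Its amplitude and locus matter for
one subtle reason: for the fastest decision-time quartile the −500..−50 ms
pre-decision window reaches back to the cue, so a large centro-parietal
transient would leak into the slope estimate of the fastest bins and could
mask the slope-vs-decision-time gradient that the real data show. With the
default settings the noiseless group slope profile is strictly decreasing
across quartiles while the transient remains clearly visible in cue-locked
ERPs. For the same reason the accumulation onset defaults to $t_0 = 50$ ms:
with a much later onset, most of the fastest bin's slope window precedes
accumulation entirely.

Reproduction errors are von Mises on the doubled orientation angle
(orientation space is 180°), sampled with the Best–Fisher algorithm; the
concentration is solved numerically (`kappaForMeanError`) so that the mean
absolute error matches a target (14.14° for the single-condition defaults;
13.0° vs 11.1° for the two conditions of the load-contrast configuration).

The load-contrast configuration (`simConfigLoadContrast()`) emulates the
selection-demand manipulation: 20% of trials require item selection
("selection_required", bound 12 µV, +250 ms decision-time shift) and 80% are
pre-selected (8 µV, no shift), with $\mu = 5.9068$ so the condition means
sit near 627.6 and 877.6 ms.

What the generator does **not** emulate: ocular artifacts (hence no ICA in
the pipeline), electrode drift, realistic volume-conduction forward models,
trial-wise variability in the bound, and any dependence of the CPP on
response accuracy. Optional trial-wise onset jitter exists
(`onsetJitterSdMs`) but defaults to 0; no claim is made that single-trial
dynamics match real data. Passing tests therefore validate the *pipeline* —
estimators, exclusion rules, statistics — not the physiological fidelity of
the simulation.

## The analysis chain

Preprocessing mirrors standard practice for this signal: rereference to the
mastoid average (reference channels retained); zero-phase FIR anti-alias
filtering (Hamming-windowed, 101 taps, cutoff 0.4 × target rate) and
decimation from 1000 Hz to 250 Hz, implemented as FFT convolution with a
wrapped symmetric kernel plus spectral folding (exactly equivalent to
filter-then-decimate, at a fraction of the cost on multi-million-sample
recordings); epoching around cue (−250..+1500 ms) or response
(−1500..+500 ms); exclusion of trials with decision times strictly below
200 ms or strictly above 2000 ms (boundary values kept — "below" and
"above" are read as strict); removal of high-variance trials; and baseline
correction (250 ms before the cue, or 250 ms after response initiation —
the post-response window avoids pre-cue memory-maintenance differences, and
the slope statistic is baseline-independent anyway). CPP time courses are
smoothed with a 30 ms SD Gaussian kernel (truncated at 4 SD, renormalized,
reflect padding) in place of low-pass filtering.

Epoch windows are a package choice (the procedure itself fixes only the
baselines and analysis windows): they cover every analysis window —
topographies to 600 ms post-cue, slope windows starting 1000 ms before the
response, the post-response baseline — with margin beyond 4 smoothing SDs,
so boundary handling cannot touch any reported statistic.

In place of visual trial rejection, the pipeline flags trials whose
log broadband variance (over the analysis channels) has a robust z score
(median/MAD) above 3.5. Like the manual original it is condition-blind — the
flagging consults no metadata — but unlike it, it is deterministic and
reproducible.

The CPP quantities: the unweighted mean over the five-channel Pz cluster;
grand-average ERPs with two-stage averaging (trials within participant,
then mean ± SEM across participants, SEM denominator = number of
participants); decision-time binning into 100 percentile bins (ERP images)
and 4 quartile bins; the pre-decision slope as the OLS coefficient of
potential (µV) on time (s) over the closed window [−500, −50] ms; the
Pearson correlation between bin *number* (not bin mean decision time — the
procedure is defined on bin number) and slope; and a window sweep computing
the group t of that correlation over a grid of window starts
(−1000..−200 ms, step 50) and ends (−400..0 ms, step 50) with a 100 ms
minimum length, which contains the a priori (−500, −50) cell.

Binning details the procedure leaves open, fixed here: trials are stable-
sorted by decision time with ties broken by trial id; bins are contiguous
and as equal as possible, remainder trials going to the earliest (fastest)
bins; window boundaries are closed at both ends; a degenerate slope profile
(zero variance) yields a missing correlation rather than 0. Whether per-bin
ERPs are smoothed before or after binning is also left open; the default
smooths after binning (`smoothBinned = TRUE` in `analyzeCohort`) — the two
orders differ only through trial-count weighting and are nearly identical in
practice.

## Statistics

Second-level inference is a one-sample t test of per-participant statistics
against zero (or of paired differences), with Cohen's
$d = t/\sqrt{n}$ — an exact identity for these designs, asserted on every
result the package emits.

The cluster-based permutation test controls the family-wise error of
time-resolved comparisons: per-timepoint t values are thresholded at the
two-sided parametric critical value for $\alpha = 0.05$ (the conventional
default of the toolboxes implementing this method; the threshold only
shapes sensitivity, not validity), contiguous same-sign suprathreshold runs
form clusters scored by the sum of t ("maxsum"), and the null is built from
whole-participant sign flips (condition swaps for paired designs — the
exchangeability unit is the participant), taking the maximum absolute
cluster mass per permutation. Monte-Carlo p values use the
$(1 + \#\{\text{null} \ge \text{observed}\})/(1 + N)$ convention, so
$p > 0$ always; with $2^n \le 2^{14}$ patterns the null is enumerated
exactly instead (`enumerateClusterNull`), which also serves as the oracle
the Monte-Carlo path is tested against. A zero-variance timepoint with
nonzero mean (infinite t) is capped at $\pm 10^6$ so degenerate fixtures
still form maximally massive clusters. `clusterTestFpr()` measures the
family-wise false-positive rate on pure-noise cohorts; the suite requires it
to land in [0.03, 0.07] over 500 simulations.

## Problem sizes and numerical choices

The validation suites simulate cohorts of 25 participants with ~605 trials
each (≈600 surviving the exclusion law) for the single-condition analysis,
and ~705 trials (≈703 retained) for the load contrast — trial counts chosen
so retained counts match the regimes the analyses are designed for. These
cohort runs use the generator's 12-channel "compact" montage (the Pz
cluster, midline/lateral context channels, and both mastoids): every
statistic in the chain is computed from the 5-channel cluster average plus
the mastoids, so the remaining 51 channels of the full 61+2 montage
contribute nothing but simulation cost. The full montage remains the
default and is exercised by the topography and container tests. Cluster
tests in the suites use 2000 permutations (minimum attainable p ≈ 5e-4);
the acceptance script uses 10000.

Numerical conventions worth knowing: decision times are recomputed from
event samples after decimation and may shift by under one 4 ms sample
period; the FIR kernel is renormalized to unit DC gain so constants pass
through exactly; FFT convolution zero-pads to a 2-3-smooth length, confining
edge transients to half a kernel at each end; Gaussian smoothing uses
reflect padding, and slope windows sit more than 4 SD from epoch edges so
the padding choice cannot reach them; permutation null-mass comparisons use
a relative tolerance of 1e-9 so that the identity permutation always counts
as an exceedance of its own mass.

## Known limitations

* The simulation validates estimator correctness, not physiology: effect
  sizes on synthetic cohorts (e.g. the group t of the slope–bin correlation)
  are set by the chosen signal-to-noise ratio and will generally be larger
  than in real recordings.
* Cluster inference is purely temporal, on the a priori channel cluster;
  spatiotemporal (channel-adjacency) clustering is out of scope.
* No ocular artifact handling exists because the generator injects none.
* The container format is bespoke (documented JSON + float32 + TSV);
  vendor EEG formats are not read.
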