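---
title: "State-conditioned phenotyping of preoptic calcium traces: models and design choices"
author: "vlpoCalcium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{State-conditioned phenotyping of preoptic calcium traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vlpoCalcium)
```

## The analysis problem

Miniscope recordings of GCaMP-expressing neurons in the ventrolateral
preoptic area (VLPO) yield one fluorescence trace (ΔF/F₀, 10 Hz) per unit
while the animal cycles through active waking (AW), quiet waking (QW), nonREM
and REM sleep, scored in 10-s epochs from EEG/EMG. The analysis asks, per
unit: *how does activity depend on vigilance state*, and per population:
*how do the resulting phenotype groups respond to homeostatic sleep
pressure* built up by sleep deprivation (SD)?

The pipeline is: condition the traces (normalise, align, average into the
10-s epochs of the hypnogram), profile each unit's mean activity per state,
classify units by ratio thresholds, grade the strength of each call,
tabulate the census across animals and genotypes (VGAT vs unidentified
units), and, for SD sessions, compare group activity across baseline,
deprivation hours and recovery together with the NREM delta-power (2–4 Hz)
rebound. All hypothesis tests are nonparametric (rank-based).

## Classification model

For unit $i$ with per-state means $m_{AW}, m_{QW}, m_{NREM}, m_{REM}$
(averaged over **all** epochs of each state in the session), three ratios
drive the rules:

$$r_{NA} = \frac{m_{NREM}}{m_{AW}},\qquad
  r_{RA} = \frac{m_{REM}}{m_{AW}},\qquad
  r_{RN} = \frac{m_{REM}}{m_{NREM}}.$$

Decision order (first match wins):

1. **REMS-active** if $r_{RA} > 2$ and $r_{RN} > 2$;
2. **nonREM sleep-active** if $r_{NA} > 1.25$ — subtype
   *nonREMS/REMS-max* if $r_{RN} > 0.5$, else *nonREMS-max*;
3. **wake-active** if $r_{NA} < 0.75$ — subtype *wake/REMS-max* if
   $0.75 < r_{RA} < 2$, else *wake-max*;
4. otherwise **state-indifferent** (±25 % band around $m_{AW}$).

Three points here were genuinely open and decided as follows:

* **REM selectivity is tested first.** REM-selective units typically carry
  $r_{NA}$ above 1.25 as well (the published REMS-active group mean has
  $r_{NA} = 1.8$); testing the nonREM rule first would absorb them, so the
  REM rule takes precedence.
* **The subtype split within nonREM sleep-active units uses
  $r_{RN} > 0.5$, i.e. REM retains at least half of the NREM activity.**
  Read literally as NREM/REM > 0.5 the published cut separates nothing (both
  subgroups satisfy it); the REM-retention reading reproduces both published
  subgroup profiles ($r_{RN} = 1.09$ → nonREMS/REMS-max, $0.32$ →
  nonREMS-max). This interpretation is deliberate and flagged here.
* **Strength grades are fold change relative to the lower state mean.**
  Grades are weak (25–50 %), moderate (>50–100 %), strong (>100 %) on
  $e = \text{fold} - 1$: sleep-active units use $r_{NA} - 1$ (REMS-active:
  $\min(r_{RA}, r_{RN}) - 1$), wake-active units use
  $m_{AW}/m_{\text{sleep}} - 1$ (the smaller of NREM and, for wake-max, REM).
  A ">100 % decline" is impossible on a $(AW - x)/AW$ scale, so suppressions
  are graded on the inverted fold change, the only arithmetic consistent
  with the published bands.

Boundary conventions: $r_{RA}$ exactly 0.75 or exactly 2.0 gives wake-max
(strict inequalities); QW is profiled and reported but never enters a rule.
Units with intermediate REM elevation ($0.75 \le r_{NA} \le 1.25$ and
$1.25 < r_{RA} \le 2$) fall to state-indifferent by the literal rules; they
are counted and flagged (`si_band_ok = FALSE`) rather than silently
absorbed. Every rule is scale-free: rescaling a unit's trace by any positive
constant leaves its call unchanged.

Each rule can be validated by logistic regression
(`logisticValidation()`): a maximum-likelihood fit of rule membership on the
rule's ratio(s), fitted jointly when a rule uses two ratios (the univariate
alternative is a one-line change). Perfect separation — expected whenever
membership is computed deterministically from the fitted ratio itself — is
detected and reported as such instead of pretending the Wald statistics are
meaningful.

## Trace conditioning

* **Normalisation.** The default is `"scale"`: divide the whole-session
  trace by its standard deviation *without centring*. Centred z-scores make
  state means signed, which breaks both ratio thresholds and the 0.5 quality
  cut (a published threshold on a scale whose reported state means are all
  positive, implying a non-centred normalisation). `"zscore"` and `"none"`
  remain available; the z-score operation itself (`zscoreTrace()`) gives
  mean 0, sd 1 and is idempotent.
* **Quality filter.** A unit is dropped when the mean of its per-state mean
  activities (over states present) is < 0.5, strictly; the boundary is
  kept. Removals are returned with their values for logging.
* **Epoching.** The first `start_offset_s` seconds are discarded
  (acquisition-start lag between imaging and EEG, 1–3 s in practice), then
  frames are averaged in blocks of `frame_rate × 10 s`; a trailing partial
  epoch is dropped, never padded; the column is truncated to the hypnogram
  length.

## Sleep scoring and delta power

The rule-based stager is a stand-in for manual scoring and is validated
only against the synthetic generator: per epoch, EMG RMS above/between/below
two thresholds separates AW / QW / atonia, and atonic epochs are REM when
the theta (6–9 Hz) to delta (2–4 Hz) band-power ratio exceeds 1, NREM
otherwise. Band power is a per-epoch Welch estimate — 2-s Hann segments,
50 % overlap, trapezoidal integration over the closed band — the one
spectral convention used everywhere, including `nremDeltaPower()`. The
delta rebound is $100 \times$ mean recovery-NREM delta power over mean
baseline-NREM delta power.

## The synthetic session generator

The generator defines the study conditions under which the pipeline is
tested; none of its parameters is estimated from real recordings, and all
are configurable (`simConfig()`).

* **Hypnogram**: semi-Markov chain; exponential bouts (means AW 90 s, QW
  40 s, NREM 180 s, REM 60 s) floored at one epoch and quantised to whole
  epochs; transition weights route wake→sleep through QW and enter REM only
  from NREM.
* **Firing**: per phenotype, state-dependent Poisson rates convolved with a
  peak-normalised double-exponential kernel (rise 0.2 s, decay 1.8 s —
  generic GCaMP6-class dynamics), event amplitude 1.5 on a resting
  fluorescence of 1, Gaussian frame noise (sd 0.05). The six rate vectors
  were calibrated once so that the *measured* ΔF/F₀ ratio profiles land
  near the published group-mean ratio profiles, then frozen.
* **ΔF/F₀ baseline**: $F_0$ is the 20th percentile of fluorescence over the
  whole session (default). A short running window (30 s was the initial
  choice) tracks bout-scale activity and systematically compresses
  sustained-activity segments — enough to invert slow contrasts such as
  recovery vs baseline. Since the generator simulates no drift, the
  session-global percentile is the efficient estimator; a running window of
  any length remains available (`baselineWindowS`) for traces with drift.
  Note the $F_0$ offset still shifts measured ratios away from 1 — real
  ΔF/F₀ ratios carry the same property — which is why rate calibration
  targets measured ratios.
* **Homeostatic pressure**: Process-S-like,
  $dP = (1-P)\,dt/\tau_{wake}$ awake and $-P\,dt/\tau_{sleep}$ asleep,
  integrated exactly per epoch ($\tau_{wake}$ = 2 h, $\tau_{sleep}$ = 1 h,
  $P_0$ = 0.25), so $P \in [0,1]$, non-decreasing during enforced wake.
  Sleep-active firing scales with $1 + 1.5\,P$; NREM delta EEG power with
  $1 + P$. Wake-active firing scales with $1 - 0.4\,P$: without this term
  the reported decline of wake-active activity in recovery waking simply
  does not exist in the generated data. The term is a deliberate extension
  of the generator model; it also mildly suppresses late-SD wake activity,
  a simplification relative to the reported SD-flat wake-active response.
  Setting `pressureGain`, `deltaGain` and `wakeSuppressGain` to 0 gives the
  null configuration in which every pressure-linked effect must vanish —
  the pipeline's calibration check.
* **Deprivation protocol**: ≥45 min baseline of spontaneous cycling, 3 h of
  enforced wakefulness, 1 h recovery with sleep-biased architecture (NREM
  bouts lengthened, wake bouts shortened, in proportion to the pressure at
  recovery onset). Imaging during deprivation covers exactly the last
  10 min of each hour. Enforced wake defaults to pure AW so that
  deprivation wake epochs are state-matched to baseline AW; with QW mixed
  in, phenotypes whose QW rate differs from their AW rate would show
  deprivation "effects" even with all gains at zero. Brief one-epoch NREM
  "sleep attempts" occur with probability `sdAttemptRate × P` per epoch and
  are terminated by a forced AW epoch; the analysis counts and excludes
  them.
* **EEG/EMG**: per-epoch Gaussian background plus a state oscillation
  (2.3–3.7 Hz during NREM with pressure-scaled power, 6.5–8.5 Hz during
  REM, broadband during wake) and EMG white noise with state-specific RMS
  (1.0 / 0.45 / 0.1 / 0.08). The stager's default thresholds (0.7 / 0.25 /
  ratio 1) are calibrated to these levels.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: photobleaching and slow drift, motion artifacts,
neuropil contamination and source-extraction cross-talk, within-state rate
fluctuations beyond Poisson variability, EEG arousals/artifacts, and
between-animal variability. Tests passing here certify the *analysis*, not
the upstream imaging.

## Statistics

The rank battery is implemented from the standard formulas: Friedman's
tie-corrected $\chi^2$ on within-subject ranks (asymptotic
$\chi^2_{k-1}$ p-values); SNK stepdown on condition rank sums with
studentized-range critical values ($SE = \sqrt{nk(k+1)/12}$,
non-significant spans block nested comparisons); Wilcoxon signed rank with
an exact null for $n \le 25$ computed by convolution over (mid-)ranks —
identical to the classical distribution when untied and still exact under
ties — else a tie- and continuity-corrected normal approximation;
Mann–Whitney U (exact when untied and $n \le 50$ per group); Kruskal–Wallis
with tie correction and Dunn's z on mean ranks, unadjusted by default
(Bonferroni/Šidák optional), matching how such post hocs are customarily
reported in this literature. Tie groups are always taken from the rank partition, which is
how base R resolves floating-point-equal values. All tests are invariant
under strictly monotone transforms, verified by property tests;
implementations are cross-checked against base R and against brute-force
enumeration oracles in the test suite.

## Problem sizes and numerical conventions

The test suite and the acceptance script run: phenotype recovery on 100
units × 1 h of spontaneous cycling (plus a 30-unit noise-free 2-h session
for the exact-recovery limit); staging fidelity on a 1-h session; the
deprivation analysis on 36 units × 5 h (1 h baseline, 3 h SD, 1 h
recovery) with a matched null run; Monte-Carlo type-I calibration with
2000–4000 replicates per test at $n = 50 \times 4$ (Friedman), $n = 25$
(Wilcoxon), $20{+}20$ (Mann–Whitney) and $3 \times 30$ (Kruskal–Wallis).
These sizes keep every state sampled well while the whole suite runs in a
few minutes.

Other conventions: ratios are undefined (and the unit unclassifiable,
reported not dropped silently) when a state is absent or its mean is not
positive; degenerate inputs error early (constant traces in `zscoreTrace`,
all-zero differences in the signed-rank test return $p = 1$ with a flag);
all simulation functions are deterministic given (config, seed), and the
result writers emit byte-identical files for identical inputs.

## Limitations

* The stager is calibrated to the synthetic EEG/EMG; its thresholds carry
  no claim about real polysomnography.
* The 0.5 quality threshold is interpreted on the non-centred normalised
  scale; on true z-scores it would be incoherent (state means can be
  negative), which is documented rather than resolved.
* The instability screen for deprivation sessions (coefficient-of-variation
  ceiling across baseline conditions, off by default) is a configurable
  stand-in for the customary exclusion of unstable units, for which no
  quantitative criterion is established.
* Logistic validation of deterministic rule membership is always perfectly
  separated; the function reports this honestly instead of returning
  pseudo-significant coefficients.
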