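---
title: "Behavior-resolved band power in cerebellar recordings: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavior-resolved band power in cerebellar recordings: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cerebpsd)
```

## The analysis

`cerebpsd` quantifies multi-unit activity (MUA) in extracellular
recordings from three cerebellar structures (Crus II, the inferior olive,
and the dentate nucleus) as a function of annotated behavior, in a design
with a control and a lesioned (parkinsonism-model) group of 12 rats each
recorded weekly for four weeks. The unit of signal is a 5-s **trace** cut
from a behavior episode; the primary outcome is the **bandwidth-normalized
band power** of the trace,

$$\mathrm{nPSD}_{[f_1,f_2]} \;=\; \frac{1}{f_2-f_1}\sum_{f_1 \le f_j < f_2}
\widehat{S}(f_j)\,\Delta f ,$$

where $\widehat{S}$ is the one-sided periodogram (rectangular taper, mean
removed, µV²/Hz) and the band of interest is 300–500 Hz, the MUA-dominated
part of the 300–3000 Hz range. The full range is segmented into six bands
(300–500, 500–1000, …, 2500–3000 Hz).

The statistical battery is nonparametric throughout: Mann–Whitney U per
structure × behavior × week between groups; Friedman across the four weeks
within the experimental group, with all six week-pair Wilcoxon signed-rank
tests Holm-adjusted *only* where the Friedman test is significant;
Mann–Whitney on per-rat total behavior durations; and Spearman correlation
between total behavior duration and normalized PSD, pooled across weeks
within the experimental group. Lilliefors and Levene diagnostics are
available and can be logged, but they never gate the analysis — the
nonparametric battery is used unconditionally. α = 0.05 everywhere; no
correction is applied across the structure × behavior × week grid (Holm
acts only inside each Friedman post-hoc family).

### Exact small-sample nulls

All tests are implemented from first principles with exact enumeration
where the study design permits:

* **Mann–Whitney**: exact rank-sum distribution via dynamic programming for
  $n_1+n_2 \le 25$ and tie-free data — the 12 vs 12 design hits this path;
  otherwise the tie-corrected normal approximation with 0.5 continuity
  correction.
* **Wilcoxon signed-rank**: exact sign-pattern generating function for
  $n \le 20$ tie-free absolute differences; zero differences are dropped
  (Wilcoxon's original proposal — the Pratt alternative changes p and is
  deliberately not used).
* **Friedman**: the classic $\chi^2_F$ statistic with average ranks for
  ties; $\chi^2$ approximation with $k-1$ df by default, full within-block
  permutation enumeration on request (feasible for $k!^n \lesssim 10^6$).
* **Holm**: step-down with running maximum, capped at 1.
* **Spearman**: Pearson correlation of average ranks; exact permutation
  null for $n \le 8$, t approximation otherwise.
* **Lilliefors**: Monte-Carlo null (seeded) rather than table lookup, so
  the p-value is reproducible at any $n$.
* **Levene**: classic mean-centered variant (not Brown–Forsythe).

Every exact path is tested against an independent brute-force enumeration
oracle on hundreds of random small instances.

### Unit of analysis

Published headline U statistics for designs like this one are often not
arithmetically consistent with 12 animals per group under standard
conventions — the unit of analysis (trace vs animal) is frequently left
implicit — so the experimental unit is exposed as a configuration switch (`aggregation`): the default
`per-rat-mean` averages the ≤ 5 trace values per rat × week × structure ×
behavior, making the rat the unit ($n = 12$ per group); `per-rat-median`
and `per-trace` are available. The choice is stamped into every output
row.

## Preprocessing

Signals are band-pass filtered 300–3000 Hz with a 4th-order Butterworth
prototype applied forward–backward (zero phase, so behavior-aligned
windows are not phase-delayed; the effective roll-off doubles the nominal
order), then notch-filtered at 60 Hz and all harmonics up to 3000 Hz. Each
notch shares a constant absolute −3 dB bandwidth of `base/q` (≈ 1.7 Hz),
so even the 50th harmonic removes only a sliver of spectrum. Filtering is
applied per channel over the whole session (not per trace), with 1 s of
odd-reflection padding, so no edge transient can sit inside a 5-s trace.

Candidate windows are non-overlapping `trace_len` windows tiled from each
episode onset; candidates are ordered by start time across the session and
the first five survivors of QC are kept per behavior and channel
(earliest-first is deterministic and auditable; the selection rule used in
the original study is not documented). QC applies two rules, saturation
first:

* **saturation** — ≥ 5 consecutive raw samples (0.5 ms at 10 kHz) exactly
  at the rail (or at the channel's absolute maximum when the rail is
  unknown);
* **excursion** — any filtered sample more than 10 SDs from the session
  mean, with mean and SD taken over the *whole filtered session channel*,
  so a fully saturated trace cannot mask itself.

Excluded traces are dropped, never repaired.

### A caveat the tests quantify: corner droop

A 4th-order Butterworth band-pass spanning a 10:1 band has wide transition
corners. Applied zero-phase, the power response is $|H|^4$: 0.0625 at
300 Hz, 0.91 at 400 Hz. Two consequences are documented rather than hidden:

* the filter is *not* idempotent over the full 300–3000 Hz AUC — a second
  application removes another ≈ 5 % (white noise) to ≈ 14 % (α = 3.2
  spectra) of in-range power, essentially all of it in the corner regions;
  away from the corners (500–1500 Hz) a second pass changes the AUC by
  < 2 %;
* the measured 300–500 Hz *share* of filtered traces under-states the
  signal's true spectral share (≈ 59.5 % measured vs 68 % true for
  α = 3.2), because the droop acts mostly on the lowest band. The
  band-dominance check (> 65 % of 300–3000 Hz power in 300–500 Hz) is
  therefore computed from the periodogram of the trace as generated; it
  matches the closed-form power-law integral
  $(300^{1-\alpha}-500^{1-\alpha})/(300^{1-\alpha}-3000^{1-\alpha})$
  (64.6 % at α = 3, 67.9 % at α = 3.2). Group *ratios* of band power are
  unaffected by the droop, which cancels between groups.

### Band bookkeeping

The printed AUC convention (inclusive at both edges) would double-count
the shared interior edges 500, 1000, … Hz. Bands are therefore half-open
$[f_1, f_2)$ with the final band closed at 3000 Hz, so the six bands
partition [300, 3000] exactly and the fractions sum to 1. With half-open
bands the flat-spectrum identity (flat PSD of height c → normalized PSD
c) is exact; the closed final band picks up one extra grid bin when the
PSD grid aligns with the band edge (relative excess Δf/bandwidth).

## The synthetic cohort

No public dataset exists, so the generator is a first-class, tested module
that emulates the statistical structure the analysis assumes. One session
= three channels sharing one behavior schedule.

**Background.** Gaussian noise shaped in the frequency domain by
$|f|^{-\alpha/2}$ (α = 3.2 by default, DC excluded), flattened below
100 Hz so session-scale signals keep a physiological amplitude (an
unflattened α = 3.2 spectrum extended to 1 Hz would put ~500 µV of RMS
into the slow band, three orders above the ~1 µV calibration of real
recordings). Expected 300–3000 Hz power equals `base_power` (1 µV²).
Generation FFTs run at the next 5-smooth length and truncate, since
session lengths are arbitrary and mixed-radix FFTs degrade badly on large
prime factors.

**Schedules.** Alternating renewal: exponential gaps at the summed
episode rate, behavior drawn proportional to its rate, log-normal episode
lengths, truncated at the session end. Baseline parameters (median 8 s
episodes, σ_log = 0.2, 0.6 episodes/s per behavior) are calibrated once so
that each behavior offers ≥ 5 episodes of ≥ 5 s with probability ≥ 0.99
even in the shortest (500 s) session — the supply needed for the
25-traces-per-session rule.

**Effects.** The injected structure mirrors the study's findings
qualitatively: a ×1.8 gain on 300–500 Hz power during grooming,
locomotion, rearing and sniffing in weeks 1–2 of the experimental group
(lesion-induced hyperactivity); longer resting (×1.6) and shorter
grooming/rearing/sniffing (×0.6) episodes in experimental week 1
(hypokinesia); and per-second duration–power coupling κ on the band
component, $\exp(\kappa\,(\ell - \ell_0))$ per episode of length $\ell$
(centered on the typical length $\ell_0$ = 8 s so the expected power stays
at `base_power` and long episodes stay bounded — centering multiplies each
behavior by a constant, so every rank-based result is unchanged by it).
The gain is applied by splitting the background into its 300–500 Hz
component and complement and rescaling the former inside episodes, with a
50 ms linear cross-fade at episode edges to avoid steps.

**Choosing κ.** Only the *signs* of the coupling are part of the stated
world (grooming −, sniffing +); the magnitudes are calibration choices.
Magnitudes interact with the other injected effects: in week 1 sniffing
episodes are shorter *and* band power is boosted, which by itself drives
the pooled rat × week duration–power correlation negative. For the
positive sniffing correlation to be recovered, κ must at least neutralize
that confound, which requires κ ≳ ln(1.8)/Δℓ ≈ 0.25 s⁻¹; the defaults are
κ = −0.3 (grooming) and +0.45 (sniffing) per second, validated by
sign-recovery simulation across all three structures. The per-rat
log-power intercept (SD 0.15, shared across weeks — the repeated-measures
structure Friedman needs) and a rat's schedule are the only quantities
shared between a rat's sessions.

**Nuisances.** 60 Hz mains plus harmonics with 1/k roll-off (synthesized
as spectral lines, random phases); Poisson-count artifacts per channel,
half 1–10 ms excursion pulses at 12–20 session SDs, half runs of 5–25
samples clipped at ±rail — one artifact class per exclusion rule.

**Seeding.** One master seed; every session, channel, schedule and
artifact stream derives its own sub-seed through a stated multiply-add
string hash, so any session is independently reproducible from
`(design$seed, rat_id, week)` and the caller's RNG state is never
disturbed.

### The desk scale

Calibration and power simulations at 10 kHz × 650 s × 96 sessions are not
desk-tractable, so `cohort_design("desk")`/`analysis_config("desk")`
define a reduced world: 2 kHz sampling, 90–110 s sessions, the frequency
axis scaled by 0.1 (analysis band 30–50 Hz of 30–300 Hz), 1 s traces,
episode lengths scaled by 1/5 (and κ by 5, preserving the per-episode
log-power spread). Every dimensionless quantity — band fractions, gain
ratios, rank statistics, rejection rates — is preserved by construction;
what the desk scale does *not* exercise is the absolute frequency layout
(e.g. 50 notch harmonics instead of 5) and full-length session edge
behavior, which the full-scale trace-count test covers.

### What a green test does and does not establish

The generator's world is Gaussian, stationary within episodes, and
artifact classes are exactly the two the QC targets. Real recordings have
non-Gaussian spike statistics, slow nonstationarities, movement artifacts
of intermediate shape, and electrode drift; a green suite establishes that
the *pipeline* recovers what was injected at the stated effect sizes and
rejects at the nominal rate under the null — not that the biological
effect sizes themselves are realistic. Absolute normalized-PSD units are
not comparable to the original study's unlabeled axes; only relative
effects are.

## Null calibration and statistical design choices

* The null-calibration simulation (g ≡ 1, κ ≡ 0) sets the per-rat
  intercept SD to 0. Rank tests are exact under the null regardless of
  between-rat variance, so this does not change the estimand; it removes
  the intercept-induced correlation between the 60 cells of a cohort
  (intra-cohort ICC ≈ 0.7 otherwise), which would make a rate estimate
  from feasible cohort counts meaninglessly noisy.
* Intergroup and duration tests use all available rats per cell; Friedman
  uses listwise-complete rats (a rat missing any week for that
  structure × behavior is excluded from that family).
* Missing cells (a behavior that never offered an eligible window) are
  flagged `insufficient data` and never tested.
* The correlation pairing level defaults to one pair per experimental
  rat × week (total duration vs aggregated normalized PSD), pooled across
  weeks; the pooling is a documented choice, not a claim about the
  original analysis, and the group is configurable.

## Tunable parameters (defaults)

| parameter | default | units | why |
|---|---|---|---|
| `fs` | 10000 | Hz | acquisition standard of the recording chain |
| band of interest | 300–500 | Hz | MUA range; dominates the 300–3000 Hz power |
| `trace_len` / `max_traces` | 5 / 5 | s / – | 25 traces per session over 5 behaviors |
| band-pass | 300–3000, order 4 | Hz | stated conditioning filter |
| notch | 60, q = 35 | Hz | mains + harmonics; ~1.7 Hz wide each |
| excursion threshold | 10 | session SD | stated exclusion rule |
| saturation run | 5 | samples | 0.5 ms at 10 kHz; "saturation" is otherwise undefined |
| `spectral_exponent` | 3.2 | – | puts ≈ 68 % of 300–3000 Hz power in 300–500 Hz (> 65 %) |
| `band_gain` | 1.8 (exp., W1–W2, non-resting) | × power | early-week hyperactivity |
| duration multipliers | resting ×1.6; groom/rear/sniff ×0.6 (exp. W1) | × length | hypokinesia |
| `duration_coupling` | −0.3 grooming, +0.45 sniffing | 1/s | sign-recovery calibration (see above) |
| `rat_sd` | 0.15 | log-power SD | between-animal heterogeneity |
| `artifact_rate` / `rail` | 2 / 100 | per session / µV | exercises both exclusion rules |
| α | 0.05 | – | stated significance level |

## Known limitations

* The literal inclusive-edge AUC formula is not implemented (half-open
  bands are); the difference is one grid bin at shared edges.
* Welch averaging exists behind a flag for exploratory use but is never
  used in the standard analysis or its tests.
* Friedman's exact path is limited to $k!^n \lesssim 10^6$; the 12-rat
  design uses the $\chi^2$ approximation, whose mild conservatism is
  visible (and tolerated) in the calibration test.
* EDF or vendor acquisition formats are out of scope; the on-disk format
  is the package's own manifest + float32 + CSV triplet.
* The original study's numerical U/p/ρ values are not reproducible (raw
  data unavailable); acceptance targets the protocol-level quantities and
  the qualitative effect pattern instead.
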