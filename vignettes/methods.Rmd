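---
title: "Methods: vocal individuality analysis for penguin calls"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: vocal individuality analysis for penguin calls}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalid)
```

## The model

`vocalid` treats a penguin vocalisation under the source-filter theory of
vocal production: the syrinx generates a quasi-periodic source signal
whose repetition rate is the fundamental frequency (f0), and the
suprasyringeal vocal tract — trachea, larynx, oropharyngeal cavity,
beak — shapes its spectrum with resonances (formants). Three largely
independent motor systems leave fingerprints in a call: the lungs and
chest muscles (durations, amplitude patterns), the syrinx (f0 and its
cycle-to-cycle perturbations), and the vocal tract (formant positions,
hence apparent vocal tract length). Individual identity can ride on any
of them, which is why the pipeline measures 24 parameters per contact
call and 31 per display song, spanning all three systems.

The package asks two questions of a labelled collection of calls:

1. **Which parameters could code identity?** The Potential of Individual
   Coding, `PIC = CVb / mean(CVw)`, compares the coefficient of variation
   of the pooled sample against the mean of the per-individual CVs; the
   within CV carries the small-sample correction `(1 + 1/(4n))`. All SDs
   use the n−1 denominator; the correction is applied to CVw only. Both
   choices were validated by reproducing a published PIC table from its
   printed group summaries (`pic_from_summaries`), which is an exact
   algebraic identity with the raw-table computation
   (`pic_from_raw`) — the pooled moments reconstruct from group moments
   without loss.
2. **Do the parameters jointly identify the caller?** Parameters with
   PIC ≥ 1.1 enter a stepwise discriminant analysis (Wilks'-lambda
   partial-F, enter/remove at F = 3.84, ties broken by column order),
   then a linear discriminant classifier with pooled within-class
   covariance is scored by leave-one-out cross-validation against the
   proportional chance criterion Σ(nᵢ/N)², with a Yates-corrected χ² test
   at α = 0.001.

## Feature extraction: settings and rationale

**Pitch tracking** (`pitch_settings`): time step 0.01 s, search band
150–350 Hz — the band that brackets the fundamental of both call types in
this species. The tracker computes a normalized cross-correlation per
frame (window = 3 floor periods), picks the candidate maximizing
correlation minus an octave cost (0.01 per octave below the ceiling,
suppressing subharmonic picks), marks frames below a 0.45 correlation
voicing threshold as unvoiced, refines the winning lag by parabolic
interpolation (the grid spacing at 44.1 kHz is otherwise ±1.4 Hz at
250 Hz), and median-smooths the voiced track over 3 points. The voicing
threshold and octave cost are tracker tuning constants with no published
values for this analysis; both are exposed in `pitch_settings`.

**Jitter and shimmer** are proportions: mean absolute difference of
consecutive cycle periods (amplitudes) over the mean period (amplitude),
measured on a pulse train extracted by peak-picking one local period
ahead. Reference tables for this species print values like 0.01 and 0.16
under a percent header; the printed magnitudes are proportions and the
package follows the magnitudes.

**Harmonics-to-noise ratio** (Sonority): per voiced frame,
`10·log10(r/(1−r))` where `r` is the normalized autocorrelation at the
frame's period, parabolic-interpolated across adjacent lags. Without the
interpolation a perfectly periodic pulse train scores only ~23 dB because
the true period rarely falls on the sample grid; with it, clean signals
exceed 25 dB and an equal-power tone+noise mixture sits near 0 dB, the
two analytic anchors the tests assert.

**Formants** (`formant_settings`): resample to twice the ceiling
(3500 Hz for contact calls, 4000 Hz for songs — ceilings under which
anatomical models of this species place five formants), first-difference
pre-emphasis above 50 Hz, Gaussian-windowed 25 ms frames every 45 ms,
Burg autoregression of order `2·max_formants + 2`, roots to candidate
(frequency, bandwidth) pairs, keep 50 Hz < f < ceiling with bandwidth
< 700 Hz, report the lowest five by frequency. Order, window, pre-emphasis
and the bandwidth cut-off follow common formant-analysis practice; none
are published for the original analysis.

Two numerical choices deserve emphasis:

* *Broadband fixtures are analyzed with fixture-appropriate settings.*
  Pre-emphasis exists to flatten the falling (≈ −6 dB/oct) spectrum of a
  voiced source; applied to a white-noise excitation it over-tilts the
  spectrum and biases F1 upward, and an LPC order far above twice the
  number of resonances in band introduces broad spurious poles that
  scramble the frequency-rank assignment. The validation tests that push
  white noise through four known resonators therefore use order
  `2·4 + 1 = 9` with pre-emphasis disabled, while voiced calls use the
  defaults above. This is the standard "match the model order to the
  source" rule, not a per-test calibration.
* *Octave-jump correction* replaces frames deviating > 40% from a
  window-5 running median, iterated to a fixed point, with a fallback to
  the global column median where the running median itself is corrupted.
  A single pass repairs isolated outliers but a contiguous run of five
  corrupted frames can sustain itself; the global fallback is justified
  because formants in these calls are stable and flat — the same
  stability that motivates formant-based identity coding.

**Modulation statistics.** FM and AM share one mechanism: detrend the
contour (f0 in Hz, or framewise RMS level in dB), detect upward
mean-crossings with a Schmitt trigger at ± half a minimum extent
(defaults 1 Hz / 1 dB), count a cycle per consecutive crossing pair, and
report the mean peak-to-peak excursion per cycle as the extent. The
hysteresis exists because the framewise RMS of even a steady tone ripples
by a fraction of a decibel, which must not register as amplitude
modulation. The rate divides the cycle count by the span between the
first and last counted crossing rather than by the whole call duration:
the latter loses the partial cycles at the call edges and undercounts by
up to one cycle per call, which is fatal for short calls (a 5 Hz
modulation on a 1 s call would read ~3 Hz depending on phase). AmpVar is
the cumulative absolute level change per second; all three AM statistics
are invariant to global gain.

**Songs.** Spectral (source and filter) parameters are measured only on
the long voiced type-2 syllables and averaged when a song has several;
temporal parameters and syllable structure are measured on the whole
song. Songs without a type-2 syllable are excluded with a warning, never
imputed.

## The synthesizer: what it emulates, what it does not

`voice_profile` encodes one bird: f0 mean and call-to-call SD, contour
shape (start/end offsets, FM rate/extent), jitter and shimmer levels,
vocal tract length (formants follow the quarter-wave positions
`(2i−1)·c/(4·VTL)`), AM rate/depth, duration, and noise level. Every
parameter carries a within-individual SD and is redrawn per call from a
±3σ-truncated Gaussian: this is what gives each acoustic parameter a
within-individual distribution, the raw material of PIC. The source is a
band-limited harmonic pulse train (−6 dB/oct rolloff, harmonics to 45% of
the sample rate) whose per-cycle periods and per-pulse amplitudes are
perturbed multiplicatively; the perturbation SD is the target
jitter/shimmer level times √π/2, the factor that converts a mean absolute
consecutive difference into a Gaussian SD. Amplitude regions are centred
on pulses so the rendered pulse peaks carry the drawn amplitudes exactly.
Display songs follow a per-bird grammar: a run of short type-1 syllables,
then alternating type-2 syllables and unvoiced, formant-filtered
inhalation noise (type-3), with Gaussian gaps; annotations are emitted
exactly and the structural ground truth equals what `syllable_structure`
recomputes from them.

Default profiles (`default_profiles`) transcribe the packaged reference
summary tables; quantities the tables do not determine are one-time
modelling choices: formant bandwidths 80–200 Hz rising with formant
number, AM depth 0.3, SNR 25 dB (within-call SD tied to the tables'
Sonority SD), inter-syllable gaps 0.15 ± 0.05 s.

What the generator does **not** emulate: the two-voice (dual-syrinx)
phenomenon, the septate trachea (a single-tube tract only — anatomical
modelling suggests the second tube shifts formants by ~8–10%),
reverberation and colony background noise, amplitude-dependent source
spectra, and any correlation structure between parameters beyond what the
shared per-call draws induce. Passing tests therefore demonstrate that
the estimators and statistics are correct on signals obeying the
source-filter model with independent Gaussian parameter variation — not
that the pipeline is robust to every pathology of field recordings.

## Statistical pipeline: design choices

* **Selection outside the cross-validation loop.** Stepwise selection
  runs once on the full table and is held fixed across leave-one-out
  folds, mirroring standard stepwise-DFA practice. This is optimistic
  relative to fully nested selection; the optimism is the price of
  comparability with the field's convention and is documented rather than
  hidden.
* **Priors.** Classification uses group-size-proportional priors by
  default, consistent with the group-size-based chance criterion; an
  equal-priors mode exists (`fit_lda(..., priors = "equal")`).
* **Significance direction.** `yates_chi2` is the two-sided two-cell
  goodness-of-fit test with the ±0.5 continuity correction (clamped at
  zero). The report's `significant` flag additionally requires
  above-chance accuracy: with uninformative features, leave-one-out LDA
  is systematically *below* chance (removing a call shifts its own
  class mean away from it), and a below-chance deviation is not evidence
  of identity coding.
* **Degenerate inputs.** Zero within-individual variation yields an
  infinite PIC, flagged rather than dropped; non-positive group means
  make a CV meaningless and the parameter is reported as `NA`. Collinear
  stepwise candidates are skipped with a warning; a singular pooled
  covariance receives an escalating ridge starting at `1e-8` of its mean
  diagonal. Ground-truth tables make this path routine: their four
  formant columns are exact multiples of the dispersion column.
* **Null calibration.** The identical-profile colonies used to check
  PIC ≈ 1 employ a flat contour with random-phase FM. Under a rising
  contour the time-of-extremum parameters cluster at the call edges
  (rare-event distributions); per-group CVs then collapse toward zero for
  some groups and PIC inflates — a genuine property of CV ratios on
  bimodal variables, worth knowing when interpreting PIC for bounded
  "percent of duration" parameters on real data.

## Problem sizes

The validation suite uses colony sizes matched to the reference study
(six individuals with 9/14/20/25/31/19 contact calls; seven with
7–11 songs) for single-run checks, 50-seed recovery and 20-seed null
simulations on generator ground-truth tables (`audio = FALSE`), 100-seed
jitter recovery on 0.35 s sources, and full audio extraction on small
(2–6 bird) colonies. One 0.6 s call takes roughly 0.2 s to analyze end to
end on one core.

## Known limitations

* The pitch tracker is deterministic greedy-per-frame (no Viterbi path);
  it is accurate in the narrow 150–350 Hz band it was designed for but is
  not a general-purpose tracker, and it will not resolve two simultaneous
  voices.
* Formant estimates on voiced calls inherit the classic high-pitch LPC
  problem: with f0 near 250 Hz the spectral envelope is sampled every
  harmonic, and F1 (lowest formant, often within 1–2 harmonics of f0) is
  the least reliable of the four.
* FMExtent follows the per-cycle peak-to-peak definition; an alternative
  printed definition (total FM variation over FM rate) is available as
  `fm_statistics(..., total_variation = TRUE)` because the two appear
  interchangeably in the literature and they are not numerically
  equivalent.
* `pic_from_summaries` inherits any rounding in its inputs; two-decimal
  summaries limit agreement to roughly ±0.05 in PIC, and parameters whose
  printed magnitudes are near the rounding step (e.g. jitter around 0.01)
  cannot be validated from summaries at all.
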