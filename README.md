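# vocalid

Vocal individuality analysis for penguin calls from a source-filter
perspective.

Colonial seabirds recognize each other by voice. For the African penguin
(*Spheniscus demersus*), the question is which acoustic features of the
two main vocalisations — the single-syllable **contact call** and the
multi-syllable **ecstatic display song** — carry individual identity.
`vocalid` implements the complete analysis chain a bioacoustician needs to
answer that question, plus a call synthesizer so every stage can be
validated without field recordings.

## What it computes

**Acoustic features.** From each call the pipeline measures 24 parameters
(31 for songs): source-related features from the fundamental-frequency
contour tracked by normalized cross-correlation in the 150–350 Hz band
(f0 start/end/mean/min/max, times of the extrema, mean absolute slope,
cumulative variation, FM rate/extent, cycle-to-cycle **jitter** and
**shimmer**, harmonics-to-noise ratio); filter-related features from Burg
LPC formant tracking with octave-jump correction (F1–F4 means, formant
dispersion ΔF, vocal tract length); and temporal features (duration,
amplitude-modulation statistics, and for songs the counts and summed
durations of the three syllable types).

**Formant dispersion and vocal tract length.** ΔF is the slope of the
regression through the origin of Fᵢ on (2i−1)/2, and

    VTL = c / (2 ΔF),   c = 350 m/s,

modelling the vocal tract as a uniform tube closed at one end.

**Potential of Individual Coding (PIC).** For each parameter,

    PIC = CVb / mean(CVw),   CVw = 100 (SD/mean) (1 + 1/(4n)),

with CVb the plain coefficient of variation of the pooled sample and CVw
the small-sample-corrected within-individual CV. PIC > 1 means a
parameter varies more between than within individuals. Parameters with
PIC ≥ 1.1 feed a stepwise discriminant function analysis (Wilks'-lambda
partial-F entry/removal at F = 3.84) with leave-one-out cross-validation,
scored against the proportional chance criterion Σ(nᵢ/N)² and a
Yates-corrected χ² test at α = 0.001.

**Synthesizer.** A source-filter generator produces labelled colonies:
a band-limited harmonic pulse train with controllable per-cycle jitter
and shimmer, a cascade of second-order resonators at the quarter-wave
positions of a chosen vocal tract length, amplitude modulation, noise,
and (for songs) a three-syllable grammar. Every call comes with a
ground-truth feature vector, so the statistical stages can be tested
independently of the signal processing.

## Worked example

Reference per-individual summary statistics for a captive colony (six
birds, 118 contact calls) ship with the package:

```r
library(vocalid)
s <- load_summary_table("contact")
pic_from_summaries(s[s$parameter == "f0Mean", ], "f0Mean")
#>   parameter mean_cvw cvb pic selected
#> 1    f0Mean     6.42   9 1.4     TRUE

rep <- pic_report_from_summaries(s)
length(select_parameters(rep))
#> [1] 16
```

Mean f0 varies 1.4 times more between birds than within a bird, so it
passes the PIC ≥ 1.1 gate, as do 15 further parameters. A synthetic
two-bird colony runs end to end:

```r
cfg <- colony_config(
  list(voice_profile("alfa",  f0_mean = 230, vtl = 26, duration_mean = 0.45),
       voice_profile("bravo", f0_mean = 300, vtl = 33, duration_mean = 0.70)),
  calls_per_individual = 8, call_type = "contact", seed = 42)
colony <- generate_colony(cfg)
features <- extract_features(colony$waveforms, "contact")
classify_calls(features)
#> Individual classification report
#>   groups: 2, calls: 16
#>   PIC-gated parameters: 17; stepwise-selected: 3
#>   correct: 100.0% (resubstitution), 100.0% (leave-one-out)
#>   chance: 50.00%;  Yates chi2 = 14.1 (df 1), significant at the 0.001 level
```

Two birds whose voices differ in pitch, tract length and call duration
are perfectly separable; the chi-square confirms the classification beats
the 50% chance level.

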