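---
title: "Methods: frequency structure and processing load in turns-at-talk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: frequency structure and processing load in turns-at-talk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnload)
```

## The scientific question

Conversational turns-at-talk show a regular internal frequency structure:
they tend to open on very high-frequency material (interjection-like
*inserts* such as "oh" or "well", and pro-form subjects such as "I" or
"it"), run through mid-frequency function words, and close on low-frequency
content words — above all nouns, which carry the bulk of hapax legomena.
Because word frequency is a strong determinant of lexical planning cost,
this anticlimactic frequency profile predicts a *climactic* processing-load
profile in the speaker: pupil size, a standard index of cognitive effort,
should rise as the turn unfolds, and rise more steeply the more steeply the
turn's word frequencies fall. turnload implements the full analysis chain
needed to test this on PoS-tagged transcripts with synchronised
pupillometry, plus a synthetic-data generator with known ground truth so
every stage can be validated by parameter recovery.

## The pipeline

1. **Turn subsetting and frequency profiling** (`select_turns`,
   `build_frequency_table`). Turns of 3–25 grammatical words are selected;
   turn size counts the tagger's grammatical words, so contractions count as
   their expanded words ("I'm gonna" = 4). Each token is assigned its
   word-tag type's *subset-internal* frequency, normalised per thousand
   subset tokens. Word position is normalised as (index − 1)/(size − 1), so
   the first word of any selected turn sits at 0 and the last at 1.
2. **Word classes and hapaxes** (`classify_tokens`, `find_hapaxes`).
   Content words are adjectives, adverbs, nouns, and lexical verbs;
   auxiliaries and modals stay function words; inserts are interjection-
   tagged tokens plus adverb-tagged "well"/"so" (a known mis-tagging in
   conversational corpora). Hapaxes are types with subset count 1.
3. **Pupil preprocessing** (`preprocess_pupil`). Two-eye averaging with
   single-eye fallback; blink gaps linearly interpolated in consecutive
   600-observation batches; each turn window baselined to its first datum;
   samples split into as many equal bins as the turn has words.
4. **Per-turn slopes** (`ols_slope`, `assemble_slope_pairs`). For each turn,
   the least-squares slope of frequency on normalised position; for each
   turn × participant, the slope of the binned pupil means on normalised bin
   position. The two are joined into the slope-pair table.
5. **Inference** (`select_polynomial_model`, `fit_mixed`,
   `emm_simple_effects`). Orthonormal polynomial growth-curve models with
   random intercepts by participant and conversation, a stepwise polynomial
   selection procedure, and estimated-marginal-means simple-effect trends
   per role.

## Model and codings

The positional models are growth-curve regressions on orthonormal
polynomial transforms of normalised position: the columns are mutually
orthogonal with unit norm and orthogonal to the intercept, so lower-order
terms are stable as higher orders enter, and each coefficient's t test reads
as the contribution of exactly that shape component. The basis is built by
modified Gram–Schmidt with a second reorthogonalisation pass (numerically
equivalent to a QR factorisation of the centred power sequence; agreement
with `stats::poly` is part of the test suite at 1e-8).

Participant role is contrast-coded −0.5 (recipient) / +0.5 (speaker), so a
trend × role interaction is the speaker-minus-recipient trend difference and
per-role trends are the main effect ± half the interaction. Word class is
deviation-coded with the function-word class omitted, so the noun and insert
coefficients are offsets against the grand mean; the omitted level is
configurable. Turn size enters z-scaled (mean 0, SD 1, computed on the
analysis table); a centred-only variant is a trivial change of scale that
does not alter test statistics.

Model selection follows a two-phase stepwise procedure: first, interactions
of the position term with control variables (turn size) are pruned when
non-significant (p > 0.05); then successive higher-order orthogonal
position terms (with their role/word-class interactions) are added and kept
while the newly added term is significant at p < 0.05, stopping at the
first non-significant addition. The procedure cannot skip a degree: a pure
odd signal with no even component stops the ladder early, which is an
inherent property of this kind of stepwise selection and is exercised in
the tests.

Mixed models are fitted by REML with random intercepts by participant and
by conversation; p-values use the Satterthwaite degrees-of-freedom
approximation, and emmeans falls back to asymptotic z tests on large
tables. Post-hoc simple-effect trends are Bonferroni-adjusted across the
role family — a deliberately conservative, dependency-free choice; the
adjustment method is an argument. Singular fits (a variance estimated at
zero, routine when only three conversations are observed) are flagged in
the result object, never hidden; degenerate-equivalence tests confirm that
with no group structure the fixed effects collapse to the ordinary
least-squares fit within 1e-4.

## The synthetic-data generator

`sim_config()` defines the study conditions; `generate_dataset()` writes a
transcript + pupil bundle with a complete latent-truth log. Default scale:
3 conversations, 2 participants each, 2,000 turns with sizes 3–25 (mass
decaying geometrically, mean ≈ 9 words).

- **Lexicon.** One Zipfian inventory per class (`weight ∝ rank^(-s)`,
  s = 1). Nouns get 4,000 types — a hapax-rich tail — against 80 function
  types and 12 inserts. The insert class uses its own exponent s = 3:
  inserts are a tiny closed class dominated by a handful of forms, and this
  skew is what makes insert tokens the most frequent tokens in the corpus,
  hence the high turn-initial mean frequency. "well" is deliberately
  tagged as an adverb to exercise the class-map override.
- **Class-position curves.** Insert probability 0.55·exp(−p/0.07) (mass
  concentrated at the first word), noun probability 0.04 + 0.28·p³ (about
  4% initially, about 30% at the final word), other content flat at 0.17,
  function words the remainder. These anchor values mirror the positional
  class percentages reported for conversational English.
- **Pupil model.** 60 Hz streams; turn duration ≈ 400 ms per word plus
  noise, so bins hold roughly 15–25 samples. Latent load is tied to words:
  the trajectory is a staircase that steps once per word, with the level at
  word w given by `slope · x_w` for speakers (slope = `15 + a_participant +
  c_conversation − 0.5 · slope_frequency(turn) + ε_turn`, px across the
  whole turn; SDs 5, 3 and 8) and `20·x_w − 10·x_w²` (rise–plateau) for
  recipients, where x_w is the word's normalised position. Tying the level
  to x_w makes the word-aligned binned estimator measure exactly the
  programmed coefficients for every turn size. A trajectory continuous in
  time would not: its per-turn slope reads as (K−1)/K of the programmed
  value in a K-word turn (bin positions span (k−1)/(K−1) while bin time
  midpoints span (k−½)/K), and baselining at the first datum leaves bin 1
  about slope/(2(K−1)) above zero — a size-dependent offset that, pooled
  across turn sizes, masquerades as curvature. Per-sample noise SD 5 px, per-eye
  noise 0.5 px, blink gaps at 0.15/s with mean length 150 ms, and a 1%
  single-eye dropout rate exercise the preprocessing chain. The coupling is
  implemented in the speaker's latent slope — not as a post-hoc
  correlation — so the slope-coupling model is correctly specified under
  the generator, and the recipient coupling defaults to 0, mirroring the
  asymmetry the analysis is designed to detect.
- **Analytic truth.** Because within-class sampling is position-independent,
  the expected assigned frequency at a position has a closed form
  (`expected_token_frequency`), and the programmed positional trend is its
  projection onto the fitted orthonormal basis (`true_frequency_trend`).
  This gives exact ground truth for trend-recovery tests without a
  simulation oracle.

What the generator does **not** emulate: overlap and turn competition,
luminance confounds and pupil foreshortening, semantic content, anaphoric
dependencies between turns, position-dependent *within*-class frequency
structure (in real talk, turn-initial function words are themselves skewed
toward pro-forms), and tagger errors beyond the "well"/"so" case. Passing
recovery tests therefore shows that the estimators are consistent and the
inference chain is correctly wired under the assumed data-generating
process — not that real conversational data satisfy those assumptions.

## Numerical and design choices

- Interpolation batches are non-overlapping consecutive 600-observation
  blocks; a gap spanning a seam is filled within each block against that
  block's nearest valid value (switchable to whole-series interpolation).
  Fully missing blocks stay missing and are reported.
- The preprocessing order is fixed as interpolate → baseline → bin, so the
  baseline datum is always defined.
- Binning distributes remainder samples to the earliest bins — any rule
  with spread ≤ 1 would be admissible; this one is pinned for
  reproducibility.
- Turn-participant pairs with fewer valid samples than words are excluded
  and tallied, never padded.
- Hapax status is computed on the selected subset, the same universe as the
  normalised frequencies (whole-corpus hapax counting is available by
  passing a table built on the full token set).
- Case folding before frequency keying is on by default and is a flag.
- Turns are taken as given in the input file; the package does not
  re-segment speech.
- Unknown tags are admitted with a warning and classed as function words.

## Problem sizes used in validation

The bundled validation suite runs the full chain on a default 2,000-turn
bundle (≈ 17,500 tokens, 6 participants, 3 conversations) for the headline
fits. Cubic-trend recovery is checked on the cubic-shaped mixed fit
directly and assessed as bias across 24 regenerated bundles, since the
single-bundle sampling error of an orthonormal cubic coefficient at this
scale is of the order of 20%; the stepwise ladder itself is exercised
separately at scales where each step's power is near 1, because at the
default bundle scale the programmed curve's quadratic component is small
relative to token-level frequency dispersion and the ladder can stop at
degree 1 before reaching the cubic. The speaker-linear/recipient-curved
asymmetry is assessed over 100 reduced (400-turn) replicates, the smallest
scale at which the recipients' plateau curvature is detected with power
near 1. These sizes were chosen to put each check's power near 1 while
keeping the whole suite comfortably fast on one CPU.

## Known limitations

- Random slopes are out of scope; only random intercepts are modelled.
- With 3 conversations the conversation variance is often estimated at the
  boundary; fits report singularity rather than reparameterising.
- The stepwise selection inherits the usual caveats of significance-driven
  model building (no skipping of degrees; no correction for the selection
  path).
- The positional pro-form heuristic (pro-form at relative position ≤ 0.2)
  is not syntactic subject detection.
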