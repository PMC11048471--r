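---
title: "Simulating a clinical 1:1 face-verification evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating a clinical 1:1 face-verification evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faceverify)
```

## What is being emulated

A hospital evaluation of deep-learning face verification enrols each of
100 patients with one reference photograph and then probes them under 18
conditions: the 16 combinations of mask (no/yes), eyes (open/closed),
posture (sitting/supine) and illumination (sufficient / 3–4 lux low),
plus right- and left-lateral recumbent postures representing nighttime
sleeping (taken mask-free, eyes closed, in low light). That is 1900
images. Every probe is compared against every reference, giving 100
genuine and 9,900 impostor comparisons per condition — 158,400 impostor
scores over the 16 factorial conditions.

The verification engine maps each face to a feature vector and scores a
pair by cosine similarity, re-scaled to the authentication score
`AS = 0.5·CS + 0.5`. Per condition, the genuine AS is summarized as a
mean ± SD over the 100 patients (the interpretation of the published ±
as a patient-level SD is an assumption of this package; the source
tables do not say otherwise). Wrong-patient scores sit at 0.50 ± 0.02
everywhere.

Patient photographs and the engine are unavailable, so `faceverify`
replaces exactly those two components with a calibrated generative
model, and keeps everything downstream — scoring, threshold selection,
rate reporting, tests — as real, tested code that would equally accept
scores from a live system via `ingest_scores()`.

## The generative model

**Genuine geometry.** A probe at target score distribution (μ, σ) is
constructed from the patient's reference `r` as

```
c ~ TruncNormal(2μ − 1, (2σ)², [−1, 1])        (inverse-CDF sampling)
w ~ Uniform(unit tangent sphere ⊥ r)
probe = c·r + sqrt(1 − c²)·w
```

so `AS(r, probe) = 0.5c + 0.5` *exactly*, and the genuine AS
distribution is the truncated-normal image of (μ, σ) by construction.
Probes perturb the *reference*, not the latent identity, which is what
pins the genuine moments to the published table regardless of every
other modelling choice.

**Impostor geometry.** Identities are
`normalize(√ρ·m + √(1−ρ)·z)` with one shared population direction `m`
per cohort and isotropic `z`. Two free parameters matter:

* `dim` (default **512**). The engine nominally uses ~2000 features,
  but real embedding coordinates are correlated; what the impostor-score
  spread reveals is the *effective* isotropic dimension. For isotropic
  unit vectors SD(CS) ≈ 1/√dim, so the observed impostor AS SD of
  ≈ 0.022 implies dim ≈ (0.5/0.022)² ≈ 516. We default to 512.
* `rho` (default **0.01**), the population-coherence weight. The mean
  impostor cosine between identities is ≈ ρ, lifting mean impostor AS
  to ≈ 0.5 + ρ/2 = 0.505, the centre of the published wrong-matching
  means (0.502–0.509).

The reference is drawn at a fixed cosine of 0.95 to the identity (the
`control` profile entry, AS 0.975, sd 0). The value is arbitrary and
configurable: genuine scores are defined against the reference, so it
affects only impostor statistics, and there only by a factor
≈ 0.95² ≈ 0.90 of attenuation on the coherence term — the full
reference→probe chain realizes a mean impostor AS of ≈ 0.502 rather
than 0.505. Both round to the published 0.50, and no acceptance
quantity depends on the difference.

## Thresholds and decisions

Acceptance is strictly greater-than (`AS > t`; a tie rejects). Zero
wrong-patient acceptance being the binding clinical requirement, the
operating threshold is the *maximum impostor score* of a calibration
subset: under strict acceptance this yields FAR = 0 with no tie-breaking
epsilon, and any strictly smaller threshold re-admits an impostor.

Masked and unmasked comparisons are calibrated separately (the engine
detects mask wearing, and the two score distributions differ). A single
pooled maximum could never produce two distinct thresholds, so
`calibrate_thresholds()` defaults to per-mask-status subsets
(8 conditions, 79,200 impostor scores each in the default cohort) and
offers pooled calibration as a sensitivity switch. How the original
study's calibration subsets were formed is not fully documented; the
subset choice here is our design decision, not a claim about the
study's procedure.

The thresholds actually measured in the clinic — 0.642 unmasked, 0.620
masked — are extreme values of the real engine's impostor tail and
cannot be recovered from printed moments; they ship as the fixed
`reference_thresholds()` policy, used when reproducing the published
rates. Simulation-calibrated thresholds (typically near 0.60, the
expected maximum of ~79,000 draws from a ≈ N(0.50, 0.022) tail) are
always reported alongside under their own name.

## Reported statistics

* **Per-condition certification rate**: `100 × successes / n`, i.e.
  `(1 − FRR) × 100`, at the condition's mask-status threshold.
* **Aggregates** (exact pooled integer counts): all 8 factorial
  conditions per mask status; the 7 "adverse" conditions excluding the
  standard open/sitting/sufficient one; and the nighttime pool (no
  mask, eyes closed, low light; supine + both laterals), thresholded at
  the unmasked value since all its conditions are mask-free. Rates are
  compared as exact fractions and displayed rounded to one decimal.
* **Welch's t-test** from summary statistics (Satterthwaite df, no
  rounding), used for genuine-vs-impostor separation per condition;
  p-values below 1e-15 print as "<1e-15" but stay numeric in JSON.
* **Analytic rate prediction** `P(AS > t) = 1 − Φ((t − μ)/σ)` under the
  untruncated normal model — the closed-form oracle against which the
  Monte-Carlo rates are checked. The truncation it ignores is many
  standard deviations away at every condition's parameters.

## Numerical and design choices

* Cosines are clamped to [−1, 1] only against floating-point overshoot
  (tolerance 1e-9); the truncated-normal draw is additionally clipped to
  ±(1 − 1e-12) to keep `sqrt(1 − c²)` real, which also resolves the
  μ = 1, σ = 0 boundary (probe ≡ reference to machine precision).
* `sample_probe` accepts μ in the closed interval [0, 1]: the clip
  handles the endpoints, and rejecting them would forbid the exact
  zero-angle case the boundary semantics define.
* Tangent directions are sampled by projecting an isotropic draw off the
  reference and normalizing, re-drawing on a residual below 1e-12 (a
  measure-zero event).
* Impostor comparisons are directional (reference_i vs probe_j) and not
  deduplicated: reference and probe are distinct images, so the 1:1
  protocol genuinely performs both comparisons.
* Reproducibility: one master seed expands into per-patient L'Ecuyer-CMRG
  streams with per-condition substreams (`parallel::nextRNGStream`).
  Growing the cohort appends patients without reshuffling existing ones;
  identical config + seed reproduces every artifact byte for byte.
* The canonical condition order is mask-major, then illumination, then
  posture, with eye state varying fastest — the row order of the
  published score table.
* A single unmasked reference per patient is assumed; whether the
  original system matched masked probes against a masked reference is
  not documented. Eyeglasses (worn by 46 of the 100 patients), age and
  ethnicity effects are unmodelled covariates.

## Problem sizes used in the tests

The test-suite defaults are chosen for statistical resolution, not
fidelity to hardware: structural and oracle checks run on cohorts of
2–7 patients at dim 8–64; distribution-recovery checks use the full
100-patient cohort (dim 64 or 512); the Monte-Carlo-vs-analytic rate
check uses 2000 probe draws per condition, since near a predicted rate
of 99.97% a 100-draw sample cannot resolve a 3-binomial-SE band; and
isotropy checks use 1000 identity pairs at dim 128–512. Stochastic
assertions use fixed seeds and bands of 3–4 standard errors.

## What passing tests do and do not show

The generator reproduces the *published summary statistics* — genuine
per-condition means and SDs, impostor mean and spread, and therefore the
certification rates that follow from them at fixed thresholds. It does
not model the real engine's tail behaviour (hence thresholds are fixed
constants, not simulation targets), per-patient correlation of scores
across conditions, photographer or device effects, or any image-level
phenomenon. Agreement of the simulated rates with the published ones
shows the published rates are consistent with the published score
distributions under the zero-FAR decision rule — not that the simulator
would predict a new engine's behaviour.
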