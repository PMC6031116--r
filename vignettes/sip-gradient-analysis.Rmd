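---
title: "Quantitative SIP gradient analysis: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative SIP gradient analysis: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sipscope)
```

## The problem

In DNA stable isotope probing (SIP), organisms that assimilate a
heavy-isotope substrate (here ¹³C, fixed by a plant from ¹³CO₂ and released
into the rhizosphere) build the label into their DNA, which raises its
buoyant density. Isopycnic centrifugation in a CsCl gradient then separates
labeled from unlabeled DNA physically, and comparing the density profile of
a labeled ("treatment", e.g. rhizosphere) community with an unlabeled
("control", e.g. bulk soil) community identifies which density range holds
isotopically enriched genomes. `sipscope` implements the quantitative side
of that workflow: the density physics, the fraction binning, the
enrichment estimate for a genome recovered from the gradient, the GC-skew
validation of a circularized genome, and comparative genome statistics.

## The buoyant-density model

Two effects set where DNA bands in CsCl:

* **Base composition.** Unlabeled DNA follows the linear Schildkraut
  relation \(\rho = 1.660 + 0.098\,\mathrm{GC}\) (g/mL, GC as a fraction).
  At 49.95% GC this gives 1.709 ≈ 1.71 g/mL, the familiar anchor for a
  mid-GC genome.
* **Isotope content.** Full substitution of ¹²C by ¹³C adds a fixed shift,
  0.036 g/mL by default (the standard DNA-SIP value); partial labeling
  scales linearly with the atom-fraction excess (AFE), so
  \(\rho = \rho_{GC} + 0.036\,\mathrm{AFE}\).

Inverting the second relation estimates AFE from an observed density:
\(\widehat{\mathrm{AFE}} = (\rho_{obs} - \rho_{GC})/0.036\), clamped to
\([0, 1]\). All three constants live in `isotope_model()` and are
overridable, because published calibrations differ by instrument and salt;
the defaults are the values consistent with the 1.71 g/mL anchor above.
The shift model is deliberately GC-independent — a GC-dependent ¹³C shift
is a second-order refinement we do not model. Fraction densities measured
by refractometry convert through a linear CsCl calibration line
(`ri_to_density()`), again with overridable coefficients; no temperature
correction is applied, so all densities are at the calibration
temperature.

When a genome is located only to a density *interval* (the bin it was
mainly recovered from), `enrichment_from_density_interval()` propagates
both interval ends into AFE bounds. For a 49.95% GC genome recovered at
1.737–1.747 g/mL the lower bound is 0.78 — comfortably above one half, the
conventional claim level for "heavily labeled".

## Fraction binning

Fractions are collected densest-first from a bottom-pierced tube
(`gradient_profile()` canonicalizes either input order) and binned into
**light** (unenriched), **middle** (partially enriched) and **heavy**
(highly enriched) density intervals. Two routes exist:

* `sip_bin_scheme()` applies the conventional fixed soil-SIP cutoffs
  (1.692–1.737 / 1.738–1.746 / 1.747–1.765 g/mL). The printed cutoffs have
  0.001 g/mL gaps because they are discrete fraction boundaries; intervals
  are treated as closed and a density falling inside a gap is assigned to
  the nearer interval, ties to the lighter bin. This tie-break is a design
  choice: boundary densities are measurement artifacts, and preferring the
  lighter bin is the conservative direction (it never inflates apparent
  enrichment).
* `auto_bin()` derives cutoffs from the data by comparing per-fraction
  relative DNA masses of treatment and control. The heavy lower bound is
  the smallest density where the control holds less than `epsilon` of its
  own mass while the treatment still holds at least `epsilon`; the middle
  lower bound is the smallest density where the treatment's relative mass
  exceeds the control's by more than `delta`. Both scans are restricted to
  densities above the control profile's mode: below the mode both tails
  vanish and the same inequalities would fire spuriously on the light
  side. Defaults `epsilon = 0.05`, `delta = 0.02` (fractions of a sample's
  total mass) were chosen once as the smallest thresholds that a visually
  obvious second mode in a 32-fraction gradient clears while per-fraction
  measurement noise does not; the underlying published procedure is
  qualitative, so both thresholds are exposed and logged.

Per-genome coverage across fractions is made comparable by rescaling each
fraction's library to a common sequencing depth
(`normalize_coverage()`; `normalized = raw × reference_depth / depth`).
The normalization basis — total sequenced bases per fraction library, with
the minimum depth as reference — is recorded in the output metadata rather
than asserted as the published convention, which is unstated. The
coverage-weighted mean of fraction densities
(`genome_density_centroid()`) then locates the genome on the density axis
more finely than its dominant bin, and feeds the enrichment estimate.

## GC-skew validation and circularization

Bidirectional replication leaves a strand asymmetry: the leading strand is
typically G-rich, so the GC skew \((G-C)/(G+C)\) in sliding windows
changes sign at the replication origin and terminus, and the *cumulative*
skew (running sum of window skews — the windows overlap at step < window,
which only rescales the curve) has a single trough at the origin and peak
at the terminus. A clean single trough/peak pair is therefore evidence
that a circularized assembly is globally correct. `gc_skew()` (window
1000 bp, step 10 bp by default), `predict_ori_ter()` (trough = origin,
peak = terminus; an `invert` flag serves organisms with the opposite bias;
ties break to the smallest coordinate; a flat curve is an error, not a
call) and `rotate_to_origin()` implement this. Coordinates are 1-based in
all reports. N and ambiguity codes count as neither G nor C, and a window
with no G or C has skew 0.

`circularize()` performs the sequence-level circularization test: the
longest prefix/suffix overlap of at least `min_overlap` bp with mismatch
rate at most `max_mismatch_rate` is trimmed once. Overlap candidates are
scanned longest-first, capped at half the sequence length and 10 kb
(terminal assembly redundancy is short compared to genomes); a sequence
with no acceptable overlap is *reported* as not circular rather than
erroring, because linearity is a legitimate finding. Assembly-graph
evidence and gap-filling curation are out of scope.

## Comparative genome statistics

`genome_stats()` recomputes the standard comparison columns from a
sequence and a gene table: genome size, gene number, unannotated genes,
mean gene length, total coding length (union of gene intervals, so
overlapping genes count once), coding density, CAZy gene count and
distinct CAZy families. `diff_from_average()` expresses the focal genome's
deviation from the group mean **as a percentage of the focal value, with
the focal genome included in the mean** — of the simple conventions, this
is the one under which the published comparative row for the complete
Saccharibacteria genomes reproduces from its printed columns (32.4% genome
size, 33.2% gene number, 39.1% unannotated, 39.9% CAZy, 31.7% distinct
CAZy). One published cell does not recompute internally: the focal mean
gene size (843.3 bp) differs from total coding / gene number (836.6 bp),
presumably an upstream rounding or definition difference, so that cell is
carried but not treated as an oracle for `genome_stats()`. Percentages are
written at one decimal in tables (integer in prose-style summaries); raw
values are retained in machine output.

## The synthetic-data generator

`simulate_gradient()` is a forward model of the isopycnic separation: the
density span (defaults 1.692–1.765 g/mL, 32 equal-width fractions,
matching a typical ~32-fraction soil-SIP run) is fixed, each taxon's band
centre is `density_from_enrichment(gc, afe)`, and its DNA mass is spread
over fractions by integrating a Gaussian band (sd `band_sd`, default
0.003 g/mL — chosen once so a taxon's mass lands in roughly five adjacent
fractions, the width real gradient profiles show). Optional multiplicative
log-normal noise perturbs per-fraction masses. Coverage is proportional to
taxon mass over genome length, scaled so the best-covered genome/fraction
peaks at 15× — a realism anchor for a well-sampled genome, nothing is
inferred from it. `simulate_genome()` writes a sequence whose halves
over-use C and G respectively, so the true origin (the switch point) and
terminus (the ends) are known by construction. `make_study_fixture()`
combines both into a complete synthetic study: a 49.95% GC focal genome at
AFE 0.85 (which bands at 1.740 g/mL, inside the conventional middle bin,
as the real rhizosphere genome did) inside a 58–70% GC background that is
mostly unlabeled, partly moderately labeled, plus one fully labeled
population so the treatment develops a genuine heavy shoulder.

What the generator does *not* emulate — and hence what passing recovery
tests do not show about real data: read-level errors and assembly,
DNA recovery efficiency varying along the gradient, gradient curvature and
diffusion physics beyond the Gaussian band, multi-replicon genomes, and
compositional biases other than the imposed two-half strand asymmetry.
Recovery results on the fixture demonstrate the estimators are correct
under the stated model, not that the model captures every property of a
soil metagenome.

## Numerical choices and degenerate inputs

* AFE estimates are clamped to [0, 1]; DNA observed at or below its
  unlabeled density reports AFE 0 with a zero-width interval.
* Observed densities must lie in [1.60, 1.85] g/mL (the physically
  plausible CsCl range); refractive indices in [1.3, 1.5].
* `auto_bin` with no density satisfying the heavy rule returns a scheme
  with an empty heavy bin plus a warning, so "no enrichment" propagates as
  a result rather than an error; identical treatment and control yield
  empty middle and heavy.
* All simulator randomness flows from a single integer seed through
  isolated RNG scopes, so fixture generation is byte-reproducible and
  never disturbs the caller's RNG state.
* Problem sizes used by the shipped analyses and checks — 32-fraction
  gradients, 100–150 kb synthetic genomes, 10–20 seeds per recovery
  property — were chosen as the smallest sizes at which the Gaussian-band
  and skew statistics are comfortably out of the noise (band sd spans ~5
  fractions; skew amplitude 0.1 gives a cumulative signal hundreds of
  window-skew units deep).

## Known limitations

The linear shift model treats labeling as uniform across the genome;
within-population labeling heterogeneity broadens the band and is absorbed
into `band_sd`, not modeled. The fixed full-label shift of 0.036 g/mL is a
community convention, not a measured constant of this workflow; enrichment
estimates scale inversely with it, which is why it is prominently
configurable. Binning thresholds are heuristics over relative-mass
profiles and should be read alongside the printed per-bin masses, not as a
hypothesis test. The origin/terminus caller assumes a single replichore
pair; plasmids and secondary replicons need per-replicon profiles.
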