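---
title: "Nucleosome occupancy and transcription-factor binding: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nucleosome occupancy and transcription-factor binding: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nuctf)
```

# The scientific setting

In nucleosome mapping by nuclease protection, each sequenced fragment is
interpreted as a 146-bp nucleosomal "tag": a sequenced 5′ end with an
inferred 3′ end 146 bp away. The number of tags spanning a basepair is the
occupancy at that basepair. Three libraries matter for the analyses here:
an *in vivo* uncrosslinked map, an *in vivo* formaldehyde-crosslinked map
(which additionally captures fast-exchanging, "labile" nucleosomes), and an
*in vitro* map of chromatin reconstituted on naked genomic DNA, which
reflects only the intrinsic, sequence-directed preferences of nucleosomes.

TF binding is defined externally: motif sites receive the ChIP-chip
enrichment p-value of the microarray probe containing the site's center,
sites with p < 0.001 are *bound* (strict inequality; p = 0.001 is
unbound), remaining sites fall into the bins (0.001, 0.01], (0.01, 0.1],
(0.1, 0.5], (0.5, 1] — with the first bin left-closed so the partition
{bound} ∪ {bins} is complete — and a TF enters genome-scale analyses when
it has at least 50 bound sites.

The package asks, for each TF: how well does (low) nucleosome occupancy
predict binding; how does that association change when the data are
degraded to lower spatial resolution; what do crosslinked-minus-
uncrosslinked difference maps add; what occupancy *shapes* surround bound
sites; and does occupancy improve a thermodynamic sequence model of
binding?

# Tracks and averaging

**Coordinates.** All coordinates, in memory and on disk, are 0-based
half-open (BED/bedGraph convention). The center of a site `[start, end)`
is `start + floor((end-start-1)/2)`; for even-length motifs the center
falls between basepairs, and centered windows are extended one basepair
rightward (in genome-coordinate direction) so the window is one basepair
longer — a stated, deterministic convention.

**Blurring.** `blur()` replaces each basepair by the mean over a centered
window, simulating low-resolution data. At chromosome ends the window
shrinks to its in-bounds part rather than producing missing values, so
downstream statistics never see NA and the genome-wide mean is preserved
up to vanishing edge terms. `blur` is linear, commutes with scalar
rescaling, and agrees with `window_average()` at interior loci — the two
averaging paths are tested against each other and against a naive loop.

**Profiles.** `extract_profile()` averages occupancy over `2H+1`-bp
windows centered on sites (default H = 600). Minus-strand windows are
reversed first, so positive offsets always mean "downstream of the
motif". Sites whose window would cross a chromosome end are dropped and
counted rather than padded. Symmetrization averages the profile with its
mirror image, the display convention for factors with palindromic
occupancy structure.

**Difference maps.** The uncrosslinked track is scaled to the crosslinked
track's genome-wide *total* before subtraction, making the difference map
mean-zero by construction; positive values mark crosslink-trapped
nucleosomes. Totals, rather than trimmed means or per-chromosome factors,
are the simplest faithful reading of a genome-wide normalization; since a
mean-based factor differs only by the shared genome size, the choice is
invisible to every downstream statistic. Flank-based scaling
(`mode = "flank"`, offsets 100–600 bp from site centers on both sides) is
provided for site-anchored comparisons where the site-proximal signal
itself is the quantity of interest.

# ROC association statistics

`roc_auc()` implements the Mann–Whitney form: with low occupancy
predicting binding, AUC = P(pos < neg) + ½·P(pos = neg). Ties get weight
½ — integer tag counts make ties routine, so the convention is load-
bearing. The implementation computes the U statistic from midranks on the
requested orientation; U is an exact multiple of ½, so results agree
bit-for-bit with an exhaustive pairwise count (tested on 200 random tied
instances) and the duality `AUC(pos,neg) + AUC(neg,pos) = 1` is exact.

Bootstrap intervals resample *both* classes with replacement (B = 1000 by
default) and report the percentile 95% interval, labeled as such.
Percentile was chosen over BCa for transparency; the interval type is part
of the output, not hidden.

`delta_auc()` scores sites and controls by windowed mean occupancy at
sizes {15, 40, 75, 150, 300, 600} bp and reports
Δ = AUC(600) − AUC(15). One control set is drawn once and reused across
all sizes, so the AUCs differ only through the window size. Controls
default to random promoter basepairs (sampled uniformly over the promoter
union, with replacement) — a deliberately conservative background, since
promoters are themselves nucleosome-poorer than the genome at large.
`classify_by_sigma()` summarizes a panel of TFs by how far each |Δ| sits
above the cross-TF mean in SD units (<1σ, 1–2σ, ≥2σ), with the sign of Δ
reported separately; if the SD is exactly zero all TFs are <1σ.

# qPCR enrichment

Per replicate, ΔCt = Ct(IP) − Ct(input) per site; ΔΔCt subtracts the mean
ΔCt of the two control sites of that replicate; a site's fold enrichment
is `2^(−mean over replicates of ΔΔCt)`. Exactly two control sites per
replicate are required and validated at parse time. For the plotted fits,
enrichments below 1 are clamped to 1 and tag counts above 600 to 600;
`pearson_fit()` then regresses log₂ enrichment on tag count. The Pearson
r is invariant to the log base; log₂ keeps the slope on the same scale as
the ΔΔCt arithmetic. A one-sided p-value for r < 0 is reported because
the scientific hypothesis is anti-correlation.

# Profile clustering

Features catenate the central 600 bp of the mean-normalized in vivo
profile with the central 600 bp of the in vitro profile (1200 values per
TF). Similarity is Pearson correlation; clustering is k-means. The
implementation standardizes each row to mean 0, SD 1 and runs Euclidean
k-means: squared Euclidean distance between z-scored rows is an affine
function of 1 − r, so cluster assignments are exactly those of
correlation-similarity k-means without a bespoke algorithm. This also
dissolves an ambiguity in the display conventions (profiles described
both as normalized to mean 1 and to mean 0): any per-profile affine
rescaling leaves the clustering invariant, so only the display default
(mean 1) had to be chosen. k = 5 by default, exposed as an argument; 20
random restarts keep the best inertia; a restart yielding an empty
cluster is redrawn; everything is deterministic under the seed. Within
clusters, TFs are ranked by blurring improvement (descending Δ), ties
broken lexicographically.

# The thermodynamic binding model

For a PWM with probabilities `p_j(b)` (pseudocount 0.01 added and rows
renormalized), each sequence window of motif length on each strand gets a
relative association constant `Ka_rel = ∏_j p_j(base_j)/0.25` — the
likelihood ratio against a uniform background, the standard
correspondence between PWM score and relative affinity. Windows
containing N are skipped and counted. At protein concentration c each
window is occupied with probability `cKa/(1+cKa)` and a promoter is
"bound" if at least one window is occupied:
`P = 1 − ∏(1−p_i)`, computed as `1 − exp(Σ log1p(−p_i))` (the two paths
agree to 1e-12 and are both tested). The default concentration sets
`c = 1/max Ka` over the scored promoters — the best site half-occupied —
and is shared across all weighting variants so their AUCs are comparable.

**Nucleosome weights.** The genome is divided into non-overlapping 15-bp
segments. A segment's local occupancy is its mean tag count; its regional
occupancy is the mean over a centered window (default 600 bp sliding, the
regional scale on which intrinsic depletion operates; 300 bp is available
via `regional_window = 300`). Q expresses the chosen occupancy in SD
units *above zero*: the occupancy divided by the genome-wide SD of
per-segment local means, with no mean subtraction — so segments with no
mapped tags (including unmappable regions in real data) get Q = 0 and
weight exactly 1. The weight is `W^(−Q)` with W = 4, fixed rather than
fitted; higher occupancy lowers predicted affinity exponentially. Each
motif window's Ka is multiplied by the weight of the segment containing
the window's center basepair — a deterministic lookup rather than an
overlap-weighted average, which would blur the 15-bp grid for no
analytical gain. Since occupancy is non-negative, Q ≥ 0 and weighting
never increases an affinity. A track with zero variance carries no
occupancy contrast; `evaluate_variants()` treats it as uniform weights
(all 1), while `segment_weights()` itself rejects it as degenerate.

# The synthetic-data generator

The generator exists so that every analysis above can be verified against
planted truth. It emulates the *statistical structure* the analyses
consume, not the biophysics that produced it.

**Geometry.** Default: one 200-kb chromosome, 120 genes, promoters the
600 bp 5′ of each gene start, placed in equal slots so promoters never
overlap; 50 bound + 50 unbound planted consensus sites (one per
promoter, random strand, ≥ 100 bp from promoter edges where room
permits). Bound sites draw ChIP p-values uniformly on (1e-6, 1e-3);
unbound sites draw a bin (default equal proportions) then a uniform
p-value within it. These sizes are chosen to look like a yeast
chromosome's gene density while keeping a full simulation around half a
second; recovery tests and the reproduction script use 60-kb / 40-gene /
15-site versions of the same conditions where many replicates are needed,
with all noise parameters at their defaults.

**Tracks.** Per-bp Poisson counts around a mean depth of 10 tags/bp —
the analyses consume only per-bp counts, so sampling counts directly
(rather than placing discrete 146-bp fragments) plants every structure
the statistics exploit; an explicit tag-start sampler
(`sample_tag_starts()`) feeds the coverage path so the 146-bp interval
arithmetic is exercised end to end as well. The in vivo rate at each
bound site carries a multiplicative dip (residual 0.2 at the center,
quadratic recovery over a 150-bp width) and flanking cosine phasing
(amplitude 0.3, repeat 165 bp, decaying over three repeats — phased
nucleosomes up to about three units out). The crosslinked track *adds*
independent Poisson excess (5 tags/bp) over the 146-bp span of a random
half of bound sites (the labile fraction), so crosslinked totals are
never below in vivo totals by construction.

**In vitro regimes.** Five intrinsic-occupancy archetypes, one per
simulated TF class: `local_ndr` (narrow dip only), `regional_depletion`
(Gaussian 600-bp-scale depression to 0.5 of the mean plus the narrow
dip), `broad_poor` (broad depression to 0.4 with site-local fine
structure scrambled per site by lognormal factors on a 15-bp grid — the
local signal is noise, the regional signal is real), `occluded_site`
(broad depression but occupancy *raised* above the regional mean over the
motif itself), and `flank_enriched` (narrow dip with strongly elevated
immediate flanks). The archetypes are deliberately mutually distinct in
shape: they are the planted truth for clustering recovery, and they
reproduce the two qualitative behaviours that matter — blurring *hurts*
when information is site-local (`local_ndr`: Δ < 0) and *helps* when
depletion is broad but locally scrambled (`broad_poor`: Δ > 0).

**qPCR.** Bound-site occupancies (150-bp windows, standardized across
sites) map to planted log₂ enrichments `−slope·occ + N(0, σ)` (slope 1,
σ = 0.25; the minus sign is the anti-correlation, so the slope argument
itself must be non-negative), which are converted exactly to Ct rows with
two control sites at enrichment 1 in every replicate. With σ = 0 the
ΔΔCt pipeline recovers planted enrichments to machine precision; with
noise, the population correlation between recovered log-enrichment and
occupancy is `−slope/√(slope² + σ²)` and the recovered r matches it
within sampling error.

**Determinism.** Every stochastic function takes an explicit seed, runs
under a save/restore RNG guard, and derives sub-stream seeds with a fixed
integer map kept inside 32-bit range; identical configuration + seed is
bit-identical, and no package function perturbs the caller's RNG state.

# What the synthetic data do and do not show

The generator plants idealized versions of the structures the statistics
detect: Poisson noise, clean consensus sites, rectangular promoters, no
mappability gaps, no MNase sequence bias, no sequence-dependent
nucleosome energies (dinucleotide periodicity is deliberately out of
scope), and ChIP p-values assigned rather than measured. Passing tests
therefore demonstrate that the *estimators and pipelines are correct and
well-calibrated* — that AUC is 0.5 under the null, that planted effects
are recovered in the planted direction with the planted magnitudes — not
that real chromatin behaves like the generator. Conclusions about real
data still require the real tag maps, probe tables and motif calls these
functions were built to consume.

# Numerical conventions and degenerate inputs

* Mean-1 normalization is exact (division by the computed mean) and
  idempotent; all-zero tracks are rejected rather than silently returned.
* bedGraph output merges equal-value runs, omits zero runs, and
  round-trips per-bp values within 1e-9.
* `roc_auc` requires both classes non-empty; `pearson_fit` requires ≥ 3
  points and non-zero variance in both variables; `classify_by_sigma`
  requires ≥ 3 TFs; profile extraction fails only when *every* window is
  clipped.
* Probe→site assignment requires non-overlapping probes, making the
  containing probe unique; containment is tested at the site center, a
  deterministic rule consistent with probes being much longer than
  motifs. Sites in no probe are dropped and counted.
* k-means rows must be non-constant (a constant profile has no Pearson
  similarity to anything); the offending TFs are named in the error.

# Problem sizes

The test suite and `scripts/acceptance.R` run full-scale (200-kb) default
simulations where single datasets suffice — the blurring-direction check
uses 20 replicates per regime at the full default scale — and the 60-kb
variant of the same conditions where 40–50 independent simulations are
averaged (clustering recovery, binding-model evaluation). Both complete
in well under a minute each on one core; the sizes are stated here as the
package's own reproducibility conditions.

# Known limitations

* Coverage is fragment-leftmost-based; dyad-centered (73-bp offset)
  coverage and fragment-length distributions are not modeled.
* No nucleosome calling or peak detection: the unit of analysis is the
  per-bp track, matching the window-averaging statistics.
* The ΔΔCt machinery assumes exactly two control sites; designs with
  other control counts need their tables reduced first.
* The binding model treats windows as independent (no TF–TF
  cooperativity, no explicit nucleosome–TF competition kinetics);
  occupancy enters only through the multiplicative weights.
* k is fixed (default 5) rather than selected by a gap statistic; the
  choice is exposed and cheap to vary.
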