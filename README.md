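# nuctf

Tools for asking how nucleosome occupancy relates to transcription-factor
(TF) binding in compact genomes such as budding yeast. Nuclease-protection
sequencing yields, for every basepair, the number of inferred 146-bp
nucleosomal fragments ("tags") spanning it; TF binding is defined by
ChIP-chip enrichment p-values at motif sites. `nuctf` builds and manipulates
these per-basepair occupancy tracks, quantifies how well occupancy predicts
binding, and feeds occupancy into a thermodynamic model of TF–promoter
association.

The package covers five connected analyses:

1. **Occupancy tracks** — coverage from tag 5′ starts (each tag spans
   `[start, start+146)`), mean-1 normalization, centered sliding-window
   "blurring" to simulate low-resolution data, site-centered average
   profiles (symmetrized, strand-aware), scaling of one library onto
   another, and the crosslinked-minus-uncrosslinked **nucleosome difference
   map** whose peaks mark crosslink-trapped (labile) nucleosomes.
2. **Association statistics** — Mann–Whitney ROC AUC (ties count ½):
   `AUC = P(score_pos < score_neg) + ½P(=)` when low occupancy predicts
   binding, with percentile bootstrap confidence intervals, window-size
   sweeps `Δ = AUC(600 bp) − AUC(15 bp)`, and classification of per-TF
   deltas by standard deviations of |Δ|.
3. **qPCR enrichment** — ΔΔCt fold enrichments
   (`fold = 2^(−mean ΔΔCt)` against the mean of two control sites), the
   standard clamps (enrichment < 1 → 1, tag count > 600 → 600), and the
   linear fit of log₂ enrichment on tag count with a one-sided test of
   anti-correlation.
4. **Profile clustering** — per-TF features catenating the central 600 bp
   of the mean-normalized in vivo and in vitro profiles, k-means under
   Pearson similarity (z-scored rows + Euclidean k-means, k = 5 by
   default), and within-cluster ranking by blurring improvement.
5. **Thermodynamic binding model** — PWM likelihood-ratio affinities
   `Ka_rel = ∏ p_j(base)/0.25` per window and strand, promoter binding
   probability `1 − ∏(1 − cKa/(1+cKa))`, optionally weighted per
   non-overlapping 15-bp segment by `W^(−Q)` where `Q` is occupancy in
   SD-above-zero units and `W = 4` — using either local 15-bp or
   regionally averaged occupancy.

A first-class synthetic-data module (`sim_config()`, `simulate_dataset()`)
generates genomes with non-overlapping promoters, planted consensus sites
with binned ChIP p-values, Poisson tag maps carrying nucleosome-depleted
regions, phased flanking nucleosomes, five intrinsic-occupancy regimes,
crosslink excess at labile sites, and matching qPCR tables — with full
ground truth, so every stage is verified end to end without external data.

## Worked example

Simulate a dataset whose intrinsic (in vitro) occupancy around bound sites
is broadly depleted but locally scrambled, then ask how window size changes
the occupancy–binding association:

```r
library(nuctf)

cfg <- sim_config(regime = "broad_poor")
sim <- simulate_dataset(cfg, seed = 20)
sim
#> sim_dataset: broad_poor regime, 50 bound / 50 unbound sites, 22 labile

bound <- sim$sites[sim$sites$bound, ]
ctrl  <- random_promoter_sites(sim$genome, sim$gene_starts, 200, seed = 21)

delta_auc(sim$maps$invivo, bound, ctrl)
#> delta_auc: 15:0.996 40:0.997 75:0.995 150:0.999 300:0.919 600:0.781  delta(600-15) = -0.2148
delta_auc(sim$maps$invitro, bound, ctrl)
#> delta_auc: 15:0.778 40:0.838 75:0.871 150:0.874 300:0.930 600:0.949  delta(600-15) = +0.1704
```

In vivo, bound sites sit in sharp nucleosome-depleted regions: occupancy in
a 15-bp window is a near-perfect (low-score) classifier of binding
(AUC 0.996) and blurring to 600 bp destroys signal (Δ = −0.21). The
intrinsic map has the opposite behaviour: the site-local signal is noisy
(AUC 0.778) but the broad depletion means 600-bp averaging *improves* the
association (Δ = +0.17) — precise nucleosome positioning is not what
carries the information there.

The difference map isolates crosslink-trapped nucleosomes at bound sites:

```r
dm  <- difference_map(sim$maps$xlink, sim$maps$invivo)
lab <- sim$sites[sim$truth$labile, ]
pos <- window_average_at(dm, data.frame(chrom = lab$chrom,
                                        center = site_center(lab$start, lab$end)), 150)
neg <- window_average_at(dm, ctrl, 150)
bootstrap_auc(pos, neg, B = 1000, seed = 22, low_predicts_positive = FALSE)
#> roc_result: AUC = 1.0000 (22 pos, 200 neg, high score predicts positive)
#>   bootstrap 95% CI [1.0000, 1.0000] (percentile, B = 1000)
```

Every planted labile site ranks above every random promoter locus on the
difference map, with a degenerate bootstrap interval at 1.

## Layout

- `R/` — implementation (I/O, tracks, site annotation, simulation, ROC,
  qPCR, clustering, binding model)
- `tests/testthat/` — unit, property and end-to-end statistical tests
- `vignettes/nucleosome-occupancy-and-tf-binding.Rmd` — the methods
  vignette: models, parameters, generator design, numerical conventions,
  limitations
- `scripts/acceptance.R` — the reproduction script above
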