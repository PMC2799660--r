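test_that("generate_genome is deterministic with non-overlapping promoters", {
  cfg <- sim_config(chrom_length = 100000L, n_genes = 50L)
  g1 <- generate_genome(cfg, 17)
  g2 <- generate_genome(cfg, 17)
  expect_identical(unclass(g1$genome), unclass(g2$genome))
  expect_identical(g1$gene_starts, g2$gene_starts)

  proms <- promoter_intervals(g1$genome, g1$gene_starts)
  expect_equal(nrow(proms), 50L)
  expect_true(all(proms$end - proms$start == 600L))
  o <- order(proms$start)
  expect_true(all(proms$start[o][-1] >= proms$end[o][-50]))

  empty <- generate_genome(sim_config(chrom_length = 5000L, n_genes = 0L), 1)
  expect_equal(nrow(empty$gene_starts), 0L)
  expect_error(sim_config(chrom_length = 5000L, n_genes = 50L), "too short")
})

test_that("plant_sites writes the consensus and draws p-values in the bins", {
  cfg <- sim_config(chrom_length = 150000L, n_genes = 110L,
                    n_bound = 50L, n_unbound = 50L)
  g <- generate_genome(cfg, 3)
  pw <- pwm({
    m <- matrix(0.1 / 3, 8, 4)
    m[cbind(1:8, c(1, 2, 3, 4, 1, 2, 3, 4))] <- 0.9
    m
  }, tf_name = "T1")
  pl <- plant_sites(g, pw, cfg, 5)
  expect_equal(nrow(pl$sites), 100L)
  expect_equal(sum(pl$sites$chip_p < 1e-3), 50L)
  expect_equal(pl$sites$bound, pl$sites$chip_p < 1e-3)

  cons <- pwm_consensus(pw)
  for (i in seq_len(nrow(pl$sites))) {
    sub <- genome_subseq(pl$genome, pl$sites$chrom[i], pl$sites$start[i],
                         pl$sites$end[i])
    if (pl$sites$strand[i] == "-") sub <- revcomp(sub)
    expect_equal(sub, cons)
  }

  # unbound p-value bins follow the requested proportions
  cfg2 <- sim_config(chrom_length = 400000L, n_genes = 350L, n_bound = 0L,
                     n_unbound = 320L,
                     unbound_bin_props = c(0.4, 0.3, 0.2, 0.1))
  pl2 <- plant_sites(generate_genome(cfg2, 8), pw, cfg2, 9)
  bins <- bin_by_pvalue(classify_bound(pl2$sites))$pbin
  gof <- stats::chisq.test(tabulate(bins, 4), p = c(0.4, 0.3, 0.2, 0.1))
  expect_gt(gof$p.value, 0.01)

  expect_error(plant_sites(g, pw, sim_config(chrom_length = 150000L,
                                             n_genes = 110L,
                                             n_bound = 100L,
                                             n_unbound = 50L), 5),
               "more sites")
})

test_that("tag maps carry the planted structures", {
  # no depletion -> in vivo indistinguishable from the flat base process
  cfg0 <- small_cfg(depletion_depth = 1, phasing_amplitude = 0,
                    labile_fraction = 0)
  sim0 <- simulate_dataset(cfg0, seed = 2)
  v <- sim0$maps$invivo$values$chr1
  set.seed(123)
  base <- stats::rpois(10000, cfg0$mean_depth)
  ks <- suppressWarnings(stats::ks.test(v[1:10000], base))
  expect_gt(ks$p.value, 0.01)

  # depletion shows up at bound sites in vivo
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, seed = 3)
  bound <- sim$sites[sim$sites$bound, ]
  site_occ <- window_average_at(sim$maps$invivo,
                                data.frame(chrom = bound$chrom,
                                           center = site_center(bound$start,
                                                                bound$end)),
                                75)
  expect_lt(mean(site_occ), 0.6 * cfg$mean_depth)

  # crosslink excess: mean(xlink - invivo) over labile spans ~ labile_excess
  cfgx <- small_cfg(labile_fraction = 1, labile_excess = 6)
  simx <- simulate_dataset(cfgx, seed = 4)
  lab <- simx$sites[simx$truth$labile, ]
  expect_equal(nrow(lab), cfgx$n_bound)
  diffs <- vapply(seq_len(nrow(lab)), function(i) {
    ce <- site_center(lab$start[i], lab$end[i])
    span <- (ce - 73):(ce - 73 + 145) + 1
    mean(simx$maps$xlink$values$chr1[span] -
           simx$maps$invivo$values$chr1[span])
  }, numeric(1))
  se <- sqrt(6 / (146 * nrow(lab)))
  expect_lt(abs(mean(diffs) - 6), 4 * se)

  # conservation: crosslinked total never falls below in vivo total
  expect_gte(map_total(simx$maps$xlink), map_total(simx$maps$invivo))

  # occluded_site: site occupancy above the 600-bp regional mean in vitro
  cfgo <- small_cfg(regime = "occluded_site")
  simo <- simulate_dataset(cfgo, seed = 5)
  bo <- simo$sites[simo$sites$bound, ]
  ctr <- data.frame(chrom = bo$chrom,
                    center = site_center(bo$start, bo$end))
  occ_site <- window_average_at(simo$maps$invitro, ctr, 25)
  occ_reg <- window_average_at(simo$maps$invitro, ctr, 600)
  expect_gt(mean(occ_site), mean(occ_reg))

  # determinism end to end
  expect_identical(simulate_dataset(cfg, seed = 3)$maps$invivo$values,
                   sim$maps$invivo$values)
})

test_that("sampled tag starts reproduce the track shape through coverage", {
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, seed = 6)
  starts <- sample_tag_starts(sim$maps$invivo, n_tags = 20000L, seed = 7)
  expect_true(all(starts$start >= 0 &
                    starts$start < chrom_lengths(sim$genome)[["chr1"]]))
  cov <- coverage_from_tags(starts, sim$genome)
  expect_equal(sum(cov$values$chr1 > 0) > 0, TRUE)
  # depleted regions stay depleted in the re-sampled coverage
  bound <- sim$sites[sim$sites$bound, ]
  ctr <- data.frame(chrom = bound$chrom,
                    center = site_center(bound$start, bound$end))
  rand <- random_promoter_sites(sim$genome, sim$gene_starts, 100, seed = 8)
  expect_lt(mean(window_average_at(cov, ctr, 75)),
            mean(window_average_at(cov, rand, 75)))
})

test_that("written simulations round-trip through the readers", {
  dir <- withr::local_tempdir()
  cfg <- small_cfg()
  sim <- simulate_dataset(cfg, seed = 9)
  files <- write_simulation(sim, dir, seed = 10)
  expect_true(all(file.exists(files)))

  g <- read_fasta(files[["genome"]])
  expect_identical(unclass(g), unclass(sim$genome))
  back <- read_bedgraph_track(files[["invivo"]], g)
  expect_equal(back$values, sim$maps$invivo$values)
  sites <- read_sites_tsv(files[["sites"]])
  expect_equal(sites$start, sim$sites$start)
  pw <- read_pwm_tsv(files[["pwm"]])
  expect_equal(unclass(pw), unclass(sim$pwm), ignore_attr = TRUE)
  ct <- read_ct_table(files[["qpcr"]])
  expect_equal(nrow(ct), nrow(sim$qpcr$table))
  truth <- jsonlite::read_json(files[["truth"]], simplifyVector = TRUE)
  expect_equal(sum(truth$bound), cfg$n_bound)
  expect_equal(truth$labile, sim$truth$labile)
})
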