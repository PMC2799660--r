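#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic-data module:
#' a compact yeast-like genome with non-overlapping 600-bp promoters,
#' planted TF motif sites, and three per-bp tag-count tracks (in vivo
#' uncrosslinked, in vivo crosslinked, in vitro reconstituted) with the
#' occupancy structure around bound sites that the downstream analyses
#' assume.
#'
#' The `regime` controls the in vitro (intrinsic) occupancy pattern at
#' bound sites:
#' * `local_ndr` - a narrow nucleosome-depleted region over the site,
#'   no broad depletion;
#' * `regional_depletion` - a broad (600-bp-scale) smooth depression
#'   plus the narrow site dip;
#' * `broad_poor` - the broad depression only, with site-local fine
#'   structure randomized per site so the 15-bp signal is uninformative;
#' * `occluded_site` - a broad depression with occupancy over the motif
#'   itself raised above the regional mean;
#' * `flank_enriched` - a narrow site dip with strongly elevated
#'   occupancy in the immediate flanks.
#'
#' The in vivo track always carries a narrow multiplicative dip at
#' bound sites plus decaying cosine phasing in the flanks; the
#' crosslinked track equals the in vivo track plus Poisson "labile"
#' excess over the 146-bp span of a random subset of bound sites.
#'
#' @param n_chromosomes number of chromosomes
#' @param chrom_length chromosome length in bp
#' @param n_genes genes per chromosome; promoters are the 600 bp 5' of
#'   each gene start and never overlap
#' @param motif_length planted motif length in bp
#' @param n_bound,n_unbound numbers of bound (ChIP p < 1e-3) and
#'   unbound planted motif occurrences
#' @param regime in vitro occupancy regime (see Details)
#' @param mean_depth mean tag count per bp
#' @param depletion_depth residual occupancy fraction at the center of
#'   the in vivo site dip (0 = total depletion, 1 = none)
#' @param depletion_width width of the site dip in bp
#' @param phasing_amplitude amplitude of the flanking cosine phasing
#' @param repeat_length nucleosome repeat length in bp
#' @param labile_fraction fraction of bound sites given crosslink excess
#' @param labile_excess excess crosslinked tags per bp over labile sites
#' @param qpcr_slope drop in log2 ChIP enrichment per SD of occupancy
#'   (>= 0; the anti-correlation sign is applied internally)
#' @param qpcr_noise SD of Gaussian noise on planted log2 enrichments
#' @param n_replicates qPCR replicates per site
#' @param unbound_bin_props target proportions of unbound sites in the
#'   four ChIP p-value bins (0.001-0.01, 0.01-0.1, 0.1-0.5, >0.5)
#' @param promoter_bp promoter length in bp
#' @param tag_length protected-fragment length in bp
#' @return a validated `sim_config` list
#' @export
sim_config <- function(n_chromosomes = 1L, chrom_length = 200000L,
                       n_genes = 120L, motif_length = 8L,
                       n_bound = 50L, n_unbound = 50L,
                       regime = c("local_ndr", "regional_depletion",
                                  "occluded_site", "flank_enriched",
                                  "broad_poor"),
                       mean_depth = 10, depletion_depth = 0.2,
                       depletion_width = 150L, phasing_amplitude = 0.3,
                       repeat_length = 165L, labile_fraction = 0.5,
                       labile_excess = 5, qpcr_slope = 1,
                       qpcr_noise = 0.25, n_replicates = 3L,
                       unbound_bin_props = c(0.25, 0.25, 0.25, 0.25),
                       promoter_bp = 600L, tag_length = 146L) {
  regime <- match.arg(regime)
  cfg <- list(n_chromosomes = as.integer(n_chromosomes),
              chrom_length = as.integer(chrom_length),
              n_genes = as.integer(n_genes),
              motif_length = as.integer(motif_length),
              n_bound = as.integer(n_bound),
              n_unbound = as.integer(n_unbound),
              regime = regime, mean_depth = mean_depth,
              depletion_depth = depletion_depth,
              depletion_width = as.integer(depletion_width),
              phasing_amplitude = phasing_amplitude,
              repeat_length = as.integer(repeat_length),
              labile_fraction = labile_fraction,
              labile_excess = labile_excess,
              qpcr_slope = qpcr_slope, qpcr_noise = qpcr_noise,
              n_replicates = as.integer(n_replicates),
              unbound_bin_props = unbound_bin_props / sum(unbound_bin_props),
              promoter_bp = as.integer(promoter_bp),
              tag_length = as.integer(tag_length))
  with(cfg, {
    if (n_chromosomes < 1L || chrom_length < 1L || n_genes < 0L ||
        n_bound < 0L || n_unbound < 0L || mean_depth <= 0)
      stop("counts must be non-negative and lengths/depth positive")
    if (depletion_depth < 0 || depletion_depth > 1)
      stop("depletion_depth must be in [0,1]")
    if (labile_fraction < 0 || labile_fraction > 1)
      stop("labile_fraction must be in [0,1]")
    if (qpcr_slope < 0)
      stop("qpcr_slope must be >= 0 (the anti-correlation sign is internal)")
    if (n_genes > 0L && chrom_length %/% n_genes < promoter_bp + motif_length)
      stop("chromosomes too short for ", n_genes,
           " non-overlapping promoters")
  })
  structure(cfg, class = "sim_config")
}

#' Generate a random genome with non-overlapping promoters
#'
#' Sequence is i.i.d. uniform over ACGT. Each chromosome is divided
#' into `n_genes` equal slots and one plus-strand gene start is placed
#' uniformly in each slot, far enough in that its 600-bp promoter fits
#' inside the slot - so promoters never overlap.
#'
#' @param cfg a [sim_config()]
#' @param seed RNG seed
#' @return list with `genome` (a [genome_seq()]) and `gene_starts`
#'   (data.frame `chrom`, `start`, `strand`)
#' @export
generate_genome <- function(cfg, seed) {
  with_seed(seed, {
    seqs <- vapply(seq_len(cfg$n_chromosomes), function(i)
      paste(sample(c("A", "C", "G", "T"), cfg$chrom_length,
                   replace = TRUE), collapse = ""), character(1))
    names(seqs) <- paste0("chr", seq_len(cfg$n_chromosomes))
    starts <- NULL
    if (cfg$n_genes > 0L) {
      slot <- cfg$chrom_length %/% cfg$n_genes
      room <- slot - cfg$promoter_bp
      if (room < 1L) stop("promoter geometry infeasible")
      for (ch in names(seqs)) {
        s0 <- (seq_len(cfg$n_genes) - 1L) * slot
        gs <- s0 + cfg$promoter_bp +
          as.integer(floor(stats::runif(cfg$n_genes) * room))
        starts <- rbind(starts, data.frame(chrom = ch, start = gs,
                                           strand = "+"))
      }
    } else {
      starts <- data.frame(chrom = character(), start = integer(),
                           strand = character())
    }
    list(genome = genome_seq(seqs), gene_starts = starts)
  })
}

#' Plant motif sites in promoters
#'
#' Writes the PWM consensus into `n_bound + n_unbound` distinct
#' promoters at a random offset and strand (the reverse complement is
#' written for minus-strand sites). Bound sites draw ChIP p-values
#' uniformly below 1e-3; unbound sites draw a p-value bin from
#' `unbound_bin_props` and then uniformly within the bin.
#'
#' @param sim_genome result of [generate_genome()]
#' @param pwm a [pwm()]
#' @param cfg a [sim_config()]
#' @param seed RNG seed
#' @return list with `genome` (sequences modified in place) and `sites`
#'   (data.frame `tf, chrom, start, end, strand, chip_p, bound`)
#' @export
plant_sites <- function(sim_genome, pwm, cfg, seed) {
  proms <- promoter_intervals(sim_genome$genome, sim_genome$gene_starts,
                              cfg$promoter_bp)
  n_sites <- cfg$n_bound + cfg$n_unbound
  if (n_sites > nrow(proms))
    stop("more sites (", n_sites, ") than promoters (", nrow(proms), ")")
  consensus <- pwm_consensus(pwm)
  m <- nchar(consensus)
  if (m > cfg$promoter_bp) stop("motif longer than promoter")
  with_seed(seed, {
    pick <- sample.int(nrow(proms), n_sites)
    # keep the motif away from promoter edges where there is room
    margin <- pmin(100L, (proms$end[pick] - proms$start[pick] - m) %/% 2L)
    lo <- proms$start[pick] + margin
    hi <- proms$end[pick] - m - margin
    start <- lo + as.integer(floor(stats::runif(n_sites) * (hi - lo + 1L)))
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    bound <- rep(c(TRUE, FALSE), c(cfg$n_bound, cfg$n_unbound))
    chip_p <- numeric(n_sites)
    chip_p[bound] <- stats::runif(cfg$n_bound, 1e-6, 1e-3)
    if (cfg$n_unbound > 0L) {
      edges <- c(1e-3, 1e-2, 1e-1, 0.5, 1)
      bin <- sample.int(4L, cfg$n_unbound, replace = TRUE,
                        prob = cfg$unbound_bin_props)
      chip_p[!bound] <- stats::runif(cfg$n_unbound, edges[bin],
                                     edges[bin + 1L])
    }
    seqs <- unclass(sim_genome$genome)
    for (i in seq_len(n_sites)) {
      word <- if (strand[i] == "+") consensus else revcomp(consensus)
      ch <- proms$chrom[pick[i]]
      substr(seqs[[ch]], start[i] + 1L, start[i] + m) <- word
    }
    sites <- data.frame(tf = attr(pwm, "tf_name"),
                        chrom = proms$chrom[pick],
                        start = start, end = start + m,
                        strand = strand, chip_p = chip_p, bound = bound)
    list(genome = genome_seq(seqs), sites = sites)
  })
}

# multiplicative modulation profiles around a site center ------------------

dip_factor <- function(d, depth, width) {
  hw <- width / 2
  ifelse(abs(d) <= hw,
         depth + (1 - depth) * (abs(d) / hw)^2,
         1)
}

phasing_factor <- function(d, amplitude, repeat_length, width) {
  hw <- width / 2
  x <- abs(d) - hw
  ifelse(x > 0,
         1 + amplitude * cos(2 * pi * x / repeat_length) *
           exp(-x / (3 * repeat_length)),
         1)
}

broad_factor <- function(d, residual, sigma = 300) {
  1 - (1 - residual) * exp(-d^2 / (2 * sigma^2))
}

apply_site_modulation <- function(rate, center, span, f) {
  n <- length(rate)
  lo <- max(0L, center - span)
  hi <- min(n - 1L, center + span)
  idx <- (lo + 1L):(hi + 1L)
  d <- (lo:hi) - center
  rate[idx] <- rate[idx] * f(d)
  rate
}

#' Simulate the in vivo, in vitro and crosslinked tag maps
#'
#' Builds per-bp Poisson tag-count tracks around a shared mean depth.
#' The in vivo track carries a narrow multiplicative dip plus decaying
#' cosine phasing at every bound site. The in vitro track carries the
#' regime-dependent intrinsic structure (see [sim_config()]). The
#' crosslinked track is the in vivo track plus independent Poisson
#' excess (`labile_excess` per bp) over the 146-bp span of each labile
#' bound site, so its total tag count never falls below the in vivo
#' total.
#'
#' @param genome a [genome_seq()]
#' @param sites planted site data.frame (needs `bound`)
#' @param cfg a [sim_config()]
#' @param seed RNG seed
#' @return list with `invivo`, `invitro`, `xlink` (`tag_map`s) and
#'   `labile` (logical per site row; FALSE for unbound sites)
#' @export
simulate_tag_maps <- function(genome, sites, cfg, seed) {
  lens <- chrom_lengths(genome)
  bound <- sites[sites$bound, , drop = FALSE]
  centers <- site_center(bound$start, bound$end)
  span_vivo <- as.integer(cfg$depletion_width / 2 + 3 * cfg$repeat_length)
  labile <- with_seed(derive_seed(seed, 1L), {
    flags <- rep(FALSE, nrow(sites))
    flags[sites$bound] <- stats::runif(nrow(bound)) < cfg$labile_fraction
    flags
  })

  vivo_rate <- lapply(names(lens), function(ch) rep(cfg$mean_depth, lens[[ch]]))
  names(vivo_rate) <- names(lens)
  vitro_rate <- vivo_rate
  for (i in seq_len(nrow(bound))) {
    ch <- bound$chrom[i]
    ce <- centers[i]
    vivo_rate[[ch]] <- apply_site_modulation(
      vivo_rate[[ch]], ce, span_vivo, function(d)
        dip_factor(d, cfg$depletion_depth, cfg$depletion_width) *
        phasing_factor(d, cfg$phasing_amplitude, cfg$repeat_length,
                       cfg$depletion_width))
    vitro_rate[[ch]] <- apply_site_modulation(
      vitro_rate[[ch]], ce, 900L,
      regime_modulation(cfg, derive_seed(seed, 100L + i)))
  }

  draw <- function(rate, k) {
    vals <- with_seed(derive_seed(seed, k), lapply(rate, function(r)
      as.numeric(stats::rpois(length(r), r))))
    tag_map(vals, tag_length = cfg$tag_length)
  }
  invivo <- draw(vivo_rate, 2L)
  invitro <- draw(vitro_rate, 3L)

  xvals <- lapply(invivo$values, identity)
  lab_sites <- sites[labile, , drop = FALSE]
  if (nrow(lab_sites) > 0L && cfg$labile_excess > 0) {
    xvals <- with_seed(derive_seed(seed, 4L), {
      for (i in seq_len(nrow(lab_sites))) {
        ch <- lab_sites$chrom[i]
        ce <- site_center(lab_sites$start[i], lab_sites$end[i])
        lo <- max(0L, ce - cfg$tag_length %/% 2L)
        hi <- min(lens[[ch]] - 1L, lo + cfg$tag_length - 1L)
        idx <- (lo + 1L):(hi + 1L)
        xvals[[ch]][idx] <- xvals[[ch]][idx] +
          stats::rpois(length(idx), cfg$labile_excess)
      }
      xvals
    })
  }
  xlink <- tag_map(xvals, tag_length = cfg$tag_length)
  list(invivo = invivo, invitro = invitro, xlink = xlink, labile = labile)
}

# per-site in vitro modulation for the configured regime; returns a
# function of signed distance d from the site center
regime_modulation <- function(cfg, site_seed) {
  depth <- cfg$depletion_depth
  width <- cfg$depletion_width
  switch(cfg$regime,
    local_ndr = function(d) dip_factor(d, depth, width),
    regional_depletion = function(d)
      broad_factor(d, 0.5) * dip_factor(d, depth, width),
    broad_poor = {
      # randomized site-local fine structure: independent lognormal
      # factors per 15-bp block within +/-75 bp, drawn once per site
      noise <- with_seed(site_seed, exp(stats::rnorm(11L, 0, 0.6)))
      function(d) {
        f <- broad_factor(d, 0.4)
        loc <- abs(d) <= 75
        blk <- ((d + 75) %/% 15L) + 1L
        f[loc] <- f[loc] * noise[blk[loc]]
        f
      }
    },
    occluded_site = function(d) {
      f <- broad_factor(d, 0.5)
      f[abs(d) <= 25] <- 1.2
      f
    },
    flank_enriched = function(d) {
      f <- dip_factor(d, depth, width)
      x <- abs(d) - width / 2
      out <- x > 0
      f[out] <- f[out] * (1 + 0.8 * exp(-x[out] / 150))
      f
    })
}

#' Sample explicit tag starts from an occupancy track
#'
#' Draws 5'-start positions with probability proportional to the track
#' value at the start, so that [coverage_from_tags()] on the result
#' reproduces the track's shape (shifted by half a tag length) at the
#' sampled depth. Used to exercise the tag-start ingestion path end to
#' end.
#'
#' @param map a `tag_map` used as the sampling rate
#' @param n_tags number of tags; default gives roughly the map's depth
#' @param seed RNG seed
#' @return data.frame with columns `chrom`, `start`
#' @export
sample_tag_starts <- function(map, n_tags = NULL, seed = 1L) {
  tot <- map_total(map)
  if (tot <= 0) stop("cannot sample from an all-zero track")
  if (is.null(n_tags)) n_tags <- max(1L, round(tot / map$tag_length))
  chrom_mass <- vapply(map$values, sum, numeric(1))
  with_seed(seed, {
    per_chrom <- stats::rmultinom(1L, n_tags, chrom_mass)[, 1L]
    out <- lapply(names(map$values), function(ch) {
      k <- per_chrom[[ch]]
      if (k == 0L) return(NULL)
      v <- map$values[[ch]]
      data.frame(chrom = ch,
                 start = sample.int(length(v), k, replace = TRUE,
                                    prob = v) - 1L)
    })
    do.call(rbind, out)
  })
}

#' Simulate a qPCR Ct table from site occupancies
#'
#' Each bound site gets a planted log2 enrichment
#' `-qpcr_slope * occupancy_sd + N(0, qpcr_noise)`: ChIP enrichment is
#' anti-correlated with nucleosome occupancy. The planted value is
#' converted to Ct rows with a fixed input Ct and two control sites at
#' enrichment 1 in every replicate, so [qpcr_enrichment()] recovers the
#' planted folds exactly.
#'
#' @param site_ids identifiers for the assayed sites
#' @param occupancy_sd site occupancies in SD units (standardized)
#' @param cfg a [sim_config()]
#' @param seed RNG seed
#' @param ct_input input-DNA Ct used for every row
#' @return list with `table` (Ct data.frame) and `planted_log2`
#'   (named numeric)
#' @export
simulate_qpcr <- function(site_ids, occupancy_sd, cfg, seed,
                          ct_input = 20) {
  stopifnot(length(site_ids) == length(occupancy_sd))
  if (cfg$qpcr_slope < 0) stop("qpcr_slope must be >= 0")
  planted <- with_seed(seed,
    -cfg$qpcr_slope * occupancy_sd +
      stats::rnorm(length(occupancy_sd), 0, cfg$qpcr_noise))
  names(planted) <- site_ids
  rows <- list()
  for (r in seq_len(cfg$n_replicates)) {
    rows[[length(rows) + 1L]] <- data.frame(
      site_id = c("control_1", "control_2", site_ids),
      replicate = r,
      ct_ip = c(ct_input, ct_input, ct_input - planted),
      ct_input = ct_input,
      is_control = c(TRUE, TRUE, rep(FALSE, length(site_ids))))
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  list(table = table, planted_log2 = planted)
}

#' Run the full synthetic-data generator
#'
#' Chains genome generation, site planting, tag-map simulation and qPCR
#' simulation under one seed and collects the ground truth needed by
#' recovery tests. The qPCR occupancies are the standardized
#' 150-bp-window in vivo occupancies at bound sites.
#'
#' @param cfg a [sim_config()]
#' @param seed master RNG seed
#' @param pwm optional [pwm()]; default is a near-deterministic PWM on a
#'   random consensus of `cfg$motif_length`
#' @return a `sim_dataset` list: `genome`, `gene_starts`, `pwm`,
#'   `sites`, `maps` (invivo/invitro/xlink), `qpcr`, `truth`
#' @export
simulate_dataset <- function(cfg = sim_config(), seed = 1L, pwm = NULL) {
  if (is.null(pwm))
    pwm <- with_seed(derive_seed(seed, 11L),
                     random_pwm(cfg$motif_length, info = 0.9))
  g <- generate_genome(cfg, derive_seed(seed, 12L))
  pl <- plant_sites(g, pwm, cfg, derive_seed(seed, 13L))
  maps <- simulate_tag_maps(pl$genome, pl$sites, cfg, derive_seed(seed, 14L))
  bound <- pl$sites[pl$sites$bound, , drop = FALSE]
  qpcr <- NULL
  occ_sd <- NULL
  if (nrow(bound) >= 2L) {
    occ <- mapply(function(ch, s, e)
      window_average(maps$invivo, ch, site_center(s, e), 150L),
      bound$chrom, bound$start, bound$end, USE.NAMES = FALSE)
    occ_sd <- as.numeric(scale(occ))
    ids <- sprintf("site_%03d", which(pl$sites$bound))
    qpcr <- simulate_qpcr(ids, occ_sd, cfg, derive_seed(seed, 15L))
  }
  truth <- list(cfg = unclass(cfg), seed = seed,
                regime = cfg$regime,
                bound = pl$sites$bound,
                chip_p = pl$sites$chip_p,
                labile = maps$labile,
                planted_log2 = if (is.null(qpcr)) NULL else qpcr$planted_log2,
                occupancy_sd = occ_sd)
  structure(list(genome = pl$genome, gene_starts = g$gene_starts,
                 pwm = pwm, sites = pl$sites, maps = maps, qpcr = qpcr,
                 truth = truth),
            class = "sim_dataset")
}

#' Random position weight matrix with a fixed information content
#'
#' Picks a random consensus and gives its base probability `info` at
#' every position, the rest split evenly - a near-deterministic PWM for
#' `info` close to 1.
#'
#' @param motif_length motif length (>= 4)
#' @param info consensus-base probability
#' @param tf_name TF name
#' @return a [pwm()]
#' @export
random_pwm <- function(motif_length = 8L, info = 0.9, tf_name = "TF_sim") {
  cons <- sample.int(4L, motif_length, replace = TRUE)
  m <- matrix((1 - info) / 3, nrow = motif_length, ncol = 4L)
  m[cbind(seq_len(motif_length), cons)] <- info
  pwm(m, tf_name = tf_name)
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset:", x$truth$regime, "regime,",
      sum(x$sites$bound), "bound /", sum(!x$sites$bound),
      "unbound sites,", sum(x$truth$labile), "labile\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Writes the genome FASTA, the three bedGraph tracks, a tag-starts TSV
#' sampled from the in vivo track, the sites TSV, the PWM TSV, the Ct
#' TSV and a ground-truth JSON into `dir`.
#'
#' @param sim a `sim_dataset`
#' @param dir output directory (created if needed)
#' @param seed seed for tag-start sampling
#' @return named character vector of written paths, invisibly
#' @export
write_simulation <- function(sim, dir, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_fasta(sim$genome, p("genome.fa"))
  write_bedgraph_track(sim$maps$invivo, p("invivo.bedgraph"), "invivo")
  write_bedgraph_track(sim$maps$invitro, p("invitro.bedgraph"), "invitro")
  write_bedgraph_track(sim$maps$xlink, p("xlink.bedgraph"), "xlink")
  starts <- sample_tag_starts(sim$maps$invivo, seed = seed)
  utils::write.table(starts, p("tag_starts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_sites_tsv(sim$sites, p("sites.tsv"))
  write_pwm_tsv(sim$pwm, p("pwm.tsv"))
  if (!is.null(sim$qpcr))
    utils::write.table(sim$qpcr$table, p("qpcr_ct.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  jsonlite::write_json(sim$truth, p("truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  files <- c(genome = p("genome.fa"), invivo = p("invivo.bedgraph"),
             invitro = p("invitro.bedgraph"), xlink = p("xlink.bedgraph"),
             tag_starts = p("tag_starts.tsv"), sites = p("sites.tsv"),
             pwm = p("pwm.tsv"), qpcr = p("qpcr_ct.tsv"),
             truth = p("truth.json"))
  invisible(files)
}
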