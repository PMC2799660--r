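uniform_pwm <- function(m = 6) pwm(matrix(0.25, m, 4), tf_name = "uni")

sharp_pwm <- function(word, info = 0.97) {
  b <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
  m <- matrix((1 - info) / 3, length(b), 4)
  m[cbind(seq_along(b), b)] <- info
  pwm(m, tf_name = word)
}

test_that("ka_landscape matches the product oracle on both strands", {
  land <- ka_landscape(uniform_pwm(), "ACGTACGTACGT")
  expect_true(all(abs(land$ka - 1) < 1e-12))

  set.seed(51)
  pw <- pwm(t(apply(matrix(stats::rexp(8 * 4), 8), 1, function(r) r / sum(r))),
            tf_name = "rnd")
  seqstr <- paste(sample(c("A", "C", "G", "T"), 30, replace = TRUE),
                  collapse = "")
  land2 <- ka_landscape(pw, seqstr, pseudocount = 0.01)
  sm <- (unclass(pw) + 0.01) / (1 + 0.04)
  oracle <- function(word) {
    b <- match(strsplit(word, "")[[1]], c("A", "C", "G", "T"))
    prod(sm[cbind(seq_along(b), b)] / 0.25)
  }
  for (o in 1:23) {
    word <- substr(seqstr, o, o + 7)
    expect_equal(unname(land2$ka["fwd", o]), oracle(word))
    expect_equal(unname(land2$ka["rev", o]), oracle(revcomp(word)))
  }

  # consensus site scores highest under a near-deterministic PWM
  pw2 <- sharp_pwm("ACGTTGCA")
  seq2 <- paste0("TTTTTTTT", "ACGTTGCA", "TTTTTTTT")
  land3 <- ka_landscape(pw2, seq2)
  expect_equal(unname(which.max(land3$ka["fwd", ])), 9L)
  expect_equal(max(land3$ka), max(land3$ka["fwd", ]))

  # windows containing N are skipped and counted
  landN <- ka_landscape(uniform_pwm(4), "ACGTNACGT")
  expect_equal(landN$n_skipped, 2L * 4L)
  expect_true(all(is.na(landN$ka[, 2:5])))
})

test_that("segment weights implement W^(-Q) with zero-tag weight 1", {
  set.seed(52)
  v <- stats::rpois(6000, 5)
  v[1:150] <- 0  # a zero-occupancy stretch
  m <- toy_map(v)
  w <- segment_weights(m, segment = 15, W = 4)
  loc <- colMeans(matrix(v, nrow = 15))
  expect_equal(w$sd_local, stats::sd(loc))
  expect_equal(w$chrom$chr1$local, loc)
  expect_equal(w$chrom$chr1$weight, 4 ^ (-loc / stats::sd(loc)))
  expect_equal(w$chrom$chr1$weight[1:10], rep(1, 10))  # zero tags

  # Q = 1 and Q = 2 give weights 1/4 and 1/16
  i1 <- which.min(abs(w$chrom$chr1$Q - 1))
  expect_equal(w$chrom$chr1$weight[i1], 4 ^ (-w$chrom$chr1$Q[i1]))
  expect_true(all(w$chrom$chr1$weight <= 1 + 1e-12))
  expect_error(segment_weights(toy_map(rep(2, 300))), "zero SD")

  # regional weights use the blurred occupancy
  wr <- segment_weights(m, segment = 15, regional_window = 600,
                        use_regional = TRUE)
  centers <- w$chrom$chr1$seg_start + 7L
  reg <- vapply(centers, function(ce) window_average(m, "chr1", ce, 600),
                numeric(1))
  expect_equal(wr$chrom$chr1$regional, reg)
  expect_equal(wr$chrom$chr1$weight, 4 ^ (-reg / stats::sd(loc)))
})

test_that("weighted_ka multiplies by the center segment's weight", {
  set.seed(53)
  v <- stats::rpois(3000, 5)
  m <- toy_map(v)
  w <- segment_weights(m, segment = 15)
  pw <- sharp_pwm("ACGTACGT")
  seqstr <- paste(sample(c("A", "C", "G", "T"), 120, replace = TRUE),
                  collapse = "")
  land <- ka_landscape(pw, seqstr)
  off <- 900L
  wl <- weighted_ka(land, w, "chr1", offset = off)
  centers <- off + (seq_len(ncol(land$ka)) - 1L) + 4L
  expect_equal(wl$ka, land$ka * rep(weight_at(w, "chr1", centers), each = 2))

  # weight 1 everywhere is the identity
  ones <- w
  ones$chrom$chr1$weight[] <- 1
  expect_equal(weighted_ka(land, ones, "chr1", off)$ka, land$ka)
})

test_that("p_bound_promoter closed forms and monotonicity hold", {
  land1 <- list(ka = matrix(1, 1, 1), motif_length = 4, tf_name = "t")
  expect_equal(p_bound_promoter(land1, 1), 0.5)
  land2 <- list(ka = matrix(c(1, 1), 1, 2), motif_length = 4, tf_name = "t")
  expect_equal(p_bound_promoter(land2, 1), 0.75)

  set.seed(54)
  ka <- matrix(stats::rexp(10), 2, 5)
  land5 <- list(ka = ka, motif_length = 4, tf_name = "t")
  brute <- 1 - prod(1 - (0.3 * ka) / (1 + 0.3 * ka))
  expect_equal(p_bound_promoter(land5, 0.3), brute)
  # monotone in c and in each Ka
  expect_gt(p_bound_promoter(land5, 0.6), p_bound_promoter(land5, 0.3))
  ka2 <- ka; ka2[1, 1] <- ka2[1, 1] * 2
  expect_gt(p_bound_promoter(list(ka = ka2, motif_length = 4, tf_name = "t"),
                             0.3),
            p_bound_promoter(land5, 0.3))
  # invariant to window order
  expect_equal(p_bound_promoter(list(ka = ka[, 5:1], motif_length = 4,
                                     tf_name = "t"), 0.3), brute)
})

test_that("evaluate_variants ranks the consensus promoter first and flat weights tie", {
  # consensus only in bound promoters, so the PWM alone separates them
  cfg <- small_cfg(n_bound = 10L, n_unbound = 0L)
  sim <- simulate_dataset(cfg, seed = 55)
  proms <- promoter_intervals(sim$genome, sim$gene_starts)
  proms$name <- sprintf("prom_%02d", seq_len(nrow(proms)))
  bound_proms <- vapply(which(sim$sites$bound), function(i)
    proms$name[proms$start <= sim$sites$start[i] &
                 sim$sites$end[i] <= proms$end][1L], character(1))

  flat <- toy_map(rep(5, cfg$chrom_length))
  ev <- evaluate_variants(proms, sim$genome, sim$pwm, flat,
                          bound_labels = bound_proms)
  expect_equal(ev$predictions$p_local15, ev$predictions$p_blurred)
  expect_gt(ev$auc[["unweighted"]], 0.9)

  # with a real occupancy track all three variants compute and report
  ev2 <- evaluate_variants(proms, sim$genome, sim$pwm, sim$maps$invivo,
                           bound_labels = bound_proms)
  expect_named(ev2$auc, c("unweighted", "local15", "blurred600"))
  expect_length(ev2$delta_vs_unweighted, 2L)
  expect_true(all(ev2$predictions$p_local15 <=
                    ev2$predictions$p_unweighted + 1e-12))
})
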