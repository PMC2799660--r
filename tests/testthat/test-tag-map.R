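test_that("coverage_from_tags spans 146 bp, truncates at ends, conserves mass", {
  g <- tiny_genome(c(chr1 = 1000L))
  m <- coverage_from_tags(data.frame(chrom = "chr1", start = 10L), g)
  expect_equal(sum(m$values$chr1), 146)
  expect_equal(m$values$chr1[11:156], rep(1, 146))
  expect_equal(m$values$chr1[c(10, 157)], c(0, 0))

  m2 <- coverage_from_tags(data.frame(chrom = "chr1", start = c(10L, 100L)), g)
  expect_equal(m2$values$chr1[101:156], rep(2, 56))

  expect_error(coverage_from_tags(data.frame(chrom = "chr1", start = -1L), g),
               "bounds")
  expect_error(coverage_from_tags(data.frame(chrom = "chr1", start = 1000L), g),
               "bounds")

  # oracle: brute-force interval painting on random tag sets
  set.seed(11)
  for (rep in 1:5) {
    starts <- sample(0:999, 200, replace = TRUE)
    mm <- coverage_from_tags(data.frame(chrom = "chr1", start = starts), g)
    ref <- numeric(1000)
    for (s in starts) {
      idx <- (s + 1):min(1000, s + 146)
      ref[idx] <- ref[idx] + 1
    }
    expect_equal(mm$values$chr1, ref)
    truncated <- sum(pmax(0, starts + 146 - 1000))
    expect_equal(sum(mm$values$chr1), 146 * 200 - truncated)
  }
})

test_that("normalize_mean1 gives exact mean 1, is idempotent, rejects zeros", {
  m <- toy_map(c(5, 5, 5, 5))
  expect_equal(normalize_mean1(m)$values$chr1, rep(1, 4))
  set.seed(2)
  r <- toy_map(stats::rexp(500))
  n1 <- normalize_mean1(r)
  expect_equal(map_mean(n1), 1, tolerance = 1e-12)
  expect_equal(normalize_mean1(n1)$values$chr1, n1$values$chr1)
  expect_error(normalize_mean1(toy_map(rep(0, 10))), "all-zero")
})

test_that("window_average matches a naive loop and handles edges", {
  expect_equal(window_average(toy_map(c(0, 0, 10, 0, 0)), "chr1", 2, 5), 2)
  expect_equal(window_average(toy_map(rep(7, 50)), "chr1", 25, 15), 7)
  set.seed(3)
  v <- stats::rexp(800)
  m <- toy_map(v)
  for (size in c(15, 40, 75, 150, 300, 600)) {
    centers <- sample(0:799, 20)
    got <- vapply(centers, function(ce) window_average(m, "chr1", ce, size),
                  numeric(1))
    want <- vapply(centers, function(ce) naive_window_mean(v, ce, size),
                   numeric(1))
    expect_equal(got, want)
  }
  # even-motif rule: one extra bp on the right
  expect_equal(window_average(m, "chr1", 100, 15, even_extend = TRUE),
               mean(v[(100 - 7):(100 + 8) + 1]))
  expect_error(window_average(m, "chr1", 5000, 15), "off chromosome")
})

test_that("blur is identity at w=1, linear, mean-preserving, delta->plateau", {
  set.seed(4)
  v <- stats::rexp(2000)
  m <- toy_map(v)
  expect_equal(blur(m, 1)$values$chr1, v)
  expect_equal(blur(toy_map(rep(3, 100)), 40)$values$chr1, rep(3, 100))

  delta <- toy_map(c(rep(0, 500), 1, rep(0, 500)))
  b <- blur(delta, 75)$values$chr1
  expect_equal(sum(b > 0), 75)
  expect_equal(unique(round(b[b > 0], 12)), round(1 / 75, 12))

  # linearity and commuting with scaling
  w <- 150
  a <- stats::rexp(2000)
  expect_equal(blur(toy_map(v + a), w)$values$chr1,
               blur(toy_map(v), w)$values$chr1 +
                 blur(toy_map(a), w)$values$chr1)
  expect_equal(blur(toy_map(3 * v), w)$values$chr1,
               3 * blur(toy_map(v), w)$values$chr1)
  expect_equal(map_mean(blur(m, 75)), map_mean(m), tolerance = 1e-3)

  # the two averaging paths agree for interior loci
  b600 <- blur(m, 600)$values$chr1
  for (ce in c(300, 700, 1100, 1699)) {
    expect_equal(b600[ce + 1], window_average(m, "chr1", ce, 600))
  }
})

test_that("extract_profile centers, reverses minus strand, symmetrizes", {
  v <- numeric(100)
  v[51] <- 1  # delta at bp 50 (0-based)
  m <- toy_map(v)
  p <- extract_profile(m, toy_sites(50), half_width = 10)
  expect_equal(p$value[p$offset == 0], 1)
  expect_equal(sum(p$value), 1)

  # minus-strand window is reversed before averaging
  v2 <- numeric(100)
  v2[54] <- 1  # +3 offset from the center at 50
  pm <- extract_profile(toy_map(v2), toy_sites(50, strand = "-"),
                        half_width = 10)
  expect_equal(pm$value[pm$offset == -3], 1)

  ps <- extract_profile(toy_map(v2), toy_sites(50), half_width = 10,
                        symmetrize = TRUE)
  expect_equal(ps$value, rev(ps$value))

  # per-offset mean across two sites equals the hand-built average
  set.seed(6)
  v3 <- stats::rexp(200)
  m3 <- toy_map(v3)
  p2 <- extract_profile(m3, toy_sites(c(60, 120)), half_width = 5)
  want <- (v3[(60 - 5):(60 + 5) + 1] + v3[(120 - 5):(120 + 5) + 1]) / 2
  expect_equal(p2$value, want)
  expect_equal(p2$n_sites, 2L)

  # clipped windows are dropped and counted
  p3 <- extract_profile(m3, toy_sites(c(2, 120)), half_width = 5)
  expect_equal(p3$n_sites, 1L)
  expect_equal(p3$n_dropped, 1L)
  expect_error(extract_profile(m3, toy_sites(2), half_width = 5), "usable")
})

test_that("scale_to_reference matches totals or flank means", {
  set.seed(7)
  v <- stats::rexp(1000)
  ref <- toy_map(v)
  m <- toy_map(2 * v)
  s <- scale_to_reference(m, ref, "genome_total")
  expect_equal(attr(s, "scale_factor"), 0.5)
  expect_equal(s$values$chr1, v)

  # flank mode: identical flanks, different site-proximal values
  base <- rep(2, 3000)
  a <- base; a[1400:1600] <- 10
  b <- base; b[1400:1600] <- 4
  sites <- toy_sites(1500)
  sf <- scale_to_reference(toy_map(a), toy_map(b), "flank", sites = sites)
  fm <- function(mm) mean(c(mm$values$chr1[(1500 - 600):(1500 - 100) + 1],
                            mm$values$chr1[(1500 + 100):(1500 + 600) + 1]))
  expect_equal(fm(sf), fm(toy_map(b)))
  expect_gt(sf$values$chr1[1501], fm(sf))   # proximal excess preserved
  # pure rescaling: ratios preserved
  expect_equal(sf$values$chr1 / a, rep(sf$values$chr1[1] / a[1], 3000))
  expect_error(scale_to_reference(toy_map(rep(0, 10)), toy_map(rep(1, 10)),
                                  "genome_total"), "zero reference")
})

test_that("difference_map is mean-zero and localizes planted excess", {
  set.seed(8)
  unx <- toy_map(stats::rpois(5000, 10))
  x <- unx
  span <- 1001:1146
  x$values$chr1[span] <- x$values$chr1[span] + 6
  d <- difference_map(x, unx)
  expect_equal(sum(d$values$chr1), 0, tolerance = 1e-9 * map_mean(unx))
  # expected on-span excess after genome-total scaling, analytically
  s <- map_total(x) / map_total(unx)
  expected_span <- mean(x$values$chr1[span] - s * unx$values$chr1[span])
  expect_equal(mean(d$values$chr1[span]), expected_span)
  expect_gt(mean(d$values$chr1[span]), 5)
  expect_lt(mean(d$values$chr1[-span]), 0)  # small negative elsewhere

  z <- difference_map(unx, unx)
  expect_equal(z$values$chr1, rep(0, 5000))
  other <- toy_map(stats::rpois(400, 10))
  expect_error(difference_map(x, other), "different genomes")
})
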