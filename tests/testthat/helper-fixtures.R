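# Small in-code fixtures shared across test files.

tiny_genome <- function(lens = c(chr1 = 60L)) {
  set.seed(42)
  genome_seq(vapply(lens, function(n)
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""),
    character(1)))
}

# a one-chromosome track with explicit values
toy_map <- function(v, name = "chr1", ...) {
  tag_map(stats::setNames(list(as.numeric(v)), name), ...)
}

toy_sites <- function(centers, chrom = "chr1", width = 5L, strand = NULL,
                      tf = "TFX", chip_p = NULL) {
  start <- as.integer(centers) - (width - 1L) %/% 2L
  df <- data.frame(tf = tf, chrom = chrom, start = start,
                   end = start + width,
                   strand = strand %||% rep("+", length(centers)))
  if (!is.null(chip_p)) df$chip_p <- chip_p
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force mean of map values in [center - floor(size/2), +size) clipped
naive_window_mean <- function(v, center, size, even_extend = FALSE) {
  lo <- center - size %/% 2
  hi <- lo + size - 1 + as.integer(even_extend)
  idx <- max(0, lo):min(length(v) - 1, hi)
  mean(v[idx + 1])
}

# exhaustive pairwise ROC AUC oracle (ties count one half)
pairwise_auc <- function(pos, neg, low_predicts_positive = TRUE) {
  tot <- 0
  for (p in pos) for (q in neg) {
    if (p == q) tot <- tot + 0.5
    else if (low_predicts_positive && p < q) tot <- tot + 1
    else if (!low_predicts_positive && p > q) tot <- tot + 1
  }
  tot / (length(pos) * length(neg))
}

# a compact simulation used where full default scale is not needed
small_cfg <- function(...) {
  args <- utils::modifyList(list(chrom_length = 60000L, n_genes = 40L,
                                 n_bound = 15L, n_unbound = 15L),
                            list(...))
  do.call(sim_config, args)
}
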