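#' ROC area under the curve (Mann-Whitney form)
#'
#' AUC is the probability that a random positive is ranked above a
#' random negative, with ties counted one half; it equals the normalized
#' Mann-Whitney U statistic. With `low_predicts_positive = TRUE`
#' (the convention for nucleosome depletion predicting binding),
#' AUC = P(score_pos < score_neg) + 0.5 * P(equal).
#'
#' @param pos_scores numeric scores for the positive class
#' @param neg_scores numeric scores for the negative class
#' @param low_predicts_positive does a low score predict the positive
#'   class?
#' @return a `roc_result`: list with `auc`, `n_pos`, `n_neg`,
#'   `orientation`, and `ci` (NULL until [bootstrap_auc()] fills it)
#' @export
roc_auc <- function(pos_scores, neg_scores, low_predicts_positive = TRUE) {
  n_pos <- length(pos_scores)
  n_neg <- length(neg_scores)
  if (n_pos == 0L || n_neg == 0L)
    stop("both classes must be non-empty")
  auc <- auc_stat(pos_scores, neg_scores, low_predicts_positive)
  structure(list(auc = auc, n_pos = n_pos, n_neg = n_neg,
                 orientation = if (low_predicts_positive) "low" else "high",
                 ci = NULL, window = NA_integer_),
            class = "roc_result")
}

auc_stat <- function(pos, neg, low_predicts_positive) {
  # U via midranks; ties contribute exactly 1/2. U is an exact multiple
  # of 0.5, so both orientations divide an exact numerator and agree
  # bit-for-bit with a pairwise concordance count.
  r <- rank(c(pos, neg))
  u_high <- sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2
  u <- if (low_predicts_positive) length(pos) * length(neg) - u_high
       else u_high
  u / (length(pos) * length(neg))
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d pos, %d neg, %s score predicts positive)\n",
              x$auc, x$n_pos, x$n_neg, x$orientation))
  if (!is.null(x$ci))
    cat(sprintf("  bootstrap 95%% CI [%.4f, %.4f] (percentile, B = %d)\n",
                x$ci[1L], x$ci[2L], attr(x$ci, "B")))
  invisible(x)
}

#' Bootstrap confidence interval for a ROC AUC
#'
#' Resamples both classes with replacement `B` times, recomputes the
#' AUC, and reports the percentile 95% interval. Deterministic under
#' `seed`.
#'
#' @inheritParams roc_auc
#' @param B number of bootstrap replicates (>= 100)
#' @param seed RNG seed
#' @param conf confidence level
#' @return a `roc_result` with the `ci` field set
#' @export
bootstrap_auc <- function(pos_scores, neg_scores, B = 1000L, seed = 1L,
                          low_predicts_positive = TRUE, conf = 0.95) {
  stopifnot(B >= 100L)
  res <- roc_auc(pos_scores, neg_scores, low_predicts_positive)
  reps <- with_seed(seed, vapply(seq_len(B), function(b) {
    auc_stat(sample(pos_scores, replace = TRUE),
             sample(neg_scores, replace = TRUE),
             low_predicts_positive)
  }, numeric(1)))
  a <- (1 - conf) / 2
  ci <- unname(stats::quantile(reps, c(a, 1 - a)))
  attr(ci, "B") <- as.integer(B)
  res$ci <- ci
  res
}

#' AUC across blurring window sizes and the resolution delta
#'
#' Scores bound sites and control loci by the mean occupancy in a
#' centered window of each size, computes one depletion-oriented AUC per
#' size (low occupancy predicts binding), and reports
#' `delta = AUC(largest) - AUC(smallest)`: the change in association
#' when high-resolution data are blurred to simulate low resolution.
#' The same control loci are reused at every size so the AUCs are
#' directly comparable.
#'
#' @param map a `tag_map`
#' @param bound_sites site data.frame (`chrom`, `start`, `end`)
#' @param control_loci data.frame (`chrom`, `center`)
#' @param sizes window sizes in bp
#' @param low_predicts_positive orientation passed to [roc_auc()]
#' @return a `delta_auc` row: list with `auc` (named by size), `delta`,
#'   `sizes`, `n_pos`, `n_neg`
#' @export
delta_auc <- function(map, bound_sites, control_loci,
                      sizes = c(15L, 40L, 75L, 150L, 300L, 600L),
                      low_predicts_positive = TRUE) {
  sizes <- sort(as.integer(sizes))
  centers <- data.frame(chrom = bound_sites$chrom,
                        center = site_center(bound_sites$start,
                                             bound_sites$end))
  motif_even <- (bound_sites$end - bound_sites$start) %% 2L == 0L
  aucs <- vapply(sizes, function(w) {
    pos <- mapply(function(ch, ce, ev)
      window_average(map, ch, ce, w, even_extend = ev),
      centers$chrom, centers$center, motif_even, USE.NAMES = FALSE)
    neg <- window_average_at(map, control_loci, w)
    auc_stat(pos, neg, low_predicts_positive)
  }, numeric(1))
  names(aucs) <- as.character(sizes)
  structure(list(auc = aucs,
                 delta = unname(aucs[length(aucs)] - aucs[1L]),
                 sizes = sizes,
                 n_pos = nrow(centers), n_neg = nrow(control_loci)),
            class = "delta_auc")
}

#' @export
print.delta_auc <- function(x, ...) {
  cat("delta_auc:", paste(sprintf("%d:%.3f", x$sizes, x$auc),
                          collapse = " "),
      sprintf(" delta(%d-%d) = %+.4f\n", x$sizes[length(x$sizes)],
              x$sizes[1L], x$delta))
  invisible(x)
}

#' Classify per-TF blurring deltas by standard deviation
#'
#' Computes the mean and SD of `|delta|` across TFs and assigns each TF
#' to `<1sd`, `1-2sd` or `>=2sd` according to how far its `|delta|` lies
#' above the cross-TF mean. If the SD is 0 all TFs are `<1sd`.
#'
#' @param deltas named numeric vector of per-TF deltas (signed)
#' @return data.frame with columns `tf`, `delta`, `abs_delta`, `z`,
#'   `sigma_class`
#' @export
classify_by_sigma <- function(deltas) {
  if (length(deltas) < 3L) stop("need at least 3 TFs")
  a <- abs(deltas)
  s <- stats::sd(a)
  z <- if (s == 0) rep(0, length(a)) else (a - mean(a)) / s
  cls <- cut(z, breaks = c(-Inf, 1, 2, Inf),
             labels = c("<1sd", "1-2sd", ">=2sd"), right = FALSE)
  data.frame(tf = names(deltas) %||% as.character(seq_along(deltas)),
             delta = unname(deltas), abs_delta = unname(a),
             z = unname(z), sigma_class = as.character(cls))
}
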