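#' qPCR fold enrichment via delta-delta-Ct
#'
#' Per replicate, each site's delta-Ct is `ct_ip - ct_input`; the
#' delta-delta-Ct subtracts the mean delta-Ct of the two control sites
#' in the same replicate. The reported fold enrichment is
#' `2^(-mean(delta-delta-Ct))` over a site's replicates. Control sites
#' come out at fold 1 by construction (each is compared against the
#' control mean, and the two controls average out only jointly, so a
#' "controls" summary row reporting their joint mean is exactly 1).
#'
#' @param table Ct data.frame with columns `site_id`, `replicate`,
#'   `ct_ip`, `ct_input`, `is_control` (two control site_ids per
#'   replicate)
#' @return data.frame with columns `site_id`, `fold`, `log2_fold`,
#'   `n_replicates`, `is_control`
#' @export
qpcr_enrichment <- function(table) {
  validate_ct_controls(table)
  table$dct <- table$ct_ip - table$ct_input
  ctl_mean <- tapply(table$dct[table$is_control],
                     table$replicate[table$is_control], mean)
  table$ddct <- table$dct - as.numeric(ctl_mean[as.character(table$replicate)])
  agg <- stats::aggregate(ddct ~ site_id, data = table, FUN = mean)
  nrep <- stats::aggregate(ddct ~ site_id, data = table, FUN = length)
  isctl <- tapply(table$is_control, table$site_id, any)
  out <- data.frame(site_id = agg$site_id,
                    fold = 2 ^ (-agg$ddct),
                    log2_fold = -agg$ddct,
                    n_replicates = nrep$ddct,
                    is_control = as.logical(isctl[as.character(agg$site_id)]))
  rownames(out) <- NULL
  out
}

#' Clamp enrichment/tag-count pairs for plotting and fitting
#'
#' Nominal fold enrichments below 1 are raised to 1 (sites not actually
#' bound in the assay), and tag counts above 600 are capped at 600
#' (a few sites sit in regions of exceptionally high occupancy).
#'
#' @param enrichments numeric fold enrichments
#' @param tag_counts numeric occupancy scores
#' @param enrichment_floor lower clamp for enrichment
#' @param tag_ceiling upper clamp for tag counts
#' @return data.frame with columns `enrichment`, `tag_count`
#' @export
clamp_for_fit <- function(enrichments, tag_counts, enrichment_floor = 1,
                          tag_ceiling = 600) {
  stopifnot(length(enrichments) == length(tag_counts))
  data.frame(enrichment = pmax(enrichments, enrichment_floor),
             tag_count = pmin(tag_counts, tag_ceiling))
}

#' Linear fit of log enrichment on nucleosome tag count
#'
#' Ordinary least squares of `log2(enrichment)` on tag count, with the
#' Pearson correlation and a one-sided test of the anti-correlation
#' expected between occupancy and binding (r < 0). Apply
#' [clamp_for_fit()] first when reproducing the plotted fits.
#'
#' @param enrichments fold enrichments (> 0)
#' @param tag_counts occupancy scores
#' @return list with `r`, `slope`, `intercept`, `p_one_sided`, `n`
#' @export
pearson_fit <- function(enrichments, tag_counts) {
  stopifnot(length(enrichments) == length(tag_counts))
  if (length(enrichments) < 3L) stop("need at least 3 points")
  y <- log2(enrichments)
  x <- tag_counts
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in enrichment or tag counts")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, alternative = "less")
  list(r = unname(ct$estimate),
       slope = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       p_one_sided = ct$p.value,
       n = length(x))
}
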