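#' Assign ChIP probe p-values to motif sites
#'
#' Each site receives the enrichment p-value of the probe containing the
#' site's center basepair; a site whose center lies in no probe is
#' dropped. Probes must be non-overlapping within a chromosome, which
#' makes the containing probe unique.
#'
#' @param sites motif-site data.frame (`tf, chrom, start, end, strand`)
#' @param probes probe data.frame (`chrom, start, end, chip_p`)
#' @return the annotated site data.frame, with attribute `n_dropped`
#' @export
assign_probe_pvalue <- function(sites, probes) {
  for (ch in unique(probes$chrom)) {
    sub <- probes[probes$chrom == ch, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
      stop("overlapping probes on ", ch)
  }
  centers <- site_center(sites$start, sites$end)
  p <- rep(NA_real_, nrow(sites))
  for (i in seq_len(nrow(sites))) {
    hit <- probes$chrom == sites$chrom[i] &
      probes$start <= centers[i] & centers[i] < probes$end
    if (any(hit)) p[i] <- probes$chip_p[which(hit)[1L]]
  }
  out <- sites[!is.na(p), , drop = FALSE]
  out$chip_p <- p[!is.na(p)]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(is.na(p))
  out
}

#' Classify sites as TF-bound by ChIP p-value
#'
#' A site is bound if and only if `chip_p < alpha` (strict inequality).
#'
#' @param sites annotated site data.frame (needs `chip_p`)
#' @param alpha binding threshold
#' @return `sites` with an added logical column `bound`
#' @export
classify_bound <- function(sites, alpha = 1e-3) {
  if (!"chip_p" %in% names(sites)) stop("sites lack an assigned chip_p")
  sites$bound <- !is.na(sites$chip_p) & sites$chip_p < alpha
  sites
}

#' Bin unbound sites by ChIP p-value
#'
#' Assigns each unbound site to one of four right-closed p-value bins:
#' (0.001, 0.01], (0.01, 0.1], (0.1, 0.5], (0.5, 1]. Bound sites
#' (p < 0.001) get bin `NA`.
#'
#' @param sites classified site data.frame (needs `chip_p`, `bound`)
#' @return `sites` with an added integer column `pbin` (1-4, NA for
#'   bound sites)
#' @export
bin_by_pvalue <- function(sites) {
  if (!"bound" %in% names(sites)) sites <- classify_bound(sites)
  edges <- c(1e-3, 1e-2, 1e-1, 0.5, 1)
  # include.lowest: p = 0.001 is unbound (bound is strict <) and belongs
  # to the first bin, keeping bound + bins a complete partition
  bin <- as.integer(cut(sites$chip_p, breaks = edges, right = TRUE,
                        include.lowest = TRUE))
  bin[sites$bound] <- NA_integer_
  sites$pbin <- bin
  sites
}

#' TFs with enough bound sites for analysis
#'
#' @param sites classified site data.frame
#' @param min_bound minimum number of bound sites
#' @return character vector of eligible TF names (sorted)
#' @export
eligible_tfs <- function(sites, min_bound = 50L) {
  if (!"bound" %in% names(sites)) sites <- classify_bound(sites)
  counts <- table(sites$tf[sites$bound])
  sort(names(counts)[counts >= min_bound])
}

#' Random control loci from promoters
#'
#' Samples `n` basepairs uniformly from the union of promoter intervals
#' (600 bp 5' of each gene start by default), with replacement, to serve
#' as the unbound comparison set for ROC analyses.
#'
#' @param genome a [genome_seq()]
#' @param gene_starts data.frame with columns `chrom`, `start` (0-based
#'   transcription start), `strand`
#' @param n number of loci
#' @param seed RNG seed
#' @param promoter_bp promoter length upstream of the gene start
#' @return data.frame with columns `chrom`, `center`
#' @export
random_promoter_sites <- function(genome, gene_starts, n, seed,
                                  promoter_bp = 600L) {
  stopifnot(n >= 1L)
  proms <- promoter_intervals(genome, gene_starts, promoter_bp)
  if (nrow(proms) == 0L) stop("empty promoter set")
  widths <- proms$end - proms$start
  draw <- with_seed(seed, {
    idx <- sample.int(nrow(proms), n, replace = TRUE,
                      prob = widths / sum(widths))
    list(idx = idx, off = floor(stats::runif(n) * widths[idx]))
  })
  data.frame(chrom = proms$chrom[draw$idx],
             center = proms$start[draw$idx] + as.integer(draw$off))
}

#' Promoter intervals upstream of gene starts
#'
#' Promoters are the `promoter_bp` basepairs 5' of each gene start,
#' on the gene's strand, clipped at chromosome ends.
#'
#' @inheritParams random_promoter_sites
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`
#'   (0-based half-open)
#' @export
promoter_intervals <- function(genome, gene_starts, promoter_bp = 600L) {
  if (is.null(gene_starts) || nrow(gene_starts) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character()))
  lens <- chrom_lengths(genome)
  strand <- if ("strand" %in% names(gene_starts)) gene_starts$strand else
    rep("+", nrow(gene_starts))
  s <- ifelse(strand == "+", gene_starts$start - promoter_bp,
              gene_starts$start + 1L)
  e <- ifelse(strand == "+", gene_starts$start,
              gene_starts$start + 1L + promoter_bp)
  s <- pmax(0L, as.integer(s))
  e <- pmin(as.integer(lens[gene_starts$chrom]), as.integer(e))
  keep <- e > s
  data.frame(chrom = gene_starts$chrom[keep], start = s[keep],
             end = e[keep], strand = strand[keep])
}
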