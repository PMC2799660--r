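#' Read a bedGraph coverage track
#'
#' Intervals are 0-based half-open, must lie within their chromosome and
#' must not overlap; uncovered basepairs get value 0. Track definition
#' lines (`track ...`) and comments are skipped.
#'
#' @param path bedGraph file
#' @param genome a [genome_seq()] giving chromosome names and lengths
#' @param tag_length stored on the resulting track
#' @return a [tag_map()]
#' @export
read_bedgraph_track <- function(path, genome, tag_length = 146L) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|#|browser)", lines) & nzchar(trimws(lines))]
  lens <- chrom_lengths(genome)
  vals <- lapply(lens, numeric)
  if (length(lines)) {
    parts <- strsplit(lines, "[ \t]+")
    nf <- lengths(parts)
    if (any(nf < 4L))
      stop("malformed bedGraph line ", which(nf < 4L)[1L], " in ", path)
    df <- data.frame(
      chrom = vapply(parts, `[`, "", 1L),
      start = as.integer(vapply(parts, `[`, "", 2L)),
      end   = as.integer(vapply(parts, `[`, "", 3L)),
      value = as.numeric(vapply(parts, `[`, "", 4L)))
    if (anyNA(df$start) || anyNA(df$end) || anyNA(df$value))
      stop("non-numeric coordinates or value in ", path)
    if (any(df$end <= df$start))
      stop("bedGraph interval with end <= start in ", path)
    unknown <- setdiff(unique(df$chrom), names(lens))
    if (length(unknown)) stop("unknown chromosome in bedGraph: ", unknown[1L])
    for (ch in unique(df$chrom)) {
      sub <- df[df$chrom == ch, , drop = FALSE]
      if (any(sub$start < 0) || any(sub$end > lens[[ch]]))
        stop("bedGraph interval beyond end of ", ch)
      sub <- sub[order(sub$start), , drop = FALSE]
      if (nrow(sub) > 1L && any(sub$start[-1L] < sub$end[-nrow(sub)]))
        stop("overlapping bedGraph intervals on ", ch)
      v <- vals[[ch]]
      for (i in seq_len(nrow(sub)))
        v[(sub$start[i] + 1L):sub$end[i]] <- sub$value[i]
      vals[[ch]] <- v
    }
  }
  tag_map(vals, tag_length = tag_length)
}

#' Write a track as bedGraph
#'
#' Runs of equal value are merged into single intervals; zero runs are
#' omitted. Reading the file back with [read_bedgraph_track()]
#' reproduces the per-bp values.
#'
#' @param map a `tag_map` with finite values
#' @param path output path
#' @param name track name for the header line
#' @return `path`, invisibly
#' @export
write_bedgraph_track <- function(map, path, name = "occupancy") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
  for (ch in names(map$values)) {
    v <- map$values[[ch]]
    if (!length(v)) next
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", ch, starts[keep], ends[keep],
                       format(r$values[keep], digits = 15,
                              scientific = FALSE, trim = TRUE)), con)
  }
  invisible(path)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop(what, " file ", path, " is missing column(s): ",
         paste(missing, collapse = ", "))
  df
}

#' Read a motif-site table
#'
#' Tab-separated with header `tf, chrom, start, end, strand, chip_p`
#' (0-based half-open coordinates; `chip_p` in (0, 1]; `chip_p` may be
#' NA for sites not yet annotated).
#'
#' @param path sites TSV
#' @return data.frame of motif sites
#' @export
read_sites_tsv <- function(path) {
  df <- read_tsv_checked(path, c("tf", "chrom", "start", "end", "strand",
                                 "chip_p"), "sites")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("site with end <= start in ", path)
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-' in ", path)
  p <- df$chip_p[!is.na(df$chip_p)]
  if (any(p <= 0 | p > 1)) stop("chip_p outside (0,1] in ", path)
  df
}

#' Write a motif-site table
#' @param sites site data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_sites_tsv <- function(sites, path) {
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a position weight matrix
#'
#' Tab-separated with header `pos, A, C, G, T`; one row per motif
#' position, base probabilities summing to 1 per row, at least 4
#' positions.
#'
#' @param path PWM TSV
#' @param tf_name name stored on the matrix (defaults to file stem)
#' @return a numeric matrix of class `pwm` (rows = positions, columns
#'   A, C, G, T) with attribute `tf_name`
#' @export
read_pwm_tsv <- function(path, tf_name = NULL) {
  df <- read_tsv_checked(path, c("pos", "A", "C", "G", "T"), "PWM")
  m <- as.matrix(df[order(df$pos), c("A", "C", "G", "T")])
  pwm(m, tf_name = tf_name %||% sub("\\.[^.]*$", "", basename(path)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Construct a PWM object
#'
#' @param m numeric matrix, one row per motif position, columns A,C,G,T
#' @param tf_name TF name
#' @return a `pwm`
#' @export
pwm <- function(m, tf_name = "TF") {
  m <- as.matrix(m)
  colnames(m) <- c("A", "C", "G", "T")
  if (nrow(m) < 4L) stop("PWM must have at least 4 positions")
  if (any(m < 0)) stop("PWM probabilities must be non-negative")
  if (any(abs(rowSums(m) - 1) > 1e-9))
    stop("PWM rows must sum to 1")
  rownames(m) <- NULL
  structure(m, class = c("pwm", "matrix", "array"), tf_name = tf_name)
}

#' @export
print.pwm <- function(x, ...) {
  cat("pwm:", attr(x, "tf_name"), "-", nrow(x), "positions, consensus",
      pwm_consensus(x), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Consensus sequence of a PWM (ties broken alphabetically)
#' @param pwm a `pwm`
#' @return character scalar
#' @export
pwm_consensus <- function(pwm) {
  paste(colnames(pwm)[apply(pwm, 1L, which.max)], collapse = "")
}

#' Write a PWM as TSV
#' @param pwm a `pwm`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_pwm_tsv <- function(pwm, path) {
  df <- data.frame(pos = seq_len(nrow(pwm)) - 1L, unclass(pwm)[, , drop = FALSE])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a qPCR Ct table
#'
#' Tab-separated with header
#' `site_id, replicate, ct_ip, ct_input, is_control`. Each replicate
#' must contain exactly two control rows (the two reference sites used
#' for the delta-delta-Ct comparison).
#'
#' @param path Ct TSV
#' @return data.frame
#' @export
read_ct_table <- function(path) {
  df <- read_tsv_checked(path, c("site_id", "replicate", "ct_ip",
                                 "ct_input", "is_control"), "Ct")
  df$ct_ip <- as.numeric(df$ct_ip)
  df$ct_input <- as.numeric(df$ct_input)
  df$is_control <- as.logical(df$is_control)
  if (any(!is.finite(df$ct_ip)) || any(!is.finite(df$ct_input)))
    stop("non-finite Ct value in ", path)
  validate_ct_controls(df)
  df
}

validate_ct_controls <- function(df) {
  for (rep in unique(df$replicate)) {
    nctl <- length(unique(df$site_id[df$replicate == rep & df$is_control]))
    if (nctl != 2L)
      stop("replicate ", rep, " has ", nctl,
           " control site(s); exactly 2 required")
  }
  invisible(df)
}

#' Read a tag 5'-start table
#'
#' Tab-separated with header `chrom, start`: the 0-based leftmost bp of
#' each 146-bp protected fragment.
#'
#' @param path tag-starts TSV
#' @return data.frame with columns `chrom`, `start`
#' @export
read_tag_starts <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start"), "tag-starts")
  df$start <- as.integer(df$start)
  if (anyNA(df$start) || any(df$start < 0))
    stop("invalid tag start in ", path)
  df
}

#' Read a ChIP probe table
#'
#' Tab-separated with header `chrom, start, end, chip_p` (0-based
#' half-open probe coordinates).
#'
#' @param path probes TSV
#' @return data.frame
#' @export
read_probes_tsv <- function(path) {
  df <- read_tsv_checked(path, c("chrom", "start", "end", "chip_p"),
                         "probes")
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  if (any(df$end <= df$start)) stop("probe with end <= start in ", path)
  df
}

#' Write an occupancy profile as TSV
#' @param profile an `occupancy_profile`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(
    data.frame(offset = profile$offset, value = profile$value,
               n_sites = profile$n_sites),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
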