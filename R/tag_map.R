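#' Per-basepair nucleosome occupancy track
#'
#' A `tag_map` stores one non-negative (or, for difference maps, signed)
#' numeric value per basepair per chromosome. Occupancy at a basepair is
#' the number of 146-bp nuclease-protection tags spanning it, or any
#' rescaled version of that count.
#'
#' @param values named list of numeric vectors, one per chromosome
#' @param tag_length nominal protected-fragment length in bp
#' @param normalization one of `"raw"`, `"mean1"`, `"scaled_to_ref"`,
#'   `"difference"`
#' @return an object of class `tag_map`
#' @export
tag_map <- function(values, tag_length = 146L,
                    normalization = c("raw", "mean1", "scaled_to_ref",
                                      "difference")) {
  normalization <- match.arg(normalization)
  if (is.null(names(values)) || anyDuplicated(names(values)))
    stop("chromosome values must be uniquely named")
  values <- lapply(values, as.numeric)
  ok <- vapply(values, function(v) all(is.finite(v)), logical(1))
  if (!all(ok))
    stop("non-finite occupancy values on chromosome ", names(values)[!ok][1L])
  if (normalization != "difference" &&
      any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("negative occupancy in a non-difference track")
  structure(list(values = values,
                 tag_length = as.integer(tag_length),
                 normalization = normalization),
            class = "tag_map")
}

#' @export
print.tag_map <- function(x, ...) {
  n <- sum(vapply(x$values, length, numeric(1)))
  m <- map_mean(x)
  cat(sprintf("tag_map: %d chromosome(s), %s bp, mean %.4g [%s]\n",
              length(x$values), format(n, big.mark = ","), m,
              x$normalization))
  invisible(x)
}

map_total <- function(map) sum(vapply(map$values, sum, numeric(1)))

map_length <- function(map) sum(vapply(map$values, length, numeric(1)))

#' Genome-wide mean of a track
#' @param map a `tag_map`
#' @return numeric scalar
#' @export
map_mean <- function(map) map_total(map) / map_length(map)

check_same_genome <- function(a, b) {
  if (!identical(names(a$values), names(b$values)) ||
      !identical(lapply(a$values, length), lapply(b$values, length)))
    stop("tracks are defined on different genomes")
}

#' Build a coverage track from tag 5' starts
#'
#' Each tag is a protected fragment with a sequenced 5' end and an
#' inferred 3' end `tag_length` bp away; it adds 1 to the occupancy of
#' every basepair in `[start, start + tag_length)`. Tags running off the
#' chromosome end contribute only their in-bounds basepairs. Any strand
#' information in the input is ignored: starts are the leftmost bp of the
#' protected interval.
#'
#' @param tag_starts data.frame with columns `chrom`, `start` (0-based)
#' @param genome a [genome_seq()] defining chromosome lengths
#' @param tag_length protected-fragment length in bp
#' @return a raw [tag_map()]
#' @export
coverage_from_tags <- function(tag_starts, genome, tag_length = 146L) {
  stopifnot(is.data.frame(tag_starts),
            all(c("chrom", "start") %in% names(tag_starts)))
  lens <- chrom_lengths(genome)
  unknown <- setdiff(unique(tag_starts$chrom), names(lens))
  if (length(unknown)) stop("unknown chromosome in tag starts: ", unknown[1L])
  vals <- lapply(names(lens), function(ch) {
    n <- lens[[ch]]
    s <- tag_starts$start[tag_starts$chrom == ch]
    if (any(s < 0 | s >= n))
      stop("tag start out of bounds on ", ch)
    # difference-array trick: +1 at start, -1 past the (clipped) end
    d <- numeric(n + 1L)
    if (length(s)) {
      t1 <- tabulate(s + 1L, nbins = n)
      e <- pmin(s + tag_length, n)
      t2 <- tabulate(e + 1L, nbins = n + 1L)
      d[seq_len(n)] <- t1
      d <- d - t2
    }
    cumsum(d)[seq_len(n)]
  })
  names(vals) <- names(lens)
  tag_map(vals, tag_length = tag_length, normalization = "raw")
}

#' Normalize a track to genome-wide mean 1
#'
#' Rescales by a single scalar so that the mean over all basepairs is
#' exactly 1; the shape of the track is unchanged.
#'
#' @param map a `tag_map`
#' @return a `tag_map` with `normalization = "mean1"`
#' @export
normalize_mean1 <- function(map) {
  m <- map_mean(map)
  if (m <= 0) stop("cannot normalize an all-zero track")
  out <- map
  out$values <- lapply(map$values, function(v) v / m)
  out$normalization <- "mean1"
  out
}

window_bounds <- function(center, size, n, even_extend = FALSE) {
  lo <- center - size %/% 2L
  hi <- lo + size - 1L + as.integer(even_extend)
  c(max(0L, lo), min(n - 1L, hi), lo, hi)
}

#' Mean occupancy in a window centered on a locus
#'
#' The window starts at `center - floor(size/2)` and spans `size` bp
#' (one extra bp on the right when `even_extend = TRUE`, the convention
#' for motifs of even length whose center falls between basepairs).
#' Basepairs beyond the chromosome ends are excluded from the mean.
#'
#' @param map a `tag_map`
#' @param chrom chromosome name
#' @param center 0-based center basepair
#' @param size window size in bp
#' @param even_extend extend the window 1 bp rightward
#' @return numeric scalar
#' @export
window_average <- function(map, chrom, center, size, even_extend = FALSE) {
  v <- map$values[[chrom]]
  if (is.null(v)) stop("unknown chromosome: ", chrom)
  b <- window_bounds(as.integer(center), as.integer(size), length(v),
                     even_extend)
  if (b[4L] < 0L || b[3L] >= length(v))
    stop("window fully off chromosome ", chrom)
  mean(v[(b[1L] + 1L):(b[2L] + 1L)])
}

#' Vectorized window averages at many loci
#'
#' @inheritParams window_average
#' @param loci data.frame with columns `chrom`, `center`
#' @return numeric vector, one value per locus
#' @export
window_average_at <- function(map, loci, size, even_extend = FALSE) {
  mapply(function(ch, ce) window_average(map, ch, ce, size, even_extend),
         loci$chrom, loci$center, USE.NAMES = FALSE)
}

blur_vec <- function(v, w) {
  n <- length(v)
  if (w <= 1L || n == 0L) return(v)
  h1 <- w %/% 2L
  h2 <- w - 1L - h1
  cs <- c(0, cumsum(v))
  i <- seq_len(n)
  lo <- pmax(1L, i - h1)
  hi <- pmin(n, i + h2)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Blur a track by a centered sliding mean
#'
#' Replaces each basepair value with the mean over a centered window,
#' simulating lower-resolution occupancy data. Windows are shrunk at
#' chromosome ends (partial windows, never NA), so the genome-wide mean
#' is preserved up to edge effects that vanish for windows much shorter
#' than the chromosome. `blur` is linear and commutes with scalar
#' rescaling; `window_bp = 1` is the identity.
#'
#' @param map a `tag_map`
#' @param window_bp window size in bp (>= 1)
#' @return a blurred `tag_map`
#' @export
blur <- function(map, window_bp) {
  stopifnot(window_bp >= 1)
  out <- map
  out$values <- lapply(map$values, blur_vec, w = as.integer(window_bp))
  out
}

#' Center basepair of a 0-based half-open interval
#'
#' For even-length intervals the basepair left of the midpoint is used;
#' window-averaging compensates with its extend-1-bp-rightward rule.
#'
#' @param start,end interval coordinates (0-based half-open)
#' @return integer center positions
#' @export
site_center <- function(start, end) {
  as.integer(start) + (as.integer(end) - as.integer(start) - 1L) %/% 2L
}

#' Average occupancy profile around a set of sites
#'
#' Extracts the `2 * half_width + 1` bp of occupancy centered on each
#' site, reverses minus-strand windows so positive offsets always mean
#' "downstream of the motif", and averages across sites. Sites whose
#' window is clipped by a chromosome end are dropped (their count is
#' reported in the result). With `symmetrize = TRUE` the profile is
#' averaged with its mirror image.
#'
#' @param map a `tag_map`
#' @param sites data.frame with columns `chrom`, `start`, `end` and
#'   optionally `strand` (`+`/`-`; missing means `+`)
#' @param half_width half-width of the window in bp
#' @param symmetrize average the profile with its mirror
#' @param label source label stored on the result
#' @return an `occupancy_profile`: list with `offset` (-H..H), `value`,
#'   `n_sites`, `n_dropped`, `symmetrized`, `label`
#' @export
extract_profile <- function(map, sites, half_width = 600L,
                            symmetrize = FALSE, label = "track") {
  stopifnot(nrow(sites) >= 1L)
  H <- as.integer(half_width)
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  acc <- numeric(2L * H + 1L)
  used <- 0L
  for (i in seq_len(nrow(sites))) {
    v <- map$values[[sites$chrom[i]]]
    if (is.null(v)) stop("unknown chromosome: ", sites$chrom[i])
    ce <- site_center(sites$start[i], sites$end[i])
    lo <- ce - H
    hi <- ce + H
    if (lo < 0L || hi >= length(v)) next
    win <- v[(lo + 1L):(hi + 1L)]
    if (strand[i] == "-") win <- rev(win)
    acc <- acc + win
    used <- used + 1L
  }
  if (used == 0L) stop("no usable sites: every window was clipped")
  prof <- acc / used
  if (symmetrize) prof <- (prof + rev(prof)) / 2
  structure(list(offset = (-H):H, value = prof, n_sites = used,
                 n_dropped = nrow(sites) - used,
                 symmetrized = symmetrize, label = label),
            class = "occupancy_profile")
}

#' @export
print.occupancy_profile <- function(x, ...) {
  cat(sprintf(
    "occupancy_profile [%s]: %d bp window, %d site(s), %d dropped%s\n",
    x$label, length(x$value), x$n_sites, x$n_dropped,
    if (x$symmetrized) ", symmetrized" else ""))
  invisible(x)
}

#' Scale a track onto a reference track
#'
#' Multiplies `map` by one scalar so that either its genome-wide total
#' matches the reference (`mode = "genome_total"`) or its mean occupancy
#' over the 100-600 bp flanks of a site set matches the reference's
#' (`mode = "flank"`). Flank offsets are taken on both sides of each
#' site center, clipped at chromosome ends.
#'
#' @param map track to rescale
#' @param ref reference `tag_map` on the same genome
#' @param mode `"genome_total"` or `"flank"`
#' @param sites site data.frame, required for `mode = "flank"`
#' @param flank_range 2-vector of distances from the site center (bp)
#' @return rescaled `tag_map` with `normalization = "scaled_to_ref"`
#' @export
scale_to_reference <- function(map, ref, mode = c("genome_total", "flank"),
                               sites = NULL, flank_range = c(100L, 600L)) {
  mode <- match.arg(mode)
  check_same_genome(map, ref)
  if (mode == "genome_total") {
    denom <- map_total(map)
    if (denom <= 0) stop("zero reference mass: map total is 0")
    s <- map_total(ref) / denom
  } else {
    if (is.null(sites)) stop("flank mode needs a site set")
    fm <- flank_mean(map, sites, flank_range)
    fr <- flank_mean(ref, sites, flank_range)
    if (fm <= 0) stop("zero reference mass in flanks")
    s <- fr / fm
  }
  out <- map
  out$values <- lapply(map$values, function(v) v * s)
  out$normalization <- "scaled_to_ref"
  attr(out, "scale_factor") <- s
  out
}

flank_mean <- function(map, sites, flank_range) {
  tot <- 0
  n <- 0L
  for (i in seq_len(nrow(sites))) {
    v <- map$values[[sites$chrom[i]]]
    ce <- site_center(sites$start[i], sites$end[i])
    for (sgn in c(-1L, 1L)) {
      lo <- ce + sgn * flank_range[2L]
      hi <- ce + sgn * flank_range[1L]
      if (sgn > 0) { tmp <- lo; lo <- hi; hi <- tmp }
      lo <- max(0L, lo)
      hi <- min(length(v) - 1L, hi)
      if (hi >= lo) {
        tot <- tot + sum(v[(lo + 1L):(hi + 1L)])
        n <- n + (hi - lo + 1L)
      }
    }
  }
  if (n == 0L) stop("no in-bounds flank basepairs")
  tot / n
}

#' Crosslinked-minus-uncrosslinked nucleosome difference map
#'
#' Scales the uncrosslinked track to the crosslinked track's genome-wide
#' total, then subtracts per basepair. Positive values mark positions
#' with excess tags in crosslinked chromatin (crosslink-trapped, labile
#' nucleosomes); the genome-wide sum is zero by construction.
#'
#' @param xlink crosslinked `tag_map`
#' @param unxlink uncrosslinked `tag_map` on the same genome
#' @return a signed `tag_map` with `normalization = "difference"`
#' @export
difference_map <- function(xlink, unxlink) {
  check_same_genome(xlink, unxlink)
  scaled <- scale_to_reference(unxlink, xlink, mode = "genome_total")
  vals <- mapply(function(a, b) a - b, xlink$values, scaled$values,
                 SIMPLIFY = FALSE)
  tag_map(vals, tag_length = xlink$tag_length, normalization = "difference")
}
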