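#' Genome sequence container
#'
#' A `genome_seq` is a named character vector of uppercase chromosome
#' sequences over the alphabet A, C, G, T, N. Chromosome names must be
#' unique. It is the in-memory form behind every coordinate in the
#' package; all coordinates are 0-based half-open.
#'
#' @param sequences named character vector of sequences
#' @return an object of class `genome_seq`
#' @export
genome_seq <- function(sequences) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(sequences)))
    stop("duplicate chromosome name: ",
         names(sequences)[duplicated(names(sequences))][1L])
  sequences <- stats::setNames(toupper(as.character(sequences)),
                               names(sequences))
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("invalid characters in chromosome ", names(sequences)[bad][1L])
  structure(sequences, class = "genome_seq")
}

#' Chromosome lengths of a genome
#'
#' @param genome a `genome_seq`
#' @return named integer vector of lengths in bp
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(nchar(unclass(genome)), names(genome))
}

#' @export
print.genome_seq <- function(x, ...) {
  len <- chrom_lengths(x)
  cat("genome_seq:", length(x), "chromosome(s),",
      format(sum(as.numeric(len)), big.mark = ","), "bp total\n")
  for (nm in utils::head(names(x), 10L))
    cat(sprintf("  %s  %s bp\n", nm, format(len[[nm]], big.mark = ",")))
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Read a genome FASTA file
#'
#' Loads all records, uppercases the sequence and checks the alphabet.
#' Duplicate headers are an error. The part of the header line before the
#' first whitespace is used as the chromosome name.
#'
#' @param path path to a FASTA file
#' @return a [genome_seq()]
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  nms <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nms))
    stop("duplicate FASTA header: ", nms[duplicated(nms)][1L])
  genome_seq(stats::setNames(as.character(set), nms))
}

#' Write a genome FASTA file
#'
#' @param genome a `genome_seq`
#' @param path output path
#' @param width line width for wrapped sequence
#' @return `path`, invisibly
#' @export
write_fasta <- function(genome, path, width = 70L) {
  set <- Biostrings::BStringSet(unclass(genome))
  names(set) <- names(genome)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Extract a subsequence (0-based half-open coordinates)
#'
#' @param genome a `genome_seq`
#' @param chrom chromosome name
#' @param start 0-based start
#' @param end 0-based exclusive end
#' @return character scalar
#' @export
genome_subseq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  len <- nchar(genome[[chrom]])
  if (start < 0 || end > len || end <= start)
    stop("subsequence [", start, ",", end, ") out of bounds for ",
         chrom, " (length ", len, ")")
  substr(unclass(genome)[[chrom]], start + 1L, end)
}

#' Reverse complement of a DNA string
#'
#' @param x character scalar over A,C,G,T,N
#' @return character scalar
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
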