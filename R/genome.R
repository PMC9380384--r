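#' Genome sequence container
#'
#' A `genome_sequence` is a named character vector of uppercase DNA strings
#' over the alphabet `{A,C,G,T,N}`, one element per contig. The constructor
#' normalizes case and replaces any other IUPAC ambiguity code by `N`.
#'
#' @param contigs Named character vector of DNA sequences. Names are contig
#'   names and must be unique and non-empty.
#' @return A `genome_sequence` object.
#' @examples
#' g <- genome_sequence(c(chr1 = "acgtACGT", chr2 = "ACRT"))
#' unclass(g)
#' @export
genome_sequence <- function(contigs) {
  if (!is.character(contigs) || length(contigs) == 0L)
    stop("'contigs' must be a non-empty named character vector")
  nm <- names(contigs)
  if (is.null(nm) || any(is.na(nm)) || any(!nzchar(nm)))
    stop("every contig must have a non-empty name")
  if (anyDuplicated(nm))
    stop("duplicate contig name: ", nm[duplicated(nm)][1L])
  x <- toupper(contigs)
  x <- gsub("[^ACGTN]", "N", x)
  structure(setNames(x, nm), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", length(x), " contig(s), ",
      format(sum(nchar(x)), big.mark = ","), " bp total\n", sep = "")
  for (i in seq_len(min(length(x), 8L)))
    cat("  ", names(x)[i], ": ", format(nchar(x[[i]]), big.mark = ","),
        " bp\n", sep = "")
  if (length(x) > 8L) cat("  ...\n")
  invisible(x)
}

contig_lengths <- function(genome) setNames(nchar(unclass(genome)), names(genome))

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of reverse complements.
#' @examples
#' dna_revcomp("ACCGT")
#' @export
dna_revcomp <- function(x) {
  rc <- vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), character(1L),
               USE.NAMES = FALSE)
  chartr("ACGTNacgtn", "TGCANtgcan", rc)
}

#' Reverse-complement an entire genome
#'
#' Each contig is replaced by its reverse complement (contig names kept).
#' Used by the strand-symmetry checks.
#'
#' @param genome A [genome_sequence()].
#' @return A `genome_sequence`.
#' @export
genome_revcomp <- function(genome) {
  genome_sequence(setNames(dna_revcomp(unclass(genome)), names(genome)))
}

gc_fraction_of <- function(x) {
  n <- nchar(x)
  gc <- nchar(gsub("[^GC]", "", x))
  ifelse(n > 0, gc / n, NA_real_)
}
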