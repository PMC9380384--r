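#' Somatic variant table
#'
#' Builds the canonical somatic variant table used throughout the package:
#' one row per tumor-unique variant with VCF-convention coordinates (`pos`
#' is the 1-based position of the first REF base), a variant class and a
#' canonical id `contig:pos:ref>alt`.
#'
#' Classes follow allele lengths: `SNV` (1/1), `INS` (alt longer), `DEL`
#' (ref longer), `MNV` (equal lengths > 1).
#'
#' @param contig,pos,ref,alt Parallel vectors describing the variants.
#' @param genome Optional [genome_sequence()]; when given, each REF allele
#'   is checked against the reference and a mismatch is an error naming the
#'   offending variant.
#' @return Data frame of class `somatic_variants` with columns
#'   `contig, pos, ref, alt, vclass, id`.
#' @examples
#' somatic_variants("chr1", 100L, "A", "G")
#' @export
somatic_variants <- function(contig, pos, ref, alt, genome = NULL) {
  contig <- as.character(contig); ref <- toupper(as.character(ref))
  alt <- toupper(as.character(alt)); pos <- as.integer(pos)
  n <- length(contig)
  stopifnot(length(pos) == n, length(ref) == n, length(alt) == n)
  if (n > 0L) {
    if (any(!nzchar(ref)) || any(!nzchar(alt)))
      stop("REF and ALT alleles must be non-empty")
    if (any(ref == alt)) stop("REF and ALT must differ")
    if (any(grepl("[^ACGTN]", c(ref, alt))))
      stop("alleles must be over {A,C,G,T,N}")
    if (any(is.na(pos)) || any(pos < 1L)) stop("positions must be >= 1")
  }
  vclass <- variant_class(ref, alt)
  id <- if (n > 0L) paste0(contig, ":", pos, ":", ref, ">", alt)
        else character(0)
  out <- data.frame(contig = contig, pos = pos, ref = ref, alt = alt,
                    vclass = vclass, id = id, stringsAsFactors = FALSE)
  class(out) <- c("somatic_variants", "data.frame")
  if (!is.null(genome)) check_ref_alleles(out, genome)
  out
}

variant_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  ifelse(lr == 1L & la == 1L, "SNV",
         ifelse(la > lr, "INS", ifelse(lr > la, "DEL", "MNV")))
}

check_ref_alleles <- function(variants, genome) {
  for (i in seq_len(nrow(variants))) {
    ctg <- variants$contig[i]
    if (!ctg %in% names(genome))
      stop("variant ", variants$id[i], " on unknown contig '", ctg, "'")
    s <- unclass(genome)[[ctg]]
    p <- variants$pos[i]; r <- variants$ref[i]
    if (p + nchar(r) - 1L > nchar(s) ||
        substr(s, p, p + nchar(r) - 1L) != r)
      stop("REF allele of variant ", variants$id[i],
           " does not match the genome")
  }
  invisible(variants)
}

#' Normalize somatic variants (parsimony + left alignment)
#'
#' Applies the standard VCF normalization: shared trailing and leading
#' bases are trimmed (keeping one anchor base for indels) and indels are
#' shifted to their leftmost equivalent position. SNVs pass through
#' unchanged and the operation is idempotent, so equivalent encodings of
#' the same indel collapse to a single canonical id.
#'
#' @param variants A [somatic_variants()] table.
#' @param genome A [genome_sequence()]; REF alleles must match it.
#' @return A normalized `somatic_variants` table (row order preserved).
#' @export
normalize_variants <- function(variants, genome) {
  check_ref_alleles(variants, genome)
  n <- nrow(variants)
  pos <- variants$pos; ref <- variants$ref; alt <- variants$alt
  for (i in seq_len(n)) {
    if (variants$vclass[i] == "SNV") next
    v <- normalize_one(unclass(genome)[[variants$contig[i]]],
                       pos[i], ref[i], alt[i])
    pos[i] <- v$pos; ref[i] <- v$ref; alt[i] <- v$alt
  }
  somatic_variants(variants$contig, pos, ref, alt)
}

# classic left-align / trim loop on one variant
normalize_one <- function(seq, pos, ref, alt) {
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0L && la > 0L &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      if (lr > 1L && la > 1L) {
        ref <- substr(ref, 1L, lr - 1L); alt <- substr(alt, 1L, la - 1L)
        next
      }
      if (pos > 1L) {
        b <- substr(seq, pos - 1L, pos - 1L)
        ref <- paste0(b, substr(ref, 1L, lr - 1L))
        alt <- paste0(b, substr(alt, 1L, la - 1L))
        pos <- pos - 1L
        next
      }
    }
    break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref)); alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Tumor-vs-normal variant set difference
#'
#' Pure set semantics on canonical variant ids: the ids present in `a` but
#' not in `b`. Both inputs should be normalized against the same genome so
#' equivalent indel encodings compare equal.
#'
#' @param a,b [somatic_variants()] tables or character vectors of ids.
#' @return Character vector of ids unique to `a`.
#' @export
variant_set_difference <- function(a, b) {
  ids <- function(x) if (is.data.frame(x)) x$id else as.character(x)
  setdiff(ids(a), ids(b))
}

#' @export
print.somatic_variants <- function(x, ...) {
  cat("<somatic_variants> ", nrow(x), " variant(s): ",
      paste(sprintf("%s=%d", names(table(x$vclass)), table(x$vclass)),
            collapse = ", "), "\n", sep = "")
  if (nrow(x) > 0L) print.data.frame(head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("  ... ", nrow(x) - 6L, " more row(s)\n", sep = "")
  invisible(x)
}
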