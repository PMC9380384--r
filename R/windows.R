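#' Paired normal/tumor haplotype window around a variant
#'
#' Extracts the reference sequence `W` bases either side of a normalized
#' variant and applies the REF->ALT edit to obtain the local tumor
#' haplotype, together with an offset map from tumor-window coordinates
#' back to 0-based genomic positions (`NA` for inserted, tumor-only
#' bases). The altered span marks, in tumor-window coordinates, the bases
#' that differ from (or are inserted relative to) the normal haplotype;
#' for a deletion it marks the two bases flanking the novel junction.
#'
#' `W >= 23` guarantees every 23-nt protospacer+PAM frame touching the
#' altered span lies fully inside the window. Windows are clipped at
#' contig edges and the clipping recorded in `$clipped`.
#'
#' @param variant One-row [somatic_variants()] table (normalized), or an
#'   equivalent named list.
#' @param genome A [genome_sequence()].
#' @param W Flank size in bases, default 30.
#' @param check Validate the variant against the genome (default `TRUE`;
#'   internal callers that already validated may skip).
#' @return An object of class `haplotype_window`: a list with elements
#'   `variant`, `contig`, `window_start` (0-based genomic), `normal_seq`,
#'   `tumor_seq`, `altered_span` (0-based half-open, tumor coordinates),
#'   `offset_map` (integer vector, one entry per tumor base), `v_off`
#'   (tumor offset of the first ALT base) and `clipped`.
#' @examples
#' g <- genome_sequence(c(chr1 = strrep("ACGT", 300)))
#' v <- somatic_variants("chr1", 601L, "A", "G")
#' w <- haplotype_window(v, g)
#' substr(w$tumor_seq, w$v_off + 1, w$v_off + 1)
#' @export
haplotype_window <- function(variant, genome, W = 30L, check = TRUE) {
  W <- as.integer(W)
  if (W < 23L) stop("W must be >= 23 so every guide frame fits the window")
  ctg <- variant$contig
  if (!ctg %in% names(genome))
    stop("variant ", variant$id, " on unknown contig '", ctg, "'")
  S <- unclass(genome)[[ctg]]
  L <- nchar(S)
  if (check) {
    if (is.data.frame(variant) && nrow(variant) != 1L)
      stop("'variant' must describe exactly one variant")
    if (substr(S, variant$pos, variant$pos + nchar(variant$ref) - 1L) !=
        variant$ref)
      stop("REF allele of variant ", variant$id,
           " does not match the genome")
  }
  ref <- variant$ref; alt <- variant$alt
  pos0 <- variant$pos - 1L                       # 0-based first REF base
  ws <- max(0L, pos0 - W)
  we <- min(L, pos0 + nchar(ref) + W)            # 0-based half-open end
  clipped <- (ws > pos0 - W) || (we < pos0 + nchar(ref) + W)
  normal_seq <- substr(S, ws + 1L, we)
  v_off <- pos0 - ws
  tumor_seq <- paste0(substr(normal_seq, 1L, v_off), alt,
                      substr(normal_seq, v_off + nchar(ref) + 1L,
                             nchar(normal_seq)))
  lt <- nchar(tumor_seq)
  vclass <- variant$vclass
  span <- switch(vclass,
    SNV = c(v_off, v_off + 1L),
    MNV = c(v_off, v_off + nchar(alt)),
    INS = c(v_off + shared_prefix_len(ref, alt),
            v_off + nchar(alt)),
    DEL = c(v_off, min(lt, v_off + 2L)))         # junction-flanking bases
  # offset map: tumor index (0-based) -> genomic 0-based position, NA inside
  # insertions
  core <- min(nchar(ref), nchar(alt))
  offset_map <- c(
    if (v_off > 0L) ws + 0:(v_off - 1L) else integer(),
    pos0 + seq_len(core) - 1L,
    rep(NA_integer_, nchar(alt) - core),
    if (we > pos0 + nchar(ref))
      (pos0 + nchar(ref)):(we - 1L) else integer())
  structure(list(variant = variant, contig = ctg, window_start = ws,
                 normal_seq = normal_seq, tumor_seq = tumor_seq,
                 altered_span = span, offset_map = offset_map,
                 v_off = v_off, clipped = clipped),
            class = "haplotype_window")
}

shared_prefix_len <- function(a, b) {
  n <- min(nchar(a), nchar(b))
  i <- 0L
  while (i < n && substr(a, i + 1L, i + 1L) == substr(b, i + 1L, i + 1L))
    i <- i + 1L
  i
}

#' @export
print.haplotype_window <- function(x, ...) {
  cat("<haplotype_window> ", x$variant$id, " (", x$variant$vclass, ")\n",
      "  window [", x$window_start, ",", x$window_start +
        nchar(x$normal_seq), ") on ", x$contig,
      if (x$clipped) "  [clipped]" else "", "\n",
      "  altered span (tumor coords): [", x$altered_span[1L], ",",
      x$altered_span[2L], ")\n", sep = "")
  invisible(x)
}

#' Apply somatic variants to a genome
#'
#' Produces the tumor genome obtained by applying every variant to the
#' reference. Variants must not overlap; they are applied per contig from
#' rightmost to leftmost so coordinates never shift under earlier edits.
#'
#' @param genome A [genome_sequence()].
#' @param variants A [somatic_variants()] table (REF alleles must match).
#' @return A `genome_sequence` carrying the tumor haplotype.
#' @export
apply_variants <- function(genome, variants) {
  check_ref_alleles(variants, genome)
  contigs <- unclass(genome)
  for (ctg in unique(variants$contig)) {
    v <- variants[variants$contig == ctg, , drop = FALSE]
    v <- v[order(v$pos, decreasing = TRUE), , drop = FALSE]
    if (nrow(v) > 1L) {
      ends <- v$pos + nchar(v$ref) - 1L
      if (any(v$pos[-nrow(v)] <= ends[-1L]))
        stop("overlapping variants on contig ", ctg)
    }
    s <- contigs[[ctg]]
    for (i in seq_len(nrow(v)))
      s <- paste0(substr(s, 1L, v$pos[i] - 1L), v$alt[i],
                  substr(s, v$pos[i] + nchar(v$ref[i]), nchar(s)))
    contigs[[ctg]] <- s
  }
  genome_sequence(contigs)
}

#' Flag variants with another variant inside their window
#'
#' Plain VCFs carry no phase, so windows are built one variant at a time;
#' this helper reports which variants have a neighbour within `W + 23`
#' bases whose co-occurrence the window cannot represent.
#'
#' @param variants A [somatic_variants()] table.
#' @param W Flank size used for windows.
#' @return Logical vector, `TRUE` where a neighbour falls inside the window.
#' @export
flag_crowded_variants <- function(variants, W = 30L) {
  n <- nrow(variants)
  flag <- logical(n)
  if (n < 2L) return(flag)
  for (i in seq_len(n)) {
    same <- variants$contig == variants$contig[i]
    same[i] <- FALSE
    d <- abs(variants$pos[same] - variants$pos[i])
    flag[i] <- any(d <= W + 23L)
  }
  flag
}
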