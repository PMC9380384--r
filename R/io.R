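#' Read a reference genome from FASTA
#'
#' Loads every record, uppercases the sequence and maps any non-`ACGTN`
#' character to `N`. Contig names are the first whitespace-delimited word of
#' each header and must be unique.
#'
#' @param path Path to a FASTA file.
#' @return A [genome_sequence()].
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm))
    stop("duplicate contig name in FASTA: ", nm[duplicated(nm)][1L])
  genome_sequence(setNames(as.character(set), nm))
}

#' Write a genome to FASTA
#'
#' @param genome A [genome_sequence()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path) {
  set <- Biostrings::DNAStringSet(unclass(genome))
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Read tumor-unique somatic variants from a VCF
#'
#' Parses a VCF v4.x file into a somatic variant table, one row per ALT
#' allele (multi-allelic records are split). Records with symbolic ALT
#' alleles (`<DEL>`, breakends, `*`) are skipped; the number skipped is
#' reported via [message()] and attached as the `n_skipped_symbolic`
#' attribute. When `genome` is supplied every REF allele is checked against
#' it and a mismatch is an error naming the variant.
#'
#' @param path Path to an (uncompressed) VCF file.
#' @param genome Optional [genome_sequence()] for REF validation.
#' @return A [somatic_variants()] data frame with attribute
#'   `n_skipped_symbolic`.
#' @export
read_vcf <- function(path, genome = NULL) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(lines))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 8L)
      stop("malformed VCF line ", i, ": expected >= 8 tab-separated fields")
    if (is.na(suppressWarnings(as.integer(f[2L]))))
      stop("malformed VCF line ", i, ": POS is not an integer")
  }
  if (length(body) == 0L) {
    out <- somatic_variants(character(), integer(), character(), character())
    attr(out, "n_skipped_symbolic") <- 0L
    return(out)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  chrom <- rep(fix[, "CHROM"], 1L)
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  chrom <- rep(chrom, n_alt); pos <- rep(pos, n_alt); ref <- rep(ref, n_alt)
  alt <- unlist(alts, use.names = FALSE)
  symbolic <- grepl("[][<>]", alt) | alt == "*" | alt == "." |
    grepl("[][<>]", ref)
  n_skip <- sum(symbolic)
  if (n_skip > 0L)
    message("read_vcf: skipped ", n_skip, " symbolic/structural ALT allele(s)")
  out <- somatic_variants(chrom[!symbolic], pos[!symbolic],
                          toupper(ref[!symbolic]), toupper(alt[!symbolic]),
                          genome = genome)
  attr(out, "n_skipped_symbolic") <- n_skip
  out
}

#' Write a somatic variant table as a minimal VCF
#'
#' Emits an 8-column VCF v4.2 file (QUAL/FILTER/INFO set to missing) with
#' `##contig` headers when a genome is supplied. Rows are sorted by contig
#' then position.
#'
#' @param variants A [somatic_variants()] table.
#' @param path Output path.
#' @param genome Optional [genome_sequence()] used to emit contig headers.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, genome = NULL) {
  hdr <- c("##fileformat=VCFv4.2", "##source=somaguide")
  if (!is.null(genome))
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>", names(genome),
                          contig_lengths(genome)))
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO"), collapse = "\t"))
  o <- order(variants$contig, variants$pos, variants$ref, variants$alt)
  v <- variants[o, , drop = FALSE]
  rows <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", v$contig, v$pos, v$id,
                  v$ref, v$alt)
  writeLines(c(hdr, rows), path)
  invisible(path)
}

guide_tsv_columns <- c("guide_id", "contig", "cut_pos_0based", "strand",
                       "protospacer", "pam", "variant_id",
                       "specificity_class", "variant_guide_position",
                       "n_offtargets_le_M", "gc_fraction", "score")

format_positions <- function(pos_list) {
  vapply(pos_list, function(p) {
    if (length(p) == 0L) return("")
    lab <- ifelse(p > 20L, paste0("P", p - 20L), as.character(p))
    paste(lab, collapse = ";")
  }, character(1L))
}

parse_positions <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(p) {
    p <- p[nzchar(p)]
    ifelse(startsWith(p, "P"), as.integer(sub("^P", "", p)) + 20L,
           as.integer(p))
  })
}

#' Write a guide table to TSV
#'
#' Writes one row per guide with the fixed column set
#' `guide_id, contig, cut_pos_0based, strand, protospacer, pam, variant_id,
#' specificity_class, variant_guide_position, n_offtargets_le_M, gc_fraction,
#' score`. An empty guide set yields a header-only file.
#'
#' @param guides Guide data frame as produced by [design_guides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides_tsv <- function(guides, path) {
  df <- as.data.frame(guides, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    writeLines(paste(guide_tsv_columns, collapse = "\t"), path)
    return(invisible(path))
  }
  if (!"variant_guide_position" %in% names(df) &&
      "variant_positions" %in% names(df))
    df$variant_guide_position <- format_positions(df$variant_positions)
  missing <- setdiff(guide_tsv_columns, names(df))
  if (length(missing)) stop("guide table lacks column(s): ",
                            paste(missing, collapse = ", "))
  out <- df[, guide_tsv_columns]
  out <- out[order(out$contig, out$cut_pos_0based, out$guide_id), ]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Read a guide table written by `write_guides_tsv()`
#'
#' @param path Path to the TSV.
#' @return Data frame with the fixed guide columns plus a parsed
#'   `variant_positions` list column.
#' @export
read_guides_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = NA)
  if (nrow(df) > 0L) {
    df$variant_guide_position <- as.character(df$variant_guide_position)
    df$variant_positions <- parse_positions(df$variant_guide_position)
  } else {
    df$variant_positions <- list()
  }
  df
}

#' Write Cas9 cut sites as BED6
#'
#' Each guide contributes one interval covering the single base immediately
#' PAM-distal of the blunt cut (between protospacer positions 3 and 4,
#' counted from the PAM), 0-based half-open. Guides whose cut site lies
#' entirely within inserted (tumor-only) sequence have no reference
#' coordinate and are omitted. Rows are sorted by contig, start, guide id.
#'
#' @param guides Guide data frame as produced by [design_guides()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cutsites_bed <- function(guides, path) {
  df <- as.data.frame(guides, stringsAsFactors = FALSE)
  df <- df[!is.na(df$cut_pos_0based), , drop = FALSE]
  if (nrow(df) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  df <- df[order(df$contig, df$cut_pos_0based, df$guide_id), , drop = FALSE]
  gr <- GenomicRanges::GRanges(
    seqnames = df$contig,
    ranges = IRanges::IRanges(start = df$cut_pos_0based + 1L, width = 1L),
    strand = df$strand)
  gr$name <- df$guide_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
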