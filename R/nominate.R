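#' Enumerate SpCas9 PAM frames in a sequence
#'
#' Finds every 23-nt protospacer+PAM frame on both strands: on the forward
#' strand a frame `[f, f+23)` requires `GG` at positions `f+21, f+22`
#' (PAM `NGG` on the right); on the reverse strand it requires `CC` at
#' `f, f+1` (the reverse-complement `CCN` layout, protospacer 3'-ward).
#' Frames containing any `N` are excluded. Output is sorted by frame start
#' then strand (`+` before `-`) and is deterministic.
#'
#' @param seq A DNA string over `{A,C,G,T,N}`.
#' @return Data frame with columns `frame_start` (0-based) and `strand`.
#' @examples
#' scan_pam_sites("ATGCATGCATGCATGCATGCAGG")
#' @export
scan_pam_sites <- function(seq) {
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(frame_start = integer(), strand = character(),
                      stringsAsFactors = FALSE)
  if (L < 23L) return(empty)
  has_n <- cumsum(strsplit(seq, "", fixed = TRUE)[[1L]] == "N")
  frame_clean <- function(f) (c(0L, has_n)[f + 24L] - c(0L, has_n)[f + 1L]) == 0L
  gg <- gregexpr("(?=GG)", seq, perl = TRUE)[[1L]]
  fwd <- if (gg[1L] == -1L) integer() else as.integer(gg) - 1L - 21L
  fwd <- fwd[fwd >= 0L & fwd + 23L <= L]
  cc <- gregexpr("(?=CC)", seq, perl = TRUE)[[1L]]
  rev <- if (cc[1L] == -1L) integer() else as.integer(cc) - 1L
  rev <- rev[rev >= 0L & rev + 23L <= L]
  out <- data.frame(
    frame_start = c(fwd, rev),
    strand = c(rep("+", length(fwd)), rep("-", length(rev))),
    stringsAsFactors = FALSE)
  out <- out[frame_clean(out$frame_start), , drop = FALSE]
  out <- out[order(out$frame_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# map a tumor-window index j inside frame [f, f+23) to PAM-proximal
# numbering: protospacer 1..20 (1 adjacent to the PAM), PAM P1..P3 as 21..23
frame_position <- function(j, f, strand) {
  if (strand == "+") {
    ifelse(j <= f + 19L, f + 20L - j, j - f + 1L)   # PAM j=f+20 -> 21
  } else {
    ifelse(j >= f + 3L, j - f - 2L, 23L - (j - f))  # PAM j=f+2 -> 21
  }
}

#' Nominate guide candidates overlapping a variant
#'
#' Enumerates every PAM frame on the tumor haplotype of a window and keeps
#' those whose protospacer+PAM overlaps the variant-altered sequence. For
#' SNVs, MNVs and insertions any intersection with the altered span
#' qualifies; for deletions the frame must span the novel junction (contain
#' both junction-flanking bases). Frames containing `N` are never emitted.
#'
#' The reported cut site is the single base immediately PAM-distal of the
#' blunt cut (between protospacer positions 3 and 4 counting from the PAM),
#' mapped to 0-based genomic coordinates through the window's offset map;
#' candidates whose cut base is inside inserted tumor-only sequence carry
#' `cut_pos_0based = NA` and `within_insertion = TRUE` and remain valid.
#'
#' @param window A [haplotype_window()].
#' @return Data frame (class `guide_candidates`) with one row per
#'   candidate: `guide_id, variant_id, contig, strand, tumor_start,
#'   protospacer, pam, variant_positions` (list column, PAM-proximal
#'   numbering, PAM positions encoded 21..23), `cut_pos_0based`,
#'   `within_insertion`, plus window bookkeeping columns `window_start`,
#'   `vclass`, `vpos`.
#' @export
nominate_candidates <- function(window) {
  stopifnot(inherits(window, "haplotype_window"))
  ts <- window$tumor_seq
  frames <- scan_pam_sites(ts)
  span <- window$altered_span
  vclass <- window$variant$vclass
  # tumor indices that actually differ from the normal haplotype: for
  # SNV/MNV the substituted bases (an MNV interior may match the
  # reference), for INS the inserted bases, for DEL the junction pair
  altered_idx <- if (vclass %in% c("SNV", "MNV")) {
    idx <- seq.int(span[1L], span[2L] - 1L)
    idx[substring(ts, idx + 1L, idx + 1L) !=
          substring(window$normal_seq, idx + 1L, idx + 1L)]
  } else {
    seq.int(span[1L], span[2L] - 1L)
  }
  rows <- vector("list", nrow(frames))
  k <- 0L
  for (i in seq_len(nrow(frames))) {
    f <- frames$frame_start[i]; strand <- frames$strand[i]
    if (vclass == "DEL") {
      # must contain both junction-flanking bases
      if (!(f <= span[1L] && f + 23L >= span[2L])) next
    } else {
      if (!(f < span[2L] && f + 23L > span[1L])) next
    }
    jj <- altered_idx[altered_idx >= f & altered_idx <= f + 22L]
    if (length(jj) == 0L) next
    vp <- sort(frame_position(jj, f, strand))
    if (strand == "+") {
      protospacer <- substr(ts, f + 1L, f + 20L)
      pam <- substr(ts, f + 21L, f + 23L)
      cut_j <- f + 16L                       # protospacer position 4
    } else {
      protospacer <- dna_revcomp(substr(ts, f + 4L, f + 23L))
      pam <- dna_revcomp(substr(ts, f + 1L, f + 3L))
      cut_j <- f + 6L                        # protospacer position 4
    }
    cut_pos <- window$offset_map[cut_j + 1L]
    k <- k + 1L
    rows[[k]] <- list(strand = strand, tumor_start = f,
                      protospacer = protospacer, pam = pam,
                      variant_positions = vp,
                      cut_pos_0based = cut_pos,
                      within_insertion = is.na(cut_pos))
  }
  rows <- rows[seq_len(k)]
  strand <- vapply(rows, `[[`, "", "strand")
  tumor_start <- vapply(rows, `[[`, 0L, "tumor_start")
  out <- list(
    guide_id = paste0(window$variant$id, "|", strand, tumor_start),
    variant_id = rep(window$variant$id, k),
    contig = rep(window$contig, k),
    strand = strand,
    tumor_start = tumor_start,
    protospacer = vapply(rows, `[[`, "", "protospacer"),
    pam = vapply(rows, `[[`, "", "pam"),
    cut_pos_0based = vapply(rows, function(r)
      as.integer(r$cut_pos_0based), 0L),
    within_insertion = vapply(rows, `[[`, FALSE, "within_insertion"),
    window_start = rep(window$window_start, k),
    vclass = rep(vclass, k),
    vpos = rep(window$variant$pos, k),
    variant_positions = lapply(rows, `[[`, "variant_positions"))
  structure(out, class = c("guide_candidates", "data.frame"),
            row.names = if (k) seq_len(k) else integer())
}
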