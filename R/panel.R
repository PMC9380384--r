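#' Score a guide candidate
#'
#' Hard filters reject guides with extreme base composition
#' (`GC < 0.30` or `> 0.80`), long homopolymers (`> 4`) or a Pol III
#' terminator-like poly-T run (`TTTT` anywhere in the protospacer); the
#' composite score is undefined (`NA`) for rejected guides. Otherwise
#'
#' `composite = class_weight - offtarget_penalty`
#'
#' with ordinal class weights `PAM_GAIN = 3`, `INDEL_DISRUPTING = 2`,
#' `SEED_DISCRIMINATING = 1` and
#' `offtarget_penalty = sum over reported non-native hits of
#' 1 / (1 + mismatches)`. The weights are declared heuristics, not
#' calibrated efficiencies.
#'
#' @param candidate One row of classified candidate output (needs
#'   `protospacer` and `specificity_class`).
#' @param hits Reported non-native off-target hits for this guide (data
#'   frame with a `mismatches` column), e.g. from
#'   [genome_specificity_filter()].
#' @return List of class `guide_score`: `gc_fraction, homopolymer_max,
#'   has_polyT, offtarget_penalty, class_weight, hard_pass, composite`.
#' @export
score_guide <- function(candidate, hits = NULL) {
  p <- candidate$protospacer
  gc <- gc_fraction_of(p)
  runs <- rle(strsplit(p, "", fixed = TRUE)[[1L]])
  homopolymer_max <- max(runs$lengths)
  has_polyT <- grepl("TTTT", p, fixed = TRUE)
  penalty <- if (is.null(hits) || nrow(hits) == 0L) 0 else
    sum(1 / (1 + hits$mismatches))
  w <- class_weight(candidate$specificity_class)
  hard_pass <- gc >= 0.30 && gc <= 0.80 && homopolymer_max <= 4L &&
    !has_polyT
  structure(list(gc_fraction = gc, homopolymer_max = homopolymer_max,
                 has_polyT = has_polyT, offtarget_penalty = penalty,
                 class_weight = w, hard_pass = hard_pass,
                 composite = if (hard_pass) w - penalty else NA_real_),
            class = "guide_score")
}

class_weight <- function(cls) {
  unname(c(PAM_GAIN = 3, INDEL_DISRUPTING = 2, SEED_DISCRIMINATING = 1,
           NON_DISCRIMINATING = 0)[cls])
}

# vectorized scoring over an annotated candidate table (pipeline path);
# needs columns protospacer, specificity_class, offtarget_penalty
score_candidates <- function(cands) {
  p <- cands$protospacer
  cands$gc_fraction <- gc_fraction_of(p)
  cands$homopolymer_max <- vapply(p, function(s)
    if (nchar(s)) max(rle(strsplit(s, "", fixed = TRUE)[[1L]])$lengths)
    else 0L, numeric(1L), USE.NAMES = FALSE)
  cands$has_polyT <- grepl("TTTT", p, fixed = TRUE)
  cands$class_weight <- class_weight(cands$specificity_class)
  cands$hard_pass <- cands$gc_fraction >= 0.30 & cands$gc_fraction <= 0.80 &
    cands$homopolymer_max <= 4 & !cands$has_polyT
  cands$score <- ifelse(cands$hard_pass,
                        cands$class_weight - cands$offtarget_penalty,
                        NA_real_)
  cands
}

#' Select a multi-guide panel
#'
#' Greedy selection by descending composite score under the panel
#' constraints: at most one guide per variant, at most `max_per_contig`
#' guides per contig, `N` guides total. Ties are broken deterministically
#' (higher composite, fewer reported off-targets, contig name, genomic
#' position, then `+` before `-`), so re-running on the same input yields
#' a byte-identical panel. When supply is short the panel is returned
#' smaller than `N` with a warning.
#'
#' @param scored Data frame of scored candidates (rows that failed the
#'   hard filters or the genome-specificity filter are ignored). Needs
#'   columns `guide_id, variant_id, contig, strand, score, hard_pass,
#'   pass, n_offtargets_le_M, cut_pos_0based, vpos, tumor_start`.
#' @param N Panel size requested, default 8.
#' @param max_per_contig Per-contig cap, default 2.
#' @return List of class `guide_panel` with elements `guides` (selected
#'   rows), `size_requested` and `constraints`.
#' @export
select_panel <- function(scored, N = 8L, max_per_contig = 2L) {
  N <- as.integer(N)
  if (is.na(N) || N < 1L) stop("panel size N must be >= 1")
  df <- as.data.frame(scored, stringsAsFactors = FALSE)
  if (!"pass" %in% names(df)) df$pass <- TRUE
  elig <- df[!is.na(df$score) & df$hard_pass & df$pass, , drop = FALSE]
  posn <- ifelse(is.na(elig$cut_pos_0based), elig$vpos,
                 elig$cut_pos_0based)
  o <- order(-elig$score, elig$n_offtargets_le_M, elig$contig, posn,
             elig$strand, elig$tumor_start)
  elig <- elig[o, , drop = FALSE]
  chosen <- integer()
  used_variant <- character()
  contig_count <- integer()
  for (i in seq_len(nrow(elig))) {
    if (length(chosen) >= N) break
    v <- elig$variant_id[i]; ctg <- elig$contig[i]
    if (v %in% used_variant) next
    cnt <- if (ctg %in% names(contig_count)) contig_count[[ctg]] else 0L
    if (cnt >= max_per_contig) next
    chosen <- c(chosen, i)
    used_variant <- c(used_variant, v)
    contig_count[[ctg]] <- cnt + 1L
  }
  guides <- elig[chosen, , drop = FALSE]
  rownames(guides) <- NULL
  if (nrow(guides) < N)
    warning("panel supply short: selected ", nrow(guides), " of ", N,
            " requested guides", call. = FALSE)
  structure(list(guides = guides, size_requested = N,
                 constraints = list(one_per_variant = TRUE,
                                    max_per_contig = max_per_contig)),
            class = "guide_panel")
}

#' @export
print.guide_panel <- function(x, ...) {
  cat("<guide_panel> ", nrow(x$guides), " guide(s) selected (requested ",
      x$size_requested, ", max ", x$constraints$max_per_contig,
      " per contig)\n", sep = "")
  if (nrow(x$guides) > 0L)
    print.data.frame(x$guides[, intersect(
      c("guide_id", "contig", "strand", "protospacer", "pam",
        "specificity_class", "score"), names(x$guides))])
  invisible(x)
}
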