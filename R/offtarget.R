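#' Build a k-mer pigeonhole index over a genome
#'
#' Partitions every 20-mer query into `max_mm + 1` disjoint `k`-length
#' chunks; any gap-free hit with at most `max_mm` mismatches must contain
#' one exact chunk, so exact k-mer lookups enumerate a candidate superset
#' that is verified base-by-base. The index lives in memory for the
#' session (it is not serializable) and records a checksum of the genome
#' it was built from.
#'
#' @param genome A [genome_sequence()].
#' @param k Chunk length, default 5 (supports `max_mm` up to 3 via the
#'   pigeonhole route; larger budgets fall back to a full scan).
#' @return An object of class `genome_index`.
#' @export
genome_index <- function(genome, k = 5L) {
  stopifnot(inherits(genome, "genome_sequence"))
  ptr <- cpp_build_index(unclass(genome), names(genome), as.integer(k))
  structure(list(ptr = ptr, k = as.integer(k),
                 contigs = names(genome),
                 lengths = unname(contig_lengths(genome)),
                 checksum = genome_checksum(genome)),
            class = "genome_index")
}

genome_checksum <- function(genome) {
  x <- unclass(genome)
  probe <- vapply(x, function(s) {
    n <- nchar(s)
    sum(utf8ToInt(substr(s, 1L, min(200L, n)))) +
      sum(utf8ToInt(substr(s, max(1L, n - 199L), n)))
  }, numeric(1L))
  sum(nchar(x)) * 1e6 + sum(probe) %% 1e6
}

#' @export
print.genome_index <- function(x, ...) {
  cat("<genome_index> k=", x$k, ", ", length(x$contigs), " contig(s), ",
      format(sum(x$lengths), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

as_genome_index <- function(x, k = 5L) {
  if (inherits(x, "genome_index")) x else genome_index(x, k = k)
}

check_index_genome <- function(index, genome) {
  if (!is.null(genome) &&
      !isTRUE(all.equal(index$checksum, genome_checksum(genome))))
    stop("genome_index checksum does not match the supplied genome")
  invisible(index)
}

sort_hits <- function(h) {
  o <- if ("query" %in% names(h))
    order(h$query, h$contig, h$start, h$strand, h$mismatches)
  else order(h$contig, h$start, h$strand, h$mismatches)
  h <- h[o, , drop = FALSE]
  rownames(h) <- NULL
  h
}

#' Indexed mismatch-tolerant protospacer search
#'
#' Finds every genomic 20-mer frame, on either strand, within `max_mm`
#' Hamming mismatches of a query protospacer and flanked by a permissive
#' PAM (`NGG` and optionally `NAG`). Frames containing `N` are excluded.
#' Returns the identical hit set to [find_matches_bruteforce()].
#'
#' @param protospacers Character vector of 20-nt queries over `ACGT`.
#' @param index A [genome_index()] (or a [genome_sequence()], indexed on
#'   the fly).
#' @param max_mm Mismatch budget, 0..6.
#' @param pam_set Permissive PAM classes, subset of `c("NGG", "NAG")`.
#' @param genome Optional genome to verify against the index checksum.
#' @return Data frame with columns `query` (1-based index into
#'   `protospacers`), `contig`, `start` (0-based start of the
#'   protospacer-aligned 20-mer on the reference), `strand`, `mismatches`,
#'   `pam` (read 5'->3' on the hit strand) and `pam_class`.
#' @export
find_matches_indexed <- function(protospacers, index, max_mm = 3L,
                                 pam_set = c("NGG", "NAG"),
                                 genome = NULL) {
  index <- as_genome_index(index)
  check_index_genome(index, genome)
  pam_set <- match.arg(pam_set, several.ok = TRUE)
  stopifnot(all(nchar(protospacers) == 20L),
            !any(grepl("[^ACGT]", protospacers)))
  h <- cpp_find_hits(index$ptr, protospacers, as.integer(max_mm),
                     "NGG" %in% pam_set, "NAG" %in% pam_set)
  sort_hits(as.data.frame(h, stringsAsFactors = FALSE))
}

#' Brute-force protospacer search (independent oracle)
#'
#' Exhaustive vectorized scan of every 20-mer frame on both strands,
#' written independently of the indexed search and used as its
#' correctness oracle. Same contract and hit columns as
#' [find_matches_indexed()] (minus `query`; one protospacer at a time).
#'
#' @param protospacer One 20-nt query over `ACGT`.
#' @param genome A [genome_sequence()].
#' @param max_mm Mismatch budget, 0..6.
#' @param pam_set Permissive PAM classes.
#' @return Hit data frame (`contig, start, strand, mismatches, pam,
#'   pam_class`).
#' @export
find_matches_bruteforce <- function(protospacer, genome, max_mm = 3L,
                                    pam_set = c("NGG", "NAG")) {
  stopifnot(length(protospacer) == 1L, nchar(protospacer) == 20L,
            !grepl("[^ACGT]", protospacer), max_mm >= 0L, max_mm <= 6L)
  pam_set <- match.arg(pam_set, several.ok = TRUE)
  pr <- charToRaw(protospacer)
  prc <- charToRaw(dna_revcomp(protospacer))
  G <- charToRaw("G"); C <- charToRaw("C"); A <- charToRaw("A")
  T <- charToRaw("T")
  res <- list()
  for (ctg in names(genome)) {
    S <- unclass(genome)[[ctg]]
    L <- nchar(S)
    if (L < 23L) next
    raw <- charToRaw(S)
    valid <- (raw == A) | (raw == C) | (raw == G) | (raw == T)
    cumN <- c(0L, cumsum(!valid))
    # forward frames: protospacer 0-based start s in 0..L-23
    ns <- L - 23L + 1L
    s0 <- 0:(ns - 1L)
    mm <- integer(ns)
    for (j in 1:20) mm <- mm + as.integer(raw[s0 + j] != pr[j])
    clean <- (cumN[s0 + 24L] - cumN[s0 + 1L]) == 0L
    p2 <- raw[s0 + 22L]; p3 <- raw[s0 + 23L]
    pam_class <- rep(NA_character_, ns)
    if ("NGG" %in% pam_set) pam_class[p2 == G & p3 == G] <- "NGG"
    if ("NAG" %in% pam_set) pam_class[p2 == A & p3 == G] <- "NAG"
    keep <- clean & mm <= max_mm & !is.na(pam_class)
    if (any(keep)) {
      ks <- s0[keep]
      res[[length(res) + 1L]] <- data.frame(
        contig = ctg, start = ks, strand = "+",
        mismatches = mm[keep],
        pam = substring(S, ks + 21L, ks + 23L),
        pam_class = pam_class[keep], stringsAsFactors = FALSE)
    }
    # reverse frames: plus-strand 20-mer start s in 3..L-20; layout
    # [CCN-style pam'][20-mer matching revcomp(protospacer)]
    s0 <- 3:(L - 20L)
    nr <- length(s0)
    mm <- integer(nr)
    for (j in 1:20) mm <- mm + as.integer(raw[s0 + j] != prc[j])
    clean <- (cumN[s0 + 21L] - cumN[s0 - 2L]) == 0L
    c1 <- raw[s0 - 2L]; c2 <- raw[s0 - 1L]
    pam_class <- rep(NA_character_, nr)
    if ("NGG" %in% pam_set) pam_class[c1 == C & c2 == C] <- "NGG"
    if ("NAG" %in% pam_set) pam_class[c1 == C & c2 == T] <- "NAG"
    keep <- clean & mm <= max_mm & !is.na(pam_class)
    if (any(keep)) {
      ks <- s0[keep]
      res[[length(res) + 1L]] <- data.frame(
        contig = ctg, start = ks, strand = "-",
        mismatches = mm[keep],
        pam = dna_revcomp(substring(S, ks - 2L, ks)),
        pam_class = pam_class[keep], stringsAsFactors = FALSE)
    }
  }
  if (length(res) == 0L)
    return(data.frame(contig = character(), start = integer(),
                      strand = character(), mismatches = integer(),
                      pam = character(), pam_class = character(),
                      stringsAsFactors = FALSE))
  sort_hits(do.call(rbind, res))
}

#' Off-target filtering policy
#'
#' @param reject_mm_threshold Hits at or below this mismatch count (outside
#'   the native-locus window) reject the guide outright. Default 0: only a
#'   perfect normal-genome match elsewhere disqualifies.
#' @param report_mm Hits up to this mismatch count are returned and used as
#'   a ranking penalty. Default 3.
#' @param pam_set Permissive off-target PAMs, default `c("NGG", "NAG")`.
#' @param native_exclusion_radius Hits within this distance (bp) of the
#'   variant's own locus are the allele-specificity question, not
#'   off-targets; they are reported separately. Default 50.
#' @return A list of class `offtarget_policy`.
#' @export
offtarget_policy <- function(reject_mm_threshold = 0L, report_mm = 3L,
                             pam_set = c("NGG", "NAG"),
                             native_exclusion_radius = 50L) {
  stopifnot(reject_mm_threshold >= 0L, report_mm >= reject_mm_threshold,
            report_mm <= 6L, native_exclusion_radius >= 0L)
  structure(list(reject_mm_threshold = as.integer(reject_mm_threshold),
                 report_mm = as.integer(report_mm),
                 pam_set = match.arg(pam_set, c("NGG", "NAG"),
                                     several.ok = TRUE),
                 native_exclusion_radius =
                   as.integer(native_exclusion_radius)),
            class = "offtarget_policy")
}

is_native_hit <- function(hits, contig, vpos, ref_len,
                          radius) {
  v0 <- vpos - 1L
  gap <- pmax(0L, pmax(hits$start - (v0 + ref_len),
                       v0 - (hits$start + 20L)))
  hits$contig == contig & gap <= radius
}

#' Genome-specificity filter for one candidate
#'
#' Searches the normal genome for matches to the candidate's protospacer
#' within the policy's reporting budget. Hits near the variant's own locus
#' (the native allele, which for a seed-SNV guide matches with exactly one
#' mismatch) are reported separately and never counted as off-targets. The
#' candidate fails iff a non-native hit exists at or below the rejection
#' threshold.
#'
#' @param candidate One row of [nominate_candidates()] output.
#' @param index A [genome_index()] of the normal genome (or a
#'   [genome_sequence()]).
#' @param policy An [offtarget_policy()].
#' @return List with `pass`, `hits` (non-native reported hits),
#'   `native_hits` and `native_hit_excluded`.
#' @export
genome_specificity_filter <- function(candidate, index,
                                      policy = offtarget_policy()) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1L)
  index <- as_genome_index(index)
  h <- find_matches_indexed(candidate$protospacer, index,
                            max_mm = policy$report_mm,
                            pam_set = policy$pam_set)
  native <- is_native_hit(h, candidate$contig, candidate$vpos,
                          nchar_ref_of(candidate),
                          policy$native_exclusion_radius)
  list(pass = !any(!native & h$mismatches <= policy$reject_mm_threshold),
       hits = h[!native, , drop = FALSE],
       native_hits = h[native, , drop = FALSE],
       native_hit_excluded = any(native))
}

nchar_ref_of <- function(candidate) {
  # window bookkeeping keeps the variant position; REF length matters only
  # for the native-locus gap and is bounded by the indel cap, so derive it
  # from the id when present
  id <- candidate$variant_id
  ref <- sub("^.*:[0-9]+:([ACGTN]+)>.*$", "\\1", id)
  if (identical(ref, id)) 1L else nchar(ref)
}
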