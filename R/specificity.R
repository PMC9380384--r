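#' Mismatches between a guide and its native normal locus
#'
#' Aligns the candidate's frame back onto the normal haplotype at the
#' native locus. For length-preserving variants (SNV/MNV) the alignment is
#' gap-free and the function reports the protospacer positions
#' (PAM-proximal numbering) at which the normal allele differs from the
#' guide, plus whether the normal allele still presents an intact PAM
#' (`GG` at P2-P3; the N position never discriminates). For indels the
#' gap-free alignment is undefined: the call reports `frame_shifted = TRUE`
#' and an unbounded mismatch sentinel (`Inf`).
#'
#' @param candidate One row of [nominate_candidates()] output.
#' @param window The [haplotype_window()] the candidate came from.
#' @return List with `positions` (integer vector, or `Inf` sentinel),
#'   `normal_pam_intact` (logical, `NA` for indels) and `frame_shifted`.
#' @export
native_locus_mismatches <- function(candidate, window) {
  check_candidate_window(candidate, window)
  vclass <- window$variant$vclass
  if (vclass %in% c("INS", "DEL")) {
    return(list(positions = Inf, normal_pam_intact = NA,
                frame_shifted = TRUE))
  }
  ns <- window$normal_seq
  f <- candidate$tumor_start
  strand <- candidate$strand
  # gap-free: tumor and normal coordinates coincide; the only differing
  # bases are the variant-altered ones, so mismatch positions are the
  # altered frame positions that fall in the protospacer
  vp <- candidate$variant_positions[[1L]]
  positions <- sort(vp[vp <= 20L])
  if (strand == "+") {
    pam_ok <- substr(ns, f + 22L, f + 23L) == "GG"
  } else {
    pam_ok <- substr(ns, f + 1L, f + 2L) == "CC"
  }
  list(positions = positions, normal_pam_intact = pam_ok,
       frame_shifted = FALSE)
}

check_candidate_window <- function(candidate, window) {
  stopifnot(inherits(window, "haplotype_window"),
            is.data.frame(candidate), nrow(candidate) == 1L)
  if (candidate$variant_id != window$variant$id)
    stop("candidate ", candidate$guide_id,
         " does not belong to window of ", window$variant$id)
  f <- candidate$tumor_start
  frame <- substr(window$tumor_seq, f + 1L, f + 23L)
  expected <- if (candidate$strand == "+")
    paste0(candidate$protospacer, candidate$pam)
  else
    paste0(dna_revcomp(candidate$pam), dna_revcomp(candidate$protospacer))
  if (frame != expected)
    stop("candidate ", candidate$guide_id,
         " is inconsistent with its window sequence")
  invisible(TRUE)
}

#' Classify a candidate's allele specificity
#'
#' Assigns exactly one of four mutually exclusive classes describing why
#' Cas9 loaded with this guide should cut the tumor allele but spare the
#' normal allele, with precedence
#' `PAM_GAIN > INDEL_DISRUPTING > SEED_DISCRIMINATING > NON_DISCRIMINATING`:
#'
#' * `PAM_GAIN` - the normal allele lacks an `NGG` at the candidate's PAM
#'   frame and strand (the somatic change created the PAM). Evaluated for
#'   length-preserving variants, where the gap-free alignment the
#'   definition requires exists.
#' * `INDEL_DISRUPTING` - the variant is an insertion or deletion whose
#'   altered span or junction intersects the protospacer+PAM frame, so the
#'   normal locus is frame-shifted relative to the guide.
#' * `SEED_DISCRIMINATING` - an SNV/MNV places at least one altered base in
#'   the PAM-proximal seed (protospacer positions `1..seed_len`).
#' * `NON_DISCRIMINATING` - none of the above (e.g. a PAM-distal SNV).
#'
#' @param candidate One row of [nominate_candidates()] output.
#' @param window The [haplotype_window()] the candidate came from.
#' @param seed_len Seed length in bases (PAM-proximal), default 12.
#' @return List with `class`, `normal_mismatch_positions` and
#'   `normal_pam_intact`.
#' @export
classify_candidate <- function(candidate, window, seed_len = 12L) {
  seed_len <- as.integer(seed_len)
  if (seed_len < 0L || seed_len > 20L)
    stop("seed_len must be in [0, 20]")
  nm <- native_locus_mismatches(candidate, window)
  vclass <- window$variant$vclass
  cls <- if (isTRUE(nm$frame_shifted)) {
    "INDEL_DISRUPTING"
  } else if (!nm$normal_pam_intact) {
    "PAM_GAIN"
  } else if (any(nm$positions >= 1L & nm$positions <= seed_len)) {
    "SEED_DISCRIMINATING"
  } else {
    "NON_DISCRIMINATING"
  }
  list(class = cls,
       normal_mismatch_positions = nm$positions,
       normal_pam_intact = nm$normal_pam_intact)
}

specificity_classes <- c("PAM_GAIN", "INDEL_DISRUPTING",
                         "SEED_DISCRIMINATING", "NON_DISCRIMINATING")

# vectorized classification used by the pipeline: candidates as produced by
# nominate_candidates() for ONE window; same rules as classify_candidate()
# without the per-row frame re-validation
classify_candidates <- function(candidates, window, seed_len = 12L) {
  n <- nrow(candidates)
  vclass <- window$variant$vclass
  vp <- candidates$variant_positions
  if (vclass %in% c("INS", "DEL")) {
    cls <- rep("INDEL_DISRUPTING", n)
    pam_ok <- rep(NA, n)
    mm <- rep(list(Inf), n)
  } else {
    ns <- window$normal_seq
    f <- candidates$tumor_start
    pam_ok <- ifelse(candidates$strand == "+",
                     substr(rep(ns, n), f + 22L, f + 23L) == "GG",
                     substr(rep(ns, n), f + 1L, f + 2L) == "CC")
    mm <- lapply(vp, function(p) sort(p[p <= 20L]))
    in_seed <- vapply(mm, function(p)
      any(p >= 1L & p <= seed_len), logical(1L))
    cls <- ifelse(!pam_ok, "PAM_GAIN",
                  ifelse(in_seed, "SEED_DISCRIMINATING",
                         "NON_DISCRIMINATING"))
  }
  candidates$specificity_class <- cls
  candidates$normal_pam_intact <- pam_ok
  candidates$normal_mismatch_positions <- mm
  candidates
}
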