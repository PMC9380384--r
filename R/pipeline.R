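#' Pipeline configuration
#'
#' Collects every tunable knob of the design pipeline with its documented
#' default.
#'
#' @param W Haplotype-window flank (bp), default 30 (must be >= 23).
#' @param seed_len PAM-proximal seed length for allele discrimination,
#'   default 12 (accepted range 0..20; 8-12 are the supported seed models).
#' @param strict If `TRUE`, only the mechanistically safest classes
#'   (`PAM_GAIN`, `INDEL_DISRUPTING`) count as allele-discriminating.
#' @param reject_mm_threshold,report_mm,pam_offtarget,native_radius
#'   Off-target policy knobs, see [offtarget_policy()].
#' @param panel_size Requested panel size, default 8.
#' @param max_per_contig Per-contig panel cap, default 2.
#' @param index_k k-mer chunk length of the genome index, default 5.
#' @return List of class `design_config`.
#' @export
design_config <- function(W = 30L, seed_len = 12L, strict = FALSE,
                          reject_mm_threshold = 0L, report_mm = 3L,
                          pam_offtarget = c("NGG", "NAG"),
                          native_radius = 50L, panel_size = 8L,
                          max_per_contig = 2L, index_k = 5L) {
  seed_len <- as.integer(seed_len)
  if (seed_len < 0L || seed_len > 20L) stop("seed_len must be in [0, 20]")
  structure(list(
    W = as.integer(W), seed_len = seed_len, strict = isTRUE(strict),
    policy = offtarget_policy(reject_mm_threshold, report_mm,
                              pam_offtarget, native_radius),
    panel_size = as.integer(panel_size),
    max_per_contig = as.integer(max_per_contig),
    index_k = as.integer(index_k)), class = "design_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Reads a flat key-value YAML file whose keys are [design_config()]
#' arguments (unknown keys are an error); `overrides` (e.g. parsed
#' command-line flags) take precedence over file values, which take
#' precedence over the documented defaults.
#'
#' @param path Path to a YAML config file, or `NULL` for defaults only.
#' @param overrides Named list of [design_config()] arguments.
#' @return A [design_config()].
#' @export
read_design_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("the 'yaml' package is required to read config files")
    vals <- yaml::read_yaml(path)
  }
  vals[names(overrides)] <- overrides
  known <- names(formals(design_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(design_config, vals)
}

discriminating_classes <- function(config) {
  if (config$strict) c("PAM_GAIN", "INDEL_DISRUPTING")
  else c("PAM_GAIN", "INDEL_DISRUPTING", "SEED_DISCRIMINATING")
}

# nominate + classify every variant; returns one combined candidate table.
# variants are assumed validated against the genome already.
design_candidates <- function(genome, variants, config = design_config()) {
  pieces <- vector("list", nrow(variants))
  for (i in seq_len(nrow(variants))) {
    v <- list(contig = variants$contig[i], pos = variants$pos[i],
              ref = variants$ref[i], alt = variants$alt[i],
              vclass = variants$vclass[i], id = variants$id[i])
    w <- haplotype_window(v, genome, W = config$W, check = FALSE)
    cand <- nominate_candidates(w)
    if (nrow(cand) == 0L) next
    pieces[[i]] <- classify_candidates(cand, w, config$seed_len)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1L))]
  if (length(pieces) == 0L) return(empty_candidates())
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

empty_candidates <- function() {
  out <- data.frame(
    guide_id = character(), variant_id = character(), contig = character(),
    strand = character(), tumor_start = integer(),
    protospacer = character(), pam = character(),
    cut_pos_0based = integer(), within_insertion = logical(),
    window_start = integer(), vclass = character(), vpos = integer(),
    specificity_class = character(), normal_pam_intact = logical(),
    stringsAsFactors = FALSE)
  out$variant_positions <- list()
  out$normal_mismatch_positions <- list()
  out
}

# batch off-target annotation: one indexed search over unique protospacers
annotate_offtargets <- function(cands, index, policy, keep_hits = FALSE) {
  n <- nrow(cands)
  cands$n_offtargets_le_M <- integer(n)
  cands$offtarget_penalty <- numeric(n)
  cands$pass <- logical(n)
  cands$native_hit_excluded <- logical(n)
  if (n == 0L) {
    if (keep_hits) attr(cands, "hits") <- NULL
    return(cands)
  }
  uniq <- unique(cands$protospacer)
  h <- find_matches_indexed(uniq, index, max_mm = policy$report_mm,
                            pam_set = policy$pam_set)
  qmap <- match(cands$protospacer, uniq)
  hsplit <- split(seq_len(nrow(h)), h$query)
  all_hits <- if (keep_hits) vector("list", n) else NULL
  ref_len <- nchar(sub("^.*:[0-9]+:([ACGTN]+)>.*$", "\\1", cands$variant_id))
  for (i in seq_len(n)) {
    idx <- hsplit[[as.character(qmap[i])]]
    hi <- h[idx, , drop = FALSE]
    native <- is_native_hit(hi, cands$contig[i], cands$vpos[i],
                            ref_len[i], policy$native_exclusion_radius)
    ot <- hi[!native, , drop = FALSE]
    cands$n_offtargets_le_M[i] <- nrow(ot)
    cands$offtarget_penalty[i] <- if (nrow(ot)) sum(1 / (1 + ot$mismatches)) else 0
    cands$pass[i] <- !any(ot$mismatches <= policy$reject_mm_threshold)
    cands$native_hit_excluded[i] <- any(native)
    if (keep_hits) {
      if (nrow(ot)) ot$guide_id <- cands$guide_id[i]
      all_hits[[i]] <- ot
    }
  }
  if (keep_hits)
    attr(cands, "hits") <- do.call(rbind, all_hits)
  cands
}

#' Design an allele-specific guide panel
#'
#' Runs the full in-memory pipeline: haplotype-window construction around
#' each tumor-unique variant, PAM-frame nomination on the tumor haplotype,
#' allele-specificity classification, mismatch-tolerant off-target search
#' against the normal genome, heuristic scoring, and greedy panel
#' selection.
#'
#' @param genome Normal reference, a [genome_sequence()].
#' @param variants Tumor-unique [somatic_variants()] (normalized against
#'   `genome`; [normalize_variants()] is applied defensively).
#' @param config A [design_config()].
#' @param index Optional prebuilt [genome_index()] of `genome`.
#' @return Object of class `guide_design`: list with `guides` (all
#'   nominated candidates, annotated), `panel` (a `guide_panel`), `counts`
#'   and `config`. `guides$variant_guide_position` carries the altered
#'   frame positions in PAM-proximal numbering (`P1..P3` for the PAM).
#' @export
design_guides <- function(genome, variants, config = design_config(),
                          index = NULL) {
  stopifnot(inherits(genome, "genome_sequence"))
  variants <- normalize_variants(variants, genome)
  crowded <- flag_crowded_variants(variants, config$W)
  cands <- design_candidates(genome, variants, config)
  cands$crowded_window <- if (nrow(cands))
    crowded[match(cands$variant_id, variants$id)] else logical(0)
  disc <- cands[cands$specificity_class %in% discriminating_classes(config),
                , drop = FALSE]
  if (is.null(index)) index <- genome_index(genome, k = config$index_k)
  disc <- annotate_offtargets(disc, index, config$policy)
  disc <- score_candidates(disc)
  disc$variant_guide_position <- format_positions(disc$variant_positions)
  panel <- withCallingHandlers(
    select_panel(disc, N = config$panel_size,
                 max_per_contig = config$max_per_contig),
    warning = function(w) {
      if (grepl("panel supply short", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(list(
    guides = disc, panel = panel,
    counts = list(n_variants = nrow(variants),
                  n_candidates = nrow(cands),
                  n_discriminating = nrow(disc),
                  n_pass = sum(disc$pass & disc$hard_pass, na.rm = TRUE),
                  n_panel = nrow(panel$guides)),
    config = config), class = "guide_design")
}

#' @export
print.guide_design <- function(x, ...) {
  c <- x$counts
  cat("<guide_design>\n",
      "  variants in:              ", c$n_variants, "\n",
      "  candidates nominated:     ", c$n_candidates, "\n",
      "  allele-discriminating:    ", c$n_discriminating, "\n",
      "  passing all filters:      ", c$n_pass, "\n",
      "  panel selected:           ", c$n_panel, " of ",
      x$config$panel_size, " requested\n", sep = "")
  invisible(x)
}
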