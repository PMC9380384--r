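#' Run the design pipeline on files
#'
#' Reads a reference FASTA and a tumor-unique VCF, runs [design_guides()]
#' and writes `guides.tsv`, `panel.tsv`, `cutsites.bed` and
#' `manifest.json` (the effective configuration plus stage counts) into
#' `out_dir`. An empty panel is a success with a warning; malformed input
#' or a REF/genome mismatch is an error.
#'
#' @param reference Path to the normal reference FASTA.
#' @param vcf Path to the somatic VCF (tumor-unique variants).
#' @param out_dir Output directory (created if absent).
#' @param config A [design_config()].
#' @return The [design_guides()] result, invisibly.
#' @export
run_design <- function(reference, vcf, out_dir,
                       config = design_config()) {
  genome <- read_fasta(reference)
  variants <- read_vcf(vcf, genome = genome)
  design <- design_guides(genome, variants, config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_guides_tsv(design$guides, file.path(out_dir, "guides.tsv"))
  write_guides_tsv(design$panel$guides, file.path(out_dir, "panel.tsv"))
  write_cutsites_bed(design$panel$guides,
                     file.path(out_dir, "cutsites.bed"))
  manifest <- list(inputs = list(reference = reference, vcf = vcf),
                   config = config_as_list(config),
                   counts = design$counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  if (design$counts$n_panel == 0L)
    warning("empty panel: no guide passed all filters", call. = FALSE)
  invisible(design)
}

config_as_list <- function(config) {
  c(unclass(config)[setdiff(names(config), "policy")],
    unclass(config$policy))
}

#' Run the per-tumor target-burden estimate
#'
#' Estimates the suitable-target fraction by Monte Carlo on a background
#' genome (supplied as FASTA or simulated) and scales it by the mutation
#' burden. The report echoes `count = burden_per_mb * genome_mb *
#' fraction` with its binomial interval.
#'
#' @param reference Path to a background FASTA, or `NULL` to simulate.
#' @param n_samples Monte-Carlo sample size, default 10000.
#' @param seed Integer seed (mandatory).
#' @param model A [burden_model()].
#' @param config A [design_config()].
#' @param simulate_length,simulate_gc Background genome size/GC when
#'   simulating (defaults 1 Mb at GC 0.41).
#' @param out Optional path for a JSON report.
#' @return List of class `burden_report` with `estimate`
#'   (`suitability_estimate`) and `targets` (`target_estimate`).
#' @export
run_estimate <- function(reference = NULL, n_samples = 10000L, seed,
                         model = burden_model(),
                         config = design_config(),
                         simulate_length = 1e6, simulate_gc = 0.41,
                         out = NULL) {
  genome <- if (is.null(reference))
    simulate_genome(simulate_length, simulate_gc, seed = seed)
  else read_fasta(reference)
  est <- estimate_suitable_fraction(genome, n_samples = n_samples,
                                    seed = seed + 1L,
                                    indel_fraction = model$indel_fraction,
                                    config = config)
  targets <- expected_targets(model, est)
  rep <- structure(list(estimate = est, targets = targets,
                        model = model), class = "burden_report")
  if (!is.null(out))
    jsonlite::write_json(
      list(fraction = est$fraction, ci_low = est$ci_low,
           ci_high = est$ci_high, n_samples = est$n_sampled,
           burden_per_mb = model$burden_per_mb,
           genome_mb = model$genome_mb,
           expected_targets = targets$count,
           targets_ci_low = targets$ci_low,
           targets_ci_high = targets$ci_high, seed = seed),
      out, auto_unbox = TRUE, digits = NA)
  rep
}

#' @export
print.burden_report <- function(x, ...) {
  print(x$estimate)
  print(x$targets)
  invisible(x)
}

#' Run the clonal-persistence analysis
#'
#' Computes exact overlap statistics between a parent mutation set and
#' one or more derived clones (VCF paths or id vectors), and the
#' closed-form probability that an `N`-guide panel loses all its targets
#' given the observed mean retention. When `simulate` parameters are
#' given, clones are simulated from the parent set and an empirical panel
#' survival is reported alongside the closed form.
#'
#' @param sets Named list (>= 2, parent first) of VCF paths, id vectors,
#'   [somatic_variants()] tables or [clone_variant_set()]s.
#' @param panel_size Panel size `N` for the survival calculation,
#'   default 10.
#' @param simulate Optional list with `n_clones`, `p_retain`, `gain_rate`,
#'   `passages`, `genome`, `seed` to add a simulation-based estimate.
#' @param out Optional path for a JSON report.
#' @return List of class `persistence_report`.
#' @export
run_persistence <- function(sets, panel_size = 10L, simulate = NULL,
                            out = NULL) {
  if (length(sets) < 2L)
    stop("need at least two variant sets (parent plus one clone)")
  sets <- lapply(sets, function(s)
    if (is.character(s) && length(s) == 1L && file.exists(s))
      read_vcf(s) else s)
  ov <- clone_overlap(sets)
  parent_rows <- ov$pairwise[ov$pairwise$parent == ov$labels[1L], ,
                             drop = FALSE]
  p_retain <- mean(parent_rows$retained_fraction)
  surv <- panel_survival_probability(p_retain, panel_size)
  rep <- list(overlap = ov, p_retain = p_retain,
              panel_size = as.integer(panel_size),
              p_all_lost = surv$p_all_lost,
              p_any_retained = surv$p_any_retained)
  if (!is.null(simulate)) {
    cs <- as_clone_sets(sets)
    parent_ids <- cs[[1L]]$ids
    panel_ids <- parent_ids[seq_len(min(panel_size, length(parent_ids)))]
    clones <- lapply(seq_len(simulate$n_clones), function(i)
      derive_clone(parent_ids, p_retain = simulate$p_retain,
                   gain_rate = simulate$gain_rate %||% 0,
                   passages = simulate$passages %||% 1L,
                   genome = simulate$genome,
                   seed = simulate$seed + i,
                   label = paste0("simclone", i)))
    rep$empirical_survival <- panel_survival_empirical(panel_ids, clones)
    rep$n_clones <- simulate$n_clones
  }
  class(rep) <- "persistence_report"
  if (!is.null(out))
    jsonlite::write_json(
      list(p_retain = p_retain, panel_size = rep$panel_size,
           p_all_lost = rep$p_all_lost,
           p_any_retained = rep$p_any_retained,
           pairwise = ov$pairwise,
           empirical_survival = rep$empirical_survival),
      out, auto_unbox = TRUE, digits = NA)
  rep
}

#' @export
print.persistence_report <- function(x, ...) {
  print(x$overlap)
  cat(sprintf(paste0("  mean retention vs parent: %.4f\n",
                     "  panel of %d: P(all lost) = %.3g, ",
                     "P(any retained) = %.6f\n"),
              x$p_retain, x$panel_size, x$p_all_lost, x$p_any_retained))
  if (!is.null(x$empirical_survival))
    cat(sprintf("  empirical survival over %d simulated clones: %.5f\n",
                x$n_clones, x$empirical_survival))
  invisible(x)
}

#' Generate a complete simulated fixture set
#'
#' Writes a normal genome, a tumor genome with spiked somatic variants,
#' the ground-truth VCF, per-clone id tables and a manifest into
#' `out_dir`. Outputs are byte-identical for identical seeds.
#'
#' @param out_dir Output directory.
#' @param genome_length_bp,gc_fraction Background genome parameters.
#' @param burden_per_mb,indel_fraction Spike-in parameters.
#' @param n_clones,clone_p_retain,clone_gain_rate,passages Clone
#'   derivation parameters (defaults emulate ~60 passages at retention
#'   0.81 gaining ~53.5 mutations per passage).
#' @param seed Integer seed (mandatory).
#' @return List with the generated objects, invisibly.
#' @export
run_simulate <- function(out_dir, genome_length_bp = 1e6,
                         gc_fraction = 0.41, burden_per_mb = 1.0,
                         indel_fraction = 817723 / 4803421,
                         n_clones = 0L, clone_p_retain = 0.81,
                         clone_gain_rate = 53.5, passages = 60L, seed) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome <- simulate_genome(genome_length_bp, gc_fraction, seed = seed)
  sp <- spike_somatic_variants(genome, burden_per_mb, indel_fraction,
                               seed = seed + 1L)
  write_fasta(genome, file.path(out_dir, "normal.fa"))
  write_fasta(sp$tumor_genome, file.path(out_dir, "tumor.fa"))
  write_vcf(sp$variants, file.path(out_dir, "truth.vcf"), genome = genome)
  clones <- list()
  if (n_clones > 0L) {
    clones <- lapply(seq_len(n_clones), function(i)
      derive_clone(sp$variants$id, p_retain = clone_p_retain,
                   gain_rate = clone_gain_rate, passages = passages,
                   genome = genome, seed = seed + 1L + i,
                   label = paste0("clone", i)))
    for (cl in clones)
      write.table(data.frame(id = cl$ids),
                  file.path(out_dir, paste0(cl$label, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(genome_length_bp = genome_length_bp,
                   gc_fraction = gc_fraction,
                   burden_per_mb = burden_per_mb,
                   indel_fraction = indel_fraction,
                   n_variants = nrow(sp$variants),
                   n_clones = n_clones, clone_p_retain = clone_p_retain,
                   clone_gain_rate = clone_gain_rate,
                   passages = passages, seed = seed)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(genome = genome, spikein = sp, clones = clones))
}
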