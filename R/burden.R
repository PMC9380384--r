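#' Somatic mutation burden model
#'
#' @param burden_per_mb Somatic mutations per megabase unique to the tumor
#'   (the prostate-cancer cohort figure is 1.0/Mb).
#' @param genome_mb Callable genome size in Mb, default 3000 (human,
#'   order-of-magnitude).
#' @param indel_fraction Fraction of mutations that are indels, default
#'   0.17 (hepatoma whole-genome ratio 817723 / 4803421).
#' @return List of class `burden_model`.
#' @export
burden_model <- function(burden_per_mb = 1.0, genome_mb = 3000,
                         indel_fraction = 817723 / 4803421) {
  stopifnot(burden_per_mb >= 0, genome_mb >= 0,
            indel_fraction >= 0, indel_fraction <= 1)
  structure(list(burden_per_mb = burden_per_mb, genome_mb = genome_mb,
                 indel_fraction = indel_fraction),
            class = "burden_model")
}

#' Monte-Carlo estimate of the suitable-target fraction
#'
#' Estimates the probability that a random somatic mutation yields at
#' least one allele-discriminating, genome-unique guide, by sampling
#' variants uniformly over a background genome and running the nomination,
#' allele-specificity and genome-specificity stages on each. SNVs mutate
#' to a uniform non-reference base; indels occur with probability
#' `indel_fraction` (insertion or deletion with equal probability, lengths
#' geometric(0.5) capped at 10). Panel-composition hard filters (GC,
#' homopolymers) are deliberately not applied: the estimate concerns
#' targetability, not library design.
#'
#' @param genome Background [genome_sequence()], total length >= 100 kb.
#' @param n_samples Number of variants to sample, >= 1000.
#' @param seed Integer seed; the estimate is reproducible given the seed.
#' @param indel_fraction Indel mixture weight, default 0.17.
#' @param config A [design_config()].
#' @param index Optional prebuilt [genome_index()] of `genome`.
#' @return Object of class `suitability_estimate`: `fraction`, exact
#'   binomial 95% `ci_low`/`ci_high`, `n_sampled`, `n_suitable`, `seed`.
#' @export
estimate_suitable_fraction <- function(genome, n_samples, seed,
                                       indel_fraction = 817723 / 4803421,
                                       config = design_config(),
                                       index = NULL) {
  stopifnot(inherits(genome, "genome_sequence"))
  total <- sum(contig_lengths(genome))
  if (total < 1e5) stop("background genome must be at least 100 kb")
  n_samples <- as.integer(n_samples)
  if (n_samples < 1000L) stop("n_samples must be >= 1000")
  variants <- with_seed(seed, sample_variants(genome, n_samples,
                                              indel_fraction))
  if (is.null(index)) index <- genome_index(genome, k = config$index_k)
  ok_classes <- discriminating_classes(config)
  suitable <- logical(n_samples)
  # process in blocks: one batched off-target search per block
  block <- 2000L
  for (lo in seq(1L, n_samples, by = block)) {
    hi <- min(lo + block - 1L, n_samples)
    cands <- design_candidates(genome, variants[lo:hi, , drop = FALSE],
                               config)
    cands <- cands[cands$specificity_class %in% ok_classes, , drop = FALSE]
    cands <- annotate_offtargets(cands, index, config$policy)
    ok <- unique(cands$variant_id[cands$pass])
    suitable[lo:hi] <- variants$id[lo:hi] %in% ok
  }
  k <- sum(suitable)
  ci <- binom.test(k, n_samples)$conf.int
  structure(list(fraction = k / n_samples, ci_low = ci[1L],
                 ci_high = ci[2L], n_sampled = n_samples, n_suitable = k,
                 seed = seed), class = "suitability_estimate")
}

# uniform variant sampler over a genome (assumes RNG already seeded)
sample_variants <- function(genome, n, indel_fraction) {
  lens <- contig_lengths(genome)
  margin <- 12L                      # keep REF alleles inside the contig
  ctg_idx <- sample.int(length(lens), n, replace = TRUE,
                        prob = pmax(lens - 2L * margin, 0))
  contig <- names(lens)[ctg_idx]
  pos <- margin + 1L +
    floor(runif(n) * (lens[ctg_idx] - 2L * margin))
  pos <- as.integer(pos)
  is_indel <- runif(n) < indel_fraction
  is_ins <- is_indel & (runif(n) < 0.5)
  ilen <- pmin(1L + rgeom(n, 0.5), 10L)
  ref <- character(n); alt <- character(n)
  bases <- c("A", "C", "G", "T")
  seqs <- unclass(genome)
  for (i in seq_len(n)) {
    S <- seqs[[contig[i]]]
    b <- substr(S, pos[i], pos[i])
    if (b == "N") { b <- "A" }       # synthetic genomes carry no N anyway
    if (!is_indel[i]) {
      ref[i] <- substr(S, pos[i], pos[i])
      alt[i] <- sample(setdiff(bases, ref[i]), 1L)
    } else if (is_ins[i]) {
      ref[i] <- substr(S, pos[i], pos[i])
      alt[i] <- paste0(ref[i], paste(sample(bases, ilen[i],
                                            replace = TRUE),
                                     collapse = ""))
    } else {
      ref[i] <- substr(S, pos[i], pos[i] + ilen[i])
      alt[i] <- substr(S, pos[i], pos[i])
    }
  }
  somatic_variants(contig, pos, ref, alt)
}

#' @export
print.suitability_estimate <- function(x, ...) {
  cat(sprintf(paste0("<suitability_estimate> %.4f (95%% CI %.4f-%.4f), ",
                     "%d / %d variants suitable, seed %d\n"),
              x$fraction, x$ci_low, x$ci_high, x$n_suitable, x$n_sampled,
              as.integer(x$seed)))
  invisible(x)
}

#' Expected suitable targets per tumor
#'
#' Scales the estimated suitable fraction by the expected mutation count
#' `burden_per_mb * genome_mb`; the interval follows the binomial CI of
#' the fraction. Linear in both the burden and the fraction.
#'
#' @param model A [burden_model()].
#' @param est A [estimate_suitable_fraction()] result (or any list with
#'   `fraction`, `ci_low`, `ci_high`).
#' @return List of class `target_estimate`: `expected_mutations`, `count`,
#'   `ci_low`, `ci_high`.
#' @export
expected_targets <- function(model, est) {
  stopifnot(inherits(model, "burden_model"))
  m <- model$burden_per_mb * model$genome_mb
  structure(list(expected_mutations = m,
                 count = m * est$fraction,
                 ci_low = m * est$ci_low,
                 ci_high = m * est$ci_high), class = "target_estimate")
}

#' @export
print.target_estimate <- function(x, ...) {
  cat(sprintf(paste0("<target_estimate> %.1f suitable target sites ",
                     "(95%% CI %.1f-%.1f) among %.0f expected mutations\n"),
              x$count, x$ci_low, x$ci_high, x$expected_mutations))
  invisible(x)
}

#' Clone variant set
#'
#' @param label Clone/sample label.
#' @param ids Character vector of canonical variant ids (deduplicated).
#' @return List of class `clone_variant_set`.
#' @export
clone_variant_set <- function(label, ids) {
  structure(list(label = as.character(label),
                 ids = unique(as.character(ids))),
            class = "clone_variant_set")
}

as_clone_sets <- function(sets) {
  stopifnot(length(sets) >= 2L)
  out <- vector("list", length(sets))
  for (i in seq_along(sets)) {
    s <- sets[[i]]
    if (inherits(s, "clone_variant_set")) out[[i]] <- s
    else if (is.data.frame(s))
      out[[i]] <- clone_variant_set(names(sets)[i] %||% paste0("set", i),
                                    s$id)
    else out[[i]] <- clone_variant_set(names(sets)[i] %||% paste0("set", i),
                                       s)
  }
  out
}

`%||%` <- function(a, b) {
  if (is.null(a) || length(a) == 0L || is.na(a) || !nzchar(a)) b else a
}

#' Mutation overlap between clones
#'
#' Exact set arithmetic over canonical variant ids. For every ordered pair
#' the earlier set plays the parent: `retained_fraction =
#' |child n parent| / |parent|` and `unique_fraction =
#' |child \ parent| / |child|` (the quantities reported for passaged
#' single-cell clones). Also reports the global core (ids shared by all
#' sets) and union.
#'
#' @param sets List (>= 2) of [clone_variant_set()]s, id vectors, or
#'   [somatic_variants()] tables.
#' @return Object of class `clone_overlap`: `pairwise` data frame,
#'   `n_core`, `n_union`, `labels`.
#' @export
clone_overlap <- function(sets) {
  cs <- as_clone_sets(sets)
  labs <- vapply(cs, `[[`, "", "label")
  n <- length(cs)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- cs[[i]]$ids; b <- cs[[j]]$ids
    common <- length(intersect(a, b))
    rows[[length(rows) + 1L]] <- data.frame(
      parent = labs[i], child = labs[j],
      n_parent = length(a), n_child = length(b),
      n_common = common,
      n_only_parent = length(a) - common,
      n_only_child = length(b) - common,
      retained_fraction = if (length(a)) common / length(a) else NA_real_,
      unique_fraction = if (length(b))
        (length(b) - common) / length(b) else NA_real_,
      stringsAsFactors = FALSE)
  }
  core <- Reduce(intersect, lapply(cs, `[[`, "ids"))
  un <- Reduce(union, lapply(cs, `[[`, "ids"))
  structure(list(pairwise = do.call(rbind, rows),
                 n_core = length(core), n_union = length(un),
                 labels = labs), class = "clone_overlap")
}

#' @export
print.clone_overlap <- function(x, ...) {
  cat("<clone_overlap> ", length(x$labels), " sets; core ", x$n_core,
      ", union ", x$n_union, "\n", sep = "")
  print.data.frame(x$pairwise)
  invisible(x)
}

#' Closed-form panel survival under clonal evolution
#'
#' With each targeted site retained independently with probability
#' `p_retain`, the chance that an `N`-guide panel loses every target is
#' `(1 - p_retain)^N`; the panel survives (retains at least one target)
#' with the complementary probability. Independence across sites is the
#' declared model assumption.
#'
#' @param p_retain Per-site retention probability in `[0, 1]`.
#' @param N Panel size, >= 1.
#' @return List with `p_all_lost` and `p_any_retained`.
#' @examples
#' panel_survival_probability(0.8105, 10)
#' @export
panel_survival_probability <- function(p_retain, N) {
  if (!is.numeric(p_retain) || any(p_retain < 0) || any(p_retain > 1))
    stop("p_retain must be in [0, 1]")
  N <- as.integer(N)
  if (any(is.na(N)) || any(N < 1L)) stop("N must be >= 1")
  p_all_lost <- (1 - p_retain)^N
  list(p_all_lost = p_all_lost, p_any_retained = 1 - p_all_lost)
}

#' Empirical panel survival across simulated clones
#'
#' Fraction of clones that retain at least one of the panel's target
#' mutations. With independent per-site retention this converges to
#' `1 - (1 - p_retain)^N` as the clone count grows.
#'
#' @param panel_ids Character vector of the panel's target variant ids
#'   (an empty panel has survival 0 by convention).
#' @param clones List of [clone_variant_set()]s or id vectors.
#' @return Fraction in `[0, 1]`.
#' @export
panel_survival_empirical <- function(panel_ids, clones) {
  if (length(clones) == 0L) stop("need at least one clone")
  if (length(panel_ids) == 0L) return(0)
  ids <- lapply(clones, function(s)
    if (inherits(s, "clone_variant_set")) s$ids else as.character(s))
  mean(vapply(ids, function(x) any(panel_ids %in% x), logical(1L)))
}
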