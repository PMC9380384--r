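#' Simulate a random background genome
#'
#' Bases are drawn i.i.d. with `P(G) = P(C) = gc_fraction / 2` and
#' `P(A) = P(T) = (1 - gc_fraction) / 2`. Bit-reproducible for a given
#' seed. The default GC content (0.41) matches the human genome.
#'
#' @param length Contig length(s) in bp; a named vector yields a
#'   multi-contig genome, an unnamed one gets contigs `sim1, sim2, ...`.
#'   Each contig must be >= 1000 bp.
#' @param gc_fraction GC content in `[0, 1]`, default 0.41.
#' @param seed Integer seed (mandatory).
#' @return A [genome_sequence()].
#' @examples
#' g <- simulate_genome(2000, gc_fraction = 0.5, seed = 1)
#' @export
simulate_genome <- function(length, gc_fraction = 0.41, seed) {
  stopifnot(all(length >= 1000), gc_fraction >= 0, gc_fraction <= 1)
  nm <- names(length)
  if (is.null(nm)) nm <- paste0("sim", seq_along(length))
  prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
            G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  contigs <- with_seed(seed, vapply(length, function(L)
    paste(sample(names(prob), L, replace = TRUE, prob = prob),
          collapse = ""), character(1L)))
  genome_sequence(setNames(contigs, nm))
}

#' Spike somatic variants into a genome
#'
#' Draws a Poisson(`burden_per_mb` x megabases) number of tumor-unique
#' variants at uniform positions, rejecting positions closer than
#' `min_spacing` (default 50 bp) to an already placed variant so each one
#' gets an unambiguous single-variant haplotype window. SNVs mutate to a
#' uniform non-reference base; indels occur with probability
#' `indel_fraction` (insertion/deletion equiprobable, lengths
#' geometric(0.5) capped at 10, VCF anchor-base convention). The returned
#' tumor genome equals the normal genome with every variant applied.
#'
#' @param genome Normal [genome_sequence()].
#' @param burden_per_mb Mutation burden per Mb, default 1.0.
#' @param indel_fraction Indel mixture weight, default 0.17.
#' @param seed Integer seed (mandatory).
#' @param min_spacing Minimum spacing between spiked variants, default 50.
#' @return List of class `somatic_spikein`: `variants`
#'   ([somatic_variants()]), `tumor_genome`, `normal_genome`, `seed`.
#' @export
spike_somatic_variants <- function(genome, burden_per_mb = 1.0,
                                   indel_fraction = 817723 / 4803421,
                                   seed, min_spacing = 50L) {
  stopifnot(inherits(genome, "genome_sequence"), burden_per_mb >= 0)
  lens <- contig_lengths(genome)
  out <- with_seed(seed, {
    n <- rpois(1L, burden_per_mb * sum(lens) / 1e6)
    margin <- 30L
    placed_ctg <- character(0); placed_pos <- integer(0)
    tries <- 0L
    while (length(placed_pos) < n && tries < 50L * max(n, 1L)) {
      tries <- tries + 1L
      ci <- sample.int(length(lens), 1L, prob = pmax(lens - 2L * margin, 0))
      p <- margin + 1L + floor(runif(1L) * (lens[ci] - 2L * margin))
      same <- placed_ctg == names(lens)[ci]
      if (any(abs(placed_pos[same] - p) < min_spacing)) next
      placed_ctg <- c(placed_ctg, names(lens)[ci])
      placed_pos <- c(placed_pos, as.integer(p))
    }
    if (length(placed_pos) < n)
      warning("spike_somatic_variants: placed ", length(placed_pos),
              " of ", n, " variants (spacing constraint)", call. = FALSE)
    m <- length(placed_pos)
    if (m == 0L) {
      somatic_variants(character(), integer(), character(), character())
    } else {
      is_indel <- runif(m) < indel_fraction
      is_ins <- is_indel & (runif(m) < 0.5)
      ilen <- pmin(1L + rgeom(m, 0.5), 10L)
      bases <- c("A", "C", "G", "T")
      ref <- character(m); alt <- character(m)
      for (i in seq_len(m)) {
        S <- unclass(genome)[[placed_ctg[i]]]
        if (!is_indel[i]) {
          ref[i] <- substr(S, placed_pos[i], placed_pos[i])
          alt[i] <- sample(setdiff(bases, ref[i]), 1L)
        } else if (is_ins[i]) {
          ref[i] <- substr(S, placed_pos[i], placed_pos[i])
          alt[i] <- paste0(ref[i], paste(sample(bases, ilen[i],
                                                replace = TRUE),
                                         collapse = ""))
        } else {
          ref[i] <- substr(S, placed_pos[i], placed_pos[i] + ilen[i])
          alt[i] <- substr(S, placed_pos[i], placed_pos[i])
        }
      }
      somatic_variants(placed_ctg, placed_pos, ref, alt)
    }
  })
  variants <- normalize_variants(out, genome)
  tumor <- apply_variants(genome, variants)
  structure(list(variants = variants, tumor_genome = tumor,
                 normal_genome = genome, seed = seed),
            class = "somatic_spikein")
}

#' @export
print.somatic_spikein <- function(x, ...) {
  cat("<somatic_spikein> ", nrow(x$variants), " variant(s) over ",
      format(sum(contig_lengths(x$normal_genome)), big.mark = ","),
      " bp (seed ", as.integer(x$seed), ")\n", sep = "")
  invisible(x)
}

#' Derive a passaged single-cell clone from a parent mutation set
#'
#' Each parent mutation is retained independently with aggregate
#' probability `p_retain` (endpoint retention, not per-passage), and
#' Poisson(`gain_rate` x `passages`) new mutations are added at fresh loci
#' of the genome. The defaults emulate a clone cultured alone for ~60
#' passages: retention 0.81 and 3208 new mutations over 60 passages
#' (~53.5 per passage).
#'
#' @param parent_ids Character vector of parent variant ids.
#' @param p_retain Aggregate retention probability, default 0.81.
#' @param gain_rate New mutations per passage, default 53.5.
#' @param passages Number of passages, default 60.
#' @param genome [genome_sequence()] used to draw fresh loci for gained
#'   mutations.
#' @param seed Integer seed (mandatory).
#' @param label Clone label.
#' @return A [clone_variant_set()].
#' @export
derive_clone <- function(parent_ids, p_retain = 0.81, gain_rate = 53.5,
                         passages = 60L, genome, seed, label = "clone") {
  stopifnot(p_retain >= 0, p_retain <= 1, gain_rate >= 0, passages >= 0)
  with_seed(seed, {
    keep <- runif(length(parent_ids)) < p_retain
    n_new <- rpois(1L, gain_rate * passages)
    new_ids <- character(0)
    if (n_new > 0L) {
      nv <- sample_variants(genome, n_new, indel_fraction = 0)
      new_ids <- setdiff(nv$id, parent_ids)
    }
    clone_variant_set(label, c(parent_ids[keep], new_ids))
  })
}
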