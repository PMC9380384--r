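# Fixture builders shared across test files. Everything is generated in
# code under fixed seeds; no data files.

rand_dna <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# A contig over {A,T} (no PAM can form) carrying exactly one '+' SpCas9
# frame: protospacer over {A,T} at 1-based [f1, f1+19] and PAM "TGG".
# Returns the genome plus frame bookkeeping.
make_isolated_frame <- function(len = 300L, f1 = 101L, seed = 1L) {
  withr::with_seed(seed, {
    S <- rand_dna(len, c("A", "T"))
    proto <- rand_dna(20L, c("A", "T"))
    substr(S, f1, f1 + 19L) <- proto
    substr(S, f1 + 20L, f1 + 22L) <- "TGG"
    list(genome = genome_sequence(c(chr1 = S)), proto = proto,
         f1 = f1, f0 = f1 - 1L)
  })
}

# SNV in the isolated frame at PAM-proximal protospacer position k;
# the tumor allele swaps A<->T so no new PAM can arise.
snv_at_protopos <- function(frame, k) {
  pos <- frame$f1 + 20L - k            # 1-based genomic position
  b <- substr(unclass(frame$genome)[[1L]], pos, pos)
  somatic_variants("chr1", pos, b, if (b == "A") "T" else "A")
}

# variant whose window/tumor-haplotype machinery is exercised at random:
# SNV at a random position of a random-genome contig
random_snv <- function(genome, seed) {
  withr::with_seed(seed, {
    ctg <- sample(names(genome), 1L)
    L <- nchar(unclass(genome)[[ctg]])
    pos <- sample(seq(40L, L - 40L), 1L)
    b <- substr(unclass(genome)[[ctg]], pos, pos)
    somatic_variants(ctg, pos, b, sample(setdiff(c("A", "C", "G", "T"), b), 1L))
  })
}

write_temp_vcf <- function(lines, dir = tempdir()) {
  path <- tempfile("vars", tmpdir = dir, fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO"), collapse = "\t"),
               lines), path)
  path
}
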