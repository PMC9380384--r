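plant_guide <- function(genome, guide, pam, at) {
  S <- unclass(genome)[[1L]]
  substr(S, at, at + 19L) <- guide
  substr(S, at + 20L, at + 22L) <- pam
  genome_sequence(setNames(S, names(genome)))
}

test_that("a verbatim planted guide is found exactly once at 0 mm", {
  g0 <- simulate_genome(100000, seed = 61)
  guide <- withr::with_seed(62, rand_dna(20))
  g <- plant_guide(g0, guide, "TGG", 5000L)
  h <- find_matches_bruteforce(guide, g, max_mm = 0L)
  expect_equal(nrow(h), 1L)
  expect_equal(h$start, 4999L)
  expect_equal(h$strand, "+")
  expect_equal(h$pam, "TGG")
  hi <- find_matches_indexed(guide, genome_index(g), max_mm = 0L)
  expect_equal(hi[, -1L], h)
})

test_that("a planted guide with an invalid PAM is not a hit", {
  g0 <- simulate_genome(100000, seed = 63)
  guide <- withr::with_seed(64, rand_dna(20))
  g <- plant_guide(g0, guide, "TTT", 5000L)
  expect_equal(nrow(find_matches_bruteforce(guide, g, max_mm = 0L)), 0L)
  expect_equal(nrow(find_matches_indexed(guide, genome_index(g),
                                         max_mm = 0L)), 0L)
})

test_that("searching the reverse-complemented genome mirrors hits", {
  g0 <- simulate_genome(50000, seed = 65)
  guide <- withr::with_seed(66, rand_dna(20))
  g <- plant_guide(g0, guide, "AGG", 12345L)
  h1 <- find_matches_bruteforce(guide, g, max_mm = 3L)
  rc <- genome_revcomp(g)
  h2 <- find_matches_bruteforce(guide, rc, max_mm = 3L)
  expect_equal(nrow(h1), nrow(h2))
  L <- nchar(unclass(g)[[1L]])
  mapped <- data.frame(start = L - 20L - h2$start,
                       strand = ifelse(h2$strand == "+", "-", "+"),
                       mismatches = h2$mismatches, pam = h2$pam,
                       stringsAsFactors = FALSE)
  o1 <- order(h1$start, h1$strand); o2 <- order(mapped$start, mapped$strand)
  expect_equal(h1[o1, c("start", "strand", "mismatches", "pam")],
               mapped[o2, ], ignore_attr = TRUE)
})

test_that("indexed search equals brute force on random guides and genomes", {
  set.seed(67)
  for (rep in 1:3) {
    g <- simulate_genome(30000, gc_fraction = runif(1, 0.3, 0.6),
                         seed = 670 + rep)
    S <- unclass(g)[[1L]]
    idx <- genome_index(g)
    guides <- c(
      # sampled from the genome with 0-3 edits (guaranteed near-hits)
      vapply(1:6, function(i) {
        s <- sample(nchar(S) - 25L, 1L)
        p <- substr(S, s, s + 19L)
        for (k in seq_len(sample(0:3, 1L))) {
          j <- sample(20L, 1L)
          substr(p, j, j) <- sample(setdiff(c("A", "C", "G", "T"),
                                            substr(p, j, j)), 1L)
        }
        p
      }, character(1L)),
      replicate(4, rand_dna(20)))
    for (mm in 0:3) {
      hi <- find_matches_indexed(guides, idx, max_mm = mm)
      for (q in seq_along(guides)) {
        a <- hi[hi$query == q, -1L]
        rownames(a) <- NULL
        b <- find_matches_bruteforce(guides[q], g, max_mm = mm)
        expect_equal(a, b)
      }
    }
  }
})

test_that("max_mm = 0 reduces to exact substring search", {
  g <- simulate_genome(50000, seed = 68)
  S <- unclass(g)[[1L]]
  guide <- substr(S, 777, 796)
  h <- find_matches_indexed(guide, genome_index(g), max_mm = 0L,
                            pam_set = "NGG")
  # oracle: regex scan for the literal guide followed by [ACGT]GG
  m <- gregexpr(paste0("(?=", guide, "[ACGT]GG)"), S, perl = TRUE)[[1L]]
  fwd_starts <- if (m[1L] == -1L) integer() else as.integer(m) - 1L
  rc <- dna_revcomp(guide)
  m2 <- gregexpr(paste0("(?=CC[ACGT]", rc, ")"), S, perl = TRUE)[[1L]]
  rev_starts <- if (m2[1L] == -1L) integer() else as.integer(m2) + 2L
  expect_setequal(h$start[h$strand == "+"], fwd_starts)
  expect_setequal(h$start[h$strand == "-"], rev_starts)
})

test_that("hit counts are monotone in the mismatch budget and PAM set", {
  g <- simulate_genome(40000, seed = 69)
  idx <- genome_index(g)
  guide <- substr(unclass(g)[[1L]], 1001, 1020)
  counts <- vapply(0:4, function(mm)
    nrow(find_matches_indexed(guide, idx, max_mm = mm)), integer(1L))
  expect_true(all(diff(counts) >= 0L))
  n_ngg <- nrow(find_matches_indexed(guide, idx, 3L, pam_set = "NGG"))
  n_both <- nrow(find_matches_indexed(guide, idx, 3L))
  expect_gte(n_both, n_ngg)
})

test_that("tiny and empty-ish genomes are handled", {
  g <- genome_sequence(c(c1 = strrep("A", 30)))
  guide <- paste(rep(c("A", "C"), 10), collapse = "")
  expect_equal(nrow(find_matches_indexed(guide, genome_index(g), 3L)), 0L)
  expect_equal(nrow(find_matches_bruteforce(guide, g, 3L)), 0L)
  g2 <- genome_sequence(c(c1 = "ACGTACGT"))       # shorter than a frame
  expect_equal(nrow(find_matches_bruteforce(guide, g2, 3L)), 0L)
})

test_that("index checksum mismatch is detected", {
  g1 <- simulate_genome(2000, seed = 70)
  g2 <- simulate_genome(2000, seed = 71)
  idx <- genome_index(g1)
  expect_error(find_matches_indexed(strrep("AC", 10), idx, genome = g2),
               "checksum")
})

test_that("genome-specificity filter separates native hits from off-targets", {
  fr <- make_isolated_frame(len = 120000L, f1 = 60001L, seed = 72)
  v <- snv_at_protopos(fr, 5L)
  d <- design_guides(fr$genome, v)
  cand <- d$guides[d$guides$strand == "+", , drop = FALSE][1L, ]
  idx <- genome_index(fr$genome)
  res <- genome_specificity_filter(cand, idx)
  expect_true(res$pass)
  expect_true(res$native_hit_excluded)
  expect_equal(nrow(res$native_hits), 1L)
  expect_equal(res$native_hits$mismatches, 1L)  # the normal allele
  # now plant a perfect second copy elsewhere: hard reject
  g2 <- plant_guide(fr$genome, cand$protospacer, "AGG", 10000L)
  res2 <- genome_specificity_filter(cand, genome_index(g2))
  expect_false(res2$pass)
  expect_true(any(res2$hits$mismatches == 0L))
})

test_that("a PAM_GAIN guide has no NGG hit at its native locus", {
  fr <- make_isolated_frame(len = 120000L, f1 = 60001L, seed = 73)
  S <- unclass(fr$genome)[[1L]]
  substr(S, fr$f1 + 20L, fr$f1 + 22L) <- "TAG"
  g <- genome_sequence(c(chr1 = S))
  v <- somatic_variants("chr1", fr$f1 + 21L, "A", "G", genome = g)
  d <- design_guides(g, v)
  pg <- d$guides[d$guides$specificity_class == "PAM_GAIN" &
                   d$guides$strand == "+", , drop = FALSE][1L, ]
  res <- genome_specificity_filter(pg, genome_index(g),
                                   offtarget_policy(pam_set = "NGG"))
  expect_equal(nrow(res$native_hits), 0L)
  expect_true(res$pass)
})
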