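test_that("seed SNVs discriminate, PAM-distal SNVs do not", {
  fr <- make_isolated_frame(seed = 51)
  # position 5: in the 12-nt seed
  v5 <- snv_at_protopos(fr, 5L)
  w5 <- haplotype_window(v5, fr$genome)
  c5 <- nominate_candidates(w5)
  c5 <- c5[c5$strand == "+", , drop = FALSE]
  call5 <- classify_candidate(c5, w5, seed_len = 12L)
  expect_identical(call5$class, "SEED_DISCRIMINATING")
  expect_identical(call5$normal_mismatch_positions, 5L)
  expect_true(call5$normal_pam_intact)

  # position 18: outside the seed
  v18 <- snv_at_protopos(fr, 18L)
  w18 <- haplotype_window(v18, fr$genome)
  c18 <- nominate_candidates(w18)
  c18 <- c18[c18$strand == "+", , drop = FALSE]
  call18 <- classify_candidate(c18, w18, seed_len = 12L)
  expect_identical(call18$class, "NON_DISCRIMINATING")
  expect_identical(call18$normal_mismatch_positions, 18L)
})

test_that("a PAM-creating SNV is PAM_GAIN with no protospacer mismatch", {
  fr <- make_isolated_frame(seed = 52)
  S <- unclass(fr$genome)[[1L]]
  substr(S, fr$f1 + 20L, fr$f1 + 22L) <- "TAG"   # normal lacks the GG
  g <- genome_sequence(c(chr1 = S))
  v <- somatic_variants("chr1", fr$f1 + 21L, "A", "G", genome = g)
  w <- haplotype_window(v, g)
  cand <- nominate_candidates(w)
  cand <- cand[cand$strand == "+" & cand$protospacer == fr$proto, ,
               drop = FALSE]
  expect_equal(nrow(cand), 1L)
  call <- classify_candidate(cand, w, seed_len = 12L)
  expect_identical(call$class, "PAM_GAIN")
  expect_identical(call$normal_mismatch_positions, integer(0))
  expect_false(call$normal_pam_intact)
})

test_that("an indel intersecting the frame is INDEL_DISRUPTING with a frame-shift sentinel", {
  # 2-bp deletion whose junction sits between protospacer positions 10 and 9
  fr <- make_isolated_frame(seed = 53)
  S <- unclass(fr$genome)[[1L]]
  anchor <- fr$f1 + 10L                 # protospacer position 10 (1-based)
  tumor_like <- fr$genome
  normal <- paste0(substr(S, 1L, anchor), "CC",
                   substr(S, anchor + 1L, nchar(S)))
  gn <- genome_sequence(c(chr1 = normal))
  v <- somatic_variants("chr1", anchor, substr(normal, anchor, anchor + 2L),
                        substr(normal, anchor, anchor), genome = gn)
  v <- normalize_variants(v, gn)
  w <- haplotype_window(v, gn)
  cand <- nominate_candidates(w)
  expect_gt(nrow(cand), 0L)
  for (i in seq_len(nrow(cand))) {
    one <- cand[i, , drop = FALSE]
    nm <- native_locus_mismatches(one, w)
    expect_true(nm$frame_shifted)
    expect_identical(nm$positions, Inf)
    call <- classify_candidate(one, w, seed_len = 12L)
    expect_identical(call$class, "INDEL_DISRUPTING")
  }
  # the deleted junction is spanned: the planted frame is recovered intact
  expect_true(any(cand$protospacer == fr$proto))
})

test_that("an MNV reports every altered protospacer position", {
  fr <- make_isolated_frame(seed = 54)
  S <- unclass(fr$genome)[[1L]]
  # alter protospacer positions 2 and 14 via one MNV covering 13 bases
  p2 <- fr$f1 + 20L - 2L; p14 <- fr$f1 + 20L - 14L
  ref <- substr(S, p14, p2)
  alt <- ref
  flip <- function(b) if (b == "A") "T" else "A"
  substr(alt, 1L, 1L) <- flip(substr(ref, 1L, 1L))
  nc <- nchar(alt)
  substr(alt, nc, nc) <- flip(substr(ref, nc, nc))
  v <- somatic_variants("chr1", p14, ref, alt, genome = fr$genome)
  w <- haplotype_window(v, fr$genome)
  cand <- nominate_candidates(w)
  cand <- cand[cand$strand == "+" &
                 cand$tumor_start + w$window_start == fr$f0, ,
               drop = FALSE]
  expect_equal(nrow(cand), 1L)
  nm <- native_locus_mismatches(cand, w)
  expect_identical(nm$positions, c(2L, 14L))
  expect_true(nm$normal_pam_intact)
  call <- classify_candidate(cand, w, seed_len = 12L)
  expect_identical(call$class, "SEED_DISCRIMINATING")
})

test_that("classes are total, exclusive, and seed calls respect seed_len", {
  classes <- c("PAM_GAIN", "INDEL_DISRUPTING", "SEED_DISCRIMINATING",
               "NON_DISCRIMINATING")
  g <- simulate_genome(30000, seed = 55)
  sp <- spike_somatic_variants(g, burden_per_mb = 400, indel_fraction = 0.3,
                               seed = 56)
  n_calls <- 0L
  for (i in seq_len(nrow(sp$variants))) {
    v <- sp$variants[i, , drop = FALSE]
    w <- haplotype_window(v, g)
    cand <- nominate_candidates(w)
    for (j in seq_len(nrow(cand))) {
      call <- classify_candidate(cand[j, , drop = FALSE], w, seed_len = 12L)
      expect_true(call$class %in% classes)          # totality
      expect_length(call$class, 1L)                 # exclusivity
      if (call$class == "SEED_DISCRIMINATING")
        expect_lte(min(call$normal_mismatch_positions), 12L)
      n_calls <- n_calls + 1L
    }
  }
  expect_gt(n_calls, 10L)
})

test_that("lowering seed_len never converts NON_DISCRIMINATING to SEED", {
  g <- simulate_genome(30000, seed = 57)
  sp <- spike_somatic_variants(g, burden_per_mb = 400, seed = 58)
  for (i in seq_len(nrow(sp$variants))) {
    v <- sp$variants[i, , drop = FALSE]
    w <- haplotype_window(v, g)
    cand <- nominate_candidates(w)
    for (j in seq_len(nrow(cand))) {
      c12 <- classify_candidate(cand[j, , drop = FALSE], w, seed_len = 12L)
      c8 <- classify_candidate(cand[j, , drop = FALSE], w, seed_len = 8L)
      if (c12$class == "NON_DISCRIMINATING")
        expect_identical(c8$class, "NON_DISCRIMINATING")
      if (c8$class == "SEED_DISCRIMINATING")
        expect_identical(c12$class, "SEED_DISCRIMINATING")
    }
  }
})

test_that("candidate/window mismatches are rejected", {
  fr <- make_isolated_frame(seed = 59)
  v1 <- snv_at_protopos(fr, 5L)
  v2 <- snv_at_protopos(fr, 6L)
  w1 <- haplotype_window(v1, fr$genome)
  w2 <- haplotype_window(v2, fr$genome)
  c1 <- nominate_candidates(w1)
  expect_error(classify_candidate(c1[1L, , drop = FALSE], w2),
               "does not belong")
})
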