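# naive frame enumeration used as the completeness oracle
scan_pam_oracle <- function(seq) {
  L <- nchar(seq)
  out <- list()
  for (f in 0:(L - 23L)) {
    frame <- substr(seq, f + 1L, f + 23L)
    if (grepl("N", frame, fixed = TRUE)) next
    if (substr(frame, 22L, 23L) == "GG")
      out[[length(out) + 1L]] <- data.frame(frame_start = f, strand = "+",
                                            stringsAsFactors = FALSE)
    if (substr(frame, 1L, 2L) == "CC")
      out[[length(out) + 1L]] <- data.frame(frame_start = f, strand = "-",
                                            stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(frame_start = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  df <- do.call(rbind, out)
  df <- df[order(df$frame_start, df$strand), ]
  rownames(df) <- NULL
  df
}

test_that("single constructed frames are found on either strand", {
  proto <- "ATGCATGCATGCATGCATGC"
  f <- scan_pam_sites(paste0(proto, "AGG"))
  expect_equal(nrow(f), 1L)
  expect_equal(f$frame_start, 0L)
  expect_equal(f$strand, "+")

  r <- scan_pam_sites(paste0("CCT", proto))
  expect_equal(nrow(r), 1L)
  expect_equal(r$strand, "-")
})

test_that("PAM scan matches the naive oracle and is strand-symmetric", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      seq <- rand_dna(400)
      got <- scan_pam_sites(seq)
      expect_equal(got, scan_pam_oracle(seq))
      # mirror: frames of the reverse complement map to flipped strands
      rc <- dna_revcomp(seq)
      mir <- scan_pam_sites(rc)
      L <- nchar(seq)
      mapped <- data.frame(frame_start = L - 23L - mir$frame_start,
                           strand = ifelse(mir$strand == "+", "-", "+"),
                           stringsAsFactors = FALSE)
      mapped <- mapped[order(mapped$frame_start, mapped$strand), ]
      rownames(mapped) <- NULL
      expect_equal(got, mapped)
    }
  })
})

test_that("frames containing N are excluded", {
  seq <- paste0("ATGCATGCATNCATGCATGC", "AGG")
  expect_equal(nrow(scan_pam_sites(seq)), 0L)
})

test_that("a variant without nearby PAM yields no candidates", {
  fr <- make_isolated_frame(seed = 43)
  # variant far from the only frame
  S <- unclass(fr$genome)[[1L]]
  pos <- fr$f1 + 120L
  b <- substr(S, pos, pos)
  v <- somatic_variants("chr1", pos, b, if (b == "A") "T" else "A")
  w <- haplotype_window(v, fr$genome)
  expect_equal(nrow(nominate_candidates(w)), 0L)
})

test_that("a PAM-creating SNV is nominated with a PAM variant position", {
  fr <- make_isolated_frame(seed = 44)
  S <- unclass(fr$genome)[[1L]]
  # break the planted PAM back to TAG in the normal genome, then let the
  # somatic A>G re-create the middle G of TGG
  substr(S, fr$f1 + 20L, fr$f1 + 22L) <- "TAG"
  g <- genome_sequence(c(chr1 = S))
  v <- somatic_variants("chr1", fr$f1 + 21L, "A", "G", genome = g)
  w <- haplotype_window(v, g)
  cand <- nominate_candidates(w)
  expect_gt(nrow(cand), 0L)
  has_pam_pos <- vapply(cand$variant_positions, function(p) any(p > 20L),
                        logical(1L))
  expect_true(any(has_pam_pos))
})

test_that("every nominated protospacer+PAM is conserved in the tumor window", {
  genomes <- lapply(1:20, function(i) simulate_genome(3000, seed = 400 + i))
  n_checked <- 0L
  for (i in seq_along(genomes)) {
    g <- genomes[[i]]
    v <- random_snv(g, seed = 500 + i)
    w <- haplotype_window(v, g)
    cand <- nominate_candidates(w)
    for (j in seq_len(nrow(cand))) {
      f <- cand$tumor_start[j]
      frame <- substr(w$tumor_seq, f + 1L, f + 23L)
      expected <- if (cand$strand[j] == "+")
        paste0(cand$protospacer[j], cand$pam[j])
      else paste0(dna_revcomp(cand$pam[j]),
                  dna_revcomp(cand$protospacer[j]))
      expect_identical(frame, expected)
      expect_gt(length(cand$variant_positions[[j]]), 0L)
      expect_match(cand$pam[j], "^[ACGT]GG$")
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 10L)
})

test_that("nomination mirrors under reverse complement of the window", {
  fr <- make_isolated_frame(seed = 46)
  v <- snv_at_protopos(fr, 7L)
  w <- haplotype_window(v, fr$genome)
  cand <- nominate_candidates(w)

  grc <- genome_revcomp(fr$genome)
  L <- nchar(unclass(fr$genome)[[1L]])
  vrc <- somatic_variants("chr1", L - v$pos + 1L, dna_revcomp(v$ref),
                          dna_revcomp(v$alt), genome = grc)
  wrc <- haplotype_window(vrc, grc)
  crc <- nominate_candidates(wrc)
  expect_equal(nrow(cand), nrow(crc))
  expect_setequal(crc$protospacer, cand$protospacer)
  expect_setequal(crc$strand, ifelse(cand$strand == "+", "-", "+"))
})

test_that("insertions fully containing a frame mark it within-insertion", {
  S <- strrep("AT", 150)
  g <- genome_sequence(c(c1 = S))
  ins_seq <- paste0("GCTTACGATCGATTACGGCTAGCTAAGG", "TCAGT")  # >23nt + PAM
  v <- somatic_variants("c1", 101L, substr(S, 101, 101),
                        paste0(substr(S, 101, 101), ins_seq), genome = g)
  w <- haplotype_window(v, g)
  cand <- nominate_candidates(w)
  expect_gt(nrow(cand), 0L)
  expect_true(any(cand$within_insertion))
  expect_true(all(is.na(cand$cut_pos_0based[cand$within_insertion])))
})
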