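test_that("no PAM can arise on an all-A genome: suitable fraction is zero", {
  g <- genome_sequence(c(c1 = strrep("A", 100000)))
  est <- estimate_suitable_fraction(g, n_samples = 1000L, seed = 91,
                                    indel_fraction = 0,
                                    config = design_config(seed_len = 0L))
  expect_equal(est$fraction, 0)
  expect_equal(est$ci_low, 0)
})

test_that("the estimate is reproducible for a fixed seed", {
  g <- simulate_genome(120000, seed = 92)
  e1 <- estimate_suitable_fraction(g, 1000L, seed = 93)
  e2 <- estimate_suitable_fraction(g, 1000L, seed = 93)
  expect_identical(e1$fraction, e2$fraction)
  expect_identical(e1$n_suitable, e2$n_suitable)
  expect_true(e1$ci_low <= e1$fraction && e1$fraction <= e1$ci_high)
})

test_that("the estimate is strand-symmetric within its confidence interval", {
  g <- simulate_genome(150000, seed = 94)
  e1 <- estimate_suitable_fraction(g, 1500L, seed = 95)
  e2 <- estimate_suitable_fraction(genome_revcomp(g), 1500L, seed = 95)
  # overlapping 95% CIs
  expect_lte(max(e1$ci_low, e2$ci_low), min(e1$ci_high, e2$ci_high))
})

test_that("expected targets scale linearly in burden and fraction", {
  est <- list(fraction = 0.5, ci_low = 0.45, ci_high = 0.55)
  t1 <- expected_targets(burden_model(1.0, 3000), est)
  expect_equal(t1$expected_mutations, 3000)
  expect_equal(t1$count, 1500)
  t2 <- expected_targets(burden_model(2.0, 3000), est)
  expect_equal(t2$count, 2 * t1$count)
  t0 <- expected_targets(burden_model(1.0, 3000),
                         list(fraction = 0, ci_low = 0, ci_high = 0))
  expect_equal(t0$count, 0)
})

test_that("binomial CI width shrinks like 1/sqrt(n)", {
  g <- simulate_genome(120000, seed = 96)
  idx <- genome_index(g)
  w <- vapply(c(1000L, 4000L), function(n) {
    e <- estimate_suitable_fraction(g, n, seed = 97, index = idx)
    e$ci_high - e$ci_low
  }, numeric(1L))
  expect_equal(w[1L] / w[2L], 2, tolerance = 0.25)
})

test_that("clone overlap reports exact set arithmetic", {
  a <- clone_variant_set("parent", paste0("m", 1:100))
  b <- clone_variant_set("child", paste0("m", c(31:100, 201:240)))
  ov <- clone_overlap(list(a, b))
  pw <- ov$pairwise
  expect_equal(pw$n_common, 70L)
  expect_equal(pw$n_only_parent, 30L)
  expect_equal(pw$n_only_child, 40L)
  expect_equal(pw$n_common + pw$n_only_parent, pw$n_parent)
  expect_equal(pw$retained_fraction, 0.70)
  expect_equal(pw$unique_fraction, 40 / 110)
  # identical sets
  ov2 <- clone_overlap(list(a, a))
  expect_equal(ov2$pairwise$retained_fraction, 1)
  expect_equal(ov2$pairwise$unique_fraction, 0)
  expect_error(clone_overlap(list(a)), "length")
})

test_that("overlap identities hold on fuzzed id sets", {
  withr::with_seed(98, {
    for (rep in 1:20) {
      a <- clone_variant_set("a", sample(paste0("x", 1:500),
                                         sample(0:300, 1L)))
      b <- clone_variant_set("b", sample(paste0("x", 1:500),
                                         sample(1:300, 1L)))
      pw <- clone_overlap(list(a, b))$pairwise
      expect_equal(pw$n_common + pw$n_only_parent, pw$n_parent)
      expect_equal(pw$n_common + pw$n_only_child, pw$n_child)
    }
  })
})

test_that("global core of three clones matches a brute-force membership oracle", {
  withr::with_seed(99, {
    parent <- paste0("m", 1:2000)
    clones <- lapply(1:3, function(i)
      clone_variant_set(paste0("c", i),
                        c(sample(parent, 1500L),
                          paste0("new", i, "_", 1:200))))
  })
  ov <- clone_overlap(clones)
  ids <- unique(unlist(lapply(clones, `[[`, "ids")))
  in_all <- vapply(ids, function(x)
    all(vapply(clones, function(cl) x %in% cl$ids, logical(1L))),
    logical(1L))
  expect_equal(ov$n_core, sum(in_all))
  expect_equal(ov$n_union, length(ids))
})

test_that("closed-form panel survival follows the independence model", {
  expect_equal(panel_survival_probability(1, 10)$p_all_lost, 0)
  expect_equal(panel_survival_probability(0.3, 1)$p_all_lost, 0.7)
  s <- panel_survival_probability(0.8105, 10)
  expect_equal(s$p_all_lost, (1 - 0.8105)^10)
  expect_lt(s$p_all_lost, 1e-7)        # "extremely low"
  expect_equal(s$p_any_retained, 1 - (0.1895)^10)
  expect_error(panel_survival_probability(1.2, 5), "p_retain")
  expect_error(panel_survival_probability(0.5, 0), "N")
})

test_that("empirical survival has the right degenerate behaviour", {
  parent <- paste0("m", 1:50)
  clones <- replicate(20, clone_variant_set("c", parent), simplify = FALSE)
  expect_equal(panel_survival_empirical(parent[1:5], clones), 1)
  expect_equal(panel_survival_empirical(character(0), clones), 0)
  none <- replicate(5, clone_variant_set("c", "other"), simplify = FALSE)
  expect_equal(panel_survival_empirical(parent[1:5], none), 0)
})

test_that("empirical survival recovers the closed form on simulated clones", {
  g <- simulate_genome(50000, seed = 100)
  parent <- paste0("m", 1:40)
  panel <- parent[1:5]
  p <- 0.8
  clones <- lapply(1:2000, function(i)
    derive_clone(parent, p_retain = p, gain_rate = 0, passages = 1L,
                 genome = g, seed = 1000L + i))
  emp <- panel_survival_empirical(panel, clones)
  theo <- panel_survival_probability(p, 5L)$p_any_retained
  se <- sqrt(theo * (1 - theo) / 2000)
  expect_lt(abs(emp - theo), 3 * se + 1e-12)
})
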