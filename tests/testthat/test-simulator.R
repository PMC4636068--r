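test_that("variant simulation hits the expected count, balance and flags", {
  cfg0 <- sim_config("fast", snv_density = 0, seed = 1L)
  sim0 <- simulate_variants(cfg0)
  expect_equal(nrow(sim0$variants), 0L)

  cfg <- sim_config("fast", locus_length = 3.5e6, snv_density = 9400 / 3.5e6,
                    seed = 2L)
  sim <- simulate_variants(cfg)
  expect_equal(nrow(sim$variants), 9400L)
  expect_true(all(diff(sim$variants$pos) > 0))
  expect_true(all(sim$haplotypes$hapA + sim$haplotypes$hapB == 1L))

  # fair-coin truth bits: mean within 3 sigma of 0.5 at n = 10,000
  cfg2 <- sim_config("fast", locus_length = 1e6, snv_density = 1e-2,
                     seed = 3L)
  sim2 <- simulate_variants(cfg2)
  n <- nrow(sim2$variants)
  expect_equal(n, 10000L)
  expect_lt(abs(mean(sim2$haplotypes$hapA) - 0.5), 3 * sqrt(0.25 / n))

  # density flags live in the top-decile 2 kb windows
  flagged <- sim$variants$density_flag
  expect_gt(mean(flagged), 0.05)
  expect_lt(mean(flagged), 0.5)
})

test_that("contact spans follow the truncated power law", {
  cfg <- sim_config("fast", seed = 5L, decay_exponent = 1.08,
                    min_span = 2000, locus_length = 1e6)
  set.seed(99)
  s <- haplotarget:::sample_truncated_powerlaw(50000, 1.08, 2000, 1e6)
  # closed-form CDF of the truncated power law
  a <- 2000; b <- 1e6; e <- 1 - 1.08
  F <- function(x) (x^e - a^e) / (b^e - a^e)
  ks <- max(abs(stats::ecdf(s)(s) - F(s)))
  expect_lt(ks, 0.02)
  expect_true(all(s >= a & s <= b))
})

test_that("noise-free fragments are consistent with a single homolog", {
  cfg <- sim_config("fast", seed = 7L, htrans_rate = 0, seq_error = 0,
                    n_fragments = 3000)
  sim <- simulate_variants(cfg)
  fr <- simulate_proximity_fragments(cfg, sim$variants, sim$haplotypes)
  hapA <- sim$haplotypes$hapA
  sp <- split(seq_len(nrow(fr$obs)), fr$obs$frag)
  ok <- vapply(sp, function(ix) {
    mm <- sum(fr$obs$allele[ix] != hapA[fr$obs$var[ix] + 1L])
    mm == 0L || mm == length(ix)
  }, TRUE)
  expect_true(all(ok))
})

test_that("htrans_rate = 1 makes every cross-end pair h-trans", {
  cfg <- sim_config("fast", seed = 8L, htrans_rate = 1, seq_error = 0,
                    snv_density = 5e-4, n_fragments = 1e5)
  sim <- simulate_variants(cfg)
  fr <- simulate_proximity_fragments(cfg, sim$variants, sim$haplotypes)
  pr <- haplotarget:::classify_pairs(fr, sim$haplotypes$hapA)
  cross <- pr[!pr$same_end, , drop = FALSE]
  expect_gt(nrow(cross), 50L)
  # every pair joining the two read ends links the two homologs ...
  expect_true(all(cross$htrans))
  # ... while pairs within one contiguous read stay cis
  expect_true(all(!pr$htrans[pr$same_end]))
})

test_that("recorded h-trans fraction converges to the configured rate", {
  cfg <- sim_config("fast", seed = 9L, htrans_rate = 0.05, seq_error = 0,
                    n_fragments = 20000)
  sim <- simulate_variants(cfg)
  fr <- simulate_proximity_fragments(cfg, sim$variants, sim$haplotypes)
  p <- mean(fr$frags$htrans)
  n <- nrow(fr$frags)
  expect_lt(abs(p - 0.05), 3 * sqrt(0.05 * 0.95 / n))

  # and the observation-pair h-trans ratio vs generative truth matches the
  # simulator's own cross-end h-trans pair fraction
  pr <- haplotarget:::classify_pairs(fr, sim$haplotypes$hapA)
  cross <- pr[!pr$same_end, , drop = FALSE]
  frac_rec <- mean(fr$frags$htrans[match(cross$frag, fr$frags$id)])
  expect_lt(abs(mean(cross$htrans) - frac_rec),
            3 * sqrt(0.05 / nrow(cross)) + 1e-9)
})

test_that("capture keeps on-target fragments and thins the rest by 1/F", {
  cfg <- sim_config("fast", seed = 10L, n_fragments = 10000,
                    enrichment_fold = 50)
  sim <- simulate_variants(cfg)
  fr <- simulate_proximity_fragments(cfg, sim$variants, sim$haplotypes)

  cfg1 <- sim_config("fast", seed = 10L, n_fragments = 10000,
                     enrichment_fold = 1)
  loc <- synthetic_locus(1e5, seed = 1)
  ps <- design_probes(loc)
  cap1 <- apply_capture(fr, ps, cfg1)
  expect_equal(nrow(cap1$frags), nrow(fr$frags))

  # no probes at all: retention rate ~ 1/F (binomial check at n = 10,000)
  empty_ps <- tile_probes(haplotarget:::iv_empty(), 120L, 4L)
  cap0 <- apply_capture(fr, empty_ps, cfg)
  p <- nrow(cap0$frags) / nrow(fr$frags)
  expect_lt(abs(p - 1 / 50), 3 * sqrt((1 / 50) * (49 / 50) / 10000))
})

test_that("LFR fragments are single-homolog and cover as expected", {
  cfg <- sim_config("fast", seed = 11L, seq_error = 0, lfr_length = 2e6,
                    lfr_n = 5)
  sim <- simulate_variants(cfg)
  lfr <- simulate_lfr_fragments(cfg, sim$variants, sim$haplotypes)
  # lfr_length >= locus: every fragment covers all variants
  expect_true(all(table(lfr$obs$frag) == nrow(sim$variants)))
  hapA <- sim$haplotypes$hapA
  sp <- split(seq_len(nrow(lfr$obs)), lfr$obs$frag)
  ok <- vapply(sp, function(ix) {
    mm <- sum(lfr$obs$allele[ix] != hapA[lfr$obs$var[ix] + 1L])
    mm == 0L || mm == length(ix)
  }, TRUE)
  expect_true(all(ok))

  cfg2 <- sim_config("fast", seed = 12L, lfr_length = 10000, lfr_n = 1000)
  lfr2 <- simulate_lfr_fragments(cfg2, sim$variants, sim$haplotypes)
  expected <- cfg2$lfr_n * cfg2$lfr_length / cfg2$locus_length
  per_var <- tabulate(lfr2$obs$var + 1L, nbins = nrow(sim$variants))
  expect_lt(abs(mean(per_var) - expected) / expected, 0.05)
})

test_that("planted truth errors flip only flagged variants at the set rate", {
  cfg <- sim_config("fast", seed = 13L, planted_error_fraction = 0)
  sim <- simulate_variants(cfg)
  r0 <- plant_truth_errors(sim$variants, sim$haplotypes, cfg)
  expect_equal(r0$haplotypes$hapA, sim$haplotypes$hapA)
  expect_length(r0$flipped, 0L)

  cfg1 <- sim_config("fast", seed = 13L, planted_error_fraction = 1)
  r1 <- plant_truth_errors(sim$variants, sim$haplotypes, cfg1)
  expect_setequal(r1$flipped, sim$variants$index[sim$variants$density_flag])

  # binomial 99% interval at fraction 0.1
  cfg2 <- sim_config("fast", seed = 13L, planted_error_fraction = 0.1)
  r2 <- plant_truth_errors(sim$variants, sim$haplotypes, cfg2)
  n_flag <- sum(sim$variants$density_flag)
  k <- length(r2$flipped)
  ci <- qbinom(c(0.005, 0.995), n_flag, 0.1)
  expect_true(k >= ci[1] && k <= ci[2])
  expect_true(all(r2$flipped %in% sim$variants$index[sim$variants$density_flag]))
})

test_that("the simulator is byte-deterministic under a fixed seed", {
  cfg <- sim_config("fast", seed = 14L, n_fragments = 5000,
                    locus_length = 2e5, snv_density = 5e-4)
  ds1 <- simulate_dataset(cfg)
  ds2 <- simulate_dataset(cfg)
  f1 <- tempfile(); f2 <- tempfile()
  write_fragments(ds1$fragments, f1)
  write_fragments(ds2$fragments, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("design evaluation ranks a probe-less design no better than 4X", {
  cfg <- sim_config("fast", seed = 15L, n_fragments = 40000,
                    locus_length = 2e5, snv_density = 2700 / 1e6)
  loc <- synthetic_locus(2e5, seed = 25L)
  ps4 <- design_probes(loc)
  none <- tile_probes(haplotarget:::iv_empty(), 120L, 4L)
  tab <- evaluate_design(cfg, list(none = none, x4 = ps4, x4b = ps4),
                         locus = loc)
  expect_lte(tab$resolution[tab$design == "none"],
             tab$resolution[tab$design == "x4"])
  # identical designs give identical results under the fixed seed
  expect_equal(tab$resolution[tab$design == "x4"],
               tab$resolution[tab$design == "x4b"])
  expect_equal(tab$mec[tab$design == "x4"], tab$mec[tab$design == "x4b"])
})
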