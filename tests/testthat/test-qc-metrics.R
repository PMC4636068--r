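test_that("h-trans ratio is zero for consistent data and counts planted flips", {
  hapA <- c(0L, 1L, 0L, 1L)
  m <- diploid_matrix(hapA, list(0:1, 1:2, 2:3, c(0L, 2L)),
                      source_hap = c(0L, 1L, 0L, 1L))
  v <- haplotarget:::new_variant_table(pos = c(10, 20, 30, 40),
                                       ref = "A", alt = "G")
  rep0 <- htrans_report(m, hapA, v, locus_length = 100)
  expect_equal(rep0$htrans_ratio, 0)

  # flip the reported phase of variant 2: every pair covering it is h-trans
  rep_hap <- hapA; rep_hap[3] <- 1L - rep_hap[3]
  rep1 <- htrans_report(m, rep_hap, v, locus_length = 100)
  covering <- 3L  # pairs (1,2), (2,3), (0,2)
  expect_equal(rep1$n_htrans, covering)
  expect_equal(rep1$htrans_ratio, covering / rep1$n_informative)
})

test_that("h-trans ratio estimates the simulated rate within binomial CI", {
  cfg <- sim_config("fast", seed = 61L, htrans_rate = 0.05, seq_error = 0,
                    n_fragments = 2e5, snv_density = 5e-4)
  # sparse variants: reads cover <= 1 site, so every pair is cross-end and
  # pair-level h-trans equals fragment-level h-trans
  sim <- simulate_variants(cfg)
  fr <- simulate_proximity_fragments(cfg, sim$variants, sim$haplotypes)
  rep <- htrans_report(fr, sim$haplotypes$hapA, sim$variants,
                       cfg$locus_length)
  n <- rep$n_informative
  expect_gt(n, 200L)
  # same-end pairs are cis by construction, so the pair-level expectation
  # is tau scaled by the cross-end pair fraction
  pr <- haplotarget:::classify_pairs(fr, sim$haplotypes$hapA)
  expected <- mean(!pr$same_end) * 0.05
  expect_lt(abs(rep$htrans_ratio - expected), 3 * sqrt(expected / n))
})

test_that("concordance filter blacklists a planted flip and nothing else", {
  set.seed(70)
  hapA <- rep(c(0L, 1L), 10)
  n <- length(hapA)
  pl <- diploid_matrix(hapA,
                       lapply(1:40, function(i) {
                         a <- sample(0:(n - 2), 1); c(a, a + 1L)
                       }),
                       source_hap = rep(0:1, 20))
  lfr <- diploid_matrix(hapA, rep(list(0:(n - 1L)), 4),
                        source_hap = c(0L, 1L, 0L, 1L))
  v <- haplotarget:::new_variant_table(pos = seq_len(n) * 10,
                                       ref = "A", alt = "G")
  rep_ok <- htrans_report(pl, hapA, v, locus_length = 300)
  expect_equal(concordance_filter(rep_ok, lfr, hapA), integer(0))

  bad <- hapA; bad[8] <- 1L - bad[8]
  rep_bad <- htrans_report(pl, bad, v, locus_length = 300)
  bl <- concordance_filter(rep_bad, lfr, bad)
  expect_equal(bl, 7L)
})

test_that("filter recall and precision are high on planted truth errors", {
  cfg <- sim_config("fast", seed = 62L, planted_error_fraction = 0.1)
  ds <- simulate_dataset(cfg)
  ht <- htrans_report(ds$fragments, ds$reported$haplotypes$hapA,
                      ds$variants, cfg$locus_length)
  bl <- concordance_filter(ht, ds$lfr, ds$reported$haplotypes$hapA)
  planted <- ds$reported$flipped
  expect_gt(length(planted), 20L)
  recall <- mean(planted %in% bl)
  precision <- mean(bl %in% planted)
  expect_gte(recall, 0.8)
  expect_gte(precision, 0.9)
})

test_that("phasing evaluation matches the worked example and is flip-invariant", {
  n <- 10L
  truth <- rep(0L, n)
  mk_result <- function(phase) {
    structure(list(assign = data.frame(var = 0:(n - 1L), block = 0L,
                                       phase = phase, support = 10,
                                       source = "mec"),
                   phase = phase,
                   blocks = data.frame(block_id = 0L, n_members = n,
                                       span = n - 1),
                   mec_score = 0L, unresolved = integer(0),
                   n_variants = n), class = "phasing_result")
  }
  v <- haplotarget:::new_variant_table(pos = seq_len(n) * 10,
                                       ref = "A", alt = "G")
  ph <- rep(0L, n); ph[4] <- 1L
  ev <- evaluate_phasing(mk_result(ph), truth, v)
  expect_equal(ev$resolution, 1.0)
  expect_equal(ev$accuracy, 0.9)
  expect_equal(ev$switch_error, 2 / 9)

  perf <- evaluate_phasing(mk_result(rep(0L, n)), truth, v)
  expect_equal(perf$accuracy, 1.0)
  expect_equal(perf$switch_error, 0)

  flipped <- evaluate_phasing(mk_result(1L - ph), truth, v)
  expect_equal(flipped$accuracy, ev$accuracy)
  expect_equal(flipped$switch_error, ev$switch_error)

  # blacklisting the wrong variant removes it from both sides of accuracy
  ev_bl <- evaluate_phasing(mk_result(ph), truth, v, blacklist = 3L)
  expect_equal(ev_bl$accuracy, 1.0)
  expect_equal(ev_bl$n_excluded, 1L)
})

test_that("gene-level evaluation counts per-gene hets and correctness", {
  n <- 6L
  truth <- rep(0L, n)
  ph <- rep(0L, n); ph[2] <- 1L
  res <- structure(list(assign = data.frame(var = 0:(n - 1L), block = 0L,
                                            phase = ph, support = 10,
                                            source = "mec"),
                        phase = ph,
                        blocks = data.frame(block_id = 0L, n_members = n,
                                            span = 50),
                        mec_score = 0L, unresolved = integer(0),
                        n_variants = n), class = "phasing_result")
  v <- haplotarget:::new_variant_table(pos = c(5, 15, 25, 35, 45, 55),
                                       ref = "A", alt = "G")
  genes <- data.frame(gene = c("G1", "G2"), start = c(0, 30), end = c(30, 60))
  ev <- evaluate_phasing(res, truth, v, genes = genes)
  expect_equal(ev$gene_level$n_het, c(3L, 3L))
  expect_equal(ev$gene_level$n_correct, c(2L, 3L))
})

test_that("blacklisting planted errors does not lower measured accuracy", {
  cfg <- sim_config("fast", seed = 63L, planted_error_fraction = 0.1,
                    n_fragments = 1e5, locus_length = 5e5,
                    snv_density = 2700 / 1e6)
  ds <- simulate_dataset(cfg)
  r <- max_cut_phase(ds$fragments, seed = 63)
  ht <- htrans_report(ds$fragments, ds$reported$haplotypes$hapA,
                      ds$variants, cfg$locus_length)
  bl <- concordance_filter(ht, ds$lfr, ds$reported$haplotypes$hapA)
  pre <- evaluate_phasing(r, ds$reported$haplotypes$hapA, ds$variants)
  post <- evaluate_phasing(r, ds$reported$haplotypes$hapA, ds$variants,
                           blacklist = bl)
  expect_gte(post$accuracy, pre$accuracy)
})

test_that("enrichment fold is 1 for uniform data and Inf with no off-target", {
  set.seed(71)
  n <- 20000
  L <- 1e6
  frags <- data.frame(id = seq_len(n), pos1 = runif(n, 0, L - 100),
                      pos2 = runif(n, 0, L - 100))
  obs <- haplotarget:::empty_obs()
  m <- haplotarget:::new_fragment_matrix(obs, frags, read_length = 100L)
  half <- haplotarget:::iv(0, L / 2)
  er <- enrichment_fold(m, half, L)
  expect_lt(abs(er$fold - 1), 0.1)

  on_only <- m
  on_only$frags <- frags[frags$pos1 < L / 2 - 100 & frags$pos2 < L / 2 - 100, ]
  er2 <- enrichment_fold(on_only, half, L)
  expect_true(is.infinite(er2$fold))
})

test_that("contact profiles: self-correlation 1, permutation null low, seeds agree", {
  cfg <- sim_config("fast", seed = 81L, n_fragments = 50000)
  sim <- simulate_variants(cfg)
  fr1 <- simulate_proximity_fragments(cfg, sim$variants, sim$haplotypes,
                                      seed = 810)
  fr2 <- simulate_proximity_fragments(cfg, sim$variants, sim$haplotypes,
                                      seed = 811)
  expect_equal(binned_contact_correlation(fr1, fr1, cfg$locus_length), 1.0)
  expect_gt(binned_contact_correlation(fr1, fr2, cfg$locus_length), 0.8)

  # permutation null: shuffle the bin-pair counts of the same dataset
  nb <- 10L
  counts <- local({
    fr <- fr1$frags
    b1 <- pmin(floor(fr$pos1 / 1e5), nb - 1); b2 <- pmin(floor(fr$pos2 / 1e5), nb - 1)
    key <- pmin(b1, b2) * nb + pmax(b1, b2) + 1
    tabulate(key, nbins = nb * nb)
  })
  set.seed(4)
  r2s <- replicate(20, {
    perm <- counts
    nz <- which(perm > 0)
    perm[nz] <- perm[sample(nz)]
    stats::cor(log10(1 + counts[counts > 0 | perm > 0]),
               log10(1 + perm[counts > 0 | perm > 0]))^2
  })
  expect_lt(stats::median(r2s), 0.2)

  one <- fr1
  one$frags <- fr1$frags[1, , drop = FALSE]
  one$frags$pos2 <- NA_real_
  expect_error(binned_contact_correlation(one, one, cfg$locus_length),
               "nonzero")
})
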