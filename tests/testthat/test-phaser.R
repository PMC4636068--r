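test_that("MEC score matches hand-enumerated fragment costs", {
  m <- toy_matrix()
  expect_equal(mec_score(m, c(0L, 0L)), 1L)   # F1:0 F2:0 F3:1
  expect_equal(mec_score(m, c(0L, 1L)), 2L)   # F1:1 F2:1 F3:0
  # single-observation fragments cost nothing under any phase
  single <- haplotarget:::new_fragment_matrix(
    data.frame(frag = 1:3, var = c(0L, 1L, 0L), allele = c(0L, 1L, 1L),
               qual = 30L, end = 1L),
    data.frame(id = 1:3, pos1 = 0, pos2 = NA))
  expect_equal(mec_score(single, c(0L, 0L)), 0L)
  expect_equal(mec_score(single, c(1L, 1L)), 0L)
})

test_that("MEC score is invariant to a global block flip", {
  for (sd in 1:5) {
    m <- random_matrix(8, 20, seed = sd)
    ph <- sample(0:1, 8, replace = TRUE)
    expect_equal(mec_score(m, ph), mec_score(m, 1L - ph))
  }
})

test_that("variant graph edges aggregate quality-weighted votes", {
  nolink <- haplotarget:::new_fragment_matrix(
    data.frame(frag = 1:2, var = 0:1, allele = 0L, qual = 30L, end = 1L),
    data.frame(id = 1:2, pos1 = 0, pos2 = NA))
  g0 <- build_graph(nolink)
  expect_equal(nrow(g0$edges), 0L)
  expect_true(all(is.na(g0$membership)))

  m <- diploid_matrix(hapA = c(0L, 0L), frag_vars = list(0:1, 0:1, 0:1),
                      source_hap = c(0L, 0L, 1L), quals = 30L)
  g <- build_graph(m)
  expect_equal(nrow(g$edges), 1L)
  w_one <- (1 - 10^-3)^2
  expect_equal(g$edges$weight, 3 * w_one, tolerance = 1e-12)
  expect_equal(g$edges$n_frags, 3L)
})

test_that("graph components equal a union-find oracle", {
  for (sd in 1:10) {
    m <- random_matrix(20, 12, seed = 100 + sd)
    g <- build_graph(m)
    oracle <- union_find_components(m, 20L)
    # compare partitions restricted to linked variants
    linked <- which(!is.na(g$membership))
    for (i in linked) for (j in linked) {
      if (i >= j) next
      expect_equal(g$membership[i] == g$membership[j],
                   oracle[i] == oracle[j])
    }
  }
})

test_that("max-cut recovers unambiguous phase and the worked example", {
  m5 <- diploid_matrix(hapA = c(0L, 1L),
                       frag_vars = rep(list(0:1), 5),
                       source_hap = c(0L, 1L, 0L, 1L, 0L))
  r5 <- max_cut_phase(m5, seed = 1)
  expect_equal(r5$mec_score, 0L)
  ph <- r5$phase
  expect_true(identical(ph, c(0L, 1L)) || identical(ph, c(1L, 0L)))

  toy <- toy_matrix()
  rt <- max_cut_phase(toy, seed = 1)
  expect_equal(rt$mec_score, 1L)
  expect_true(identical(rt$phase, c(0L, 0L)) ||
              identical(rt$phase, c(1L, 1L)))
})

test_that("brute force is optimal, tie-broken, and bounds the heuristic", {
  one <- haplotarget:::new_fragment_matrix(
    data.frame(frag = 1L, var = 0L, allele = 1L, qual = 30L, end = 1L),
    data.frame(id = 1L, pos1 = 0, pos2 = NA))
  r1 <- brute_force_phase(one)
  expect_equal(r1$mec_score, 0L)

  toy <- toy_matrix()
  rb <- brute_force_phase(toy)
  expect_equal(rb$mec_score, 1L)
  expect_equal(rb$phase, c(0L, 0L))  # lexicographically smallest optimum

  for (sd in 1:50) {
    m <- random_matrix(sample(4:10, 1), sample(8:30, 1), seed = 200 + sd)
    opt <- brute_force_phase(m)$mec_score
    heu <- max_cut_phase(m, n_restarts = 20, seed = sd,
                         prune_min_margin = 0)$mec_score
    expect_gte(heu, opt)
  }

  big <- random_matrix(20, 200, seed = 1)
  expect_error(brute_force_phase(big), "too large")
})

test_that("adding concordant fragments never raises the optimal MEC", {
  for (sd in 1:10) {
    m <- random_matrix(6, 12, seed = 300 + sd)
    base <- brute_force_phase(m)
    ph <- base$phase
    # append a fragment perfectly consistent with the current optimum
    vs <- sort(sample(which(!is.na(ph)) - 1L, 2L))
    extra <- data.frame(frag = max(m$frags$id) + 1L, var = vs,
                        allele = ph[vs + 1L], qual = 30L, end = 1:2)
    m2 <- haplotarget:::new_fragment_matrix(
      rbind(m$obs, extra),
      rbind(m$frags, data.frame(id = max(m$frags$id) + 1L, pos1 = 0,
                                pos2 = 100)))
    expect_lte(brute_force_phase(m2)$mec_score, base$mec_score)
  }
})

test_that("result MEC equals independent rescoring (self-consistency)", {
  for (sd in 1:5) {
    m <- random_matrix(12, 40, seed = 400 + sd)
    r <- max_cut_phase(m, seed = sd)
    expect_equal(r$mec_score, mec_score(m, r$phase))
  }
})

test_that("noise-free simulation phases every component exactly", {
  cfg <- sim_config("fast", seed = 41L, htrans_rate = 0, seq_error = 0,
                    locus_length = 2e5, snv_density = 2700 / 1e6,
                    n_fragments = 60000)
  ds <- simulate_dataset(cfg)
  r <- max_cut_phase(ds$fragments, seed = 41)
  expect_equal(r$mec_score, 0L)
  ev <- evaluate_phasing(r, ds$haplotypes$hapA, ds$variants,
                         largest_block_only = FALSE)
  expect_equal(ev$accuracy, 1.0)
  # blocks cover exactly the graph components
  g <- build_graph(ds$fragments)
  expect_equal(sort(r$assign$var),
               sort(which(!is.na(g$membership)) - 1L))
})

test_that("LCP refinement is a no-op without unresolved variants", {
  m5 <- diploid_matrix(hapA = c(0L, 1L), frag_vars = rep(list(0:1), 5),
                       source_hap = rep(0L, 5))
  r <- max_cut_phase(m5, seed = 1)
  v <- haplotarget:::new_variant_table(pos = c(10, 20), ref = "A", alt = "G")
  panel <- rbind(c(0L, 1L), c(1L, 0L))
  r2 <- lcp_refine(r, v, panel)
  expect_equal(r2$assign, r$assign)
})

test_that("a truth-faithful panel phases all unresolved variants correctly", {
  set.seed(51)
  n <- 60
  hapA <- sample(0:1, n, replace = TRUE)
  # fragments link only the first 40 variants; the last 20 are unresolved
  frag_vars <- lapply(1:120, function(i) sort(sample(0:39, 2)))
  m <- diploid_matrix(hapA, frag_vars, source_hap = rep(0:1, 60))
  r <- max_cut_phase(m, seed = 5)
  # matrix only knows 40 variants; widen to the full set
  r$phase <- c(r$phase, rep(NA_integer_, n - r$n_variants))
  r$unresolved <- c(r$unresolved, seq(r$n_variants, n - 1L))
  r$n_variants <- n
  v <- haplotarget:::new_variant_table(pos = seq_len(n) * 100,
                                       ref = "A", alt = "G")
  panel <- rbind(matrix(hapA, 10, n, byrow = TRUE),
                 matrix(1L - hapA, 10, n, byrow = TRUE))
  r2 <- lcp_refine(r, v, panel)
  expect_length(r2$unresolved, 0L)
  ev <- evaluate_phasing(r2, hapA, v)
  expect_equal(ev$accuracy, 1.0)
  expect_true(all(r2$assign$source[r2$assign$var >= 40] == "lcp"))
})

test_that("panel-phased variants beat the coin-flip baseline on noisy panels", {
  set.seed(52)
  n <- 500
  hapA <- sample(0:1, n, replace = TRUE)
  frag_vars <- lapply(1:1500, function(i) {
    a <- sample(0:(n - 2), 1); c(a, a + 1)
  })
  keep <- sample(0:(n - 1), 400)  # unresolved: the other 100
  frag_vars <- Filter(function(v) all(v %in% keep), frag_vars)
  m <- diploid_matrix(hapA, frag_vars, rep(0:1, length.out = length(frag_vars)))
  r <- max_cut_phase(m, seed = 6)
  if (r$n_variants < n) {
    r$phase <- c(r$phase, rep(NA_integer_, n - r$n_variants))
    r$unresolved <- c(r$unresolved, seq(r$n_variants, n - 1L))
    r$n_variants <- n
  }
  v <- haplotarget:::new_variant_table(pos = seq_len(n) * 50,
                                       ref = "A", alt = "G")
  panel <- simulate_panel(list(hapA = hapA, hapB = 1L - hapA),
                          n_haplotypes = 20, mutation_rate = 0.01,
                          switches_per_haplotype = 0.2 * 5, seed = 3)
  r2 <- lcp_refine(r, v, panel)
  lcp_vars <- r2$assign$var[r2$assign$source == "lcp"]
  expect_gt(length(lcp_vars), 10L)
  lb <- haplotarget:::largest_block_id(r2)
  sc <- r2$assign[r2$assign$block == lb, ]
  truth <- hapA[sc$var + 1L]
  agree <- sum(sc$phase == truth)
  flip <- agree < nrow(sc) - agree
  corr <- (sc$phase == truth) != flip
  acc_lcp <- mean(corr[sc$var %in% lcp_vars])
  expect_gt(acc_lcp, 0.5)
})

test_that("phased VCF output carries PS tags and survives a round trip", {
  r0 <- structure(list(assign = data.frame(var = integer(0),
                                           block = integer(0),
                                           phase = integer(0),
                                           support = numeric(0),
                                           source = character(0)),
                       phase = integer(0), blocks = data.frame(),
                       mec_score = 0L, unresolved = integer(0),
                       n_variants = 0L), class = "phasing_result")
  v0 <- haplotarget:::new_variant_table(numeric(0), character(0), character(0))
  p <- tempfile(fileext = ".vcf")
  write_phased_vcf(r0, v0, p)
  expect_true(all(grepl("^#", readLines(p))))

  m <- diploid_matrix(hapA = c(0L, 1L, 1L),
                      frag_vars = list(0:1, 1:2, 0:2, 0:1, 1:2),
                      source_hap = c(0L, 1L, 0L, 1L, 0L))
  r <- max_cut_phase(m, seed = 2)
  v <- haplotarget:::new_variant_table(pos = c(5, 15, 25),
                                       ref = c("A", "C", "G"),
                                       alt = c("T", "A", "C"))
  write_phased_vcf(r, v, p)
  lines <- grep("^[^#]", readLines(p), value = TRUE)
  ps <- sub(".*:", "", sapply(strsplit(lines, "\t"), `[`, 10L))
  expect_equal(length(unique(ps)), 1L)   # one block, one PS value
  back <- read_variants_vcf(p)
  expect_equal(back$truth_phase, r$phase)
})
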