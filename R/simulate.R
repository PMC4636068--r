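#' Simulation configuration for targeted proximity-ligation data
#'
#' Bundles every generative parameter of the synthetic diploid locus and
#' its sequencing data. Two profiles mirror the study conditions:
#' `"paper"` is an MHC-scale locus (3.5 Mb, ~9,400 het SNVs, 50-fold
#' capture enrichment, h-trans rate 0.02, 0.5% base error) and `"fast"` is
#' a 1 Mb / ~2,700-SNV locus with the same rates for quick runs.
#'
#' The fragment count defaults are calibrated so that, after capture, the
#' median number of informative (two or more allele observations) fragments
#' per variant is about 5 — the coverage regime the method is designed for.
#'
#' @param profile `"paper"` or `"fast"`.
#' @param ... overrides for individual fields (e.g. `htrans_rate = 0`).
#' @return a `sim_config` list with fields `locus_length`, `snv_density`,
#'   `n_fragments`, `read_length`, `decay_exponent`, `min_span`,
#'   `htrans_rate`, `enrichment_fold`, `seq_error`, `lfr_n`, `lfr_length`,
#'   `planted_error_fraction`, `seed`.
#' @export
sim_config <- function(profile = c("paper", "fast"), ...) {
  profile <- match.arg(profile)
  cfg <- switch(profile,
    paper = list(locus_length = 3.5e6, snv_density = 9400 / 3.5e6,
                 n_fragments = 1.0e6),
    fast = list(locus_length = 1e6, snv_density = 2700 / 1e6,
                n_fragments = 2.7e5))
  cfg <- c(cfg, list(read_length = 100L, decay_exponent = 1.08,
                     min_span = 2000, htrans_rate = 0.02,
                     enrichment_fold = 50, seq_error = 0.005,
                     lfr_length = 10000, planted_error_fraction = 0,
                     seed = 1L, profile = profile))
  over <- list(...)
  unknown <- setdiff(names(over), c(names(cfg), "lfr_n"))
  if (length(unknown))
    stop("unknown sim_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  # LFR count defaults to ~10x long-fragment coverage of the locus
  if (is.null(cfg$lfr_n))
    cfg$lfr_n <- round(10 * cfg$locus_length / cfg$lfr_length)
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$htrans_rate, cfg$seq_error, cfg$planted_error_fraction)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (cfg$decay_exponent <= 0) stop("decay_exponent must be > 0")
  if (cfg$enrichment_fold < 1) stop("enrichment_fold must be >= 1")
  if (cfg$locus_length * cfg$snv_density < 2 && cfg$snv_density > 0)
    stop("locus must hold at least 2 variants")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> profile=", x$profile, ", locus ", x$locus_length,
      " bp, ~", round(x$locus_length * x$snv_density), " SNVs, ",
      x$n_fragments, " fragments, F=", x$enrichment_fold,
      ", tau=", x$htrans_rate, ", eps=", x$seq_error, ", seed=", x$seed,
      "\n", sep = "")
  invisible(x)
}

#' Write / read a flat key=value echo of a simulation config
#' @param config a `sim_config`.
#' @param path output path.
#' @export
write_config <- function(config, path) {
  keys <- setdiff(names(config), "profile")
  writeLines(c(paste0("profile=", config$profile),
               paste0(keys, "=", vapply(config[keys], format, "",
                                        scientific = FALSE))), path)
  invisible(path)
}

phred_from_error <- function(eps) {
  as.integer(round(pmin(40, -10 * log10(pmax(eps, 1e-4)))))
}

#' Generate a synthetic reference locus
#'
#' Random uniform DNA of the requested length with randomly placed repeat
#' intervals (geometric lengths, ~500 bp mean) and evenly spread multi-exon
#' genes, as a stand-in reference for end-to-end runs. The restriction
#' motif occurs at its natural background rate (every ~4 kb for a 6-cutter).
#'
#' @param locus_length length in bp.
#' @param seed RNG seed.
#' @param repeat_frac approximate fraction of the locus under repeats.
#' @param n_genes number of genes; each gets `exons_per_gene` exons of
#'   `exon_length` bp.
#' @param exons_per_gene,exon_length gene geometry.
#' @return a `reference_locus`.
#' @export
synthetic_locus <- function(locus_length, seed = 1L, repeat_frac = 0.08,
                            n_genes = 20L, exons_per_gene = 4L,
                            exon_length = 200L) {
  set.seed(seed)
  L <- as.integer(locus_length)
  sequence <- paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                    collapse = "")
  reps <- iv_empty()
  if (repeat_frac > 0) {
    target <- repeat_frac * L
    n_rep <- ceiling(target / 500)
    starts <- sort(sample.int(L, n_rep))
    lens <- pmax(50, stats::rgeom(n_rep, 1 / 500))
    reps <- iv_merge(iv_clip(iv(starts - 1, starts - 1 + lens), 0, L))
  }
  genes <- data.frame(gene = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  exons <- data.frame(gene = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (n_genes > 0L) {
    span <- exons_per_gene * exon_length * 5
    gstart <- round(seq(0.02 * L, 0.98 * L - span, length.out = n_genes))
    ex <- lapply(seq_len(n_genes), function(g) {
      es <- gstart[g] + sort(sample.int(span - exon_length, exons_per_gene))
      data.frame(gene = sprintf("GENE%03d", g), start = es,
                 end = es + exon_length, stringsAsFactors = FALSE)
    })
    exons <- do.call(rbind, ex)
    genes <- data.frame(gene = sprintf("GENE%03d", seq_len(n_genes)),
                        start = gstart, end = gstart + span,
                        stringsAsFactors = FALSE)
  }
  structure(list(name = "synthetic_locus", sequence = sequence, length = L,
                 offset = 0L, repeats = reps, genes = genes, exons = exons),
            class = "reference_locus")
}

#' Simulate heterozygous SNVs and their diploid truth haplotypes
#'
#' Positions are drawn uniformly without replacement at the expected count
#' `locus_length * snv_density`; truth phase bits are i.i.d. fair coins;
#' the density flag marks variants in 2 kb windows whose SNV count is in
#' the top decile. When a locus is supplied, reference alleles come from
#' its sequence (variants falling on `N` are re-drawn) and alternate
#' alleles are drawn uniformly from the remaining bases.
#'
#' @param config a `sim_config`.
#' @param locus optional `reference_locus` providing reference bases.
#' @param seed RNG seed (default `config$seed`).
#' @return list with `variants` (variant table) and `haplotypes`
#'   (list `hapA`, `hapB` of complementary bit vectors).
#' @export
simulate_variants <- function(config, locus = NULL, seed = config$seed) {
  set.seed(seed)
  L <- config$locus_length
  n <- round(L * config$snv_density)
  if (n > L) stop("snv_density too high: more variants than positions")
  if (n == 0L) {
    variants <- new_variant_table(numeric(0), character(0), character(0))
    return(list(variants = variants,
                haplotypes = list(hapA = integer(0), hapB = integer(0))))
  }
  pos <- sort(sample.int(L, n)) - 1
  bases <- c("A", "C", "G", "T")
  if (!is.null(locus)) {
    ref <- substring(locus$sequence, pos + 1, pos + 1)
    ok <- ref %in% bases
    for (tries in 1:20) {
      if (all(ok)) break
      repl <- sample(setdiff(0:(L - 1), pos), sum(!ok))
      pos[!ok] <- repl
      ref <- substring(locus$sequence, pos + 1, pos + 1)
      ok <- ref %in% bases
    }
    keep <- ok
    pos <- sort(pos[keep]); ref <- substring(locus$sequence, pos + 1, pos + 1)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  } else {
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), "")
  }
  hapA <- stats::rbinom(length(pos), 1L, 0.5)
  variants <- new_variant_table(pos, ref, alt, truth_phase = hapA)
  variants$density_flag <- flag_high_density(variants$pos, L)
  list(variants = variants,
       haplotypes = list(hapA = hapA, hapB = 1L - hapA))
}

# inverse-CDF sampler for p(s) ~ s^(-alpha) truncated to [a, b]
sample_truncated_powerlaw <- function(n, alpha, a, b) {
  u <- stats::runif(n)
  if (abs(alpha - 1) < 1e-12) {
    exp(log(a) + u * (log(b) - log(a)))
  } else {
    e <- 1 - alpha
    (a^e + u * (b^e - a^e))^(1 / e)
  }
}

#' Simulate proximity-ligation fragments over a diploid locus
#'
#' Each fragment joins two read-length anchors on the locus: the first
#' anchor is uniform, the genomic span follows a truncated power law
#' `p(s) ~ s^-decay_exponent` on `[min_span, locus_length]` (the canonical
#' intra-chromosomal contact decay), and the second anchor sits at that
#' span in a uniform direction, reflected at the locus bounds. The source
#' homolog of anchor 1 is a fair coin; with probability `htrans_rate` the
#' second anchor reads from the *other* homolog (a homologous-trans
#' ligation, recorded in the origin metadata). Each anchor reports the
#' source haplotype's allele at every heterozygous site it covers, flipped
#' independently with probability `seq_error`; base qualities are the
#' Phred equivalent of `seq_error`.
#'
#' @param config a `sim_config`.
#' @param variants,haplotypes from [simulate_variants()].
#' @param n_fragments number of fragments (default `config$n_fragments`).
#' @param seed RNG seed (default `config$seed + 1`).
#' @return a `fragment_matrix` whose `frags` table carries origin metadata
#'   (`hap1`, `hap2`, `htrans`, anchors).
#' @export
simulate_proximity_fragments <- function(config, variants, haplotypes,
                                         n_fragments = config$n_fragments,
                                         seed = config$seed + 1L) {
  if (nrow(variants) < 2L) stop("need >= 2 variants to simulate fragments")
  if (config$min_span >= config$locus_length)
    stop("min_span must be smaller than the locus")
  set.seed(seed)
  L <- config$locus_length
  rl <- config$read_length
  n <- as.integer(n_fragments)
  hi <- L - rl

  pos1 <- sample.int(hi + 1L, n, replace = TRUE) - 1
  span <- round(sample_truncated_powerlaw(n, config$decay_exponent,
                                          config$min_span, L))
  dir <- sample(c(-1, 1), n, replace = TRUE)
  pos2 <- pos1 + dir * span
  # reflect at the bounds until inside [0, hi]
  for (it in 1:4) {
    out <- pos2 < 0 | pos2 > hi
    if (!any(out)) break
    pos2 <- abs(pos2)
    pos2 <- ifelse(pos2 > hi, 2 * hi - pos2, pos2)
  }
  pos2 <- pmin(pmax(pos2, 0), hi)

  hap1 <- stats::rbinom(n, 1L, 0.5)           # 0 = homolog A, 1 = homolog B
  htrans <- stats::runif(n) < config$htrans_rate
  hap2 <- ifelse(htrans, 1L - hap1, hap1)

  q <- phred_from_error(config$seq_error)
  vp <- variants$pos
  hapA <- haplotypes$hapA

  end_obs <- function(p, hap, end_label) {
    lo <- findInterval(p - 0.5, vp) + 1L
    hi_i <- findInterval(p + rl - 0.5, vp)
    cnt <- pmax(0L, hi_i - lo + 1L)
    sel <- cnt > 0L
    if (!any(sel)) return(empty_obs())
    frag <- rep.int(which(sel), cnt[sel])
    vidx <- sequence(cnt[sel], from = lo[sel])      # 1-based into variants
    truth <- ifelse(rep.int(hap[sel], cnt[sel]) == 0L,
                    hapA[vidx], 1L - hapA[vidx])
    err <- stats::runif(length(vidx)) < config$seq_error
    data.frame(frag = frag, var = vidx - 1L,
               allele = as.integer(xor(truth == 1L, err)),
               qual = q, end = end_label)
  }
  obs <- rbind(end_obs(pos1, hap1, 1L), end_obs(pos2, hap2, 2L))
  # boundary reflection can land the two reads on overlapping windows; a
  # fragment observes each variant once (first end wins)
  obs <- obs[!duplicated(obs[, c("frag", "var")]), , drop = FALSE]
  frags <- data.frame(id = seq_len(n), pos1 = pos1, pos2 = pos2,
                      hap1 = hap1, hap2 = hap2, htrans = htrans)
  new_fragment_matrix(obs, frags, read_length = rl)
}

#' Apply probe capture enrichment to a fragment set
#'
#' A fragment is on-target when at least one of its reads overlaps at
#' least one probe; on-target fragments are always retained, off-target
#' fragments survive with probability `1/enrichment_fold`. Retention
#' decisions and on-target flags are recorded in the `frags` table.
#'
#' @param matrix simulator `fragment_matrix`.
#' @param probe_set a `probe_set`.
#' @param config a `sim_config` (supplies `enrichment_fold`, `read_length`).
#' @param seed RNG seed (default `config$seed + 2`).
#' @return captured `fragment_matrix`; attribute `capture_stats` holds
#'   `n_input`, `n_on_target`, `n_kept`.
#' @export
apply_capture <- function(matrix, probe_set, config,
                          seed = config$seed + 2L) {
  set.seed(seed)
  fr <- matrix$frags
  n <- nrow(fr)
  Fold <- config$enrichment_fold
  rl <- if (!is.na(matrix$read_length)) matrix$read_length else config$read_length
  pv <- probe_intervals(probe_set)
  on1 <- if (nrow(pv)) iv_overlaps_any(iv(fr$pos1, fr$pos1 + rl), pv)
         else rep(FALSE, n)
  on2 <- if (nrow(pv) && !all(is.na(fr$pos2)))
    iv_overlaps_any(iv(ifelse(is.na(fr$pos2), 0, fr$pos2),
                       ifelse(is.na(fr$pos2), 0, fr$pos2) + rl), pv) &
      !is.na(fr$pos2)
  else rep(FALSE, n)
  on_target <- on1 | on2
  keep <- on_target | stats::runif(n) < 1 / Fold
  fr$on_target <- on_target
  out <- new_fragment_matrix(matrix$obs[matrix$obs$frag %in% fr$id[keep], ,
                                        drop = FALSE],
                             fr[keep, , drop = FALSE],
                             read_length = rl)
  attr(out, "capture_stats") <- c(n_input = n, n_on_target = sum(on_target),
                                  n_kept = sum(keep))
  out
}

#' Simulate long-fragment reads (LFR)
#'
#' Contiguous single-molecule fragments of `lfr_length` bp with uniform
#' starts, each reading one homolog end to end (no h-trans by
#' construction), with per-base allele error `seq_error`. The orthogonal
#' phase witness used by the h-trans concordance filter.
#'
#' @param config a `sim_config`.
#' @param variants,haplotypes from [simulate_variants()].
#' @param seed RNG seed (default `config$seed + 3`).
#' @return a `fragment_matrix`; all end labels are 1.
#' @export
simulate_lfr_fragments <- function(config, variants, haplotypes,
                                   seed = config$seed + 3L) {
  set.seed(seed)
  L <- config$locus_length
  len <- min(config$lfr_length, L)
  n <- as.integer(config$lfr_n)
  start <- sample.int(L - len + 1L, n, replace = TRUE) - 1
  hap <- stats::rbinom(n, 1L, 0.5)
  vp <- variants$pos
  hapA <- haplotypes$hapA
  lo <- findInterval(start - 0.5, vp) + 1L
  hi <- findInterval(start + len - 0.5, vp)
  cnt <- pmax(0L, hi - lo + 1L)
  sel <- cnt > 0L
  obs <- empty_obs()
  if (any(sel)) {
    frag <- rep.int(which(sel), cnt[sel])
    vidx <- sequence(cnt[sel], from = lo[sel])
    truth <- ifelse(rep.int(hap[sel], cnt[sel]) == 0L, hapA[vidx],
                    1L - hapA[vidx])
    err <- stats::runif(length(vidx)) < config$seq_error
    obs <- data.frame(frag = frag, var = vidx - 1L,
                      allele = as.integer(xor(truth == 1L, err)),
                      qual = phred_from_error(config$seq_error), end = 1L)
  }
  frags <- data.frame(id = seq_len(n), pos1 = start, pos2 = NA_real_,
                      hap1 = hap, hap2 = hap, htrans = FALSE)
  new_fragment_matrix(obs, frags, read_length = len)
}

#' Plant phase errors into a reported truth set
#'
#' Short-read trio-style truth sets accumulate local phasing mistakes in
#' high-variant-density regions. This corrupts the generative truth the
#' same way: among density-flagged variants, the reported phase bit is
#' flipped independently with probability `planted_error_fraction`. The
#' generative truth is untouched; the flipped index set is returned so
#' filter recall/precision can be scored.
#'
#' @param variants variant table (supplies `density_flag`).
#' @param haplotypes generative truth haplotypes.
#' @param config a `sim_config`.
#' @param seed RNG seed (default `config$seed + 4`).
#' @return list with `haplotypes` (corrupted reported truth) and
#'   `flipped` (0-based variant indices that were flipped).
#' @export
plant_truth_errors <- function(variants, haplotypes, config,
                               seed = config$seed + 4L) {
  set.seed(seed)
  flip <- variants$density_flag &
    stats::runif(nrow(variants)) < config$planted_error_fraction
  hapA <- as.integer(xor(haplotypes$hapA == 1L, flip))
  list(haplotypes = list(hapA = hapA, hapB = 1L - hapA),
       flipped = variants$index[flip])
}

#' Simulate a complete targeted proximity-ligation dataset
#'
#' Convenience wrapper running locus synthesis (unless supplied), probe
#' design, variant and haplotype simulation, fragment generation, capture,
#' LFR simulation and truth-error planting, all deterministically from
#' `config$seed`.
#'
#' @param config a `sim_config`.
#' @param locus optional `reference_locus` (synthesized when `NULL`).
#' @param probe_set optional `probe_set` (designed on the locus when `NULL`).
#' @return list with `locus`, `probe_set`, `variants`, `haplotypes`
#'   (generative truth), `reported` (list `haplotypes`, `flipped`),
#'   `fragments` (post-capture `fragment_matrix`), `lfr`, `config`.
#' @export
simulate_dataset <- function(config, locus = NULL, probe_set = NULL) {
  if (is.null(locus))
    locus <- synthetic_locus(config$locus_length, seed = config$seed + 10L)
  if (is.null(probe_set))
    probe_set <- design_probes(locus)
  sim <- simulate_variants(config, locus = locus)
  fragments_all <- simulate_proximity_fragments(config, sim$variants,
                                                sim$haplotypes)
  fragments <- apply_capture(fragments_all, probe_set, config)
  lfr <- simulate_lfr_fragments(config, sim$variants, sim$haplotypes)
  reported <- plant_truth_errors(sim$variants, sim$haplotypes, config)
  list(locus = locus, probe_set = probe_set, variants = sim$variants,
       haplotypes = sim$haplotypes, reported = reported,
       fragments = fragments, lfr = lfr, config = config)
}

#' Compare candidate probe designs by simulation
#'
#' Runs the simulate -> capture -> phase -> evaluate loop once per
#' candidate design under a shared seed and reports the achieved phasing
#' resolution and accuracy, supporting the choice of tiling density the
#' way the capture design itself was chosen.
#'
#' @param config a `sim_config` (use a small profile; the loop phases each
#'   candidate's captured data in full).
#' @param probe_set_candidates named list of `probe_set` objects.
#' @param locus optional shared `reference_locus`.
#' @return data.frame with one row per design: `design`, `n_probes`,
#'   `resolution`, `accuracy`, `mec`.
#' @export
evaluate_design <- function(config, probe_set_candidates, locus = NULL) {
  if (is.null(locus))
    locus <- synthetic_locus(config$locus_length, seed = config$seed + 10L)
  sim <- simulate_variants(config, locus = locus)
  frag_all <- simulate_proximity_fragments(config, sim$variants,
                                           sim$haplotypes)
  nm <- names(probe_set_candidates)
  if (is.null(nm)) nm <- paste0("design", seq_along(probe_set_candidates))
  rows <- lapply(seq_along(probe_set_candidates), function(k) {
    ps <- probe_set_candidates[[k]]
    cap <- apply_capture(frag_all, ps, config)
    res <- max_cut_phase(cap, seed = config$seed)
    ev <- evaluate_phasing(res, sim$haplotypes$hapA, sim$variants)
    data.frame(design = nm[k], n_probes = nrow(ps$probes),
               resolution = ev$resolution, accuracy = ev$accuracy,
               mec = res$mec_score, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
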