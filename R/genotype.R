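# De novo genotyping from captured-read allele counts. Capture sequencing
# is blind to the genotype, so allele depths at candidate sites support
# direct het/hom calls; a frequency-threshold caller with an explicit
# ambiguous zone reflects that hom calls are intrinsically harder here
# (one stray allele observation can masquerade as heterozygosity).

#' Per-site allele counts from a fragment matrix
#'
#' @param matrix a `fragment_matrix` (allele-level observations; the
#'   `other` count is 0 by construction for this input).
#' @param sites variant table of candidate sites.
#' @param min_baseq minimum base quality (default 20).
#' @return data.frame with `var`, `pos`, `ref_count`, `alt_count`,
#'   `other_count`, `depth`.
#' @export
pileup_counts <- function(matrix, sites, min_baseq = 20L) {
  obs <- matrix$obs[matrix$obs$qual >= min_baseq, , drop = FALSE]
  n <- nrow(sites)
  rc <- tabulate(obs$var[obs$allele == 0L] + 1L, nbins = n)
  ac <- tabulate(obs$var[obs$allele == 1L] + 1L, nbins = n)
  data.frame(var = sites$index, pos = sites$pos, ref_count = rc,
             alt_count = ac, other_count = 0L, depth = rc + ac)
}

#' Simulate base-level allele counts at candidate sites
#'
#' Multinomial counts under the standard substitution-error model: a true
#' allele read is miscalled with probability `seq_error`, going to each of
#' the three other bases uniformly — so at expected depth `d` the expected
#' `other` fraction at a het site is `2/3 * seq_error`. Depths are Poisson.
#'
#' @param truth_gt character vector in `c("hom_ref", "het", "hom_alt")`.
#' @param mean_depth expected depth per site.
#' @param seq_error per-base error rate.
#' @param seed RNG seed.
#' @return data.frame of counts as in [pileup_counts()].
#' @export
simulate_site_counts <- function(truth_gt, mean_depth, seq_error,
                                 seed = 1L) {
  set.seed(seed)
  n <- length(truth_gt)
  depth <- stats::rpois(n, mean_depth)
  p_alt_true <- c(hom_ref = 0, het = 0.5, hom_alt = 1)[truth_gt]
  # a read drawn from the ref allele: ref w.p. 1-e, alt w.p. e/3, other 2e/3
  e <- seq_error
  p_ref <- (1 - p_alt_true) * (1 - e) + p_alt_true * (e / 3)
  p_alt <- p_alt_true * (1 - e) + (1 - p_alt_true) * (e / 3)
  p_oth <- 1 - p_ref - p_alt
  counts <- t(vapply(seq_len(n), function(i)
    as.integer(stats::rmultinom(1L, depth[i],
                                c(p_ref[i], p_alt[i], p_oth[i]))),
    integer(3)))
  data.frame(var = seq_len(n) - 1L, pos = seq_len(n) - 1L,
             ref_count = counts[, 1], alt_count = counts[, 2],
             other_count = counts[, 3], depth = depth)
}

#' Call genotypes from allele counts
#'
#' Frequency-threshold caller: `no_call` below `min_depth`; `het` when the
#' minor allele reaches both `het_minor_frac` of the depth and
#' `min_minor_count` reads; homozygous for the major allele when the minor
#' fraction is at most `hom_minor_frac`; the zone in between stays
#' `no_call` rather than guessing.
#'
#' @param counts data.frame from [pileup_counts()] /
#'   [simulate_site_counts()].
#' @param min_depth minimum depth to call (default 8).
#' @param het_minor_frac minor-allele fraction for het (default 0.2).
#' @param hom_minor_frac maximum minor fraction for hom (default 0.05).
#' @param min_minor_count minimum minor-allele reads for het (default 2).
#' @return character vector in
#'   `c("hom_ref", "het", "hom_alt", "no_call")`.
#' @export
call_genotype <- function(counts, min_depth = 8L, het_minor_frac = 0.2,
                          hom_minor_frac = 0.05, min_minor_count = 2L) {
  stopifnot(het_minor_frac > hom_minor_frac,
            het_minor_frac > 0, het_minor_frac < 1,
            hom_minor_frac >= 0, hom_minor_frac < 1)
  d2 <- counts$ref_count + counts$alt_count
  minor <- pmin(counts$ref_count, counts$alt_count)
  frac <- ifelse(d2 > 0, minor / d2, NA_real_)
  call <- rep("no_call", nrow(counts))
  callable <- counts$depth >= min_depth & d2 > 0
  is_het <- callable & frac >= het_minor_frac & minor >= min_minor_count
  is_hom <- callable & frac <= hom_minor_frac & !is_het
  call[is_het] <- "het"
  call[is_hom] <- ifelse(counts$ref_count[is_hom] >= counts$alt_count[is_hom],
                         "hom_ref", "hom_alt")
  call
}

#' Evaluate genotype calls against truth
#'
#' @param calls vector from [call_genotype()].
#' @param truth_genotypes truth vector (`hom_ref`/`het`/`hom_alt`).
#' @return list with `call_rate` (called / all truth sites),
#'   `het_accuracy` (correct het calls / het calls) and `hom_accuracy`
#'   (correct hom calls / hom calls); accuracies are `NA` when no such
#'   call was made.
#' @export
evaluate_genotyping <- function(calls, truth_genotypes) {
  stopifnot(length(calls) == length(truth_genotypes))
  called <- calls != "no_call"
  het_calls <- calls == "het"
  hom_calls <- calls %in% c("hom_ref", "hom_alt")
  list(call_rate = mean(called),
       het_accuracy = if (any(het_calls))
         mean(truth_genotypes[het_calls] == "het") else NA_real_,
       hom_accuracy = if (any(hom_calls))
         mean(calls[hom_calls] == truth_genotypes[hom_calls]) else NA_real_)
}
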