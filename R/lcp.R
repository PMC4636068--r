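# Local conditional phasing (LCP): phases variants the fragment evidence
# left unresolved by a haplotype-copying vote against a reference panel,
# conditional on the assembled scaffold. A deliberately simple stand-in
# for HMM-based imputation: panel haplotypes that agree with the scaffold
# near the unresolved variant vote with the allele they carry there.

#' Simulate a haplotype reference panel
#'
#' Panel haplotypes are mosaic copies of the two truth haplotypes with
#' uniformly placed recombination switch points plus independent per-site
#' mutations — the usual population-panel caricature: high local linkage
#' disequilibrium with the sample, broken at random switch points.
#'
#' @param haplotypes truth haplotypes (list `hapA`, `hapB`).
#' @param n_haplotypes panel size K (default 20).
#' @param mutation_rate per-site bit-flip probability (default 0.01).
#' @param switches_per_haplotype expected recombination switches (default 5).
#' @param seed RNG seed.
#' @return integer matrix, one row per panel haplotype.
#' @export
simulate_panel <- function(haplotypes, n_haplotypes = 20L,
                           mutation_rate = 0.01,
                           switches_per_haplotype = 5, seed = 1L) {
  set.seed(seed)
  n <- length(haplotypes$hapA)
  H <- rbind(haplotypes$hapA, haplotypes$hapB)
  out <- matrix(0L, nrow = n_haplotypes, ncol = n)
  for (k in seq_len(n_haplotypes)) {
    n_sw <- stats::rpois(1L, switches_per_haplotype)
    cuts <- sort(sample.int(n - 1L, min(n_sw, n - 1L)))
    src <- (sample(0:1, 1L) + cumsum(c(0L, tabulate(cuts, nbins = n - 1L)))) %% 2L
    hap <- ifelse(src == 0L, H[1L, ], H[2L, ])
    mut <- stats::runif(n) < mutation_rate
    out[k, ] <- as.integer(xor(hap == 1L, mut))
  }
  out
}

#' Phase residual variants against a reference panel (LCP step)
#'
#' For each unresolved variant: take the `window` nearest already-phased
#' members of the scaffold (the largest assembled block); every panel
#' haplotype matching the scaffold's haplotype-A alleles at >= 80% of
#' those positions casts a vote for the variant's allele; when the winning
#' allele reaches `vote_threshold` of the votes, the variant joins the
#' scaffold block with `source = "lcp"`. One pass only — newly assigned
#' variants never serve as scaffold for later ones.
#'
#' @param result a `phasing_result` from [max_cut_phase()].
#' @param variants variant table (positions drive "nearest").
#' @param panel_haplotypes matrix from [simulate_panel()] (or a real panel
#'   over the same variant set).
#' @param window number of scaffold anchors consulted (default 10).
#' @param vote_threshold winning-allele majority required (default 0.9).
#' @param match_threshold scaffold agreement a panel haplotype needs to
#'   vote (default 0.8).
#' @return an augmented `phasing_result`.
#' @export
lcp_refine <- function(result, variants, panel_haplotypes, window = 10L,
                       vote_threshold = 0.9, match_threshold = 0.8) {
  if (is.null(panel_haplotypes) || nrow(panel_haplotypes) == 0L) {
    warning("empty reference panel; LCP refinement skipped")
    return(result)
  }
  lb <- largest_block_id(result)
  if (is.na(lb)) return(result)
  scaffold <- result$assign[result$assign$block == lb, , drop = FALSE]
  if (nrow(scaffold) < 2L) return(result)
  sc_pos <- variants$pos[scaffold$var + 1L]
  o <- order(sc_pos)
  sc_pos <- sc_pos[o]
  sc_var <- scaffold$var[o]
  sc_phase <- scaffold$phase[o]

  phase <- result$phase
  block_of <- rep(NA_integer_, result$n_variants)
  block_of[result$assign$var + 1L] <- result$assign$block
  support <- rep(NA_real_, result$n_variants)
  support[result$assign$var + 1L] <- result$assign$support
  source <- rep(NA_character_, result$n_variants)
  source[result$assign$var + 1L] <- result$assign$source

  K <- nrow(panel_haplotypes)
  for (v in result$unresolved) {
    vpos <- variants$pos[v + 1L]
    nearest <- order(abs(sc_pos - vpos))[seq_len(min(window, length(sc_pos)))]
    anchors <- sc_var[nearest]
    target <- sc_phase[nearest]
    agree <- panel_haplotypes[, anchors + 1L, drop = FALSE] ==
      matrix(target, nrow = K, ncol = length(anchors), byrow = TRUE)
    voters <- rowMeans(agree) >= match_threshold
    if (!any(voters)) next
    votes <- panel_haplotypes[voters, v + 1L]
    frac1 <- mean(votes == 1L)
    win_frac <- max(frac1, 1 - frac1)
    if (win_frac < vote_threshold) next
    phase[v + 1L] <- if (frac1 >= 0.5) 1L else 0L
    block_of[v + 1L] <- lb
    source[v + 1L] <- "lcp"
    support[v + 1L] <- sum(voters) * (2 * win_frac - 1)
  }
  out <- finalize_phasing(list(obs = NULL), phase, block_of, support, source,
                          result$n_variants)
  # keep the fragment-derived MEC score: LCP adds no fragment evidence
  out$mec_score <- result$mec_score
  out
}

#' Write a phased VCF
#'
#' VCF 4.2 with phased genotypes `0|1` / `1|0` for resolved variants
#' (`0|1` = ref allele on haplotype A), a `PS` phase-set tag equal to the
#' 1-based position of the block's first member, unphased `0/1` for
#' unresolved variants, and an `LCP` INFO flag on panel-phased sites.
#'
#' @param result a `phasing_result`.
#' @param variants variant table.
#' @param path output path.
#' @param contig contig name.
#' @param contig_length optional contig length for the header.
#' @param sample sample column name.
#' @export
write_phased_vcf <- function(result, variants, path, contig = "locus",
                             contig_length = NULL, sample = "SAMPLE") {
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_length))
             sprintf("##contig=<ID=%s,length=%d>", contig,
                     as.integer(contig_length))
           else sprintf("##contig=<ID=%s>", contig),
           "##INFO=<ID=LCP,Number=0,Type=Flag,Description=\"Phased by local conditional (panel) refinement\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=PS,Number=1,Type=Integer,Description=\"Phase set (position of first block member)\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  n <- nrow(variants)
  body <- character(0)
  if (n > 0L) {
    ph <- result$phase[variants$index + 1L]
    block_of <- rep(NA_integer_, result$n_variants)
    source <- rep(NA_character_, result$n_variants)
    if (nrow(result$assign)) {
      block_of[result$assign$var + 1L] <- result$assign$block
      source[result$assign$var + 1L] <- result$assign$source
    }
    blk <- block_of[variants$index + 1L]
    src <- source[variants$index + 1L]
    ps <- rep(NA_integer_, n)
    has <- !is.na(blk)
    ps[has] <- as.integer(variants$pos[match(blk[has], variants$index)] + 1L)
    gt <- ifelse(is.na(ph), "0/1", ifelse(ph == 1L, "1|0", "0|1"))
    fmt <- ifelse(is.na(ph), "GT", "GT:PS")
    gtf <- ifelse(is.na(ph), gt, paste0(gt, ":", ps))
    info <- ifelse(!is.na(src) & src == "lcp", "LCP", ".")
    body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t%s\t%s\t%s", contig,
                    as.integer(variants$pos + 1L), variants$ref, variants$alt,
                    info, fmt, gtf)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
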