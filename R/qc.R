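# Evaluation layer: h-trans diagnostics, phasing metrics, capture
# enrichment and contact-profile concordance.

# classify every within-fragment observation pair as cis or h-trans
# against a haplotype-A bit vector; returns the obs_pairs frame plus
# `htrans` and `same_end` columns.
classify_pairs <- function(matrix, hapA) {
  pr <- obs_pairs(matrix)
  if (nrow(pr) == 0L) {
    pr$htrans <- logical(0); pr$same_end <- logical(0)
    return(pr)
  }
  mi <- pr$ai != hapA[pr$vi + 1L]
  mj <- pr$aj != hapA[pr$vj + 1L]
  pr$htrans <- xor(mi, mj)
  pr$same_end <- pr$ei == pr$ej
  pr
}

#' Homologous-trans interaction report
#'
#' Classifies every pair of allele observations within a fragment as cis
#' (both alleles on one reported haplotype) or h-trans (linking the two
#' homologs) against a reported truth, and aggregates the diagnostics the
#' h-trans artifact analysis rests on: the overall h-trans ratio, the
#' fraction of h-trans pairs whose two observations come from the same
#' read end, and the ratio stratified by variant-density decile (a pair is
#' binned by the denser of its two variants).
#'
#' @param matrix proximity-ligation `fragment_matrix`.
#' @param reported_hapA haplotype-A bit vector of the reported truth.
#' @param variants variant table (positions drive the density deciles).
#' @param locus_length locus length in bp.
#' @param density_bins number of density strata (default 10).
#' @param window density window in bp (default 2000).
#' @return an `htrans_report`: list with `n_informative`, `n_htrans`,
#'   `htrans_ratio`, `same_end_fraction`, `per_density_bin` (data.frame),
#'   and `per_variant` (data.frame `var`, `n_pairs`, `n_htrans`,
#'   `n_same_end_htrans`).
#' @export
htrans_report <- function(matrix, reported_hapA, variants, locus_length,
                          density_bins = 10L, window = 2000) {
  pr <- classify_pairs(matrix, reported_hapA)
  n_var <- nrow(variants)
  # per-variant density decile from 2 kb window SNV counts
  nb <- max(1L, ceiling(locus_length / window))
  wid <- pmin(floor(variants$pos / window), nb - 1L)
  counts <- tabulate(wid + 1L, nbins = nb)
  dens <- counts[wid + 1L]
  qs <- stats::quantile(dens, probs = seq(0, 1, length.out = density_bins + 1L),
                        type = 1)
  decile <- pmin(findInterval(dens, unique(qs), rightmost.closed = TRUE),
                 density_bins)

  if (nrow(pr) == 0L) {
    return(structure(list(n_informative = 0L, n_htrans = 0L,
                          htrans_ratio = NaN, same_end_fraction = NaN,
                          per_density_bin = data.frame(bin = integer(0),
                                                       n_pairs = integer(0),
                                                       htrans_ratio = numeric(0)),
                          per_variant = data.frame(var = integer(0),
                                                   n_pairs = integer(0),
                                                   n_htrans = integer(0),
                                                   n_same_end_htrans = integer(0))),
                     class = "htrans_report"))
  }

  pair_bin <- pmax(decile[pr$vi + 1L], decile[pr$vj + 1L])
  per_bin <- do.call(rbind, lapply(sort(unique(pair_bin)), function(b) {
    sel <- pair_bin == b
    data.frame(bin = b, n_pairs = sum(sel), htrans_ratio = mean(pr$htrans[sel]))
  }))

  vv <- c(pr$vi, pr$vj)
  ht <- rep(pr$htrans, 2L)
  se_ht <- rep(pr$htrans & pr$same_end, 2L)
  agg <- rowsum(cbind(n_pairs = 1L, n_htrans = as.integer(ht),
                      n_same_end_htrans = as.integer(se_ht)), group = vv)
  per_variant <- data.frame(var = as.integer(rownames(agg)),
                            n_pairs = as.integer(agg[, "n_pairs"]),
                            n_htrans = as.integer(agg[, "n_htrans"]),
                            n_same_end_htrans = as.integer(agg[, "n_same_end_htrans"]))
  rownames(per_variant) <- NULL

  structure(list(n_informative = nrow(pr),
                 n_htrans = sum(pr$htrans),
                 htrans_ratio = mean(pr$htrans),
                 same_end_fraction = if (any(pr$htrans))
                   mean(pr$same_end[pr$htrans]) else NaN,
                 per_density_bin = per_bin,
                 per_variant = per_variant),
            class = "htrans_report")
}

#' @export
print.htrans_report <- function(x, ...) {
  cat("<htrans_report> ", x$n_htrans, "/", x$n_informative,
      " observation pairs h-trans (ratio ",
      formatC(x$htrans_ratio, digits = 4, format = "f"),
      "); same-end fraction of h-trans pairs: ",
      formatC(x$same_end_fraction, digits = 3, format = "f"), "\n", sep = "")
  invisible(x)
}

#' Long-fragment concordance filter for suspect truth-set phases
#'
#' Flags variants the reported truth set has probably mis-phased: a
#' variant enters the blacklist when both data types independently find
#' it h-trans — (a) the majority of its observation pairs in the
#' proximity-ligation data link the two reported homologs, and (b) the
#' majority of its pairs in the long-fragment data do too, with at least
#' `min_lfr_support` distinct LFR molecules showing the inter-haplotype
#' pairing. A genuine homologous-trans ligation cannot appear in a
#' single-molecule long fragment at all, and scattered base errors never
#' reach a majority at a covered variant, so joint majority h-trans
#' status isolates reported-truth phase errors. Blacklisted variants are
#' meant to be excluded from truth-based accuracy evaluation (and
#' optionally from phasing input).
#'
#' @param report_hic `htrans_report` of the proximity-ligation data.
#' @param lfr_matrix LFR `fragment_matrix` over the same variants.
#' @param reported_hapA reported-truth haplotype-A bit vector.
#' @param min_lfr_support minimum distinct LFR molecules with an
#'   inter-haplotype pairing at the variant (default 2).
#' @param htrans_frac minimum h-trans fraction of a variant's pairs, in
#'   each dataset (default 0.5).
#' @return sorted integer vector of blacklisted 0-based variant indices.
#' @export
concordance_filter <- function(report_hic, lfr_matrix, reported_hapA,
                               min_lfr_support = 2L, htrans_frac = 0.5) {
  pv <- report_hic$per_variant
  cand <- pv$var[pv$n_htrans >= 1L & pv$n_htrans / pv$n_pairs >= htrans_frac]
  if (!length(cand)) return(integer(0))
  lp <- classify_pairs(lfr_matrix, reported_hapA)
  if (nrow(lp) == 0L) return(integer(0))
  vv <- c(lp$vi, lp$vj)
  ht <- rep(lp$htrans, 2L)
  agg <- rowsum(cbind(n = 1L, n_ht = as.integer(ht)), group = vv)
  frac_ok <- agg[, "n_ht"] / agg[, "n"] >= htrans_frac & agg[, "n_ht"] > 0L
  # distinct LFR molecules with an h-trans pair at the variant
  hp <- lp[lp$htrans, , drop = FALSE]
  vf <- unique(data.frame(var = c(hp$vi, hp$vj), frag = c(hp$frag, hp$frag)))
  supp <- table(factor(vf$var, levels = rownames(agg)))
  lfr_ok <- as.integer(rownames(agg))[frac_ok &
                                      as.integer(supp) >= min_lfr_support]
  sort(intersect(cand, lfr_ok))
}

#' Evaluate phasing against a truth standard
#'
#' Completeness, resolution and the per-variant ("worst-case") accuracy in
#' which every wrongly phased variant counts — unlike switch error, which
#' penalizes a flipped stretch only at its boundaries. Per block, the
#' orientation maximizing agreement with the truth (majority vote) is
#' chosen, so all metrics are invariant to global block flips; the switch
#' error is also reported (flips of relative phase between adjacent
#' resolved variants of a block). When a blacklist is supplied those
#' variants leave both the numerator and denominator of accuracy.
#'
#' @param result a `phasing_result`.
#' @param truth_hapA truth haplotype-A bit vector.
#' @param variants variant table.
#' @param genes optional gene table (`gene`, `start`, `end`) for per-gene
#'   stats.
#' @param blacklist optional 0-based variant indices to exclude.
#' @param largest_block_only restrict resolution/accuracy to the single
#'   spanning haplotype structure (default TRUE); otherwise all blocks
#'   count.
#' @return a `phasing_evaluation`: list with `n_total_het`, `n_resolved`,
#'   `resolution`, `n_correct`, `accuracy`, `switch_error`, `n_excluded`,
#'   and `gene_level` (data.frame or NULL).
#' @export
evaluate_phasing <- function(result, truth_hapA, variants, genes = NULL,
                             blacklist = NULL, largest_block_only = TRUE) {
  n_total <- nrow(variants)
  asg <- result$assign
  if (largest_block_only && nrow(asg)) {
    lb <- largest_block_id(result)
    asg <- asg[asg$block == lb, , drop = FALSE]
  }
  excl <- if (is.null(blacklist)) integer(0) else intersect(blacklist, asg$var)
  keep <- !(asg$var %in% excl)
  n_resolved <- nrow(asg)
  eval_set <- asg[keep, , drop = FALSE]

  truth <- truth_hapA[eval_set$var + 1L]
  missing <- is.na(truth)
  n_missing <- sum(missing)
  eval_set <- eval_set[!missing, , drop = FALSE]
  truth <- truth[!missing]

  n_correct <- 0L
  sw_num <- 0L; sw_den <- 0L
  if (nrow(eval_set)) {
    for (b in unique(eval_set$block)) {
      sel <- eval_set$block == b
      agree <- sum(eval_set$phase[sel] == truth[sel])
      n_correct <- n_correct + max(agree, sum(sel) - agree)
      # switch error over position-adjacent resolved members of the block
      o <- order(variants$pos[eval_set$var[sel] + 1L])
      ph <- eval_set$phase[sel][o]
      tr <- truth[sel][o]
      if (length(ph) >= 2L) {
        rel_p <- diff(ph) != 0L
        rel_t <- diff(tr) != 0L
        sw_num <- sw_num + sum(rel_p != rel_t)
        sw_den <- sw_den + length(rel_p)
      }
    }
  }
  n_eval <- nrow(eval_set)

  gene_level <- NULL
  if (!is.null(genes) && nrow(genes)) {
    resolved_vars <- eval_set$var
    correct_flags <- logical(nrow(eval_set))
    for (b in unique(eval_set$block)) {
      sel <- eval_set$block == b
      agree <- sum(eval_set$phase[sel] == truth[sel])
      flip <- agree < sum(sel) - agree
      correct_flags[sel] <- (eval_set$phase[sel] == truth[sel]) != flip
    }
    gene_level <- do.call(rbind, lapply(seq_len(nrow(genes)), function(g) {
      inside <- variants$pos >= genes$start[g] & variants$pos < genes$end[g]
      vin <- variants$index[inside]
      rsel <- resolved_vars %in% vin
      data.frame(gene = genes$gene[g], n_het = sum(inside),
                 n_resolved = sum(rsel),
                 n_correct = sum(correct_flags[rsel]),
                 stringsAsFactors = FALSE)
    }))
  }

  structure(list(n_total_het = n_total,
                 n_resolved = n_resolved,
                 resolution = if (n_total) n_resolved / n_total else NaN,
                 n_correct = n_correct,
                 n_evaluated = n_eval,
                 accuracy = if (n_eval) n_correct / n_eval else NaN,
                 switch_error = if (sw_den) sw_num / sw_den else NaN,
                 n_excluded = length(excl),
                 n_truth_missing = n_missing,
                 gene_level = gene_level),
            class = "phasing_evaluation")
}

#' @export
print.phasing_evaluation <- function(x, ...) {
  cat("<phasing_evaluation>\n",
      "  resolution:   ", x$n_resolved, "/", x$n_total_het, " = ",
      formatC(100 * x$resolution, digits = 2, format = "f"), "%\n",
      "  accuracy:     ", x$n_correct, "/", x$n_evaluated, " = ",
      formatC(100 * x$accuracy, digits = 2, format = "f"), "%",
      if (x$n_excluded) paste0(" (", x$n_excluded, " blacklisted excluded)"),
      "\n  switch error: ",
      formatC(100 * x$switch_error, digits = 2, format = "f"), "%\n", sep = "")
  invisible(x)
}

#' Capture enrichment fold
#'
#' Measures how strongly capture concentrated the library on the targets.
#' Fragments are classified on-target (>= 1 read overlapping a target
#' interval) or off-target, and the fold is the ratio of the two counts
#' each normalized by its expected share under uniform anchors — the
#' read-length-padded target footprint `c` gives expected shares
#' `1-(1-c)^2` (paired) and `(1-c)^2`. For uniform pre-capture data the
#' fold is 1; after capture at fold F it estimates F. With no off-target
#' fragments the fold is `Inf`.
#'
#' Also reports per-100 kb read counts and, when a restriction map is
#' supplied, per-probe read coverage against size-matched "virtual probes"
#' drawn off-target near cut sites (seeded), with the fraction of probes
#' reaching >= 5x the virtual-probe mean.
#'
#' @param matrix captured `fragment_matrix` (anchors in `frags`).
#' @param target_intervals merged target interval matrix.
#' @param locus_length locus length (bp).
#' @param probe_set optional `probe_set` for the virtual-probe comparison.
#' @param restriction_map optional `restriction_map` used to place virtual
#'   probes near cut sites.
#' @param bin_size bin size for read counts (default 100 kb).
#' @param seed seed for virtual-probe sampling.
#' @return an `enrichment_report`: list with `fold`, `n_on`, `n_off`,
#'   `per_bin`, and optionally `probe_sensitivity` (fraction of probes
#'   with >= 5x virtual coverage) and `virtual_mean`.
#' @export
enrichment_fold <- function(matrix, target_intervals, locus_length,
                            probe_set = NULL, restriction_map = NULL,
                            bin_size = 1e5, seed = 1L) {
  fr <- matrix$frags
  rl <- if (!is.na(matrix$read_length)) matrix$read_length else 100L
  paired <- !is.na(fr$pos2)
  on1 <- iv_overlaps_any(iv(fr$pos1, fr$pos1 + rl), target_intervals)
  on2 <- rep(FALSE, nrow(fr))
  if (any(paired))
    on2[paired] <- iv_overlaps_any(iv(fr$pos2[paired], fr$pos2[paired] + rl),
                                   target_intervals)
  on <- on1 | on2
  n_on <- sum(on); n_off <- sum(!on)

  # expected on/off shares under uniform anchors, read-length padding
  pad <- iv_merge(iv_clip(iv(target_intervals[, "start"] - (rl - 1),
                             target_intervals[, "end"]), 0, locus_length))
  c_eff <- iv_width(pad) / locus_length
  p_on_paired <- 1 - (1 - c_eff)^2
  p_on_single <- c_eff
  exp_on <- sum(ifelse(paired, p_on_paired, p_on_single))
  exp_off <- nrow(fr) - exp_on
  fold <- if (n_off == 0L) Inf else (n_on / exp_on) / (n_off / exp_off)

  reads <- c(fr$pos1, fr$pos2[paired])
  nb <- max(1L, ceiling(locus_length / bin_size))
  per_bin <- data.frame(bin_start = (seq_len(nb) - 1L) * bin_size,
                        n_reads = tabulate(pmin(floor(reads / bin_size),
                                                nb - 1L) + 1L, nbins = nb))

  out <- list(fold = fold, n_on = n_on, n_off = n_off, c_eff = c_eff,
              per_bin = per_bin)
  if (!is.null(probe_set) && nrow(probe_set$probes)) {
    set.seed(seed)
    pv <- probe_intervals(probe_set)
    plen <- probe_set$design_params$probe_length
    # virtual probes: same count and length, placed near cut sites but
    # outside the real target footprint
    cand_anchor <- if (!is.null(restriction_map) &&
                       length(restriction_map$sites))
      restriction_map$sites else sample.int(locus_length, 5000L)
    vstart <- numeric(0)
    offsets <- sample(500:5000, nrow(pv) * 4L, replace = TRUE) *
      sample(c(-1, 1), nrow(pv) * 4L, replace = TRUE)
    anchors <- sample(cand_anchor, nrow(pv) * 4L, replace = TRUE)
    cand <- anchors + offsets
    cand <- cand[cand >= 0 & cand + plen <= locus_length]
    keep <- !iv_overlaps_any(iv(cand, cand + plen), target_intervals)
    vstart <- utils::head(cand[keep], nrow(pv))
    rr <- IRanges::IRanges(reads + 1L, reads + rl)
    cov_real <- IRanges::countOverlaps(to_iranges(pv), rr)
    cov_virt <- IRanges::countOverlaps(to_iranges(iv(vstart, vstart + plen)), rr)
    vm <- mean(cov_virt)
    out$virtual_mean <- vm
    out$probe_sensitivity <- if (is.finite(vm) && vm > 0)
      mean(cov_real >= 5 * vm) else NaN
  }
  structure(out, class = "enrichment_report")
}

#' @export
print.enrichment_report <- function(x, ...) {
  cat("<enrichment_report> fold = ",
      if (is.infinite(x$fold)) "Inf" else formatC(x$fold, digits = 1,
                                                  format = "f"),
      " (", x$n_on, " on-target / ", x$n_off, " off-target fragments)\n",
      sep = "")
  invisible(x)
}

#' Binned contact-profile concordance between two datasets
#'
#' Bins both anchors of every paired fragment (default 100 kb), counts
#' fragments per bin pair (i <= j), and returns the squared Pearson
#' correlation of `log10(1 + count)` over all bin pairs with a nonzero
#' count in either dataset. A dataset against itself gives exactly 1.
#'
#' @param matrix_a,matrix_b `fragment_matrix` objects over the same locus.
#' @param locus_length locus length (bp).
#' @param bin_size bin size (default 100 kb).
#' @return squared Pearson correlation (r^2).
#' @export
binned_contact_correlation <- function(matrix_a, matrix_b, locus_length,
                                       bin_size = 1e5) {
  nb <- max(1L, ceiling(locus_length / bin_size))
  pair_counts <- function(m) {
    fr <- m$frags[!is.na(m$frags$pos2), , drop = FALSE]
    b1 <- pmin(floor(fr$pos1 / bin_size), nb - 1L)
    b2 <- pmin(floor(fr$pos2 / bin_size), nb - 1L)
    i <- pmin(b1, b2); j <- pmax(b1, b2)
    key <- i * nb + j + 1L
    tabulate(key, nbins = nb * nb)
  }
  ca <- pair_counts(matrix_a)
  cb <- pair_counts(matrix_b)
  nz <- ca > 0L | cb > 0L
  if (sum(nz) < 2L)
    stop("fewer than 2 nonzero bin pairs; correlation undefined")
  stats::cor(log10(1 + ca[nz]), log10(1 + cb[nz]))^2
}
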