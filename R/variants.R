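# Heterozygous SNV tables. A variant table is a data.frame with columns
#   index        dense 0-based rank within the locus
#   pos          0-based position
#   ref, alt     single bases, ref != alt
#   truth_phase  allele carried by haplotype A (0 = ref, 1 = alt) or NA
#   density_flag TRUE when the variant lies in a high-variant-density window
# Positions are strictly increasing with index; all sites are heterozygous.

new_variant_table <- function(pos, ref, alt, truth_phase = NA_integer_,
                              density_flag = FALSE) {
  o <- order(pos)
  pos <- pos[o]
  if (anyDuplicated(pos)) stop("duplicate variant positions")
  n <- length(pos)
  df <- data.frame(index = seq_len(n) - 1L, pos = as.numeric(pos),
                   ref = rep_len(ref, n)[o], alt = rep_len(alt, n)[o],
                   truth_phase = as.integer(rep_len(truth_phase, n)[o]),
                   density_flag = rep_len(density_flag, n)[o],
                   stringsAsFactors = FALSE)
  if (any(df$ref == df$alt)) stop("ref and alt alleles must differ")
  df
}

#' Flag variants in high-variant-density windows
#'
#' Tiles the locus into fixed windows (default 2 kb), counts SNVs per
#' window, and flags every variant lying in a window whose count reaches
#' the top decile of window counts. This operationalizes "high variant
#' density": the windows where proximity-ligation phasing and short-read
#' truth sets are both most error prone.
#'
#' @param pos variant positions (0-based).
#' @param locus_length locus length in bp.
#' @param window window size in bp (default 2000).
#' @param top_frac fraction of windows counted as high density (default 0.1).
#' @return logical vector along `pos`.
#' @export
flag_high_density <- function(pos, locus_length, window = 2000,
                              top_frac = 0.1) {
  if (length(pos) == 0L) return(logical(0))
  nb <- max(1L, ceiling(locus_length / window))
  w <- pmin(floor(pos / window), nb - 1L)
  counts <- tabulate(w + 1L, nbins = nb)
  thr <- stats::quantile(counts, probs = 1 - top_frac, names = FALSE, type = 1)
  thr <- max(thr, 1)
  hot <- which(counts >= thr) - 1L
  w %in% hot
}

#' Read heterozygous SNVs from a VCF
#'
#' Keeps biallelic SNVs with a heterozygous genotype (`0/1`, `0|1`, `1|0`);
#' indels, multiallelic records and non-het genotypes are dropped with a
#' warning count. Phased genotypes supply the truth phase (`0|1` means the
#' reference allele is on haplotype A). VCF positions (1-based) are
#' converted to the package's 0-based convention.
#'
#' @param path VCF 4.x file (plain text or gzip).
#' @param locus_length optional bound used to set density flags; if `NULL`
#'   flags are left `FALSE`.
#' @return a variant table (see [simulate_variants()]); attribute
#'   `n_rejected` counts dropped records.
#' @export
read_variants_vcf <- function(path, locus_length = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  n_in <- nrow(fix)
  if (n_in == 0L) {
    out <- new_variant_table(numeric(0), character(0), character(0))
    attr(out, "n_rejected") <- 0L
    return(out)
  }
  gt_raw <- if (ncol(v@gt) >= 2L) v@gt[, 2L] else rep(NA_character_, n_in)
  gt <- sub(":.*$", "", gt_raw)
  snv <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT) & fix$REF %in% c("A", "C", "G", "T") &
    fix$ALT %in% c("A", "C", "G", "T")
  het <- gt %in% c("0/1", "1/0", "0|1", "1|0")
  keep <- snv & het
  n_rej <- sum(!keep)
  if (n_rej > 0L)
    warning(n_rej, " VCF record(s) dropped (not biallelic het SNVs)")
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep]
  phase <- ifelse(gt == "0|1", 0L, ifelse(gt == "1|0", 1L, NA_integer_))
  out <- new_variant_table(pos = as.numeric(fix$POS) - 1, ref = fix$REF,
                           alt = fix$ALT, truth_phase = phase)
  if (!is.null(locus_length))
    out$density_flag <- flag_high_density(out$pos, locus_length)
  attr(out, "n_rejected") <- n_rej
  out
}

#' Write a phased truth VCF
#'
#' Emits a minimal VCF 4.2 with phased genotypes `0|1` / `1|0` taken from a
#' haplotype bit vector (bit = alt allele on haplotype A). Used by the
#' simulator to serialize both the generative truth and the corrupted
#' "reported truth".
#'
#' @param variants variant table.
#' @param hapA bit vector: alt allele carried by haplotype A.
#' @param path output path.
#' @param contig contig name written to the header and CHROM column.
#' @param contig_length contig length for the header.
#' @param sample sample column name.
#' @export
write_truth_vcf <- function(variants, hapA, path, contig = "locus",
                            contig_length = NULL, sample = "SIM") {
  stopifnot(length(hapA) == nrow(variants))
  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_length))
             sprintf("##contig=<ID=%s,length=%d>", contig, as.integer(contig_length))
           else sprintf("##contig=<ID=%s>", contig),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  gt <- ifelse(hapA == 1L, "1|0", "0|1")
  body <- if (nrow(variants) > 0L)
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t%s", contig,
            as.integer(variants$pos + 1L), variants$ref, variants$alt, gt)
  else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
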