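#' Render simulated fragments as an aligned SAM file
#'
#' Optional read-level emitter for exercising the alignment-consuming
#' path: every simulated anchor becomes one aligned read whose sequence
#' comes from its source homolog, with each recorded allele observation
#' patched in (so allele-level errors are faithfully reflected in the
#' bases). Paired anchors share a query name with first/second-of-pair
#' flags; LFR fragments are written single-end.
#'
#' @param matrix simulator `fragment_matrix` (origin metadata required).
#' @param variants variant table.
#' @param hap_sequences named character vector from
#'   [haplotype_sequences()].
#' @param path output SAM path.
#' @param chrom contig name.
#' @param chrom_length contig length for the header.
#' @export
write_sam <- function(matrix, variants, hap_sequences, path,
                      chrom = "locus", chrom_length = nchar(hap_sequences[[1]])) {
  fr <- matrix$frags
  obs <- matrix$obs
  rl <- matrix$read_length
  stopifnot(!is.null(fr$hap1))
  qual_char <- function(q) strrep(intToUtf8(q + 33L), rl)
  qconst <- qual_char(if (nrow(obs)) obs$qual[1] else 30L)
  allele_base <- function(vidx, allele)
    ifelse(allele == 1L, variants$alt[vidx + 1L], variants$ref[vidx + 1L])

  read_seq <- function(fr_sub, p, hap, end_label) {
    s <- substring(hap_sequences[hap + 1L], p + 1, p + rl)
    o <- obs[obs$end == end_label & obs$frag %in% fr_sub$id, , drop = FALSE]
    if (nrow(o)) {
      row <- match(o$frag, fr_sub$id)
      off <- variants$pos[o$var + 1L] - p[row] + 1L
      b <- allele_base(o$var, o$allele)
      for (k in seq_along(row))
        if (off[k] >= 1L && off[k] <= rl)
          substr(s[row[k]], off[k], off[k]) <- b[k]
    }
    s
  }

  nm <- sprintf("F%06d", fr$id)
  paired <- !is.na(fr$pos2)
  lines <- c(sprintf("@HD\tVN:1.6\tSO:unsorted"),
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, as.integer(chrom_length)))
  seq1 <- read_seq(fr, fr$pos1, fr$hap1, 1L)
  body1 <- sprintf("%s\t%d\t%s\t%d\t60\t%dM\t%s\t%d\t0\t%s\t%s",
                   nm, ifelse(paired, 65L, 0L), chrom,
                   as.integer(fr$pos1 + 1L), rl,
                   ifelse(paired, "=", "*"),
                   as.integer(ifelse(paired, fr$pos2 + 1L, 0L)),
                   seq1, qconst)
  body2 <- character(0)
  if (any(paired)) {
    fp <- fr[paired, , drop = FALSE]
    s2 <- read_seq(fp, fp$pos2, fp$hap2, 2L)
    body2 <- sprintf("%s\t129\t%s\t%d\t60\t%dM\t=\t%d\t0\t%s\t%s",
                     sprintf("F%06d", fp$id), chrom,
                     as.integer(fp$pos2 + 1L), rl,
                     as.integer(fp$pos1 + 1L), s2, qconst)
  }
  writeLines(c(lines, body1, body2), path)
  invisible(path)
}

# parse a CIGAR string into ref-consuming aligned blocks:
# returns data.frame(qstart, rstart, len) with 0-based starts
cigar_blocks <- function(cigar, pos0) {
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1]]
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  q <- 0L; r <- pos0
  out <- list()
  for (op in ops) {
    n <- as.integer(sub("[A-Z=]$", "", op))
    t <- substr(op, nchar(op), nchar(op))
    if (t %in% c("M", "=", "X")) {
      out[[length(out) + 1L]] <- c(q, r, n)
      q <- q + n; r <- r + n
    } else if (t %in% c("I", "S")) q <- q + n
    else if (t %in% c("D", "N")) r <- r + n
  }
  if (!length(out))
    return(data.frame(qstart = integer(0), rstart = numeric(0),
                      len = integer(0)))
  m <- do.call(rbind, out)
  data.frame(qstart = m[, 1], rstart = m[, 2], len = m[, 3])
}

#' Extract the allele-observation fragment matrix from aligned reads
#'
#' Converts aligned paired-end reads plus a heterozygous SNV table into
#' phasing evidence: both mates of a pair merge into one fragment; at
#' every covered het site the base call maps to allele 0/1 (or is
#' discarded when it matches neither allele, or its base quality is below
#' `min_baseq`); reads with mapping quality below `min_mapq` or unmapped
#' reads are dropped. Read-end labels come from the mate flags. A variant
#' observed twice within one fragment keeps the higher-quality call;
#' quality ties with conflicting alleles drop the site. Exact duplicate
#' fragments (same anchors, same alleles) are collapsed with a count.
#' All dropped material is tallied in `filter_stats`.
#'
#' @param sam_path SAM (or BAM) file over the locus.
#' @param variants variant table of biallelic het SNVs.
#' @param min_mapq minimum mapping quality (default 30).
#' @param min_baseq minimum base quality (default 20).
#' @return a `fragment_matrix` with `filter_stats`.
#' @export
extract_fragments <- function(sam_path, variants, min_mapq = 30L,
                              min_baseq = 20L) {
  if (!file.exists(sam_path)) stop("SAM file not found: ", sam_path)
  bam <- sam_path
  if (!grepl("\\.bam$", sam_path)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(
      Rsamtools::asBam(sam_path, dest, overwrite = TRUE,
                       indexDestination = FALSE))
  }
  what <- c("qname", "flag", "pos", "mapq", "cigar", "seq", "qual")
  b <- Rsamtools::scanBam(bam,
        param = Rsamtools::ScanBamParam(what = what))[[1]]
  n_reads <- length(b$qname)
  stats_v <- c(unmapped = 0L, mapq = 0L, baseq = 0L, allele_mismatch = 0L,
               conflict_dropped = 0L, duplicates_collapsed = 0L)
  vp <- variants$pos
  obs_rows <- list()
  read_meta <- list()
  for (i in seq_len(n_reads)) {
    flag <- b$flag[i]
    if (bitwAnd(flag, 4L) > 0L) { stats_v["unmapped"] <- stats_v["unmapped"] + 1L; next }
    if (!is.na(b$mapq[i]) && b$mapq[i] < min_mapq) {
      stats_v["mapq"] <- stats_v["mapq"] + 1L; next
    }
    end <- if (bitwAnd(flag, 128L) > 0L) 2L else 1L
    pos0 <- b$pos[i] - 1L
    blocks <- cigar_blocks(as.character(b$cigar[i]), pos0)
    sq <- as.character(b$seq[i])
    qv <- as.integer(charToRaw(as.character(b$qual[i]))) - 33L
    for (k in seq_len(nrow(blocks))) {
      lo <- findInterval(blocks$rstart[k] - 0.5, vp) + 1L
      hi <- findInterval(blocks$rstart[k] + blocks$len[k] - 0.5, vp)
      if (hi < lo) next
      for (v in lo:hi) {
        off <- vp[v] - blocks$rstart[k] + blocks$qstart[k] + 1L
        base <- substr(sq, off, off)
        q <- qv[off]
        if (q < min_baseq) { stats_v["baseq"] <- stats_v["baseq"] + 1L; next }
        al <- if (base == variants$ref[v]) 0L
              else if (base == variants$alt[v]) 1L else NA_integer_
        if (is.na(al)) {
          stats_v["allele_mismatch"] <- stats_v["allele_mismatch"] + 1L; next
        }
        obs_rows[[length(obs_rows) + 1L]] <-
          c(i = i, var = v - 1L, allele = al, qual = q, end = end)
      }
    }
    read_meta[[length(read_meta) + 1L]] <-
      list(i = i, qname = b$qname[i], end = end, pos0 = pos0)
  }

  if (!length(read_meta)) {
    return(new_fragment_matrix(empty_obs(),
                               data.frame(id = integer(0), name = character(0),
                                          pos1 = numeric(0), pos2 = numeric(0)),
                               filter_stats = stats_v))
  }
  meta <- data.frame(i = vapply(read_meta, `[[`, 0, "i"),
                     qname = vapply(read_meta, `[[`, "", "qname"),
                     end = vapply(read_meta, function(x) x$end, 0L),
                     pos0 = vapply(read_meta, `[[`, 0, "pos0"),
                     stringsAsFactors = FALSE)
  qnames <- unique(meta$qname)
  fid <- match(meta$qname, qnames)

  om <- if (length(obs_rows)) as.data.frame(do.call(rbind, obs_rows))
        else data.frame(i = integer(0), var = integer(0), allele = integer(0),
                        qual = integer(0), end = integer(0))
  om$frag <- fid[match(om$i, meta$i)]

  # resolve duplicate observations of one variant within a fragment
  if (nrow(om)) {
    om <- om[order(om$frag, om$var, -om$qual), , drop = FALSE]
    key <- paste(om$frag, om$var)
    first <- !duplicated(key)
    # conflicting tie: best and second-best have equal quality, different allele
    drop_keys <- character(0)
    dupk <- key[!first]
    if (length(dupk)) {
      for (kk in unique(dupk)) {
        rows <- which(key == kk)
        best <- rows[1]
        ties <- rows[om$qual[rows] == om$qual[best]]
        if (length(unique(om$allele[ties])) > 1L) drop_keys <- c(drop_keys, kk)
      }
    }
    if (length(drop_keys)) {
      stats_v["conflict_dropped"] <- length(drop_keys)
      om <- om[!(key %in% drop_keys), , drop = FALSE]
      key <- paste(om$frag, om$var)
      first <- !duplicated(key)
    }
    om <- om[first, , drop = FALSE]
  }

  pos1 <- suppressWarnings(
    tapply(ifelse(meta$end == 1L, meta$pos0, NA_real_), fid, min, na.rm = TRUE))
  pos2 <- suppressWarnings(
    tapply(ifelse(meta$end == 2L, meta$pos0, NA_real_), fid, min, na.rm = TRUE))
  pos1[!is.finite(pos1)] <- NA_real_
  pos2[!is.finite(pos2)] <- NA_real_
  frags <- data.frame(id = seq_along(qnames), name = qnames,
                      pos1 = as.numeric(pos1[as.character(seq_along(qnames))]),
                      pos2 = as.numeric(pos2[as.character(seq_along(qnames))]),
                      stringsAsFactors = FALSE)

  obs <- data.frame(frag = om$frag, var = om$var, allele = om$allele,
                    qual = om$qual, end = om$end)

  # collapse exact duplicates: same anchors and same allele string
  sig_obs <- vapply(split(seq_len(nrow(obs)), factor(obs$frag, levels = frags$id)),
                    function(ix) paste(obs$var[ix], obs$allele[ix],
                                       collapse = ";"), "")
  sig <- paste(frags$pos1, frags$pos2, sig_obs)
  dup <- duplicated(sig)
  if (any(dup)) {
    stats_v["duplicates_collapsed"] <- sum(dup)
    frags$dup_count <- as.integer(table(factor(sig, levels = sig[!dup]))[
      match(sig, sig[!dup])])
    keep_ids <- frags$id[!dup]
    obs <- obs[obs$frag %in% keep_ids, , drop = FALSE]
    frags <- frags[!dup, , drop = FALSE]
  }
  new_fragment_matrix(obs, frags, filter_stats = stats_v)
}
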