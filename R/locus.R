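#' Read a BED3/BED6 file
#'
#' Minimal BED reader with strict per-line validation: BED is 0-based
#' half-open; `track`/`browser`/comment lines are skipped. A malformed line
#' is rejected with its line number so hand-edited annotation files fail
#' loudly rather than silently shifting coordinates.
#'
#' @param path path to a BED file.
#' @return data.frame with columns `chrom`, `start`, `end` and, when a 4th
#'   column is present, `name`.
#' @keywords internal
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  out <- list(chrom = character(0), start = numeric(0), end = numeric(0),
              name = character(0))
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 3L)
      stop("malformed BED line ", i, " in ", path, ": fewer than 3 fields")
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0 || e < s)
      stop("malformed BED line ", i, " in ", path,
           ": bad coordinates '", f[2], "', '", f[3], "'")
    rows[[k]] <- list(chrom = f[1], start = s, end = e,
                      name = if (length(f) >= 4L) f[4] else NA_character_)
  }
  if (length(rows) == 0L)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), name = character(0),
                      stringsAsFactors = FALSE))
  data.frame(chrom = vapply(rows, `[[`, "", "chrom"),
             start = vapply(rows, `[[`, 0, "start"),
             end = vapply(rows, `[[`, 0, "end"),
             name = vapply(rows, `[[`, "", "name"),
             stringsAsFactors = FALSE)
}

#' Load a reference locus with repeats and gene annotations
#'
#' Reads a single-record FASTA (or a named record from a multi-record file)
#' together with optional repeat and gene/exon BED annotations and returns a
#' `reference_locus` object that every other module consumes. Coordinates are
#' 0-based half-open throughout; intervals are clipped to the sequence bounds.
#' Soft-masked (lower-case) stretches of the FASTA are added to the repeat
#' set before the sequence is upper-cased, so a repeat-masked reference needs
#' no separate repeat BED.
#'
#' Gene annotations are read from a BED file whose 4th column names the gene;
#' each line is treated as one exon of that gene and the gene interval is the
#' span of its exons.
#'
#' @param fasta_path path to the locus FASTA.
#' @param repeats_bed_path optional BED of repeat intervals.
#' @param genes_bed_path optional BED of exons (name column = gene id).
#' @param record optional record name when the FASTA holds several.
#' @param offset 0-based genomic start of the locus (bookkeeping only).
#' @return object of class `reference_locus` with fields `name`, `sequence`
#'   (upper-case character string), `length`, `offset`, `repeats` (merged
#'   interval matrix), `genes` and `exons` (data.frames).
#' @export
load_locus <- function(fasta_path, repeats_bed_path = NULL,
                       genes_bed_path = NULL, record = NULL, offset = 0L) {
  if (!file.exists(fasta_path)) stop("FASTA file not found: ", fasta_path)
  # BStringSet preserves case so soft-masking survives the read
  ss <- Biostrings::readBStringSet(fasta_path)
  if (length(ss) == 0L) stop("FASTA has no records: ", fasta_path)
  if (is.null(record)) {
    if (length(ss) > 1L)
      stop("FASTA has ", length(ss), " records; select one with `record`")
    rec <- 1L
  } else {
    rec <- match(record, sub("\\s.*$", "", names(ss)))
    if (is.na(rec)) stop("record not found in FASTA: ", record)
  }
  name <- sub("\\s.*$", "", names(ss)[rec])
  seq_raw <- as.character(ss[[rec]])
  n <- nchar(seq_raw)

  # soft-mask convention: lower-case runs count as repeats
  soft <- iv_empty()
  low <- gregexpr("[acgtn]+", seq_raw)[[1]]
  if (low[1] != -1L)
    soft <- iv(low - 1L, low - 1L + attr(low, "match.length"))
  sequence <- toupper(seq_raw)
  if (grepl("[^ACGTN]", sequence))
    stop("sequence contains characters outside {A,C,G,T,N}")

  repeats <- soft
  if (!is.null(repeats_bed_path)) {
    rb <- read_bed(repeats_bed_path)
    if (nrow(rb) > 0L) repeats <- rbind(repeats, iv(rb$start, rb$end))
  }
  repeats <- iv_merge(iv_clip(repeats, 0L, n))

  exons <- data.frame(gene = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  genes <- data.frame(gene = character(0), start = numeric(0),
                      end = numeric(0), stringsAsFactors = FALSE)
  if (!is.null(genes_bed_path)) {
    gb <- read_bed(genes_bed_path)
    if (nrow(gb) > 0L) {
      gb$name[is.na(gb$name)] <- sprintf("gene%04d", seq_len(sum(is.na(gb$name))))
      gb$start <- pmax(gb$start, 0)
      gb$end <- pmin(gb$end, n)
      gb <- gb[gb$end > gb$start, , drop = FALSE]
      exons <- data.frame(gene = gb$name, start = gb$start, end = gb$end,
                          stringsAsFactors = FALSE)
      sp <- split(seq_len(nrow(exons)), exons$gene)
      genes <- data.frame(
        gene = names(sp),
        start = vapply(sp, function(i) min(exons$start[i]), 0),
        end = vapply(sp, function(i) max(exons$end[i]), 0),
        stringsAsFactors = FALSE)
      genes <- genes[order(genes$start), , drop = FALSE]
      rownames(genes) <- NULL
    }
  }

  structure(list(name = name, sequence = sequence, length = n,
                 offset = as.integer(offset), repeats = repeats,
                 genes = genes, exons = exons),
            class = "reference_locus")
}

#' @export
print.reference_locus <- function(x, ...) {
  cat("<reference_locus> ", x$name, "\n", sep = "")
  cat("  length: ", x$length, " bp; repeats: ", nrow(x$repeats),
      " intervals (", iv_width(x$repeats), " bp); genes: ",
      nrow(x$genes), "\n", sep = "")
  invisible(x)
}

IUPAC_ALPHABET <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
                    "B", "D", "H", "V", "N")

#' Locate restriction enzyme cut sites
#'
#' Scans the locus sequence for a restriction motif (IUPAC codes allowed)
#' and returns the 0-based cut positions `match_start + cut_offset`.
#' Overlapping matches are reported. Palindromic motifs (their own reverse
#' complement, e.g. HindIII A^AGCTT) need only the forward scan; for
#' non-palindromic motifs the reverse strand is scanned as well and the
#' reverse-strand cut position is mirrored onto the forward strand.
#'
#' @param locus a `reference_locus` (or a plain DNA character string).
#' @param motif IUPAC recognition sequence; default HindIII `AAGCTT`.
#' @param cut_offset cut position within the motif, in `[0, nchar(motif)]`;
#'   default 1 (A^AGCTT).
#' @param enzyme_name label stored in the map.
#' @return object of class `restriction_map` with sorted unique `sites`.
#' @export
find_restriction_sites <- function(locus, motif = "AAGCTT", cut_offset = 1L,
                                   enzyme_name = "HindIII") {
  seqstr <- if (inherits(locus, "reference_locus")) locus$sequence else
    toupper(as.character(locus))
  motif <- toupper(motif)
  if (nchar(motif) == 0L) stop("motif must be non-empty")
  bad <- setdiff(strsplit(motif, "")[[1]], IUPAC_ALPHABET)
  if (length(bad) > 0L)
    stop("invalid IUPAC character(s) in motif: ", paste(bad, collapse = ", "))
  if (cut_offset < 0L || cut_offset > nchar(motif))
    stop("cut_offset must lie within [0, motif length]")

  subject <- Biostrings::DNAString(seqstr)
  fwd <- Biostrings::matchPattern(motif, subject, fixed = FALSE)
  sites <- Biostrings::start(fwd) - 1L + cut_offset

  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(motif)))
  if (!identical(rc, motif)) {
    rev <- Biostrings::matchPattern(rc, subject, fixed = FALSE)
    # motif matched on minus strand at forward positions [m, m+k): the cut,
    # cut_offset into the minus-strand motif, mirrors to m + k - cut_offset
    sites <- c(sites,
               Biostrings::start(rev) - 1L + nchar(motif) - cut_offset)
  }
  structure(list(enzyme_name = enzyme_name, motif = motif,
                 cut_offset = as.integer(cut_offset),
                 sites = sort(unique(as.integer(sites)))),
            class = "restriction_map")
}

#' @export
print.restriction_map <- function(x, ...) {
  cat("<restriction_map> ", x$enzyme_name, " (", x$motif, ", cut offset ",
      x$cut_offset, "): ", length(x$sites), " sites\n", sep = "")
  invisible(x)
}

#' Construct the two haplotype sequences of a diploid locus
#'
#' Substitutes the alternate allele into the reference wherever a haplotype
#' carries the alt bit, yielding the full-length sequence of each homolog.
#' A variant whose stated reference allele disagrees with the reference base
#' is rejected (genotype/reference inconsistency).
#'
#' @param locus a `reference_locus`.
#' @param variants variant table (see [simulate_variants()]).
#' @param haplotypes list with bit vectors `hapA`, `hapB` (1 = alt allele).
#' @return named character vector of length 2 (`hapA`, `hapB`).
#' @export
haplotype_sequences <- function(locus, variants, haplotypes) {
  stopifnot(inherits(locus, "reference_locus"))
  if (nrow(variants) == 0L)
    return(c(hapA = locus$sequence, hapB = locus$sequence))
  if (any(variants$pos < 0 | variants$pos >= locus$length))
    stop("variant position outside locus")
  refbase <- substring(locus$sequence, variants$pos + 1L, variants$pos + 1L)
  bad <- which(refbase != variants$ref)
  if (length(bad) > 0L)
    stop("reference allele mismatch at ", length(bad), " site(s), first at pos ",
         variants$pos[bad[1]])
  sub_alleles <- function(bits) {
    s <- strsplit(locus$sequence, "")[[1]]
    s[variants$pos + 1L] <- ifelse(bits == 1L, variants$alt, variants$ref)
    paste(s, collapse = "")
  }
  c(hapA = sub_alleles(haplotypes$hapA), hapB = sub_alleles(haplotypes$hapB))
}
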