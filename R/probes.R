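#' Target intervals flanking restriction cut sites
#'
#' Capture targets for proximity-ligation libraries are the regions
#' immediately flanking the restriction cut sites, because every ligation
#' junction carries sequence from two cut-site neighborhoods. Returns the
#' symmetric `[site - flank, site + flank)` window per cut site, clipped to
#' the locus and merged where windows overlap.
#'
#' @param restriction_map a `restriction_map`.
#' @param flank flank size in bp on each side of the cut (default 400).
#' @param locus_length locus length for clipping.
#' @return merged interval matrix (0-based half-open).
#' @export
flank_targets <- function(restriction_map, flank = 400, locus_length) {
  stopifnot(flank > 0)
  sites <- restriction_map$sites
  if (length(sites) == 0L) {
    warning("restriction map has no sites; no targets")
    return(iv_empty())
  }
  iv_merge(iv_clip(iv(sites - flank, sites + flank), 0, locus_length))
}

#' Remove repeat intervals from target intervals
#'
#' @param intervals merged target intervals.
#' @param repeats merged repeat intervals.
#' @return sorted non-overlapping intervals covering `intervals \ repeats`;
#'   zero-length pieces are dropped.
#' @export
subtract_repeats <- function(intervals, repeats) {
  iv_subtract(intervals, repeats)
}

#' Tile fixed-length probes across target intervals
#'
#' Probes of `probe_length` nt are laid down from each interval start with
#' step `probe_length / tiling_density` (default 120 nt at 4X = 30 nt step);
#' if the regular grid leaves the 3' end uncovered a final probe is placed
#' flush with the interval end. Intervals shorter than one probe yield no
#' probe (their count is recorded in attribute `n_short_skipped`).
#'
#' @param intervals merged interval matrix.
#' @param probe_length probe length in nt (default 120).
#' @param tiling_density tiling density X (default 4).
#' @param source label for the probes (`"cut_site"` or `"exon"`).
#' @return a `probe_set`: list with `probes` data.frame
#'   (`start`, `end`, `source`) and `design_params`.
#' @export
tile_probes <- function(intervals, probe_length = 120L, tiling_density = 4L,
                        source = "cut_site") {
  if (tiling_density < 1L) stop("tiling_density must be >= 1")
  probe_length <- as.integer(probe_length)
  if (probe_length %% tiling_density != 0L)
    warning("probe_length not divisible by tiling_density; step rounded down")
  step <- max(1L, probe_length %/% as.integer(tiling_density))
  starts <- numeric(0)
  n_short <- 0L
  if (nrow(intervals) > 0L) {
    for (k in seq_len(nrow(intervals))) {
      a <- intervals[k, "start"]; b <- intervals[k, "end"]
      if (b - a < probe_length) { n_short <- n_short + 1L; next }
      s <- seq(a, b - probe_length, by = step)
      if (s[length(s)] + probe_length < b) s <- c(s, b - probe_length)
      starts <- c(starts, s)
    }
  }
  probes <- data.frame(start = starts, end = starts + probe_length,
                       source = rep_len(source, length(starts)),
                       stringsAsFactors = FALSE)
  structure(list(probes = probes,
                 design_params = list(probe_length = probe_length,
                                      tiling_density = as.integer(tiling_density),
                                      step = step)),
            class = "probe_set", n_short_skipped = n_short)
}

#' Tile probes over exonic targets
#'
#' Exon intervals are repeat-subtracted and tiled like cut-site targets,
#' except that pieces shorter than one probe are padded symmetrically to
#' `probe_length` (centered on the piece) rather than skipped — genic
#' targets must not be dropped just because an exon is short. If the padded
#' window would overlap a repeat it is slid within the locus to avoid it;
#' a piece with no repeat-free placement is dropped (counted).
#'
#' @param locus a `reference_locus` with exon annotations.
#' @param probe_length,tiling_density see [tile_probes()].
#' @return a `probe_set` with `source = "exon"`.
#' @export
exon_targets <- function(locus, probe_length = 120L, tiling_density = 4L) {
  stopifnot(inherits(locus, "reference_locus"))
  probe_length <- as.integer(probe_length)
  if (nrow(locus$exons) == 0L)
    return(tile_probes(iv_empty(), probe_length, tiling_density, "exon"))
  pieces <- iv_subtract(iv(locus$exons$start, locus$exons$end), locus$repeats)
  long <- pieces[pieces[, "end"] - pieces[, "start"] >= probe_length, ,
                 drop = FALSE]
  short <- pieces[pieces[, "end"] - pieces[, "start"] < probe_length, ,
                  drop = FALSE]
  padded <- iv_empty()
  n_dropped <- 0L
  if (nrow(short) > 0L) {
    for (k in seq_len(nrow(short))) {
      w <- short[k, "end"] - short[k, "start"]
      pad <- probe_length - w
      a <- short[k, "start"] - floor(pad / 2)
      a <- max(0, min(a, locus$length - probe_length))
      cand <- iv(a, a + probe_length)
      if (!any(iv_overlaps_any(cand, locus$repeats))) {
        padded <- rbind(padded, cand)
        next
      }
      # slide to the nearest repeat-free placement still covering the piece
      lo <- max(0, short[k, "end"] - probe_length)
      hi <- min(locus$length - probe_length, short[k, "start"])
      placed <- FALSE
      if (hi >= lo) for (a2 in seq(lo, hi)) {
        cand <- iv(a2, a2 + probe_length)
        if (!any(iv_overlaps_any(cand, locus$repeats))) {
          padded <- rbind(padded, cand); placed <- TRUE; break
        }
      }
      if (!placed) n_dropped <- n_dropped + 1L
    }
  }
  ps <- tile_probes(iv_merge(rbind(long, padded)), probe_length,
                    tiling_density, "exon")
  attr(ps, "n_unplaceable") <- n_dropped
  ps
}

#' Full capture design: cut-site flanks plus exons
#'
#' The complete probe design for a locus: non-repetitive restriction-site
#' flanks tiled at the stated density, plus exonic targets. Identical
#' intervals arising from both sources are deduplicated (cut-site label
#' wins). Deterministic: identical inputs give identical output.
#'
#' @param locus a `reference_locus`.
#' @param restriction_map a `restriction_map` (default: HindIII scan).
#' @param flank flank size around each cut site (bp).
#' @param probe_length,tiling_density probe geometry.
#' @param include_exons tile exonic targets as well (default TRUE).
#' @return a `probe_set`; its `targets` field holds the repeat-subtracted
#'   cut-site target intervals.
#' @export
design_probes <- function(locus, restriction_map = NULL, flank = 400,
                          probe_length = 120L, tiling_density = 4L,
                          include_exons = TRUE) {
  stopifnot(inherits(locus, "reference_locus"))
  if (is.null(restriction_map))
    restriction_map <- find_restriction_sites(locus)
  targets <- subtract_repeats(
    flank_targets(restriction_map, flank, locus$length), locus$repeats)
  cs <- tile_probes(targets, probe_length, tiling_density, "cut_site")
  probes <- cs$probes
  if (include_exons && nrow(locus$exons) > 0L) {
    ex <- exon_targets(locus, probe_length, tiling_density)
    probes <- rbind(probes, ex$probes)
  }
  o <- order(probes$start, probes$source)  # "cut_site" < "exon"
  probes <- probes[o, , drop = FALSE]
  probes <- probes[!duplicated(probes[, c("start", "end")]), , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(probes = probes,
                 targets = targets,
                 design_params = list(probe_length = as.integer(probe_length),
                                      tiling_density = as.integer(tiling_density),
                                      flank = flank,
                                      enzyme = restriction_map$enzyme_name)),
            class = "probe_set")
}

#' @export
print.probe_set <- function(x, ...) {
  cat("<probe_set> ", nrow(x$probes), " probes (",
      sum(x$probes$source == "cut_site"), " cut-site, ",
      sum(x$probes$source == "exon"), " exon), length ",
      x$design_params$probe_length, " nt\n", sep = "")
  invisible(x)
}

probe_intervals <- function(probe_set) {
  if (nrow(probe_set$probes) == 0L) return(iv_empty())
  iv(probe_set$probes$start, probe_set$probes$end)
}

#' Merged footprint of a probe design
#'
#' The union of all probe intervals — the capture bait space. This is the
#' interval set to measure enrichment against, since capture retains
#' fragments by probe overlap.
#'
#' @param probe_set a `probe_set`.
#' @return merged interval matrix.
#' @export
probe_footprint <- function(probe_set) {
  iv_merge(probe_intervals(probe_set))
}

#' Summarize a probe design
#'
#' @param probe_set a `probe_set`.
#' @param locus_length locus length in bp.
#' @param bin_size bin size for the per-bin probe counts (default 100 kb).
#' @return list with `total_probes`, `bases_covered` (>= 1 probe),
#'   `mean_depth` (mean per-base probe depth over the probe footprint) and
#'   `per_bin` (data.frame of probe counts per bin, binned by probe start).
#' @export
design_summary <- function(probe_set, locus_length, bin_size = 1e5) {
  pr <- probe_set$probes
  nb <- max(1L, ceiling(locus_length / bin_size))
  bins <- data.frame(bin_start = (seq_len(nb) - 1L) * bin_size,
                     n_probes = tabulate(
                       if (nrow(pr)) pmin(floor(pr$start / bin_size), nb - 1L) + 1L
                       else integer(0), nbins = nb))
  if (nrow(pr) == 0L)
    return(list(total_probes = 0L, bases_covered = 0, mean_depth = 0,
                per_bin = bins))
  cov <- iv_merge(probe_intervals(probe_set))
  footprint <- iv_width(cov)
  list(total_probes = nrow(pr),
       bases_covered = footprint,
       mean_depth = sum(pr$end - pr$start) / footprint,
       per_bin = bins)
}

#' Write probes as BED6 (name = source, score = 0, strand = +)
#' @param probe_set a `probe_set`.
#' @param path output BED path.
#' @param chrom contig name for column 1.
#' @export
write_probes_bed <- function(probe_set, path, chrom = "locus") {
  pr <- probe_set$probes
  lines <- if (nrow(pr)) sprintf("%s\t%d\t%d\t%s\t0\t+", chrom,
                                 as.integer(pr$start), as.integer(pr$end),
                                 pr$source) else character(0)
  writeLines(lines, path)
  invisible(path)
}

#' Write target intervals as BED3
#' @param intervals interval matrix.
#' @param path output path.
#' @param chrom contig name.
#' @export
write_targets_bed <- function(intervals, path, chrom = "locus") {
  lines <- if (nrow(intervals))
    sprintf("%s\t%d\t%d", chrom, as.integer(intervals[, "start"]),
            as.integer(intervals[, "end"])) else character(0)
  writeLines(lines, path)
  invisible(path)
}
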