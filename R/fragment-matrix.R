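# The fragment matrix: allele-level phasing evidence.
#
# A `fragment_matrix` holds one row per allele observation:
#   obs   data.frame(frag, var, allele, qual, end)
#         frag   integer fragment id (matches frags$id)
#         var    0-based variant index
#         allele observed allele bit (0 = ref, 1 = alt)
#         qual   Phred-scaled base quality
#         end    read-end label (1 or 2)
#   frags data.frame(id, pos1, pos2, ...) one row per fragment; simulator
#         output additionally carries origin metadata (hap1, hap2, htrans,
#         on_target), which is never consulted by the phaser.
# Observations are sorted by (frag, var); a fragment observes a variant at
# most once. Fragments with < 2 observations are uninformative for phasing
# but are kept for genotyping.

new_fragment_matrix <- function(obs, frags, read_length = NA_integer_,
                                filter_stats = integer(0)) {
  o <- order(obs$frag, obs$var)
  obs <- obs[o, , drop = FALSE]
  rownames(obs) <- NULL
  rownames(frags) <- NULL
  structure(list(obs = obs, frags = frags, read_length = read_length,
                 filter_stats = filter_stats),
            class = "fragment_matrix")
}

empty_obs <- function() {
  data.frame(frag = integer(0), var = integer(0), allele = integer(0),
             qual = integer(0), end = integer(0))
}

#' @export
print.fragment_matrix <- function(x, ...) {
  k <- table(factor(x$obs$frag, levels = x$frags$id))
  cat("<fragment_matrix> ", nrow(x$frags), " fragments, ", nrow(x$obs),
      " allele observations (", sum(k >= 2L), " informative fragments)\n",
      sep = "")
  if (length(x$filter_stats))
    cat("  filters: ",
        paste(names(x$filter_stats), x$filter_stats, sep = "=", collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

# fragment ids (not row numbers) of fragments with >= min_obs observations
informative_frag_ids <- function(matrix, min_obs = 2L) {
  tab <- table(matrix$obs$frag)
  as.integer(names(tab)[tab >= min_obs])
}

FRAGMENT_FILE_HEADER <- "#targeted-haploseq-fragments v1"

#' Write a fragment matrix to the tab-separated fragment file format
#'
#' Format (bit-exact): a header line, then one line per fragment:
#' `frag_id  n_obs  obs...  quals` where each obs is `index:allele:endlabel`
#' and `quals` is a Phred+33 string aligned to the observations. Fragments
#' with zero observations are not written.
#'
#' @param matrix a `fragment_matrix`.
#' @param path output path.
#' @export
write_fragments <- function(matrix, path) {
  obs <- matrix$obs
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(FRAGMENT_FILE_HEADER, con)
  if (nrow(obs) > 0L) {
    nm <- if ("name" %in% names(matrix$frags))
      stats::setNames(matrix$frags$name, matrix$frags$id)
    else stats::setNames(sprintf("F%06d", matrix$frags$id), matrix$frags$id)
    fld <- sprintf("%d:%d:%d", obs$var, obs$allele, obs$end)
    sp <- split(seq_len(nrow(obs)), obs$frag)
    lines <- vapply(sp, function(i) {
      paste(nm[[as.character(obs$frag[i[1]])]], length(i),
            paste(fld[i], collapse = "\t"),
            intToUtf8(obs$qual[i] + 33L, multiple = FALSE), sep = "\t")
    }, "")
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a fragment file back into a `fragment_matrix`
#'
#' Inverse of [write_fragments()]; a write -> read -> write round trip is
#' byte-identical. Malformed lines are rejected with their line number.
#'
#' @param path fragment file path.
#' @export
read_fragments <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || lines[1] != FRAGMENT_FILE_HEADER)
    stop("not a fragment file (missing header): ", path)
  body <- lines[-1]
  body <- body[nzchar(body)]
  obs_list <- vector("list", length(body))
  names_out <- character(length(body))
  for (k in seq_along(body)) {
    f <- strsplit(body[k], "\t", fixed = TRUE)[[1]]
    n_obs <- suppressWarnings(as.integer(f[2]))
    if (length(f) < 4L || is.na(n_obs) || length(f) != n_obs + 3L)
      stop("malformed fragment line ", k + 1L, " in ", path)
    parts <- strsplit(f[3:(2 + n_obs)], ":", fixed = TRUE)
    if (any(lengths(parts) != 3L))
      stop("malformed observation on line ", k + 1L, " in ", path)
    m <- matrix(suppressWarnings(as.integer(unlist(parts))), ncol = 3L,
                byrow = TRUE)
    quals <- utf8ToInt(f[length(f)]) - 33L
    if (anyNA(m) || length(quals) != n_obs)
      stop("malformed fragment line ", k + 1L, " in ", path)
    names_out[k] <- f[1]
    obs_list[[k]] <- data.frame(frag = k, var = m[, 1], allele = m[, 2],
                                qual = quals, end = m[, 3])
  }
  obs <- if (length(obs_list)) do.call(rbind, obs_list) else empty_obs()
  frags <- data.frame(id = seq_along(body), name = names_out,
                      pos1 = rep(NA_real_, length(body)),
                      pos2 = rep(NA_real_, length(body)),
                      stringsAsFactors = FALSE)
  new_fragment_matrix(obs, frags)
}
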