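# Internal interval arithmetic. All intervals in this package are 0-based
# half-open [start, end), stored as two-column integer matrices; IRanges
# (1-based closed) does the set algebra behind the scenes.

iv <- function(start, end) {
  m <- cbind(start = as.numeric(start), end = as.numeric(end))
  if (any(m[, "end"] < m[, "start"])) stop("interval end < start")
  m
}

iv_empty <- function() cbind(start = numeric(0), end = numeric(0))

to_iranges <- function(x) {
  IRanges::IRanges(start = x[, "start"] + 1L, end = x[, "end"])
}

from_iranges <- function(r) {
  iv(IRanges::start(r) - 1L, IRanges::end(r))
}

# merge overlapping or adjacent intervals, sort by start
iv_merge <- function(x) {
  if (nrow(x) == 0L) return(iv_empty())
  x <- x[x[, "end"] > x[, "start"], , drop = FALSE]
  if (nrow(x) == 0L) return(iv_empty())
  from_iranges(IRanges::reduce(to_iranges(x)))
}

# set difference a \ b; both need not be merged
iv_subtract <- function(a, b) {
  if (nrow(a) == 0L) return(iv_empty())
  if (nrow(b) == 0L) return(iv_merge(a))
  from_iranges(IRanges::setdiff(to_iranges(a), to_iranges(b)))
}

iv_clip <- function(x, lo, hi) {
  if (nrow(x) == 0L) return(x)
  x[, "start"] <- pmax(x[, "start"], lo)
  x[, "end"] <- pmin(x[, "end"], hi)
  x[x[, "end"] > x[, "start"], , drop = FALSE]
}

iv_width <- function(x) sum(x[, "end"] - x[, "start"])

# TRUE for each position (0-based) lying inside some interval of x
iv_contains <- function(x, pos) {
  if (nrow(x) == 0L) return(rep(FALSE, length(pos)))
  r <- to_iranges(x)
  IRanges::overlapsAny(IRanges::IRanges(pos + 1L, pos + 1L), r)
}

# TRUE for each query interval overlapping any subject interval
iv_overlaps_any <- function(query, subject) {
  if (nrow(query) == 0L) return(logical(0))
  if (nrow(subject) == 0L) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(to_iranges(query), to_iranges(subject))
}
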