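# Haplotype assembly by minimum-error-correction (MEC) max-cut.
#
# Fragments vote on the relative phase of every variant pair they cover;
# the variant graph aggregates those votes into signed edge weights and a
# greedy max-cut local search (C++ inner loop, multiple restarts) finds a
# phase assignment per connected component. The achieved objective is
# always reported as the exact MEC score, not the cut surrogate.

# all within-fragment observation pairs of informative fragments, vectorized
# by fragment size. Columns: frag, vi, vj (vi < vj), ai, aj, qi, qj, ei, ej.
obs_pairs <- function(matrix) {
  obs <- matrix$obs
  empty <- data.frame(frag = integer(0), vi = integer(0), vj = integer(0),
                      ai = integer(0), aj = integer(0), qi = integer(0),
                      qj = integer(0), ei = integer(0), ej = integer(0))
  if (nrow(obs) < 2L) return(empty)
  sp <- split(seq_len(nrow(obs)), obs$frag)
  ks <- lengths(sp)
  sp <- sp[ks >= 2L]
  ks <- ks[ks >= 2L]
  if (!length(sp)) return(empty)
  out <- lapply(sort(unique(ks)), function(k) {
    rows <- matrix(unlist(sp[ks == k], use.names = FALSE), ncol = k,
                   byrow = TRUE)
    cmb <- utils::combn(k, 2L)
    i_idx <- as.vector(rows[, cmb[1L, ], drop = FALSE])
    j_idx <- as.vector(rows[, cmb[2L, ], drop = FALSE])
    data.frame(frag = obs$frag[i_idx], vi = obs$var[i_idx],
               vj = obs$var[j_idx], ai = obs$allele[i_idx],
               aj = obs$allele[j_idx], qi = obs$qual[i_idx],
               qj = obs$qual[j_idx], ei = obs$end[i_idx],
               ej = obs$end[j_idx])
  })
  do.call(rbind, out)
}

#' Build the variant graph from a fragment matrix
#'
#' Nodes are variants; an edge joins two variants co-covered by at least
#' one fragment. Each co-covering fragment votes for "same phase" (equal
#' alleles) or "opposite phase", weighted by the probability that both
#' base calls are correct; the edge weight is the signed sum
#' (cis votes - trans votes). Connected components bound the maximal
#' possible haplotype blocks.
#'
#' @param matrix a `fragment_matrix`.
#' @return list with `edges` (data.frame `vi`, `vj`, `weight`, `n_frags`),
#'   `membership` (component id per variant index, NA for variants with no
#'   informative edge) and `n_variants`.
#' @export
build_graph <- function(matrix) {
  pr <- obs_pairs(matrix)
  n_var <- if (nrow(matrix$obs)) max(matrix$obs$var) + 1L else 0L
  if (nrow(pr) == 0L) {
    return(list(edges = data.frame(vi = integer(0), vj = integer(0),
                                   weight = numeric(0), n_frags = integer(0)),
                membership = rep(NA_integer_, n_var), n_variants = n_var))
  }
  p_ok <- (1 - 10^(-pr$qi / 10)) * (1 - 10^(-pr$qj / 10))
  vote <- ifelse(pr$ai == pr$aj, p_ok, -p_ok)
  key <- pr$vi * n_var + pr$vj
  agg <- rowsum(cbind(w = vote, n = 1), group = key)
  keys <- as.numeric(rownames(agg))
  edges <- data.frame(vi = as.integer(keys %/% n_var),
                      vj = as.integer(keys %% n_var),
                      weight = agg[, "w"], n_frags = as.integer(agg[, "n"]))
  rownames(edges) <- NULL
  g <- igraph::graph_from_edgelist(
    cbind(as.character(edges$vi), as.character(edges$vj)), directed = FALSE)
  comp <- igraph::components(g)
  membership <- rep(NA_integer_, n_var)
  membership[as.integer(igraph::V(g)$name) + 1L] <- comp$membership
  list(edges = edges, membership = membership, n_variants = n_var)
}

#' Exact MEC score of a phase assignment
#'
#' The minimum-error-correction objective: per fragment, the smaller of
#' the mismatch counts against haplotype A and against its complement,
#' over the fragment's phased observations; summed over fragments.
#' Observations at unphased variants are excluded.
#'
#' @param matrix a `fragment_matrix`.
#' @param phase integer vector over 0-based variant indices (allele on
#'   haplotype A; `NA` = unphased).
#' @return integer MEC score.
#' @export
mec_score <- function(matrix, phase) {
  obs <- matrix$obs
  if (is.null(obs) || nrow(obs) == 0L) return(0L)
  ph <- phase[obs$var + 1L]
  keep <- !is.na(ph)
  if (!any(keep)) return(0L)
  mism <- as.integer(obs$allele[keep] != ph[keep])
  g <- obs$frag[keep]
  m <- rowsum(cbind(mism = mism, k = 1L), group = g)
  as.integer(sum(pmin(m[, "mism"], m[, "k"] - m[, "mism"])))
}

# BFS spanning-tree initialization: assign each newly reached node the spin
# that agrees with the signed majority of its already-assigned neighbours.
# Recovers the exact optimum on noise-free (balanced) components.
bfs_init <- function(n, adj) {
  s <- integer(n)
  s[1L] <- 1L
  visited <- logical(n)
  visited[1L] <- TRUE
  queue <- integer(n)
  queue[1L] <- 1L
  head <- 1L; tail <- 1L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    nb <- adj$idx[[i]]
    for (j in nb[!visited[nb]]) {
      w <- adj$w[[j]]
      k <- adj$idx[[j]]
      vis <- visited[k]
      f <- sum(w[vis] * s[k[vis]])
      s[j] <- if (f >= 0) 1L else -1L
      visited[j] <- TRUE
      tail <- tail + 1L
      queue[tail] <- j
    }
  }
  s[!visited] <- 1L
  s
}

#' Assemble haplotype blocks by max-cut local search
#'
#' Per connected component of the variant graph: random phase
#' initializations (plus one spanning-tree propagation start) are refined
#' by a best-improvement flip search on the signed graph; the restart with
#' the lowest exact MEC score wins. Variants not linked by any informative
#' fragment stay unresolved. Deterministic under a fixed seed.
#'
#' The cut search is then polished against the exact MEC objective:
#' single members and contiguous runs (up to `prune_max_segment` members)
#' are flipped while that lowers the true MEC — the cut surrogate
#' over-credits correlated votes when one multi-SNV read yields several
#' observation pairs. Finally, weakly supported members are pruned: any
#' run whose flip would change the MEC by less than `prune_min_margin`
#' observations is released to unresolved, because a single erroneous or
#' homologous-trans ligation can otherwise phase a small stretch
#' confidently wrong. Pruning only engages in components whose optimum
#' shows conflicting evidence (MEC > 0) and that are larger than twice
#' the segment scale; noise-free and small components are kept whole.
#' Pruned variants can be recovered by [lcp_refine()].
#'
#' @param matrix a `fragment_matrix`.
#' @param n_restarts restarts per component (default 20; the first is the
#'   spanning-tree start).
#' @param max_iters flip-sweep budget multiplier passed to the search.
#' @param seed RNG seed.
#' @param prune_min_margin minimum exact-MEC margin (in observations) to
#'   keep a member or short run (default 2; 0 disables pruning).
#' @param prune_max_segment longest run considered for flip polishing and
#'   pruning (default 8).
#' @return a `phasing_result`: list with `assign` (data.frame `var`,
#'   `block`, `phase`, `support`, `source`), `phase` (vector over all
#'   variant indices, NA = unresolved), `blocks` summary, `mec_score`,
#'   `unresolved`, `n_variants`.
#' @export
max_cut_phase <- function(matrix, n_restarts = 20L, max_iters = 100L,
                          seed = 1L, prune_min_margin = 2,
                          prune_max_segment = 8L) {
  set.seed(seed)
  graph <- build_graph(matrix)
  n_var <- graph$n_variants
  phase <- rep(NA_integer_, n_var)
  block_of <- rep(NA_integer_, n_var)
  support <- rep(NA_real_, n_var)

  comps <- split(which(!is.na(graph$membership)) - 1L,
                 graph$membership[!is.na(graph$membership)])
  comps <- comps[order(vapply(comps, min, 0))]

  ed <- graph$edges
  edge_comp <- graph$membership[ed$vi + 1L]
  obs_comp_frag <- NULL
  if (nrow(matrix$obs)) {
    fr_comp <- tapply(graph$membership[matrix$obs$var + 1L], matrix$obs$frag,
                      function(x) x[!is.na(x)][1])
  }

  for (cname in names(comps)) {
    nodes <- comps[[cname]]
    n <- length(nodes)
    if (n < 2L) next
    sub <- ed[edge_comp == as.integer(cname), , drop = FALSE]
    li <- match(sub$vi, nodes)
    lj <- match(sub$vj, nodes)
    # symmetric CSR
    src <- c(li, lj); dst <- c(lj, li); w <- c(sub$weight, sub$weight)
    o <- order(src)
    src <- src[o]; dst <- dst[o]; w <- w[o]
    ptr <- as.integer(c(0L, cumsum(tabulate(src, nbins = n))))
    adj <- list(idx = split(dst, factor(src, levels = seq_len(n))),
                w = split(w, factor(src, levels = seq_len(n))))

    frag_ids <- names(fr_comp)[!is.na(fr_comp) & fr_comp == as.integer(cname)]
    sub_obs <- matrix$obs[matrix$obs$frag %in% as.integer(frag_ids), ,
                          drop = FALSE]
    sub_mat <- list(obs = sub_obs)

    comp_mec <- function(s) {
      ph <- rep(NA_integer_, n_var)
      ph[nodes + 1L] <- ifelse(s == 1L, 0L, 1L)
      mec_score(sub_mat, ph)
    }

    best_s <- NULL
    best_mec <- Inf
    for (r in seq_len(n_restarts)) {
      s0 <- if (r == 1L) bfs_init(n, adj)
            else sample(c(-1L, 1L), n, replace = TRUE)
      s <- maxcut_local_search(ptr, dst - 1L, w, s0, as.integer(max_iters))
      m <- comp_mec(s)
      if (m < best_mec) { best_mec <- m; best_s <- s }
      if (best_mec == 0L) break
    }
    # polish against the exact MEC objective and measure flip margins
    h0 <- ifelse(best_s == 1L, 0L, 1L)
    io <- sub_obs[sub_obs$var %in% nodes, , drop = FALSE]
    fidx <- match(io$frag, unique(io$frag))
    oo <- order(fidx, io$var)
    io <- io[oo, , drop = FALSE]; fidx <- fidx[oo]
    rank <- match(io$var, nodes) - 1L
    frag_ptr <- as.integer(c(0L, cumsum(tabulate(fidx))))
    vo <- order(rank)
    var_ptr <- as.integer(c(0L, cumsum(tabulate(rank[vo] + 1L, nbins = n))))
    # margins are only meaningful well above the segment scale; tiny
    # components are reported whole
    ref <- mec_refine(frag_ptr, rank, as.integer(io$allele), h0,
                      var_ptr, fidx[vo] - 1L, vo - 1L,
                      as.integer(prune_max_segment), prune_min_margin,
                      do_prune = prune_min_margin > 0 && best_mec > 0L &&
                        n > 2L * prune_max_segment)
    best_s <- ifelse(ref$h == 0L, 1L, -1L)

    # per-member support: signed agreement field under the final phase
    fld <- numeric(n)
    for (i in seq_len(n))
      fld[i] <- sum(adj$w[[i]] * best_s[adj$idx[[i]]]) * best_s[i]

    kept <- !ref$pruned
    if (!any(kept)) next
    # pruning may split the component: re-derive blocks on the kept subgraph
    ek <- kept[li] & kept[lj]
    if (all(kept)) {
      pieces <- list(seq_len(n))
    } else if (!any(ek)) {
      pieces <- list()
    } else {
      gsub <- igraph::graph_from_edgelist(
        cbind(as.character(li[ek]), as.character(lj[ek])), directed = FALSE)
      cm <- igraph::components(gsub)$membership
      pieces <- split(as.integer(names(cm)), cm)
    }
    for (piece in pieces) {
      if (length(piece) < 2L) next
      s_p <- best_s[piece]
      if (s_p[which.min(nodes[piece])] == -1L) s_p <- -s_p
      phase[nodes[piece] + 1L] <- ifelse(s_p == 1L, 0L, 1L)
      block_of[nodes[piece] + 1L] <- min(nodes[piece])
      support[nodes[piece] + 1L] <- fld[piece]
    }
  }

  finalize_phasing(matrix, phase, block_of, support,
                   source = ifelse(is.na(phase), NA_character_, "mec"),
                   n_var = n_var)
}

finalize_phasing <- function(matrix, phase, block_of, support, source,
                             n_var) {
  resolved <- which(!is.na(phase)) - 1L
  assign_df <- data.frame(var = resolved,
                          block = block_of[resolved + 1L],
                          phase = phase[resolved + 1L],
                          support = support[resolved + 1L],
                          source = source[resolved + 1L],
                          stringsAsFactors = FALSE)
  blocks <- if (nrow(assign_df)) {
    sp <- split(assign_df$var, assign_df$block)
    data.frame(block_id = as.integer(names(sp)),
               n_members = lengths(sp),
               span = vapply(sp, function(v) max(v) - min(v), 0))
  } else data.frame(block_id = integer(0), n_members = integer(0),
                    span = numeric(0))
  rownames(blocks) <- NULL
  structure(list(assign = assign_df, phase = phase, blocks = blocks,
                 mec_score = mec_score(matrix, phase),
                 unresolved = setdiff(seq_len(n_var) - 1L, resolved),
                 n_variants = n_var),
            class = "phasing_result")
}

#' @export
print.phasing_result <- function(x, ...) {
  cat("<phasing_result> ", nrow(x$assign), "/", x$n_variants,
      " variants phased in ", nrow(x$blocks), " block(s); MEC = ",
      x$mec_score, "\n", sep = "")
  if (nrow(x$blocks)) {
    lb <- x$blocks[which.max(x$blocks$n_members), ]
    cat("  largest block: ", lb$n_members, " variants (id ", lb$block_id,
        ")\n", sep = "")
  }
  invisible(x)
}

largest_block_id <- function(result) {
  if (!nrow(result$blocks)) return(NA_integer_)
  b <- result$blocks
  b$block_id[order(-b$n_members, b$block_id)][1L]
}

#' Exhaustive MEC optimum (test oracle)
#'
#' Enumerates all `2^(n-1)` relative phasings per connected component
#' (first member fixed to phase 0) and returns the global MEC optimum;
#' ties break to the lexicographically smallest phase vector. Components
#' larger than 16 variants are rejected.
#'
#' @param matrix a `fragment_matrix`.
#' @return a `phasing_result` with the exact optimum.
#' @export
brute_force_phase <- function(matrix) {
  graph <- build_graph(matrix)
  n_var <- graph$n_variants
  phase <- rep(NA_integer_, n_var)
  block_of <- rep(NA_integer_, n_var)
  support <- rep(NA_real_, n_var)
  comps <- split(which(!is.na(graph$membership)) - 1L,
                 graph$membership[!is.na(graph$membership)])
  for (nodes in comps) {
    n <- length(nodes)
    if (n < 2L) next
    if (n > 16L) stop("component too large for brute force (", n, " variants)")
    sub_obs <- matrix$obs[matrix$obs$var %in% nodes, , drop = FALSE]
    sp <- split(seq_len(nrow(sub_obs)), sub_obs$frag)
    sp <- sp[lengths(sp) >= 2L]
    best <- NULL; best_mec <- Inf
    n_assign <- 2^(n - 1L)
    for (idx in 0:(n_assign - 1L)) {
      h <- c(0L, as.integer(intToBits(idx))[(n - 1L):1])
      hv <- h[match(sub_obs$var, nodes)]
      m <- 0L
      for (ix in sp) {
        mm <- sum(sub_obs$allele[ix] != hv[ix])
        m <- m + min(mm, length(ix) - mm)
      }
      if (m < best_mec) { best_mec <- m; best <- h }
    }
    phase[nodes + 1L] <- best
    block_of[nodes + 1L] <- min(nodes)
    support[nodes + 1L] <- NA_real_
  }
  finalize_phasing(matrix, phase, block_of, support,
                   source = ifelse(is.na(phase), NA_character_, "mec"),
                   n_var = n_var)
}
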