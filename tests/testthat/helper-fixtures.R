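# Shared fixtures, built in code.

# the canonical 3-fragment, 2-variant example: F1 and F2 vote for the
# same relative phase, F3 against it
toy_matrix <- function(q = 30L) {
  obs <- data.frame(frag = c(1L, 1L, 2L, 2L, 3L, 3L),
                    var = c(0L, 1L, 0L, 1L, 0L, 1L),
                    allele = c(0L, 0L, 1L, 1L, 0L, 1L),
                    qual = q, end = c(1L, 2L, 1L, 2L, 1L, 2L))
  frags <- data.frame(id = 1:3, pos1 = c(0, 0, 0), pos2 = c(50, 50, 50))
  haplotarget:::new_fragment_matrix(obs, frags, read_length = 10L)
}

# random fragment matrix over n_var variants: n_frag fragments each
# observing 2..4 random variants with random alleles
random_matrix <- function(n_var, n_frag, seed) {
  set.seed(seed)
  rows <- lapply(seq_len(n_frag), function(f) {
    k <- sample(2:min(4L, n_var), 1L)
    vs <- sort(sample.int(n_var, k)) - 1L
    data.frame(frag = f, var = vs,
               allele = sample(0:1, k, replace = TRUE),
               qual = 30L, end = sample(1:2, k, replace = TRUE))
  })
  frags <- data.frame(id = seq_len(n_frag), pos1 = 0, pos2 = 100)
  haplotarget:::new_fragment_matrix(do.call(rbind, rows), frags,
                                    read_length = 10L)
}

# noiseless diploid fragment matrix: fragments copy one of two complementary
# haplotypes at chosen variant subsets
diploid_matrix <- function(hapA, frag_vars, source_hap, quals = 30L) {
  rows <- lapply(seq_along(frag_vars), function(f) {
    vs <- frag_vars[[f]]
    al <- if (source_hap[f] == 0L) hapA[vs + 1L] else 1L - hapA[vs + 1L]
    data.frame(frag = f, var = vs, allele = al, qual = quals,
               end = rep_len(1:2, length(vs)))
  })
  frags <- data.frame(id = seq_along(frag_vars), pos1 = 0, pos2 = 100)
  haplotarget:::new_fragment_matrix(do.call(rbind, rows), frags,
                                    read_length = 10L)
}

write_tmp_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  writeLines(as.vector(rbind(paste0(">", names(seqs)), unname(seqs))), path)
  path
}

write_tmp_bed <- function(df, path = tempfile(fileext = ".bed")) {
  lines <- apply(df, 1L, function(r) paste(r[!is.na(r) & nzchar(r)],
                                           collapse = "\t"))
  writeLines(lines, path)
  path
}

# independent union-find over fragment co-coverage, used as the component
# oracle for build_graph
union_find_components <- function(matrix, n_var) {
  parent <- seq_len(n_var)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  sp <- split(matrix$obs$var, matrix$obs$frag)
  for (vs in sp) {
    vs <- unique(vs)
    if (length(vs) < 2L) next
    r <- find(vs[1L] + 1L)
    for (v in vs[-1L]) {
      rv <- find(v + 1L)
      if (rv != r) parent[rv] <- r
    }
  }
  vapply(seq_len(n_var), find, 0L)
}
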