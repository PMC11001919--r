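# Independent brute-force oracles used by the tests. They avoid the
# package's code paths: the genetic code comes from Biostrings, chains are
# enumerated by depth-first search, and k-mer counts by naive set
# arithmetic.

oracle_code <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- as.character(Biostrings::GENETIC_CODE)
    names(gc) <- names(Biostrings::GENETIC_CODE)
    gc
  }
})

oracle_codons <- function(cds) {
  substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
}

# NG86 sites by enumerating all 9 single-base mutants of every codon.
oracle_sites <- function(cds) {
  code <- oracle_code()
  S <- 0
  for (codon in oracle_codons(cds)) {
    ch <- strsplit(codon, "")[[1L]]
    for (p in 1:3) for (nb in setdiff(c("A", "C", "G", "T"), ch[p])) {
      mut <- ch
      mut[p] <- nb
      if (code[[paste(mut, collapse = "")]] == code[[codon]]) S <- S + 1 / 3
    }
  }
  c(S = S, N = nchar(cds) - S)
}

oracle_perms <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (r in oracle_perms(x[-i])) out[[length(out) + 1L]] <- c(x[i], r)
  out
}

# NG86 pathway-averaged differences by exhaustive pathway enumeration;
# pathways through stops excluded (all-blocked codons fall back to
# counting stop steps as non-synonymous).
oracle_diffs <- function(cds1, cds2) {
  code <- oracle_code()
  ca <- oracle_codons(cds1)
  cb <- oracle_codons(cds2)
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    a <- strsplit(ca[i], "")[[1L]]
    b <- strsplit(cb[i], "")[[1L]]
    pos <- which(a != b)
    if (length(pos) == 0L) next
    walk <- function(ord, allow_stop) {
      cur <- a; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        aa1 <- code[[paste(cur, collapse = "")]]
        aa2 <- code[[paste(nxt, collapse = "")]]
        if (aa1 == "*" || aa2 == "*") {
          if (!allow_stop) return(NULL)
          nd <- nd + 1
        } else if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    paths <- oracle_perms(pos)
    res <- Filter(Negate(is.null), lapply(paths, walk, allow_stop = FALSE))
    if (length(res) == 0L) res <- lapply(paths, walk, allow_stop = TRUE)
    m <- do.call(rbind, res)
    Sd <- Sd + mean(m[, 1L]); Nd <- Nd + mean(m[, 2L])
  }
  c(Sd = Sd, Nd = Nd)
}

# Longest collinear chain (either orientation, gap-constrained on both
# axes) by exhaustive depth-first enumeration of all chains.
oracle_longest_chain <- function(q, t, max_gap) {
  n <- length(q)
  best <- 0L
  for (dir in c(1L, -1L)) {
    ok <- function(i, j) {
      dq <- q[j] - q[i]
      dt <- dir * (t[j] - t[i])
      dq > 0L && dq <= max_gap && dt > 0L && dt <= max_gap
    }
    dfs <- function(last, len) {
      if (len > best) best <<- len
      for (nxt in seq_len(n)) if (ok(last, nxt)) dfs(nxt, len + 1L)
    }
    for (s in seq_len(n)) dfs(s, 1L)
  }
  best
}

# Naive k-mer set difference and per-sequence counting.
oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  vapply(seq_len(n - k + 1L), function(i) substr(seq, i, i + k - 1L), "")
}

oracle_specific_counts <- function(contig_seq, roc_seqs, yz_seqs, k) {
  kr <- unique(unlist(lapply(roc_seqs, oracle_kmers, k = k)))
  ky <- unique(unlist(lapply(yz_seqs, oracle_kmers, k = k)))
  km <- oracle_kmers(contig_seq, k)
  c(roc = sum(km %in% setdiff(kr, ky)), yz = sum(km %in% setdiff(ky, kr)))
}

# Hamming mismatch fraction between equal-length strings.
oracle_mismatch <- function(a, b) {
  mean(strsplit(a, "")[[1L]] != strsplit(b, "")[[1L]])
}

tiny_config <- function(seed = 1L, ...) {
  defaults <- list(
    seed = seed, n_homologous_groups = 2L, so_haplotypes_per_group = 2L,
    ss_haplotypes_per_group = 1L, n_rec_chromosomes = 1L,
    chromosome_length = 2e4, contig_n50 = 4e3, chimera_fraction = 0)
  do.call(simulation_config, utils::modifyList(defaults, list(...)))
}
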