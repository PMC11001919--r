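# Reference (brute-force) implementations used by the demo's verification
# battery. They deliberately avoid the package's production code paths:
# chain search enumerates every path, and codon classification uses the
# Biostrings genetic code with direct mutant/pathway enumeration.

# Longest collinear chain by exhaustive depth-first enumeration of all
# chains (paths over the consecutive-anchor validity relation).
ref_longest_chain_exhaustive <- function(q, t, max_gap) {
  n <- length(q)
  best <- 0L
  edge_ok <- function(i, j, dir) {
    dq <- q[j] - q[i]
    dt <- dir * (t[j] - t[i])
    dq > 0L && dq <= max_gap && dt > 0L && dt <= max_gap
  }
  for (dir in c(1L, -1L)) {
    dfs <- function(last, len) {
      if (len > best) best <<- len
      for (nxt in seq_len(n)) if (edge_ok(last, nxt, dir)) dfs(nxt, len + 1L)
    }
    for (s in seq_len(n)) dfs(s, 1L)
  }
  best
}

ref_code <- function() {
  gc <- Biostrings::GENETIC_CODE
  stats::setNames(as.character(gc), names(gc))
}

# NG86 site counts by direct enumeration of the 9 single-base mutants of
# every codon.
ref_count_sites <- function(cds) {
  code <- ref_code()
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  S <- 0
  for (codon in codons) {
    chars <- strsplit(codon, "")[[1L]]
    for (p in 1:3) for (nb in setdiff(c("A", "C", "G", "T"), chars[p])) {
      mut <- chars
      mut[p] <- nb
      if (code[[paste(mut, collapse = "")]] == code[[codon]]) S <- S + 1 / 3
    }
  }
  c(S = S, N = nchar(cds) - S)
}

ref_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in ref_permutations(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# NG86 pathway-averaged differences by exhaustive pathway enumeration.
ref_count_differences <- function(cds1, cds2) {
  code <- ref_code()
  c1 <- substring(cds1, seq(1L, nchar(cds1), 3L), seq(3L, nchar(cds1), 3L))
  c2 <- substring(cds2, seq(1L, nchar(cds2), 3L), seq(3L, nchar(cds2), 3L))
  Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    a <- strsplit(c1[i], "")[[1L]]
    b <- strsplit(c2[i], "")[[1L]]
    pos <- which(a != b)
    if (length(pos) == 0L) next
    paths <- ref_permutations(pos)
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
    res <- Filter(Negate(is.null), lapply(paths, walk, allow_stop = FALSE))
    if (length(res) == 0L) res <- lapply(paths, walk, allow_stop = TRUE)
    m <- do.call(rbind, res)
    Sd <- Sd + mean(m[, 1L]); Nd <- Nd + mean(m[, 2L])
  }
  c(Sd = Sd, Nd = Nd)
}
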