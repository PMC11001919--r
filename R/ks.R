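# Nei-Gojobori (NG86) synonymous / non-synonymous substitution rates with
# Jukes-Cantor correction, for gapless codon alignments.

# Standard genetic code, NCBI table 1 (codon order T/C/A/G, first base
# slowest).
GENETIC_CODE_TABLE <- local({
  aa <- strsplit(paste0(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"), "")[[1L]]
  b <- c("T", "C", "A", "G")
  codons <- paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
  stats::setNames(aa, codons)
})

# Fraction of the 9 single-base mutants of each sense codon that are
# synonymous, per position (mutants to stop codons count as
# non-synonymous). S contribution of a codon = sum over positions of
# syn/3.
SYN_SITES_PER_CODON <- local({
  sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
  bases <- c("A", "C", "G", "T")
  vapply(sense, function(codon) {
    aa <- GENETIC_CODE_TABLE[[codon]]
    chars <- strsplit(codon, "")[[1L]]
    s <- 0
    for (p in 1:3) for (nb in setdiff(bases, chars[p])) {
      mut <- chars; mut[p] <- nb
      if (GENETIC_CODE_TABLE[[paste(mut, collapse = "")]] == aa) s <- s + 1 / 3
    }
    s
  }, numeric(1L))
})

split_codons <- function(cds, arg = "cds") {
  if (!is.character(cds) || length(cds) != 1L)
    stop(sprintf("%s must be a single character string", arg), call. = FALSE)
  cds <- toupper(cds)
  if (nchar(cds) %% 3L != 0L)
    stop(sprintf("%s length (%d) is not a multiple of 3", arg, nchar(cds)), call. = FALSE)
  if (grepl("[^ACGT]", cds))
    stop(sprintf("%s contains non-ACGT characters", arg), call. = FALSE)
  codons <- substring(cds, seq(1L, nchar(cds), 3L), seq(3L, nchar(cds), 3L))
  if (any(GENETIC_CODE_TABLE[codons] == "*"))
    stop(sprintf("%s contains a stop codon", arg), call. = FALSE)
  codons
}

#' Count synonymous and non-synonymous sites of a coding sequence
#'
#' NG86 site counting: each codon position contributes the fraction of its
#' three possible single-nucleotide changes that are synonymous; `S` sums
#' these fractions and `N = length - S`.
#'
#' @param cds a gapless coding sequence (multiple of 3, A/C/G/T, no stop
#'   codons).
#' @return named numeric vector `c(S = , N = )`.
#' @export
count_sites <- function(cds) {
  codons <- split_codons(cds)
  S <- sum(SYN_SITES_PER_CODON[codons])
  c(S = S, N = 3 * length(codons) - S)
}

# Pathway-averaged synonymous/non-synonymous differences between two sense
# codons: average over all orderings of the differing positions, with equal
# weights; orderings passing through a stop codon are excluded. If every
# ordering is blocked by a stop, fall back to averaging over all orderings
# with steps into or out of a stop codon counted as non-synonymous.
.codon_pair_cache <- new.env(parent = emptyenv())

codon_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .codon_pair_cache[[key]]
  if (!is.null(hit)) return(hit)
  a <- strsplit(c1, "")[[1L]]
  b <- strsplit(c2, "")[[1L]]
  diff_pos <- which(a != b)
  d <- length(diff_pos)
  res <- if (d == 0L) c(Sd = 0, Nd = 0) else {
    orders <- switch(d,
      list(diff_pos),
      list(diff_pos, rev(diff_pos)),
      {
        p <- diff_pos
        list(p[c(1, 2, 3)], p[c(1, 3, 2)], p[c(2, 1, 3)],
             p[c(2, 3, 1)], p[c(3, 1, 2)], p[c(3, 2, 1)])
      })
    walk <- function(ord, stop_as_nonsyn) {
      cur <- a; sd <- 0; nd <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- b[p]
        aa1 <- GENETIC_CODE_TABLE[[paste(cur, collapse = "")]]
        aa2 <- GENETIC_CODE_TABLE[[paste(nxt, collapse = "")]]
        if (aa2 == "*" || aa1 == "*") {
          if (!stop_as_nonsyn) return(NULL)
          nd <- nd + 1
        } else if (aa1 == aa2) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    counts <- Filter(Negate(is.null), lapply(orders, walk, stop_as_nonsyn = FALSE))
    if (length(counts) == 0L)
      counts <- lapply(orders, walk, stop_as_nonsyn = TRUE)
    m <- do.call(rbind, counts)
    c(Sd = mean(m[, 1L]), Nd = mean(m[, 2L]))
  }
  assign(key, res, envir = .codon_pair_cache)
  res
}

#' Count pathway-averaged synonymous and non-synonymous differences
#'
#' For each aligned codon pair, averages the synonymous and non-synonymous
#' difference counts over all minimal mutational pathways with equal
#' weights (NG86); pathways through stop codons are excluded.
#'
#' @param cds1,cds2 equal-length gapless coding sequences.
#' @return named numeric vector `c(Sd = , Nd = )`.
#' @export
count_differences <- function(cds1, cds2) {
  a <- split_codons(cds1, "cds1")
  b <- split_codons(cds2, "cds2")
  if (length(a) != length(b))
    stop("cds1 and cds2 must have equal length", call. = FALSE)
  idx <- which(a != b)
  if (length(idx) == 0L) return(c(Sd = 0, Nd = 0))
  m <- vapply(idx, function(i) codon_pair_diffs(a[i], b[i]), numeric(2L))
  c(Sd = sum(m[1L, ]), Nd = sum(m[2L, ]))
}

#' Nei-Gojobori synonymous and non-synonymous substitution rates
#'
#' NG86 with Jukes-Cantor correction: site counts are averaged over the two
#' sequences, `pS = Sd / S`, and `Ks = -3/4 log(1 - 4/3 pS)` (analogously
#' `Ka`). The result is flagged invalid (with `Ks`/`Ka` set to `NA`) when a
#' proportion reaches 3/4, where the correction diverges, or when `S = 0`.
#'
#' @param cds1,cds2 equal-length gapless coding sequences.
#' @return one-row data frame: S, N, Sd, Nd, pS, pN, Ks, Ka, valid.
#' @export
nei_gojobori <- function(cds1, cds2) {
  s1 <- count_sites(cds1)
  s2 <- count_sites(cds2)
  S <- (s1[["S"]] + s2[["S"]]) / 2
  N <- (s1[["N"]] + s2[["N"]]) / 2
  d <- count_differences(cds1, cds2)
  pS <- if (S > 0) d[["Sd"]] / S else NA_real_
  pN <- if (N > 0) d[["Nd"]] / N else NA_real_
  jc <- function(p) -3 / 4 * log(1 - 4 / 3 * p)
  valid <- S > 0 && !is.na(pS) && pS < 3 / 4 && !is.na(pN) && pN < 3 / 4
  data.frame(S = S, N = N, Sd = d[["Sd"]], Nd = d[["Nd"]],
             pS = pS, pN = pN,
             Ks = if (valid) jc(pS) else NA_real_,
             Ka = if (valid) jc(pN) else NA_real_,
             valid = valid)
}

#' Median Ks over a set of gene-pair results
#'
#' @param results data frame with columns `Ks` and `valid`, e.g. rows bound
#'   from [nei_gojobori()].
#' @return list with `median` (median Ks over valid entries), `n_valid`,
#'   and `n_excluded`.
#' @export
median_ks <- function(results) {
  stopifnot(is.data.frame(results), all(c("Ks", "valid") %in% names(results)))
  ok <- results$valid
  if (!any(ok)) stop("no valid Ks results to summarise", call. = FALSE)
  list(median = stats::median(results$Ks[ok]),
       n_valid = sum(ok), n_excluded = sum(!ok))
}
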