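# Homoeolog expression dominance: per-sample twofold classification,
# dominance-fraction summaries, lineage-dominant expression (LDE) under
# infection, and clustering of z-scaled infection/control fold-changes.

#' Classify homoeolog expression dominance
#'
#' A pair is SO-dominant when the So member's FPKM is strictly more than
#' `fold` times the Ss member's (SS-dominant symmetrically); exactly
#' `fold`-fold is neutral. Pairs with both members below `floor` are
#' undetermined. Vectorised; scale-invariant above the floor.
#'
#' @param fpkm_so,fpkm_ss FPKM of the So and Ss members (>= 0).
#' @param fold dominance fold-change threshold (strict; default 2).
#' @param floor minimum FPKM for a determinable call (default 0.1).
#' @return character vector: `"SO-dominant"`, `"SS-dominant"`,
#'   `"neutral"`, or `"undetermined"`.
#' @export
classify_dominance <- function(fpkm_so, fpkm_ss, fold = 2.0, floor = 0.1) {
  stopifnot(all(fpkm_so >= 0), all(fpkm_ss >= 0))
  ifelse(fpkm_so < floor & fpkm_ss < floor, "undetermined",
  ifelse(fpkm_so > fold * fpkm_ss, "SO-dominant",
  ifelse(fpkm_ss > fold * fpkm_so, "SS-dominant", "neutral")))
}

#' Per-sample dominance fractions
#'
#' Fractions of SO-dominant, SS-dominant and neutral pairs per sample,
#' over pairs with a determinable call (fractions sum to 1). Samples with
#' no determinable pair are reported empty with a warning.
#'
#' @param calls data frame with columns `sample` and `class` (one call per
#'   pair and sample).
#' @return data frame: sample, n_determined, so_dominant, ss_dominant,
#'   neutral.
#' @export
summarize_dominance <- function(calls) {
  stopifnot(all(c("sample", "class") %in% names(calls)))
  out <- lapply(split(calls, calls$sample), function(d) {
    det <- d$class != "undetermined"
    n <- sum(det)
    if (n == 0L) {
      warning("sample ", d$sample[1L], " has no determinable pairs")
      return(data.frame(sample = d$sample[1L], n_determined = 0L,
                        so_dominant = NA_real_, ss_dominant = NA_real_,
                        neutral = NA_real_, stringsAsFactors = FALSE))
    }
    data.frame(sample = d$sample[1L], n_determined = n,
               so_dominant = sum(d$class == "SO-dominant") / n,
               ss_dominant = sum(d$class == "SS-dominant") / n,
               neutral = sum(d$class == "neutral") / n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Lineage-dominant expression under infection
#'
#' Per tissue, the LDE-SO set contains the pairs SO-dominant in that
#' tissue's infected sample (LDE-SS symmetrically); the two sets are
#' disjoint by construction.
#'
#' @param expr long expression table with columns `pair`, `tissue`,
#'   `condition`, `fpkm_so`, `fpkm_ss`.
#' @param fold dominance threshold (strict).
#' @param floor determinability floor.
#' @return named list per tissue, each with character vectors `LDE_SO` and
#'   `LDE_SS`.
#' @export
call_lde <- function(expr, fold = 2.0, floor = 0.1) {
  stopifnot(all(c("pair", "tissue", "condition", "fpkm_so", "fpkm_ss") %in%
                  names(expr)))
  inf <- expr[expr$condition == "infected", , drop = FALSE]
  if (nrow(inf) == 0L) stop("no infected-condition samples in input", call. = FALSE)
  lapply(split(inf, inf$tissue), function(d) {
    cls <- classify_dominance(d$fpkm_so, d$fpkm_ss, fold = fold, floor = floor)
    list(LDE_SO = d$pair[cls == "SO-dominant"],
         LDE_SS = d$pair[cls == "SS-dominant"])
  })
}

#' Cluster z-scaled infection/control fold-changes
#'
#' Computes `log10((infected + p) / (control + p))` per lineage member and
#' tissue, z-scales the fold-change profile within each gene pair, and
#' partitions pairs into `k` clusters by hierarchical clustering (Ward
#' linkage on Euclidean distances). Clusters are labelled I, II, ... in
#' decreasing order of the mean So-member fold-change. Pairs whose profile
#' has zero variance (e.g. identical control and infected values) cannot
#' be z-scaled and are flagged as degenerate.
#'
#' @param expr long expression table with columns `pair`, `tissue`,
#'   `condition`, `fpkm_so`, `fpkm_ss` (both conditions present).
#' @param k number of clusters (default 4).
#' @param pseudocount offset `p` protecting zeros (default 0.01).
#' @param seed unused by the deterministic Ward clustering; accepted for
#'   interface stability.
#' @return list with `clusters` (data frame: pair, cluster), `features`
#'   (the z-scaled fold-change matrix), and `degenerate` (pair ids).
#' @export
fold_change_clusters <- function(expr, k = 4L, pseudocount = 0.01, seed = NULL) {
  stopifnot(all(c("pair", "tissue", "condition", "fpkm_so", "fpkm_ss") %in%
                  names(expr)))
  tissues <- sort(unique(expr$tissue))
  pairs <- sort(unique(expr$pair))
  feats <- list()
  for (tis in tissues) {
    ctl <- expr[expr$tissue == tis & expr$condition == "control", , drop = FALSE]
    inf <- expr[expr$tissue == tis & expr$condition == "infected", , drop = FALSE]
    ctl <- ctl[match(pairs, ctl$pair), ]
    inf <- inf[match(pairs, inf$pair), ]
    feats[[paste0("so_", tis)]] <-
      log10((inf$fpkm_so + pseudocount) / (ctl$fpkm_so + pseudocount))
    feats[[paste0("ss_", tis)]] <-
      log10((inf$fpkm_ss + pseudocount) / (ctl$fpkm_ss + pseudocount))
  }
  m <- do.call(cbind, feats)
  rownames(m) <- pairs
  if (k > nrow(m)) stop("k exceeds the number of gene pairs", call. = FALSE)
  rsd <- apply(m, 1L, stats::sd)
  degenerate <- pairs[rsd == 0 | is.na(rsd)]
  keep <- rsd > 0 & !is.na(rsd)
  z <- (m[keep, , drop = FALSE] - rowMeans(m[keep, , drop = FALSE])) /
    rsd[keep]
  if (nrow(z) < k)
    stop("fewer non-degenerate gene pairs than clusters", call. = FALSE)
  hc <- stats::hclust(stats::dist(z), method = "ward.D2")
  cl <- stats::cutree(hc, k = k)
  so_cols <- grepl("^so_", colnames(z))
  cluster_mean <- tapply(rowMeans(z[, so_cols, drop = FALSE]), cl, mean)
  lab <- stats::setNames(as.character(utils::as.roman(seq_len(k))),
                         names(sort(cluster_mean, decreasing = TRUE)))
  clusters <- data.frame(pair = rownames(z), cluster = unname(lab[as.character(cl)]),
                         stringsAsFactors = FALSE)
  list(clusters = clusters, features = z, degenerate = degenerate)
}
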