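# Allele-table construction: anchor predicted genes to ancestral monoploid
# gene sets by best protein hits, group alleles by homology within synteny
# blocks, merge by coordinate overlap, rescue unanchored genes in a second
# alignment round, and annotate So-Ss homoeologs via reciprocal best hits.

#' Best-hit anchoring of query genes
#'
#' Keeps, per query, the single hit with maximal bitscore among hits
#' passing the e-value cutoff; ties are broken by higher identity, then by
#' lexicographic target id. Malformed rows (missing fields) are skipped and
#' counted.
#'
#' @param hits data frame with columns `query`, `target`, `identity`,
#'   `coverage`, `evalue`, `bitscore`.
#' @param e_cut e-value cutoff (default 1e-5).
#' @return data frame of best hits (one row per anchored query); attribute
#'   `"n_malformed"` counts skipped rows.
#' @export
best_hit_anchor <- function(hits, e_cut = 1e-5) {
  need <- c("query", "target", "identity", "coverage", "evalue", "bitscore")
  stopifnot(all(need %in% names(hits)))
  ok <- stats::complete.cases(hits[, need])
  n_bad <- sum(!ok)
  if (n_bad > 0L) message(n_bad, " malformed hit row(s) skipped")
  hits <- hits[ok & hits$evalue <= e_cut, , drop = FALSE]
  if (nrow(hits) == 0L) {
    out <- hits
    attr(out, "n_malformed") <- n_bad
    return(out)
  }
  o <- order(hits$query, -hits$bitscore, -hits$identity, hits$target)
  hits <- hits[o, , drop = FALSE]
  out <- hits[!duplicated(hits$query), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_malformed") <- n_bad
  out
}

# Longest collinear chain (one orientation) by dynamic programming:
# anchors strictly increasing in query index, strictly monotone in target
# index, with index differences of at most max_gap on both axes between
# consecutive anchors.
longest_chain <- function(q, t, max_gap, direction) {
  n <- length(q)
  o <- order(q, t)
  q <- q[o]; t <- t[o]
  len <- rep(1L, n); prev <- rep(0L, n)
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      dq <- q[i] - q[j]
      dt <- direction * (t[i] - t[j])
      if (dq > 0L && dq <= max_gap && dt > 0L && dt <= max_gap &&
          len[j] + 1L > len[i]) {
        len[i] <- len[j] + 1L
        prev[i] <- j
      }
    }
  }
  best <- which.max(len)
  chain <- integer(0)
  while (best != 0L) {
    chain <- c(best, chain)
    best <- prev[best]
  }
  o[chain]
}

#' Find synteny blocks among anchor pairs
#'
#' Greedy longest-chain-first extraction of maximal collinear anchor
#' chains: each block is strictly monotone in both gene orders (increasing,
#' or decreasing for inverted blocks), has at least `min_anchors` anchors,
#' and consecutive anchors differ by at most `max_gap` order indices on
#' both genomes. Each anchor belongs to at most one block.
#'
#' @param anchors data frame with integer columns `query_idx`,
#'   `target_idx` (gene order indices on the two genomes); other columns
#'   are carried through.
#' @param min_anchors minimum anchors per block (default 5).
#' @param max_gap maximum order-index gap between consecutive anchors
#'   (default 25).
#' @return list of blocks; each block is a list with `anchors` (rows of
#'   `anchors`) and `orientation` (`"same"` or `"inverted"`).
#' @export
find_synteny_blocks <- function(anchors, min_anchors = 5L, max_gap = 25L) {
  stopifnot(all(c("query_idx", "target_idx") %in% names(anchors)))
  blocks <- list()
  remaining <- anchors
  while (nrow(remaining) >= min_anchors) {
    up <- longest_chain(remaining$query_idx, remaining$target_idx, max_gap, 1L)
    dn <- longest_chain(remaining$query_idx, remaining$target_idx, max_gap, -1L)
    if (length(up) >= length(dn)) {
      chain <- up; orient <- "same"
    } else {
      chain <- dn; orient <- "inverted"
    }
    if (length(chain) < min_anchors) break
    blocks[[length(blocks) + 1L]] <-
      list(anchors = remaining[chain, , drop = FALSE], orientation = orient)
    remaining <- remaining[-chain, , drop = FALSE]
  }
  blocks
}

#' Group alleles by shared anchor, synteny and similarity
#'
#' Genes anchored to the same ancestral gene join one allele group when
#' they lie in a synteny block against that ancestor and share identity of
#' at least `id_cut` and coverage of at least `cov_cut` (inclusive bounds).
#' Groups are capped at `ploidy_cap` members (highest identities kept).
#' Members carry the ancestry call of their contig as subgenome tag
#' (`"So"`, `"Ss"`, `"Rec"`; missing calls are tagged `"untagged"` and
#' reported).
#'
#' @param anchored data frame: `gene`, `anchor`, `identity`, `coverage`,
#'   `in_block` (logical), `ancestry` (contig ancestry call or NA).
#' @param id_cut,cov_cut inclusive thresholds (percent).
#' @param ploidy_cap maximum alleles per group (default 12).
#' @return list with `table` (group, gene, identity, coverage, tag) and
#'   `excluded` (gene, reason).
#' @export
group_alleles_by_homology <- function(anchored, id_cut = 70, cov_cut = 60,
                                      ploidy_cap = 12L) {
  need <- c("gene", "anchor", "identity", "coverage", "in_block", "ancestry")
  stopifnot(all(need %in% names(anchored)))
  pass <- anchored$in_block & anchored$identity >= id_cut &
    anchored$coverage >= cov_cut
  tab <- anchored[pass, , drop = FALSE]
  excluded <- data.frame(
    gene = anchored$gene[!pass],
    reason = ifelse(!anchored$in_block[!pass], "not in synteny block",
                    "below identity/coverage threshold"),
    stringsAsFactors = FALSE)
  table <- data.frame(group = tab$anchor, gene = tab$gene,
                      identity = tab$identity, coverage = tab$coverage,
                      tag = ancestry_tag(tab$ancestry), stringsAsFactors = FALSE)
  # ploidy cap: keep the highest-identity members
  if (nrow(table) > 0L) {
    table <- table[order(table$group, -table$identity), , drop = FALSE]
    rk <- stats::ave(seq_len(nrow(table)), table$group, FUN = seq_along)
    over <- rk > ploidy_cap
    if (any(over)) {
      excluded <- rbind(excluded, data.frame(
        gene = table$gene[over], reason = "ploidy cap exceeded",
        stringsAsFactors = FALSE))
      table <- table[!over, , drop = FALSE]
    }
    rownames(table) <- NULL
  }
  list(table = table, excluded = excluded)
}

ancestry_tag <- function(ancestry) {
  out <- c(SO = "So", SS = "Ss", Rec = "Rec")[ancestry]
  out[is.na(out)] <- "untagged"
  unname(out)
}

#' Merge genes into allele groups by coordinate overlap
#'
#' Genes outside the current table whose placed intervals reciprocally
#' overlap a placed member interval by strictly more than `overlap_cut`
#' (fraction of the shorter interval) join that member's group. A gene
#' pulled toward several groups goes to the group with the highest mean
#' member identity.
#'
#' @param placements data frame: `gene`, `chrom`, `start`, `end`, `rank`
#'   (0-based half-open intervals, ploidy-capped ranks).
#' @param table current allele table from [group_alleles_by_homology()].
#' @param candidates data frame of unplaced genes: `gene`, `identity`,
#'   `coverage`, `ancestry`.
#' @param overlap_cut strict reciprocal-overlap threshold (default 0.5).
#' @return list with `table` (augmented), `merges` (gene, group), and
#'   `unmerged` (character vector).
#' @export
group_alleles_by_coordinate <- function(placements, table, candidates,
                                        overlap_cut = 0.5) {
  stopifnot(all(c("gene", "chrom", "start", "end") %in% names(placements)))
  if (nrow(candidates) == 0L)
    return(list(table = table, merges = NULL, unmerged = character(0)))
  group_of <- stats::setNames(table$group, table$gene)
  mean_id <- tapply(table$identity, table$group, mean, na.rm = TRUE)
  member_pl <- placements[placements$gene %in% table$gene, , drop = FALSE]
  merges <- list(); unmerged <- character(0)
  for (g in candidates$gene) {
    pl <- placements[placements$gene == g, , drop = FALSE]
    hit_groups <- character(0)
    if (nrow(pl) > 0L && nrow(member_pl) > 0L) {
      for (i in seq_len(nrow(pl))) {
        mp <- member_pl[member_pl$chrom == pl$chrom[i], , drop = FALSE]
        if (nrow(mp) == 0L) next
        ov <- pmax(0, pmin(mp$end, pl$end[i]) - pmax(mp$start, pl$start[i]))
        shorter <- pmin(mp$end - mp$start, pl$end[i] - pl$start[i])
        frac <- ifelse(shorter > 0, ov / shorter, 0)
        hit_groups <- c(hit_groups, group_of[mp$gene[frac > overlap_cut]])
      }
    }
    hit_groups <- unique(hit_groups[!is.na(hit_groups)])
    if (length(hit_groups) == 0L) {
      unmerged <- c(unmerged, g)
      next
    }
    grp <- if (length(hit_groups) == 1L) hit_groups
           else hit_groups[which.max(mean_id[hit_groups])]
    cand <- candidates[candidates$gene == g, , drop = FALSE]
    table <- rbind(table, data.frame(
      group = grp, gene = g, identity = cand$identity[1L],
      coverage = cand$coverage[1L], tag = ancestry_tag(cand$ancestry[1L]),
      stringsAsFactors = FALSE))
    merges[[g]] <- data.frame(gene = g, group = grp, stringsAsFactors = FALSE)
  }
  list(table = table, merges = do.call(rbind, merges), unmerged = unmerged)
}

#' Rescue unanchored genes with a second alignment round
#'
#' Unanchored genes are re-searched against the member sequences of
#' existing groups; the best-hit rules of [best_hit_anchor()] assign each
#' to its target member's group. Genes without a passing hit remain
#' unassigned.
#'
#' @param table current allele table.
#' @param hits2 second-round hit table (`target` values are member gene
#'   ids of `table`).
#' @param ancestry named vector of contig-derived ancestry calls for the
#'   rescued genes (optional).
#' @param e_cut e-value cutoff.
#' @return list with `table`, `assigned` (gene, group), and
#'   `still_unassigned`.
#' @export
rescue_unanchored <- function(table, hits2, ancestry = NULL, e_cut = 1e-5) {
  if (is.null(hits2) || nrow(hits2) == 0L)
    return(list(table = table, assigned = NULL, still_unassigned = character(0)))
  hits2 <- hits2[!hits2$query %in% table$gene, , drop = FALSE]
  best <- best_hit_anchor(hits2, e_cut)
  group_of <- stats::setNames(table$group, table$gene)
  ok <- best$target %in% names(group_of)
  assigned <- data.frame(gene = best$query[ok],
                         group = unname(group_of[best$target[ok]]),
                         identity = best$identity[ok],
                         coverage = best$coverage[ok], stringsAsFactors = FALSE)
  if (nrow(assigned) > 0L) {
    anc <- if (is.null(ancestry)) rep(NA_character_, nrow(assigned))
           else unname(ancestry[assigned$gene])
    table <- rbind(table, data.frame(
      group = assigned$group, gene = assigned$gene,
      identity = assigned$identity, coverage = assigned$coverage,
      tag = ancestry_tag(anc), stringsAsFactors = FALSE))
  }
  still <- setdiff(unique(hits2$query), assigned$gene)
  list(table = table, assigned = assigned, still_unassigned = still)
}

#' Reciprocal best hits between two gene sets
#'
#' @param best_ab,best_ba best-hit maps from [best_hit_anchor()] for the
#'   two search directions.
#' @return data frame of pairs: `gene_a`, `gene_b` (each gene in at most
#'   one pair).
#' @export
find_rbh <- function(best_ab, best_ba) {
  map_ab <- stats::setNames(best_ab$target, best_ab$query)
  map_ba <- stats::setNames(best_ba$target, best_ba$query)
  a <- names(map_ab)
  mutual <- !is.na(map_ba[map_ab[a]]) & map_ba[map_ab[a]] == a
  data.frame(gene_a = a[mutual], gene_b = unname(map_ab[a[mutual]]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Annotate homoeolog links between allele groups
#'
#' Allele groups whose ancestral anchors form a reciprocal best-hit pair
#' (and whose partner anchor also heads a group) are cross-linked; groups
#' without a partner are marked So- or Ss-specific by their subgenome tag.
#'
#' @param table allele table (member rows).
#' @param rbh pair table from [find_rbh()] over ancestral anchors.
#' @return data frame per group: group, tag, n_alleles, partner, status
#'   (`"linked"`, `"So-specific"`, `"Ss-specific"`, or `"untagged"`).
#' @export
annotate_homoeologs <- function(table, rbh) {
  groups <- unique(table$group)
  tag <- vapply(groups, function(g) {
    tg <- table$tag[table$group == g]
    if (any(tg == "Rec")) return("Rec")
    tt <- table(tg[tg %in% c("So", "Ss")])
    if (length(tt) == 0L) return("untagged")
    names(tt)[which.max(tt)]
  }, "")
  partner <- rep(NA_character_, length(groups))
  m1 <- match(groups, rbh$gene_a)
  partner[!is.na(m1)] <- rbh$gene_b[m1[!is.na(m1)]]
  m2 <- match(groups, rbh$gene_b)
  partner[!is.na(m2)] <- rbh$gene_a[m2[!is.na(m2)]]
  linked <- !is.na(partner) & partner %in% groups
  status <- ifelse(linked, "linked",
            ifelse(tag == "So", "So-specific",
            ifelse(tag == "Ss", "Ss-specific", "untagged")))
  n_alleles <- as.integer(table(table$group)[groups])
  data.frame(group = groups, tag = tag, n_alleles = n_alleles,
             partner = ifelse(linked, partner, NA_character_),
             status = status, stringsAsFactors = FALSE, row.names = NULL)
}

#' Distribution of allele counts per group
#'
#' @param table allele table (member rows).
#' @param cap maximum allele count reported (default 12).
#' @return data frame: allele_count, n_groups, fraction (fractions sum
#'   to 1).
#' @export
allele_count_distribution <- function(table, cap = 12L) {
  counts <- table(table(table$group))
  k <- as.integer(names(counts))
  stopifnot(all(k >= 1L), all(k <= cap))
  data.frame(allele_count = k, n_groups = as.integer(counts),
             fraction = as.numeric(counts) / sum(counts))
}
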