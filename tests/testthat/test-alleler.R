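# Allele-table operations: best-hit anchoring, synteny chaining,
# homology/coordinate grouping, rescue, RBH and summaries.

hit_row <- function(query, target, identity = 90, coverage = 90,
                    evalue = 1e-20, bitscore = 400) {
  data.frame(query = query, target = target, identity = identity,
             coverage = coverage, evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

test_that("best-hit anchoring keeps the top passing hit with tie-breaks", {
  h <- rbind(hit_row("q1", "t1", bitscore = 300),
             hit_row("q1", "t2", bitscore = 250),
             hit_row("q2", "t3", evalue = 1e-4),        # fails e-cut
             hit_row("q3", "tB", bitscore = 400, identity = 95),
             hit_row("q3", "tA", bitscore = 400, identity = 95),
             hit_row("q3", "tC", bitscore = 400, identity = 99))
  b <- best_hit_anchor(h)
  expect_equal(b$target[b$query == "q1"], "t1")
  expect_false("q2" %in% b$query)
  # ties: higher identity first, then lexicographic target
  expect_equal(b$target[b$query == "q3"], "tC")
  h2 <- h[h$query == "q3" & h$target != "tC", ]
  expect_equal(best_hit_anchor(h2)$target, "tA")
  # malformed rows are skipped and counted
  h3 <- rbind(h, hit_row("q4", NA))
  expect_message(b3 <- best_hit_anchor(h3), "malformed")
  expect_equal(attr(b3, "n_malformed"), 1L)
})

test_that("synteny chaining matches the exhaustive search", {
  # 10 anchors on a perfect diagonal: one block of 10
  d <- data.frame(query_idx = 1:10, target_idx = 1:10)
  b <- find_synteny_blocks(d)
  expect_length(b, 1L)
  expect_equal(nrow(b[[1]]$anchors), 10L)
  expect_equal(b[[1]]$orientation, "same")
  # inverted diagonal is recognised
  di <- data.frame(query_idx = 1:10, target_idx = 10:1)
  bi <- find_synteny_blocks(di)
  expect_equal(bi[[1]]$orientation, "inverted")
  # a diagonal of 4 is below min_anchors
  expect_length(find_synteny_blocks(data.frame(query_idx = 1:4,
                                               target_idx = 1:4)), 0L)
  # seeded random permutation: no chain of >= 5 unless the oracle finds one
  set.seed(17)
  for (i in 1:25) {
    n <- sample(6:12, 1L)
    gap <- sample(2:25, 1L)
    q <- sample.int(n); t <- sample.int(n)
    blocks <- find_synteny_blocks(data.frame(query_idx = q, target_idx = t),
                                  min_anchors = 3L, max_gap = gap)
    got <- if (length(blocks) == 0L) 0L else nrow(blocks[[1]]$anchors)
    want <- oracle_longest_chain(q, t, gap)
    expect_equal(got, if (want >= 3L) want else 0L)
  }
})

test_that("homology grouping applies inclusive >=70/>=60 bounds and caps", {
  df <- data.frame(
    gene = sprintf("g%d", 1:6), anchor = "A",
    identity = c(95, 99, 70, 69, 98, 97), coverage = c(95, 96, 60, 95, 59, 90),
    in_block = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    ancestry = c("SO", "SO", "SO", "SO", "SO", "SO"), stringsAsFactors = FALSE)
  out <- group_alleles_by_homology(df)
  expect_setequal(out$table$gene, c("g1", "g2", "g3"))
  expect_true(all(c("g4", "g5", "g6") %in% out$excluded$gene))
  expect_equal(out$table$tag, rep("So", 3))
  # ploidy cap keeps the highest identities
  big <- data.frame(gene = sprintf("h%02d", 1:14), anchor = "B",
                    identity = 80 + 1:14, coverage = 95, in_block = TRUE,
                    ancestry = "SS", stringsAsFactors = FALSE)
  capped <- group_alleles_by_homology(big)
  expect_equal(nrow(capped$table), 12L)
  expect_false(any(c("h01", "h02") %in% capped$table$gene))
})

test_that("coordinate merging uses strict reciprocal overlap of the shorter", {
  tabl <- data.frame(group = "A", gene = "m", identity = 95, coverage = 95,
                     tag = "So", stringsAsFactors = FALSE)
  cand <- data.frame(gene = "g", identity = 85, coverage = 85,
                     ancestry = "SO", stringsAsFactors = FALSE)
  pl <- function(s) data.frame(gene = c("m", "g"), chrom = "c1",
                               start = c(0, s), end = c(100, s + 100),
                               rank = 1L, stringsAsFactors = FALSE)
  expect_true("g" %in% group_alleles_by_coordinate(pl(20), tabl, cand)$table$gene)
  expect_true("g" %in% group_alleles_by_coordinate(pl(50), tabl, cand)$unmerged)
  expect_true("g" %in% group_alleles_by_coordinate(pl(200), tabl, cand)$unmerged)
  # conflict: gene overlapping two groups goes to the higher mean identity
  tab2 <- rbind(tabl, data.frame(group = "B", gene = "n", identity = 80,
                                 coverage = 90, tag = "So"))
  pl2 <- data.frame(gene = c("m", "n", "g"), chrom = "c1",
                    start = c(0, 10, 5), end = c(100, 110, 105), rank = 1L,
                    stringsAsFactors = FALSE)
  out <- group_alleles_by_coordinate(pl2, tab2, cand)
  expect_equal(out$table$group[out$table$gene == "g"], "A")
})

test_that("second-round rescue preserves table invariants", {
  tabl <- data.frame(group = c("A", "A"), gene = c("m1", "m2"),
                     identity = c(95, 94), coverage = c(95, 94),
                     tag = "So", stringsAsFactors = FALSE)
  h2 <- rbind(hit_row("u1", "m1", identity = 90),
              hit_row("u2", "zz", identity = 90),   # unknown member
              hit_row("u3", "m2", evalue = 1e-3))   # fails e-cut
  out <- rescue_unanchored(tabl, h2)
  expect_equal(out$table$group[out$table$gene == "u1"], "A")
  expect_setequal(out$still_unassigned, c("u2", "u3"))
  expect_equal(nrow(out$table), nrow(tabl) + 1L)
  expect_false(any(duplicated(out$table$gene)))
})

test_that("RBH pairing is mutual and symmetric", {
  ab <- rbind(hit_row("a1", "b1"), hit_row("a2", "b2"), hit_row("a3", "b9"))
  ba <- rbind(hit_row("b1", "a1"), hit_row("b2", "a7"), hit_row("b9", "a3"))
  r <- find_rbh(best_hit_anchor(ab), best_hit_anchor(ba))
  expect_setequal(paste(r$gene_a, r$gene_b), c("a1 b1", "a3 b9"))
  expect_false(any(duplicated(c(r$gene_a, r$gene_b))))
  # symmetry under swapping the two input tables (random toy instances)
  set.seed(23)
  for (i in 1:10) {
    n <- 8L
    a_best <- data.frame(query = sprintf("a%d", 1:n),
                         target = sprintf("b%d", sample.int(n, n, TRUE)),
                         identity = 90, coverage = 90, evalue = 1e-20,
                         bitscore = 400)
    b_best <- data.frame(query = sprintf("b%d", 1:n),
                         target = sprintf("a%d", sample.int(n, n, TRUE)),
                         identity = 90, coverage = 90, evalue = 1e-20,
                         bitscore = 400)
    r1 <- find_rbh(a_best, b_best)
    r2 <- find_rbh(b_best, a_best)
    expect_setequal(paste(r1$gene_a, r1$gene_b), paste(r2$gene_b, r2$gene_a))
  }
})

test_that("homoeolog annotation partitions groups and counts alleles", {
  tabl <- data.frame(
    group = c("SO_1", "SO_1", "SS_1", "SO_2", "SS_3"),
    gene = sprintf("g%d", 1:5), identity = 90, coverage = 90,
    tag = c("So", "So", "Ss", "So", "Ss"), stringsAsFactors = FALSE)
  rbh <- data.frame(gene_a = c("SO_1", "SO_9"), gene_b = c("SS_1", "SS_9"))
  ann <- annotate_homoeologs(tabl, rbh)
  expect_equal(ann$status[ann$group == "SO_1"], "linked")
  expect_equal(ann$partner[ann$group == "SS_1"], "SO_1")
  expect_equal(ann$status[ann$group == "SO_2"], "So-specific")
  expect_equal(ann$status[ann$group == "SS_3"], "Ss-specific")
  expect_equal(sum(ann$n_alleles), nrow(tabl))

  d <- allele_count_distribution(tabl)
  expect_equal(d$fraction[d$allele_count == 1], 3 / 4)
  expect_equal(d$fraction[d$allele_count == 2], 1 / 4)
  expect_equal(sum(d$fraction), 1, tolerance = 1e-12)
})

test_that("planted allele groups are reconstructed perfectly when clean", {
  cfg <- allele_sim_config(seed = 33L)
  hyb <- simulate_hybrid_chromosomes(cfg)
  res <- run_allele_pipeline(hyb, cfg, identity_noise_sd = 0)
  expect_equal(unname(res$metrics[["ari"]]), 1)
  expect_equal(unname(res$metrics[["duplicated_genes"]]), 0)
  # planted ploidy four: every reconstructed group has four alleles
  expect_true(all(res$distribution$allele_count == 4L))
})
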