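# Parent/ancestry assignment rules, the Hi-C signal formula, recombinant
# detection and six-group construction.

test_that("depth normalization scales each sample to median 1", {
  d <- data.frame(contig = c("a", "b", "c"), sample = "s1",
                  depth = c(10, 20, 30))
  out <- normalize_depths(d)
  expect_equal(out$depth, c(0.5, 1, 1.5))
  expect_equal(normalize_depths(out)$depth, out$depth)  # idempotent
  expect_equal(normalize_depths(data.frame(contig = 1:3, sample = "s",
                                           depth = c(2, 2, 2)))$depth,
               c(1, 1, 1))
  expect_error(normalize_depths(data.frame(contig = 1:3, sample = "s",
                                           depth = c(0, 0, 1))),
               "zero median")
})

test_that("parent assignment follows the 1.5x depth and 2x k-mer rules", {
  expect_equal(assign_parent_by_depth(3.0, 1.0), "ROC")
  expect_equal(assign_parent_by_depth(1.2, 1.0), "ambiguous")
  expect_equal(assign_parent_by_depth(0, 0), "ambiguous")
  expect_equal(assign_parent_by_depth(1.0, 3.0), "YZ")
  expect_equal(assign_parent_by_depth(1.5, 1.0), "ROC")  # boundary inclusive

  expect_equal(assign_parent_by_kmer(200, 90), "ROC")
  expect_equal(assign_parent_by_kmer(100, 60), "ambiguous")
  expect_equal(assign_parent_by_kmer(0, 0), "ambiguous")
  expect_equal(assign_parent_by_kmer(0, 10), "YZ")

  expect_equal(combine_parent_calls("ROC", "ROC"), "ROC",
               ignore_attr = TRUE)
  expect_equal(combine_parent_calls("ambiguous", "YZ"), "YZ",
               ignore_attr = TRUE)
  out <- combine_parent_calls("ROC", "YZ")
  expect_equal(unclass(out)[1], "ambiguous", ignore_attr = TRUE)
  expect_equal(attr(out, "n_conflicts"), 1L)
})

test_that("ancestry t-test requires significance and uniform separation", {
  so <- c(2.0, 2.1, 1.9, 2.0, 2.2)
  ss <- c(0.1, 0.0, 0.2, 0.1, 0.1)
  r <- assign_ancestry_by_depth(so, ss)
  expect_equal(r$call, "SO")
  expect_lt(r$p_value, 1e-4)
  expect_equal(assign_ancestry_by_depth(ss, so)$call, "SS")
  # zero-variance identical panels: undetermined, not an error
  expect_equal(assign_ancestry_by_depth(rep(1, 5), rep(1, 5))$call,
               "undetermined")
  # overlapping ranges fail the uniformity clause even when p < alpha
  r2 <- assign_ancestry_by_depth(c(2, 2, 2, 2, 0.05), c(0.1, 0.1, 0.12, 0.1, 0.1))
  expect_equal(r2$call, "undetermined")
  # invariant to sample order within a panel
  expect_equal(assign_ancestry_by_depth(rev(so), sample(ss))$call, "SO")
})

test_that("similarity fallback needs strict double dominance", {
  expect_equal(assign_ancestry_by_similarity(20, 0.95, 60, 0.99), "SS")
  expect_equal(assign_ancestry_by_similarity(60, 0.99, 20, 0.95), "SO")
  expect_equal(assign_ancestry_by_similarity(50, 0.97, 50, 0.97), "undetermined")
  # mixed evidence: mapping quality favours SS, identity favours SO
  expect_equal(assign_ancestry_by_similarity(20, 0.99, 60, 0.95), "undetermined")
  expect_equal(assign_ancestry_by_similarity(NA, 0.99, 60, 0.95), "undetermined")
})

test_that("hic_signal evaluates the normalization formula exactly", {
  expect_equal(hic_signal(0, 100, 100, 1), 0)
  expect_equal(hic_signal(40, 100, 100, 1), 0.4)
  set.seed(31)
  for (i in 1:50) {
    l <- rpois(1, 100); a <- runif(1, 1, 1e6); b <- runif(1, 1, 1e6)
    d <- runif(1, 0.1, 50)
    expect_identical(hic_signal(l, a, b, d), hic_signal(l, b, a, d))
    expect_equal(hic_signal(3 * l, a, b, d), 3 * hic_signal(l, a, b, d))
    expect_equal(hic_signal(l, a, b, 2 * d), hic_signal(l, a, b, d) / 2)
  }
  expect_error(hic_signal(1, 0, 10, 1), "positive")
  expect_error(hic_signal(1, 10, 10, 0), "positive")
})

test_that("recombinant detection flags exactly the linked SO-SS contacts", {
  contacts <- data.frame(contigA = c("a", "a", "b", "c"),
                         contigB = c("b", "c", "d", "d"),
                         links = c(400, 10, 500, 400))
  anc <- c(a = "SO", b = "SS", c = "SS", d = "SO")
  len <- c(a = 1000, b = 1000, c = 1000, d = 1000)
  r <- detect_recombinants(contacts, anc, len, seq_depth = 1, threshold = 0.4)
  # signals: a-b 0.4, a-c 0.01, b-d 0.5, c-d 0.4 -> all four flagged at 0.4
  expect_setequal(r$rec_contigs, c("a", "b", "c", "d"))
  r2 <- detect_recombinants(contacts, anc, len, 1, threshold = 0.45)
  expect_setequal(r2$rec_contigs, c("b", "d"))
  # raising the threshold never grows the set
  for (th in c(0.1, 0.5, 0.9, 1.5)) {
    lo <- detect_recombinants(contacts, anc, len, 1, th)$rec_contigs
    hi <- detect_recombinants(contacts, anc, len, 1, th + 0.2)$rec_contigs
    expect_true(all(hi %in% lo))
  }
  # same-ancestry contacts never qualify
  anc2 <- c(a = "SO", b = "SO", c = "SO", d = "SO")
  expect_length(detect_recombinants(contacts, anc2, len, 1, 0.4)$rec_contigs, 0L)
  expect_error(detect_recombinants(contacts, anc, len[1:3], 1), "unknown contigs")
})

test_that("six-group construction partitions contigs with Rec override", {
  parent <- c(t1 = "ROC", t2 = "YZ", t3 = "ambiguous", t4 = "YZ")
  anc <- c(t1 = "SO", t2 = "SO", t3 = "SS", t4 = "undetermined")
  g <- build_groups(parent, anc, rec_contigs = "t2")
  expect_equal(g$group[g$contig == "t1"], "ROC-So")
  expect_equal(g$group[g$contig == "t2"], "YZ-Rec")  # Rec overrides ancestry
  expect_equal(g$group[g$contig == "t3"], "unassigned")
  expect_equal(g$reason[g$contig == "t3"], "ambiguous parent")
  expect_equal(g$reason[g$contig == "t4"], "undetermined ancestry")
  # partition: every contig in exactly one group
  expect_equal(nrow(g), 4L)
  expect_false(any(duplicated(g$contig)))
})

test_that("threshold calibration finds the valley of a bimodal signal", {
  set.seed(7)
  sig <- c(10^rnorm(500, -2.5, 0.3), 10^rnorm(200, 0.5, 0.3))
  th <- calibrate_rec_threshold(sig)
  expect_gt(th, 10^-2)
  expect_lt(th, 10^0.2)
  expect_equal(calibrate_rec_threshold(rep(1, 5)), 0.4)  # degenerate fallback
})
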