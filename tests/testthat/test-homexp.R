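# Homoeolog expression dominance classification, summaries, LDE calls and
# fold-change clustering.

test_that("dominance classification is strict at twofold with a floor", {
  expect_equal(classify_dominance(10, 4), "SO-dominant")
  expect_equal(classify_dominance(10, 5), "neutral")   # exactly twofold
  expect_equal(classify_dominance(4, 10), "SS-dominant")
  expect_equal(classify_dominance(0.05, 0.02), "undetermined")
  # scale invariance above the floor
  set.seed(41)
  so <- runif(200, 0.2, 50); ss <- runif(200, 0.2, 50)
  base <- classify_dominance(so, ss)
  for (c_ in c(2, 10, 0.5)) {
    scaled <- classify_dominance(c_ * so, c_ * ss)
    keep <- pmax(c_ * so, c_ * ss) >= 0.1 & pmin(c_ * so, c_ * ss) >= 0 &
      !(c_ * so < 0.1 & c_ * ss < 0.1)
    expect_identical(scaled[keep], base[keep])
  }
})

test_that("dominance summary gives per-sample fractions that sum to one", {
  calls <- data.frame(
    sample = "s1",
    class = c(rep("SO-dominant", 2), "SS-dominant", rep("neutral", 7)))
  s <- summarize_dominance(calls)
  expect_equal(s$so_dominant, 0.2)
  expect_equal(s$ss_dominant, 0.1)
  expect_equal(s$neutral, 0.7)
  expect_equal(s$so_dominant + s$ss_dominant + s$neutral, 1)
  # swapping the lineages swaps the two dominant fractions
  swapped <- calls
  swapped$class <- chartr("OS", "SO", sub("SO", "xx", swapped$class))
  swapped$class[swapped$class == "xx-dominant"] <- "SS-dominant"
  s2 <- summarize_dominance(data.frame(sample = "s1", class = ifelse(
    calls$class == "SO-dominant", "SS-dominant",
    ifelse(calls$class == "SS-dominant", "SO-dominant", calls$class))))
  expect_equal(s2$so_dominant, s$ss_dominant)
  expect_equal(s2$ss_dominant, s$so_dominant)
  expect_warning(summarize_dominance(data.frame(sample = "s2",
                                                class = "undetermined")),
                 "no determinable")
})

test_that("planted dominance fractions are recovered within 3 binomial SEs", {
  cfg <- simulation_config(seed = 51L)
  sim <- simulate_expression(10000L, cfg)
  e <- sim$expression[sim$expression$sample == "stem_control", ]
  cls <- classify_dominance(e$fpkm_so, e$fpkm_ss)
  s <- summarize_dominance(data.frame(sample = "stem_control", class = cls))
  se <- function(p) sqrt(p * (1 - p) / s$n_determined)
  expect_lt(abs(s$so_dominant - 0.071), 3 * se(0.071))
  expect_lt(abs(s$ss_dominant - 0.030), 3 * se(0.030))
})

test_that("LDE sets are per-tissue, disjoint, and order-independent", {
  expr <- data.frame(
    pair = rep(c("p1", "p2", "p3"), 2),
    tissue = rep(c("leaf", "stem"), each = 3),
    condition = "infected",
    fpkm_so = c(10, 1, 5, 10, 10, 1),
    fpkm_ss = c(1, 10, 5, 1, 1, 10))
  lde <- call_lde(expr)
  expect_setequal(lde$leaf$LDE_SO, "p1")
  expect_setequal(lde$leaf$LDE_SS, "p2")
  expect_false("p3" %in% c(lde$leaf$LDE_SO, lde$leaf$LDE_SS))
  expect_length(intersect(lde$stem$LDE_SO, lde$stem$LDE_SS), 0L)
  lde2 <- call_lde(expr[sample(nrow(expr)), ])
  expect_setequal(lde2$leaf$LDE_SO, lde$leaf$LDE_SO)
  expect_error(call_lde(expr[expr$condition == "control", ]), "no infected")
})

test_that("fold-change clustering recovers noise-free archetypes", {
  cfg <- simulation_config(seed = 61L, fpkm_dispersion = 0,
                           dominance_fraction_so = 0, dominance_fraction_ss = 0)
  sim <- simulate_expression(200L, cfg)
  out <- fold_change_clusters(sim$expression, k = 4L)
  truth <- sim$truth$archetype[match(out$clusters$pair, sim$truth$pair)]
  # four pure clusters: cluster labels map one-to-one onto archetypes
  tab <- table(out$clusters$cluster, truth)
  expect_equal(sum(tab > 0), 4L)
  expect_equal(mclust::adjustedRandIndex(out$clusters$cluster, truth), 1)
  # cluster I has the highest mean So fold-change
  so_means <- tapply(rowMeans(out$features[, grepl("^so_", colnames(out$features))]),
                     out$clusters$cluster[match(rownames(out$features),
                                                out$clusters$pair)], mean)
  expect_equal(names(which.max(so_means)), "I")
  # determinism
  out2 <- fold_change_clusters(sim$expression, k = 4L)
  expect_identical(out$clusters, out2$clusters)
})

test_that("degenerate fold-change profiles are flagged, not clustered", {
  expr <- expand.grid(pair = sprintf("p%d", 1:6),
                      tissue = c("leaf", "stem"),
                      condition = c("control", "infected"),
                      stringsAsFactors = FALSE)
  expr$fpkm_so <- 10; expr$fpkm_ss <- 10  # identical control and infected
  expr$fpkm_so[expr$pair %in% c("p1", "p2", "p3") & expr$condition == "infected"] <-
    c(20, 40, 80)
  out <- fold_change_clusters(expr, k = 2L)
  expect_setequal(out$degenerate, c("p4", "p5", "p6"))
  expect_false(any(out$clusters$pair %in% out$degenerate))
  expect_error(fold_change_clusters(expr, k = 50L), "k exceeds")
})
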