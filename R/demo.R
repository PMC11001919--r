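# End-to-end demonstration pipeline on synthetic data: simulate -> QC ->
# six-group binning -> allele table -> homoeolog expression -> Ks, plus a
# verification battery that re-measures every stage against ground truth
# and brute-force references.

demo_log <- function(quiet, stage, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, paste0(...)))
}

#' Run the six-group binning pipeline on a simulated assembly
#'
#' Simulates a hybrid assembly with evidence layers, applies QC (artifact,
#' contamination and misjoin detection), assigns parent and ancestry to
#' every contig, detects recombinant contigs from normalized Hi-C signals,
#' and scores the calls against the simulation truth.
#'
#' @param config a [simulation_config()].
#' @param rec_threshold normalized Hi-C signal threshold for recombinant
#'   flagging (default 0.4).
#' @param flank_bins,drop_fraction misjoin-detection parameters for the
#'   within-contig signal tracks.
#' @param quiet suppress progress messages.
#' @return list with the simulated objects, per-contig calls, group table,
#'   and recovery metrics.
#' @export
run_binning_pipeline <- function(config, rec_threshold = 0.4, flank_bins = 4L,
                                 drop_fraction = 0.25, quiet = TRUE) {
  demo_log(quiet, "simulate", "generating genomes and contigs")
  anc <- if (config$emit_sequences) simulate_ancestral_genomes(config) else NULL
  hyb <- simulate_hybrid_chromosomes(config, anc)
  frag <- fragment_into_contigs(hyb, config)
  ct <- frag$contigs

  demo_log(quiet, "simulate", nrow(ct), " contigs; simulating evidence")
  qc <- simulate_assembly_artifacts(frag, hyb$genes, config)
  hic <- simulate_hic(frag, config)
  depth <- simulate_depth_panel(frag, default_panel_spec(), config)
  sim_tab <- simulate_similarity(frag, config)
  kmer <- if (config$emit_sequences)
    simulate_kmer_evidence(frag, parental_genome_sequences(hyb)) else NULL

  demo_log(quiet, "qc", "artifact/contamination filters and misjoin detection")
  kv <- filter_artifactual(qc$kmer_stats$total, qc$kmer_stats$absent)
  cv <- filter_contamination(qc$overlap$fraction)
  qc_removed <- qc$kmer_stats$contig[kv == "remove" | cv == "remove"]
  min_bins <- 2L * flank_bins + 1L
  misjoined <- character(0)
  breakpoints <- list()
  for (id in names(hic$tracks)) {
    tr <- hic$tracks[[id]]
    if (length(tr) < min_bins) next
    bp <- detect_misjoins(tr, hic$bin_size, drop_fraction, flank_bins)
    if (length(bp) > 0L) {
      misjoined <- c(misjoined, id)
      breakpoints[[id]] <- bp
    }
  }

  demo_log(quiet, "bin", "parent and ancestry assignment")
  dep <- function(s) {
    d <- depth[depth$sample == s, ]
    stats::setNames(d$depth, d$contig)[ct$contig]
  }
  p_depth <- assign_parent_by_depth(dep("ROC_1"), dep("YZ_1"))
  parent_call <- p_depth
  if (!is.null(kmer)) {
    km <- kmer[match(ct$contig, kmer$contig), ]
    p_kmer <- assign_parent_by_kmer(km$roc_specific, km$yz_specific)
    parent_call <- combine_parent_calls(p_depth, p_kmer)
  }
  so_mat <- vapply(sprintf("SO_%d", 1:5), dep, numeric(nrow(ct)))
  ss_mat <- vapply(sprintf("SS_%d", 1:5), dep, numeric(nrow(ct)))
  anc_call <- vapply(seq_len(nrow(ct)), function(i)
    assign_ancestry_by_depth(so_mat[i, ], ss_mat[i, ])$call, "")
  und <- anc_call == "undetermined"
  if (any(und)) {
    st <- sim_tab[match(ct$contig, sim_tab$contig), ]
    anc_call[und] <- assign_ancestry_by_similarity(
      st$mq_so[und], st$id_so[und], st$mq_ss[und], st$id_ss[und])
  }
  names(parent_call) <- names(anc_call) <- ct$contig

  demo_log(quiet, "bin", "recombinant detection (threshold ", rec_threshold, ")")
  eligible <- setdiff(ct$contig, c(misjoined, qc_removed))
  contacts <- hic$contacts
  contacts <- contacts[contacts$contigA %in% eligible &
                         contacts$contigB %in% eligible, ]
  lengths <- stats::setNames(ct$length, ct$contig)
  rec <- detect_recombinants(contacts, anc_call[eligible], lengths,
                             config$seq_depth, rec_threshold)
  groups <- build_groups(parent_call, anc_call, rec$rec_contigs)

  nonchim <- !ct$is_chimera
  acc <- mean(parent_call[nonchim] == ct$parent[nonchim] &
                anc_call[nonchim] == ct$ancestry[nonchim])
  pred_rec <- intersect(rec$rec_contigs, ct$contig[nonchim])
  true_rec <- ct$contig[nonchim & ct$rec]
  tp <- length(intersect(pred_rec, true_rec))
  rec_precision <- if (length(pred_rec) == 0L) 1 else tp / length(pred_rec)
  rec_recall <- if (length(true_rec) == 0L) 1 else tp / length(true_rec)

  list(hybrid = hyb, fragments = frag, hic = hic, depth = depth, kmer = kmer,
       similarity = sim_tab, qc = qc,
       qc_removed = qc_removed, misjoined = misjoined, breakpoints = breakpoints,
       parent_call = parent_call, ancestry_call = anc_call, rec = rec,
       groups = groups,
       metrics = c(binning_accuracy = acc, rec_precision = rec_precision,
                   rec_recall = rec_recall, n_contigs = nrow(ct)))
}

# In-block flags from best-hit anchors: per chromosome and target
# monoploid, chain the anchored genes (query order = position rank, target
# order = locus index of the anchor) and collect block members.
anchor_in_block <- function(genes, best, min_anchors = 5L, max_gap = 25L) {
  anchor_of <- stats::setNames(best$target, best$query)
  g <- genes[genes$gene %in% best$query, , drop = FALSE]
  g$target <- unname(anchor_of[g$gene])
  g$target_lineage <- substr(g$target, 1L, 2L)
  g$target_idx <- as.integer(sub(".*_l", "", g$target))
  in_block <- character(0)
  for (d in split(g, g$chrom)) {
    d <- d[order(d$start), ]
    d$query_idx <- seq_len(nrow(d))
    for (sub in split(d, d$target_lineage)) {
      if (nrow(sub) == 0L) next
      blocks <- find_synteny_blocks(
        data.frame(query_idx = sub$query_idx, target_idx = sub$target_idx,
                   gene = sub$gene, stringsAsFactors = FALSE),
        min_anchors = min_anchors, max_gap = max_gap)
      for (b in blocks) in_block <- c(in_block, b$anchors$gene)
    }
  }
  in_block
}

#' Run the allele-table pipeline on simulated alignment evidence
#'
#' Anchors genes to the ancestral monoploid sets, groups alleles by
#' homology within synteny blocks, merges remaining genes by coordinate
#' overlap, rescues unanchored genes in a second round, annotates
#' homoeolog links via RBH, and scores the reconstruction against the
#' planted groups (adjusted Rand index).
#'
#' @param hyb output of [simulate_hybrid_chromosomes()].
#' @param config the configuration used for `hyb`.
#' @param ancestry_by_gene named character vector (`"SO"`/`"SS"`/`"Rec"`)
#'   of contig ancestry calls per gene; defaults to the truth lineage.
#' @param identity_noise_sd similarity noise passed to
#'   [simulate_allele_evidence()].
#' @return list with the allele `table`, group annotation, allele-count
#'   distribution, RBH pairs, and metrics (`ari`, `duplicated_genes`).
#' @export
run_allele_pipeline <- function(hyb, config, ancestry_by_gene = NULL,
                                identity_noise_sd = 0) {
  ev <- simulate_allele_evidence(hyb, config, identity_noise_sd)
  genes <- ev$genes
  if (is.null(ancestry_by_gene))
    ancestry_by_gene <- stats::setNames(genes$lineage, genes$gene)
  best <- best_hit_anchor(ev$hits1)
  in_block <- anchor_in_block(genes, best)
  anchored <- data.frame(
    gene = best$query, anchor = best$target, identity = best$identity,
    coverage = best$coverage, in_block = best$query %in% in_block,
    ancestry = unname(ancestry_by_gene[best$query]), stringsAsFactors = FALSE)
  hom <- group_alleles_by_homology(anchored)
  cand <- anchored[!anchored$gene %in% hom$table$gene,
                   c("gene", "identity", "coverage", "ancestry")]
  coord <- group_alleles_by_coordinate(ev$placements, hom$table, cand)
  resc <- rescue_unanchored(coord$table, ev$hits2, ancestry_by_gene)
  table <- resc$table

  rbh <- find_rbh(best_hit_anchor(ev$hits_so_ss), best_hit_anchor(ev$hits_ss_so))
  annot <- annotate_homoeologs(table, rbh)
  dist <- allele_count_distribution(table)

  truth_lab <- genes$anchor
  pred_lab <- table$group[match(genes$gene, table$gene)]
  pred_lab[is.na(pred_lab)] <- paste0("unassigned_", genes$gene[is.na(pred_lab)])
  ari <- mclust::adjustedRandIndex(truth_lab, pred_lab)
  list(table = table, groups = annot, distribution = dist, rbh = rbh,
       evidence = ev,
       metrics = c(ari = ari, duplicated_genes = sum(duplicated(table$gene)),
                   n_groups = length(unique(table$group))))
}

# ---- verification battery -------------------------------------------------

eval_hic_formula <- function(seed, n = 1000L) {
  with_stage_seed(seed, 21L, {
    links <- stats::rpois(n, 50)
    l1 <- stats::runif(n, 1e3, 1e6)
    l2 <- stats::runif(n, 1e3, 1e6)
    d <- stats::runif(n, 0.5, 100)
    sig <- hic_signal(links, l1, l2, d)
    direct <- links * 2 / (l1 + l2) * (1 / d)
    list(max_err = max(abs(sig - direct)),
         symmetric = identical(sig, hic_signal(links, l2, l1, d)),
         linear = max(abs(hic_signal(2 * links, l1, l2, d) - 2 * sig)) == 0,
         inverse = max(abs(hic_signal(links, l1, l2, 2 * d) - sig / 2)) < 1e-15)
  })
}

eval_threshold_semantics <- function() {
  hom <- group_alleles_by_homology(data.frame(
    gene = c("a", "b", "c", "d"), anchor = "X",
    identity = c(70, 69, 80, 95), coverage = c(60, 90, 59, 95),
    in_block = TRUE, ancestry = "SO", stringsAsFactors = FALSE))
  tabl <- data.frame(group = "X", gene = "m", identity = 95, coverage = 95,
                     tag = "So", stringsAsFactors = FALSE)
  pl <- function(cand_start) data.frame(
    gene = c("m", "g"), chrom = "c1", start = c(0, cand_start),
    end = c(100, cand_start + 100), rank = 1L, stringsAsFactors = FALSE)
  cand <- data.frame(gene = "g", identity = 80, coverage = 80,
                     ancestry = "SO", stringsAsFactors = FALSE)
  exact50 <- group_alleles_by_coordinate(pl(50), tabl, cand)
  over50 <- group_alleles_by_coordinate(pl(49), tabl, cand)
  all(
    filter_artifactual(100, 41) == "remove",
    filter_artifactual(100, 40) == "keep",
    filter_contamination(0.41) == "remove",
    filter_contamination(0.40) == "keep",
    setequal(hom$table$gene, c("a", "d")),
    "g" %in% exact50$unmerged,
    "g" %in% over50$table$gene,
    classify_dominance(10, 5) == "neutral",
    classify_dominance(10, 4.9) == "SO-dominant",
    filter_gene_models(FALSE, FALSE, 3.0, 90, 0) == "discard",
    filter_gene_models(FALSE, FALSE, 3.01, 81, 0) == "retain",
    filter_gene_models(FALSE, FALSE, 0, 0, 80) == "discard",
    filter_gene_models(FALSE, FALSE, 0, 0, 81) == "retain",
    filter_gene_models(TRUE, FALSE, 0, 0, 0) == "retain")
}

eval_misjoin <- function(seed, noisy) {
  cfg <- misjoin_sim_config(seed, depth_noise_cv = if (noisy) 0.1 else 0)
  hyb <- simulate_hybrid_chromosomes(cfg)
  frag <- fragment_into_contigs(hyb, cfg)
  hic <- simulate_hic(frag, cfg)
  ct <- frag$contigs
  tol <- hic$bin_size
  tp <- 0L; n_pred <- 0L; matched_pred <- 0L; max_off <- 0
  for (i in seq_len(nrow(ct))) {
    tr <- hic$tracks[[ct$contig[i]]]
    bp <- if (is.null(tr) || length(tr) < 11L) numeric(0)
          else detect_misjoins(tr, hic$bin_size)
    n_pred <- n_pred + length(bp)
    if (ct$is_chimera[i]) {
      off <- abs(bp - ct$breakpoint[i])
      hit <- off <= tol
      if (any(hit)) {
        tp <- tp + 1L
        max_off <- max(max_off, min(off))
      }
      matched_pred <- matched_pred + sum(hit)
    }
  }
  n_chim <- sum(ct$is_chimera)
  list(recall = if (n_chim == 0L) 1 else tp / n_chim,
       precision = if (n_pred == 0L) 1 else matched_pred / n_pred,
       max_offset = max_off, n_contigs = nrow(ct), n_chimeras = n_chim)
}

eval_alleles <- function(seed, identity_noise_sd) {
  cfg <- allele_sim_config(seed)
  hyb <- simulate_hybrid_chromosomes(cfg)
  res <- run_allele_pipeline(hyb, cfg, identity_noise_sd = identity_noise_sd)
  res$metrics
}

eval_dominance <- function(seed, n_pairs = 10000L) {
  cfg0 <- simulation_config(seed = seed, fpkm_dispersion = 0)
  sim0 <- simulate_expression(n_pairs, cfg0)
  e0 <- sim0$expression[sim0$expression$sample == "leaf_control", ]
  cls0 <- classify_dominance(e0$fpkm_so, e0$fpkm_ss)
  truth0 <- sim0$truth$class[match(e0$pair, sim0$truth$pair)]
  det0 <- cls0 != "undetermined"
  errors0 <- sum(cls0[det0] != truth0[det0])

  cfg1 <- simulation_config(seed = seed)
  sim1 <- simulate_expression(n_pairs, cfg1)
  e1 <- sim1$expression[sim1$expression$sample == "leaf_control", ]
  cls1 <- classify_dominance(e1$fpkm_so, e1$fpkm_ss)
  fr <- summarize_dominance(data.frame(sample = "leaf_control", class = cls1,
                                       stringsAsFactors = FALSE))
  list(errors_noisefree = errors0,
       so_fraction = fr$so_dominant, ss_fraction = fr$ss_dominant,
       n = fr$n_determined,
       planted_so = cfg1$dominance_fraction_so,
       planted_ss = cfg1$dominance_fraction_ss)
}

eval_ks <- function(seed, n_pairs = 40L, n_codons = 2500L,
                    divergence = 0.037) {
  res <- do.call(rbind, lapply(seq_len(n_pairs), function(i) {
    p <- simulate_cds_pair(n_codons, divergence, seed = seed * 100L + i)
    nei_gojobori(p$cds1, p$cds2)
  }))
  med <- median_ks(res)
  list(median = med$median,
       rel_err = abs(med$median - divergence) / divergence,
       n_valid = med$n_valid)
}

eval_ng_oracle <- function(seed, n_cases = 200L, n_codons = 30L) {
  with_stage_seed(seed, 22L, {
    sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
    max_diff <- 0
    for (case in seq_len(n_cases)) {
      a <- paste(sample(sense, n_codons, replace = TRUE), collapse = "")
      b <- if (case %% 2L == 0L) {
        # closely related pair: mutate a few codons of a
        p <- simulate_cds_pair(n_codons, 0.05)
        a <- p$cds1
        p$cds2
      } else paste(sample(sense, n_codons, replace = TRUE), collapse = "")
      s <- count_sites(a)
      rs <- ref_count_sites(a)
      d <- count_differences(a, b)
      rd <- ref_count_differences(a, b)
      max_diff <- max(max_diff, abs(s - rs), abs(d - rd))
    }
    site_example <- abs(count_sites("ATGTTTGGG")[["S"]] - 4 / 3)
    list(max_diff = max_diff, site_example_err = site_example)
  })
}

eval_synteny_oracle <- function(seed, n_cases = 100L) {
  with_stage_seed(seed, 23L, {
    agree <- 0L
    for (case in seq_len(n_cases)) {
      n <- sample(6:12, 1L)
      gap <- sample(2:25, 1L)
      q <- sample.int(n)
      t <- if (stats::runif(1) < 0.3) {
        # noisy diagonal: mostly collinear with a few swaps
        tt <- q
        sw <- sample.int(n, 2L)
        tt[sw] <- tt[rev(sw)]
        tt
      } else sample.int(n)
      blocks <- find_synteny_blocks(
        data.frame(query_idx = q, target_idx = t), min_anchors = 3L,
        max_gap = gap)
      got <- if (length(blocks) == 0L) 0L else nrow(blocks[[1L]]$anchors)
      want <- ref_longest_chain_exhaustive(q, t, gap)
      if (want < 3L) want <- 0L
      if (got == want) agree <- agree + 1L
    }
    agree / n_cases
  })
}

#' Run the full synthetic demonstration pipeline with verification gates
#'
#' Executes simulation, QC, six-group binning, allele-table construction,
#' homoeolog expression analysis and Ks estimation on a synthetic hybrid
#' assembly, then runs a verification battery: origin-binning recovery,
#' exactness of the Hi-C signal formula, misjoin detection recall and
#' precision (noise-free and noisy), threshold boundary semantics,
#' allele-group reconstruction (ARI), synteny chaining against an
#' exhaustive search, Nei-Gojobori counts against brute-force enumeration
#' plus divergence recovery, and dominance-fraction recovery.
#'
#' @param config a [simulation_config()]; its seed drives every stage.
#' @param outdir optional directory for result tables.
#' @param rec_threshold normalized Hi-C signal threshold (default 0.4).
#' @param quiet suppress progress messages.
#' @param dry_run print the stage plan and return without computing.
#' @return list with `metrics` (named numeric vector), `gates` (named
#'   logical vector), and the main result tables.
#' @export
run_demo <- function(config = simulation_config(), outdir = NULL,
                     rec_threshold = 0.4, quiet = FALSE, dry_run = FALSE) {
  stages <- c("simulate", "qc", "bin", "alleles", "homexp", "ks", "verify")
  if (dry_run) {
    message("planned stages: ", paste(stages, collapse = " -> "))
    if (!is.null(outdir)) message("would write results under ", outdir)
    return(invisible(NULL))
  }
  seed <- config$seed

  bin <- run_binning_pipeline(config, rec_threshold = rec_threshold,
                              quiet = quiet)

  demo_log(quiet, "alleles", "allele table on the binned assembly")
  gene_contig <- gene_contig_map(bin$hybrid$genes, bin$fragments$segments)
  anc_by_gene <- stats::setNames(bin$ancestry_call[gene_contig],
                                 bin$hybrid$genes$gene)
  rec_genes <- gene_contig %in% bin$rec$rec_contigs
  anc_by_gene[rec_genes] <- "Rec"
  al_main <- run_allele_pipeline(bin$hybrid, config, anc_by_gene)

  demo_log(quiet, "homexp", "expression dominance, LDE and clustering")
  expr <- simulate_expression(bin$hybrid$genes, config)
  lde <- call_lde(expr$expression)
  clus <- fold_change_clusters(expr$expression)

  demo_log(quiet, "verify", "running the verification battery")
  formula <- eval_hic_formula(seed)
  thresholds_ok <- eval_threshold_semantics()
  mj0 <- eval_misjoin(seed, noisy = FALSE)
  mj1 <- eval_misjoin(seed, noisy = TRUE)
  al0 <- eval_alleles(seed, 0)
  al2 <- eval_alleles(seed, 2)
  dom <- eval_dominance(seed)
  ks <- eval_ks(seed)
  ng <- eval_ng_oracle(seed)
  syn <- eval_synteny_oracle(seed)

  se <- function(p, n) sqrt(p * (1 - p) / n)
  metrics <- c(
    bin$metrics,
    misjoin_recall_noisefree = mj0$recall,
    misjoin_precision_noisefree = mj0$precision,
    misjoin_recall = mj1$recall,
    misjoin_precision = mj1$precision,
    hic_formula_max_err = formula$max_err,
    allele_ari_noisefree = unname(al0[["ari"]]),
    allele_ari_noisy = unname(al2[["ari"]]),
    allele_ari_main = unname(al_main$metrics[["ari"]]),
    so_dominant_pct = 100 * dom$so_fraction,
    ss_dominant_pct = 100 * dom$ss_fraction,
    dominance_errors_noisefree = dom$errors_noisefree,
    median_ks = ks$median,
    ks_rel_err = ks$rel_err,
    ng_oracle_max_diff = ng$max_diff,
    synteny_oracle_agreement = syn,
    lde_so_leaf = length(lde$leaf$LDE_SO),
    lde_ss_leaf = length(lde$leaf$LDE_SS))

  gates <- c(
    binning_recovery = unname(bin$metrics[["binning_accuracy"]] >= 0.95 &&
      bin$metrics[["rec_precision"]] >= 0.9 &&
      bin$metrics[["rec_recall"]] >= 0.9),
    hic_formula_exact = formula$max_err < 1e-12 && formula$symmetric &&
      formula$linear && formula$inverse,
    misjoin_detection = mj0$recall == 1 && mj0$precision == 1 &&
      mj1$recall >= 0.9 && mj1$precision >= 0.9,
    threshold_semantics = thresholds_ok,
    allele_reconstruction = al0[["ari"]] == 1 && al2[["ari"]] >= 0.95 &&
      al0[["duplicated_genes"]] == 0 && al2[["duplicated_genes"]] == 0,
    synteny_oracle = syn == 1,
    ng_oracle = ng$max_diff < 1e-9 && ng$site_example_err == 0 &&
      ks$rel_err <= 0.10,
    dominance_recovery = dom$errors_noisefree == 0 &&
      abs(dom$so_fraction - dom$planted_so) <= 3 * se(dom$planted_so, dom$n) &&
      abs(dom$ss_fraction - dom$planted_ss) <= 3 * se(dom$planted_ss, dom$n))

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_tsv(bin$groups, file.path(outdir, "origin_calls.tsv"))
    write_tsv(al_main$table, file.path(outdir, "allele_table.tsv"))
    write_tsv(al_main$groups, file.path(outdir, "allele_groups.tsv"))
    write_tsv(al_main$distribution, file.path(outdir, "allele_counts.tsv"))
    write_tsv(clus$clusters, file.path(outdir, "fold_change_clusters.tsv"))
    write_tsv(data.frame(metric = names(metrics), value = unname(metrics)),
              file.path(outdir, "metrics.tsv"))
    write_tsv(data.frame(gate = names(gates), passed = unname(gates)),
              file.path(outdir, "gates.tsv"))
  }
  demo_log(quiet, "verify", sum(gates), "/", length(gates), " gates passed")
  list(metrics = metrics, gates = gates, binning = bin, alleles = al_main,
       expression = expr, lde = lde, clusters = clus)
}
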