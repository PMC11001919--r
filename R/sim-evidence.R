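# Evidence-layer generators: depth panels, parental-specific k-mers, Hi-C
# contacts and within-contig signal tracks, homoeolog expression, assembly
# QC statistics, reference similarity, and allele-pipeline hit tables. All
# are driven by the truth tables produced by the genome generators.

#' Default resequencing panel specification
#'
#' One sample per parent (ROC, YZ) and `n_ancestral` resequenced
#' individuals per ancestral species (SO, SS).
#'
#' @param n_ancestral individuals per ancestral species.
#' @return data frame with columns `sample`, `species`.
#' @export
default_panel_spec <- function(n_ancestral = 5L) {
  rbind(
    data.frame(sample = c("ROC_1", "YZ_1"), species = c("ROC", "YZ"),
               stringsAsFactors = FALSE),
    data.frame(sample = sprintf("SO_%d", seq_len(n_ancestral)), species = "SO",
               stringsAsFactors = FALSE),
    data.frame(sample = sprintf("SS_%d", seq_len(n_ancestral)), species = "SS",
               stringsAsFactors = FALSE))
}

#' Simulate a normalized read-depth panel
#'
#' Per contig and sample, depth on the normalized scale: expectation 1.0
#' when the sample's genome contains the contig's haplotype lineage,
#' `depth_leakage` otherwise, with multiplicative lognormal noise
#' (`depth_noise_cv`). Contigs of mixed composition (recombinant or
#' chimeric) receive composition-weighted expectations.
#'
#' @param fragments output of [fragment_into_contigs()].
#' @param panel_spec data frame with columns `sample` and `species`
#'   (one of `"SO"`, `"SS"`, `"ROC"`, `"YZ"`), e.g. [default_panel_spec()].
#' @param config a [simulation_config()].
#' @return long data frame: contig, sample, species, depth.
#' @export
simulate_depth_panel <- function(fragments, panel_spec, config) {
  validate_config(config)
  stopifnot(all(c("sample", "species") %in% names(panel_spec)))
  bad <- setdiff(panel_spec$species, c("SO", "SS", "ROC", "YZ"))
  if (length(bad) > 0L)
    stop("unknown sample species: ", paste(bad, collapse = ", "), call. = FALSE)
  ct <- fragments$contigs
  leak <- config$depth_leakage
  with_stage_seed(config$seed, 4L, {
    out <- lapply(seq_len(nrow(panel_spec)), function(i) {
      sp <- panel_spec$species[i]
      own <- switch(sp, SO = ct$so_fraction, SS = 1 - ct$so_fraction,
                    ROC = ct$roc_fraction, YZ = 1 - ct$roc_fraction)
      e <- own + (1 - own) * leak
      data.frame(contig = ct$contig, sample = panel_spec$sample[i],
                 species = sp, depth = e * lognoise(nrow(ct), config$depth_noise_cv),
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

#' Parental haplotype sequences grouped by parent of origin
#'
#' @param hybrid output of [simulate_hybrid_chromosomes()] with sequences.
#' @return list with character vectors `ROC` and `YZ`.
#' @export
parental_genome_sequences <- function(hybrid) {
  if (is.null(hybrid$sequences))
    stop("hybrid set carries no sequences (emit_sequences = FALSE)", call. = FALSE)
  split(unlist(hybrid$sequences, use.names = FALSE),
        hybrid$chromosomes$parent)[c("ROC", "YZ")]
}

#' Count parental-specific k-mers on each contig
#'
#' Identifies the exact k-mers unique to each parental genome (forward
#' strand set difference) and counts their occurrences per contig.
#'
#' @param fragments output of [fragment_into_contigs()] with sequences.
#' @param parental_genomes list with character vectors `ROC` and `YZ`,
#'   e.g. [parental_genome_sequences()].
#' @param k k-mer length, between 11 and 31.
#' @return data frame: contig, roc_specific, yz_specific.
#' @export
simulate_kmer_evidence <- function(fragments, parental_genomes, k = 21L) {
  if (k < 11L || k > 31L)
    stop("k must be between 11 and 31", call. = FALSE)
  if (is.null(fragments$sequences))
    stop("fragments carry no sequences (emit_sequences = FALSE)", call. = FALSE)
  genome_kmers <- function(seqs) unique(unlist(lapply(seqs, seq_kmers, k = k),
                                               use.names = FALSE))
  k_roc <- genome_kmers(parental_genomes$ROC)
  k_yz <- genome_kmers(parental_genomes$YZ)
  roc_spec <- setdiff(k_roc, k_yz)
  yz_spec <- setdiff(k_yz, k_roc)

  seqs <- fragments$sequences
  km <- lapply(seqs, seq_kmers, k = k)
  all_km <- unlist(km, use.names = FALSE)
  idx <- rep(seq_along(km), lengths(km))
  n <- length(seqs)
  data.frame(
    contig = names(seqs),
    roc_specific = tabulate(idx[all_km %in% roc_spec], nbins = n),
    yz_specific = tabulate(idx[all_km %in% yz_spec], nbins = n),
    stringsAsFactors = FALSE)
}

#' Simulate Hi-C contacts between contigs and within-contig signal tracks
#'
#' Expected links between contigs on the same chromosome follow a power-law
#' decay over inter-segment distance
#' (`hic_intra_scale * l1 * l2 / d^hic_decay_exponent`); pairs on different
#' chromosomes receive `hic_background_rate * l1 * l2`. Counts are Poisson.
#' Per-contig binned signal tracks are emitted for misjoin testing: bins
#' around a chimeric junction drop to `hic_track_background` of the normal
#' level.
#'
#' @param fragments output of [fragment_into_contigs()].
#' @param config a [simulation_config()].
#' @return list with `contacts` (data frame contigA, contigB, links;
#'   zero-link pairs omitted), `tracks` (named list of per-bin signal
#'   vectors), and `bin_size`.
#' @export
simulate_hic <- function(fragments, config) {
  validate_config(config)
  ct <- fragments$contigs
  sg <- fragments$segments
  n <- nrow(ct)
  with_stage_seed(config$seed, 5L, {
    id <- ct$contig
    len <- ct$length
    pr <- utils::combn(n, 2L)
    mu <- config$hic_background_rate * len[pr[1L, ]] * len[pr[2L, ]]

    # add intra-chromosomal decay terms per same-chromosome segment pair
    sg$mid <- (sg$chrom_start + sg$chrom_end) / 2
    sg$len <- sg$chrom_end - sg$chrom_start
    sg$ci <- match(sg$contig, id)
    key_of <- function(i, j) (pmin(i, j) - 1) * n + pmax(i, j)
    pair_key <- key_of(pr[1L, ], pr[2L, ])
    for (chrom_sg in split(sg, sg$chrom)) {
      m <- nrow(chrom_sg)
      if (m < 2L) next
      sp <- utils::combn(m, 2L)
      a <- sp[1L, ]; b <- sp[2L, ]
      keep <- chrom_sg$ci[a] != chrom_sg$ci[b]
      a <- a[keep]; b <- b[keep]
      if (length(a) == 0L) next
      d <- pmax(abs(chrom_sg$mid[a] - chrom_sg$mid[b]),
                (chrom_sg$len[a] + chrom_sg$len[b]) / 2)
      add <- config$hic_intra_scale * chrom_sg$len[a] * chrom_sg$len[b] /
        d^config$hic_decay_exponent
      at <- match(key_of(chrom_sg$ci[a], chrom_sg$ci[b]), pair_key)
      agg <- tapply(add, at, sum)
      mu[as.integer(names(agg))] <- mu[as.integer(names(agg))] + agg
    }

    links <- stats::rpois(length(mu), mu)
    keep <- links > 0L
    contacts <- data.frame(contigA = id[pr[1L, keep]], contigB = id[pr[2L, keep]],
                           links = links[keep], stringsAsFactors = FALSE)

    bin <- config$hic_bin_size
    tracks <- list()
    for (i in seq_len(n)) {
      nb <- floor(len[i] / bin)
      if (nb < 1L) next
      level <- rep(config$hic_track_level, nb)
      if (ct$is_chimera[i] && !is.na(ct$breakpoint[i])) {
        jb <- floor(ct$breakpoint[i] / bin) + 1L
        if (jb >= 1L && jb <= nb)
          level[jb] <- config$hic_track_level * config$hic_track_background
      }
      tracks[[id[i]]] <- level * lognoise(nb, config$depth_noise_cv)
    }
    list(contacts = contacts, tracks = tracks, bin_size = bin)
  })
}

#' Simulate homoeolog expression with configurable dominance fractions
#'
#' For every homoeolog pair (an SO/SS monoploid anchor pair present in the
#' gene truth table, or `n_pairs` free-standing pairs), FPKM values are
#' drawn from a log-normal model over two tissues (leaf, stem) and two
#' conditions (control, infected). A `dominance_fraction_so` share of pairs
#' receives a true So/Ss log2 ratio above the twofold threshold (and
#' conversely for Ss); neutral pairs have ratio 1 in expectation. Infected
#' samples additionally receive one of four lineage-by-tissue response
#' archetypes. True classes and archetypes are recorded.
#'
#' @param truth gene truth table from [simulate_hybrid_chromosomes()]
#'   (`$genes`), or a single integer number of pairs.
#' @param config a [simulation_config()].
#' @return list with `expression` (long data frame: pair, sample, tissue,
#'   condition, fpkm_so, fpkm_ss) and `truth` (pair, class, archetype).
#' @export
simulate_expression <- function(truth, config) {
  validate_config(config)
  if (config$dominance_fraction_so + config$dominance_fraction_ss > 1)
    stop("dominance fractions must sum to <= 1", call. = FALSE)
  if (is.numeric(truth) && length(truth) == 1L) {
    pairs <- data.frame(pair = sprintf("pair%05d", seq_len(truth)),
                        gene_so = sprintf("SO_sim_%05d", seq_len(truth)),
                        gene_ss = sprintf("SS_sim_%05d", seq_len(truth)),
                        stringsAsFactors = FALSE)
  } else {
    genes <- if (is.data.frame(truth)) truth else truth$genes
    so <- unique(genes$anchor[genes$lineage == "SO"])
    ss <- unique(genes$anchor[genes$lineage == "SS"])
    both <- intersect(sub("^SO", "", so), sub("^SS", "", ss))
    if (length(both) == 0L) stop("no homoeolog pairs in truth set", call. = FALSE)
    pairs <- data.frame(pair = paste0("pair", both),
                        gene_so = paste0("SO", both),
                        gene_ss = paste0("SS", both), stringsAsFactors = FALSE)
  }
  n <- nrow(pairs)
  with_stage_seed(config$seed, 6L, {
    cls <- sample(c("SO-dominant", "SS-dominant", "neutral"), n, replace = TRUE,
                  prob = c(config$dominance_fraction_so,
                           config$dominance_fraction_ss,
                           1 - config$dominance_fraction_so - config$dominance_fraction_ss))
    delta <- ifelse(cls == "SO-dominant", stats::runif(n, 1.2, 3),
             ifelse(cls == "SS-dominant", -stats::runif(n, 1.2, 3), 0))
    base <- stats::rnorm(n, mean = log2(20), sd = 1.5)
    arch <- sample(c("SO_up_both", "SS_up_both", "SO_up_leaf", "SS_up_leaf"),
                   n, replace = TRUE)
    eff <- function(lineage, tissue) {
      e <- numeric(n)
      e[arch == "SO_up_both" & lineage == "SO"] <- 3
      e[arch == "SS_up_both" & lineage == "SS"] <- 3
      e[arch == "SO_up_leaf" & lineage == "SO" & tissue == "leaf"] <- 3
      e[arch == "SS_up_leaf" & lineage == "SS" & tissue == "leaf"] <- 3
      e
    }
    rows <- list()
    for (tissue in c("leaf", "stem")) for (cond in c("control", "infected")) {
      noise <- function() stats::rnorm(n, 0, config$fpkm_dispersion)
      inf <- as.numeric(cond == "infected")
      lso <- base + delta / 2 + inf * eff("SO", tissue) + noise()
      lss <- base - delta / 2 + inf * eff("SS", tissue) + noise()
      rows[[paste(tissue, cond)]] <- data.frame(
        pair = pairs$pair, gene_so = pairs$gene_so, gene_ss = pairs$gene_ss,
        sample = paste(tissue, cond, sep = "_"), tissue = tissue,
        condition = cond, fpkm_so = 2^lso, fpkm_ss = 2^lss,
        stringsAsFactors = FALSE)
    }
    list(expression = do.call(rbind, rows),
         truth = data.frame(pair = pairs$pair, class = cls, archetype = arch,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate assembly QC statistics with planted junk contigs
#'
#' Appends artifact-like and contaminant-like junk entries to the contig
#' set and emits the per-contig statistics consumed by
#' [filter_artifactual()] and [filter_contamination()], plus gene-model
#' evidence (a share of junk gene models fails every retention clause).
#'
#' @param fragments output of [fragment_into_contigs()].
#' @param genes gene truth table (may be NULL).
#' @param config a [simulation_config()].
#' @return list with `kmer_stats`, `overlap`, `gene_evidence`, and `truth`
#'   (contig, artifact, contaminant).
#' @export
simulate_assembly_artifacts <- function(fragments, genes, config) {
  validate_config(config)
  ct <- fragments$contigs
  n <- nrow(ct)
  n_art <- round(config$artifact_fraction * n)
  n_con <- round(config$contamination_fraction * n)
  with_stage_seed(config$seed, 7L, {
    ids <- c(ct$contig,
             if (n_art > 0L) sprintf("junkA%03d", seq_len(n_art)),
             if (n_con > 0L) sprintf("junkC%03d", seq_len(n_con)))
    artifact <- c(rep(FALSE, n), rep(TRUE, n_art), rep(FALSE, n_con))
    contam <- c(rep(FALSE, n), rep(FALSE, n_art), rep(TRUE, n_con))
    total <- round(c(ct$length, stats::runif(n_art + n_con, 2e3, 2e4)))
    absent_frac <- ifelse(artifact, stats::runif(length(ids), 0.5, 0.8),
                          stats::runif(length(ids), 0, 0.05))
    overlap_frac <- ifelse(contam, stats::runif(length(ids), 0.5, 0.9),
                           stats::runif(length(ids), 0, 0.1))
    gene_ev <- NULL
    if (!is.null(genes)) {
      m <- nrow(genes)
      n_junk <- round(0.05 * m)
      gid <- c(genes$gene, sprintf("junk_gene%04d", seq_len(n_junk)))
      real <- c(rep(TRUE, m), rep(FALSE, n_junk))
      gene_ev <- data.frame(
        gene = gid,
        has_pfam_domain = ifelse(real, stats::runif(length(gid)) < 0.7, FALSE),
        has_uniprot_homolog = ifelse(real, stats::runif(length(gid)) < 0.6, FALSE),
        fpkm = ifelse(real, stats::rlnorm(length(gid), log(20), 1), stats::runif(length(gid), 0, 2)),
        read_coverage = ifelse(real, stats::runif(length(gid), 82, 100), stats::runif(length(gid), 0, 60)),
        augustus_support = ifelse(real, stats::runif(length(gid), 60, 100), stats::runif(length(gid), 0, 50)),
        is_real = real,
        stringsAsFactors = FALSE)
    }
    list(
      kmer_stats = data.frame(contig = ids, total = total,
                              absent = round(absent_frac * total),
                              stringsAsFactors = FALSE),
      overlap = data.frame(contig = ids, fraction = overlap_frac,
                           stringsAsFactors = FALSE),
      gene_evidence = gene_ev,
      truth = data.frame(contig = ids, artifact = artifact,
                         contaminant = contam, stringsAsFactors = FALSE))
  })
}

#' Simulate mapping similarity of contigs against the two ancestral
#' reference genomes
#'
#' Identity against a reference decreases with the contig's divergence from
#' that lineage; mapping quality is high for the matching lineage. Mixed
#' contigs get intermediate values on both references.
#'
#' @param fragments output of [fragment_into_contigs()].
#' @param config a [simulation_config()].
#' @return data frame: contig, mq_so, id_so, mq_ss, id_ss.
#' @export
simulate_similarity <- function(fragments, config) {
  validate_config(config)
  ct <- fragments$contigs
  n <- nrow(ct)
  with_stage_seed(config$seed, 8L, {
    jit <- function() stats::rnorm(n, 0, 0.001)
    d_anc <- config$ancestral_divergence
    d_par <- config$parental_divergence
    id_so <- 1 - (ct$so_fraction * d_par + (1 - ct$so_fraction) * d_anc) + jit()
    id_ss <- 1 - ((1 - ct$so_fraction) * d_par + ct$so_fraction * d_anc) + jit()
    data.frame(contig = ct$contig,
               mq_so = pmax(0, 20 + 40 * ct$so_fraction + stats::rnorm(n, 0, 1)),
               id_so = pmin(1, pmax(0, id_so)),
               mq_ss = pmax(0, 20 + 40 * (1 - ct$so_fraction) + stats::rnorm(n, 0, 1)),
               id_ss = pmin(1, pmax(0, id_ss)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate the tabular alignment evidence for the allele pipeline
#'
#' Emits first-round protein hit tables against the ancestral monoploid
#' gene sets (true anchor, homoeolog distractor, and a weak distractor
#' failing the e-value cutoff), coding-sequence placements of each gene on
#' every haplotype of its subgenome (ploidy-capped), second-round rescue
#' hits for deliberately unanchored genes, and reciprocal monoploid hit
#' tables for homoeolog (RBH) detection.
#'
#' @param hybrid output of [simulate_hybrid_chromosomes()].
#' @param config a [simulation_config()].
#' @param identity_noise_sd Gaussian jitter (percentage points) on identity
#'   and coverage, with proportional bitscore jitter; 0 gives noise-free
#'   evidence.
#' @param unanchored_fraction share of genes whose first-round hits all
#'   fail the e-value cutoff (rescued in round two).
#' @param rbh_missing_fraction share of monoploid loci without a
#'   cross-subgenome hit (lineage-specific genes).
#' @return list: `hits1`, `placements`, `hits2`, `hits_so_ss`,
#'   `hits_ss_so`, `unanchored` (gene ids), `genes` (truth table).
#' @export
simulate_allele_evidence <- function(hybrid, config, identity_noise_sd = 0,
                                     unanchored_fraction = 0.05,
                                     rbh_missing_fraction = 0.1) {
  validate_config(config)
  genes <- hybrid$genes
  chroms <- hybrid$chromosomes
  with_stage_seed(config$seed, 10L, {
    n <- nrow(genes)
    unanchored <- genes$gene[stats::runif(n) < unanchored_fraction]
    anchored <- setdiff(genes$gene, unanchored)
    jit <- function(m) stats::rnorm(m, 0, identity_noise_sd)

    g_anc <- genes[match(anchored, genes$gene), ]
    m <- nrow(g_anc)
    id_true <- pmin(100, pmax(0, 98 + jit(m)))
    cov_true <- pmin(100, pmax(0, 96 + jit(m)))
    id_hom <- pmin(100, pmax(0, 89 + jit(m)))
    hits1 <- rbind(
      data.frame(query = g_anc$gene, target = g_anc$anchor,
                 identity = id_true, coverage = cov_true,
                 evalue = 1e-80, bitscore = 5 * id_true,
                 stringsAsFactors = FALSE),
      data.frame(query = g_anc$gene, target = g_anc$homoeolog,
                 identity = id_hom, coverage = pmin(100, pmax(0, 90 + jit(m))),
                 evalue = 1e-40, bitscore = 5 * id_hom,
                 stringsAsFactors = FALSE),
      data.frame(query = g_anc$gene,
                 target = sprintf("%s_%s_l%02d", g_anc$lineage, g_anc$group,
                                  (g_anc$locus %% max(g_anc$locus)) + 1L),
                 identity = 55, coverage = 40, evalue = 1e-3, bitscore = 180,
                 stringsAsFactors = FALSE))
    if (length(unanchored) > 0L) {
      g_un <- genes[match(unanchored, genes$gene), ]
      hits1 <- rbind(hits1, data.frame(
        query = g_un$gene, target = g_un$anchor, identity = 95, coverage = 90,
        evalue = 1e-4, bitscore = 400, stringsAsFactors = FALSE))
    }

    # placements of each anchored gene's CDS on every haplotype of its own
    # subgenome at the homologous locus, ploidy-capped
    placements <- do.call(rbind, lapply(seq_len(m), function(i) {
      g <- g_anc[i, ]
      same_locus <- genes[genes$group == g$group & genes$locus == g$locus &
                            genes$lineage == g$lineage, ]
      same_locus <- same_locus[seq_len(min(nrow(same_locus), 12L)), ]
      data.frame(gene = g$gene, chrom = same_locus$chrom,
                 start = same_locus$start, end = same_locus$end,
                 rank = seq_len(nrow(same_locus)), stringsAsFactors = FALSE)
    }))

    hits2 <- NULL
    if (length(unanchored) > 0L) {
      rows <- lapply(unanchored, function(gi) {
        g <- genes[genes$gene == gi, ]
        member <- anchored[anchored %in%
                             genes$gene[genes$anchor == g$anchor & genes$gene != gi]]
        if (length(member) == 0L) return(NULL)
        data.frame(query = gi, target = member[1L], identity = 90 + jit(1L),
                   coverage = 88, evalue = 1e-30, bitscore = 450,
                   stringsAsFactors = FALSE)
      })
      hits2 <- do.call(rbind, Filter(Negate(is.null), rows))
    }

    # reciprocal monoploid hit tables over the full group x locus grid
    loci <- unique(genes[, c("group", "locus")])
    anchor_so <- sprintf("SO_%s_l%02d", loci$group, loci$locus)
    anchor_ss <- sprintf("SS_%s_l%02d", loci$group, loci$locus)
    present <- stats::runif(nrow(loci)) >= rbh_missing_fraction
    hits_so_ss <- data.frame(query = anchor_so[present], target = anchor_ss[present],
                             identity = 96, coverage = 95, evalue = 1e-60,
                             bitscore = 480, stringsAsFactors = FALSE)
    hits_ss_so <- data.frame(query = anchor_ss[present], target = anchor_so[present],
                             identity = 96, coverage = 95, evalue = 1e-60,
                             bitscore = 480, stringsAsFactors = FALSE)

    list(hits1 = hits1, placements = placements, hits2 = hits2,
         hits_so_ss = hits_so_ss, hits_ss_so = hits_ss_so,
         unanchored = unanchored, genes = genes)
  })
}

# Contig carrying each gene (by midpoint), from the truth segment map.
gene_contig_map <- function(genes, segments) {
  mid <- (genes$start + genes$end) / 2
  out <- rep(NA_character_, nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- segments$contig[segments$chrom == genes$chrom[i] &
                             segments$chrom_start <= mid[i] &
                             segments$chrom_end > mid[i]]
    if (length(hit) > 0L) out[i] <- hit[1L]
  }
  out
}
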