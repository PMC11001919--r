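# Synthetic hybrid-aneuploid genome generator: ancestral genomes, hybrid
# chromosome sets (including interspecific recombinants), and contig
# fragmentation with optional chimeras. All coordinates are 0-based
# half-open; mutation is substitution-only so coordinates stay comparable
# across lineages.

#' Simulate two diverged ancestral genomes
#'
#' Draws a random ancestor per homologous group and mutates it
#' independently into an So-type and an Ss-type genome so that the expected
#' pairwise divergence equals `ancestral_divergence`.
#'
#' @param config a [simulation_config()].
#' @return list with named character vectors `ancestor`, `genome_SO`,
#'   `genome_SS` (one sequence per homologous group).
#' @export
simulate_ancestral_genomes <- function(config) {
  validate_config(config)
  with_stage_seed(config$seed, 1L, {
    groups <- sprintf("g%02d", seq_len(config$n_homologous_groups))
    r <- branch_rate(config$ancestral_divergence)
    ancestor <- vapply(groups, function(g) random_dna(config$chromosome_length), "")
    genome_SO <- vapply(ancestor, mutate_sequence, "", rate = r)
    genome_SS <- vapply(ancestor, mutate_sequence, "", rate = r)
    names(genome_SO) <- names(genome_SS) <- groups
    list(ancestor = ancestor, genome_SO = genome_SO, genome_SS = genome_SS)
  })
}

#' Simulate the hybrid chromosome set
#'
#' Emits So haplotypes, Ss haplotypes and recombinant (Rec) chromosomes for
#' each homologous group, splits them between the two parents (ROC, YZ),
#' and plants gene models at regular intervals so allele ground truth is
#' positional. Each Rec chromosome joins an So segment to an Ss segment at
#' one crossover; groups configured with zero Ss haplotypes contain no Ss
#' chromosome.
#'
#' @param config a [simulation_config()].
#' @param ancestral output of [simulate_ancestral_genomes()]; may be NULL
#'   when `config$emit_sequences` is FALSE.
#' @return list with `chromosomes` (data frame: chrom, group, lineage,
#'   parent, length, crossover), `sequences` (named list or NULL), and
#'   `genes` (data frame: gene, chrom, start, end, group, locus, lineage,
#'   parent, anchor, homoeolog).
#' @export
simulate_hybrid_chromosomes <- function(config, ancestral = NULL) {
  validate_config(config)
  if (config$n_rec_chromosomes > 0L && all(config$ss_haplotypes_per_group == 0L))
    stop("n_rec_chromosomes > 0 requires at least one group with Ss haplotypes",
         call. = FALSE)
  if (config$emit_sequences && is.null(ancestral))
    stop("ancestral genomes are required when emit_sequences is TRUE", call. = FALSE)

  with_stage_seed(config$seed, 2L, {
    L <- config$chromosome_length
    r_hap <- branch_rate(config$parental_divergence)
    rows <- list()
    seqs <- list()
    add_chrom <- function(id, group, lineage, parent, crossover, seq) {
      rows[[length(rows) + 1L]] <<- data.frame(
        chrom = id, group = group, lineage = lineage, parent = parent,
        length = L, crossover = crossover, stringsAsFactors = FALSE)
      if (!is.null(seq)) seqs[[id]] <<- seq
    }

    for (g in seq_len(config$n_homologous_groups)) {
      gid <- sprintf("g%02d", g)
      for (lin in c("SO", "SS")) {
        n_h <- if (lin == "SO") config$so_haplotypes_per_group[g]
               else config$ss_haplotypes_per_group[g]
        if (n_h == 0L) next
        base <- if (config$emit_sequences) {
          if (lin == "SO") ancestral$genome_SO[[gid]] else ancestral$genome_SS[[gid]]
        } else NULL
        for (h in seq_len(n_h)) {
          parent <- if (h %% 2L == 1L) "ROC" else "YZ"
          id <- sprintf("%s_%s_h%d_%s", gid, lin, h, parent)
          seq <- if (!is.null(base)) mutate_sequence(base, r_hap) else NULL
          add_chrom(id, gid, lin, parent, NA_real_, seq)
        }
      }
    }

    # Rec chromosomes: round-robin over groups that carry Ss haplotypes.
    eligible <- which(config$ss_haplotypes_per_group > 0L)
    if (config$n_rec_chromosomes > 0L) {
      for (i in seq_len(config$n_rec_chromosomes)) {
        g <- eligible[((i - 1L) %% length(eligible)) + 1L]
        gid <- sprintf("g%02d", g)
        parent <- if (i %% 2L == 1L) "ROC" else "YZ"
        x <- round(stats::runif(1L, 0.35, 0.65) * L)
        id <- sprintf("%s_Rec_r%d_%s", gid, i, parent)
        seq <- NULL
        if (config$emit_sequences) {
          so_side <- mutate_sequence(ancestral$genome_SO[[gid]], r_hap)
          ss_side <- mutate_sequence(ancestral$genome_SS[[gid]], r_hap)
          seq <- paste0(substr(so_side, 1L, x), substr(ss_side, x + 1L, L))
        }
        add_chrom(id, gid, "Rec", parent, x, seq)
      }
    }

    chromosomes <- do.call(rbind, rows)
    genes <- plant_genes(chromosomes, config)
    list(chromosomes = chromosomes,
         sequences = if (config$emit_sequences) seqs else NULL,
         genes = genes)
  })
}

# Genes at fixed offsets on every haplotype; the ancestral (monoploid)
# anchor of a gene is determined by its group, locus index and the local
# lineage at the gene position (Rec chromosomes switch lineage at the
# crossover). Homoeolog partners pair the SO and SS monoploid anchors of
# the same group and locus.
plant_genes <- function(chromosomes, config) {
  last_start <- config$chromosome_length - config$gene_length
  if (last_start < config$gene_spacing / 2) return(NULL)
  starts <- seq(config$gene_spacing / 2, last_start,
                by = config$gene_spacing)
  out <- lapply(seq_len(nrow(chromosomes)), function(i) {
    ch <- chromosomes[i, ]
    mid <- starts + config$gene_length / 2
    lin <- if (ch$lineage == "Rec") ifelse(mid < ch$crossover, "SO", "SS")
           else rep(ch$lineage, length(starts))
    locus <- seq_along(starts)
    data.frame(
      gene = sprintf("%s_gene%02d", ch$chrom, locus),
      chrom = ch$chrom,
      start = starts,
      end = starts + config$gene_length,
      group = ch$group,
      locus = locus,
      lineage = lin,
      parent = ch$parent,
      anchor = sprintf("%s_%s_l%02d", lin, ch$group, locus),
      stringsAsFactors = FALSE)
  })
  genes <- do.call(rbind, out)
  genes$homoeolog <- ifelse(genes$lineage == "SO",
                            sub("^SO", "SS", genes$anchor),
                            sub("^SS", "SO", genes$anchor))
  genes
}

#' Fragment chromosomes into contigs, optionally planting chimeras
#'
#' Cuts each chromosome into pieces of approximately the configured N50;
#' a `chimera_fraction` of the resulting contigs is formed by concatenating
#' two pieces from different chromosomes, recording the junction as a truth
#' breakpoint. Total contig length equals total chromosome length.
#'
#' @param hybrid output of [simulate_hybrid_chromosomes()].
#' @param config a [simulation_config()].
#' @return list with `contigs` (data frame: contig, length, is_chimera,
#'   breakpoint, parent, ancestry, rec, so_fraction, roc_fraction),
#'   `segments` (contig-to-chromosome mapping, 0-based half-open), and
#'   `sequences` (named character vector or NULL).
#' @export
fragment_into_contigs <- function(hybrid, config) {
  validate_config(config)
  if (config$contig_n50 >= config$chromosome_length)
    stop("contig_n50 must be smaller than chromosome_length", call. = FALSE)

  with_stage_seed(config$seed, 3L, {
    n50 <- config$contig_n50
    pieces <- list()
    for (i in seq_len(nrow(hybrid$chromosomes))) {
      ch <- hybrid$chromosomes[i, ]
      pos <- 0
      while (pos < ch$length) {
        len <- round(stats::runif(1L, 0.7, 1.3) * n50)
        if (ch$length - pos - len < 0.4 * n50) len <- ch$length - pos
        pieces[[length(pieces) + 1L]] <- data.frame(
          chrom = ch$chrom, chrom_start = pos, chrom_end = pos + len,
          stringsAsFactors = FALSE)
        pos <- pos + len
      }
    }
    pieces <- do.call(rbind, pieces)
    n_pieces <- nrow(pieces)

    # choose chimera pairs from distinct chromosomes
    k <- round(config$chimera_fraction * n_pieces / (1 + config$chimera_fraction))
    chim_a <- integer(0); chim_b <- integer(0)
    if (k > 0L) {
      idx <- sample.int(n_pieces)
      used <- rep(FALSE, n_pieces)
      for (a in idx) {
        if (length(chim_a) >= k) break
        if (used[a]) next
        partner <- idx[!used[idx] & idx != a &
                         pieces$chrom[idx] != pieces$chrom[a]]
        if (length(partner) == 0L) next
        b <- partner[1L]
        used[c(a, b)] <- TRUE
        chim_a <- c(chim_a, a); chim_b <- c(chim_b, b)
      }
    }

    plain <- setdiff(seq_len(n_pieces), c(chim_a, chim_b))
    seg_rows <- list(); contig_rows <- list()
    tig_id <- function(n) sprintf("tig%05d", n)
    n_tig <- 0L
    add_contig <- function(piece_idx, chimera) {
      n_tig <<- n_tig + 1L
      id <- tig_id(n_tig)
      offs <- 0
      for (p in piece_idx) {
        len <- pieces$chrom_end[p] - pieces$chrom_start[p]
        seg_rows[[length(seg_rows) + 1L]] <<- data.frame(
          contig = id, seg_start = offs, seg_end = offs + len,
          chrom = pieces$chrom[p], chrom_start = pieces$chrom_start[p],
          chrom_end = pieces$chrom_end[p], stringsAsFactors = FALSE)
        offs <- offs + len
      }
      contig_rows[[length(contig_rows) + 1L]] <<- data.frame(
        contig = id, length = offs, is_chimera = chimera,
        breakpoint = if (chimera)
          pieces$chrom_end[piece_idx[1L]] - pieces$chrom_start[piece_idx[1L]]
        else NA_real_,
        stringsAsFactors = FALSE)
    }
    for (p in plain) add_contig(p, FALSE)
    if (k > 0L) for (j in seq_along(chim_a)) add_contig(c(chim_a[j], chim_b[j]), TRUE)

    contigs <- do.call(rbind, contig_rows)
    segments <- do.call(rbind, seg_rows)

    comp <- segment_composition(segments, hybrid$chromosomes)
    contigs <- merge(contigs, comp, by = "contig", sort = FALSE)
    contigs <- contigs[order(contigs$contig), ]
    rownames(contigs) <- NULL

    sequences <- NULL
    if (!is.null(hybrid$sequences)) {
      sequences <- vapply(split(segments, segments$contig), function(sg) {
        sg <- sg[order(sg$seg_start), ]
        paste(vapply(seq_len(nrow(sg)), function(j) {
          substr(hybrid$sequences[[sg$chrom[j]]],
                 sg$chrom_start[j] + 1L, sg$chrom_end[j])
        }, ""), collapse = "")
      }, "")
    }
    list(contigs = contigs, segments = segments, sequences = sequences)
  })
}

# Per-contig truth composition: fraction of bp from the SO lineage (Rec
# chromosomes contribute SO left of the crossover, SS right of it), the
# fraction inherited from the ROC parent, a majority ancestry/parent label,
# and the Rec flag (any segment on a Rec chromosome).
segment_composition <- function(segments, chromosomes) {
  info <- chromosomes[match(segments$chrom, chromosomes$chrom), ]
  seg_len <- segments$chrom_end - segments$chrom_start
  so_bp <- ifelse(info$lineage == "SO", seg_len,
           ifelse(info$lineage == "SS", 0,
                  pmax(0, pmin(segments$chrom_end, info$crossover) - segments$chrom_start)))
  roc_bp <- ifelse(info$parent == "ROC", seg_len, 0)
  rec_seg <- info$lineage == "Rec"
  agg <- function(x) tapply(x, segments$contig, sum)
  tot <- agg(seg_len)
  out <- data.frame(
    contig = names(tot),
    so_fraction = as.numeric(agg(so_bp) / tot),
    roc_fraction = as.numeric(agg(roc_bp) / tot),
    rec = as.logical(tapply(rec_seg, segments$contig, any)),
    stringsAsFactors = FALSE)
  out$ancestry <- ifelse(out$so_fraction >= 0.5, "SO", "SS")
  out$parent <- ifelse(out$roc_fraction >= 0.5, "ROC", "YZ")
  out
}

#' Simulate an aligned coding-sequence pair at a given divergence
#'
#' Generates a random stop-free CDS and mutates two copies independently so
#' the expected pairwise evolutionary distance (substitution events per
#' site, the quantity a Jukes-Cantor-corrected rate estimates) equals
#' `divergence`. Events hit uniform positions (multiple hits allowed) and
#' proposals that would create an internal stop codon are rejected.
#' Useful for parameter recovery of synonymous substitution rates.
#'
#' @param n_codons number of codons.
#' @param divergence expected pairwise substitution events per site.
#' @param seed optional integer seed.
#' @return list with elements `cds1`, `cds2` (equal-length strings).
#' @export
simulate_cds_pair <- function(n_codons, divergence, seed = NULL) {
  run <- function() {
    sense <- names(GENETIC_CODE_TABLE)[GENETIC_CODE_TABLE != "*"]
    anc <- sample(sense, n_codons, replace = TRUE)
    mut <- function(codons) {
      chars <- strsplit(paste(codons, collapse = ""), "", fixed = TRUE)[[1L]]
      n <- length(chars)
      n_events <- stats::rpois(1L, n * divergence / 2)
      if (n_events > 0L) {
        for (pos in sample.int(n, n_events, replace = TRUE)) {
          old <- chars[pos]
          new <- sample(setdiff(DNA_BASES, old), 1L)
          cidx <- (pos - 1L) %/% 3L
          codon <- chars[(cidx * 3L + 1L):(cidx * 3L + 3L)]
          codon[((pos - 1L) %% 3L) + 1L] <- new
          if (GENETIC_CODE_TABLE[[paste(codon, collapse = "")]] == "*") next
          chars[pos] <- new
        }
      }
      paste(chars, collapse = "")
    }
    list(cds1 = mut(anc), cds2 = mut(anc))
  }
  if (is.null(seed)) run() else with_stage_seed(seed, 9L, run())
}
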