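#' Simulation configuration for synthetic hybrid-aneuploid genomes
#'
#' Builds and validates the configuration object consumed by every
#' `simulate_*` generator. The defaults emulate, at desk scale, a modern
#' hybrid sugarcane-like karyotype: ten homologous groups carrying six
#' S. officinarum-derived (So) and three S. spontaneum-derived (Ss)
#' haplotypes each (Ss absent from groups 5 and 8, mirroring a hybrid that
#' lacks intact Ss chromosomes in two groups), plus interspecific
#' recombinant (Rec) chromosomes, an So/Ss divergence matching a median
#' synonymous substitution rate of 0.037, and homoeolog expression
#' dominance fractions of 7.1% (So) and 3.0% (Ss).
#'
#' @param seed integer seed; identical configurations give bit-identical
#'   simulator output.
#' @param n_homologous_groups number of homologous chromosome groups.
#' @param so_haplotypes_per_group,ss_haplotypes_per_group integer vectors
#'   (length `n_homologous_groups`, or length 1, recycled) of haplotype
#'   counts per group; `0` Ss haplotypes models missing ancestral
#'   chromosomes.
#' @param n_rec_chromosomes number of recombinant chromosomes, each built
#'   by a crossover joining an So segment to an Ss segment.
#' @param ancestral_divergence expected pairwise substitution divergence
#'   between the two ancestral genomes (substitutions/site).
#' @param parental_divergence expected pairwise divergence between
#'   haplotypes within a lineage (substitutions/site).
#' @param chromosome_length chromosome length in bp.
#' @param contig_n50 target contig N50 in bp (must be < chromosome_length).
#' @param chimera_fraction proportion of final contigs that are misjoined
#'   (two segments from different chromosomes).
#' @param depth_leakage cross-mapping read-depth expectation for a sample
#'   whose genome does not contain the contig's lineage.
#' @param depth_noise_cv coefficient of variation of multiplicative depth
#'   noise.
#' @param hic_decay_exponent power-law exponent of intra-chromosomal Hi-C
#'   contact decay with distance.
#' @param hic_intra_scale scale of intra-chromosomal expected link counts
#'   (links x bp^(exponent) / bp-pair).
#' @param hic_background_rate expected inter-chromosomal links per bp-pair.
#' @param hic_bin_size bin size (bp) of the within-contig Hi-C signal
#'   tracks used for misjoin detection.
#' @param hic_track_level expected links/bin inside a correctly assembled
#'   contig region.
#' @param hic_track_background signal level at a chimeric junction,
#'   relative to `hic_track_level`.
#' @param seq_depth Hi-C fold-coverage used to normalise contact signals
#'   (the `1/seq depth` factor of the signal formula).
#' @param gene_spacing distance (bp) between planted gene starts; allele
#'   ground truth is positional.
#' @param gene_length length (bp) of planted gene models.
#' @param dominance_fraction_so,dominance_fraction_ss proportions of
#'   homoeolog pairs with expression dominance toward each lineage
#'   (must sum to <= 1).
#' @param fpkm_dispersion sd (log2 units) of multiplicative FPKM noise.
#' @param emit_sequences if FALSE, only coordinates and evidence tables are
#'   generated (fast large-scale runs for misjoin testing).
#' @param artifact_fraction,contamination_fraction proportions of extra
#'   junk contigs appended to the assembly to exercise the QC filters.
#'
#' @return A validated list of class `"sim_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_homologous_groups = 10L,
                              so_haplotypes_per_group = 6L,
                              ss_haplotypes_per_group = c(3L, 3L, 3L, 3L, 0L, 3L, 3L, 0L, 3L, 3L),
                              n_rec_chromosomes = 12L,
                              ancestral_divergence = 0.037,
                              parental_divergence = 0.01,
                              chromosome_length = 5e4,
                              contig_n50 = 5e3,
                              chimera_fraction = 0.05,
                              depth_leakage = 0.1,
                              depth_noise_cv = 0.1,
                              hic_decay_exponent = 1.0,
                              hic_intra_scale = 8,
                              hic_background_rate = 4e-7,
                              hic_bin_size = 500,
                              hic_track_level = 100,
                              hic_track_background = 0.05,
                              seq_depth = 1.0,
                              gene_spacing = 1e4,
                              gene_length = 900,
                              dominance_fraction_so = 0.071,
                              dominance_fraction_ss = 0.030,
                              fpkm_dispersion = 0.15,
                              emit_sequences = TRUE,
                              artifact_fraction = 0.02,
                              contamination_fraction = 0.02) {
  cfg <- list(
    seed = as.integer(seed),
    n_homologous_groups = as.integer(n_homologous_groups),
    so_haplotypes_per_group = as.integer(rep_len(so_haplotypes_per_group, n_homologous_groups)),
    ss_haplotypes_per_group = as.integer(rep_len(ss_haplotypes_per_group, n_homologous_groups)),
    n_rec_chromosomes = as.integer(n_rec_chromosomes),
    ancestral_divergence = ancestral_divergence,
    parental_divergence = parental_divergence,
    chromosome_length = chromosome_length,
    contig_n50 = contig_n50,
    chimera_fraction = chimera_fraction,
    depth_leakage = depth_leakage,
    depth_noise_cv = depth_noise_cv,
    hic_decay_exponent = hic_decay_exponent,
    hic_intra_scale = hic_intra_scale,
    hic_background_rate = hic_background_rate,
    hic_bin_size = hic_bin_size,
    hic_track_level = hic_track_level,
    hic_track_background = hic_track_background,
    seq_depth = seq_depth,
    gene_spacing = gene_spacing,
    gene_length = gene_length,
    dominance_fraction_so = dominance_fraction_so,
    dominance_fraction_ss = dominance_fraction_ss,
    fpkm_dispersion = fpkm_dispersion,
    emit_sequences = isTRUE(emit_sequences),
    artifact_fraction = artifact_fraction,
    contamination_fraction = contamination_fraction
  )
  class(cfg) <- "sim_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(field, why) {
    stop(sprintf("invalid simulation config: field '%s' %s", field, why), call. = FALSE)
  }
  pos <- c("chromosome_length", "contig_n50", "hic_bin_size", "hic_track_level",
           "seq_depth", "gene_spacing", "gene_length")
  for (f in pos) if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1L || cfg[[f]] <= 0)
    fail(f, "must be a positive number")
  props <- c("chimera_fraction", "depth_leakage", "dominance_fraction_so",
             "dominance_fraction_ss", "hic_track_background",
             "artifact_fraction", "contamination_fraction")
  for (f in props) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0 || cfg[[f]] > 1)
    fail(f, "must be a proportion in [0, 1]")
  nonneg <- c("ancestral_divergence", "parental_divergence", "depth_noise_cv",
              "hic_decay_exponent", "hic_intra_scale", "hic_background_rate",
              "fpkm_dispersion")
  for (f in nonneg) if (!is.numeric(cfg[[f]]) || cfg[[f]] < 0)
    fail(f, "must be non-negative")
  if (cfg$ancestral_divergence >= 0.75) fail("ancestral_divergence", "must be < 0.75")
  if (cfg$parental_divergence >= 0.75) fail("parental_divergence", "must be < 0.75")
  if (cfg$n_homologous_groups < 1L) fail("n_homologous_groups", "must be >= 1")
  if (any(cfg$so_haplotypes_per_group < 0L)) fail("so_haplotypes_per_group", "must be >= 0")
  if (any(cfg$ss_haplotypes_per_group < 0L)) fail("ss_haplotypes_per_group", "must be >= 0")
  if (cfg$n_rec_chromosomes < 0L) fail("n_rec_chromosomes", "must be >= 0")
  if (cfg$dominance_fraction_so + cfg$dominance_fraction_ss > 1)
    fail("dominance_fraction_so", "and dominance_fraction_ss must sum to <= 1")
  if (cfg$contig_n50 >= cfg$chromosome_length)
    fail("contig_n50", "must be smaller than chromosome_length")
  invisible(cfg)
}

#' Coordinate-only preset for misjoin-detection studies
#'
#' Long contigs (600 kb N50 from 2 Mb chromosomes, about 500 contigs) and
#' 20 kb Hi-C signal bins, without sequence emission. Used to measure
#' breakpoint recall/precision of [detect_misjoins()].
#'
#' @param seed integer seed.
#' @param chimera_fraction proportion of misjoined contigs.
#' @param depth_noise_cv track noise (0 for the noise-free setting).
#' @return A `"sim_config"`.
#' @export
misjoin_sim_config <- function(seed = 1L, chimera_fraction = 0.05,
                               depth_noise_cv = 0.1) {
  simulation_config(
    seed = seed,
    n_homologous_groups = 10L,
    so_haplotypes_per_group = 10L,
    ss_haplotypes_per_group = 6L,
    n_rec_chromosomes = 0L,
    chromosome_length = 2e6,
    contig_n50 = 6e5,
    chimera_fraction = chimera_fraction,
    depth_noise_cv = depth_noise_cv,
    hic_bin_size = 2e4,
    emit_sequences = FALSE
  )
}

#' Preset with planted four-allele loci for allele-table studies
#'
#' Five homologous groups with four So and four Ss haplotypes each and no
#' recombinants, so every planted locus carries exactly four alleles per
#' subgenome.
#'
#' @param seed integer seed.
#' @return A `"sim_config"`.
#' @export
allele_sim_config <- function(seed = 1L) {
  simulation_config(
    seed = seed,
    n_homologous_groups = 5L,
    so_haplotypes_per_group = 4L,
    ss_haplotypes_per_group = 4L,
    n_rec_chromosomes = 0L,
    chimera_fraction = 0,
    emit_sequences = FALSE
  )
}
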