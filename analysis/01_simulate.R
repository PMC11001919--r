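#!/usr/bin/env Rscript
# Stage 1 — simulate the synthetic hybrid-aneuploid genome and its
# evidence layers (depth panels, parental 21-mers, Hi-C contacts,
# homoeolog FPKM), and write them under results/sim/.
#
# Every later stage re-derives the same simulation deterministically from
# the seed in this config, so the pipeline state lives in code, not in
# serialized R objects.

library(hybridbin)

outdir <- "results/sim"
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 1L)
anc <- simulate_ancestral_genomes(cfg)
hyb <- simulate_hybrid_chromosomes(cfg, anc)
frag <- fragment_into_contigs(hyb, cfg)

write_fasta(frag$sequences, file.path(outdir, "contigs.fasta"))
write_tsv(frag$segments, file.path(outdir, "truth_segments.tsv"))
write_tsv(frag$contigs, file.path(outdir, "truth_contigs.tsv"))
write_tsv(hyb$chromosomes, file.path(outdir, "truth_chromosomes.tsv"))
write_tsv(hyb$genes, file.path(outdir, "truth_genes.tsv"))

depth <- simulate_depth_panel(frag, default_panel_spec(), cfg)
write_tsv(depth, file.path(outdir, "depth.tsv"))
kmer <- simulate_kmer_evidence(frag, parental_genome_sequences(hyb))
write_tsv(kmer, file.path(outdir, "kmer.tsv"))
hic <- simulate_hic(frag, cfg)
write_tsv(hic$contacts, file.path(outdir, "contacts.tsv"))
expr <- simulate_expression(hyb$genes, cfg)
write_tsv(expr$expression, file.path(outdir, "fpkm.tsv"))
write_tsv(expr$truth, file.path(outdir, "truth_expression.tsv"))
write_tsv(data.frame(key = names(unlist(cfg)), value = unlist(cfg)),
          file.path(outdir, "config.tsv"))

cat(sprintf(
  "Simulated %d chromosomes in %d groups -> %d contigs (%d chimeric),\n",
  nrow(hyb$chromosomes), cfg$n_homologous_groups, nrow(frag$contigs),
  sum(frag$contigs$is_chimera)))
cat(sprintf("%d planted genes, %d Hi-C contact pairs, %d homoeolog pairs.\n",
            nrow(hyb$genes), nrow(hic$contacts), length(unique(expr$expression$pair))))
cat("Tables written under", outdir, "\n")
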