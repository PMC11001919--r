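---
title: "Binning a hybrid aneuploid genome: models, thresholds and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning a hybrid aneuploid genome: models, thresholds and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`hybridbin` re-creates, as tested R code, the computational skeleton used
to resolve a modern hybrid sugarcane genome: contig quality control,
origin binning into six scaffolding groups, allele-aware gene grouping,
homoeolog expression dominance, and synonymous substitution rates. This
vignette is the package's account of the underlying models, of every
tunable that matters, and of the design decisions taken where the
procedure was genuinely open.

## The biological setting and its statistical signatures

A hybrid cultivar genome of this kind carries, per homologous group, a
majority of chromosomes from *S. officinarum* (So), a minority from
*S. spontaneum* (Ss), and some interspecific recombinants (Rec); two of
the ten groups lack intact Ss chromosomes altogether. Each chromosome is
additionally inherited from one of the two cultivar parents (ROC, YZ).
Four signals separate these origins:

1. **Parental read depth.** Short reads from each parent cover the
   contigs that parent contributed at full depth and the other parent's
   contigs only through cross-mapping.
2. **Parental-specific 21-mers.** Substitutions that differ between the
   parents create *k*-mers present in exactly one parental read set; a
   contig inherited from one parent carries that parent's specific
   *k*-mers and essentially none of the other's.
3. **Ancestral resequencing depth.** Panels of resequenced So and Ss
   individuals cover So- and Ss-derived contigs asymmetrically; a
   *t*-test over 5+5 individuals, combined with a uniform-separation
   requirement, assigns ancestry. Mapping similarity against the two
   ancestral reference genomes breaks the remaining ties.
4. **Hi-C contacts.** Intra-chromosomal contact frequency decays with
   genomic distance but dwarfs the inter-chromosomal background. On a
   Rec chromosome, So- and Ss-derived contigs are physically linked, so
   strong So–Ss contacts are the signature of recombination. Contacts
   are compared on the normalized scale
   `signal = links * 2 / (len1 + len2) / seq_depth`, and a contact at or
   above the threshold (default 0.4) flags both endpoints as Rec.

## The synthetic genome generator

All stages are exercised by `simulation_config()` and the `simulate_*`
generators, which emulate exactly these signatures with full ground
truth. Defaults were fixed once, as the study conditions:

| parameter | default | meaning |
|---|---|---|
| `n_homologous_groups` | 10 | homologous chromosome groups |
| `so_haplotypes_per_group` | 6 | So haplotypes per group |
| `ss_haplotypes_per_group` | 3 (0 in groups 5, 8) | Ss haplotypes; the zeros emulate the two groups without intact Ss chromosomes |
| `n_rec_chromosomes` | 12 | one-crossover So×Ss recombinants |
| `ancestral_divergence` | 0.037 subs/site | So–Ss divergence, matching the median synonymous rate scale |
| `parental_divergence` | 0.01 subs/site | haplotype-level divergence within a lineage |
| `chromosome_length` | 50 kb | desk-scale chromosome |
| `contig_n50` | 5 kb | gives ≈ 1000 contigs from 96 chromosomes |
| `chimera_fraction` | 0.05 | contigs misjoined from two chromosomes |
| `depth_leakage` | 0.1 | cross-mapping depth expectation; nonzero but separable, keeping the *t*-test regime realistic |
| `depth_noise_cv` | 0.1 | multiplicative lognormal depth noise |
| `hic_decay_exponent` | 1.0 | standard polymer-contact decay default |
| `hic_intra_scale` | 8 | sets adjacent-contig signals well above, and chromosome-span signals slightly above, the 0.4 threshold |
| `hic_background_rate` | 4e-7 links/bp² | inter-chromosomal background (signal ≈ 0.002 at these contig sizes) |
| `seq_depth` | 1.0 | Hi-C fold-coverage entering the normalization |
| `gene_spacing` | 10 kb | genes planted positionally, 5 per chromosome, so allele truth is positional |
| `dominance_fraction_so` / `ss` | 0.071 / 0.030 | planted homoeolog dominance shares |
| `fpkm_dispersion` | 0.15 (log2 sd) | FPKM noise; small enough that neutral pairs essentially never cross the twofold line by chance |

The 96-chromosome karyotype (60 So, 24 Ss, 12 Rec) is a scaled-down
version of the 68:31:15 chromosome split of the real cultivar, at about
1/1000 of the sequence volume so the full pipeline runs in minutes on
one CPU.

Modelling choices worth knowing:

- **Substitution-only mutation.** No indels, so coordinates remain
  comparable across lineages and the truth ledger stays exact. The
  per-branch rate is solved from the target pairwise mismatch
  (`2r(1−r) + (2/3)r²`), so the expected Hamming divergence equals the
  configured value exactly.
- **Verbatim inheritance.** Hybrid chromosomes copy their parental
  haplotype sequence exactly; parental genomes are the union of each
  parent's haplotypes. A contig from a YZ haplotype therefore has zero
  ROC-specific *k*-mers — cleaner than real read data, where sequencing
  errors blur the sets.
- **Depth is emitted on the normalized scale** (expectation 1 when the
  sample's genome contains the contig's lineage), i.e. after the
  CNV-caller-style normalization that precedes binning in practice.
  `normalize_depths()` implements per-sample median scaling for raw
  input, but median scaling is only valid when most contigs belong to
  the sample's genome — in a hybrid where a minority of contigs derive
  from one ancestor it would erase the separation, which is why the
  generator models the already-normalized quantity.
- **Poisson Hi-C counts** with mean
  `intra_scale · l1 · l2 / d^exponent` within chromosomes (distance
  floored at the half-sum of lengths) and `background_rate · l1 · l2`
  between chromosomes. Restriction-fragment structure is ignored.
- **Misjoin tracks.** Per-contig binned signal with chimeric junctions
  at `hic_track_background` (5%) of the normal level. The main config
  uses 500 bp bins (contigs are ~5 kb); the `misjoin_sim_config()`
  preset uses 600 kb contigs with 20 kb bins, the scale at which
  breakpoint localisation to ±1 bin is meaningful.
- **Expression.** Log-normal FPKM with a pair-level base, a planted
  dominance offset (uniform in 1.2–3 log2 units, safely above the
  twofold line), and one of four infection-response archetypes
  (So-up-both-tissues, Ss-up-both, So-up-leaf-only, Ss-up-leaf-only)
  that remain distinguishable after per-pair z-scaling.

## Thresholds and their exact semantics

All decision thresholds follow the strictness of their verbal
definitions, and the boundary cases are unit-tested:

- artifactual *k*-mers and contamination overlap: remove when **strictly
  more than** 40%;
- gene retention: FPKM **strictly above** 3 with coverage **strictly
  above** 80%, or support **strictly above** 80, or domain/homolog
  evidence;
- parent fold-changes: assign at **at least** 1.5× (depth) and 2×
  (*k*-mers) — the fold is read as a minimum evidence bar, so a contig
  exactly at the fold is assigned;
- allele grouping: identity ≥ 70% and coverage ≥ 60% **inclusive**;
- coordinate merging: reciprocal overlap **strictly more than** 50% of
  the shorter interval (the denominator choice is ours; the rule's
  direction was unspecified);
- dominance: **strictly more than** twofold; exactly twofold is neutral.

The Rec threshold 0.4 is a property of the signal's units (lengths in
bp, `seq_depth` as fold-coverage). It is a config value, and
`calibrate_rec_threshold()` re-derives a working threshold from the
valley of the bimodal signal histogram when the units differ.

## Numerical and procedural choices

- **Welch *t*-test** by default for the 5-vs-5 ancestry panels (the safe
  choice under unequal variances); `pooled = TRUE` restores the
  classical test. Zero-variance panels return `undetermined`, not an
  error.
- **Parent-call combination**: the two strategies run independently;
  agreement keeps the label, a single ambiguous call defers to the
  other, and a genuine conflict is conservatively `ambiguous` and
  counted. The original procedure names no combiner; this is our rule.
- **Misjoin operator**: a bin is anomalous when below
  `drop_fraction` (0.25) times the median of `flank_bins` (5) bins on
  each side; runs of anomalous bins merge to the minimum-signal bin and
  report its left edge. The published correction idea names no
  parameters; these are our defaults, exposed as arguments. All-zero
  tracks yield no breakpoints (no contrast), and tracks shorter than
  the window warn and return empty. Detection reports breakpoints but
  does not auto-split, keeping the truth ledger auditable.
- **Synteny chaining**: greedy longest-chain-first extraction of
  strictly monotone (both orientations) anchor chains with order-index
  gaps ≤ `max_gap` on both axes; `min_anchors = 5`, `max_gap = 25` are
  stand-ins for default collinearity-tool parameters. The chain DP is
  verified against an exhaustive path enumeration on small instances.
- **Best-hit ties** break by higher identity, then lexicographic target
  id, making anchoring deterministic.
- **Coordinate-merge conflicts** (a gene pulled toward two groups) go to
  the group with the higher mean member identity, and are logged.
- **Fold-change clustering**: log10 infection/control ratios with a
  0.01 pseudocount, z-scaled within each gene pair **across the
  lineage × tissue feature columns jointly**. Z-scaling only two values
  degenerates to ±0.707 regardless of magnitude, so single-tissue
  clustering is not meaningful; with two tissues the four response
  archetypes stay separable. Ward (`ward.D2`) hierarchical clustering
  with `k = 4` is a declared stand-in — the reference analysis shows
  four clusters but names no algorithm. Zero-variance profiles are
  flagged degenerate rather than clustered. The expression floor
  (0.1 FPKM) and pseudocount are exposed as arguments; the source
  analysis is silent on zero handling.
- **Nei–Gojobori**: site counts per NG86 (mutants to stop codons count
  as non-synonymous), pathway averaging with equal weights over minimal
  mutational paths, paths through stop codons excluded (with a
  non-synonymous-stop fallback when every path is blocked — standard
  NG86 practice). Site counts are averaged over the two sequences;
  `pS ≥ 3/4` or `S = 0` invalidates the Jukes–Cantor correction and is
  reported as an invalid result, not an exception.
  `simulate_cds_pair()` parameterises divergence as substitution
  *events* per site — the quantity a JC-corrected estimator recovers
  without bias — and rejects stop-creating proposals (synonymous
  changes are never rejected, so Ks is unaffected).

## What the verification battery shows — and what it does not

`run_demo()` executes every stage on the default configuration and then
re-measures: binning recovery and Rec precision/recall against the truth
ledger (over non-chimeric contigs; QC-flagged misjoins are excluded from
Rec detection first, mirroring the correct-then-bin order), misjoin
recall/precision at the 20 kb-bin scale (noise-free and noisy),
Formula exactness on random tuples, threshold boundaries, allele-group
reconstruction (ARI, clean and with 2-percentage-point similarity
noise), synteny chaining against exhaustive search, NG86 counts against
brute-force enumeration, Ks recovery at the 0.037 divergence scale
(40 pairs × 2500 codons), and dominance-fraction recovery over 10,000
pairs. Problem sizes were chosen so the whole battery runs in a few
minutes on one CPU.

Passing these gates demonstrates internal correctness: the rules do what
their definitions say, and under the generator's assumptions the
pipeline recovers the planted truth. It does **not** demonstrate
performance on real assemblies, where depth is confounded by repeats and
copy-number variation, *k*-mer sets are blurred by sequencing error,
Hi-C signal depends on restriction sites and mappability, gene models
are imperfect, and alignments produce soft boundaries rather than the
generator's crisp identities. The synthetic noise levels (cv 0.1,
leakage 0.1, 2-point identity jitter) are plausible but optimistic;
real data will sit closer to the decision boundaries.

## Known limitations

- No indels, structural variants (beyond the modelled crossovers and
  chimeras), or read-level simulation (FASTQ, error models).
- Scaffolding itself (haplotype phasing, ordering/orientation, manual
  curation) is out of scope; the pipeline ends at the six pre-assigned
  groups plus QC verdicts.
- Rec flagging is contact-level: contigs are flagged, chromosomes are
  not reconstructed.
- The Hi-C model ignores restriction-fragment boundaries and
  mappability.
- The allele pipeline consumes tabular alignment evidence; it does not
  run an aligner, and the simulated evidence's distractor structure
  (homoeolog at ~89% identity vs true anchor at ~98%) sets the
  difficulty of the reconstruction task.
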