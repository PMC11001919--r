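# Contig quality control: Hi-C misjoin breakpoint detection on binned
# signal tracks, artifactual k-mer filtering, contamination-overlap
# filtering, and gene-model retention rules.

#' Detect misjoin breakpoints from a binned Hi-C signal track
#'
#' A bin is anomalous when its signal falls below `drop_fraction` times the
#' median of the `flank_bins` bins on each side; runs of adjacent anomalous
#' bins are merged and reported at the left edge of the minimum-signal bin.
#' Coordinates are 0-based bp offsets at bin boundaries.
#'
#' @param signal numeric vector of per-bin intra-contig Hi-C signal,
#'   ordered along the contig.
#' @param bin_size bin width in bp.
#' @param drop_fraction anomaly threshold relative to the flanking medians.
#' @param flank_bins bins on each side used for the local medians.
#' @return numeric vector of breakpoint offsets (possibly empty). Tracks
#'   shorter than `2 * flank_bins + 1` bins give an empty result with a
#'   warning.
#' @export
detect_misjoins <- function(signal, bin_size, drop_fraction = 0.25,
                            flank_bins = 5L) {
  stopifnot(is.numeric(signal), bin_size > 0, drop_fraction > 0, flank_bins >= 1L)
  if (any(signal < 0)) stop("signals must be >= 0", call. = FALSE)
  nb <- length(signal)
  if (nb < 2L * flank_bins + 1L) {
    warning("track shorter than the detection window; no breakpoints reported")
    return(numeric(0))
  }
  anomalous <- rep(FALSE, nb)
  for (b in (flank_bins + 1L):(nb - flank_bins)) {
    left <- stats::median(signal[(b - flank_bins):(b - 1L)])
    right <- stats::median(signal[(b + 1L):(b + flank_bins)])
    anomalous[b] <- signal[b] < drop_fraction * left &&
      signal[b] < drop_fraction * right
  }
  if (!any(anomalous)) return(numeric(0))
  runs <- rle(anomalous)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  out <- numeric(0)
  for (j in which(runs$values)) {
    bins <- starts[j]:ends[j]
    bmin <- bins[which.min(signal[bins])]
    out <- c(out, (bmin - 1L) * bin_size)
  }
  out
}

#' Filter contigs dominated by artifactual k-mers
#'
#' A contig is removed when strictly more than `threshold` of its distinct
#' k-mers are absent from the sequencing reads.
#'
#' @param total distinct k-mers on the contig (vectorised).
#' @param absent k-mers absent from the read set.
#' @param threshold removal threshold (strict inequality).
#' @return character vector: `"keep"`, `"remove"`, or `"undetermined"`
#'   (when `total` is 0).
#' @export
filter_artifactual <- function(total, absent, threshold = 0.40) {
  stopifnot(length(total) == length(absent), all(absent <= total, na.rm = TRUE))
  ifelse(total <= 0, "undetermined",
         ifelse(absent / total > threshold, "remove", "keep"))
}

#' Filter contigs overlapping contaminant references
#'
#' A contig is removed when strictly more than `threshold` of its length is
#' covered by alignments to contaminant sequences.
#'
#' @param fraction covered fraction in `[0, 1]` (vectorised).
#' @param threshold removal threshold (strict inequality).
#' @return character vector of `"keep"` / `"remove"`.
#' @export
filter_contamination <- function(fraction, threshold = 0.40) {
  stopifnot(all(fraction >= 0 & fraction <= 1, na.rm = TRUE))
  ifelse(fraction > threshold, "remove", "keep")
}

#' Gene-model retention rules
#'
#' A gene model is retained when it satisfies at least one of: (1) a Pfam
#' domain or a plant UniProt homolog; (2) FPKM strictly above 3 and
#' RNA-seq paired-read coverage strictly above 80%; (3) ab initio
#' (Augustus) support strictly above 80.
#'
#' @param has_pfam_domain,has_uniprot_homolog logical (vectorised).
#' @param fpkm expression level (FPKM).
#' @param read_coverage percent of the model covered by RNA-seq pairs.
#' @param augustus_support ab initio support score, 0-100.
#' @return character vector of `"retain"` / `"discard"`.
#' @export
filter_gene_models <- function(has_pfam_domain, has_uniprot_homolog, fpkm,
                               read_coverage, augustus_support) {
  stopifnot(all(fpkm >= 0, na.rm = TRUE),
            all(read_coverage >= 0 & read_coverage <= 100, na.rm = TRUE))
  keep <- (has_pfam_domain | has_uniprot_homolog) |
    (fpkm > 3 & read_coverage > 80) |
    (augustus_support > 80)
  ifelse(keep, "retain", "discard")
}
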