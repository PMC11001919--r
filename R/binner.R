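# Origin binning: assign each contig to a parent (ROC/YZ) by read depth
# and parental-specific k-mers, to an ancestry (SO/SS) by depth t-tests
# with a reference-similarity fallback, detect recombinant contigs from
# normalized Hi-C signals, and build the six scaffolding groups.

#' Normalize a raw read-depth table
#'
#' Divides each sample's depths by that sample's genome-wide median over
#' contigs, so every per-sample median becomes 1. Intended for raw depth
#' input; the operation is idempotent.
#'
#' @param depths long data frame with columns `contig`, `sample`, `depth`
#'   (raw depths, >= 0).
#' @return the same data frame with `depth` normalized.
#' @export
normalize_depths <- function(depths) {
  stopifnot(all(c("contig", "sample", "depth") %in% names(depths)),
            all(depths$depth >= 0))
  med <- tapply(depths$depth, depths$sample, stats::median)
  if (any(med == 0))
    stop("sample(s) with zero median depth: ",
         paste(names(med)[med == 0], collapse = ", "), call. = FALSE)
  depths$depth <- as.numeric(depths$depth / med[depths$sample])
  depths
}

#' Assign a contig's parent from depth fold-change
#'
#' ROC when the ROC depth is at least `fold_cut` times the YZ depth
#' (and conversely); otherwise ambiguous. Vectorised.
#'
#' @param depth_roc,depth_yz normalized depths (>= 0).
#' @param fold_cut minimum fold-change (default 1.5).
#' @return character vector: `"ROC"`, `"YZ"`, or `"ambiguous"`.
#' @export
assign_parent_by_depth <- function(depth_roc, depth_yz, fold_cut = 1.5) {
  stopifnot(all(depth_roc >= 0), all(depth_yz >= 0))
  ifelse(depth_roc > 0 & depth_roc >= fold_cut * depth_yz, "ROC",
  ifelse(depth_yz > 0 & depth_yz >= fold_cut * depth_roc, "YZ", "ambiguous"))
}

#' Assign a contig's parent from parental-specific k-mer counts
#'
#' ROC when the ROC-specific count is at least `fold_cut` times the
#' YZ-specific count and positive (and conversely); otherwise ambiguous.
#'
#' @param roc_specific,yz_specific parental-specific k-mer counts.
#' @param fold_cut minimum fold-change (default 2).
#' @return character vector: `"ROC"`, `"YZ"`, or `"ambiguous"`.
#' @export
assign_parent_by_kmer <- function(roc_specific, yz_specific, fold_cut = 2.0) {
  stopifnot(all(roc_specific >= 0), all(yz_specific >= 0))
  ifelse(roc_specific > 0 & roc_specific >= fold_cut * yz_specific, "ROC",
  ifelse(yz_specific > 0 & yz_specific >= fold_cut * roc_specific, "YZ",
         "ambiguous"))
}

#' Combine the depth-based and k-mer-based parent calls
#'
#' Agreement keeps the label; a single ambiguous call defers to the other;
#' a conflict is conservatively ambiguous (conflicts are reported via an
#' attribute).
#'
#' @param depth_call,kmer_call character vectors of parent calls.
#' @return character vector of combined calls; attribute `"n_conflicts"`
#'   carries the conflict count.
#' @export
combine_parent_calls <- function(depth_call, kmer_call) {
  stopifnot(length(depth_call) == length(kmer_call))
  out <- ifelse(depth_call == kmer_call, depth_call,
         ifelse(depth_call == "ambiguous", kmer_call,
         ifelse(kmer_call == "ambiguous", depth_call, "ambiguous")))
  conflicts <- depth_call != kmer_call &
    depth_call != "ambiguous" & kmer_call != "ambiguous"
  attr(out, "n_conflicts") <- sum(conflicts)
  out
}

#' Assign a contig's ancestry from a resequencing depth panel
#'
#' SO when a two-sample t-test rejects equality at `alpha` AND the SO-panel
#' depths are uniformly higher (minimum exceeds the SS maximum); SS
#' symmetrically; otherwise undetermined. Welch's unequal-variance test is
#' the default; `pooled = TRUE` restores the pooled-variance test.
#'
#' @param so_depths,ss_depths normalized depths of the SO and SS panels
#'   (>= 2 samples each).
#' @param alpha significance cutoff (default 0.05).
#' @param pooled use the pooled-variance t-test.
#' @return list with `call` (`"SO"`, `"SS"`, or `"undetermined"`) and
#'   `p_value`.
#' @export
assign_ancestry_by_depth <- function(so_depths, ss_depths, alpha = 0.05,
                                     pooled = FALSE) {
  stopifnot(length(so_depths) >= 2L, length(ss_depths) >= 2L)
  p <- tryCatch(
    stats::t.test(so_depths, ss_depths, var.equal = pooled)$p.value,
    error = function(e) NA_real_)
  call <- "undetermined"
  if (!is.na(p) && p < alpha) {
    if (min(so_depths) > max(ss_depths)) call <- "SO"
    else if (min(ss_depths) > max(so_depths)) call <- "SS"
  }
  list(call = call, p_value = p)
}

#' Assign ancestry from mapping similarity against the ancestral references
#'
#' SS when both mapping quality and identity against the S. spontaneum
#' reference strictly exceed those against the S. officinarum reference
#' (SO symmetrically); ties or mixed evidence are undetermined. Applied to
#' contigs the depth t-test left undetermined.
#'
#' @param mq_so,id_so mapping quality and identity vs the SO reference.
#' @param mq_ss,id_ss mapping quality and identity vs the SS reference.
#' @return character vector: `"SO"`, `"SS"`, or `"undetermined"`.
#' @export
assign_ancestry_by_similarity <- function(mq_so, id_so, mq_ss, id_ss) {
  miss <- is.na(mq_so) | is.na(id_so) | is.na(mq_ss) | is.na(id_ss)
  out <- ifelse(mq_ss > mq_so & id_ss > id_so, "SS",
         ifelse(mq_so > mq_ss & id_so > id_ss, "SO", "undetermined"))
  out[miss] <- "undetermined"
  out
}

#' Normalized Hi-C signal between two contigs
#'
#' `signal = links * 2 / (len1 + len2) * 1 / seq_depth`, exactly.
#'
#' @param links Hi-C link count between the contigs (>= 0).
#' @param len1,len2 contig lengths (> 0).
#' @param seq_depth Hi-C fold-coverage (> 0).
#' @return numeric signal (vectorised).
#' @export
hic_signal <- function(links, len1, len2, seq_depth) {
  if (any(len1 <= 0) || any(len2 <= 0))
    stop("contig lengths must be positive", call. = FALSE)
  if (any(seq_depth <= 0))
    stop("seq_depth must be positive", call. = FALSE)
  links * 2 / (len1 + len2) * 1 / seq_depth
}

#' Detect recombinant contigs from SO-SS Hi-C contacts
#'
#' A contig is flagged as recombinant when it participates in at least one
#' contact with a contig of the other ancestry whose normalized signal
#' reaches `threshold`; both endpoints of such a contact are flagged.
#'
#' @param contacts data frame: contigA, contigB, links.
#' @param ancestry named character vector of ancestry calls
#'   (`"SO"`/`"SS"`/other) indexed by contig id.
#' @param lengths named numeric vector of contig lengths.
#' @param seq_depth Hi-C fold-coverage for the signal normalization.
#' @param threshold minimum normalized signal (default 0.4).
#' @return list with `rec_contigs` (character vector) and `supporting`
#'   (the qualifying contacts with their signals).
#' @export
detect_recombinants <- function(contacts, ancestry, lengths, seq_depth,
                                threshold = 0.4) {
  unknown <- setdiff(c(contacts$contigA, contacts$contigB), names(lengths))
  if (length(unknown) > 0L)
    stop("contacts reference unknown contigs: ",
         paste(utils::head(unknown, 5L), collapse = ", "), call. = FALSE)
  aA <- ancestry[contacts$contigA]
  aB <- ancestry[contacts$contigB]
  cross <- (aA == "SO" & aB == "SS") | (aA == "SS" & aB == "SO")
  cross[is.na(cross)] <- FALSE
  sub <- contacts[cross, , drop = FALSE]
  if (nrow(sub) == 0L)
    return(list(rec_contigs = character(0),
                supporting = cbind(sub, signal = numeric(0))))
  sig <- hic_signal(sub$links, lengths[sub$contigA], lengths[sub$contigB],
                    seq_depth)
  hit <- sig >= threshold
  supporting <- cbind(sub[hit, , drop = FALSE], signal = sig[hit])
  rownames(supporting) <- NULL
  list(rec_contigs = sort(unique(c(supporting$contigA, supporting$contigB))),
       supporting = supporting)
}

#' Calibrate the recombination signal threshold from its bimodal histogram
#'
#' Locates the density valley between the background mode and the
#' same-chromosome mode of log10 normalized signals; returns the signal at
#' the valley. Falls back to `fallback` when no interior valley exists.
#'
#' @param signals positive normalized Hi-C signals.
#' @param fallback threshold returned for degenerate histograms.
#' @return numeric threshold.
#' @export
calibrate_rec_threshold <- function(signals, fallback = 0.4) {
  signals <- signals[signals > 0]
  if (length(signals) < 10L) return(fallback)
  d <- stats::density(log10(signals))
  y <- d$y
  # interior local minima between the two highest local maxima
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  if (length(is_max) < 2L) return(fallback)
  top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
  seg <- top2[1L]:top2[2L]
  10^d$x[seg[which.min(y[seg])]]
}

#' Build the six pre-assignment groups
#'
#' Combines parent and ancestry calls into the groups ROC-So, ROC-Ss,
#' ROC-Rec, YZ-So, YZ-Ss, YZ-Rec; the Rec flag overrides the SO/SS
#' ancestry. Contigs with an ambiguous parent or undetermined ancestry go
#' to the `unassigned` sink with a reason.
#'
#' @param parent named character vector of parent calls.
#' @param ancestry named character vector of ancestry calls (same contigs).
#' @param rec_contigs character vector of recombinant-flagged contigs.
#' @return data frame: contig, parent, ancestry, rec, group, reason.
#' @export
build_groups <- function(parent, ancestry, rec_contigs = character(0)) {
  stopifnot(identical(names(parent), names(ancestry)))
  contig <- names(parent)
  rec <- contig %in% rec_contigs
  anc_eff <- ifelse(rec, "Rec", ancestry)
  ok_parent <- parent %in% c("ROC", "YZ")
  ok_anc <- anc_eff %in% c("SO", "SS", "Rec")
  label <- ifelse(ok_parent & ok_anc,
                  paste0(parent, "-", c(SO = "So", SS = "Ss", Rec = "Rec")[anc_eff]),
                  "unassigned")
  reason <- ifelse(label != "unassigned", "",
            ifelse(!ok_parent & !ok_anc, "ambiguous parent and ancestry",
            ifelse(!ok_parent, "ambiguous parent", "undetermined ancestry")))
  data.frame(contig = contig, parent = unname(parent),
             ancestry = unname(ancestry), rec = rec, group = unname(label),
             reason = unname(reason), stringsAsFactors = FALSE, row.names = NULL)
}
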