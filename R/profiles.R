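#' Meta-profile configuration
#'
#' @param span bp covered on each side of the anchor (default 10000).
#' @param tss_bin bin width in bp for TSS-relative peak-distribution
#'   profiles (default 100).
#' @param mark_bin bin width in bp for mark-frequency meta-profiles
#'   (default 1000, the "per 1 kb span" convention).
#' @param anchor_point how a peak is reduced to a point: \code{"midpoint"}
#'   (floor of the interval midpoint, default) or \code{"summit"} (uses the
#'   narrowPeak summit offset when present, midpoint otherwise).
#' @return list of class \code{profile_config}.
#' @export
profile_config <- function(span = 10000, tss_bin = 100, mark_bin = 1000,
                           anchor_point = c("midpoint", "summit")) {
  anchor_point <- match.arg(anchor_point)
  stopifnot(span > 0, tss_bin > 0, mark_bin > 0)
  if (span %% tss_bin != 0 || span %% mark_bin != 0)
    stop("span must be divisible by both bin widths")
  structure(list(span = span, tss_bin = tss_bin, mark_bin = mark_bin,
                 anchor_point = anchor_point), class = "profile_config")
}

# Bin event points relative to anchor points.  Offsets are event - anchor,
# negated for mirrored ("-" strand) anchors, and an event contributes to the
# bin containing its offset within [-span, span).  Events are matched to
# anchors by chromosome via findOverlaps on anchor windows; one event can
# contribute to several nearby anchors.
binned_offset_counts <- function(anchor_chrom, anchor_pos, anchor_mirror,
                                 event_chrom, event_pos, span, bin) {
  nbins <- as.integer(2 * span / bin)
  if (!length(anchor_pos) || !length(event_pos))
    return(integer(nbins))
  # window one base wider on each side than needed so that mirrored offsets
  # at the boundary survive until the explicit filter below
  win <- GenomicRanges::GRanges(
    anchor_chrom,
    IRanges::IRanges(pmax(1, anchor_pos - span), anchor_pos + span + 1))
  ev <- GenomicRanges::GRanges(event_chrom,
                               IRanges::IRanges(event_pos + 1, event_pos + 1))
  hs <- harmonize_seqlevels(win, ev)
  h <- GenomicRanges::findOverlaps(hs$a, hs$b, ignore.strand = TRUE)
  qi <- S4Vectors::queryHits(h)
  off <- event_pos[S4Vectors::subjectHits(h)] - anchor_pos[qi]
  off <- ifelse(anchor_mirror[qi], -off, off)
  keep <- off >= -span & off < span
  idx <- floor((off[keep] + span) / bin) + 1
  tabulate(idx, nbins)
}

new_profile <- function(counts, span, bin, n_anchors, normalization) {
  nbins <- length(counts)
  offsets <- -span + (seq_len(nbins) - 0.5) * bin
  if (normalization == "max100") {
    if (max(counts) > 0) {
      values <- 100 * counts / max(counts)
      normalized <- TRUE
    } else {
      values <- rep(0, nbins)
      normalized <- FALSE
    }
  } else {
    values <- if (n_anchors > 0) 100 * counts / n_anchors else rep(0, nbins)
    normalized <- n_anchors > 0
  }
  structure(list(offsets = offsets, values = values, counts = counts,
                 n_anchors = n_anchors, normalization = normalization,
                 span = span, bin = bin, normalized = normalized),
            class = "normalized_profile")
}

#' @export
print.normalized_profile <- function(x, ...) {
  cat(sprintf("normalized_profile: %d bins of %d bp over +/-%d bp, %s, %d anchors\n",
              length(x$values), x$bin, x$span, x$normalization, x$n_anchors))
  if (!x$normalized) cat("  (no events in span: normalization skipped)\n")
  invisible(x)
}

#' @export
as.data.frame.normalized_profile <- function(x, ...) {
  data.frame(offset = x$offsets, value = x$values, n_anchors = x$n_anchors)
}

#' @export
plot.normalized_profile <- function(x, ...) {
  graphics::plot(x$offsets, x$values, type = "l",
                 xlab = "offset from anchor (bp)",
                 ylab = sprintf("signal (%s)", x$normalization), ...)
}

#' TSS-relative peak distribution, scaled to a maximum of 100
#'
#' For every gene, peak anchor points (midpoints by default) falling within
#' \code{span} bp of the TSS are binned at strand-aware offsets (negative =
#' upstream; offsets are mirrored for "-" genes). Bin counts are summed over
#' genes and scaled so the maximal bin equals 100. If no peak falls in any
#' window the profile is all zero and flagged unnormalized.
#'
#' @param p GRanges of peaks.
#' @param ann gene_annotation.
#' @param cfg \code{\link{profile_config}}; uses \code{tss_bin}.
#' @return \code{normalized_profile} (normalization \code{"max100"}).
#' @export
tss_peak_distribution <- function(p, ann, cfg = profile_config()) {
  stopifnot(inherits(ann, "gene_annotation"), nrow(ann) > 0)
  counts <- binned_offset_counts(ann$chrom, ann$tss, ann$strand == "-",
                                 as.character(GenomicRanges::seqnames(p)),
                                 anchor_positions(p, cfg$anchor_point),
                                 cfg$span, cfg$tss_bin)
  prof <- new_profile(counts, cfg$span, cfg$tss_bin, nrow(ann), "max100")
  if (!prof$normalized)
    message("tss_peak_distribution: no peaks within span of any TSS")
  prof
}

#' Mark frequency per 100 anchor peaks
#'
#' For each anchor peak's anchor point, every mark-peak anchor point within
#' \code{span} bp contributes to the bin of its offset; bin values are
#' 100 x contributions / number of anchors, i.e. mark events per 100 anchor
#' peaks per bin. Strand is ignored (peak-to-peak geometry).
#'
#' @param anchors GRanges anchor peaks (must be non-empty).
#' @param marks GRanges of histone-mark peaks.
#' @param cfg \code{\link{profile_config}}; uses \code{mark_bin}.
#' @return \code{normalized_profile} (normalization \code{"per100"}).
#' @export
mark_meta_profile <- function(anchors, marks, cfg = profile_config()) {
  stopifnot(length(anchors) > 0)
  apos <- anchor_positions(anchors, cfg$anchor_point)
  counts <- binned_offset_counts(
    as.character(GenomicRanges::seqnames(anchors)), apos,
    rep(FALSE, length(anchors)),
    as.character(GenomicRanges::seqnames(marks)),
    anchor_positions(marks, cfg$anchor_point),
    cfg$span, cfg$mark_bin)
  new_profile(counts, cfg$span, cfg$mark_bin, length(anchors), "per100")
}

#' Mark frequency per 100 TSS, genome wide
#'
#' As \code{\link{mark_meta_profile}} with strand-aware TSS points as
#' anchors (offsets mirrored for "-" genes).
#'
#' @param marks GRanges of histone-mark peaks.
#' @param ann gene_annotation.
#' @param cfg \code{\link{profile_config}}.
#' @return \code{normalized_profile} (normalization \code{"per100"}).
#' @export
tss_meta_profile <- function(marks, ann, cfg = profile_config()) {
  stopifnot(inherits(ann, "gene_annotation"), nrow(ann) > 0)
  counts <- binned_offset_counts(ann$chrom, ann$tss, ann$strand == "-",
                                 as.character(GenomicRanges::seqnames(marks)),
                                 anchor_positions(marks, cfg$anchor_point),
                                 cfg$span, cfg$mark_bin)
  new_profile(counts, cfg$span, cfg$mark_bin, nrow(ann), "per100")
}
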