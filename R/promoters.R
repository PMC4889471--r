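#' Promoter windows around every TSS
#'
#' One strand-aware window TSS +/- \code{flank} per gene, clipped at 0 and
#' at the chromosome end when lengths are known. The 3 kb default follows
#' the observation that factor binding concentrates within +/-3 kb of the
#' TSS.
#'
#' @param ann gene_annotation.
#' @param flank half-width in bp (> 0), default 3000.
#' @param genome optional named chromosome-length vector for clipping.
#' @return GRanges named by gene_id, in annotation order.
#' @export
promoter_windows <- function(ann, flank = 3000, genome = NULL) {
  stopifnot(inherits(ann, "gene_annotation"), flank > 0)
  gr <- window_around(ann$chrom, ann$tss, ann$strand, flank, flank,
                      genome = genome)
  names(gr) <- ann$gene_id
  S4Vectors::metadata(gr)$flank <- flank
  gr
}

# which members of q lie within gap d of any member of s (same chromosome;
# overlap counts as distance 0)
near_any <- function(q, s, d) {
  out <- logical(length(q))
  if (!length(q) || !length(s)) return(out)
  hs <- harmonize_seqlevels(q, s)
  h <- GenomicRanges::distanceToNearest(hs$a, hs$b, ignore.strand = TRUE)
  out[S4Vectors::queryHits(h)] <- mcols(h)$distance <= d
  out
}

#' Classify H3K27me3-marked promoters by factor occupancy
#'
#' A promoter carries the mark (\code{has_k27}) iff at least one H3K27me3
#' peak overlaps its window. Marked promoters are then classified by a
#' fixed precedence over their overlapping H3K27me3 peaks:
#' \code{IK_HDAC1} if any such peak lies within \code{d} bp (edge-to-edge
#' gap, overlap = 0) of a factor--HDAC1 overlapped peak; else
#' \code{HDAC1_ONLY} if within \code{d} of any HDAC1 peak; else
#' \code{IK_ONLY} if within \code{d} of any factor peak; else
#' \code{NEITHER}. The classes are mutually exclusive and exhaustive over
#' marked promoters.
#'
#' @param promoters GRanges from \code{\link{promoter_windows}} (named by
#'   gene_id).
#' @param k27 GRanges of H3K27me3 peaks.
#' @param ik,hdac GRanges of the factor and HDAC1 peak sets.
#' @param ik_hdac_overlapped GRanges of overlapped peaks, typically
#'   \code{overlapped_peaks(ik, hdac)}.
#' @param d association distance in bp, inclusive (default 1000: "within
#'   1 kb").
#' @return data.frame of class \code{promoter_class_table} with columns
#'   gene_id, has_k27, occupancy_class (NA where has_k27 is FALSE);
#'   parameters kept in attributes.
#' @export
classify_promoters <- function(promoters, k27, ik, hdac, ik_hdac_overlapped,
                               d = 1000) {
  stopifnot(d >= 0)
  cls <- k27_peak_classes(k27, ik, hdac, ik_hdac_overlapped, d)
  hs <- harmonize_seqlevels(promoters, k27)
  ph <- GenomicRanges::findOverlaps(hs$a, hs$b, ignore.strand = TRUE)
  has <- logical(length(promoters))
  has[unique(S4Vectors::queryHits(ph))] <- TRUE
  agg <- function(flag) {
    v <- logical(length(promoters))
    if (length(ph)) {
      t <- tapply(flag[S4Vectors::subjectHits(ph)],
                  S4Vectors::queryHits(ph), any)
      v[as.integer(names(t))] <- as.logical(t)
    }
    v
  }
  a_ovl <- agg(cls$near_overlapped)
  a_hdac <- agg(cls$near_hdac)
  a_ik <- agg(cls$near_ik)
  klass <- ifelse(!has, NA_character_,
           ifelse(a_ovl, "IK_HDAC1",
           ifelse(a_hdac, "HDAC1_ONLY",
           ifelse(a_ik, "IK_ONLY", "NEITHER"))))
  out <- data.frame(gene_id = names(promoters), has_k27 = has,
                    occupancy_class = klass, stringsAsFactors = FALSE)
  attr(out, "assoc_distance") <- d
  attr(out, "promoter_flank") <- S4Vectors::metadata(promoters)$flank
  class(out) <- c("promoter_class_table", "data.frame")
  out
}

# per-H3K27me3-peak proximity flags and precedence class
k27_peak_classes <- function(k27, ik, hdac, ik_hdac_overlapped, d) {
  near_ovl <- near_any(k27, ik_hdac_overlapped, d)
  near_hdac <- near_any(k27, hdac, d)
  near_ik <- near_any(k27, ik, d)
  klass <- ifelse(near_ovl, "IK_HDAC1",
           ifelse(near_hdac, "HDAC1_ONLY",
           ifelse(near_ik, "IK_ONLY", "NEITHER")))
  list(near_overlapped = near_ovl, near_hdac = near_hdac, near_ik = near_ik,
       class = klass)
}

promoter_class_levels <- c("IK_HDAC1", "HDAC1_ONLY", "IK_ONLY", "NEITHER")

#' Class fractions over H3K27me3-marked promoters
#'
#' Headline percentages of the promoter classification:
#' \code{pct_hdac_bound} is the share of marked promoters with any HDAC1
#' association (classes IK_HDAC1 + HDAC1_ONLY), \code{pct_ik_hdac} the
#' share in class IK_HDAC1, and analogously for the remaining classes.
#'
#' @param t \code{promoter_class_table}.
#' @return list of class \code{promoter_class_fractions} with the four
#'   percentages (full precision) and the underlying counts.
#' @export
class_fractions <- function(t) {
  stopifnot(inherits(t, "promoter_class_table"))
  k <- t$occupancy_class[t$has_k27]
  n <- length(k)
  if (n == 0) stop("no H3K27me3-marked promoters: fractions undefined")
  counts <- vapply(promoter_class_levels, function(l) sum(k == l), integer(1))
  structure(list(
    n_k27_promoters = n,
    counts = counts,
    pct_hdac_bound = 100 * (counts[["IK_HDAC1"]] + counts[["HDAC1_ONLY"]]) / n,
    pct_ik_hdac = 100 * counts[["IK_HDAC1"]] / n,
    pct_ik_only = 100 * counts[["IK_ONLY"]] / n,
    pct_neither = 100 * counts[["NEITHER"]] / n),
    class = "promoter_class_fractions")
}

#' @export
print.promoter_class_fractions <- function(x, ...) {
  cat(sprintf("%d H3K27me3-marked promoters\n", x$n_k27_promoters))
  cat(sprintf("  HDAC1-bound (IK_HDAC1 + HDAC1_ONLY): %.1f%%\n",
              x$pct_hdac_bound))
  cat(sprintf("  IK_HDAC1: %.1f%%  IK_ONLY: %.1f%%  NEITHER: %.1f%%\n",
              x$pct_ik_hdac, x$pct_ik_only, x$pct_neither))
  invisible(x)
}

#' Classify H3K27me3 peaks genome wide (peak-wise reading)
#'
#' Applies the same precedence rule per H3K27me3 peak rather than per
#' promoter, optionally restricted to peaks overlapping a region set (e.g.
#' promoter windows).
#'
#' @param k27,ik,hdac,ik_hdac_overlapped GRanges as in
#'   \code{\link{classify_promoters}}.
#' @param d association distance in bp, inclusive.
#' @param within optional GRanges; when given, only H3K27me3 peaks
#'   overlapping it are classified.
#' @return list with \code{class} (character per retained peak) and
#'   \code{counts} (named integer vector over the four classes).
#' @export
classify_k27_peaks <- function(k27, ik, hdac, ik_hdac_overlapped, d = 1000,
                               within = NULL) {
  if (!is.null(within) && length(k27)) {
    hs <- harmonize_seqlevels(k27, within)
    k27 <- k27[GenomicRanges::countOverlaps(hs$a, hs$b,
                                            ignore.strand = TRUE) > 0]
  }
  if (!length(k27)) {
    counts <- stats::setNames(integer(4), promoter_class_levels)
    return(list(class = character(), counts = counts))
  }
  cls <- k27_peak_classes(k27, ik, hdac, ik_hdac_overlapped, d)$class
  counts <- vapply(promoter_class_levels, function(l) sum(cls == l),
                   integer(1))
  list(class = cls, counts = counts)
}
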