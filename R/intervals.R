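#' Construct a peak set
#'
#' Builds a sorted \link[GenomicRanges]{GRanges} from 0-based half-open
#' coordinates. This is the container every pipeline stage consumes: peaks,
#' promoter windows and merged regions are all peak sets. Strand defaults to
#' \code{"."} (unstranded, stored as \code{"*"}); peak-to-peak operations
#' ignore strand throughout.
#'
#' @param chrom character vector of chromosome names (taken verbatim, no
#'   \code{"chr"} aliasing).
#' @param start,end integer vectors, 0-based half-open: \code{start} is the
#'   first base covered, \code{end} the first base not covered. Must satisfy
#'   \code{0 <= start < end}.
#' @param strand optional vector in \code{c("+", "-", ".")}.
#' @param name,score optional per-peak label and numeric score.
#' @param label optional set-level label (factor or mark name, e.g.
#'   \code{"IK"}); stored in \code{metadata()}.
#' @param genome optional named vector of chromosome lengths; when supplied,
#'   intervals are checked against it and it is attached as
#'   \code{seqlengths}.
#' @return A \code{GRanges}, sorted by (chrom, start, end).
#' @examples
#' p <- peak_set("chr1", c(100, 400), c(200, 900), label = "IK")
#' @export
peak_set <- function(chrom, start, end, strand = NULL, name = NULL,
                     score = NULL, label = NULL, genome = NULL) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end)))
    stop("non-numeric start/end coordinates")
  if (any(start < 0)) stop("negative start coordinate")
  if (any(start >= end)) stop("invalid interval: start >= end")
  if (is.null(strand)) strand <- rep(".", length(chrom))
  strand <- as.character(strand)
  if (!all(strand %in% c("+", "-", ".", "*")))
    stop("strand must be one of '+', '-', '.'")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end),
                               strand = strand)
  if (!is.null(name)) mcols(gr)$name <- as.character(name)
  if (!is.null(score)) mcols(gr)$score <- as.numeric(score)
  if (!is.null(genome)) {
    bad <- setdiff(unique(as.character(chrom)), names(genome))
    if (length(bad))
      stop("chromosomes absent from genome: ", paste(bad, collapse = ", "))
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome[GenomeInfoDb::seqlevels(gr)])
  } else {
    # deterministic chromosome order regardless of first appearance
    GenomeInfoDb::seqlevels(gr) <- sort(GenomeInfoDb::seqlevels(gr))
  }
  gr <- sort_peaks(gr)
  if (!is.null(label)) S4Vectors::metadata(gr)$label <- label
  gr
}

#' @rdname peak_set
#' @param x a GRanges.
#' @export
peak_label <- function(x) S4Vectors::metadata(x)$label

# put two GRanges on the union of their seqlevels so cross-set operations
# on disjoint chromosomes stay silent
harmonize_seqlevels <- function(a, b) {
  lv <- union(GenomeInfoDb::seqlevels(a), GenomeInfoDb::seqlevels(b))
  GenomeInfoDb::seqlevels(a) <- lv
  GenomeInfoDb::seqlevels(b) <- lv
  list(a = a, b = b)
}

# canonical (chrom, start, end) order, strand ignored
sort_peaks <- function(gr) {
  o <- order(as.integer(GenomicRanges::seqnames(gr)),
             GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr[o]
}

#' Convert a peak set back to 0-based half-open coordinates
#'
#' @param x a GRanges.
#' @return data.frame with columns chrom, start, end, strand plus any
#'   metadata columns.
#' @export
as_bed_frame <- function(x) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(x)),
                   start = GenomicRanges::start(x) - 1,
                   end = GenomicRanges::end(x),
                   strand = sub("\\*", ".", as.character(GenomicRanges::strand(x))),
                   stringsAsFactors = FALSE)
  m <- as.data.frame(mcols(x))
  if (ncol(m)) df <- cbind(df, m)
  rownames(df) <- NULL
  df
}

#' Pairwise at-least-1-bp overlap test
#'
#' True iff the two intervals lie on the same chromosome and their half-open
#' spans share at least one base. Strand is ignored; abutting intervals
#' (\code{end(a) == start(b)}) share zero bases and do not overlap.
#' Vectorized over pairs (shorter argument recycled if length 1).
#'
#' @param a,b GRanges of equal length (or either of length 1).
#' @return logical vector.
#' @export
peaks_overlap <- function(a, b) {
  if (length(a) == 1 && length(b) > 1) a <- rep(a, length(b))
  if (length(b) == 1 && length(a) > 1) b <- rep(b, length(a))
  stopifnot(length(a) == length(b))
  same <- as.character(GenomicRanges::seqnames(a)) ==
    as.character(GenomicRanges::seqnames(b))
  inter <- pmin(GenomicRanges::end(a), GenomicRanges::end(b)) -
    pmax(GenomicRanges::start(a), GenomicRanges::start(b)) + 1
  same & inter >= 1
}

#' Merge a peak set into distinct regions
#'
#' Collapses overlapping and abutting intervals into the minimal set of
#' non-overlapping, non-abutting regions covering the same bases (the
#' operation that makes "distinct binding sites" well defined). Per-peak
#' names of merged members are concatenated with ",".
#'
#' @param p a GRanges.
#' @return merged GRanges; metadata label is preserved.
#' @export
merge_peaks <- function(p) {
  r <- GenomicRanges::reduce(p, ignore.strand = TRUE, with.revmap = TRUE)
  if (!is.null(mcols(p)$name)) {
    nm <- mcols(p)$name
    mcols(r)$name <- vapply(mcols(r)$revmap, function(i)
      paste(nm[i], collapse = ","), character(1))
  }
  mcols(r)$revmap <- NULL
  S4Vectors::metadata(r)$label <- peak_label(p)
  sort_peaks(r)
}

#' Members of each set overlapped by the other
#'
#' Returns the members of \code{A} that overlap (>= 1 bp) at least one
#' member of \code{B}, and symmetrically the members of \code{B} overlapped
#' by \code{A}. Each member appears once no matter how many partners it has.
#'
#' @param A,B GRanges.
#' @return list with elements \code{a_hit}, \code{b_hit} (GRanges) and
#'   \code{a_idx}, \code{b_idx} (integer indices into A and B).
#' @export
intersect_peak_sets <- function(A, B) {
  hs <- harmonize_seqlevels(A, B)
  h <- GenomicRanges::findOverlaps(hs$a, hs$b, ignore.strand = TRUE)
  ai <- sort(unique(S4Vectors::queryHits(h)))
  bi <- sort(unique(S4Vectors::subjectHits(h)))
  list(a_hit = A[ai], b_hit = B[bi], a_idx = ai, b_idx = bi)
}

#' Edge-to-edge gap between two intervals
#'
#' 0 when the intervals overlap (or abut), otherwise the number of bases
#' strictly between them; \code{NA} ("not comparable") across chromosomes.
#' This is the distance used by the within-1-kb promoter association rule.
#'
#' @param a,b GRanges (recycled like \code{peaks_overlap}).
#' @return integer vector, NA across chromosomes.
#' @export
gap_distance <- function(a, b) {
  if (length(a) == 1 && length(b) > 1) a <- rep(a, length(b))
  if (length(b) == 1 && length(a) > 1) b <- rep(b, length(a))
  hs <- harmonize_seqlevels(a, b)
  GenomicRanges::distance(hs$a, hs$b, ignore.strand = TRUE)
}

#' Strand-aware window around a point
#'
#' Builds \code{[pos - flank_up, pos + flank_down)} for "+" anchors and the
#' mirror image for "-" anchors, clipped at 0 and (when chromosome lengths
#' are known) at the chromosome end. This is how promoter windows and
#' profile spans are constructed around a TSS.
#'
#' @param chrom,pos,strand vectors describing anchor points (0-based pos).
#' @param flank_up,flank_down non-negative flank sizes in bp (upstream /
#'   downstream in the anchor's own orientation).
#' @param genome optional named vector of chromosome lengths for clipping.
#' @return GRanges of windows, in input order (not re-sorted), strand kept.
#' @export
window_around <- function(chrom, pos, strand, flank_up, flank_down,
                          genome = NULL) {
  stopifnot(all(pos >= 0), flank_up >= 0, flank_down >= 0)
  strand <- as.character(strand)
  minus <- strand == "-"
  left <- ifelse(minus, flank_down, flank_up)
  right <- ifelse(minus, flank_up, flank_down)
  s0 <- pmax(0, pos - left)
  e0 <- pos + right
  if (!is.null(genome)) e0 <- pmin(e0, unname(genome[as.character(chrom)]))
  if (any(e0 <= s0)) stop("degenerate window (zero width after clipping)")
  strand[strand == "."] <- "*"
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s0 + 1, e0),
                               strand = strand)
  if (!is.null(genome)) {
    GenomeInfoDb::seqlevels(gr) <- names(genome)
    GenomeInfoDb::seqlengths(gr) <- unname(genome[GenomeInfoDb::seqlevels(gr)])
  }
  gr
}

# integer midpoint floor((start0 + end0) / 2), in 0-based coordinates
peak_midpoints <- function(gr) {
  floor((GenomicRanges::start(gr) - 1 + GenomicRanges::end(gr)) / 2)
}

# anchor position per peak: midpoint, or summit (start0 + summit offset)
# when requested and recorded
anchor_positions <- function(gr, anchor_point = c("midpoint", "summit")) {
  anchor_point <- match.arg(anchor_point)
  if (anchor_point == "summit" && !is.null(mcols(gr)$summit)) {
    s <- mcols(gr)$summit
    pos <- GenomicRanges::start(gr) - 1 + ifelse(is.na(s) | s < 0, 0, s)
    mid <- peak_midpoints(gr)
    return(ifelse(is.na(s) | s < 0, mid, pos))
  }
  peak_midpoints(gr)
}
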