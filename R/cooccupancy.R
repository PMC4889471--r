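#' Target-assignment configuration
#'
#' Controls how peaks are assigned to genes. \code{window-overlap} (the
#' default) assigns a peak to every gene whose assignment window -- the gene
#' span extended \code{upstream_flank} bp upstream of the TSS -- overlaps the
#' peak by at least 1 bp; multi-assignment is allowed. \code{nearest-tss}
#' assigns each peak to the single nearest TSS by peak-midpoint distance
#' when that distance is at most \code{max_distance}, ties broken by the
#' lexicographically lower gene_id.
#'
#' @param upstream_flank bp added upstream of the TSS in window mode
#'   (default 5000).
#' @param mode \code{"window-overlap"} or \code{"nearest-tss"}.
#' @param max_distance maximum midpoint-to-TSS distance in nearest-tss mode
#'   (default 10000 bp).
#' @return list of class \code{assignment_config}.
#' @export
assignment_config <- function(upstream_flank = 5000,
                              mode = c("window-overlap", "nearest-tss"),
                              max_distance = 10000) {
  stopifnot(upstream_flank >= 0, max_distance >= 0)
  structure(list(upstream_flank = upstream_flank, mode = match.arg(mode),
                 max_distance = max_distance),
            class = "assignment_config")
}

# assignment window per gene: gene span extended upstream of the TSS
assignment_windows <- function(ann, upstream_flank) {
  s0 <- ifelse(ann$strand == "+", pmax(0, ann$gene_start - upstream_flank),
               ann$gene_start)
  e0 <- ifelse(ann$strand == "+", ann$gene_end,
               ann$gene_end + upstream_flank)
  gr <- GenomicRanges::GRanges(ann$chrom, IRanges::IRanges(s0 + 1, e0),
                               strand = ann$strand)
  names(gr) <- ann$gene_id
  gr
}

#' Assign peaks to target genes
#'
#' @param p GRanges of peaks.
#' @param ann gene_annotation (see \code{\link{read_tss_table}}).
#' @param cfg \code{\link{assignment_config}}.
#' @return named list, gene_id -> sorted integer indices into \code{p};
#'   genes with no assigned peak are omitted.
#' @export
assign_targets <- function(p, ann, cfg = assignment_config()) {
  stopifnot(inherits(ann, "gene_annotation"), nrow(ann) > 0)
  if (!length(p)) return(stats::setNames(list(), character()))
  if (cfg$mode == "window-overlap") {
    win <- assignment_windows(ann, cfg$upstream_flank)
    hs <- harmonize_seqlevels(win, p)
    h <- GenomicRanges::findOverlaps(hs$a, hs$b, ignore.strand = TRUE)
    gid <- ann$gene_id[S4Vectors::queryHits(h)]
    m <- split(S4Vectors::subjectHits(h), gid)
    m <- lapply(m, function(i) sort(unique(i)))
    return(m[order(names(m))])
  }
  # nearest-tss: per chromosome, locate the nearest TSS to each midpoint
  mid <- peak_midpoints(p)
  chr <- as.character(GenomicRanges::seqnames(p))
  gene_of <- rep(NA_character_, length(p))
  for (cc in unique(chr)) {
    on_c <- which(ann$chrom == cc)
    if (!length(on_c)) next
    pk <- which(chr == cc)
    tpos <- ann$tss[on_c]
    gids <- ann$gene_id[on_c]
    upos <- sort(unique(tpos))
    # lexicographically smallest gene_id at each distinct TSS position
    minid <- vapply(split(gids, tpos), min, character(1))
    minid <- minid[as.character(upos)]
    fi <- findInterval(mid[pk], upos)
    li <- pmax(fi, 1L)
    ri <- pmin(fi + 1L, length(upos))
    dl <- ifelse(fi >= 1, abs(mid[pk] - upos[li]), Inf)
    dr <- ifelse(fi + 1L <= length(upos), abs(upos[ri] - mid[pk]), Inf)
    dmin <- pmin(dl, dr)
    choice <- ifelse(dl < dr, minid[li],
                     ifelse(dr < dl, minid[ri], pmin(minid[li], minid[ri])))
    ok <- dmin <= cfg$max_distance
    gene_of[pk[ok]] <- choice[ok]
  }
  keep <- !is.na(gene_of)
  m <- split(which(keep), gene_of[keep])
  m <- lapply(m, function(i) sort(unique(i)))
  m[order(names(m))]
}

#' Two-factor co-occupancy statistics
#'
#' The core genome-wide co-occupancy summary between two factors: peak
#' counts, counts and fractions of peaks of each factor overlapped (>= 1 bp)
#' by the other, target-gene counts under the assignment rule, and the
#' number of genes targeted jointly -- genes with at least one assigned,
#' overlapped peak of \emph{each} factor.
#'
#' @param A,B GRanges peak sets (e.g. a transcription factor and an HDAC).
#' @param ann gene_annotation.
#' @param cfg \code{\link{assignment_config}}.
#' @return list of class \code{cooccupancy_stats} with fields n_a, n_b,
#'   n_a_hit, n_b_hit, frac_a_hit, frac_b_hit, genes_a, genes_b,
#'   genes_joint, plus labels and the resolved config.
#' @export
compute_cooccupancy <- function(A, B, ann, cfg = assignment_config()) {
  hit <- intersect_peak_sets(A, B)
  n_a <- length(A); n_b <- length(B)
  n_a_hit <- length(hit$a_idx); n_b_hit <- length(hit$b_idx)
  map_a <- assign_targets(A, ann, cfg)
  map_b <- assign_targets(B, ann, cfg)
  aflag <- logical(n_a); aflag[hit$a_idx] <- TRUE
  bflag <- logical(n_b); bflag[hit$b_idx] <- TRUE
  ga_ov <- names(map_a)[vapply(map_a, function(i) any(aflag[i]), logical(1))]
  gb_ov <- names(map_b)[vapply(map_b, function(i) any(bflag[i]), logical(1))]
  structure(list(
    label_a = peak_label(A), label_b = peak_label(B),
    n_a = n_a, n_b = n_b, n_a_hit = n_a_hit, n_b_hit = n_b_hit,
    frac_a_hit = if (n_a) n_a_hit / n_a else 0,
    frac_b_hit = if (n_b) n_b_hit / n_b else 0,
    genes_a = length(map_a), genes_b = length(map_b),
    genes_joint = length(intersect(ga_ov, gb_ov)),
    config = cfg), class = "cooccupancy_stats")
}

#' @export
print.cooccupancy_stats <- function(x, ...) {
  la <- if (is.null(x$label_a)) "A" else x$label_a
  lb <- if (is.null(x$label_b)) "B" else x$label_b
  cat(sprintf("Co-occupancy %s vs %s\n", la, lb))
  cat(sprintf("  %s peaks: %d (%d overlapped, %s%% / full %.4f%%)\n", la,
              x$n_a, x$n_a_hit, format(round_half_up(100 * x$frac_a_hit)),
              100 * x$frac_a_hit))
  cat(sprintf("  %s peaks: %d (%d overlapped, %s%% / full %.4f%%)\n", lb,
              x$n_b, x$n_b_hit,
              format(round_half_up(100 * x$frac_b_hit, 1)),
              100 * x$frac_b_hit))
  cat(sprintf("  target genes: %s %d, %s %d, joint %d\n", la, x$genes_a,
              lb, x$genes_b, x$genes_joint))
  cat(sprintf("  assignment: %s (upstream_flank=%d, max_distance=%d)\n",
              x$config$mode, x$config$upstream_flank, x$config$max_distance))
  invisible(x)
}

#' Overlapped peaks of one factor, represented from the A side
#'
#' Returns the members of \code{A} that share at least 1 bp with any member
#' of \code{B} -- e.g. the Ikaros peak of each Ikaros--HDAC1 overlapped
#' pair, the anchor set used for overlapped-peak meta-profiles and the
#' promoter occupancy classifier. Set \code{representation =
#' "intersection"} to get the shared spans instead.
#'
#' @param A,B GRanges.
#' @param representation \code{"a-side"} (default) or \code{"intersection"}.
#' @return GRanges.
#' @export
overlapped_peaks <- function(A, B, representation = c("a-side", "intersection")) {
  representation <- match.arg(representation)
  if (representation == "a-side") {
    out <- intersect_peak_sets(A, B)$a_hit
  } else {
    hs <- harmonize_seqlevels(granges(A), granges(B))
    out <- GenomicRanges::intersect(hs$a, hs$b, ignore.strand = TRUE)
  }
  lab <- paste0(if (is.null(peak_label(A))) "A" else peak_label(A), "-",
                if (is.null(peak_label(B))) "B" else peak_label(B))
  S4Vectors::metadata(out)$label <- lab
  out
}
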