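# Brute-force oracles, deliberately independent of the package's
# GenomicRanges-based implementation: plain data.frames of 0-based
# half-open intervals, all-pairs loops and per-base coverage vectors.

rand_intervals <- function(n, chroms = c("cA", "cB"), max_pos = 5000,
                           max_len = 300) {
  start <- sample.int(max_pos, n, replace = TRUE) - 1
  len <- sample.int(max_len, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + len, stringsAsFactors = FALSE)
}

df2gr <- function(df, ...) peak_set(df$chrom, df$start, df$end, ...)

# half-open 1 bp overlap between interval rows i of a and j of b
ovl_pair <- function(a, i, b, j) {
  a$chrom[i] == b$chrom[j] &&
    min(a$end[i], b$end[j]) - max(a$start[i], b$start[j]) >= 1
}

# indices of rows of A overlapping >= 1 row of B (all-pairs)
brute_hits <- function(A, B) {
  hit <- logical(nrow(A))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      if (ovl_pair(A, i, B, j)) { hit[i] <- TRUE; break }
  which(hit)
}

# union of intervals via a per-base coverage vector, per chromosome
brute_merge <- function(df) {
  out <- NULL
  for (cc in sort(unique(df$chrom))) {
    d <- df[df$chrom == cc, ]
    cov <- logical(max(d$end) + 1)
    for (i in seq_len(nrow(d)))
      cov[(d$start[i] + 1):d$end[i]] <- TRUE
    r <- rle(cov)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    out <- rbind(out, data.frame(chrom = cc, start = starts[keep],
                                 end = ends[keep],
                                 stringsAsFactors = FALSE))
  }
  out[order(out$chrom, out$start), ]
}

# edge-to-edge gap between two 0-based half-open intervals; NA across chroms
brute_gap <- function(c1, s1, e1, c2, s2, e2) {
  if (c1 != c2) return(NA_integer_)
  if (min(e1, e2) - max(s1, s2) >= 1) return(0L)
  as.integer(max(s1, s2) - min(e1, e2))
}

# all-pairs window-overlap assignment: genes as data.frame
# (gene_id, chrom, strand, start, end)
brute_assign_window <- function(peaks, genes, flank) {
  m <- list()
  for (g in seq_len(nrow(genes))) {
    ws <- if (genes$strand[g] == "+") max(0, genes$start[g] - flank)
          else genes$start[g]
    we <- if (genes$strand[g] == "+") genes$end[g]
          else genes$end[g] + flank
    hits <- integer()
    for (i in seq_len(nrow(peaks)))
      if (peaks$chrom[i] == genes$chrom[g] &&
          min(peaks$end[i], we) - max(peaks$start[i], ws) >= 1)
        hits <- c(hits, i)
    if (length(hits)) m[[genes$gene_id[g]]] <- hits
  }
  m[order(names(m))]
}

brute_assign_nearest <- function(peaks, genes, maxd) {
  tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1)
  m <- list()
  for (i in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    on_c <- which(genes$chrom == peaks$chrom[i])
    if (!length(on_c)) next
    d <- abs(tss[on_c] - mid)
    dmin <- min(d)
    if (dmin > maxd) next
    gid <- min(genes$gene_id[on_c][d == dmin])
    m[[gid]] <- c(m[[gid]], i)
  }
  m <- lapply(m, function(i) sort(unique(i)))
  m[order(names(m))]
}

# double-loop offset histogram: anchors/events as (chrom, pos, mirror)
brute_profile_counts <- function(anc, ev, span, bin) {
  nb <- 2 * span / bin
  counts <- integer(nb)
  for (i in seq_len(nrow(anc)))
    for (j in seq_len(nrow(ev))) {
      if (anc$chrom[i] != ev$chrom[j]) next
      o <- ev$pos[j] - anc$pos[i]
      if (isTRUE(anc$mirror[i])) o <- -o
      if (o >= -span && o < span) {
        b <- floor((o + span) / bin) + 1
        counts[b] <- counts[b] + 1
      }
    }
  counts
}

# all-pairs precedence classification of k27 rows against peak tables
brute_k27_classes <- function(k27, ik, hdac, ovl, d) {
  near_set <- function(i, s) {
    if (!nrow(s)) return(FALSE)
    for (j in seq_len(nrow(s))) {
      g <- brute_gap(k27$chrom[i], k27$start[i], k27$end[i],
                     s$chrom[j], s$start[j], s$end[j])
      if (!is.na(g) && g <= d) return(TRUE)
    }
    FALSE
  }
  vapply(seq_len(nrow(k27)), function(i) {
    if (near_set(i, ovl)) "IK_HDAC1"
    else if (near_set(i, hdac)) "HDAC1_ONLY"
    else if (near_set(i, ik)) "IK_ONLY"
    else "NEITHER"
  }, character(1))
}

# tiny annotation builder (0-based half-open spans)
make_ann <- function(gene_id, chrom, strand, start, end) {
  path <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
               paste(gene_id, chrom, strand, start, end, sep = "\t")),
             path)
  read_tss_table(path)
}

target_map_as_names <- function(m, p) {
  lapply(m, function(i) sort(i))
}
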