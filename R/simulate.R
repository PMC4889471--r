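# Geometry constants of the constructive layout.  Everything is placed
# relative to a gene grid with one desert band per inter-gene gap, so that
# no peak can be assigned ambiguously and every planted count is recovered
# exactly by the analysis stages regardless of assignment mode.
.gen <- list(
  gene_jitter = 2000,   # genes move +/- this much around their grid point
  group_step = 1500,    # spacing between pair groups within one gene
  w_hdac_pair = 600, w_ik_pair = 400, pair_overlap = 100,
  w_k27 = 800, w_k4 = 500, w_k9me3 = 500, w_k9ac = 400,
  mark_offset = 300, k4_offset = 800,
  n_k9_genes = 2000     # factor-only genes that also get K9me3/K9ac marks
)

#' Scenario configuration for the synthetic-data generator
#'
#' Describes a toy genome, a gene layout and the planted peak/target/class
#' structure that \code{\link{build_scenario}} realizes constructively.
#' Planted counts must be mutually consistent
#' (\code{\link{validate_config}}).
#'
#' @param genome named vector of chromosome lengths (default five 40 Mb
#'   chromosomes).
#' @param n_ik,n_hdac total peak counts for the factor and HDAC1.
#' @param ik_overlapped,hdac_overlapped planted overlapped peak counts on
#'   each side (realized as one-to-one pairs plus
#'   \code{ik_overlapped - hdac_overlapped} HDAC1 peaks overlapped by two
#'   factor peaks).
#' @param genes_ik,genes_hdac,genes_joint planted target-gene counts.
#' @param k27_promoters named integer vector of H3K27me3 promoter class
#'   counts (IK_HDAC1, HDAC1_ONLY, IK_ONLY, NEITHER).
#' @param peak_width min/mode/max (bp) of the triangular width distribution
#'   used for unconstrained peaks.
#' @param gene_length,gene_spacing,margin layout parameters in bp.
#' @param upstream_flank,promoter_flank,assoc_distance,max_distance the
#'   analysis parameters the layout must keep unambiguous.
#' @param seed integer RNG seed; same config + seed gives byte-identical
#'   output files.
#' @return list of class \code{scenario_config}.
#' @export
scenario_config <- function(genome = stats::setNames(rep(40e6, 5),
                                                     paste0("chr", 1:5)),
                            n_ik = 200, n_hdac = 160,
                            ik_overlapped = 40, hdac_overlapped = 36,
                            genes_ik = 120, genes_hdac = 100,
                            genes_joint = 30,
                            k27_promoters = c(IK_HDAC1 = 10,
                                              HDAC1_ONLY = 30,
                                              IK_ONLY = 10, NEITHER = 10),
                            peak_width = c(min = 200, mode = 400, max = 1500),
                            gene_length = 2000, gene_spacing = 30000,
                            margin = 100000,
                            upstream_flank = 5000, promoter_flank = 3000,
                            assoc_distance = 1000, max_distance = 10000,
                            seed = 1) {
  structure(as.list(environment()), class = "scenario_config")
}

#' The fixed full-scale replica scenario
#'
#' A \code{\link{scenario_config}} that plants the full published
#' co-occupancy structure of the Nalm6 Ikaros/HDAC1 study system:
#' 12464 factor and 9971 HDAC1 peaks; 1496 / 1456 overlapped peaks on the
#' two sides (the smallest integers whose fractions round half-up to the
#' printed 12 and 14.6 percent, realized as 1416 one-to-one pairs plus 40
#' HDAC1 peaks each overlapped by two factor peaks); 6722 / 6182 / 934
#' target genes; and 2000 H3K27me3-marked promoters split 420 / 1280 /
#' 100 / 200 across the occupancy classes (420/2000 = 21 percent IK_HDAC1,
#' 1700/2000 = 85 percent HDAC1-bound; the 100/200 split of the remaining
#' promoters is a free construction choice). Chromosomes are 80 Mb so the
#' 12370 genes fit at unambiguous 30 kb spacing.
#'
#' @param seed integer RNG seed.
#' @return \code{scenario_config}.
#' @export
nalm6_replica_plan <- function(seed = 1) {
  scenario_config(
    genome = stats::setNames(rep(80e6, 5), paste0("chr", 1:5)),
    n_ik = 12464, n_hdac = 9971,
    ik_overlapped = 1496, hdac_overlapped = 1456,
    genes_ik = 6722, genes_hdac = 6182, genes_joint = 934,
    k27_promoters = c(IK_HDAC1 = 420, HDAC1_ONLY = 1280,
                      IK_ONLY = 100, NEITHER = 200),
    seed = seed)
}

scenario_totals <- function(cfg) {
  k <- cfg$k27_promoters
  n_ik_only <- cfg$genes_ik - cfg$genes_joint
  n_hdac_only <- cfg$genes_hdac - cfg$genes_joint
  list(n_ik_only = n_ik_only, n_hdac_only = n_hdac_only,
       n_neither = unname(k[["NEITHER"]]),
       total_genes = cfg$genes_joint + n_ik_only + n_hdac_only +
         k[["NEITHER"]],
       lone_ik = n_ik_only, lone_hdac = n_hdac_only,
       desert_ik = cfg$n_ik - cfg$ik_overlapped - n_ik_only,
       desert_hdac = cfg$n_hdac - cfg$hdac_overlapped - n_hdac_only,
       n_pairs_double = cfg$ik_overlapped - cfg$hdac_overlapped,
       n_extra_groups = cfg$hdac_overlapped - cfg$genes_joint)
}

#' Check a scenario configuration for internal consistency
#'
#' Lists every violated consistency rule; an empty report means the
#' scenario is buildable.
#'
#' @param cfg \code{scenario_config}.
#' @return character vector of violations (empty when valid).
#' @export
validate_config <- function(cfg) {
  v <- character()
  add <- function(cond, msg) if (cond) v <<- c(v, msg)
  t <- scenario_totals(cfg)
  k <- cfg$k27_promoters
  add(!all(c("IK_HDAC1", "HDAC1_ONLY", "IK_ONLY", "NEITHER") %in% names(k)),
      "k27_promoters must name all four occupancy classes")
  add(cfg$ik_overlapped > cfg$n_ik,
      "overlapped factor peaks exceed total factor peaks")
  add(cfg$hdac_overlapped > cfg$n_hdac,
      "overlapped HDAC1 peaks exceed total HDAC1 peaks")
  add(cfg$ik_overlapped < cfg$hdac_overlapped,
      "factor-side overlapped count below HDAC1-side count (pairs infeasible)")
  add(cfg$ik_overlapped > 2 * cfg$hdac_overlapped,
      "factor-side overlapped count exceeds 2x HDAC1-side count")
  add(cfg$genes_joint > min(cfg$genes_ik, cfg$genes_hdac),
      "joint genes exceed a factor's gene count")
  add(cfg$genes_joint > 0 && cfg$hdac_overlapped < cfg$genes_joint,
      "fewer overlapped pairs than joint genes")
  add(cfg$genes_joint == 0 && cfg$hdac_overlapped > 0,
      "overlapped pairs planted but no joint genes to host them")
  add(cfg$genes_joint > 0 && cfg$hdac_overlapped > 2 * cfg$genes_joint,
      "more than two pair groups per joint gene")
  add(t$n_pairs_double > cfg$genes_joint,
      "more double-overlap groups than joint genes")
  if ("IK_HDAC1" %in% names(k)) {
    add(k[["IK_HDAC1"]] > cfg$genes_joint,
        "IK_HDAC1 promoter count exceeds joint genes")
    add(k[["HDAC1_ONLY"]] > t$n_hdac_only,
        "HDAC1_ONLY promoter count exceeds HDAC1-only genes")
    add(k[["IK_ONLY"]] > t$n_ik_only,
        "IK_ONLY promoter count exceeds factor-only genes")
  }
  add(t$desert_ik < 0, "fewer factor peaks than planted targets require")
  add(t$desert_hdac < 0, "fewer HDAC1 peaks than planted targets require")
  add(t$desert_ik + t$desert_hdac > t$total_genes,
      "more desert peaks than inter-gene desert bands")
  capv <- floor((cfg$genome - 2 * cfg$margin) / cfg$gene_spacing) + 1
  cap <- sum(capv[capv > 0])
  add(cap < t$total_genes, "genome too small for gene count at this spacing")
  add(cfg$gene_spacing <= 2 * (cfg$upstream_flank + cfg$promoter_flank),
      "gene spacing must exceed twice (upstream_flank + promoter_flank)")
  wmax <- cfg$peak_width[["max"]]
  add(cfg$gene_spacing < 2 * .gen$gene_jitter + cfg$gene_length +
        2 * cfg$max_distance + wmax + 2,
      "gene spacing too small for unassignable desert bands")
  add(cfg$max_distance <= cfg$upstream_flank + wmax,
      "max_distance must exceed upstream_flank + max peak width")
  add(cfg$promoter_flank <= .gen$w_k27 / 2 + cfg$assoc_distance,
      "promoter flank too small for planted H3K27me3 placement")
  v
}

# triangular(min, mode, max) widths, rounded to integer bp
rtri <- function(n, lo, mode, hi) {
  u <- stats::runif(n)
  fc <- (mode - lo) / (hi - lo)
  w <- ifelse(u < fc, lo + sqrt(u * (hi - lo) * (mode - lo)),
              hi - sqrt((1 - u) * (hi - lo) * (hi - mode)))
  round(w)
}

#' Build a synthetic scenario file bundle
#'
#' Realizes a \code{\link{scenario_config}} as a directory of plain-text
#' files: \code{genome.tsv}, \code{genes.tsv}, one BED file per factor or
#' mark (\code{ik.bed}, \code{hdac1.bed}, \code{h3k27me3.bed},
#' \code{h3k9me3.bed}, \code{h3k9ac.bed}, \code{h3k4me3.bed}), a serial
#' qChIP table \code{qchip.csv} for the four signature genes, and a
#' \code{provenance.json} restating every planted value. Placement is
#' constructive: genes sit on a jittered grid whose spacing makes every
#' peak-to-gene assignment unambiguous, planted target genes receive their
#' peaks inside their assignment windows, overlapped pairs share at least
#' 1 bp by construction, and surplus peaks go to inter-gene desert bands
#' out of reach of every window and TSS. The generator shares no interval
#' arithmetic with the analysis stages, so recovery of the planted
#' statistics is a genuine cross-check.
#'
#' @param cfg \code{scenario_config}; must validate cleanly.
#' @param outdir output directory (created if needed).
#' @return invisibly, a list with \code{files} (named paths),
#'   \code{planted} (the planted statistics) and \code{config}.
#' @export
build_scenario <- function(cfg, outdir) {
  viol <- validate_config(cfg)
  if (length(viol))
    stop("infeasible scenario config:\n  ", paste(viol, collapse = "\n  "))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  set.seed(cfg$seed)
  t <- scenario_totals(cfg)
  G <- .gen
  k <- cfg$k27_promoters

  ## --- gene layout -------------------------------------------------------
  n <- t$total_genes
  category <- rep(c("joint", "ik_only", "hdac_only", "neither"),
                  c(cfg$genes_joint, t$n_ik_only, t$n_hdac_only,
                    t$n_neither))
  cap <- floor((cfg$genome - 2 * cfg$margin) / cfg$gene_spacing) + 1
  cap[cap < 0] <- 0
  chrom <- character(n); grid <- numeric(n)
  left <- n; i0 <- 0
  for (cc in names(cfg$genome)) {
    take <- min(cap[[cc]], left)
    if (take == 0) next
    idx <- i0 + seq_len(take)
    chrom[idx] <- cc
    grid[idx] <- cfg$margin + (seq_len(take) - 1) * cfg$gene_spacing
    i0 <- i0 + take; left <- left - take
    if (left == 0) break
  }
  jit <- sample(seq(-G$gene_jitter, G$gene_jitter), n, replace = TRUE)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  gstart <- grid + jit
  gend <- gstart + cfg$gene_length
  tss <- ifelse(strand == "+", gstart, gend - 1)
  sgn <- ifelse(strand == "+", 1, -1)
  gene_id <- sprintf("g%06d", seq_len(n))

  ## --- overlapped pair groups on joint genes -----------------------------
  joint <- which(category == "joint")
  n_groups <- length(joint) + t$n_extra_groups
  host <- c(joint, joint[seq_len(t$n_extra_groups)])
  step <- c(rep(0, length(joint)), rep(1, t$n_extra_groups))
  center <- tss[host] + sgn[host] * G$group_step * step
  dbl <- seq_len(t$n_pairs_double)  # first groups (distinct genes) doubled
  hw <- G$w_hdac_pair / 2
  hdac_pair <- data.frame(chrom = chrom[host], start = center - hw,
                          end = center + hw)
  ik_right <- data.frame(chrom = chrom[host],
                         start = center + hw - G$pair_overlap,
                         end = center + hw - G$pair_overlap + G$w_ik_pair)
  ik_left <- if (t$n_pairs_double > 0)
    data.frame(chrom = chrom[host][dbl],
               start = center[dbl] - hw + G$pair_overlap - G$w_ik_pair,
               end = center[dbl] - hw + G$pair_overlap)
  else NULL

  ## --- lone target peaks -------------------------------------------------
  lone <- function(idx, widths) {
    data.frame(chrom = chrom[idx],
               start = tss[idx] - floor(widths / 2),
               end = tss[idx] - floor(widths / 2) + widths)
  }
  ik_only <- which(category == "ik_only")
  hdac_only <- which(category == "hdac_only")
  pw <- cfg$peak_width
  ik_lone <- lone(ik_only, rtri(length(ik_only), pw[["min"]], pw[["mode"]],
                                pw[["max"]]))
  hdac_lone <- lone(hdac_only, rtri(length(hdac_only), pw[["min"]],
                                    pw[["mode"]], pw[["max"]]))

  ## --- desert peaks (one band per inter-gene gap, unreachable) -----------
  n_desert <- t$desert_ik + t$desert_hdac
  desert <- NULL
  if (n_desert > 0) {
    bi <- seq_len(n_desert)  # band after gene bi
    wmax <- pw[["max"]]
    m_lo <- grid[bi] + G$gene_jitter + cfg$gene_length + cfg$max_distance +
      ceiling(wmax / 2)
    m_hi <- grid[bi] + cfg$gene_spacing - G$gene_jitter -
      cfg$max_distance - 1 - ceiling(wmax / 2)
    m <- m_lo + floor(stats::runif(n_desert) * (m_hi - m_lo + 1))
    wd <- rtri(n_desert, pw[["min"]], pw[["mode"]], pw[["max"]])
    desert <- data.frame(chrom = chrom[bi], start = m - floor(wd / 2),
                         end = m - floor(wd / 2) + wd)
  }
  ik_desert <- if (t$desert_ik > 0) desert[seq_len(t$desert_ik), ] else NULL
  hdac_desert <- if (t$desert_hdac > 0)
    desert[t$desert_ik + seq_len(t$desert_hdac), ] else NULL

  ## --- H3K27me3 peaks realizing the promoter classes ---------------------
  k27_idx <- c(joint[seq_len(k[["IK_HDAC1"]])],
               hdac_only[seq_len(k[["HDAC1_ONLY"]])],
               ik_only[seq_len(k[["IK_ONLY"]])],
               which(category == "neither"))
  k27 <- lone(k27_idx, rep(G$w_k27, length(k27_idx)))

  ## --- other marks (profile structure only) ------------------------------
  centered <- function(idx, off, w) {
    ctr <- tss[idx] + sgn[idx] * off
    data.frame(chrom = chrom[idx], start = ctr - floor(w / 2),
               end = ctr - floor(w / 2) + w)
  }
  k4 <- centered(joint, G$k4_offset, G$w_k4)
  k9g <- ik_only[seq_len(min(G$n_k9_genes, length(ik_only)))]
  k9me3 <- centered(k9g, G$mark_offset, G$w_k9me3)
  k9ac <- centered(k9g, -G$mark_offset, G$w_k9ac)

  ## --- write bundle ------------------------------------------------------
  mk <- function(df, label, prefix) {
    if (is.null(df) || !nrow(df))
      return(peak_set(character(), integer(), integer(), label = label,
                      genome = cfg$genome))
    peak_set(df$chrom, df$start, df$end,
             name = sprintf("%s_%06d", prefix, seq_len(nrow(df))),
             label = label, genome = cfg$genome)
  }
  ik_all <- rbind(ik_right, ik_left, ik_lone, ik_desert)
  hdac_all <- rbind(hdac_pair, hdac_lone, hdac_desert)
  stopifnot(nrow(ik_all) == cfg$n_ik, nrow(hdac_all) == cfg$n_hdac)
  files <- c(genome = file.path(outdir, "genome.tsv"),
             genes = file.path(outdir, "genes.tsv"),
             ik = file.path(outdir, "ik.bed"),
             hdac1 = file.path(outdir, "hdac1.bed"),
             h3k27me3 = file.path(outdir, "h3k27me3.bed"),
             h3k9me3 = file.path(outdir, "h3k9me3.bed"),
             h3k9ac = file.path(outdir, "h3k9ac.bed"),
             h3k4me3 = file.path(outdir, "h3k4me3.bed"),
             qchip = file.path(outdir, "qchip.csv"),
             provenance = file.path(outdir, "provenance.json"))
  write_genome_table(cfg$genome, files[["genome"]])
  write_tsv_table(data.frame(gene_id = gene_id, gene_name = gene_id,
                             chrom = chrom, strand = strand,
                             start = format_coord(gstart),
                             end = format_coord(gend)),
                  files[["genes"]], params = list(seed = cfg$seed))
  write_bed(mk(ik_all, "IK", "IK"), files[["ik"]])
  write_bed(mk(hdac_all, "HDAC1", "HD"), files[["hdac1"]])
  write_bed(mk(k27, "H3K27me3", "K27"), files[["h3k27me3"]])
  write_bed(mk(k9me3, "H3K9me3", "K9M"), files[["h3k9me3"]])
  write_bed(mk(k9ac, "H3K9ac", "K9A"), files[["h3k9ac"]])
  write_bed(mk(k4, "H3K4me3", "K4"), files[["h3k4me3"]])
  qd <- simulate_qchip(c("CDC7", "ANAPC7", "CDC2", "ANAPC1"),
                       c(CDC7 = "IKAROS_ONLY", ANAPC7 = "IKAROS_ONLY",
                         CDC2 = "IKAROS_HDAC1", ANAPC1 = "IKAROS_HDAC1"),
                       seed = cfg$seed)
  utils::write.csv(qd, files[["qchip"]], row.names = FALSE, quote = FALSE)
  planted <- list(
    n_ik = cfg$n_ik, n_hdac = cfg$n_hdac,
    ik_overlapped = cfg$ik_overlapped,
    hdac_overlapped = cfg$hdac_overlapped,
    pct_ik_overlapped = round_half_up(100 * cfg$ik_overlapped / cfg$n_ik),
    pct_hdac_overlapped = round_half_up(100 * cfg$hdac_overlapped /
                                          cfg$n_hdac, 1),
    genes_ik = cfg$genes_ik, genes_hdac = cfg$genes_hdac,
    genes_joint = cfg$genes_joint,
    k27_promoters = as.list(cfg$k27_promoters),
    pct_hdac_bound = 100 * (k[["IK_HDAC1"]] + k[["HDAC1_ONLY"]]) / sum(k),
    pct_ik_hdac = 100 * k[["IK_HDAC1"]] / sum(k),
    note = paste("overlapped integer counts are one consistent realization",
                 "of the published rounded percentages"))
  jsonlite::write_json(list(planted = planted,
                            config = cfg[setdiff(names(cfg), "genome")],
                            genome = as.list(cfg$genome)),
                       files[["provenance"]], auto_unbox = TRUE, digits = NA)
  invisible(list(files = files, planted = planted, config = cfg))
}

#' Simulate serial qChIP series with planted repression signatures
#'
#' For each gene, five primer pairs at offsets -2000..+2000 bp around the
#' TSS, a peak-shaped baseline enrichment per target, and a treated
#' condition whose informative marks are scaled by \code{2^(+/-effect)}
#' according to the planted label (IKAROS_ONLY: H3K9me3 up, H3K9ac down,
#' factor binding up; IKAROS_HDAC1: H3K27me3 up, H3K9ac down, factor and
#' HDAC1 binding up; NONE: no change). Multiplicative log-normal noise
#' (sd in log2 units) is applied per replicate and measurement.
#'
#' @param genes character vector of gene names.
#' @param labels named character vector gene -> label (IKAROS_ONLY,
#'   IKAROS_HDAC1 or NONE), or an unnamed vector parallel to \code{genes}.
#' @param effect_log2fc planted effect size in log2 units (default 1.5).
#' @param noise_sd log2-scale noise standard deviation (default 0.2).
#' @param n_reps replicates per condition (default 3).
#' @param seed integer RNG seed.
#' @return \code{qchip_dataset} with conditions \code{"control"} and
#'   \code{"treated"}.
#' @export
simulate_qchip <- function(genes, labels, effect_log2fc = 1.5,
                           noise_sd = 0.2, n_reps = 3, seed = 1) {
  stopifnot(noise_sd >= 0, n_reps >= 1)
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(genes))
    names(labels) <- genes
  }
  bad <- setdiff(unique(labels), c("IKAROS_ONLY", "IKAROS_HDAC1", "NONE"))
  if (length(bad)) stop("unknown label: ", paste(bad, collapse = ", "))
  set.seed(seed)
  offsets <- c(-2000, -1000, 0, 1000, 2000)
  shape <- c(0.5, 0.8, 1.0, 0.8, 0.5)
  base_level <- c(H3K27me3 = 3, H3K9me3 = 2, H3K9ac = 4, H3K4me3 = 5,
                  IK = 2, HDAC1 = 2)
  dir_of <- function(label) switch(label,
    IKAROS_ONLY = c(H3K27me3 = 0, H3K9me3 = 1, H3K9ac = -1, H3K4me3 = 0,
                    IK = 1, HDAC1 = 0),
    IKAROS_HDAC1 = c(H3K27me3 = 1, H3K9me3 = 0, H3K9ac = -1, H3K4me3 = 0,
                     IK = 1, HDAC1 = 1),
    NONE = c(H3K27me3 = 0, H3K9me3 = 0, H3K9ac = 0, H3K4me3 = 0,
             IK = 0, HDAC1 = 0))
  out <- vector("list", length(genes) * length(base_level) * 2)
  z <- 0
  for (g in genes) {
    dirs <- dir_of(labels[[g]])
    for (tg in names(base_level)) {
      for (cond in c("control", "treated")) {
        mu <- base_level[[tg]] * shape
        if (cond == "treated") mu <- mu * 2^(dirs[[tg]] * effect_log2fc)
        noise <- if (noise_sd > 0)
          2^stats::rnorm(5 * n_reps, 0, noise_sd) else rep(1, 5 * n_reps)
        z <- z + 1
        out[[z]] <- data.frame(
          gene = g, target = tg, condition = cond,
          primer_index = rep(1:5, n_reps),
          primer_offset = rep(offsets, n_reps),
          enrichment = rep(mu, n_reps) * noise,
          replicate = rep(seq_len(n_reps), each = 5),
          stringsAsFactors = FALSE)
      }
    }
  }
  validate_qchip(do.call(rbind, out))
}
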