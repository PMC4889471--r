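test_that("promoter windows are TSS +/- flank, strand aware and clipped", {
  ann <- make_ann(c("g1", "g2", "g3"), "chr1", c("+", "-", "+"),
                  c(10000, 20000, 1000), c(12000, 24000, 3000))
  w <- promoter_windows(ann, 3000)
  f <- as_bed_frame(w)
  expect_equal(f$start[1], 7000)   # TSS 10000 +/- 3000
  expect_equal(f$end[1], 13000)
  expect_equal(f$start[2], 23999 - 3000)  # "-" TSS at end - 1
  expect_equal(f$start[3], 0)      # clipped at origin
  expect_length(w, 3)
  expect_identical(names(w), ann$gene_id)
})

make_class_fixture <- function() {
  # one gene per class, far apart on one chromosome
  ann <- make_ann(paste0("g", 1:5), "chr1", "+",
                  c(10000, 50000, 90000, 130000, 170000) - 0,
                  c(10000, 50000, 90000, 130000, 170000) + 2000)
  ik <- peak_set("chr1", c(10000, 90100), c(10400, 90500), label = "IK")
  hdac <- peak_set("chr1", c(10200, 50000), c(10600, 50400), label = "HDAC1")
  ovl <- overlapped_peaks(ik, hdac)          # the IK peak at g1
  k27 <- peak_set("chr1", c(9900, 49900, 89900, 129900),
                  c(10300, 50300, 90300, 130300), label = "H3K27me3")
  list(ann = ann, ik = ik, hdac = hdac, ovl = ovl, k27 = k27)
}

test_that("promoter classification applies the precedence rule", {
  fx <- make_class_fixture()
  prom <- promoter_windows(fx$ann, 3000)
  tb <- classify_promoters(prom, fx$k27, fx$ik, fx$hdac, fx$ovl, 1000)
  expect_identical(tb$occupancy_class[tb$gene_id == "g1"], "IK_HDAC1")
  expect_identical(tb$occupancy_class[tb$gene_id == "g2"], "HDAC1_ONLY")
  expect_identical(tb$occupancy_class[tb$gene_id == "g3"], "IK_ONLY")
  expect_identical(tb$occupancy_class[tb$gene_id == "g4"], "NEITHER")
  expect_false(tb$has_k27[tb$gene_id == "g5"])
  expect_true(is.na(tb$occupancy_class[tb$gene_id == "g5"]))
  # classes partition the marked promoters
  expect_equal(sum(!is.na(tb$occupancy_class)), sum(tb$has_k27))
})

test_that("the within-1-kb boundary is inclusive at exactly d", {
  ann <- make_ann("g1", "chr1", "+", 10000, 12000)
  prom <- promoter_windows(ann, 3000)
  k27 <- peak_set("chr1", 9000, 9500)
  none <- peak_set(character(), integer(), integer())
  # gap exactly 1000: within; gap 1001: outside
  hdac_in <- peak_set("chr1", 10500, 10900)
  hdac_out <- peak_set("chr1", 10501, 10901)
  tb_in <- classify_promoters(prom, k27, none, hdac_in, none, 1000)
  tb_out <- classify_promoters(prom, k27, none, hdac_out, none, 1000)
  expect_identical(tb_in$occupancy_class, "HDAC1_ONLY")
  expect_identical(tb_out$occupancy_class, "NEITHER")
})

test_that("classification is order independent and monotone in d", {
  fx <- make_class_fixture()
  prom <- promoter_windows(fx$ann, 3000)
  base <- classify_promoters(prom, fx$k27, fx$ik, fx$hdac, fx$ovl, 1000)
  # permute the peak order inside every input set
  perm <- function(p) p[sample(length(p))]
  set.seed(67)
  for (i in 1:5) {
    tb <- classify_promoters(prom, perm(fx$k27), perm(fx$ik),
                             perm(fx$hdac), perm(fx$ovl), 1000)
    expect_identical(tb$occupancy_class, base$occupancy_class)
  }
  # growing d never moves a promoter toward NEITHER
  prev <- classify_promoters(prom, fx$k27, fx$ik, fx$hdac, fx$ovl, 0)
  for (d in c(300, 1000, 5000, 50000)) {
    cur <- classify_promoters(prom, fx$k27, fx$ik, fx$hdac, fx$ovl, d)
    keep <- !is.na(prev$occupancy_class)
    expect_true(all((prev$occupancy_class[keep] != "NEITHER") <=
                      (cur$occupancy_class[keep] != "NEITHER")))
    prev <- cur
  }
})

test_that("random promoters classify identically to the all-pairs oracle", {
  set.seed(71)
  n <- 100
  tss <- sort(sample(seq(5000, 2e6, by = 15000), n))
  ann <- local({
    p <- tempfile()
    writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
                 paste(sprintf("g%03d", 1:n), "cA", "+", tss, tss + 2000,
                       sep = "\t")), p)
    read_tss_table(p)
  })
  ikdf <- rand_intervals(150, chroms = "cA", max_pos = 2e6, max_len = 600)
  hddf <- rand_intervals(150, chroms = "cA", max_pos = 2e6, max_len = 600)
  k27df <- rand_intervals(120, chroms = "cA", max_pos = 2e6, max_len = 800)
  ik <- df2gr(ikdf); hdac <- df2gr(hddf); k27 <- df2gr(k27df)
  ovl <- overlapped_peaks(ik, hdac)
  ovldf <- as_bed_frame(ovl)
  k27df_s <- as_bed_frame(k27)
  # per-peak classes against the brute-force oracle
  got <- classify_k27_peaks(k27, ik, hdac, ovl, 1000)
  want <- brute_k27_classes(k27df_s, as_bed_frame(ik), as_bed_frame(hdac),
                            ovldf, 1000)
  expect_identical(got$class, want)
  # promoter-level classes: any-k27-peak aggregation under precedence
  prom <- promoter_windows(ann, 3000)
  tb <- classify_promoters(prom, k27, ik, hdac, ovl, 1000)
  rank_of <- c(IK_HDAC1 = 1, HDAC1_ONLY = 2, IK_ONLY = 3, NEITHER = 4)
  for (g in seq_len(n)) {
    in_prom <- which(k27df_s$chrom == "cA" &
                       pmin(k27df_s$end, tss[g] + 3000) -
                         pmax(k27df_s$start, tss[g] - 3000) >= 1)
    if (!length(in_prom)) {
      expect_false(tb$has_k27[g])
    } else {
      expect_true(tb$has_k27[g])
      best <- names(rank_of)[min(rank_of[want[in_prom]])]
      expect_identical(tb$occupancy_class[g], best)
    }
  }
})

test_that("class fractions report the headline percentages", {
  tb <- data.frame(
    gene_id = sprintf("g%04d", 1:2100),
    has_k27 = c(rep(TRUE, 2000), rep(FALSE, 100)),
    occupancy_class = c(rep("IK_HDAC1", 420), rep("HDAC1_ONLY", 1280),
                        rep("IK_ONLY", 100), rep("NEITHER", 200),
                        rep(NA_character_, 100)),
    stringsAsFactors = FALSE)
  class(tb) <- c("promoter_class_table", "data.frame")
  fr <- class_fractions(tb)
  expect_equal(fr$pct_hdac_bound, 85)
  expect_equal(fr$pct_ik_hdac, 21)
  expect_equal(fr$pct_ik_only, 5)
  expect_equal(fr$pct_neither, 10)
  expect_equal(fr$pct_ik_hdac + fr$pct_ik_only + fr$pct_neither +
                 fr$pct_hdac_bound - fr$pct_ik_hdac, 100)
  # degenerate inputs
  one <- tb[1, ]; class(one) <- class(tb)
  expect_equal(class_fractions(one)$pct_ik_hdac, 100)
  none <- tb[2001:2100, ]; class(none) <- class(tb)
  expect_error(class_fractions(none), "undefined")
})

test_that("peak-wise classification counts k27 peaks, optionally in promoters", {
  fx <- make_class_fixture()
  cnt <- classify_k27_peaks(fx$k27, fx$ik, fx$hdac, fx$ovl, 1000)$counts
  expect_equal(unname(cnt), c(1L, 1L, 1L, 1L))
  # restricted to a region set covering only g1 and g2 promoters
  prom <- promoter_windows(fx$ann, 3000)[1:2]
  cnt2 <- classify_k27_peaks(fx$k27, fx$ik, fx$hdac, fx$ovl, 1000,
                             within = prom)$counts
  expect_equal(sum(cnt2), 2L)
  empty <- classify_k27_peaks(peak_set(character(), integer(), integer()),
                              fx$ik, fx$hdac, fx$ovl, 1000)
  expect_equal(sum(empty$counts), 0L)
})
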