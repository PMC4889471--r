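test_that("TSS peak distribution scales the maximal bin to 100", {
  # single peak centered on a + strand TSS -> 100 in the bin containing 0
  ann <- make_ann("g1", "chr1", "+", 5000, 9000)
  prof <- tss_peak_distribution(peak_set("chr1", 4950, 5050), ann)
  expect_equal(max(prof$values), 100)
  central <- which(prof$offsets > 0 & prof$offsets < 100)
  expect_equal(prof$values[central], 100)
  expect_equal(sum(prof$values > 0), 1)
  # raw counts [2,5,10,4] scale to [20,50,100,40]
  expect_equal(chromsig:::new_profile(c(2, 5, 10, 4), 200, 100, 1,
                                      "max100")$values,
               c(20, 50, 100, 40))
  # no peaks in any window: all zero and flagged unnormalized
  empty <- suppressMessages(
    tss_peak_distribution(peak_set("chr2", 0, 100), ann))
  expect_true(all(empty$values == 0))
  expect_false(empty$normalized)
})

test_that("mirrored minus-strand data give an identical TSS profile", {
  set.seed(43)
  L <- 100000
  npk <- 40
  tsss <- c(30000, 60000)
  ann_plus <- local({
    p <- tempfile()
    writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
                 paste(c("g1", "g2"), "chr1", "+", tsss, tsss + 2000,
                       sep = "\t")), p)
    read_tss_table(p)
  })
  st <- sample.int(L - 500, npk)
  pk <- peak_set("chr1", st, st + 200)
  prof <- tss_peak_distribution(pk, ann_plus)
  # mirror the genome: x -> L - x; genes flip to "-" with mirrored spans
  ann_minus <- local({
    p <- tempfile()
    writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
                 paste(c("g1", "g2"), "chr1", "-", L - (tsss + 2000),
                       L - tsss, sep = "\t")), p)
    read_tss_table(p)
  })
  # mirrored TSS of a "-" gene sits at L - tss - 1; shift peaks by 1 so
  # midpoints mirror exactly onto the new offsets
  pk_m <- peak_set("chr1", L - (st + 200) - 1, L - st - 1)
  prof_m <- tss_peak_distribution(pk_m, ann_minus)
  expect_equal(prof_m$counts, prof$counts)
  expect_equal(prof_m$values, prof$values)
})

test_that("per-100 meta-profile counts mark events per anchor", {
  anchors <- peak_set("chr1", c(1e4, 3e4, 5e4, 7e4) - 100,
                      c(1e4, 3e4, 5e4, 7e4) + 100)
  marks <- peak_set("chr1", 1e4 - 50, 1e4 + 50)  # centered on anchor 1
  prof <- mark_meta_profile(anchors, marks)
  central <- which(prof$offsets == 500)  # bin [0, 1000)
  expect_equal(prof$values[central], 25)  # 100 x 1/4
  expect_equal(sum(prof$values), 25)
  # empty marks: all-zero profile
  none <- mark_meta_profile(anchors, peak_set(character(), integer(),
                                              integer()))
  expect_true(all(none$values == 0))
})

test_that("per-100 profiles are invariant under dataset duplication", {
  set.seed(47)
  adf <- rand_intervals(30, chroms = "cA", max_pos = 60000, max_len = 400)
  mdf <- rand_intervals(50, chroms = "cA", max_pos = 60000, max_len = 300)
  p1 <- mark_meta_profile(df2gr(adf), df2gr(mdf))
  # duplicate the whole dataset onto a second chromosome, each anchor copy
  # keeping its local mark structure: per-anchor frequencies unchanged
  dup <- function(df) rbind(df, transform(df, chrom = "cB"))
  p2 <- mark_meta_profile(df2gr(dup(adf)), df2gr(dup(mdf)))
  expect_equal(p2$counts, 2L * p1$counts)
  expect_equal(p2$n_anchors, 2L * p1$n_anchors)
  expect_equal(p2$values, p1$values)
})

test_that("meta-profiles equal the double-loop oracle", {
  set.seed(53)
  adf <- rand_intervals(50, chroms = c("cA", "cB"), max_pos = 50000,
                        max_len = 500)
  mdf <- rand_intervals(50, chroms = c("cA", "cB"), max_pos = 50000,
                        max_len = 500)
  prof <- mark_meta_profile(df2gr(adf), df2gr(mdf))
  adf_s <- adf[order(adf$chrom, adf$start, adf$end), ]
  mdf_s <- mdf[order(mdf$chrom, mdf$start, mdf$end), ]
  anc <- data.frame(chrom = adf_s$chrom,
                    pos = floor((adf_s$start + adf_s$end) / 2),
                    mirror = FALSE)
  ev <- data.frame(chrom = mdf_s$chrom,
                   pos = floor((mdf_s$start + mdf_s$end) / 2))
  expect_equal(prof$counts, brute_profile_counts(anc, ev, 10000, 1000))
  expect_equal(prof$values, 100 * prof$counts / nrow(adf))
})

test_that("TSS meta-profile handles strand and matches the oracle", {
  set.seed(59)
  ng <- 30
  gstart <- sort(sample.int(900000, ng))
  genes <- data.frame(gene_id = sprintf("g%02d", 1:ng), chrom = "cA",
                      strand = sample(c("+", "-"), ng, TRUE),
                      start = gstart, end = gstart + 1000,
                      stringsAsFactors = FALSE)
  ann <- local({
    p <- tempfile()
    writeLines(c("gene_id\tchrom\tstrand\tstart\tend",
                 paste(genes$gene_id, genes$chrom, genes$strand,
                       genes$start, genes$end, sep = "\t")), p)
    read_tss_table(p)
  })
  mdf <- rand_intervals(60, chroms = "cA", max_pos = 900000, max_len = 400)
  prof <- tss_meta_profile(df2gr(mdf), ann)
  mdf_s <- mdf[order(mdf$chrom, mdf$start, mdf$end), ]
  anc <- data.frame(chrom = ann$chrom, pos = ann$tss,
                    mirror = ann$strand == "-")
  ev <- data.frame(chrom = mdf_s$chrom,
                   pos = floor((mdf_s$start + mdf_s$end) / 2))
  expect_equal(prof$counts, brute_profile_counts(anc, ev, 10000, 1000))
  # single gene, single mark at the TSS -> 100 in the central bin
  ann1 <- make_ann("g1", "chr1", "+", 50000, 52000)
  p1 <- tss_meta_profile(peak_set("chr1", 49900, 50100), ann1)
  expect_equal(p1$values[which(p1$offsets == 500)], 100)
})

test_that("profiles are invariant under renaming and translation", {
  set.seed(61)
  adf <- rand_intervals(25, chroms = "cA", max_pos = 40000, max_len = 400)
  mdf <- rand_intervals(40, chroms = "cA", max_pos = 40000, max_len = 400)
  p1 <- mark_meta_profile(df2gr(adf), df2gr(mdf))
  shift <- 12345
  adf2 <- transform(adf, chrom = "weird_name", start = start + shift,
                    end = end + shift)
  mdf2 <- transform(mdf, chrom = "weird_name", start = start + shift,
                    end = end + shift)
  p2 <- mark_meta_profile(df2gr(adf2), df2gr(mdf2))
  expect_equal(p2$values, p1$values)
})

test_that("summit anchoring uses the narrowPeak summit when present", {
  p <- tempfile()
  writeLines("chr1\t1000\t2000\tpk\t0\t.\t1\t1\t1\t100", p)
  pk <- read_bed(p)
  cfg <- profile_config(anchor_point = "summit")
  ann <- make_ann("g1", "chr1", "+", 1100, 3000)
  prof <- tss_peak_distribution(pk, ann, cfg)
  expect_equal(prof$values[which(prof$offsets == 50)], 100)  # summit at 1100
})
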