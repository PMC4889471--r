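test_that("validate_config reports every inconsistency", {
  expect_length(validate_config(scenario_config()), 0)
  expect_length(validate_config(nalm6_replica_plan()), 0)
  bad <- scenario_config(genes_joint = 1000)
  expect_true(any(grepl("joint genes exceed", validate_config(bad))))
  bad <- scenario_config(ik_overlapped = 500)
  expect_true(any(grepl("exceed total factor peaks|2x HDAC1-side",
                        validate_config(bad))))
  bad <- scenario_config(genome = c(chr1 = 3e6))
  expect_true(any(grepl("genome too small", validate_config(bad))))
  expect_error(build_scenario(bad, tempfile()), "infeasible")
})

test_that("a minimal planted target round trips through the pipeline", {
  cfg <- scenario_config(n_ik = 2, n_hdac = 0, ik_overlapped = 0,
                         hdac_overlapped = 0, genes_ik = 1, genes_hdac = 0,
                         genes_joint = 0,
                         k27_promoters = c(IK_HDAC1 = 0, HDAC1_ONLY = 0,
                                           IK_ONLY = 0, NEITHER = 0),
                         seed = 2)
  b <- build_scenario(cfg, file.path(tempdir(), "mini"))
  ann <- read_tss_table(b$files[["genes"]])
  ik <- suppressMessages(read_bed(b$files[["ik"]]))
  m <- assign_targets(ik, ann)
  expect_identical(names(m), "g000001")
  expect_length(m[[1]], 1)
})

test_that("the generator is byte-deterministic in the seed", {
  d1 <- file.path(tempdir(), "det1"); d2 <- file.path(tempdir(), "det2")
  d3 <- file.path(tempdir(), "det3")
  build_scenario(scenario_config(seed = 9), d1)
  build_scenario(scenario_config(seed = 9), d2)
  b3 <- build_scenario(scenario_config(seed = 10), d3)
  for (f in c("genes.tsv", "ik.bed", "hdac1.bed", "h3k27me3.bed",
              "qchip.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  # different seed: different coordinates, same planted statistics
  expect_false(identical(readLines(file.path(d1, "ik.bed")),
                         readLines(file.path(d3, "ik.bed"))))
})

test_that("planted statistics are recovered across seeds (generator vs analyzer)", {
  for (seed in c(1, 7, 23, 101, 4242)) {
    cfg <- scenario_config(seed = seed)
    b <- build_scenario(cfg, file.path(tempdir(), paste0("xchk", seed)))
    genome <- chromsig:::read_genome_table(b$files[["genome"]])
    ann <- read_tss_table(b$files[["genes"]])
    ik <- suppressMessages(read_bed(b$files[["ik"]], "IK", genome))
    hd <- suppressMessages(read_bed(b$files[["hdac1"]], "HDAC1", genome))
    k27 <- suppressMessages(read_bed(b$files[["h3k27me3"]], "H3K27me3",
                                     genome))
    st <- compute_cooccupancy(ik, hd, ann)
    expect_equal(st$n_a, cfg$n_ik)
    expect_equal(st$n_b, cfg$n_hdac)
    expect_equal(st$n_a_hit, cfg$ik_overlapped)
    expect_equal(st$n_b_hit, cfg$hdac_overlapped)
    expect_equal(st$genes_a, cfg$genes_ik)
    expect_equal(st$genes_b, cfg$genes_hdac)
    expect_equal(st$genes_joint, cfg$genes_joint)
    fr <- class_fractions(classify_promoters(
      promoter_windows(ann, cfg$promoter_flank, genome), k27, ik, hd,
      overlapped_peaks(ik, hd), cfg$assoc_distance))
    expect_equal(unname(fr$counts), unname(cfg$k27_promoters))
  }
})

test_that("planted gene counts do not depend on the assignment mode", {
  cfg <- scenario_config(seed = 31)
  b <- build_scenario(cfg, file.path(tempdir(), "modeinv"))
  ann <- read_tss_table(b$files[["genes"]])
  ik <- suppressMessages(read_bed(b$files[["ik"]]))
  hd <- suppressMessages(read_bed(b$files[["hdac1"]]))
  for (mode in c("window-overlap", "nearest-tss")) {
    st <- compute_cooccupancy(ik, hd, ann, assignment_config(mode = mode))
    expect_equal(st$genes_a, cfg$genes_ik)
    expect_equal(st$genes_b, cfg$genes_hdac)
    expect_equal(st$genes_joint, cfg$genes_joint)
  }
})

test_that("simulated qChIP recovers planted labels without noise", {
  genes <- sprintf("g%02d", 1:12)
  labs <- stats::setNames(rep(c("IKAROS_ONLY", "IKAROS_HDAC1", "NONE"), 4),
                          genes)
  qd <- simulate_qchip(genes, labs, effect_log2fc = 1.5, noise_sd = 0,
                       n_reps = 3, seed = 3)
  sig <- call_signatures(qd, "control", "treated")
  expect_identical(sig$label, unname(labs[sig$gene]))
  # zero effect: everything called NONE
  qd0 <- simulate_qchip(genes, labs, effect_log2fc = 0, noise_sd = 0.2,
                        n_reps = 3, seed = 3)
  expect_true(all(call_signatures(qd0, "control", "treated")$label == "NONE"))
})

test_that("the replica plan plants the published co-occupancy arithmetic", {
  cfg <- nalm6_replica_plan()
  # planted integers' fractions round half-up to the printed percentages
  expect_equal(chromsig:::round_half_up(100 * cfg$ik_overlapped / cfg$n_ik),
               12)
  expect_equal(chromsig:::round_half_up(100 * cfg$hdac_overlapped /
                                          cfg$n_hdac, 1), 14.6)
  expect_equal(sum(cfg$k27_promoters), 2000)
  expect_equal(100 * (cfg$k27_promoters[["IK_HDAC1"]] +
                        cfg$k27_promoters[["HDAC1_ONLY"]]) /
                 sum(cfg$k27_promoters), 85)
  expect_equal(100 * cfg$k27_promoters[["IK_HDAC1"]] /
                 sum(cfg$k27_promoters), 21)
})
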