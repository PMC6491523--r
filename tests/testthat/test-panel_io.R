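test_that("HapMap genotype strings map to dosages by the alleles column", {
  hmp <- c(
    paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
            "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
            "S1", "S2", "S3"), collapse = "\t"),
    paste(c("m1", "A/G", "1", "100", "+", rep("NA", 6),
            "AA", "AG", "GG"), collapse = "\t"),
    paste(c("m2", "C/T", "1", "200", "+", rep("NA", 6),
            "NN", "CC", "TT"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  writeLines(hmp, path)
  gm <- read_hapmap(path)
  expect_equal(unname(gm$dosage[, "m1"]), c(0L, 1L, 2L))
  expect_equal(unname(gm$dosage[, "m2"]), c(NA_integer_, 0L, 2L))
  expect_equal(gm$marker_map$ref, c("A", "C"))
  expect_equal(gm$marker_map$alt, c("G", "T"))
})

test_that("ambiguous alleles column falls back to major-allele inference and triallelic markers are dropped", {
  hmp <- c(
    paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
            "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
            "S1", "S2", "S3"), collapse = "\t"),
    paste(c("m1", "N/N", "1", "100", "+", rep("NA", 6),
            "TT", "TT", "CC"), collapse = "\t"),
    paste(c("m2", "A/G", "1", "200", "+", rep("NA", 6),
            "AA", "GG", "CC"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  writeLines(hmp, path)
  expect_warning(gm <- read_hapmap(path), "two alleles")
  expect_equal(colnames(gm$dosage), "m1")
  # major allele T becomes reference
  expect_equal(unname(gm$dosage[, "m1"]), c(0L, 0L, 2L))
})

test_that("malformed rows are reported with their line number", {
  hmp <- c(
    paste(c("rs#", "alleles", "chrom", "pos", "strand", "assembly#",
            "center", "protLSID", "assayLSID", "panelLSID", "QCcode",
            "S1"), collapse = "\t"),
    "m1\tA/G\t1")
  path <- withr::local_tempfile(fileext = ".hmp.txt")
  writeLines(hmp, path)
  expect_error(read_hapmap(path), "line 2")
})

test_that("HapMap and dosage-CSV round trips are identities", {
  sim <- two_group_panel(n_per_group = 8, n_markers = 40, seed = 21)
  gm <- sim$panel
  hp <- withr::local_tempfile(fileext = ".hmp.txt")
  write_hapmap(gm, hp)
  back <- read_hapmap(hp)
  expect_identical(back$dosage, gm$dosage)
  expect_equal(back$marker_map$pos, gm$marker_map$pos)

  prefix <- file.path(withr::local_tempdir(), "panel")
  write_dosage_csv(gm, prefix)
  back2 <- read_dosage_csv(prefix)
  expect_identical(back2$dosage, gm$dosage)
  expect_equal(back2$passport, gm$passport)
})

test_that("VCF panels read into the same dosages", {
  skip_if_not_installed("vcfR")
  vcf <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "S1", "S2"), collapse = "\t"),
           paste(c("1", "100", "m1", "A", "G", ".", "PASS", ".", "GT",
                   "0/0", "1/1"), collapse = "\t"),
           paste(c("1", "200", "m2", "C", "T", ".", "PASS", ".", "GT",
                   "0|1", "./."), collapse = "\t"),
           paste(c("1", "300", "m3", "A", "G,T", ".", "PASS", ".", "GT",
                   "0/0", "0/0"), collapse = "\t"))
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf, path)
  gm <- read_vcf_panel(path)
  expect_equal(colnames(gm$dosage), c("m1", "m2"))  # multiallelic dropped
  expect_equal(unname(gm$dosage[, "m1"]), c(0L, 2L))
  expect_equal(unname(gm$dosage[, "m2"]), c(1L, NA_integer_))
})

test_that("marker filters apply call-rate then MAF with exact thresholds", {
  # marker 1: missing in 6/100 samples -> call rate 0.94 < 0.95, removed
  # marker 2: 9 alt alleles / 191 ref -> MAF 0.045 < 0.05, removed
  # marker 3: clean
  d <- matrix(0L, 100, 3, dimnames = list(sprintf("a%03d", 1:100), c("m1", "m2", "m3")))
  d[1:6, 1] <- NA
  d[7:50, 1] <- 1L
  d[1:9, 2] <- 1L              # 9 alt copies of 200
  d[1:50, 3] <- 2L
  gm <- toy_panel(d)
  res <- filter_markers(gm)
  expect_equal(res$report[[1]]$removed, "m1")
  expect_equal(res$report[[2]]$removed, "m2")
  expect_equal(colnames(res$panel$dosage), "m3")
  # dimension bookkeeping
  expect_equal(ncol(gm$dosage),
               ncol(res$panel$dosage) + sum(lengths(lapply(res$report, `[[`, "removed"))))
  # idempotence
  res2 <- filter_markers(res$panel)
  expect_equal(res2$report[[1]]$n_removed + res2$report[[2]]$n_removed, 0)
})

test_that("sample filter removes exactly the planted low-call accessions", {
  cfg <- panel_config(n_markers = 400, groups = data.frame(
    group = "A", n = 60, F = 0), selfing_generations = 0,
    n_duplicates = 0, missing_rate = 0.005,
    n_low_call_samples = 10, low_call_missing_rate = 0.2, rng_seed = 17)
  sim <- simulate_panel(cfg)
  res <- filter_samples(sim$panel, min_call_rate = 0.95)
  expect_setequal(res$report[[1]]$removed, sim$truth$low_call_samples)
  # complete panel is an identity
  clean <- toy_panel(matrix(c(0L, 1L, 2L, 0L), 2, 2))
  expect_equal(filter_samples(clean)$report[[1]]$n_removed, 0)
})

test_that("planted marker failures are recovered in the QC report counts", {
  sim <- two_group_panel(n_per_group = 50, n_markers = 300, selfing = 0,
                         missing = 0, seed = 33)
  gm <- sim$panel
  # plant 12 low-call markers and 7 rare markers
  low <- sample(colnames(gm$dosage), 12)
  for (m in low) gm$dosage[sample(100, 8), m] <- NA  # call rate 0.92
  rare_pool <- setdiff(colnames(gm$dosage), low)
  rare <- sample(rare_pool, 7)
  for (m in rare) gm$dosage[, m] <- c(1L, rep(0L, 99))  # MAF 0.005
  res <- filter_markers(gm)
  expect_setequal(res$report[[1]]$removed, low)
  expect_true(all(rare %in% res$report[[2]]$removed))
})

test_that("LD pruning removes the downstream member of correlated pairs", {
  sim <- two_group_panel(n_per_group = 40, n_markers = 30, selfing = 0,
                         missing = 0, seed = 9)
  gm <- sim$panel
  # exact duplicate column: r2 = 1, downstream copy removed
  gm2 <- inject_ld_block(gm, colnames(gm$dosage)[5],
                         colnames(gm$dosage)[6])
  res <- ld_prune(gm2, window = 30, increment = 1)
  expect_true(colnames(gm$dosage)[6] %in% res$report[[1]]$removed)
  expect_false(colnames(gm$dosage)[5] %in% res$report[[1]]$removed)
})

test_that("independent markers are not pruned", {
  cfg <- panel_config(n_markers = 60, groups = data.frame(
    group = "A", n = 200, F = 0), selfing_generations = 0,
    n_duplicates = 0, missing_rate = 0, rng_seed = 12)
  gm <- simulate_panel(cfg)$panel
  res <- ld_prune(gm, window = 60, increment = 1, r2_threshold = 0.8)
  expect_equal(res$report[[1]]$n_removed, 0)
})

test_that("windowed pruning equals brute-force all-pairs pruning when the window covers the panel", {
  sim <- two_group_panel(n_per_group = 30, n_markers = 10, selfing = 2,
                         missing = 0.02, seed = 77)
  gm <- sim$panel
  gm <- inject_ld_block(gm, colnames(gm$dosage)[2],
                        colnames(gm$dosage)[c(4, 7)], flip_rate = 0.05,
                        rng_seed = 3)
  res <- ld_prune(gm, window = 10, increment = 1, r2_threshold = 0.8)

  # oracle: greedy all-pairs scan in map order with the same removal rule
  keep <- rep(TRUE, 10)
  for (i in 1:9) {
    if (!keep[i]) next
    for (j in (i + 1):10) {
      if (!keep[j]) next
      r2 <- composite_r2(gm$dosage[, i], gm$dosage[, j])
      if (!is.na(r2) && r2 > 0.8) keep[j] <- FALSE
    }
  }
  expect_setequal(res$report[[1]]$removed, colnames(gm$dosage)[!keep])

  # invariant: no surviving within-window pair above the threshold
  d <- res$panel$dosage
  for (i in seq_len(ncol(d) - 1)) {
    for (j in (i + 1):ncol(d)) {
      r2 <- composite_r2(d[, i], d[, j])
      expect_false(!is.na(r2) && r2 > 0.8)
    }
  }
  # idempotence
  expect_equal(ld_prune(res$panel, window = 10, increment = 1)$report[[1]]$n_removed, 0)
})

test_that("degenerate QC inputs are rejected explicitly", {
  d <- matrix(NA_integer_, 4, 2)
  d[, 1] <- c(0L, NA, NA, NA)
  d[, 2] <- c(NA, 0L, NA, NA)
  gm <- toy_panel(d)
  expect_error(filter_markers(gm), "all markers removed")
  expect_error(ld_prune(toy_panel(matrix(0L, 3, 3)), window = 1), "window")
})
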