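test_that("region filter excludes only regions below 100 reads in both samples", {
  cov <- mk_coverage(chrom = "1", start = (0:3) * 1000, end = (0:3) * 1000 + 500,
                     tumor = c(150, 40, 100, 40), normal = c(40, 40, 100, 150))
  kept <- filter_regions(cov)
  expect_equal(kept$tumor_reads, c(150, 100, 40))   # (40,40) excluded, 100 is not < 100
  either <- filter_regions(cov, run_config(region_filter_mode = "either"))
  expect_equal(either$tumor_reads, c(100))
  low <- mk_coverage("1", 0, 500, 10, 10)
  expect_error(filter_regions(low), "excluded")
})

test_that("log2 ratios are normalised, corrected and handle zero normals", {
  cov <- mk_coverage(chrom = "1", start = (0:2) * 1000, end = (0:2) * 1000 + 500,
                     tumor = c(75, 125, 100), normal = c(100, 100, 100))
  # purity 1: corrected equals raw; equal normalised counts map to 0
  prof <- compute_log2(cov, purity = 1)
  expect_equal(prof$log2_raw[3], 0)
  expect_equal(prof$log2_corrected, prof$log2_raw)
  # r = 0.75 at purity 0.5 -> corrected ratio 0.5 -> log2 = -1
  prof <- compute_log2(cov, purity = 0.5)
  expect_equal(prof$log2_corrected[1], -1)
  # r = 1.25 at purity 0.5 -> corrected 1.5
  expect_equal(prof$log2_corrected[2], log2(1.5))

  cov$normal_reads[2] <- 0
  expect_warning(prof <- compute_log2(cov, purity = 1), "zero normal")
  expect_equal(nrow(prof), 2)

  # segment-mean correction uses the same inversion: r 1.5 at p 0.5 -> 2.0
  segs <- data.frame(chrom = "1", start = 0, end = 1000, n_regions = 10,
                     seg_mean = log2(c(0.75, 1.5)))
  segs <- correct_segment_means(segs, purity = 0.5)
  expect_equal(segs$seg_mean, c(-1, 1))
  expect_equal(segs$call, c("loss", "gain"))
})

test_that("segment means map to the five published call classes", {
  expect_equal(classify_segment(c(1.2, 0.7, 0, -0.7, -1.3)),
               c("amplified", "gain", "neutral", "loss", "deletion"))
  # boundaries: log2 of exactly 1 is gain, -1 is loss, +-0.5 neutral
  expect_equal(classify_segment(c(1, 0.5, -0.5, -1)),
               c("gain", "neutral", "neutral", "loss"))
})

test_that("CBS returns one segment for a constant profile and finds planted steps", {
  mkprof <- function(x, chrom = "1") {
    data.frame(chrom = chrom, start = seq_along(x) * 1000,
               end = seq_along(x) * 1000 + 500, log2_corrected = x)
  }
  set.seed(2)
  flat <- segment_cbs(mkprof(rnorm(200, 0, 0.2) * 0 ), seed = 1)
  expect_equal(nrow(flat), 1)
  expect_equal(flat$seg_mean, 0)
  expect_equal(flat$n_regions, 200)

  set.seed(8)
  x <- c(rnorm(100, 0, 0.2), rnorm(100, -1.2, 0.2))
  segs <- segment_cbs(mkprof(x), seed = 3)
  expect_equal(nrow(segs), 2)
  bp <- segs$n_regions[1]
  expect_lte(abs(bp - 100), 3)
  expect_lt(abs(segs$seg_mean[1] - 0), 0.1)
  expect_lt(abs(segs$seg_mean[2] + 1.2), 0.1)
  expect_equal(segs$call, c("neutral", "deletion"))
  expect_equal(sum(segs$n_regions), 200)          # conservation
  # seg_mean equals the arithmetic mean of member values
  expect_equal(segs$seg_mean[1], mean(x[1:bp]), tolerance = 1e-9)
  expect_equal(segs$seg_mean[2], mean(x[(bp + 1):200]), tolerance = 1e-9)

  # two planted events on separate chromosomes recover their classes
  set.seed(13)
  y <- c(rnorm(60, 0, 0.2), rnorm(30, 0.6, 0.2), rnorm(30, 0, 0.2))
  z <- c(rnorm(40, -1.2, 0.2), rnorm(80, 0, 0.2))
  prof <- rbind(mkprof(y, "2"), mkprof(z, "5"))
  segs <- segment_cbs(prof, seed = 4)
  expect_true(any(segs$call == "gain" & segs$chrom == "2"))
  expect_true(any(segs$call == "deletion" & segs$chrom == "5"))
  expect_equal(sum(segs$n_regions[segs$chrom == "2"]), 120)
  expect_equal(sum(segs$n_regions[segs$chrom == "5"]), 120)
})

test_that("CBS agrees with an exhaustive single-split oracle on a clean step", {
  # independent R implementation of the max two-sample t statistic
  max_stat_oracle <- function(x, min_width = 3) {
    n <- length(x); cs <- c(0, cumsum(x)); sd <- sd(x)
    best <- list(stat = -1, i = NA, j = NA)
    for (i in 0:(n - 1)) for (j in (i + 1):n) {
      k <- j - i; m <- n - k
      if (k < min_width || m < min_width) next
      s <- abs((cs[j + 1] - cs[i + 1]) / k - (cs[n + 1] - cs[j + 1] + cs[i + 1]) / m) /
        (sd * sqrt(1 / k + 1 / m))
      if (s > best$stat) best <- list(stat = s, i = i, j = j)
    }
    best
  }
  set.seed(19)
  x <- c(rnorm(40, 0, 0.1), rnorm(40, -1, 0.1))
  oracle <- max_stat_oracle(x)
  cpp <- ccrccwes:::cbs_max_stat_cpp(x, 3L)
  expect_equal(cpp$stat, oracle$stat, tolerance = 1e-9)
  expect_equal(c(cpp$i, cpp$j), c(oracle$i, oracle$j))
  # with a generous alpha the first CBS breakpoint is the oracle split
  prof <- data.frame(chrom = "1", start = seq_along(x), end = seq_along(x) + 0.5,
                     log2_corrected = x)
  segs <- segment_cbs(prof, alpha = 0.2, seed = 5)
  expect_true(oracle$j %in% cumsum(segs$n_regions))

  # alpha below 1/(nperm+1) can never accept a split
  segs1 <- segment_cbs(prof, alpha = 1e-6, nperm = 200, seed = 6)
  expect_equal(nrow(segs1), 1)
})

test_that("cytoband annotation and the genome-wide review flag behave", {
  cyto <- synthetic_cytobands()
  segs <- data.frame(chrom = c("3", "8"), start = c(0, 3e6), end = c(2.2e6, 6e6),
                     n_regions = c(20, 30), seg_mean = c(-0.8, 0),
                     call = c("loss", "neutral"))
  ann <- annotate_and_flag(segs, cyto)
  expect_match(ann$segments$cytobands[1], "3p25")
  expect_match(ann$segments$cytobands[1], "3p21")
  expect_false(grepl("3q", ann$segments$cytobands[1]))
  expect_false(ann$review_flag)   # one focal loss out of ~9 Mb

  shifted <- data.frame(chrom = as.character(1:22), start = 0, end = 6e6,
                        n_regions = 60, seg_mean = -0.6, call = "loss")
  ann2 <- annotate_and_flag(shifted, cyto)
  expect_true(ann2$review_flag)
  expect_equal(ann2$fraction_altered, 1)
})

test_that("CNA burden is order invariant and excludes sex chromosomes by default", {
  segs <- data.frame(chrom = c("1", "2", "X"), start = 0, end = c(4e6, 6e6, 6e6),
                     n_regions = 10, seg_mean = c(-0.8, 0, -0.9),
                     call = c("loss", "neutral", "loss"))
  b1 <- cna_burden(segs)
  b2 <- cna_burden(segs[c(3, 1, 2), ])
  expect_equal(b1$fraction_altered, 0.4)   # 4 Mb of 10 Mb autosomal
  expect_equal(b1$fraction_altered, b2$fraction_altered)
  b3 <- cna_burden(segs, run_config(include_sex_chroms = TRUE))
  expect_equal(b3$fraction_altered, 10 / 16)
})

test_that("cohort recurrence counts patients once however many samples hit", {
  cyto <- synthetic_cytobands()
  loss9p <- data.frame(chrom = "9", start = 0, end = 3e6, n_regions = 30,
                       seg_mean = -0.8, call = "loss")
  neutral <- data.frame(chrom = "9", start = 0, end = 3e6, n_regions = 30,
                        seg_mean = 0, call = "neutral")
  ann <- function(s) annotate_and_flag(s, cyto)$segments
  segs <- list(S1 = ann(loss9p), S2 = ann(loss9p), S3 = ann(loss9p),
               S4 = ann(neutral))
  meta <- data.frame(sample_id = c("S1", "S2", "S3", "S4"),
                     patient_id = c("P1", "P1", "P2", "P3"),
                     site = "lung", pretreated = FALSE, tissue_type = "metastasis")
  rec <- cohort_recurrence(segs, meta, cyto)
  expect_equal(rec$loss_count[rec$cytoband == "9p21"], 2)  # P1 deduplicated
  expect_equal(rec$gain_count[rec$cytoband == "9p21"], 0)
  expect_equal(sum(rec$loss_count[!grepl("^9p", rec$cytoband)]), 0)
})

test_that("planted 3p25-loss prevalence is recovered across a cohort", {
  menu <- data.frame(cytoband = "3p25", event = "loss", prob = 0.4)
  # purity >= 0.4, the regime where single-sample detection of an arm loss
  # is expected (the same regime the SNV-sensitivity and tree-recovery
  # properties use); below it detection power, not recurrence counting, is
  # what a failure would measure
  cfg <- sim_config(n_patients = 50, n_multi_patients = 0,
                    purity_range = c(0.4, 0.9),
                    driver_cnv_menu = menu, rng_seed = 77)
  co <- emit_cohort(cfg)
  res <- suppressMessages(run_pipeline(co, run_config(rng_seed = 19)))
  rec <- res$recurrence
  got <- rec$loss_count[rec$cytoband == "3p25"] / 50
  ci <- 1.96 * sqrt(0.4 * 0.6 / 50)
  expect_gt(got, 0.4 - ci)
  expect_lt(got, 0.4 + ci)
})
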