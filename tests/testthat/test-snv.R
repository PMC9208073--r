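test_that("VAF correction follows the admixture closed forms", {
  expect_equal(correct_vaf(0.25, purity = 0.5, local_cn = 2), 0.5)
  expect_equal(correct_vaf(0.3, purity = 1, local_cn = 2), 0.3)   # identity
  expect_equal(correct_vaf(0.6, purity = 0.5, local_cn = 2), 1.0) # capped
  # one-copy loss: denominator p*1 + 2(1-p)
  expect_equal(correct_vaf(0.25, purity = 0.5, local_cn = 1), 0.25 * 1.5 / 0.5)
  expect_error(correct_vaf(0.2, purity = 0, local_cn = 2), "purity")
  expect_error(correct_vaf(0.2, purity = 0.5, local_cn = 0), "local_cn")
})

test_that("the COSMIC rescue rule enforces all three boundaries", {
  cfg <- run_config()
  expect_true(cosmic_rescue(15, 0.07, 0.002, cfg))
  expect_true(cosmic_rescue(10, 0.07, 0.002, cfg))    # >= 10 reports
  expect_false(cosmic_rescue(9, 0.07, 0.002, cfg))
  expect_false(cosmic_rescue(15, 0.05, 0.002, cfg))   # needs > 5%
  expect_false(cosmic_rescue(15, 0.07, 0.02, cfg))    # normal must be < 1%
  expect_false(cosmic_rescue(15, 0.07, 0.01, cfg))
})

test_that("variant filtering hits every drop reason with the right precedence", {
  calls <- rbind(
    mk_variant(pos = 1, t_alt = 20, t_ref = 80),                      # keep
    mk_variant(pos = 2, t_alt = 20, t_ref = 80, n_alt = 45, n_ref = 55), # in_normal
    mk_variant(pos = 3, effect = "synonymous", t_alt = 20, t_ref = 80),  # synonymous
    mk_variant(pos = 4, t_alt = 4, t_ref = 5),                        # low_reads (9 total)
    mk_variant(pos = 5, t_alt = 4, t_ref = 96),                       # low corrected VAF
    mk_variant(pos = 6, t_alt = 7, t_ref = 93, cosmic = 15),          # rescued
    # precedence: in_normal wins over synonymous, synonymous over low_reads
    mk_variant(pos = 7, effect = "synonymous", t_alt = 20, t_ref = 80,
               n_alt = 45, n_ref = 55),
    mk_variant(pos = 8, effect = "synonymous", t_alt = 3, t_ref = 4)
  )
  out <- suppressMessages(filter_variants(calls, purity = 1))
  expect_equal(out$filter_status,
               c("keep", "in_normal", "synonymous", "low_reads",
                 "low_corrected_vaf", "keep", "in_normal", "synonymous"))
  expect_equal(out$rescued_by_cosmic,
               c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE))
  expect_equal(nrow(out), nrow(calls))  # conservation of records

  # low corrected VAF with weak COSMIC support stays dropped
  weak <- mk_variant(t_alt = 8, t_ref = 92, cosmic = 3)
  out <- suppressMessages(filter_variants(weak, purity = 1))
  expect_equal(out$filter_status, "low_corrected_vaf")
})

test_that("purity rescales VAFs before the 10% rule and uses local CN", {
  # raw VAF 8% at purity 0.4 corrects to 8% * 2 / 0.8 = 20%: kept
  v <- mk_variant(t_alt = 8, t_ref = 92)
  out <- suppressMessages(filter_variants(v, purity = 0.4))
  expect_equal(out$vaf_corrected, 0.2)
  expect_equal(out$filter_status, "keep")
  # same variant on a one-copy loss corrects further up
  segs <- data.frame(chrom = "1", start = 0, end = 1e6, n_regions = 10,
                     seg_mean = -1, call = "loss")
  out <- suppressMessages(filter_variants(v, purity = 0.4, segments = segs))
  expect_equal(out$local_cn, 1)
  expect_equal(out$vaf_corrected, 0.08 * (0.4 + 1.2) / 0.4)
})

test_that("raising the corrected-VAF threshold never keeps more variants", {
  set.seed(3)
  calls <- do.call(rbind, lapply(1:60, function(i)
    mk_variant(pos = i, t_alt = rbinom(1, 100, 0.2), t_ref = 80,
               cosmic = sample(c(0, 15), 1))))
  kept <- vapply(c(0.05, 0.1, 0.2, 0.3, 0.5), function(thr) {
    out <- suppressMessages(
      filter_variants(calls, 0.8, config = run_config(min_corrected_vaf = thr)))
    sum(out$filter_status == "keep")
  }, numeric(1))
  expect_true(all(diff(kept) <= 0))
})

test_that("filtering decisions are per-variant (order independent)", {
  set.seed(9)
  calls <- do.call(rbind, lapply(1:30, function(i)
    mk_variant(pos = i, t_alt = rbinom(1, 100, 0.15), t_ref = 85,
               effect = sample(effect_levels(), 1))))
  a <- suppressMessages(filter_variants(calls, 0.6))
  perm <- sample(nrow(calls))
  b <- suppressMessages(filter_variants(calls[perm, ], 0.6))
  expect_equal(b$filter_status[order(perm)], a$filter_status)
})

test_that("TMB divides kept non-synonymous mutations by covered megabases", {
  # 34 regions of 1 Mb passing the coverage rule
  cov <- mk_coverage(chrom = rep("1", 35), start = (0:34) * 1e6,
                     end = (1:35) * 1e6,
                     tumor = c(rep(150, 34), 50), normal = c(rep(150, 34), 40))
  calls <- do.call(rbind, lapply(1:90, function(i)
    mk_variant(pos = i, effect = if (i <= 85) "missense" else "synonymous")))
  calls$filter_status <- "keep"
  tm <- compute_tmb(calls, cov)
  expect_equal(tm$covered_mb, 34)
  expect_equal(tm$n_nonsynonymous, 85)
  expect_equal(tm$tmb, 2.5)
  expect_equal(tm$indel_fraction, 0)

  tm0 <- compute_tmb(calls[0, ], cov)
  expect_equal(tm0$tmb, 0)

  cov_bad <- mk_coverage("1", 0, 1e6, 150, 150)[0, ]
  expect_error(compute_tmb(calls, rbind(cov_bad)), "excluded|covered")
})

test_that("planted clonal nonsynonymous SNVs survive filtering at purity >= 0.4", {
  cfg <- sim_config(n_patients = 6, n_multi_patients = 0,
                    purity_range = c(0.4, 0.9), rng_seed = 33)
  co <- emit_cohort(cfg)
  sens <- c()
  for (sid in co$meta$sample_id) {
    truth <- co$truth$samples[[sid]]
    out <- suppressMessages(filter_variants(co$variants[[sid]], truth$purity))
    k <- paste(out$chrom, out$pos, out$ref, out$alt, sep = ":")
    clonal <- names(truth$clonality)[!is.na(truth$clonality) &
                                       truth$clonality == 1]
    eligible <- k %in% clonal & out$effect != "synonymous"
    sens <- c(sens, sum(eligible & out$filter_status == "keep") / sum(eligible))
  }
  expect_gt(mean(sens), 0.95)
})
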