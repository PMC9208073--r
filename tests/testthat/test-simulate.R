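test_that("patient trees are reproducible, cover degenerate sizes and hit Poisson rates", {
  expect_error(simulate_patient_tree(0), ">= 1")

  set.seed(4)
  single <- simulate_patient_tree(1, "S1")
  expect_equal(nrow(single$tree$edges), 1L)
  expect_equal(single$tree$edges$parent, "germline")

  set.seed(11); a <- simulate_patient_tree(3)
  set.seed(11); b <- simulate_patient_tree(3)
  expect_identical(a$tree$edges, b$tree$edges)

  # mean truncal SNV count over 200 patients within 3 SE of the Poisson mean
  set.seed(21)
  cfg <- sim_config()
  trunk <- replicate(200, {
    s <- simulate_patient_tree(3, config = cfg)
    i <- which(vapply(s$edge_samples, length, integer(1)) == 3)[1]
    s$tree$edges$length[i]
  })
  se <- sqrt(cfg$n_truncal_snvs / 200)
  expect_lt(abs(mean(trunk) - cfg$n_truncal_snvs), 3 * se)
})

test_that("simulated coverage matches the admixture closed forms", {
  regions <- synthetic_capture_regions()
  expect_error(simulate_coverage(regions, NULL, purity = 0), "purity")
  expect_error(simulate_coverage(regions, NULL, purity = 1.2), "purity")

  set.seed(31)
  # neutral genome at purity 1: mean ratio 1
  cov <- simulate_coverage(regions, NULL, purity = 1, depth = 200)
  expect_lt(abs(mean(cov$tumor_reads) / mean(cov$normal_reads) - 1), 0.02)

  # one-copy loss at purity 0.5: expected ratio (0.5*1 + 2*0.5)/2 = 0.75
  segs <- data.frame(chrom = "3", start = 0, end = 3e6, cn = 1)
  cov <- simulate_coverage(regions, segs, purity = 0.5, depth = 500)
  on3p <- cov$chrom == "3" & cov$start < 3e6
  expect_lt(abs(mean(cov$tumor_reads[on3p]) / mean(cov$normal_reads[on3p]) - 0.75), 0.04)

  # CN 4 at purity 0.5: expected ratio (0.5*4 + 1)/2 = 1.5
  segs$cn <- 4
  cov <- simulate_coverage(regions, segs, purity = 0.5, depth = 500)
  on3p <- cov$chrom == "3" & cov$start < 3e6
  expect_lt(abs(mean(cov$tumor_reads[on3p]) / mean(cov$normal_reads[on3p]) - 1.5), 0.08)
})

test_that("simulated variant reads hit the expected VAF closed forms", {
  expect_error(simulate_variant_reads(1, 0.5, local_cn = 2, multiplicity = 3),
               "multiplicity")
  set.seed(41)
  # clonal het in a pure diploid tumour: VAF 1/2
  r <- simulate_variant_reads(rep(1, 3000), 1, 2, 1, 100, 100)
  expect_equal(unique(r$expected_vaf), 0.5)
  # clonality 1, purity 0.4, CN 2: VAF = 0.4/2 = 0.2
  r <- simulate_variant_reads(rep(1, 3000), 0.4, 2, 1, 100, 100)
  expect_equal(unique(r$expected_vaf), 0.2)
  obs <- mean(r$tumor_alt_reads / 100)
  expect_lt(abs(obs - 0.2), 3 * sqrt(0.2 * 0.8 / 100 / 3000))
  # clonality 0.5, purity 0.5, CN 2: VAF = 0.125
  r <- simulate_variant_reads(rep(0.5, 3000), 0.5, 2, 1, 100, 100)
  expect_equal(unique(r$expected_vaf), 0.125)
  obs <- mean(r$tumor_alt_reads / 100)
  expect_lt(abs(obs - 0.125), 3 * sqrt(0.125 * 0.875 / 100 / 3000))
})

test_that("het-SNP fractions follow the allele-mixture expectations", {
  regions <- synthetic_capture_regions()
  set.seed(51)
  # balanced CN 2: tumour fraction 0.5
  sn <- simulate_het_snps(regions, NULL, purity = 0.8, n_snps = 2000, depth = 400)
  expect_lt(abs(mean(sn$tumor_alt_fraction) - 0.5), 0.01)

  # one-copy loss at purity 0.5: folded fraction 1/(2-p) = 2/3 either way
  segs <- data.frame(chrom = "3", start = 0, end = 6e6, cn = 1)
  sn <- simulate_het_snps(regions, segs, purity = 0.5, n_snps = 4000, depth = 400)
  on3 <- sn$chrom == "3"
  b <- pmax(sn$tumor_alt_fraction[on3], 1 - sn$tumor_alt_fraction[on3])
  expect_lt(abs(median(b) - 2/3), 0.01)
  # unfolded fractions split between 2/3 (retained) and 1/3 (lost allele)
  expect_lt(abs(mean(sn$tumor_alt_fraction[on3]) - 0.5), 0.02)
})

test_that("emit_cohort is deterministic, cross-consistent and honours scale", {
  cfg <- sim_config(n_patients = 3, n_multi_patients = 1, rng_seed = 61)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  co <- emit_cohort(cfg, out_dir = d1)
  emit_cohort(cfg, out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     info = f)
  }
  # cross-consistency: every sample in metadata has its three tables, every
  # variant lies inside a capture region
  expect_setequal(names(co$variants), co$meta$sample_id)
  reg <- co$regions
  for (sid in co$meta$sample_id) {
    v <- co$variants[[sid]]
    hit <- ccrccwes:::locate_positions(v$chrom, v$pos, reg)
    expect_false(anyNA(hit))
  }
  # round trip through the readers
  back <- suppressMessages(read_cohort_dir(d1))
  expect_equal(back$meta$sample_id, co$meta$sample_id)
  expect_equal(back$variants[[1]]$pos, co$variants[[1]]$pos)

  # empty cohort still emits valid tables
  co0 <- emit_cohort(sim_config(n_patients = 0, n_multi_patients = 0))
  expect_equal(nrow(co0$meta), 0)
  expect_length(co0$variants, 0)
})

test_that("a 13-patient multi-sample cohort supports tree building throughout", {
  cfg <- sim_config(n_patients = 13, n_multi_patients = 13, rng_seed = 71)
  co <- emit_cohort(cfg)
  counts <- table(co$meta$patient_id)
  expect_true(all(counts >= 2))
  purities <- vapply(co$truth$samples, function(s) s$purity, numeric(1))
  for (pid in unique(co$meta$patient_id)) {
    sids <- co$meta$sample_id[co$meta$patient_id == pid]
    calls <- lapply(co$variants[sids], function(v) {
      v$filter_status <- "keep"; v$local_cn <- 2; v
    })
    pres <- build_presence_matrix(calls, purities[sids], threshold = 0.25)
    tree <- build_tree(pres)
    expect_setequal(tree$samples, sids)
  }
})
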