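mk_kept <- function(genes, vafs = 0.4) {
  v <- do.call(rbind, lapply(seq_along(genes), function(i)
    mk_variant(pos = i * 100, gene = genes[i])))
  v$filter_status <- "keep"
  v$vaf_corrected <- rep_len(vafs, length(genes))
  v
}

mk_meta <- function(samples, patients, pretreated = FALSE) {
  data.frame(sample_id = samples, patient_id = patients, site = "lung",
             pretreated = rep_len(pretreated, length(samples)),
             tissue_type = "metastasis", stringsAsFactors = FALSE)
}

test_that("gene frequencies are patient-level and sorted with alphabetical ties", {
  calls <- list(S1 = mk_kept(c("SETD2", "SETD2", "VHL")),
                S2 = mk_kept("SETD2"),          # same patient as S1
                S3 = mk_kept(c("PBRM1", "VHL")),
                S4 = mk_kept("APC"))
  meta <- mk_meta(paste0("S", 1:4), c("P1", "P1", "P2", "P3"))
  freq <- gene_frequencies(calls, meta)
  expect_equal(freq$n_patients, rep(3, nrow(freq)))
  expect_equal(freq$n_mutated_patients[freq$gene == "SETD2"], 1)  # dedup
  expect_equal(freq$n_mutated_patients[freq$gene == "VHL"], 2)
  expect_equal(freq$frequency[freq$gene == "VHL"], 2 / 3)
  # VHL leads; the three singletons tie and sort alphabetically
  expect_equal(freq$gene, c("VHL", "APC", "PBRM1", "SETD2"))
  expect_error(gene_frequencies(calls, meta[0, ]), "empty")
})

test_that("frequencies are invariant to sample order and duplicated samples", {
  calls <- list(S1 = mk_kept("SETD2"), S2 = mk_kept("SETD2"),
                S3 = mk_kept("VHL"))
  meta <- mk_meta(paste0("S", 1:3), c("P1", "P1", "P2"))
  f1 <- gene_frequencies(calls, meta)
  f2 <- gene_frequencies(calls[c(3, 1, 2)], meta[c(2, 3, 1), ])
  expect_equal(f1, f2)
})

test_that("Mann-Whitney matches exhaustive enumeration on small groups", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$method, "exact")
  # enumeration oracle: all 20 assignments of ranks 1..6 to group A
  pooled <- c(1, 2, 3, 4, 5, 6)
  u_for <- function(a_idx) {
    a <- pooled[a_idx]; b <- pooled[-a_idx]
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  }
  us <- combn(6, 3, u_for)
  p_enum <- mean(us <= 0) + mean(us >= 9)   # two-sided, U from 0 to 9
  expect_equal(p_enum, 0.1)
  expect_equal(mw$p, p_enum)

  # identical multisets: no evidence of a shift
  expect_equal(mann_whitney_u(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("the normal approximation tracks the exact test at n = 8", {
  set.seed(12)
  for (i in 1:20) {
    a <- rnorm(8); b <- rnorm(8, 0.5)
    exact <- mann_whitney_u(a, b)           # n = 8, no ties: exact path
    expect_equal(exact$method, "exact")
    approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
    expect_lt(abs(exact$p - approx), 0.03)
  }
})

test_that("Benjamini-Hochberg matches the hand-computed step-up", {
  # by hand: q_i = min over j >= i of p_(j) * m / j = 0.04 for all four
  expect_equal(adjust_bh(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_bh(0.2), 0.2)
  expect_equal(adjust_bh(rep(1, 5)), rep(1, 5))
  set.seed(3)
  p <- runif(30)
  q <- adjust_bh(p)
  expect_true(all(q >= p))
  perm <- sample(30)
  expect_equal(adjust_bh(p[perm]), q[perm])  # order equivariance
})

test_that("treatment comparisons emit one row per metric with BH on the VAF family", {
  set.seed(31)
  calls <- c(lapply(1:6, function(i) mk_kept(c("SETD2", "VHL"), rnorm(2, 0.4, 0.05))),
             lapply(1:6, function(i) mk_kept(c("SETD2", "VHL"), rnorm(2, 0.4, 0.05))))
  names(calls) <- paste0("S", 1:12)
  meta <- mk_meta(paste0("S", 1:12), paste0("P", 1:12),
                  pretreated = rep(c(FALSE, TRUE), each = 6))
  tmb <- lapply(1:12, function(i)
    list(tmb = rnorm(1, 2.5, 0.3), indel_fraction = 0.1))
  names(tmb) <- names(calls)
  burden <- lapply(1:12, function(i) list(fraction_altered = runif(1, 0.1, 0.3)))
  names(burden) <- names(calls)
  cmp <- compare_by_treatment(calls, tmb, burden, meta)
  expect_setequal(setdiff(cmp$metric, c("tmb", "indel_fraction", "cna_burden")),
                  c("vaf_SETD2", "vaf_VHL"))
  expect_true(all(cmp$q >= cmp$p, na.rm = TRUE))
  # identical groups: no small p-values
  expect_true(all(cmp$p > 0.2, na.rm = TRUE))
  expect_equal(cmp$n_naive[cmp$metric == "tmb"], 6)

  # a metric with < 2 observations in a group gets NA and a warning
  calls$S1 <- mk_kept("EGFR", 0.5)
  expect_warning(cmp2 <- compare_by_treatment(calls, tmb, burden, meta,
                                              vaf_genes = "EGFR"),
                 "<2 observations")
  expect_true(is.na(cmp2$p[cmp2$metric == "vaf_EGFR"]))
})

test_that("a planted pretreatment VAF shift is detected, unshifted genes are not", {
  cfg <- sim_config(n_patients = 40, n_multi_patients = 0,
                    snv_gene_panel = c(SETD2 = 0.62, PBRM1 = 0.57, VHL = 0.36,
                                       EGFR = 0.6),
                    pretreated_vaf_shift = list(gene = "EGFR", delta = 0.3),
                    purity_range = c(0.4, 0.9), rng_seed = 41)
  co <- emit_cohort(cfg)
  res <- suppressMessages(run_pipeline(co, run_config(rng_seed = 23)))
  cmp <- res$comparisons
  q_egfr <- cmp$q[cmp$metric == "vaf_EGFR"]
  expect_lt(q_egfr, 0.05)
  others <- cmp$q[grepl("^vaf_", cmp$metric) & cmp$metric != "vaf_EGFR"]
  expect_gt(mean(others >= 0.05, na.rm = TRUE), 0.7)
})
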