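#' Synthetic exome capture design
#'
#' A reduced exome used by the cohort simulator: chromosomes 1..22 and X,
#' each with six cytobands (p25, p21, p11, q11, q14, q25) of 10 capture
#' regions of 500 bp.  Known ccRCC genes sit at their approximate real
#' bands (VHL 3p25, SETD2/PBRM1 3p21, CDKN1A 6p21, CDKN2A 9p21, RB1 13q14,
#' APC 5q, KDM5C/RBM10 Xp11, ...); remaining regions carry filler gene
#' symbols.  Coordinates are synthetic.
#'
#' @param regions_per_band capture regions per cytoband.
#' @return `synthetic_capture_regions()`: data frame with columns
#'   `chrom, start, end, gene, cytoband`; `synthetic_cytobands()`: cytoband
#'   table with columns `chrom, start, end, band`.
#' @export
synthetic_capture_regions <- function(regions_per_band = 10) {
  bands <- c("p25", "p21", "p11", "q11", "q14", "q25")
  chroms <- c(as.character(1:22), "X")
  band_bp <- 1e6
  rows <- list()
  for (ch in chroms) {
    for (b in seq_along(bands)) {
      band_start <- (b - 1) * band_bp
      i <- seq_len(regions_per_band)
      start <- band_start + (i - 1) * 50000
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = start, end = start + 500,
        gene = paste0("G", ch, "_", bands[b], "_", i),
        cytoband = paste0(ch, bands[b]),
        stringsAsFactors = FALSE
      )
    }
  }
  reg <- do.call(rbind, rows)
  panel <- c(VHL = "3p25", SETD2 = "3p21", PBRM1 = "3p21", TRAK1 = "3p21",
             BAP1 = "3p21", APC = "5q14", CDKN1A = "6p21", EGFR = "7p11",
             CDKN2A = "9p21", PTEN = "10q25", RB1 = "13q14", HIF1A = "14q25",
             TP53 = "17p11", FBXW7 = "4q25", KDM5C = "Xp11", RBM10 = "Xp11")
  used <- integer(0)
  for (g in names(panel)) {
    idx <- setdiff(which(reg$cytoband == panel[[g]]), used)
    reg$gene[idx[1]] <- g
    used <- c(used, idx[1])
  }
  sort_karyotypic(reg)
}

#' @rdname synthetic_capture_regions
#' @export
synthetic_cytobands <- function() {
  bands <- c("p25", "p21", "p11", "q11", "q14", "q25")
  chroms <- c(as.character(1:22), "X")
  band_bp <- 1e6
  out <- expand.grid(b = seq_along(bands), chrom = chroms,
                     stringsAsFactors = FALSE)
  data.frame(chrom = out$chrom,
             start = (out$b - 1) * band_bp,
             end = out$b * band_bp,
             band = paste0(out$chrom, bands[out$b]),
             stringsAsFactors = FALSE)
}

# bands making up the arm that contains a named band ("3p25" -> 3p25,3p21,3p11)
arm_bands <- function(band) {
  m <- regmatches(band, regexec("^([0-9XY]+)([pq])", band))[[1]]
  if (length(m) < 3) stop("cannot parse cytoband label: ", band)
  paste0(m[2], m[3], c("25", "21", "11")[if (m[3] == "p") 1:3 else 3:1])
}

#' Simulation configuration
#'
#' Defaults emulate the published metastatic ccRCC cohort: 44 patients and
#' about 68 samples (13 patients with 2-4 samples), tumour purity uniform
#' on 0.2-0.9, mean region depth 100x, driver copy-number event
#' probabilities equal to the printed per-patient prevalences (3p25 loss
#' 36/44, 9p21 loss 30/44, 14q25 loss 17/44, 6p21 loss 18/44, 13q14 loss
#' 23/44, 5q gain 21/44) and gene-panel mutation probabilities equal to the
#' printed frequencies (SETD2 0.62, PBRM1 0.57, APC 0.43, VHL 0.36, KDM5C
#' 0.31, HIF1A 0.24, RBM10 0.21, FBXW7 0.19, TRAK1 0.16, EGFR 0.09).
#' Copy-number events span the chromosome arm containing the named band,
#' as ccRCC losses at 3p/9p/14q are typically arm-scale.
#'
#' @param n_patients number of patients.
#' @param n_multi_patients patients receiving 2-4 samples (the rest get 1).
#' @param multi_sample_probs probabilities of 2, 3, 4 samples for a
#'   multi-sample patient.
#' @param purity_range uniform range of true tumour purity.
#' @param mean_region_depth mean reads per capture region (and per variant
#'   locus).
#' @param coverage_dispersion negative-binomial size parameter for read
#'   counts (smaller = more overdispersed).
#' @param n_truncal_snvs,n_branch_snvs,n_private_snvs Poisson means of SNV
#'   counts on the trunk, internal branches and leaf edges.
#' @param n_subclonal_snvs Poisson mean of low-clonality private SNVs per
#'   sample (clonality uniform 0.1-0.3; exercises the COSMIC rescue arm).
#' @param n_germline_leak Poisson mean of germline heterozygous variants
#'   leaking into the tumour table per sample (present in the normal).
#' @param driver_cnv_menu data frame `cytoband, event, prob`; event is one
#'   of loss, deletion, gain, amplification; drawn per patient, truncal.
#' @param snv_gene_panel named numeric vector of per-gene truncal driver
#'   mutation probabilities.
#' @param vhl_truncal_prob probability that the trunk is forced to carry a
#'   VHL-pathway event (VHL mutation added when neither a VHL mutation nor
#'   a 3p loss was drawn).
#' @param pretreated_fraction probability a sample is post-therapy.
#' @param pretreated_vaf_shift optional `list(gene=, delta=)`: adds `delta`
#'   to the expected VAF of that gene's mutations in pretreated samples
#'   (a planted treatment effect for power checks).
#' @param variant_error_rate sequencing error rate used for alt reads in
#'   the normal and in samples not carrying a variant.
#' @param n_het_snps germline heterozygous SNPs assayed per sample.
#' @param primary_fraction probability a sample is labelled primary.
#' @param rng_seed seed for [emit_cohort()].
#' @return a list of class `rcc_sim_config`.
#' @export
sim_config <- function(n_patients = 44,
                       n_multi_patients = 13,
                       multi_sample_probs = c(0.40, 0.35, 0.25),
                       purity_range = c(0.2, 0.9),
                       mean_region_depth = 100,
                       coverage_dispersion = 100,
                       n_truncal_snvs = 50,
                       n_branch_snvs = 15,
                       n_private_snvs = 10,
                       n_subclonal_snvs = 4,
                       n_germline_leak = 5,
                       driver_cnv_menu = NULL,
                       snv_gene_panel = NULL,
                       vhl_truncal_prob = 0.9,
                       pretreated_fraction = 38 / 68,
                       pretreated_vaf_shift = NULL,
                       variant_error_rate = 0.002,
                       n_het_snps = 334,
                       primary_fraction = 14 / 68,
                       rng_seed = 1L) {
  if (is.null(driver_cnv_menu)) {
    driver_cnv_menu <- data.frame(
      cytoband = c("3p25", "9p21", "14q25", "6p21", "13q14", "5q14"),
      event = c("loss", "loss", "loss", "loss", "loss", "gain"),
      prob = c(36, 30, 17, 18, 23, 21) / 44,
      stringsAsFactors = FALSE
    )
  }
  if (is.null(snv_gene_panel)) {
    snv_gene_panel <- c(SETD2 = 0.62, PBRM1 = 0.57, APC = 0.43, VHL = 0.36,
                        KDM5C = 0.31, HIF1A = 0.24, RBM10 = 0.21,
                        FBXW7 = 0.19, TRAK1 = 0.16, EGFR = 0.09)
  }
  stopifnot(all(driver_cnv_menu$prob >= 0 & driver_cnv_menu$prob <= 1),
            all(snv_gene_panel >= 0 & snv_gene_panel <= 1),
            mean_region_depth > 0,
            n_multi_patients <= n_patients)
  structure(list(
    n_patients = n_patients,
    n_multi_patients = n_multi_patients,
    multi_sample_probs = multi_sample_probs,
    purity_range = purity_range,
    mean_region_depth = mean_region_depth,
    coverage_dispersion = coverage_dispersion,
    n_truncal_snvs = n_truncal_snvs,
    n_branch_snvs = n_branch_snvs,
    n_private_snvs = n_private_snvs,
    n_subclonal_snvs = n_subclonal_snvs,
    n_germline_leak = n_germline_leak,
    driver_cnv_menu = driver_cnv_menu,
    snv_gene_panel = snv_gene_panel,
    vhl_truncal_prob = vhl_truncal_prob,
    pretreated_fraction = pretreated_fraction,
    pretreated_vaf_shift = pretreated_vaf_shift,
    variant_error_rate = variant_error_rate,
    n_het_snps = n_het_snps,
    primary_fraction = primary_fraction,
    rng_seed = as.integer(rng_seed)
  ), class = "rcc_sim_config")
}

cn_for_event <- function(event) {
  switch(event, loss = 1L, deletion = 0L, gain = 3L, amplification = 5L,
         stop("unknown CNV event: ", event))
}

#' Simulate a patient's clonal sample tree
#'
#' Draws a random rooted tree over `n_samples` tumour samples (germline at
#' the root) by recursive random bipartition, then assigns Poisson SNV
#' counts: truncal SNVs shared by all samples, branch SNVs by the subtree
#' below an internal edge, private SNVs by one sample.  A single-sample
#' patient gets one edge carrying truncal plus private SNVs.
#'
#' @param n_samples number of tumour samples (>= 1).
#' @param sample_ids leaf names (default S1..Sn).
#' @param config an [sim_config()] providing the Poisson means.
#' @return a list with `tree` (an [rcc_tree()] whose edge lengths are the
#'   drawn SNV counts) and `edge_samples` (list of the sample set below
#'   each edge, parallel to `tree$edges`).
#' @export
simulate_patient_tree <- function(n_samples,
                                  sample_ids = paste0("S", seq_len(n_samples)),
                                  config = sim_config()) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  stopifnot(length(sample_ids) == n_samples)
  counter <- 0L
  edges <- data.frame(parent = character(0), child = character(0),
                      length = numeric(0), stringsAsFactors = FALSE)
  edge_samples <- list()
  add_edge <- function(parent, child, length, samples) {
    edges <<- rbind(edges, data.frame(parent = parent, child = child,
                                      length = length, stringsAsFactors = FALSE))
    edge_samples[[nrow(edges)]] <<- samples
  }
  descend <- function(parent, set) {
    if (length(set) == 1) {
      add_edge(parent, set, stats::rpois(1, config$n_private_snvs), set)
      return(invisible())
    }
    # random bipartition, both sides non-empty
    repeat {
      side <- stats::rbinom(length(set), 1, 0.5)
      if (any(side == 0) && any(side == 1)) break
    }
    for (s in 0:1) {
      part <- set[side == s]
      if (length(part) == 1) {
        add_edge(parent, part, stats::rpois(1, config$n_private_snvs), part)
      } else {
        counter <<- counter + 1L
        node <- paste0(parent, ".", counter)
        add_edge(parent, node, stats::rpois(1, config$n_branch_snvs), part)
        descend(node, part)
      }
    }
  }
  if (n_samples == 1) {
    n <- stats::rpois(1, config$n_truncal_snvs) +
      stats::rpois(1, config$n_private_snvs)
    add_edge("germline", sample_ids, n, sample_ids)
  } else {
    trunk <- "MRCA"
    add_edge("germline", trunk, stats::rpois(1, config$n_truncal_snvs),
             sample_ids)
    descend(trunk, sample_ids)
  }
  list(tree = rcc_tree(edges, sample_ids), edge_samples = edge_samples)
}

#' Simulate paired tumour/normal coverage for one sample
#'
#' Normal read counts are negative binomial around the target depth; tumour
#' counts are negative binomial around depth times the admixture ratio
#' (purity * CN + 2 * (1 - purity)) / 2 for the region's true copy number.
#'
#' @param regions capture-region table (see [synthetic_capture_regions()]).
#' @param true_segments data frame `chrom, start, end, cn` of non-neutral
#'   true segments (regions outside them are CN 2).
#' @param purity true tumour purity in (0, 1].
#' @param depth mean reads per region.
#' @param dispersion negative-binomial size.
#' @return the `regions` table with `tumor_reads` and `normal_reads` added.
#' @export
simulate_coverage <- function(regions, true_segments, purity,
                              depth = 100, dispersion = 100) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  cn <- region_true_cn(regions, true_segments)
  ratio <- (purity * cn + 2 * (1 - purity)) / 2
  regions$normal_reads <- stats::rnbinom(nrow(regions), mu = depth,
                                         size = dispersion)
  regions$tumor_reads <- stats::rnbinom(nrow(regions), mu = depth * ratio,
                                        size = dispersion)
  regions
}

# integer true CN per region (default 2 outside any true segment)
region_true_cn <- function(regions, true_segments) {
  cn <- rep(2L, nrow(regions))
  if (is.null(true_segments) || !nrow(true_segments)) return(cn)
  hits <- overlap_pairs(regions, true_segments)
  if (nrow(hits)) cn[hits$query_idx] <- as.integer(true_segments$cn[hits$subject_idx])
  cn
}

#' Simulate read support for one variant
#'
#' Tumour alt reads are binomial at the admixture-expected VAF
#' `clonality * purity * multiplicity / (purity * cn + 2 * (1 - purity))`;
#' normal alt reads are binomial at the sequencing error rate.
#'
#' @param clonality fraction of tumour cells carrying the variant.
#' @param purity tumour purity in (0, 1].
#' @param local_cn tumour copy number at the locus.
#' @param multiplicity mutated copies per carrying cell (<= local_cn).
#' @param tumor_depth,normal_depth total reads at the locus.
#' @param error_rate normal-sample sequencing error rate.
#' @return data frame with tumour/normal ref and alt read counts and the
#'   expected VAF used.
#' @export
simulate_variant_reads <- function(clonality, purity, local_cn,
                                   multiplicity = 1, tumor_depth = 100,
                                   normal_depth = 100, error_rate = 0.002) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  if (any(multiplicity > local_cn)) stop("multiplicity cannot exceed local_cn")
  n <- max(length(clonality), length(local_cn), length(tumor_depth))
  clonality <- rep_len(clonality, n); local_cn <- rep_len(local_cn, n)
  multiplicity <- rep_len(multiplicity, n)
  tumor_depth <- rep_len(tumor_depth, n); normal_depth <- rep_len(normal_depth, n)
  denom <- purity * local_cn + 2 * (1 - purity)
  vaf <- ifelse(denom > 0, clonality * purity * multiplicity / denom, 0)
  vaf <- pmin(pmax(vaf, 0), 1)
  # a sequencing-error floor keeps absent variants occasionally visible
  p_obs <- pmax(vaf, error_rate)
  alt <- stats::rbinom(n, tumor_depth, p_obs)
  nalt <- stats::rbinom(n, normal_depth, error_rate)
  data.frame(tumor_ref_reads = tumor_depth - alt, tumor_alt_reads = alt,
             normal_ref_reads = normal_depth - nalt, normal_alt_reads = nalt,
             expected_vaf = vaf)
}

#' Simulate a heterozygous-SNP allelic-fraction table for one sample
#'
#' SNPs are placed uniformly over the capture regions.  The normal allelic
#' fraction is binomial around 0.5; the tumour fraction is binomial around
#' the allele-mixture expectation for the overlying true segment: with alt
#' allele copies `a` out of copy number `cn`, the expectation is
#' `(purity * a + (1 - purity)) / (purity * cn + 2 * (1 - purity))` (the
#' retained allele of a one-copy loss gives `1 / (2 - purity)`, the lost
#' allele `(1 - purity) / (2 - purity)`).
#'
#' @inheritParams simulate_coverage
#' @param n_snps number of SNPs (the assay uses 334).
#' @return het-SNP data frame (see [read_het_snp_table()]).
#' @export
simulate_het_snps <- function(regions, true_segments, purity, n_snps = 334,
                              depth = 100, dispersion = 100) {
  if (purity <= 0 || purity > 1) stop("purity must be in (0, 1]")
  idx <- sample.int(nrow(regions), n_snps, replace = TRUE)
  pos <- regions$start[idx] +
    sample.int(500, n_snps, replace = TRUE)  # 1-based inside the region
  cn <- region_true_cn(regions[idx, , drop = FALSE], true_segments)
  # alt-allele copy count in the tumour: each parental allele equally likely
  # to be the one duplicated/retained
  a <- vapply(cn, function(k) {
    if (k == 2L) 1L
    else if (k == 1L) sample(c(0L, 1L), 1)
    else if (k == 0L) 0L
    else sample(c(k - 1L, 1L), 1)  # one allele gained the extra copies
  }, integer(1))
  denom <- purity * cn + 2 * (1 - purity)
  tumor_expect <- ifelse(denom > 0, (purity * a + (1 - purity)) / denom, 0.5)
  tumor_depth <- stats::rnbinom(n_snps, mu = depth, size = dispersion)
  normal_depth <- stats::rnbinom(n_snps, mu = depth, size = dispersion)
  tumor_depth <- pmax(tumor_depth, 1L)
  normal_depth <- pmax(normal_depth, 1L)
  df <- data.frame(
    chrom = regions$chrom[idx],
    pos = pos,
    normal_alt_fraction = stats::rbinom(n_snps, normal_depth, 0.5) / normal_depth,
    tumor_alt_fraction = stats::rbinom(n_snps, tumor_depth, tumor_expect) / tumor_depth,
    tumor_depth = tumor_depth,
    normal_depth = normal_depth,
    stringsAsFactors = FALSE
  )
  sort_karyotypic(df)
}
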