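.bases <- c("A", "C", "G", "T")

draw_effect <- function(n, driver = FALSE) {
  if (driver) {
    # ccRCC tumour suppressors carry a high truncating fraction
    probs <- c(missense = 0.40, nonsense = 0.25, frameshift_indel = 0.20,
               splice = 0.10, inframe_indel = 0.05, synonymous = 0)
  } else {
    probs <- c(missense = 0.55, synonymous = 0.20, nonsense = 0.07,
               frameshift_indel = 0.07, inframe_indel = 0.04, splice = 0.07)
  }
  sample(names(probs), n, replace = TRUE, prob = probs)
}

new_snv_records <- function(n, regions, region_idx = NULL, gene = NULL,
                            driver = FALSE) {
  if (n == 0) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      gene = character(0), effect = character(0),
                      cosmic_count = integer(0), stringsAsFactors = FALSE))
  }
  if (is.null(region_idx)) region_idx <- sample.int(nrow(regions), n, replace = TRUE)
  ref <- sample(.bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1), character(1))
  eff <- draw_effect(n, driver)
  ins <- eff %in% c("frameshift_indel", "inframe_indel")
  alt[ins] <- paste0(ref[ins], sample(.bases, sum(ins), replace = TRUE))
  cosmic <- if (driver) 10L + stats::rpois(n, 40) else {
    ifelse(stats::runif(n) < 0.05, stats::rpois(n, 3), 0L)
  }
  data.frame(
    chrom = regions$chrom[region_idx],
    pos = regions$start[region_idx] + sample.int(500, n, replace = TRUE),
    ref = ref, alt = unname(alt), gene = if (is.null(gene))
      regions$gene[region_idx] else gene,
    effect = eff, cosmic_count = as.integer(cosmic),
    stringsAsFactors = FALSE
  )
}

variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

# truncal copy-number segments for one patient from the drawn menu events;
# each event covers the whole arm containing the named band
patient_true_segments <- function(events, cytobands) {
  if (!nrow(events)) {
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cn = integer(0),
                      stringsAsFactors = FALSE))
  }
  segs <- lapply(seq_len(nrow(events)), function(i) {
    bands <- arm_bands(events$cytoband[i])
    rows <- cytobands[cytobands$band %in% bands, , drop = FALSE]
    data.frame(chrom = rows$chrom[1], start = min(rows$start),
               end = max(rows$end), cn = cn_for_event(events$event[i]),
               stringsAsFactors = FALSE)
  })
  sort_karyotypic(do.call(rbind, segs))
}

#' Generate a full synthetic cohort
#'
#' Draws, per patient, a clonal sample tree, truncal driver mutations from
#' the gene panel, truncal arm-scale copy-number events from the CNV menu,
#' and per sample a purity, paired coverage, a het-SNP table and a MAF-like
#' variant table with binomial read sampling, all under one seed.  Ground
#' truth (purity, segments, per-variant clonality, tree) is kept alongside
#' for recovery tests.
#'
#' @param config an [sim_config()].
#' @param out_dir optional directory; when given, all tables are written as
#'   the pipeline's file formats plus `truth.json`.
#' @return an `rcc_cohort` list: `config`, `regions`, `cytobands`, `meta`,
#'   and named-by-sample lists `coverage`, `snps`, `variants`, plus
#'   `cosmic` (lookup table) and `truth`.
#' @export
emit_cohort <- function(config = sim_config(), out_dir = NULL) {
  set.seed(config$rng_seed)
  regions <- synthetic_capture_regions()
  cytobands <- synthetic_cytobands()
  meta <- data.frame(sample_id = character(0), patient_id = character(0),
                     site = character(0), pretreated = logical(0),
                     tissue_type = character(0), stringsAsFactors = FALSE)
  coverage <- list(); snps <- list(); variants <- list()
  truth <- list(patients = list(), samples = list())
  met_sites <- c("lung", "bone", "lymph_node", "brain", "soft_tissue",
                 "liver", "adrenal")
  shift <- config$pretreated_vaf_shift

  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%02d", p)
    n_s <- if (p <= config$n_multi_patients) {
      sample(2:4, 1, prob = config$multi_sample_probs)
    } else 1L
    sample_ids <- sprintf("%s_T%d", pid, seq_len(n_s))
    sim <- simulate_patient_tree(n_s, sample_ids, config)
    tree <- sim$tree; edge_samples <- sim$edge_samples

    # truncal copy-number events
    take <- stats::runif(nrow(config$driver_cnv_menu)) < config$driver_cnv_menu$prob
    events <- config$driver_cnv_menu[take, , drop = FALSE]
    segs <- patient_true_segments(events, cytobands)

    # truncal driver mutations; the VHL-pathway trunk rule
    panel <- config$snv_gene_panel
    hit <- names(panel)[stats::runif(length(panel)) < panel]
    if (stats::runif(1) < config$vhl_truncal_prob &&
        !"VHL" %in% hit && !"3p25" %in% events$cytoband) {
      hit <- c(hit, "VHL")
    }
    trunk_edge <- which(vapply(edge_samples, function(s)
      length(s) == n_s, logical(1)))[1]

    # passenger SNVs per edge, then drivers appended to the trunk
    snv_tab <- list(); snv_edge <- integer(0)
    for (e in seq_len(nrow(tree$edges))) {
      recs <- new_snv_records(tree$edges$length[e], regions)
      snv_tab[[e]] <- recs
      snv_edge <- c(snv_edge, rep(e, nrow(recs)))
    }
    if (length(hit)) {
      ridx <- match(hit, regions$gene)
      drecs <- new_snv_records(length(hit), regions, region_idx = ridx,
                               gene = hit, driver = TRUE)
      snv_tab[[length(snv_tab) + 1]] <- drecs
      snv_edge <- c(snv_edge, rep(trunk_edge, nrow(drecs)))
      tree$edges$length[trunk_edge] <- tree$edges$length[trunk_edge] + nrow(drecs)
    }
    snvs <- do.call(rbind, snv_tab)
    # unique keys within the patient
    if (nrow(snvs)) {
      for (tries in 1:100) {
        dup <- duplicated(variant_key(snvs))
        if (!any(dup)) break
        snvs$pos[dup] <- snvs$pos[dup] + sample.int(400, sum(dup), replace = TRUE)
      }
      rownames(snvs) <- NULL
    }
    per_edge_keys <- split(variant_key(snvs), factor(snv_edge, levels = seq_along(edge_samples)))
    tree$edges$snvs <- unname(per_edge_keys)

    truth$patients[[pid]] <- list(
      tree = tree, edge_samples = edge_samples, drivers = hit,
      cnv_events = events, segments = segs
    )

    for (si in seq_len(n_s)) {
      sid <- sample_ids[si]
      purity <- stats::runif(1, config$purity_range[1], config$purity_range[2])
      pretreated <- stats::runif(1) < config$pretreated_fraction
      primary <- stats::runif(1) < config$primary_fraction
      meta <- rbind(meta, data.frame(
        sample_id = sid, patient_id = pid,
        site = if (primary) "kidney" else sample(met_sites, 1),
        pretreated = pretreated,
        tissue_type = if (primary) "primary" else "metastasis",
        stringsAsFactors = FALSE
      ))

      coverage[[sid]] <- simulate_coverage(regions, segs, purity,
                                           config$mean_region_depth,
                                           config$coverage_dispersion)
      snps[[sid]] <- simulate_het_snps(regions, segs, purity,
                                       config$n_het_snps,
                                       config$mean_region_depth,
                                       config$coverage_dispersion)

      # clonality of each patient SNV in this sample: 1 on the root path
      carried <- vapply(seq_len(nrow(snvs)), function(i)
        sid %in% edge_samples[[snv_edge[i]]], logical(1))
      clon <- as.numeric(carried)
      vtab <- snvs
      # private subclonal SNVs (low clonality; exercises COSMIC rescue)
      n_sub <- stats::rpois(1, config$n_subclonal_snvs)
      if (n_sub) {
        sub <- new_snv_records(n_sub, regions)
        sub$cosmic_count <- ifelse(stats::runif(n_sub) < 0.5,
                                   10L + stats::rpois(n_sub, 20), 0L)
        vtab <- rbind(vtab, sub)
        clon <- c(clon, stats::runif(n_sub, 0.1, 0.3))
      }
      cn <- region_true_cn(
        data.frame(chrom = vtab$chrom, start = vtab$pos - 1, end = vtab$pos),
        segs)
      mult <- pmin(1L, cn)
      clon_eff <- clon
      if (!is.null(shift) && pretreated) {
        sel <- vtab$gene == shift$gene & clon > 0
        denom <- purity * cn[sel] + 2 * (1 - purity)
        clon_eff[sel] <- clon[sel] + shift$delta * denom / (purity * pmax(mult[sel], 1))
      }
      tdepth <- pmax(stats::rnbinom(nrow(vtab), mu = config$mean_region_depth,
                                    size = config$coverage_dispersion), 1L)
      ndepth <- pmax(stats::rnbinom(nrow(vtab), mu = config$mean_region_depth,
                                    size = config$coverage_dispersion), 1L)
      reads <- simulate_variant_reads(clon_eff, purity, cn, mult, tdepth,
                                      ndepth, config$variant_error_rate)
      vtab <- cbind(vtab, reads[, 1:4])
      # germline heterozygous variants leaking into the tumour table
      n_leak <- stats::rpois(1, config$n_germline_leak)
      if (n_leak) {
        leak <- new_snv_records(n_leak, regions)
        ld <- pmax(stats::rnbinom(2 * n_leak, mu = config$mean_region_depth,
                                  size = config$coverage_dispersion), 1L)
        lt <- ld[seq_len(n_leak)]; ln <- ld[n_leak + seq_len(n_leak)]
        lalt <- stats::rbinom(n_leak, lt, 0.5)
        lnalt <- stats::rbinom(n_leak, ln, 0.5)
        leak$tumor_ref_reads <- lt - lalt; leak$tumor_alt_reads <- lalt
        leak$normal_ref_reads <- ln - lnalt; leak$normal_alt_reads <- lnalt
        vtab <- rbind(vtab, leak)
        clon <- c(clon, rep(NA_real_, n_leak))
      }
      tot <- vtab$tumor_ref_reads + vtab$tumor_alt_reads
      vtab$vaf_raw <- ifelse(tot > 0, vtab$tumor_alt_reads / tot, 0)
      vtab <- vtab[, c("chrom", "pos", "ref", "alt", "gene", "effect",
                       "tumor_ref_reads", "tumor_alt_reads",
                       "normal_ref_reads", "normal_alt_reads",
                       "cosmic_count", "vaf_raw")]
      key_order <- order(chrom_rank(vtab$chrom), vtab$pos)
      variants[[sid]] <- `rownames<-`(vtab[key_order, , drop = FALSE], NULL)
      truth$samples[[sid]] <- list(
        purity = purity, segments = segs,
        clonality = stats::setNames(clon[key_order], variant_key(vtab)[key_order]),
        n_tree_snvs = nrow(snvs)
      )
    }
  }

  cosmic <- if (length(variants)) {
    all_v <- do.call(rbind, lapply(variants, function(v)
      v[, c("chrom", "pos", "ref", "alt", "cosmic_count")]))
    unique(all_v[all_v$cosmic_count > 0, , drop = FALSE])
  } else {
    data.frame(chrom = character(0), pos = integer(0), ref = character(0),
               alt = character(0), cosmic_count = integer(0))
  }
  rownames(cosmic) <- NULL

  cohort <- structure(list(config = config, regions = regions,
                           cytobands = cytobands, meta = meta,
                           coverage = coverage, snps = snps,
                           variants = variants, cosmic = cosmic,
                           truth = truth),
                      class = "rcc_cohort")
  if (!is.null(out_dir)) write_cohort_dir(cohort, out_dir)
  cohort
}

#' Write / read a cohort directory
#'
#' The on-disk layout is one TSV per sample for coverage, het SNPs and
#' variants, plus `meta.tsv`, `cytobands.bed`, `cosmic_counts.tsv` and
#' (for simulated cohorts) `truth.json` with the per-sample purity, the
#' per-patient tree in Newick form and the planted segment table.
#'
#' @param cohort an `rcc_cohort`.
#' @param dir directory (created if needed).
#' @return `write_cohort_dir()` the directory invisibly;
#'   `read_cohort_dir()` an `rcc_cohort` (without truth).
#' @export
write_cohort_dir <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(df, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  wt(cohort$meta, "meta.tsv")
  utils::write.table(cohort$cytobands, file.path(dir, "cytobands.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  wt(cohort$cosmic, "cosmic_counts.tsv")
  for (sid in names(cohort$coverage)) {
    wt(cohort$coverage[[sid]], paste0("coverage_", sid, ".tsv"))
    wt(cohort$snps[[sid]], paste0("snps_", sid, ".tsv"))
    wt(cohort$variants[[sid]], paste0("variants_", sid, ".tsv"))
  }
  truth_json <- list(
    samples = lapply(cohort$truth$samples, function(s) list(
      purity = s$purity, segments = s$segments,
      clonality = as.list(s$clonality), n_tree_snvs = s$n_tree_snvs)),
    patients = lapply(cohort$truth$patients, function(p) list(
      newick = write_newick(p$tree), drivers = p$drivers,
      cnv_events = p$cnv_events, segments = p$segments))
  )
  jsonlite::write_json(truth_json, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @rdname write_cohort_dir
#' @export
read_cohort_dir <- function(dir) {
  meta <- read_sample_meta(file.path(dir, "meta.tsv"))
  cytobands <- read_cytoband_bed(file.path(dir, "cytobands.bed"))
  cosmic <- read_cosmic_counts(file.path(dir, "cosmic_counts.tsv"))
  coverage <- list(); snps <- list(); variants <- list()
  for (sid in meta$sample_id) {
    coverage[[sid]] <- read_coverage_table(file.path(dir, paste0("coverage_", sid, ".tsv")))
    snps[[sid]] <- read_het_snp_table(file.path(dir, paste0("snps_", sid, ".tsv")))
    variants[[sid]] <- read_variant_table(file.path(dir, paste0("variants_", sid, ".tsv")))
  }
  regions <- if (length(coverage)) {
    coverage[[1]][, c("chrom", "start", "end", "gene", "cytoband")]
  } else synthetic_capture_regions()
  structure(list(config = NULL, regions = regions, cytobands = cytobands,
                 meta = meta, coverage = coverage, snps = snps,
                 variants = variants, cosmic = cosmic, truth = NULL),
            class = "rcc_cohort")
}
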