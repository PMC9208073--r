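Package: ccrccwes
Title: Downstream Whole-Exome Analysis of Metastatic Clear Cell Renal Cell Carcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for the downstream analysis of paired
    tumour/normal whole-exome sequencing in metastatic clear cell renal
    cell carcinoma: tumour-purity estimation from heterozygous-SNP allelic
    imbalance, purity-corrected somatic variant filtering with a COSMIC
    rescue rule, tumour mutational burden, copy-number calling with
    circular binary segmentation and cytoband-level cohort recurrence,
    clonality-based multi-sample phylogenies, and cohort-level contrasts
    between therapy-naive and pretreated samples.  A synthetic-cohort
    generator with known ground truth makes every stage testable without
    external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
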