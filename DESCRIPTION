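Package: gsmscreen
Title: Screening Genes with Genotype-Specific DNA Methylation by
    PCA-Based Unsupervised Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements a screening pipeline for genes whose DNA
    methylation depends on genotype in squamous cell carcinoma.  Paired
    probe-by-sample genotype and methylation SNP-array matrices over
    blood, normal-tissue and tumor samples are decomposed by (by default
    uncentered) singular value decomposition; principal components that
    separate the three tissue classes are identified by a one-way F
    statistic on sample loadings, top outlier probes are selected along
    the chosen axis in each modality, and the cross-modality
    intersection is scored with an upper-tail hypergeometric overlap
    test, filtered by three pairwise one-sided Welch t-tests with
    false-discovery-rate control, and checked for a systematic
    genotype-minus-methylation intensity bias against a resampling null.
    Comparison feature selectors (Pearson, Spearman, partial least
    squares), drug-screening statistics (Tanimoto fingerprint filtering,
    expected overlap of top-k ranked lists across repeated scoring
    trials) and a synthetic paired-data generator with planted
    class-ordered signal complete the toolkit.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    mixOmics
Config/testthat/edition: 3
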