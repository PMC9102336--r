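Package: funcblup
Title: Two-Stage SNP-BLUP and Gene-Set Association for Deregressed Proofs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-SNP mixed-model association (SNP-BLUP with a residual
    polygenic effect, solved through Henderson's mixed-model equations) for
    deregressed proofs weighted by effective daughter contributions,
    followed by a second mixed model that estimates gene-ontology and
    pathway effects from absolute SNP effects using a term-overlap
    covariance matrix. Includes pedigree relationship-matrix construction
    with inbreeding, genotype quality control, Wald tests with Bonferroni
    correction, the genomic inflation factor, SNP-to-gene interval
    annotation, and a synthetic-data generator for pedigrees, genotypes,
    annotations, and phenotypes with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    fgsea,
    vcfR
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
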