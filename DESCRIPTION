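Package: kinsnp
Title: Kinship Inference Workbench for Medium-Density Forensic SNP Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating pairwise kinship inference on medium-density
    (~10,000 marker) autosomal SNP panels of the kind used in forensic
    investigative genetic genealogy. Provides two identity-by-descent (IBD)
    segment detectors (a genotype-concordance run scan with SNP-informativity
    filtering, and a sliding-window kinship-coefficient scan with purity
    filtering), five kinship classifiers (mean total segment length, gamma
    segment-length profiles, conditional probability of relationship given
    total sharing, IBD0 proportion, and the robust kinship coefficient),
    exploratory PCA/PCoA pair embeddings, a gene-dropping pedigree simulator
    with Poisson recombination for generating truth-annotated sample pairs,
    and an evaluation harness (degree-level accuracy, confusion matrices,
    margin-sweep ROC/AUROC).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    IRanges,
    vcfR,
    fitdistrplus,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
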