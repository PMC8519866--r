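Package: ibdqtl
Title: IBD-Based Mixed-Model QTL Mapping for Multiparental Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A unified identity-by-descent (IBD) based mixed-model framework
    for quantitative trait locus (QTL) mapping in multiparental populations
    (diallel, nested association mapping, and MAGIC designs). Founder-origin
    probabilities are reconstructed along the genome with a hidden Markov
    model and used as genetic predictors in a family of residual maximum
    likelihood (REML) mixed models that combine random parental QTL effects,
    composite-interval-mapping cofactors, a kinship-structured polygenic term
    with leave-one-chromosome-out correction, and family-specific residual
    variances. Includes a breeding-design simulator (Poisson crossovers,
    single-seed descent to F6), genome-scan orchestration with Bonferroni
    thresholds and iterative cofactor selection, BIC-based model selection,
    and a replication harness measuring mapping power, resolution, and
    false-positive behaviour.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
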