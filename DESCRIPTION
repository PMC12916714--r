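Package: regalign
Title: Regulatory Alignment Modelling for CRISPR-Cas Crop Edits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for modelling the regulatory status of CRISPR-Cas
    genome edits in crops across jurisdictions. Provides a formal edit
    calculus (edit application and interpretable featurization), a
    conjunctive rule DSL for jurisdictional compliance predicates and
    exemption contexts, a regulation-aware alignment network that embeds
    edits and regulatory descriptors in a shared latent space behind a
    symbolic exclusion gate, a constraint-aware policy-induction strategy
    for selecting edits under heterogeneous and drifting regimes, and a
    synthetic scenario generator with planted, recoverable ground truth
    for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    pROC,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
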