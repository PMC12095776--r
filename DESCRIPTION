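Package: gradr
Title: Gradient-Based Prediction of RNA-Protein Interactomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Predicts the protein interactome of every expressed RNA from a
    single set of gradient co-sedimentation (Grad-seq), RNA-binding-proteome
    (OOPS-MS) and subcellular-fractionation experiments. Co-sedimentation
    profiles across gradient fractions are correlated by Pearson r; candidate
    proteins are restricted to RNA-binding proteins (RNase +/- elution
    fold-change and t-test), to proteins detectable in the RNA's subcellular
    compartment and, for nuclear RNAs, to non-mitochondrial proteins. Also
    provides a BLAST-window lncRNA sequence-conservation score, spike-in
    normalisation for cytoplasm/nucleus RNA-seq, an expressed-RNA filter and
    a synthetic co-sedimentome simulator with planted ground truth for
    end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    ape
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
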