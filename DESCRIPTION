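Package: orthotransfer
Title: Quality-Gated Homology Transfer of Disorder Annotations to Orthologs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds ortholog-family multiple sequence alignments for proteins
    carrying curated intrinsically-disordered-region annotations (GO and IDPO
    terms), gates the alignments globally and per annotated region with
    identity filters and the NorMD alignment-quality objective, and projects
    region annotations from the reference protein onto the orthologs that
    survive both gates. Includes a greedy identity clusterer for reference
    redundancy removal, a deterministic builtin progressive aligner plus
    adapters for external aligners, a synthetic ortholog-family generator
    with controlled identities and ground truth, overlap-based internal
    validation, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    yaml,
    Rcpp,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
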