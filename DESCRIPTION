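Package: litwas
Title: Literature-Wide Association Studies from Concept Co-Occurrence Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for literature-wide association studies (LWAS) over
    abstract-level concept co-occurrence. Builds weighted concept profiles
    from a thesaurus-tagged document corpus using the symmetric uncertainty
    coefficient, scores implicit gene-disease associations as sparse profile
    inner products, decomposes scores into connecting-concept contributions,
    percentile-ranks associations, compares against external GWAS-style hit
    lists by fold enrichment, and publishes associations as nanopublications
    (TriG / N-Quads named graphs) and CSV. Includes a synthetic corpus
    generator with planted Swanson A-B-C bridge structure for end-to-end
    validation without a licensed literature corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    xml2,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'normalize.R'
    'thesaurus.R'
    'indexer.R'
    'profiles.R'
    'matching.R'
    'lwas.R'
    'hits.R'
    'nanopub.R'
    'synthcorpus.R'
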