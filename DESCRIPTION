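Package: mapforge
Title: Ad Hoc Assembly of Molecular Disease Maps for Rare Diseases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Construction of prototype molecular disease maps for rare
    diseases from file-backed knowledge sources.  Starting from an Orphanet
    identifier or a set of Human Phenotype Ontology terms, the package
    consolidates disease-associated genes and variants across association
    tables (Orphanet, DisGeNET-, OpenTargets- and ClinVar-style exports),
    filters variants by population allele frequency, identifies pathway
    diagrams enriched for the disease genes by hypergeometric
    over-representation, refines a scored text-mining interaction network
    with curated directed interactions and lays it out with the
    Fruchterman-Reingold algorithm, converts GPML, SBML layout+render and
    CellDesigner SBML diagrams into a common glyph-and-arc model, merges all
    components into a single CellDesigner SBML map on a mesh grid, and
    bundles the map with gene, variant and expression data overlays into a
    ZIP archive ready for upload to a visualization platform.  A
    deterministic synthetic-data generator produces complete offline input
    worlds with planted ground truth for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
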