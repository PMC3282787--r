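Package: irefkit
Title: Manipulate Consolidated Protein-Protein Interaction Data in the
    iRefIndex MITAB Dialect
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for working with consolidated protein-protein
    interaction data distributed in the iRefIndex dialect of the PSI-MI
    MITAB 2.6 tab-delimited format. Supports subset selection by
    interaction type, source database, protein, publication,
    experimental method, bibliometric score and taxon; redundancy
    resolution via ROGID/canonical-ROGID interactor keys and
    RIGID/canonical-RIGID interaction keys; interconversion among MITAB,
    complexList, edgeList and graph representations with explicit n-ary
    expansion policies (spoke, matrix, bipartite, exclude); detection of
    spoke-represented ("regenerated") protein complexes hidden in binary
    records; bibliometric scoring (np, lpr, hpr) and throughput
    classification; descriptive network summaries; and discrete
    power-law fitting of degree distributions with KS-minimizing xmin
    and a semiparametric bootstrap goodness-of-fit test. A deterministic
    synthetic-fixture generator with a complete ground-truth manifest
    makes every analysis testable without downloading any release file.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    digest,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml,
    pracma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
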