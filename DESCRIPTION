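Package: coaldisc
Title: Multispecies-Coalescent Simulation and Gene-Tree Discordance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting phylogenomic discordance in plant genomes:
    simulation of gene trees under the multispecies coalescent on a species
    tree (with optional hybridization edges and an organelle-tree sampler for
    cyto-nuclear scenarios), node-wise concordance/conflict accounting of gene
    trees against a reference tree, Robinson-Foulds distance-distribution
    comparison as a test of incomplete lineage sorting, and the post-hoc site
    filtering and supermatrix construction rules used in genome-skimming SNP
    pipelines (depth/quality/heterozygosity masking, missing-data column
    thresholds, invariant-site removal, concatenation with partition
    bookkeeping). A synthetic-data generator produces species trees, gene-tree
    sets, alignments and VCF-like site records with exactly known truth so the
    whole pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    vcfR
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
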