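Package: allodose
Title: Subgenome Dosage and Genome Composition Analysis for Young Allopolyploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Read-backed analysis of genome composition in recently formed
    allopolyploids from targeted capture sequencing. Starting from a
    multi-sample VCF with per-sample allele depths, the package applies
    depth and biallelic site filters, calls read-frequency genotype states,
    discovers SNPs reciprocally fixed between two parental taxa, estimates
    per-site and per-probe subgenome allele dosage in triploid and hexaploid
    hybrids, decomposes capture hybridization bias by reference-allele match,
    detects missing parental alleles and allele gain/loss between a triploid
    and its genome-doubled derivative, runs sliding-window allele-frequency
    difference scans along linkage groups, and reconstructs sample
    relationships with Nei's genetic distance, neighbor-joining trees with
    locus bootstrap, and principal component analysis, all implemented from
    first principles. A ground-truthed simulator of allopolyploid capture
    read counts (diploid x tetraploid parents, triploid bridge, doubled
    hexaploid, injected loss/conversion/gain events, reference-biased read
    sampling) makes every stage testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
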