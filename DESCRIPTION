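Package: pedhla
Title: Pedigree-Based HLA Allele Imputation via Weighted Haplotype
    Similarity Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers multi-allelic HLA gene types for untyped individuals
    from bi-allelic SNP genotypes of pedigrees together with the known HLA
    types of a reference subset. Pedigree haplotype configurations
    satisfying the Mendelian and zero-recombinant constraints are
    represented as a compact solution space over GF(2); a weighted
    haplotype-similarity graph with constraint edges is labeled with HLA
    alleles by a feasibility-preserving heuristic; haplotype configurations
    are selected incrementally by exhaustive enumeration or a genetic
    algorithm maximizing the within-label similarity; and unknown types are
    called from maximum-weight labeled neighbors. Includes PED-style
    readers and writers, a pedigree population simulator, and
    leave-one-out / leave-one-pedigree-out evaluation harnesses.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    methods,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
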