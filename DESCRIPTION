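Package: snprecomb
Title: Detection of Homologous Recombination Events from SNP Matrices and a
    Species Tree
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects homologous recombination events (HREs), mutations and
    sequencing errors across a set of closely related microbial genomes, given
    a SNP matrix with positional information and a rooted species tree.
    Genomes are first partitioned into locally collinear blocks under an
    agreement relation that tolerates missing loci, duplicated SNPs and contig
    breaks; within each block, internal-node alleles are inferred by weighted
    small parsimony, and a per-node dynamic program with affine out-group
    penalties decides whether each run of SNP alleles is inherited vertically
    (with mutations or errors) or horizontally from a non-descendant donor.
    Includes a branching-process simulator of trees, mutation/HRE/error/missing
    event streams with nullified-event bookkeeping, and a recall/precision
    benchmarking harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    phytools,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    optparse
Config/testthat/edition: 3
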