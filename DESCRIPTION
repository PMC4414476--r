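Package: hapdiv
Title: Haplotype-Block Diversity, Differentiation and Nucleus Selection
    for Admixed Livestock Populations
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Treats short phased haplotype blocks (four consecutive SNPs
    closer than 50 kb) as multi-allelic markers and computes per-breed
    diversity (allele counts, private/rare/common alleles, observed and
    expected heterozygosity, rarefaction allelic richness), Weir-Cockerham
    F-statistics, pairwise G_ST and Jost's D_EST combined across loci by a
    variance-corrected harmonic mean, Nei's D_A and proportion-of-shared-
    alleles distances, a principal-coordinates plus great-deluge 2D
    ordination, allele-frequency-standardized genomic relationships, a
    supervised admixture-fraction estimator, and a staged selection of a
    most-unrelated purebred nucleus for de-introgression of admixed
    populations.  Includes a synthetic multi-breed SNP panel generator with
    known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    ape
Config/testthat/edition: 3
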