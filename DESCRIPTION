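Package: fuzzyseed
Title: Fuzzy Seed Matching for Genomic Sequences via SimHash Seed Hashing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds both exact and approximate (fuzzy) seed matches between
    nucleotide sequences with a single hash-table lookup. Seeds are hashed
    with a locality-sensitive SimHash scheme over the hash values of their
    sub-k-mers (substitution-sensitive mode) or of strobemer-style linked
    k-mers (indel-tolerant mode), so that highly similar seeds receive the
    same hash value and collide in the index. Includes minimizer seeding,
    seed indexing with repeat filtering, co-linear anchor chaining into
    overlap/mapping records in PAF format, FASTA/FASTQ input, a read
    simulator with truth intervals, and evaluation utilities (collision
    histograms by edit distance, same-hash uplift experiments, overlap
    recall against simulated truth).
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    withr,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
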