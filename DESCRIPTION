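Package: darkbin
Title: Single-Sample Metagenome Deconvolution by Homology Filtering,
    Mixture-Model Binning and Composition-Based Contig Assignment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staged pipeline for separating bacterial genome bins from a
    host-contaminated shotgun metagenome assembly of a single sample, without
    differential-coverage information from replicate samples.  Contigs are
    classified taxonomically by windowed lowest-common-ancestor analysis of
    ORF homology hits followed by per-rank majority voting; non-bacterial
    contigs are removed; contigs shared with a second sample are split off by
    coverage; single-copy marker genes locate bin nuclei which are clustered
    in GC/coverage space by Gaussian mixture models with BIC model selection;
    remaining contigs are assigned by tetranucleotide composition on a
    toroidal self-organizing map; bins can be polished by iterative read
    recruitment and reassembly.  Includes per-bin completeness and redundancy
    scoring from single-copy markers, RPKMO expression normalization for
    metatranscriptome counts, 16S-identity novelty calling, and a fully
    ground-truthed synthetic community generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    mclust,
    data.table,
    jsonlite,
    yaml,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
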