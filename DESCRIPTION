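Package: amplihijack
Title: Forensics and Mitigation of Host Off-Target Amplicons in 16S rRNA
    Gene Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Detects where and why universal 16S rRNA V3-V4 primers
    (341F/805R) mis-prime on a host genome, characterizes the resulting
    off-target amplicons, and quantifies the community-analysis bias they
    introduce. Provides an IUPAC-aware 3'-anchored mis-priming scanner,
    convergent off-target amplicon prediction, host/microbial partitioning
    of amplicon sequence variants with per-chromosome position clustering,
    position-frequency-matrix IUPAC consensus calling, design and in-silico
    validation of a 3'-C3-spacer blocking oligonucleotide against the
    recurrent off-target motif, abundance/prevalence filtering, analytic
    rarefaction saturation, Hellinger-distance principal coordinate
    analysis, and a fully seeded synthetic-data generator (host genome with
    planted mis-priming loci, mock 16S community, kitome templates, and a
    per-cycle PCR efficiency model with inhibitor suppression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    vegan,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
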