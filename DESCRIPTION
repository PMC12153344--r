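Package: PPRedit
Title: Detection and Characterisation of C-to-U RNA Editing by Synthetic
    PPR Factors in Bacterial Transcriptomes
Version: 0.1.0
Authors@R:
    person("PPRedit", "Developers", email = "ppredit@example.org",
           role = c("aut", "cre"))
Description: A pipeline for calling C-to-U RNA editing events (on- and
    off-target) from strand-specific per-site base counts of a bacterial
    transcriptome expressing a synthetic PLS-class pentatricopeptide-repeat
    (PPR) editing factor.  Candidate RNA-DNA differences are scored with a
    2x2 G-statistic, passed through a filter cascade (editing fraction
    difference, DNA error bound, depth quantile, per-sample score
    percentiles, negative-control subtraction), and summarised across
    samples.  Companion tools score candidate cis-elements with a PPR
    recognition-code table, scan genomes for predicted binding sites, build
    editing-extent-weighted sequence logos, quantify Sanger-trace editing
    extents, and estimate dissociation constants from REMSA titrations.  A
    synthetic-data module generates every input with known ground truth so
    the whole pipeline can be exercised at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
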