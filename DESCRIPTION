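Package: rtkfusion
Title: Triage of Receptor Tyrosine Kinase Fusion Transcripts from FFPE RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Distinguishes true, clinically relevant receptor tyrosine kinase
    (RTK) fusion transcripts from library-preparation artifacts in bulk RNA-seq
    of formalin-fixed paraffin-embedded (FFPE) tumor samples. Screens chimeric
    reads for exact exon-boundary junctions between two transcripts, annotates
    candidate fusions for reading-frame preservation and tyrosine kinase domain
    retention, computes double-normalized exon coverage profiles and a
    downstream/upstream coverage asymmetry test with a control-cohort baseline,
    and combines five binary criteria into a threshold classifier whose
    sensitivity and specificity can be evaluated against RT-PCR validation
    labels. Includes a synthetic-data module generating toy annotations,
    junction reads and coverage profiles with controlled fusion signal.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    yaml,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    rtracklayer
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
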