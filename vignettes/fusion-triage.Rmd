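---
title: "Triage of RTK fusion transcripts from FFPE RNA-seq: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of RTK fusion transcripts from FFPE RNA-seq: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtkfusion)
```

## Why triage is needed

RNA-seq of formalin-fixed paraffin-embedded (FFPE) tumor tissue is the most
practical route to fusion biomarkers in archival material, but the RNA is
fragmented: reads are short (~50 nt) and the library chemistry
(reverse-transcriptase template switching, cross-ligation of fragments)
manufactures chimeric molecules that mimic fusion junctions. Candidate lists
from fusion callers on such material are therefore dominated by artifacts,
and the historically reliable answer — manual genome-browser inspection plus
RT-PCR — does not scale. `rtkfusion` encodes that curation as deterministic,
testable rules for the twelve clinically relevant receptor tyrosine kinase
(RTK) genes in `RTK_GENES`.

The package deliberately does *not* discover fusions: it consumes chimeric
read candidates produced upstream (any caller whose intermediate output can
be mapped to a two-segment-per-read table) and an exon annotation, and
returns a credibility assessment per candidate.

## Coordinate model

All internal coordinates are 0-based half-open; GTF input (1-based
inclusive) is converted on read. Exons are stored in transcript (5′→3′)
orientation, so "exon 1" is always the 5′-most exon regardless of genomic
strand; user-facing exon indices are 1-based. A transcript breakpoint is
expressed as the number of transcript nucleotides retained from the 5′
partner (`bp5`) or the first retained transcript coordinate of the 3′
partner (`bp3`); both are snapped to the matched annotated exon boundary.
One transcript per gene (a MANE-style selection) is the expected input, but
several isoforms per gene are allowed and junction matching tries every
isoform pair from different genes, keeping the pair whose junction is
closest to annotated exon termini — real cases exist where a read matches
an alternative isoform's 5′-UTR rather than the canonical transcript, so
the isoform actually matched is always reported alongside exon numbers.

## Screening rules and their parameters

A candidate read passes when four conditions hold: different genes on the
two segments (c1), unambiguous mapping (c2: a single transcript hit per
segment and aligner-reported multiplicity 1), exact exon-boundary match of
the junction (c3), and sense orientation of both segments (c4).

Two parameters matter:

* `tolerance_nt` (default **0 nt**) — maximum distance between a segment
  terminus and the matching exon boundary. Zero encodes the rule that a
  spliced fusion junction must coincide exactly with established splice
  sites; a small positive value is available because 50-nt FFPE reads can
  carry soft-clipped terminal bases.
* `min_segment_nt` (default **10 nt**) — minimum moiety length inside the
  read. A shorter overhang cannot be assigned to a gene with confidence;
  the default is our choice (the original manual curation did not state
  one) and is exposed as a parameter.

The original "unambiguously mapped" check was a BLAT search; here it is
replaced by trusting the upstream aligner's multiplicity field, which is the
information actually available in caller intermediate files.

## Frame and kinase-domain annotation

The open reading frame is called preserved iff both breakpoints lie inside
their partners' CDS and their phases match:
`(bp5 − cds_start5) ≡ (bp3 − cds_start3) (mod 3)`. A junction in a UTR is
always "no", even though a native downstream start codon might still yield a
protein: the test is purely structural, which keeps it monotone and
reproduces how out-of-frame UTR-junction fusions are scored in the
validation matrix. The test suite verifies this phase arithmetic against a
brute-force oracle that splices the retained coding fragments, translates
them (`Biostrings::translate`, with initiator-codon special-casing
disabled, since a junction codon is not an initiation site), and checks the
3′ partner's native-frame protein continues across the junction.

The tyrosine kinase domain is retained iff its transcript interval is
*entirely* inside the retained moiety (`[bp3, length)` for a 3′ RTK,
`[0, bp5)` for a 5′ RTK). Partial retention counts as loss: a truncated
kinase domain is not the druggable entity the criteria target. When both
partners are RTKs, the 3′ partner is the one assessed, consistent with the
downstream-coverage criterion being defined for 3′-RTK fusions. Domain
coordinates are supplied as a TSV (`transcript_id, tk_start, tk_end`), not
computed: domain delineation (Pfam vs UniProt boundaries) is the user's
choice and out of scope; the packaged toy domain tables are synthetic.

## Coverage normalization: why two modes

Per-exon read counts are obtained with >=1-base-overlap semantics (the
`bedtools multicov` default; a junction-spanning read increments every exon
it touches, implemented over indexed BAM via `Rsamtools::countBam`).
Counts are double-normalized in one of two modes:

* **depth mode**: `count / (length/10^3) / (depth/10^6)` — reads per
  kilobase of exon per million mapped reads. Used for the *within-sample*
  asymmetry test, where any per-sample constant cancels, and for moiety
  expression levels.
* **gene mode**: `count / length / Σ counts` — removes the gene's overall
  expression level. Used for the *cross-sample* cohort comparison, where
  samples differ in both depth and expression; an unexpressed gene yields
  all zeros rather than a division error.

Keeping both modes reconciles the two normalizations the criteria were
defined with (sample depth for the exon profiles, overall gene expression
for cohort figures).

A caveat of gene-mode in the fusion sample itself: when the downstream
elevation is strong, it inflates the gene total and *depresses* the
upstream exons' gene-mode values relative to controls, which can keep the
strict cohort pattern from firing even for a real fusion. The combined
downstream criterion is an *or* of the t-test and the cohort pattern, and
the t-test is insensitive to this renormalization, so detection does not
depend on the cohort pattern in that regime.

## The asymmetry test and cohort pattern

The within-sample test is a **one-sided Welch** two-sample t-test on
exon-level normalized values, alternative "downstream exons higher", at
`alpha = 0.05`. The original description says only "t-test"; we choose
one-sided because the hypothesis is explicitly directional, and Welch
because the two exon groups have no reason to share a variance. Both
choices are exposed (`two_sided`, `var_equal`). Exons are treated as
independent observations — a simplification inherited from the original
analysis; exon counts within a transcript are in truth correlated, so the
nominal p-value is approximate (the simulated type-I error is checked in
the test suite). Degenerate inputs are defined away: fewer than two exons
on a side is "not testable" (criterion "no", with a reason), and
zero-variance identical sides return t = 0, one-sided p = 0.5.

The cohort pattern asks whether every downstream exon exceeds that exon's
empirical 95th percentile (type-7 quantile interpolation) across >= 2 (in
practice >= 5 recommended, 20 in our simulations) control samples, while
every upstream exon lies within the t-based 95% CI of the control mean
(`mean ± t(0.975, n−1)·sd/√n`). Whether the "all exons" aggregation should
instead be per-side fractions is not specified anywhere; we default to
strict all-exons (`f = 1`) and expose `f`. The per-exon condition (not a
condition on side means) is likewise a documented choice. With a gene
silent in controls, percentile and CI collapse to zero and any downstream
expression fires the pattern — the behaviour wanted for fusions that switch
on a normally silent 3′ partner.

The combined downstream criterion is "ND" (not determined) for 5′-RTK and
non-RTK fusions, else "yes" iff t-test *or* cohort pattern fires.

## Classifier and evaluation conventions

The five criteria (ORF, TK domain, ordered gene pair in the fusion-database
catalog, downstream coverage, >1 non-duplicated read) are summed with ND
counting as not-positive; `classify_fusion` thresholds the score at `k`
(default 2). Evaluation against labels uses two distinct ND conventions,
both forced by internal consistency of the validation matrix: in
*per-criterion* Sn/Sp, ND rows are excluded from the denominators (the
criterion was not assessable for them); in *threshold* scoring, ND counts
as not-met but the row is retained (a 5′-RTK fusion can still reach k = 2
on other criteria). Sn/Sp are reported raw and rounded to two decimals.

Catalog membership is on the ordered (5′, 3′) pair — fusion databases index
directional fusions. For the in-frame + domain-retained subgroup (at least
2 of the 3 remaining criteria), the sensitivity is reported under two
conventions: strict catalog membership, and a variant where a pair marked
as literature-reported (`db_literature`) counts as database-positive; the
two differ for fusions published but absent from the databases, and we
report both rather than guess which a given reader intends.

The sixth candidate criterion — concordance of mean 5′ and 3′ moiety
expression — is computed (`moiety_expression`) and reported, but never
enters the score: it did not separate true from artifact fusions reliably.

## The synthetic-data generator

`sim_config()` defaults describe the validated regime: 50 nt single-end
reads (FFPE fragment lengths), a 20-exon RTK 3′ partner joined at exon 12
to exon 3 of a non-RTK partner (the classic intra-chromosomal RET
rearrangement geometry: 11 upstream / 9 downstream exons), 150 nt exons, a
ten-fold downstream coverage step, lognormal per-exon count noise at
CV 0.2 around a mean of 100 reads per exon, 20 control samples, and a TK
domain downstream of the junction. Lognormal noise was chosen as a simple,
heavy-tailed count model with a direct CV parameterization; nothing in the
source analyses prescribes a noise model. Counts are rounded to integers.

What the generator does *not* emulate: sequence-specific FFPE degradation
gradients, GC bias, isoform mixtures, paired-end reads, alignment errors,
or correlated exon noise. Tests passing on this generator therefore show
the statistics behave as designed under clean assumptions — not that the
thresholds are optimal on any particular real cohort.

Problem sizes used by the test suite and the acceptance script are the
package's own: 240 randomized fusions for the translation-oracle check,
junction offsets −5..+5 at tolerances 0 and 3, 500 null simulations for the
t-test type-I error, 200 seeds for the fold-10 detection rate and for the
cohort false-positive rate. All are deterministic given the seed.

## Known limitations

* Exon-level pseudo-replication in the t-test (above).
* The cohort baseline assumes controls of the same tissue/cancer type;
  the package cannot check that assumption.
* Highly amplified genes (e.g. *ERBB2* in HER2-positive breast cancer) can
  mask the fusion coverage signature: all exons are elevated, so the
  downstream criterion may fail for a real fusion. This is a known failure
  mode of the coverage criterion itself, visible in the validation matrix.
* The multiread criterion depends on sequencing depth and read length;
  its threshold (>1) was established at ~30M 50-nt reads per library.
* Screening trusts the upstream aligner's multiplicity field instead of
  re-searching the genome.
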