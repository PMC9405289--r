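# Structural annotation of screened fusion candidates: which side carries
# the receptor tyrosine kinase, whether the reading frame is preserved
# across the junction, and whether the kinase domain survives in the
# retained moiety.

#' Which side of the fusion carries the RTK
#'
#' @param gene5,gene3 gene symbols of the 5' and 3' partners.
#' @param ann a `gene_annotation` (its `rtk_genes` set is used).
#' @return `"5'"`, `"3'"`, `"both"` or `"none"`.
#' @export
assign_rtk_side <- function(gene5, gene3, ann) {
  in5 <- toupper(gene5) %in% ann$rtk_genes
  in3 <- toupper(gene3) %in% ann$rtk_genes
  if (in5 && in3) "both" else if (in5) "5'" else if (in3) "3'" else "none"
}

#' Is the open reading frame preserved across the junction?
#'
#' Yes iff both breakpoints fall inside their partners' CDS and the
#' reading-frame phases match, so the 3' protein continues in its native
#' frame. A breakpoint in a UTR (including the 5'-UTR of the 3' partner)
#' is "no": the test is purely structural and does not credit potential
#' re-initiation at a downstream native start codon.
#'
#' @param model5,model3 `transcript_model`s of the 5' and 3' partners.
#' @param bp5 5' breakpoint: number of transcript nt retained from the 5'
#'   partner (transcript coordinate of the junction).
#' @param bp3 3' breakpoint: first retained transcript coordinate of the 3'
#'   partner.
#' @return `"yes"` or `"no"`.
#' @export
orf_preserved <- function(model5, bp5, model3, bp3) {
  if (is.na(model5$cds_start) || is.na(model3$cds_start)) return("no")
  in5 <- model5$cds_start < bp5 && bp5 <= model5$cds_end
  in3 <- model3$cds_start <= bp3 && bp3 < model3$cds_end
  if (!in5 || !in3) return("no")
  p5 <- phase_at(model5, bp5)
  p3 <- phase_at(model3, bp3)
  if (!is.na(p5) && !is.na(p3) && p5 == p3) "yes" else "no"
}

#' Is the tyrosine kinase domain retained in the fusion?
#'
#' All-or-nothing containment of the annotated TK domain interval in the
#' retained moiety of the RTK partner: for a 3'-side RTK the domain must lie
#' entirely in `[bp3, transcript length)`; for a 5'-side RTK entirely in
#' `[0, bp5)`. A partially truncated domain counts as not retained. When the
#' RTK is on both sides, the 3' RTK partner is the one assessed.
#'
#' @param rtk_model `transcript_model` of the RTK partner being assessed.
#' @param bp breakpoint on that partner (same convention as in
#'   [orf_preserved()]).
#' @param side `"3'"` or `"5'"`: where the RTK sits in the fusion.
#' @return `"yes"` or `"no"`.
#' @export
tk_retained <- function(rtk_model, bp, side) {
  if (is.na(rtk_model$tk_start))
    stop("domain coordinates required: transcript ", rtk_model$tx_id,
         " has no annotated tyrosine kinase domain")
  if (side == "3'") {
    if (rtk_model$tk_start >= bp) "yes" else "no"
  } else if (side == "5'") {
    if (rtk_model$tk_end <= bp) "yes" else "no"
  } else stop("side must be \"3'\" or \"5'\"")
}

#' Annotate grouped fusion candidates
#'
#' Produces one annotated fusion call per candidate: RTK side, ORF
#' preservation, TK-domain retention (evaluated on the 3' partner when the
#' RTK is on both sides), and the non-duplicated read count.
#'
#' @param candidates list of `fusion_candidate` from [group_candidates()].
#' @param ann a `gene_annotation`.
#' @return data.frame with one row per call: `sample_id, gene5, tx5, exon5,
#'   bp5, gene3, tx3, exon3, bp3, rtk_side, orf, tk, n_unique_reads`.
#' @export
annotate_candidates <- function(candidates, ann) {
  rows <- lapply(candidates, function(cand) {
    m5 <- ann$transcripts[[cand$tx5]]
    m3 <- ann$transcripts[[cand$tx3]]
    if (is.null(m5) || is.null(m3))
      stop("candidate transcripts absent from annotation: ",
           cand$tx5, " / ", cand$tx3)
    side <- assign_rtk_side(cand$gene5, cand$gene3, ann)
    tk <- if (side %in% c("3'", "both")) tk_retained(m3, cand$bp3, "3'")
          else if (side == "5'") tk_retained(m5, cand$bp5, "5'")
          else NA_character_
    data.frame(sample_id = cand$sample_id,
               gene5 = cand$gene5, tx5 = cand$tx5, exon5 = cand$exon5,
               bp5 = cand$bp5,
               gene3 = cand$gene3, tx3 = cand$tx3, exon3 = cand$exon3,
               bp3 = cand$bp3,
               rtk_side = side,
               orf = orf_preserved(m5, cand$bp5, m3, cand$bp3),
               tk = tk,
               n_unique_reads = count_unique_reads(cand),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
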