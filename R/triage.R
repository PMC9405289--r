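# End-to-end triage: chimeric-read candidates -> screened junctions ->
# annotated calls -> five-criterion vectors and verdicts.

#' Triage chimeric-read candidates into classified fusion calls
#'
#' Runs the full pipeline: screen every read against the four junction
#' criteria, group passing reads into per-junction candidates, annotate RTK
#' side / reading frame / TK-domain retention, evaluate the downstream
#' coverage criterion where exon counts are available, look the gene pair
#' up in the known-fusion catalog, and apply the at-least-k-of-5 classifier
#' and the in-frame+TK subgroup rule.
#'
#' @param candidates chimeric-read table (see [read_candidates()]).
#' @param ann a `gene_annotation` (TK domain coordinates required for RTK
#'   transcripts).
#' @param catalog a `fusion_catalog`, or `NULL` (database criterion then
#'   scores "no" for every pair).
#' @param counts optional long-format exon counts: data.frame with columns
#'   `sample_id, transcript_id, exon_index, count`.
#' @param depths named numeric vector of total mapped reads per sample
#'   (required for depth-mode normalization when `counts` is given).
#' @param control_samples sample ids in `counts` forming the fusion-free
#'   cohort baseline; when absent the downstream criterion falls back to
#'   the within-sample asymmetry test alone.
#' @param alpha significance level of the asymmetry test.
#' @param tolerance_nt junction boundary tolerance for screening.
#' @param min_segment_nt minimum moiety length for screening.
#' @param f cohort-pattern aggregation fraction (see [cohort_pattern()]).
#' @param k classification threshold reported in `verdict` (verdicts at
#'   k = 2 and k = 3 are always included).
#' @return data.frame of annotated calls with criterion columns
#'   (`orf, tk, in_db, downstream, multiread`), `asym_p`, `expr5`, `expr3`,
#'   `score`, `verdict_k2`, `verdict_k3`, `verdict`, `subgroup`.
#' @export
triage_fusions <- function(candidates, ann, catalog = NULL,
                           counts = NULL, depths = NULL,
                           control_samples = NULL,
                           alpha = 0.05, tolerance_nt = 0L,
                           min_segment_nt = 10L, f = 1.0, k = 2L) {
  screened <- screen_candidates(candidates, ann, tolerance_nt, min_segment_nt)
  cands <- group_candidates(screened)
  if (!length(cands)) {
    return(data.frame(sample_id = character(), gene5 = character(),
                      gene3 = character()))
  }
  calls <- annotate_candidates(cands, ann)

  counts_for <- function(sample, tx) {
    if (is.null(counts)) return(NULL)
    sel <- counts$sample_id == sample & counts$transcript_id == tx
    if (!any(sel)) return(NULL)
    model <- ann$transcripts[[tx]]
    v <- integer(length(model$exon_starts))
    v[counts$exon_index[sel]] <- counts$count[sel]
    v
  }
  depth_for <- function(sample) {
    if (is.null(depths) || !sample %in% names(depths)) NA_real_
    else unname(depths[[sample]])
  }

  extra <- lapply(seq_len(nrow(calls)), function(i) {
    call <- calls[i, ]
    model3 <- ann$transcripts[[call$tx3]]
    model5 <- ann$transcripts[[call$tx5]]
    out <- list(downstream = "ND", asym_p = NA_real_,
                expr5 = NA_real_, expr3 = NA_real_)

    cts3 <- counts_for(call$sample_id, call$tx3)
    cts5 <- counts_for(call$sample_id, call$tx5)
    dp <- depth_for(call$sample_id)
    if (!is.null(cts3) && !is.null(cts5) && !is.na(dp)) {
      p5 <- coverage_profile(call$sample_id, model5, cts5, dp, "depth")
      p3 <- coverage_profile(call$sample_id, model3, cts3, dp, "depth")
      me <- moiety_expression(p5, p3, call$exon5, call$exon3)
      out$expr5 <- me[["mean5"]]; out$expr3 <- me[["mean3"]]
    }

    if (call$rtk_side %in% c("3'", "both") && !is.null(cts3) && !is.na(dp)) {
      prof <- coverage_profile(call$sample_id, model3, cts3, dp, "depth")
      halves <- split_at_junction(prof, call$exon3)
      asym <- asymmetry_ttest(halves$upstream, halves$downstream, alpha)
      out$asym_p <- asym$p_value
      cohort <- NULL
      ctrl_ids <- setdiff(control_samples, call$sample_id)
      if (length(ctrl_ids) >= 2) {
        ctrl_profiles <- Filter(Negate(is.null), lapply(ctrl_ids, function(s) {
          cc <- counts_for(s, call$tx3)
          if (is.null(cc)) NULL
          else coverage_profile(s, model3, cc, depth_for(s), "gene")
        }))
        if (length(ctrl_profiles) >= 2) {
          base <- cohort_baseline(ctrl_profiles)
          gprof <- coverage_profile(call$sample_id, model3, cts3, dp, "gene")
          cohort <- cohort_pattern(gprof, base, call$exon3, f = f)
        }
      }
      out$downstream <- downstream_criterion(asym, cohort, call$rtk_side)
    } else {
      out$downstream <- downstream_criterion(NULL, NULL, call$rtk_side)
    }
    out
  })

  calls$downstream <- vapply(extra, `[[`, "", "downstream")
  calls$asym_p <- vapply(extra, `[[`, 0, "asym_p")
  calls$expr5 <- vapply(extra, `[[`, 0, "expr5")
  calls$expr3 <- vapply(extra, `[[`, 0, "expr3")
  calls$in_db <- vapply(seq_len(nrow(calls)), function(i) {
    if (is.null(catalog)) "no"
    else db_lookup(calls$gene5[i], calls$gene3[i], catalog)
  }, "")
  calls$multiread <- ifelse(calls$n_unique_reads > 1, "yes", "no")

  calls$score <- vapply(seq_len(nrow(calls)),
                        function(i) score_criteria(calls[i, ]), integer(1))
  calls$verdict_k2 <- ifelse(calls$score >= 2, "positive", "negative")
  calls$verdict_k3 <- ifelse(calls$score >= 3, "positive", "negative")
  calls$verdict <- ifelse(calls$score >= k, "positive", "negative")
  calls$subgroup <- vapply(seq_len(nrow(calls)),
                           function(i) classify_subgroup(calls[i, ]), "")
  calls
}
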