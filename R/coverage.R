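# Exon coverage profiles and the downstream-coverage criterion.
#
# Coverage is "double normalized": per-exon read counts divided by exon
# length and by a per-sample factor — total mapped reads (depth mode, i.e.
# reads per kilobase per million mapped) for within-sample comparisons, or
# total gene counts (gene mode) for cross-sample comparisons where overall
# expression differences must cancel.

#' Per-exon read counts (multicov-equivalent)
#'
#' Counts reads overlapping each exon by at least one base, so a
#' junction-spanning read increments every exon it touches. The source may
#' be a coordinate-sorted indexed BAM file, a `GRanges` of aligned reads, or
#' a precomputed counts TSV with columns `transcript_id, exon_index, count`.
#'
#' @param source BAM path, `GRanges`, or TSV path.
#' @param model a `transcript_model`.
#' @return integer vector of counts, one per exon in transcript order.
#' @export
exon_counts <- function(source, model) {
  n <- length(model$exon_starts)
  if (is.character(source) && length(source) == 1) {
    ext <- tolower(tools::file_ext(source))
    if (ext == "bam") return(exon_counts_bam(source, model))
    tab <- utils::read.delim(source, stringsAsFactors = FALSE)
    need <- c("transcript_id", "exon_index", "count")
    if (!all(need %in% names(tab)))
      stop("counts table must have columns: ", paste(need, collapse = ", "))
    tab <- tab[tab$transcript_id == model$tx_id, ]
    counts <- integer(n)
    counts[tab$exon_index] <- tab$count
    return(counts)
  }
  if (methods::is(source, "GRanges")) {
    return(as.integer(GenomicRanges::countOverlaps(exon_granges(model), source,
                                                   ignore.strand = TRUE)))
  }
  stop("unsupported alignment source")
}

exon_counts_bam <- function(bam, model) {
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!model$chrom %in% names(hdr))
    stop("chromosome ", model$chrom, " absent from alignment header of ", bam)
  ex <- exon_granges(model)
  param <- Rsamtools::ScanBamParam(
    which = ex, flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE))
  cb <- Rsamtools::countBam(bam, param = param)
  # countBam returns one row per 'which' range, in order
  as.integer(cb$records)
}

#' Double-normalize per-exon counts
#'
#' @param counts integer per-exon read counts.
#' @param lengths per-exon lengths (nt), all positive.
#' @param depth total mapped reads in the sample (used in depth mode).
#' @param norm_mode `"depth"`: reads per kilobase of exon per million mapped
#'   reads, `count / (length/1e3) / (depth/1e6)`. `"gene"`: `count / length /
#'   sum(counts)`, which removes the gene's overall expression level; an
#'   unexpressed gene (all zero counts) yields all zeros.
#' @return numeric vector of normalized values.
#' @export
normalize_coverage <- function(counts, lengths, depth = NULL,
                               norm_mode = c("depth", "gene")) {
  norm_mode <- match.arg(norm_mode)
  stopifnot(length(counts) == length(lengths), all(lengths > 0))
  if (norm_mode == "depth") {
    if (is.null(depth) || is.na(depth) || depth <= 0)
      stop("depth mode requires a positive total mapped-read depth")
    counts / (lengths / 1e3) / (depth / 1e6)
  } else {
    tot <- sum(counts)
    if (tot == 0) return(rep(0, length(counts)))
    counts / lengths / tot
  }
}

#' Build an exon coverage profile
#'
#' @param sample_id sample identifier.
#' @param model a `transcript_model`.
#' @param counts per-exon raw counts (or an alignment source accepted by
#'   [exon_counts()]).
#' @param depth total mapped reads in the sample.
#' @param norm_mode see [normalize_coverage()].
#' @return object of class `coverage_profile` with `counts`, `lengths`,
#'   `depth`, `norm_mode` and normalized `values`.
#' @export
coverage_profile <- function(sample_id, model, counts, depth = NULL,
                             norm_mode = c("depth", "gene")) {
  norm_mode <- match.arg(norm_mode)
  if (!is.numeric(counts)) counts <- exon_counts(counts, model)
  lens <- exon_lengths(model)
  stopifnot(length(counts) == length(lens))
  structure(list(sample_id = sample_id, tx_id = model$tx_id,
                 counts = as.integer(counts), lengths = lens,
                 depth = depth, norm_mode = norm_mode,
                 values = normalize_coverage(counts, lens, depth, norm_mode)),
            class = "coverage_profile")
}

#' @export
print.coverage_profile <- function(x, ...) {
  cat(sprintf("<coverage_profile> %s / %s: %d exons, %s-normalized, total count %d\n",
              x$sample_id, x$tx_id, length(x$counts), x$norm_mode, sum(x$counts)))
  invisible(x)
}

#' Split a profile at the fusion junction
#'
#' Upstream exons `1..k-1` are absent from the fusion transcript; downstream
#' exons `k..n` (k = 1-based first retained exon) are retained and driven by
#' the 5' partner's promoter.
#'
#' @param profile a `coverage_profile` (any normalization).
#' @param first_retained_exon 1-based index of the first retained exon.
#' @return list with `upstream` and `downstream` value vectors; when `k = 1`
#'   the whole gene is retained, upstream is empty and the asymmetry test is
#'   not assessable.
#' @export
split_at_junction <- function(profile, first_retained_exon) {
  n <- length(profile$values)
  k <- first_retained_exon
  if (k < 1 || k > n) stop("first retained exon index out of range")
  list(upstream = profile$values[seq_len(k - 1)],
       downstream = profile$values[k:n])
}

#' One-sided exon coverage asymmetry test
#'
#' Welch two-sample t-test on exon-level normalized coverage, alternative:
#' downstream exons (retained in the fusion) have higher coverage than
#' upstream exons. Exons are treated as independent observations.
#'
#' @param upstream,downstream normalized coverage values on each side of the
#'   junction.
#' @param alpha significance level (default 0.05).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @param two_sided use a two-sided alternative (the criterion then
#'   additionally requires the downstream mean to be the larger one).
#' @return object of class `asymmetry_test`: `t_statistic`, `p_value`,
#'   `direction` (`downstream_greater`/`upstream_greater`/`none`), `n_up`,
#'   `n_down`, `criterion_met` (`"yes"`/`"no"`), and a `reason` when the
#'   test is not computable.
#' @export
asymmetry_ttest <- function(upstream, downstream, alpha = 0.05,
                            var_equal = FALSE, two_sided = FALSE) {
  n_up <- length(upstream); n_down <- length(downstream)
  out <- list(t_statistic = NA_real_, p_value = NA_real_, direction = "none",
              n_up = n_up, n_down = n_down, criterion_met = "no",
              reason = NULL, alpha = alpha)
  if (n_up < 2 || n_down < 2) {
    out$reason <- "insufficient exons"
    return(structure(out, class = "asymmetry_test"))
  }
  md <- mean(downstream) - mean(upstream)
  out$direction <- if (md > 0) "downstream_greater"
                   else if (md < 0) "upstream_greater" else "none"
  if (stats::sd(upstream) == 0 && stats::sd(downstream) == 0) {
    # degenerate constant data: t is 0/0; no evidence either way
    out$t_statistic <- 0; out$p_value <- if (two_sided) 1 else 0.5
    return(structure(out, class = "asymmetry_test"))
  }
  tt <- stats::t.test(downstream, upstream, var.equal = var_equal,
                      alternative = if (two_sided) "two.sided" else "greater")
  out$t_statistic <- unname(tt$statistic)
  out$p_value <- tt$p.value
  met <- out$p_value < alpha && out$direction == "downstream_greater"
  out$criterion_met <- if (met) "yes" else "no"
  structure(out, class = "asymmetry_test")
}

#' @export
print.asymmetry_test <- function(x, ...) {
  cat(sprintf("<asymmetry_test> t = %.3f, one-sided p = %.4g (%d up / %d down exons)\n",
              x$t_statistic, x$p_value, x$n_up, x$n_down))
  cat(sprintf("  direction: %s; criterion at alpha %.2g: %s%s\n", x$direction,
              x$alpha, x$criterion_met,
              if (!is.null(x$reason)) paste0(" (", x$reason, ")") else ""))
  invisible(x)
}

#' Per-exon cohort baseline from control samples
#'
#' For each exon, the mean, SD, empirical 95th percentile and t-based 95%
#' confidence interval of the mean of normalized coverage across control
#' samples of the same cancer type without the fusion.
#'
#' @param profiles list of `coverage_profile`s for the same transcript
#'   (gene-mode normalization recommended for cross-sample comparison).
#' @return object of class `cohort_baseline` with per-exon `mean`, `sd`,
#'   `n`, `p95`, `ci_low`, `ci_high`.
#' @export
cohort_baseline <- function(profiles) {
  stopifnot(length(profiles) >= 2)
  tx <- unique(vapply(profiles, `[[`, "", "tx_id"))
  if (length(tx) != 1) stop("control profiles span multiple transcripts")
  vals <- do.call(rbind, lapply(profiles, `[[`, "values"))
  n <- nrow(vals)
  m <- colMeans(vals)
  s <- apply(vals, 2, stats::sd)
  half <- stats::qt(0.975, df = n - 1) * s / sqrt(n)
  structure(list(tx_id = tx, n = n, mean = m, sd = s,
                 p95 = apply(vals, 2, stats::quantile, probs = 0.95),
                 ci_low = m - half, ci_high = m + half,
                 norm_mode = profiles[[1]]$norm_mode),
            class = "cohort_baseline")
}

#' @export
print.cohort_baseline <- function(x, ...) {
  cat(sprintf("<cohort_baseline> %s: %d control samples, %d exons (%s-normalized)\n",
              x$tx_id, x$n, length(x$mean), x$norm_mode))
  invisible(x)
}

#' Cross-sample cohort coverage pattern
#'
#' The fusion-specific coverage signature relative to a control cohort:
#' every downstream (retained) exon's coverage exceeds that exon's 95th
#' percentile across controls, while every upstream exon stays within the
#' 95% confidence interval of the control mean. The all-exons requirement
#' can be relaxed to a fraction `f` of exons per side.
#'
#' @param profile the fusion sample's `coverage_profile` (same normalization
#'   as the baseline).
#' @param baseline a `cohort_baseline` for the same transcript.
#' @param first_retained_exon 1-based first retained exon.
#' @param f minimum fraction of exons satisfying the condition on each side
#'   (default 1: all exons).
#' @return `"yes"` or `"no"`.
#' @export
cohort_pattern <- function(profile, baseline, first_retained_exon, f = 1.0) {
  if (profile$tx_id != baseline$tx_id)
    stop("profile transcript ", profile$tx_id,
         " does not match baseline transcript ", baseline$tx_id)
  if (profile$norm_mode != baseline$norm_mode)
    stop("profile and baseline use different normalization modes")
  n <- length(profile$values)
  k <- first_retained_exon
  down <- k:n
  up <- seq_len(k - 1)
  down_ok <- profile$values[down] > baseline$p95[down]
  up_ok <- profile$values[up] >= baseline$ci_low[up] &
           profile$values[up] <= baseline$ci_high[up]
  ok <- mean(down_ok) >= f && (length(up) == 0 || mean(up_ok) >= f)
  if (ok) "yes" else "no"
}

#' Combined downstream-coverage criterion
#'
#' Assessable only for fusions with the RTK on the 3' side (including
#' "both", where the 3' RTK partner is assessed); `"ND"` otherwise. When
#' assessable, the criterion fires if the within-sample asymmetry test
#' and/or the cohort pattern is positive.
#'
#' @param asym an `asymmetry_test` (or `NULL` if not computed).
#' @param cohort `"yes"`/`"no"` from [cohort_pattern()] (or `NULL`).
#' @param rtk_side `"3'"`, `"5'"`, `"both"` or `"none"`.
#' @return `"yes"`, `"no"` or `"ND"`.
#' @export
downstream_criterion <- function(asym, cohort, rtk_side) {
  if (!rtk_side %in% c("3'", "both")) return("ND")
  t_yes <- !is.null(asym) && identical(asym$criterion_met, "yes")
  c_yes <- identical(cohort, "yes")
  if (t_yes || c_yes) "yes" else "no"
}

#' Mean coverage of the retained moieties
#'
#' Averaged depth-normalized exon coverage over the retained exons of the 5'
#' partner and the retained (downstream) exons of the 3' partner. Reported
#' alongside the criteria but deliberately not part of the classifier: the
#' concordance of 5'/3' moiety expression proved an unreliable signal.
#'
#' @param profile5,profile3 depth-normalized `coverage_profile`s.
#' @param last_retained_exon5 1-based last retained exon of the 5' partner.
#' @param first_retained_exon3 1-based first retained exon of the 3' partner.
#' @return named numeric `c(mean5, mean3)`; `NA` for an empty retained set.
#' @export
moiety_expression <- function(profile5, profile3,
                              last_retained_exon5, first_retained_exon3) {
  v5 <- profile5$values[seq_len(last_retained_exon5)]
  v3 <- profile3$values[first_retained_exon3:length(profile3$values)]
  c(mean5 = if (length(v5)) mean(v5) else NA_real_,
    mean3 = if (length(v3)) mean(v3) else NA_real_)
}
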