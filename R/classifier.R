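# Five-criterion fusion classifier and its sensitivity/specificity
# evaluation against RT-PCR validation labels.
#
# Criteria: (i) ORF preserved, (ii) TK domain retained, (iii) fusion pair
# present in public fusion databases, (iv) downstream coverage criterion
# (assessable only for 3'-RTK fusions, "ND" otherwise), (v) supported by
# more than one non-duplicated chimeric read. "ND" never counts as a
# positive criterion.

CRITERIA <- c("orf", "tk", "in_db", "downstream", "multiread")

#' Load a known-fusion catalog
#'
#' TSV with columns `gene5, gene3` (and optionally `source`), one row per
#' directional fusion pair, emulating the union of the public chimeric
#' transcript databases.
#'
#' @param path TSV path.
#' @return object of class `fusion_catalog`.
#' @export
load_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene5", "gene3") %in% names(df)))
    stop("catalog must have columns gene5, gene3")
  structure(list(pairs = unique(paste(toupper(df$gene5), toupper(df$gene3),
                                      sep = "|"))),
            class = "fusion_catalog")
}

#' Ordered catalog membership of a fusion pair
#'
#' Membership is on the ordered (5', 3') pair: databases index directional
#' fusions, so the reversed pair does not match. Symbol casing is
#' normalized.
#'
#' @param gene5,gene3 partner gene symbols.
#' @param catalog a `fusion_catalog`.
#' @return `"yes"` or `"no"`.
#' @export
db_lookup <- function(gene5, gene3, catalog) {
  if (paste(toupper(gene5), toupper(gene3), sep = "|") %in% catalog$pairs)
    "yes" else "no"
}

#' Number of positive criteria
#'
#' @param vector a list or one-row data.frame with entries `orf, tk, in_db,
#'   downstream, multiread`, each `"yes"`, `"no"` or (for `downstream`)
#'   `"ND"`. `"ND"` counts as not positive.
#' @return integer in 0..5.
#' @export
score_criteria <- function(vector) {
  sum(vapply(CRITERIA, function(k) identical(as.character(vector[[k]]), "yes"),
             logical(1)))
}

#' Threshold classification
#'
#' @inheritParams score_criteria
#' @param k minimum number of positive criteria (1..5).
#' @return `"positive"` or `"negative"`.
#' @export
classify_fusion <- function(vector, k = 2L) {
  stopifnot(k >= 1, k <= 5)
  if (score_criteria(vector) >= k) "positive" else "negative"
}

#' Clinically relevant subgroup classification
#'
#' Only fusions with an intact ORF and retained TK domain encode a
#' potentially druggable kinase; for those, the verdict is at least two
#' positive of the three remaining criteria (database presence, downstream
#' coverage, multiple reads).
#'
#' @inheritParams score_criteria
#' @return `"positive"`, `"negative"`, or `"not_applicable"` when the fusion
#'   is out of frame or the domain is lost.
#' @export
classify_subgroup <- function(vector) {
  if (!identical(as.character(vector$orf), "yes") ||
      !identical(as.character(vector$tk), "yes")) return("not_applicable")
  n <- sum(vapply(c("in_db", "downstream", "multiread"),
                  function(k) identical(as.character(vector[[k]]), "yes"),
                  logical(1)))
  if (n >= 2) "positive" else "negative"
}

# normalize a feature table: derive multiread from n_reads if absent
as_criterion_frame <- function(df) {
  if (!"multiread" %in% names(df)) {
    if (!"n_reads" %in% names(df))
      stop("feature table needs a multiread or n_reads column")
    df$multiread <- ifelse(df$n_reads > 1, "yes", "no")
  }
  missing <- setdiff(CRITERIA, names(df))
  if (length(missing))
    stop("feature table lacks criterion columns: ", paste(missing, collapse = ", "))
  df
}

#' Evaluate the criteria against validation labels
#'
#' Computes, over fusions labeled `confirmed` vs `non_confirmed`
#' (`unexplored` rows are excluded):
#' per-criterion sensitivity and specificity (for the downstream criterion,
#' `ND` rows drop out of both denominators because the criterion is not
#' assessable for them); threshold sensitivity/specificity for
#' at-least-k-of-5 at every k (here `ND` counts as "criterion not met" and
#' rows are retained); the fraction of confirmed fusions positive for all
#' five criteria; and the in-frame + TK-retained subgroup analysis over the
#' remaining three criteria at threshold 2. When a `db_literature` column is
#' present, the subgroup threshold sensitivity is also reported with
#' literature-only database reports counted as database-positive, since
#' either convention is defensible.
#'
#' @param features data.frame with columns `orf, tk, in_db, downstream`,
#'   `multiread` (or `n_reads`), `label`, and optionally `db_literature`.
#' @return object of class `fusion_eval`.
#' @export
evaluate_criteria <- function(features) {
  df <- as_criterion_frame(features)
  if (!"label" %in% names(df)) stop("feature table needs a label column")
  lab <- df$label
  if (!any(lab == "confirmed") || !any(lab == "non_confirmed"))
    stop("need at least one confirmed and one non-confirmed label")
  conf <- df[lab == "confirmed", , drop = FALSE]
  nonc <- df[lab == "non_confirmed", , drop = FALSE]

  per_criterion <- lapply(CRITERIA, function(crit) {
    cv <- as.character(conf[[crit]]); nv <- as.character(nonc[[crit]])
    ca <- cv != "ND"; na_ <- nv != "ND"        # assessable rows
    list(criterion = crit,
         sn_num = sum(cv[ca] == "yes"), sn_den = sum(ca),
         sp_num = sum(nv[na_] == "no"), sp_den = sum(na_))
  })
  names(per_criterion) <- CRITERIA
  per_criterion <- lapply(per_criterion, function(x) {
    x$sn <- x$sn_num / x$sn_den; x$sp <- x$sp_num / x$sp_den; x
  })

  score_conf <- vapply(seq_len(nrow(conf)),
                       function(i) score_criteria(conf[i, ]), integer(1))
  score_nonc <- vapply(seq_len(nrow(nonc)),
                       function(i) score_criteria(nonc[i, ]), integer(1))
  thresholds <- data.frame(
    k = 1:5,
    sn = vapply(1:5, function(k) mean(score_conf >= k), numeric(1)),
    sp = vapply(1:5, function(k) mean(score_nonc < k), numeric(1)))

  frac_all_five <- mean(score_conf == 5)

  # in-frame + TK-retained subgroup over {in_db, downstream, multiread}
  sub_conf <- conf[conf$orf == "yes" & conf$tk == "yes", , drop = FALSE]
  sub_nonc <- nonc[nonc$orf == "yes" & nonc$tk == "yes", , drop = FALSE]
  sub3 <- c("in_db", "downstream", "multiread")
  sub_criterion <- lapply(sub3, function(crit) {
    cv <- as.character(sub_conf[[crit]]); ca <- cv != "ND"
    list(criterion = crit, sn_num = sum(cv[ca] == "yes"), sn_den = sum(ca),
         sn = sum(cv[ca] == "yes") / sum(ca))
  })
  names(sub_criterion) <- sub3
  sub_score <- function(d) vapply(seq_len(nrow(d)), function(i)
    sum(vapply(sub3, function(k) identical(as.character(d[[k]][i]), "yes"),
               logical(1))), integer(1))
  subgroup_sn <- mean(sub_score(sub_conf) >= 2)
  subgroup_sp <- if (nrow(sub_nonc)) mean(sub_score(sub_nonc) < 2) else NA_real_
  subgroup_sn_literature <- NA_real_
  if ("db_literature" %in% names(df)) {
    lit <- sub_conf
    lit$in_db <- ifelse(as.character(lit$db_literature) == "yes", "yes",
                        as.character(lit$in_db))
    subgroup_sn_literature <- mean(sub_score(lit) >= 2)
  }

  structure(list(
    n_confirmed = nrow(conf), n_non_confirmed = nrow(nonc),
    n_unexplored = sum(lab == "unexplored"),
    per_criterion = per_criterion,
    thresholds = thresholds,
    frac_all_five = frac_all_five,
    subgroup = list(n_confirmed = nrow(sub_conf), n_non_confirmed = nrow(sub_nonc),
                    per_criterion = sub_criterion,
                    sn = subgroup_sn, sp = subgroup_sp,
                    sn_literature = subgroup_sn_literature)),
    class = "fusion_eval")
}

#' @export
print.fusion_eval <- function(x, digits = 2, ...) {
  cat(sprintf("<fusion_eval> %d confirmed, %d non-confirmed, %d unexplored\n",
              x$n_confirmed, x$n_non_confirmed, x$n_unexplored))
  cat("per-criterion (Sn, Sp):\n")
  for (pc in x$per_criterion)
    cat(sprintf("  %-11s Sn %.2f (%d/%d)  Sp %.2f (%d/%d)\n", pc$criterion,
                round(pc$sn, digits), pc$sn_num, pc$sn_den,
                round(pc$sp, digits), pc$sp_num, pc$sp_den))
  cat("threshold >=k of 5 (Sn, Sp):\n")
  for (i in seq_len(nrow(x$thresholds)))
    cat(sprintf("  k=%d  Sn %.2f  Sp %.2f\n", x$thresholds$k[i],
                round(x$thresholds$sn[i], digits), round(x$thresholds$sp[i], digits)))
  cat(sprintf("confirmed fusions positive for all five: %.0f%%\n",
              100 * x$frac_all_five))
  cat(sprintf("in-frame+TK subgroup (n=%d): >=2-of-3 Sn %.2f (literature DB convention %.2f), Sp %s\n",
              x$subgroup$n_confirmed, round(x$subgroup$sn, digits),
              round(x$subgroup$sn_literature, digits),
              ifelse(is.na(x$subgroup$sp), "NA",
                     sprintf("%.2f", round(x$subgroup$sp, digits)))))
  invisible(x)
}

#' Flatten an evaluation to a named numeric vector
#'
#' Convenience accessor used by reports: per-criterion Sn/Sp, threshold
#' Sn/Sp at each k, the all-five fraction, and the subgroup summaries, all
#' unrounded.
#'
#' @param x a `fusion_eval`.
#' @return named numeric vector.
#' @export
eval_metrics <- function(x) {
  out <- c()
  for (pc in x$per_criterion) {
    out[paste0("sn_", pc$criterion)] <- pc$sn
    out[paste0("sp_", pc$criterion)] <- pc$sp
  }
  for (i in seq_len(nrow(x$thresholds))) {
    out[paste0("sn_k", x$thresholds$k[i])] <- x$thresholds$sn[i]
    out[paste0("sp_k", x$thresholds$k[i])] <- x$thresholds$sp[i]
  }
  out["frac_all_five"] <- x$frac_all_five
  out["subgroup_sn_in_db"] <- x$subgroup$per_criterion$in_db$sn
  out["subgroup_sn_downstream"] <- x$subgroup$per_criterion$downstream$sn
  out["subgroup_sn_multiread"] <- x$subgroup$per_criterion$multiread$sn
  out["subgroup_sn"] <- x$subgroup$sn
  out["subgroup_sn_literature"] <- x$subgroup$sn_literature
  out["subgroup_sp"] <- x$subgroup$sp
  out
}

#' Packaged feature matrix of putative RTK fusions
#'
#' The curated feature matrix of 36 putative RTK fusions detected in an FFPE
#' bulk RNA-seq cohort (solid tumors, leukemias and two cell lines), with
#' the five criterion columns, moiety expression levels, read counts and
#' RT-PCR validation labels (`confirmed` / `non_confirmed` / `unexplored`).
#' `db_literature` marks pairs absent from the fusion databases but
#' reported in the literature.
#'
#' @return data.frame, one row per putative fusion.
#' @export
fusion_feature_matrix <- function() {
  path <- system.file("extdata", "fusion_feature_matrix.tsv",
                      package = "rtkfusion", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
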