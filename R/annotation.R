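# Transcript models and coordinate arithmetic.
#
# All internal coordinates are 0-based half-open. GTF input (1-based,
# inclusive) is converted on read; BED12 is already 0-based half-open.
# Exons are stored in transcript (5'->3') orientation, so exon 1 is the
# 5'-most exon regardless of genomic strand.

#' Clinically relevant receptor tyrosine kinase gene symbols
#'
#' The twelve RTK genes whose fusions the triage criteria target.
#' @export
RTK_GENES <- c("ABL1", "ALK", "ERBB2", "FGFR1", "FGFR2", "FGFR3", "FGFR4",
               "NTRK1", "NTRK2", "NTRK3", "RET", "ROS1")

#' Construct a transcript model
#'
#' @param gene gene symbol (HGNC).
#' @param tx_id transcript identifier, unique within an annotation.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends genomic exon coordinates, 0-based half-open,
#'   given in any order; they are sorted into transcript orientation.
#' @param cds_start,cds_end CDS bounds in transcript coordinates (nt, 0-based
#'   half-open), or `NA` for a non-coding transcript.
#' @param tk_start,tk_end tyrosine-kinase domain interval in transcript
#'   coordinates (nt, 0-based half-open), or `NA` if not annotated.
#' @return an object of class `transcript_model`.
#' @export
transcript_model <- function(gene, tx_id, chrom, strand, exon_starts, exon_ends,
                             cds_start = NA_integer_, cds_end = NA_integer_,
                             tk_start = NA_integer_, tk_end = NA_integer_) {
  stopifnot(strand %in% c("+", "-"), length(exon_starts) == length(exon_ends),
            all(exon_starts < exon_ends))
  ord <- order(exon_starts)
  exon_starts <- exon_starts[ord]; exon_ends <- exon_ends[ord]
  if (any(exon_starts[-1] < exon_ends[-length(exon_ends)]))
    stop("overlapping exons in transcript ", tx_id)
  if (strand == "-") {                    # exon 1 must be 5'-most
    exon_starts <- rev(exon_starts); exon_ends <- rev(exon_ends)
  }
  len <- sum(exon_ends - exon_starts)
  if (!is.na(cds_start)) {
    if (is.na(cds_end) || cds_start < 0 || cds_start >= cds_end || cds_end > len)
      stop("invalid CDS bounds for transcript ", tx_id)
  }
  if (!is.na(tk_start)) {
    if (is.na(tk_end) || tk_start < 0 || tk_start >= tk_end || tk_end > len)
      stop("tyrosine-kinase domain interval outside transcript ", tx_id)
  }
  structure(list(gene = gene, tx_id = tx_id, chrom = chrom, strand = strand,
                 exon_starts = as.integer(exon_starts),
                 exon_ends = as.integer(exon_ends),
                 cds_start = as.integer(cds_start), cds_end = as.integer(cds_end),
                 tk_start = as.integer(tk_start), tk_end = as.integer(tk_end)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cds <- if (is.na(x$cds_start)) "non-coding"
         else sprintf("CDS [%d,%d)", x$cds_start, x$cds_end)
  tk <- if (is.na(x$tk_start)) "" else sprintf(", TK [%d,%d)", x$tk_start, x$tk_end)
  cat(sprintf("<transcript_model> %s (%s) %s:%s, %d exons, %d nt, %s%s\n",
              x$tx_id, x$gene, x$chrom, x$strand, length(x$exon_starts),
              transcript_length(x), cds, tk))
  invisible(x)
}

#' Total exonic length of a transcript (nt)
#' @param model a `transcript_model`.
#' @export
transcript_length <- function(model) {
  sum(model$exon_ends - model$exon_starts)
}

#' Exon lengths in transcript order (nt)
#' @param model a `transcript_model`.
#' @export
exon_lengths <- function(model) {
  as.integer(model$exon_ends - model$exon_starts)
}

# cumulative transcript-coordinate start of each exon (0-based)
exon_tx_starts <- function(model) {
  c(0L, cumsum(exon_lengths(model))[-length(model$exon_starts)])
}

#' Map a genomic position to a transcript coordinate
#'
#' Returns the cumulative exonic offset in transcript orientation, or `NA`
#' when the position is intronic or outside the transcript ("not exonic").
#'
#' @param model a `transcript_model`.
#' @param pos genomic position(s), 0-based.
#' @return integer transcript coordinate(s); `NA` for non-exonic positions.
#' @export
genomic_to_transcript <- function(model, pos) {
  txs <- exon_tx_starts(model)
  vapply(pos, function(p) {
    i <- which(model$exon_starts <= p & p < model$exon_ends)
    if (length(i) != 1L) return(NA_integer_)
    if (model$strand == "+") txs[i] + (p - model$exon_starts[i])
    else txs[i] + (model$exon_ends[i] - 1L - p)
  }, integer(1))
}

#' Map a transcript coordinate back to a genomic position
#'
#' Inverse of [genomic_to_transcript()] for exonic positions.
#'
#' @param model a `transcript_model`.
#' @param tpos transcript coordinate(s), 0-based, in `[0, transcript length)`.
#' @return integer genomic position(s), 0-based.
#' @export
transcript_to_genomic <- function(model, tpos) {
  txs <- exon_tx_starts(model)
  lens <- exon_lengths(model)
  vapply(tpos, function(tp) {
    if (tp < 0 || tp >= transcript_length(model)) return(NA_integer_)
    i <- max(which(txs <= tp))
    off <- tp - txs[i]
    if (model$strand == "+") model$exon_starts[i] + off
    else model$exon_ends[i] - 1L - off
  }, integer(1))
}

# 1-based exon index containing transcript coordinate tpos
exon_index_at <- function(model, tpos) {
  txs <- exon_tx_starts(model)
  if (tpos < 0 || tpos >= transcript_length(model)) return(NA_integer_)
  max(which(txs <= tpos))
}

#' Reading-frame phase at a transcript coordinate
#'
#' @param model a `transcript_model`.
#' @param tpos transcript coordinate (nt, 0-based).
#' @return 0, 1 or 2 when `cds_start <= tpos <= cds_end`; `NA` (non-coding)
#'   when the transcript has no CDS or `tpos` lies in a UTR.
#' @export
phase_at <- function(model, tpos) {
  if (is.na(model$cds_start)) return(NA_integer_)
  if (tpos < model$cds_start || tpos > model$cds_end) return(NA_integer_)
  as.integer((tpos - model$cds_start) %% 3L)
}

#' Assemble a gene annotation from transcript models
#'
#' @param transcripts list of `transcript_model` objects.
#' @param rtk_genes character vector of RTK gene symbols; defaults to the
#'   twelve clinically relevant RTKs in [RTK_GENES].
#' @return an object of class `gene_annotation`.
#' @export
gene_annotation <- function(transcripts, rtk_genes = RTK_GENES) {
  ids <- vapply(transcripts, `[[`, "", "tx_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  genes <- vapply(transcripts, `[[`, "", "gene")
  structure(list(transcripts = transcripts,
                 by_gene = split(ids, genes),
                 rtk_genes = toupper(rtk_genes)),
            class = "gene_annotation")
}

#' @export
print.gene_annotation <- function(x, ...) {
  cat(sprintf("<gene_annotation> %d transcripts, %d genes (%d RTK symbols tracked)\n",
              length(x$transcripts), length(x$by_gene), length(x$rtk_genes)))
  invisible(x)
}

#' Transcripts of a gene
#' @param ann a `gene_annotation`.
#' @param gene gene symbol.
#' @return list of `transcript_model` (empty if the gene is absent).
#' @export
gene_transcripts <- function(ann, gene) {
  ids <- ann$by_gene[[gene]]
  if (is.null(ids)) list() else ann$transcripts[ids]
}

# ---- file input ------------------------------------------------------------

# quick structural validation so malformed lines are reported by number
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(lines)
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  bad <- which(body)[nf < 9]
  if (length(bad))
    stop("parse error in ", path, " at line ", bad[1],
         ": expected >= 9 tab-separated fields", call. = FALSE)
  invisible(TRUE)
}

#' Load a transcript annotation (GTF or BED12)
#'
#' Reads an Ensembl-dialect GTF (`exon` and `CDS` features with
#' `gene_name`/`gene_id` and `transcript_id` attributes) or a BED12 file and
#' normalizes everything to the internal 0-based half-open convention with
#' exons in transcript orientation. CDS bounds are converted to transcript
#' coordinates. For BED12 the `name` field supplies the transcript id; a
#' `GENE|TX` name is split into gene symbol and transcript id.
#'
#' @param path annotation file (`.gtf`/`.gff` or `.bed`).
#' @param domain_table optional TSV with header
#'   `transcript_id, tk_start, tk_end` giving tyrosine-kinase domain intervals
#'   in transcript coordinates (nt, 0-based half-open).
#' @param rtk_genes RTK symbol set, defaulting to [RTK_GENES].
#' @return a `gene_annotation`.
#' @export
load_annotation <- function(path, domain_table = NULL, rtk_genes = RTK_GENES) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  models <- if (ext %in% c("gtf", "gff", "gff2")) {
    validate_gtf_lines(path)
    gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
    models_from_gtf(gr)
  } else if (ext == "bed") {
    gr <- tryCatch(rtracklayer::import(path, format = "bed"),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e), call. = FALSE))
    models_from_bed12(gr)
  } else stop("unrecognized annotation format: .", ext, " (expected GTF or BED)")

  if (!is.null(domain_table)) models <- apply_domain_table(models, domain_table)
  gene_annotation(models, rtk_genes = rtk_genes)
}

models_from_gtf <- function(gr) {
  md <- S4Vectors::mcols(gr)
  keep <- md$type %in% c("exon", "CDS")
  gr <- gr[keep]; md <- S4Vectors::mcols(gr)
  if (!length(gr)) stop("no exon/CDS features found")
  txid <- as.character(md$transcript_id)
  gname <- if (!is.null(md$gene_name)) as.character(md$gene_name)
           else as.character(md$gene_id)
  out <- list()
  for (tx in unique(txid)) {
    sel <- txid == tx
    sub <- gr[sel]
    types <- as.character(S4Vectors::mcols(sub)$type)
    ex <- sub[types == "exon"]
    if (!length(ex)) next
    strand <- as.character(BiocGenerics::strand(ex))[1]
    m <- transcript_model(
      gene = gname[sel][1], tx_id = tx,
      chrom = as.character(GenomicRanges::seqnames(ex))[1], strand = strand,
      exon_starts = BiocGenerics::start(ex) - 1L, exon_ends = BiocGenerics::end(ex))
    cds <- sub[types == "CDS"]
    if (length(cds)) {
      cs <- BiocGenerics::start(cds) - 1L; ce <- BiocGenerics::end(cds)
      # 5'-most and 3'-most coding bases in transcript orientation
      b5 <- if (strand == "+") min(cs) else max(ce) - 1L
      b3 <- if (strand == "+") max(ce) - 1L else min(cs)
      t5 <- genomic_to_transcript(m, b5); t3 <- genomic_to_transcript(m, b3)
      if (is.na(t5) || is.na(t3)) stop("CDS outside exons for transcript ", tx)
      m$cds_start <- t5; m$cds_end <- t3 + 1L
    }
    out[[tx]] <- m
  }
  unname(out)
}

models_from_bed12 <- function(gr) {
  md <- S4Vectors::mcols(gr)
  out <- vector("list", length(gr))
  for (i in seq_along(gr)) {
    nm <- as.character(md$name[i])
    parts <- strsplit(nm, "|", fixed = TRUE)[[1]]
    gene <- parts[1]; tx <- if (length(parts) > 1) parts[2] else parts[1]
    blocks <- md$blocks[[i]]                       # relative 1-based within chromStart
    cstart <- BiocGenerics::start(gr[i]) - 1L
    es <- cstart + BiocGenerics::start(blocks) - 1L
    ee <- cstart + BiocGenerics::end(blocks)
    strand <- as.character(BiocGenerics::strand(gr[i]))
    m <- transcript_model(gene, tx, as.character(GenomicRanges::seqnames(gr[i])),
                          strand, es, ee)
    thick <- md$thick[i]
    ts <- BiocGenerics::start(thick) - 1L; te <- BiocGenerics::end(thick)
    if (te > ts) {                                 # thick interval = CDS
      b5 <- if (strand == "+") ts else te - 1L
      b3 <- if (strand == "+") te - 1L else ts
      t5 <- genomic_to_transcript(m, b5); t3 <- genomic_to_transcript(m, b3)
      if (!is.na(t5) && !is.na(t3)) { m$cds_start <- t5; m$cds_end <- t3 + 1L }
    }
    out[[i]] <- m
  }
  out
}

apply_domain_table <- function(models, domain_table) {
  dt <- utils::read.delim(domain_table, stringsAsFactors = FALSE)
  need <- c("transcript_id", "tk_start", "tk_end")
  if (!all(need %in% names(dt)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  ids <- vapply(models, `[[`, "", "tx_id")
  for (j in seq_len(nrow(dt))) {
    i <- match(dt$transcript_id[j], ids)
    if (is.na(i)) next
    len <- transcript_length(models[[i]])
    if (dt$tk_start[j] < 0 || dt$tk_end[j] > len || dt$tk_start[j] >= dt$tk_end[j])
      stop("domain interval [", dt$tk_start[j], ",", dt$tk_end[j],
           ") outside transcript ", dt$transcript_id[j], " (length ", len, ")")
    models[[i]]$tk_start <- as.integer(dt$tk_start[j])
    models[[i]]$tk_end <- as.integer(dt$tk_end[j])
  }
  models
}

# exon GRanges for one transcript (genomic order), used for counting
exon_granges <- function(model) {
  GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(start = model$exon_starts + 1L, end = model$exon_ends),
    strand = model$strand)
}
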