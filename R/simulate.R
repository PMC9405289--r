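# Synthetic data with controlled fusion signal: toy two-gene annotations,
# junction-spanning chimeric reads, and exon coverage profiles with an
# optional downstream step change. Everything is deterministic under the
# config seed, so the screening, annotation, coverage and classifier
# modules are testable without any external data.

#' Simulation configuration
#'
#' Defaults emulate the FFPE study conditions the triage criteria were
#' derived under: 50 nt single-end reads, a 20-exon RTK 3' partner fused at
#' exon 12 (the classic intra-chromosomal RET rearrangement geometry), and
#' a strong promoter-driven downstream coverage step.
#'
#' @param n_exons exons per toy gene.
#' @param exon_length exon length (nt).
#' @param junction_exon 1-based first retained exon of the 3' (RTK) gene.
#' @param donor_exon 1-based last retained exon of the 5' partner.
#' @param fold_change downstream/upstream mean coverage ratio (>= 1) in the
#'   fusion sample.
#' @param noise_cv coefficient of variation of per-exon count noise.
#' @param n_controls number of control (fusion-free) samples.
#' @param n_reads_junction chimeric reads placed on the junction.
#' @param read_length read length (nt); FFPE libraries yield ~50 nt reads.
#' @param boundary_offset shift (nt) of the acceptor segment away from the
#'   exon boundary; 0 is a clean, splice-site-exact junction.
#' @param min_overhang minimum moiety length within a read (nt).
#' @param duplicate_rate fraction of junction reads that are exact sequence
#'   duplicates of another read.
#' @param base_mean mean per-exon read count in controls.
#' @param depth total mapped reads per simulated sample.
#' @param tk_straddle place the toy TK domain straddling the junction
#'   instead of fully downstream of it.
#' @param seed integer seed; every generator is reproducible given it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_exons = 20L, exon_length = 150L, junction_exon = 12L,
                       donor_exon = 3L, fold_change = 10, noise_cv = 0.2,
                       n_controls = 20L, n_reads_junction = 5L,
                       read_length = 50L, boundary_offset = 0L,
                       min_overhang = 10L, duplicate_rate = 0,
                       base_mean = 100, depth = 1e6, tk_straddle = FALSE,
                       seed = 1L) {
  cfg <- list(n_exons = as.integer(n_exons), exon_length = as.integer(exon_length),
              junction_exon = as.integer(junction_exon),
              donor_exon = as.integer(donor_exon),
              fold_change = fold_change, noise_cv = noise_cv,
              n_controls = as.integer(n_controls),
              n_reads_junction = as.integer(n_reads_junction),
              read_length = as.integer(read_length),
              boundary_offset = as.integer(boundary_offset),
              min_overhang = as.integer(min_overhang),
              duplicate_rate = duplicate_rate,
              base_mean = base_mean, depth = depth, tk_straddle = tk_straddle,
              seed = as.integer(seed))
  stopifnot(cfg$n_exons >= 2, cfg$junction_exon >= 1,
            cfg$junction_exon <= cfg$n_exons, cfg$fold_change >= 1,
            cfg$read_length >= 2 * cfg$min_overhang)
  structure(cfg, class = "sim_config")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

#' Toy two-gene annotation with reference sequences
#'
#' Builds a non-RTK 5' partner (`PRTN1`, transcript `TOY5P`) and an RTK 3'
#' partner (`RET`, transcript `TOYRTK`) on one toy chromosome, both plus
#' strand, with a CDS starting 60 nt into each transcript and a TK domain
#' on the RTK gene placed (by default) fully downstream of the junction
#' exon. Also draws a random transcript sequence for each gene.
#'
#' @param config a `sim_config`.
#' @return list with `ann` (a `gene_annotation`) and `seqs` (named character
#'   vector of transcript sequences, transcript orientation).
#' @export
sim_annotation <- function(config) {
  set.seed(config$seed)
  n <- config$n_exons; el <- config$exon_length; intron <- 100L
  mk_exons <- function(origin) {
    starts <- origin + (0:(n - 1)) * (el + intron)
    list(starts = starts, ends = starts + el)
  }
  len <- n * el
  e5 <- mk_exons(1000L)
  e3 <- mk_exons(1000L + n * (el + intron) + 10000L)
  txs <- c(0L, cumsum(rep(el, n)))[1:n]            # exon tx starts
  jt <- txs[config$junction_exon]                  # junction tpos on RTK gene
  if (config$tk_straddle) {
    tk <- c(max(0L, jt - 100L), min(len, jt + 100L))
  } else {
    tk <- c(min(jt + el, len - 200L), min(jt + el + 200L, len))
  }
  m5 <- transcript_model("PRTN1", "TOY5P", "chrT", "+", e5$starts, e5$ends,
                         cds_start = 60L, cds_end = len - 60L)
  m3 <- transcript_model("RET", "TOYRTK", "chrT", "+", e3$starts, e3$ends,
                         cds_start = 60L, cds_end = len - 60L,
                         tk_start = tk[1], tk_end = tk[2])
  seqs <- c(TOY5P = random_dna(len), TOYRTK = random_dna(len))
  list(ann = gene_annotation(list(m5, m3)), seqs = seqs)
}

# genomic CDS segments of a model (list of start/end pairs), for GTF export
cds_genomic_segments <- function(model) {
  if (is.na(model$cds_start)) return(NULL)
  txs <- exon_tx_starts(model); lens <- exon_lengths(model)
  segs <- list()
  for (i in seq_along(lens)) {
    a <- max(model$cds_start, txs[i]); b <- min(model$cds_end, txs[i] + lens[i])
    if (a >= b) next
    g1 <- transcript_to_genomic(model, a)
    g2 <- transcript_to_genomic(model, b - 1L)
    segs[[length(segs) + 1L]] <- c(min(g1, g2), max(g1, g2) + 1L)
  }
  segs
}

#' Write a gene annotation as GTF
#'
#' Ensembl-dialect exon and CDS features (1-based inclusive coordinates),
#' suitable for re-reading with [load_annotation()].
#'
#' @param ann a `gene_annotation`.
#' @param path output file.
#' @export
write_gtf <- function(ann, path) {
  lines <- character()
  for (m in ann$transcripts) {
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                        m$gene, m$tx_id, m$gene)
    for (i in seq_along(m$exon_starts)) {
      lines <- c(lines, paste(m$chrom, "toy", "exon",
                              m$exon_starts[i] + 1L, m$exon_ends[i],
                              ".", m$strand, ".", attr_str, sep = "\t"))
    }
    for (seg in cds_genomic_segments(m)) {
      lines <- c(lines, paste(m$chrom, "toy", "CDS", seg[1] + 1L, seg[2],
                              ".", m$strand, ".", attr_str, sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Simulate junction-spanning chimeric reads
#'
#' Each read splits into a 5' moiety ending on the donor exon's 3' boundary
#' of the 5' partner and a 3' moiety starting `boundary_offset` nt from the
#' acceptor exon's 5' boundary of the RTK gene. With offset 0 every read
#' passes screening at tolerance 0; any non-zero offset breaks the
#' exact-boundary criterion.
#'
#' @param config a `sim_config`.
#' @param annset output of [sim_annotation()] (regenerated from `config`
#'   when omitted).
#' @param sample_id sample label for the candidate rows.
#' @return data.frame in the candidate-table layout of [read_candidates()].
#' @export
sim_chimeric_reads <- function(config, annset = sim_annotation(config),
                               sample_id = "SIM-1") {
  set.seed(config$seed + 1L)
  m5 <- annset$ann$transcripts[["TOY5P"]]
  m3 <- annset$ann$transcripts[["TOYRTK"]]
  el <- config$exon_length
  bp5 <- config$donor_exon * el                 # tx nt retained from 5' gene
  bp3 <- (config$junction_exon - 1L) * el       # first retained tpos, RTK gene
  off <- config$boundary_offset
  n <- config$n_reads_junction
  lo <- config$min_overhang; hi <- config$read_length - config$min_overhang
  # without replacement where possible, so equal sequences arise only from
  # the explicit duplicate injection below
  split_at <- sample(lo:hi, n, replace = n > (hi - lo + 1L))
  dup <- stats::runif(n) < config$duplicate_rate
  dup[1] <- FALSE
  for (i in which(dup)) split_at[i] <- split_at[i - 1L]

  rows <- lapply(seq_len(n), function(i) {
    l5 <- split_at[i]; l3 <- config$read_length - l5
    seq5 <- substr(annset$seqs[["TOY5P"]], bp5 - l5 + 1L, bp5)
    seq3 <- substr(annset$seqs[["TOYRTK"]], bp3 + off + 1L, bp3 + off + l3)
    # both toy genes are plus strand with exon-aligned segments
    g5_end <- transcript_to_genomic(m5, bp5 - 1L) + 1L
    g3_start <- transcript_to_genomic(m3, bp3) + off
    data.frame(sample_id = sample_id,
               read_id = sprintf("simread_%03d", i),
               sequence = paste0(seq5, seq3),
               seg5_chrom = m5$chrom, seg5_start = g5_end - l5,
               seg5_end = g5_end, seg5_strand = "+", seg5_nhits = 1L,
               seg3_chrom = m3$chrom, seg3_start = g3_start,
               seg3_end = g3_start + l3, seg3_strand = "+", seg3_nhits = 1L,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# lognormal counts with mean mu and coefficient of variation cv
rlnorm_mean_cv <- function(n, mu, cv) {
  if (cv <= 0) return(rep(mu, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate exon coverage with a fusion-induced downstream step
#'
#' Control samples draw i.i.d. per-exon counts around `base_mean` with
#' lognormal noise at `noise_cv`; the fusion sample multiplies the means of
#' exons from `junction_exon` onward by `fold_change`. Counts are rounded
#' to integers.
#'
#' @param config a `sim_config`.
#' @param model the transcript the profiles describe (defaults to the toy
#'   RTK transcript implied by `config`).
#' @param norm_mode normalization of the returned profiles (`"depth"` for
#'   the within-sample asymmetry test, `"gene"` for cohort comparison).
#' @return list with `fusion` (a `coverage_profile`) and `controls` (list of
#'   `coverage_profile`s).
#' @export
sim_coverage <- function(config, model = NULL,
                         norm_mode = c("depth", "gene")) {
  norm_mode <- match.arg(norm_mode)
  if (is.null(model)) model <- sim_annotation(config)$ann$transcripts[["TOYRTK"]]
  set.seed(config$seed + 2L)
  n <- length(model$exon_starts)
  k <- config$junction_exon
  mu <- rep(config$base_mean, n)
  mu_fusion <- mu
  mu_fusion[k:n] <- mu_fusion[k:n] * config$fold_change
  controls <- lapply(seq_len(config$n_controls), function(i) {
    cts <- round(rlnorm_mean_cv(n, mu, config$noise_cv))
    coverage_profile(sprintf("CTRL-%02d", i), model, cts,
                     depth = config$depth, norm_mode = norm_mode)
  })
  fus_cts <- round(rlnorm_mean_cv(n, mu_fusion, config$noise_cv))
  list(fusion = coverage_profile("FUSION-1", model, fus_cts,
                                 depth = config$depth, norm_mode = norm_mode),
       controls = controls)
}
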