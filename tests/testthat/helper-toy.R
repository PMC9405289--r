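# Shared toy constructors used across the suite.

# simple plus/minus strand toy transcript: exons of given lengths separated
# by 100 nt introns, starting at genomic position 1000
toy_model <- function(exon_lens, strand = "+", gene = "TOYG", tx = "TOYT",
                      cds_start = NA, cds_end = NA, tk_start = NA, tk_end = NA,
                      chrom = "chrT", origin = 1000L) {
  starts <- origin + cumsum(c(0L, head(exon_lens, -1) + 100L))
  transcript_model(gene, tx, chrom, strand, starts, starts + exon_lens,
                   cds_start = cds_start, cds_end = cds_end,
                   tk_start = tk_start, tk_end = tk_end)
}

# a coverage_profile carrying given normalized values directly (for tests of
# cohort statistics, which only read values/tx_id/norm_mode)
profile_from_values <- function(values, sample_id = "S", tx_id = "TOYT",
                                norm_mode = "gene") {
  structure(list(sample_id = sample_id, tx_id = tx_id,
                 counts = rep(NA_integer_, length(values)),
                 lengths = rep(1L, length(values)), depth = NA,
                 norm_mode = norm_mode, values = values),
            class = "coverage_profile")
}

# random-sequence toy gene pair with controllable CDS bounds, for frame tests
toy_coding_pair <- function(len5 = 600L, len3 = 900L, cds5 = c(60L, 540L),
                            cds3 = c(60L, 840L), seed = 1) {
  set.seed(seed)
  seq5 <- paste(sample(c("A", "C", "G", "T"), len5, TRUE), collapse = "")
  seq3 <- paste(sample(c("A", "C", "G", "T"), len3, TRUE), collapse = "")
  m5 <- toy_model(c(len5), gene = "G5", tx = "TX5",
                  cds_start = cds5[1], cds_end = cds5[2])
  m3 <- toy_model(c(len3), gene = "G3", tx = "TX3", origin = 100000L,
                  cds_start = cds3[1], cds_end = cds3[2])
  list(m5 = m5, seq5 = seq5, m3 = m3, seq3 = seq3)
}

# Sequence-level reading-frame oracle, independent of phase arithmetic:
# splice the retained coding fragments, translate, and check the fused
# protein continues the 3' partner's native protein (its translation from
# the first native codon boundary at/after the breakpoint is a suffix of
# the fused translation).
orf_oracle <- function(pair, bp5, bp3) {
  m5 <- pair$m5; m3 <- pair$m3
  if (bp5 <= m5$cds_start || bp5 > m5$cds_end) return("no")
  if (bp3 < m3$cds_start || bp3 >= m3$cds_end) return("no")
  frag5 <- substr(pair$seq5, m5$cds_start + 1L, bp5)
  frag3 <- substr(pair$seq3, bp3 + 1L, m3$cds_end)
  fused <- paste0(frag5, frag3)
  trim <- function(s) substr(s, 1L, 3L * (nchar(s) %/% 3L))
  aa <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(trim(s)), no.init.codon = TRUE, if.fuzzy.codon = "X"))
  off <- (3L - (bp3 - m3$cds_start) %% 3L) %% 3L
  native3 <- substr(pair$seq3, bp3 + off + 1L, m3$cds_end)
  aa_fused <- aa(fused)
  aa_native <- aa(native3)
  stopifnot(nchar(aa_native) >= 5)        # enough codons to make a match decisive
  if (endsWith(aa_fused, aa_native)) "yes" else "no"
}
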