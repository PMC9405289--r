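# Exon counting, double normalization, asymmetry test and cohort baseline.

test_that("normalization follows the RPKM-style and gene-total formulas", {
  expect_equal(normalize_coverage(c(100, 100), c(1000, 1000), 1e6, "depth"),
               c(100, 100))
  # doubling counts doubles depth-mode values, leaves gene-mode unchanged
  v1 <- normalize_coverage(c(10, 30), c(100, 200), 1e6, "depth")
  expect_equal(normalize_coverage(c(20, 60), c(100, 200), 1e6, "depth"), 2 * v1)
  g1 <- normalize_coverage(c(10, 30), c(100, 200), norm_mode = "gene")
  expect_equal(normalize_coverage(c(20, 60), c(100, 200), norm_mode = "gene"), g1)
  # uniform counts and equal lengths -> equal gene-mode values summing via lengths to 1
  g <- normalize_coverage(rep(5, 4), rep(100, 4), norm_mode = "gene")
  expect_equal(length(unique(g)), 1)
  expect_equal(sum(g * rep(100, 4)), 1)
  # unexpressed gene degenerates to zeros without division error
  expect_equal(normalize_coverage(c(0, 0, 0), c(100, 100, 100), norm_mode = "gene"),
               c(0, 0, 0))
  expect_error(normalize_coverage(c(1, 2), c(100, 100), 0, "depth"), "depth")
})

test_that("exon counting matches brute-force interval overlap", {
  m <- toy_model(c(150L, 120L, 90L))
  reads <- GenomicRanges::GRanges("chrT", IRanges::IRanges(
    start = c(m$exon_starts[2] + c(1, 5, 40), m$exon_ends[1] - 4),
    width = c(50, 50, 50, 120)))
  cts <- exon_counts(reads, m)
  # brute force: overlap of each read with each exon by >= 1 base
  brute <- vapply(seq_along(m$exon_starts), function(i)
    sum(GenomicRanges::start(reads) <= m$exon_ends[i] &
        GenomicRanges::end(reads) >= m$exon_starts[i] + 1), 0)
  expect_equal(cts, as.integer(brute))
  expect_equal(cts[1], 1L)              # junction read touches exon 1
  expect_equal(cts[2], 4L)              # three internal + the junction read
  expect_equal(exon_counts(GenomicRanges::GRanges(), m), c(0L, 0L, 0L))
})

test_that("BAM counting is multicov-equivalent including junction reads", {
  m <- toy_model(c(150L, 120L))        # exons chrT:1001-1150 and 1251-1370 (1-based)
  sam <- tempfile(fileext = ".sam")
  reads <- c(
    "r1\t0\tchrT\t1260\t60\t50M\t*\t0\t0\t*\t*",     # inside exon 2
    "r2\t0\tchrT\t1300\t60\t50M\t*\t0\t0\t*\t*",     # inside exon 2
    "r3\t0\tchrT\t1141\t60\t10M100N10M\t*\t0\t0\t*\t*")  # spans the junction
  writeLines(c("@HD\tVN:1.6\tSO:coordinate", "@SQ\tSN:chrT\tLN:5000", reads), sam)
  bam <- Rsamtools::asBam(sam, tempfile(), overwrite = TRUE)
  expect_equal(exon_counts(bam, m), c(1L, 3L))
  other <- toy_model(c(100L), chrom = "chrX", tx = "TX_OTHER")
  expect_error(exon_counts(bam, other), "chrX")
})

test_that("counts TSV input fills exons by index", {
  m <- toy_model(c(100L, 100L, 100L))
  path <- tempfile(fileext = ".tsv")
  write.table(data.frame(transcript_id = c("TOYT", "TOYT", "OTHER"),
                         exon_index = c(1, 3, 2), count = c(7, 9, 99)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_equal(exon_counts(path, m), c(7L, 0L, 9L))
})

test_that("junction split partitions exons into upstream and downstream", {
  m <- toy_model(rep(150L, 20))
  prof <- coverage_profile("S", m, rep(10L, 20), depth = 1e6)
  halves <- split_at_junction(prof, 12)
  expect_length(halves$upstream, 11)
  expect_length(halves$downstream, 9)
  expect_length(split_at_junction(prof, 2)$upstream, 1)
  expect_length(split_at_junction(prof, 1)$upstream, 0)
  expect_error(split_at_junction(prof, 21), "out of range")
})

test_that("asymmetry test matches the closed-form Welch statistic", {
  set.seed(5)
  up <- rnorm(10, 1, 0.1); down <- rnorm(10, 10, 1)
  res <- asymmetry_ttest(up, down)
  # independent closed form: t and Welch-Satterthwaite df from sample moments
  se <- sqrt(var(up) / 10 + var(down) / 10)
  t_hand <- (mean(down) - mean(up)) / se
  df_hand <- se^4 / ((var(up) / 10)^2 / 9 + (var(down) / 10)^2 / 9)
  p_hand <- stats::pt(t_hand, df_hand, lower.tail = FALSE)
  expect_equal(res$t_statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$p_value, p_hand, tolerance = 1e-12)
  expect_lt(res$p_value, 0.001)
  expect_equal(res$criterion_met, "yes")
})

test_that("asymmetry test handles identical, reversed and degenerate inputs", {
  expect_equal(asymmetry_ttest(rep(1, 5), rep(1, 5))$p_value, 0.5)
  expect_equal(asymmetry_ttest(rep(1, 5), rep(1, 5))$criterion_met, "no")
  # downstream uniformly lower: never met regardless of p
  set.seed(8)
  res <- asymmetry_ttest(rnorm(10, 10, 0.5), rnorm(10, 1, 0.5))
  expect_equal(res$direction, "upstream_greater")
  expect_equal(res$criterion_met, "no")
  # one exon on a side is not testable
  res1 <- asymmetry_ttest(2, c(5, 6, 7))
  expect_equal(res1$criterion_met, "no")
  expect_equal(res1$reason, "insufficient exons")
})

test_that("cohort baseline reproduces independently computed percentiles and CI", {
  set.seed(12)
  vals <- matrix(rlnorm(20 * 6, 0, 0.3), nrow = 20)
  profiles <- lapply(1:20, function(i)
    profile_from_values(vals[i, ], sample_id = paste0("C", i)))
  base <- cohort_baseline(profiles)
  expect_equal(base$mean, colMeans(vals))
  expect_equal(base$p95, apply(vals, 2, quantile, 0.95))
  i <- 3
  ci <- t.test(vals[, i])$conf.int
  expect_equal(unname(base$ci_low[i]), ci[1])
  expect_equal(unname(base$ci_high[i]), ci[2])
  expect_true(all(base$ci_low <= base$mean & base$mean <= base$ci_high))
})

test_that("cohort pattern fires on a downstream step and not on the cohort mean", {
  set.seed(33)
  n_ex <- 12; k <- 6
  vals <- matrix(rnorm(20 * n_ex, 1, 0.1), nrow = 20)
  base <- cohort_baseline(lapply(1:20, function(i) profile_from_values(vals[i, ])))
  fusion <- profile_from_values(c(colMeans(vals)[1:(k - 1)],
                                  10 * colMeans(vals)[k:n_ex]))
  expect_equal(cohort_pattern(fusion, base, k), "yes")
  flat <- profile_from_values(colMeans(vals))
  expect_equal(cohort_pattern(flat, base, k), "no")
  # relaxed aggregation: one lagging downstream exon passes at f = 0.8
  lagging <- fusion; lagging$values[n_ex] <- base$mean[n_ex]
  expect_equal(cohort_pattern(lagging, base, k), "no")
  expect_equal(cohort_pattern(lagging, base, k, f = 0.8), "yes")
  expect_error(cohort_pattern(profile_from_values(rep(1, n_ex), tx_id = "X"),
                              base, k), "transcript")
})

test_that("a gene silent in controls but driven downstream in the fusion sample fires", {
  # the unexpressed-partner pattern: controls have no reads at all
  ctrl <- lapply(1:10, function(i) profile_from_values(rep(0, 8)))
  base <- cohort_baseline(ctrl)
  fusion <- profile_from_values(c(rep(0, 3), rep(0.4, 5)))
  expect_equal(cohort_pattern(fusion, base, 4), "yes")
})

test_that("downstream criterion combines the tests and respects ND semantics", {
  yes_t <- asymmetry_ttest(rnorm(10, 1, 0.1), rnorm(10, 10, 0.5))
  no_t <- asymmetry_ttest(rep(1, 5), rep(1, 5))
  expect_equal(downstream_criterion(yes_t, "no", "3'"), "yes")
  expect_equal(downstream_criterion(no_t, "yes", "3'"), "yes")   # the and/or
  expect_equal(downstream_criterion(no_t, "no", "3'"), "no")
  expect_equal(downstream_criterion(yes_t, "yes", "5'"), "ND")
  expect_equal(downstream_criterion(yes_t, "yes", "none"), "ND")
  expect_equal(downstream_criterion(yes_t, NULL, "both"), "yes")
})

test_that("moiety expression averages retained exons in depth mode", {
  m <- toy_model(rep(100L, 4))
  p5 <- coverage_profile("S", m, c(10L, 20L, 30L, 40L), depth = 1e6)
  p3 <- coverage_profile("S", m, c(8L, 8L, 8L, 8L), depth = 1e6)
  me <- moiety_expression(p5, p3, last_retained_exon5 = 2, first_retained_exon3 = 3)
  expect_equal(unname(me["mean5"]), mean(c(10, 20) / 0.1 / 1))   # RPKM arithmetic
  expect_equal(unname(me["mean3"]), mean(c(8, 8) / 0.1 / 1))
  expect_equal(unname(me["mean5"] > me["mean3"]), TRUE)
})
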