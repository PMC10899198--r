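dr_track <- function(starts, dr, chrom = "chr1") {
  data.frame(chrom = chrom, start = starts, end = starts + 500L, dr = dr,
             stringsAsFactors = FALSE)
}

test_that("depletion-rank means average the covering 500 bp windows", {
  v <- data.frame(chrom = "chr1", pos = 1000L)
  # 50 bp grid: windows with start in (499, 999] cover 0-based pos 999
  grid <- dr_track(seq(0L, 2000L, by = 50L), 0.4)
  expect_equal(dr_mean(v, grid), 0.4)
  covering <- grid$start <= 999L & grid$end > 999L
  expect_equal(sum(covering), 10L) # ~10 windows per variant on this grid
  # arithmetic mean of distinct covering scores
  t3 <- dr_track(c(600L, 700L, 800L), c(0.1, 0.2, 0.3))
  expect_equal(dr_mean(v, t3), 0.2)
  # shuffling the track does not change the mean
  expect_equal(dr_mean(v, t3[c(3, 1, 2), ]), 0.2)
  # variant outside the track extent
  expect_true(is.na(dr_mean(data.frame(chrom = "chr1", pos = 99999L), t3)))
  bad <- data.frame(chrom = "chr1", start = 0L, end = 400L, dr = 0.5)
  expect_error(dr_mean(v, bad), class = "mpra_validation_error")
})

test_that("TFBS filtering keeps |score| >= 0.8 inclusive, with direction", {
  sc <- data.frame(
    variant_id = c("rs1", "rs1", "rs2", "rs2", "rs3"),
    tf_name = c("TFa", "TFb", "TFc", "TFd", "TFe"),
    score = c(-0.85, 0.8, 0.5, -0.3, 0.95),
    stringsAsFactors = FALSE)
  out <- filter_tfbs(sc)
  expect_setequal(out$kept$tf_name, c("TFa", "TFb", "TFe"))
  expect_equal(out$kept$direction[out$kept$tf_name == "TFa"], "disrupt")
  expect_equal(out$kept$direction[out$kept$tf_name == "TFe"], "create")
  flags <- setNames(out$flags$disrupts_tfbs, out$flags$variant_id)
  expect_true(flags[["rs1"]]); expect_false(flags[["rs2"]])
  sc$score[1] <- -1.2
  expect_error(filter_tfbs(sc), class = "mpra_validation_error")
})

test_that("flanked overlap uses the +/-100 bp window on BED intervals", {
  v <- data.frame(variant_id = "rs1", chrom = "chr1", pos = 1000L,
                  stringsAsFactors = FALSE)
  hit <- data.frame(chrom = "chr1", start = 1090L, end = 1200L)
  expect_true(overlap_flank(v, hit))
  miss <- data.frame(chrom = "chr1", start = 1101L, end = 1200L)
  expect_false(overlap_flank(v, miss))
  # flank 0: only intervals containing the base itself
  covers <- data.frame(chrom = "chr1", start = 999L, end = 1000L)
  expect_true(overlap_flank(v, covers, flank = 0L))
  expect_false(overlap_flank(v, data.frame(chrom = "chr1", start = 1000L,
                                           end = 1001L), flank = 0L))
  expect_error(overlap_flank(v, hit, flank = -1L),
               class = "mpra_validation_error")
  # track column yields a per-track matrix
  iv <- rbind(cbind(hit, track = "atac"), cbind(miss, track = "h3k27ac"))
  m <- overlap_flank(v, iv)
  expect_equal(dim(m), c(1L, 2L))
  expect_true(m[, "atac"]); expect_false(m[, "h3k27ac"])
})

test_that("k-group proportion tests reproduce the published p-values", {
  # three sub-groups, promoter-state overlap: uncorrected chi-square
  p3 <- proportion_test(c(1, 22, 856), c(27, 91, 5094))
  expect_equal(p3$df, 2)
  expect_equal(round(p3$p.value, 3), 0.033)
  # merged enhancers vs background: Yates-corrected 2x2
  p2 <- proportion_test(c(23, 856), c(118, 5094))
  expect_equal(p2$p.value, 0.518, tolerance = 0.002)
  # DNase class, merged layout
  expect_equal(proportion_test(c(46, 1529), c(118, 5094))$p.value, 0.046,
               tolerance = 0.002)
  # identical proportions at large n
  expect_gt(proportion_test(c(500, 500), c(1000, 1000))$p.value, 0.99)
  expect_error(proportion_test(c(5, 20), c(4, 30)),
               class = "mpra_validation_error")
})

test_that("uncorrected 2-group chi-square equals the squared z-statistic", {
  set.seed(2)
  for (i in 1:20) {
    n <- sample(50:500, 2)
    x <- c(rbinom(1, n[1], 0.3), rbinom(1, n[2], 0.4))
    chi <- proportion_test(x, n, correct = FALSE)$statistic
    # two-proportion z with pooled variance
    p1 <- x[1] / n[1]; p2 <- x[2] / n[2]; pp <- sum(x) / sum(n)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n[1] + 1 / n[2]))
    expect_equal(chi, z^2, tolerance = 1e-10)
  }
})

published_counts <- function() {
  f <- system.file("extdata", "epimark_overlap_counts.tsv",
                   package = "mpracall")
  x <- read.delim(f, comment.char = "#", stringsAsFactors = FALSE)
  counts <- as.matrix(x[, -(1:2)])
  rownames(counts) <- x$group
  list(counts = counts, sizes = setNames(x$size, x$group))
}

test_that("overlap summaries reproduce the published percentage grid", {
  pc <- published_counts()
  os <- summarize_overlaps(pc$counts, pc$sizes,
                           enhancer_groups = c("allele_specific", "general"))
  s <- os$summary
  cell <- function(g, cl) s$pct[s$group == g & s$class == cl]
  expect_equal(cell("allele_specific", "enhancer_state"), 59.26)
  expect_equal(cell("general", "dnase"), 40.66)
  expect_equal(cell("allele_specific", "promoter"), 3.70)
  expect_equal(cell("background", "promoter"), 16.80)
  expect_equal(cell("general", "protein_binding"), 25.27)
  # test layouts: three-group and merged two-group per class
  tests <- os$tests
  expect_equal(round(tests$p_groups[tests$class == "promoter"], 3), 0.033)
  expect_equal(tests$p_merged[tests$class == "promoter"], 0.518,
               tolerance = 0.002)
  expect_equal(tests$p_merged[tests$class == "dnase"], 0.046,
               tolerance = 0.002)
  expect_lt(tests$p_merged[tests$class == "protein_binding"], 0.01)
})

test_that("merging enhancer groups adds counts exactly", {
  pc <- published_counts()
  merged_count <- sum(pc$counts[c("allele_specific", "general"), "promoter"])
  expect_equal(merged_count, 23)
  expect_equal(sum(pc$sizes[c("allele_specific", "general")]), 118)
  # empty class reports a 0 count and 0.00 percent
  counts <- cbind(pc$counts, none = c(0, 0, 0))
  os <- summarize_overlaps(counts, pc$sizes,
                           enhancer_groups = c("allele_specific", "general"))
  expect_true(all(os$summary$pct[os$summary$class == "none"] == 0))
})
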