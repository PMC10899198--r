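FL <- "CCGACGCTCTTCCGATCT"  # forward left guide
FR <- "TCTAGAATTATTACACGG"  # forward right guide
BC <- "ACGTACGTACGTACGTACGT"
rc <- function(x) as.character(
  Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))

test_that("count barcodes are found via assay-specific guide pairs", {
  fwd <- paste0(FL, BC, FR, "CGATT")
  # RNA forward reads anchor on the guide attached at the barcode's end
  expect_identical(extract_count_barcode(paste0(BC, FR, "TT"), NULL, "RNA"), BC)
  expect_identical(extract_count_barcode(fwd, NULL, "RNA"), BC)
  # DNA forward reads require both flanking guides
  expect_identical(extract_count_barcode(fwd, NULL, "DNA"), BC)
  expect_identical(extract_count_barcode(paste0(BC, FR), NULL, "DNA"),
                   NA_character_)
  # reverse reads carry the barcode reverse-complemented
  rev <- rc(paste0(FL, BC, FR, "CGA"))
  expect_identical(extract_count_barcode(NULL, rev, "DNA"), BC)
  expect_identical(extract_count_barcode(NULL, rev, "RNA"), BC)
  # disagreeing mates are rejected as inconsistent
  other <- "TTTTTTTTTTGGGGGGGGGG"
  expect_identical(
    extract_count_barcode(fwd, rc(paste0(FL, other, FR, "CGA")), "DNA"),
    NA_character_)
  # neither read contains guides
  expect_identical(extract_count_barcode("AAAA", "TTTT", "DNA"), NA_character_)
})

make_reads <- function(barcodes) paste0(FL, barcodes, FR, "CGA")

test_that("counting increments mapped cells and tallies orphans", {
  map <- build_barcode_map(c(rep("B1" , 2), "B2"), c("e1", "e1", "e2"))
  map$barcode <- c(BC, "TTTTTTTTTTGGGGGGGGGG")
  reads <- list(
    DNA = list(`1` = list(fwd = make_reads(rep(BC, 10L))),
               `2` = list(fwd = make_reads(c(BC, "GGGGGGGGGGGGGGGGGGGG")))),
    RNA = list(`1` = list(fwd = character()),
               `2` = list(fwd = make_reads("TTTTTTTTTTGGGGGGGGGG"))))
  bc <- count_barcodes(reads, map)
  expect_equal(bc$counts[BC, "dna_1"], 10L)
  expect_equal(bc$counts[BC, "dna_2"], 1L)
  expect_equal(unname(bc$orphans["DNA_2"]), 1L) # unmapped barcode
  expect_equal(sum(bc$counts[, "rna_1"]), 0L)   # empty input, no error
  expect_equal(bc$counts["TTTTTTTTTTGGGGGGGGGG", "rna_2"], 1L)
})

test_that("inconsistent replicate labels between assays error out", {
  map <- build_barcode_map("B1", "e1")
  reads <- list(DNA = list(a = list(fwd = character())),
                RNA = list(b = list(fwd = character())))
  expect_error(count_barcodes(reads, map), class = "mpra_config_error")
})

make_counts <- function(mat) {
  R <- ncol(mat) / 2L
  structure(list(counts = mat, replicates = as.character(seq_len(R)), R = R,
                 orphans = integer(), stats = NULL),
            class = "barcode_counts")
}

test_that("aggregation applies the presence and minimum-barcode rules", {
  # element e1: 6 barcodes present in all replicates; e2: only 4
  bcs <- c(paste0("a", 1:6), paste0("b", 1:4), "c1")
  cm <- matrix(5L, nrow = 11L, ncol = 6L,
               dimnames = list(bcs, c(paste0("dna_", 1:3), paste0("rna_", 1:3))))
  cm["c1", "dna_2"] <- 0L # barcode with DNA counts (5, 0, 5) is excluded
  map <- build_barcode_map(bcs, c(rep("e1", 6), rep("e2", 4), "e1"))
  el <- aggregate_elements(make_counts(cm), map, min_barcodes = 5L)
  expect_equal(el$element_id, "e1")
  expect_equal(el$n_barcodes, 6L)
  expect_equal(el$dna_1, 30L) # c1 not aggregated
  drop <- attr(el, "drop_log")
  expect_equal(drop$element_id, "e2")
  # boundary: exactly 5 qualifying barcodes is retained
  el5 <- aggregate_elements(make_counts(cm), map, min_barcodes = 4L)
  expect_setequal(el5$element_id, c("e1", "e2"))
})

test_that("aggregated counts never exceed the mapped barcode totals", {
  sim <- tiny_sim(seed = 31L)
  smc <- simulate_counts(sim$truth, sim$config)
  map <- build_barcode_map(sim$truth$barcodes$barcode,
                           sim$truth$barcodes$element_id)
  el <- aggregate_elements(smc$counts, map)
  for (col in colnames(smc$counts$counts)) {
    expect_lte(sum(el[[col]]), sum(smc$counts$counts[, col]))
  }
})

test_that("adding reads never decreases contributing barcodes", {
  set.seed(9)
  bcs <- paste0("b", 1:30)
  map <- build_barcode_map(bcs, rep(c("e1", "e2", "e3"), each = 10L))
  cm1 <- matrix(rpois(30 * 6, 1), nrow = 30,
                dimnames = list(bcs, c(paste0("dna_", 1:3), paste0("rna_", 1:3))))
  extra <- matrix(rpois(30 * 6, 1), nrow = 30, dimnames = dimnames(cm1))
  el1 <- aggregate_elements(make_counts(cm1), map, min_barcodes = 1L)
  el2 <- aggregate_elements(make_counts(cm1 + extra), map, min_barcodes = 1L)
  common <- intersect(el1$element_id, el2$element_id)
  expect_true(all(el1$element_id %in% el2$element_id))
  expect_true(all(el2$n_barcodes[match(common, el2$element_id)] >=
                    el1$n_barcodes[match(common, el1$element_id)]))
})

test_that("element counts from simulated FASTQ equal the drawn counts", {
  sim <- tiny_sim(seed = 32L)
  fq <- file.path(tempfile("cnt"), "fq")
  smc <- simulate_counts(sim$truth, sim$config, fastq_dir = fq)
  map <- build_barcode_map(sim$truth$barcodes$barcode,
                           sim$truth$barcodes$element_id)
  cnt <- count_barcodes(smc$fastq, map)
  expect_identical(cnt$counts[rownames(smc$counts$counts), ],
                   smc$counts$counts)
  expect_equal(sum(cnt$orphans), 0L)
})
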