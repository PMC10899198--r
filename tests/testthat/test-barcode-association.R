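ASSOC_AD <- "GGCCTAACTGGCCGCTTGACG"
GL <- "CGCCGAGGCCCGACGCTCTTCCGATCT"
GR <- "TCTAGAGGTACCGCAGGAGCCGCAGTG"

test_that("adapter trimming is an exact-prefix contract", {
  expect_identical(trim_assoc_adapter(paste0(ASSOC_AD, "ACGT")), "ACGT")
  expect_identical(trim_assoc_adapter("TTTT"), NA_character_)
  # read exactly equal to the adapter trims to empty string
  expect_identical(trim_assoc_adapter(ASSOC_AD), "")
  # one substitution inside the adapter rejects the read
  bad <- paste0(sub("^G", "T", ASSOC_AD), "ACGT")
  expect_identical(trim_assoc_adapter(bad), NA_character_)
})

test_that("element matching allows no mismatches and no ambiguity", {
  rl <- random_library(n = 6L, seed = 5L)
  lib <- rl$library
  ref1 <- paste0(lib$insert[1], "CACTGCGGCTCCTGC")
  # a 120-base read spans the variant offset, so it is allele-unique
  expect_identical(match_element(substr(ref1, 1, 120), lib), lib$element_id[1])
  # one substitution -> no match
  mut <- substr(ref1, 1, 120)
  substr(mut, 40, 40) <- if (substr(mut, 40, 40) == "A") "C" else "A"
  expect_identical(match_element(mut, lib), NA_character_)
  # a read shorter than the variant offset is shared by the allele pair
  shared <- substr(lib$insert[1], 1, 90)
  expect_identical(match_element(shared, lib), NA_character_)
  # brute-force confirmation that exactly two elements share that prefix
  refs <- paste0(lib$insert, "CACTGCGGCTCCTGC")
  expect_equal(sum(startsWith(refs, shared)), 2L)
  # empty trimmed read never matches
  expect_identical(match_element("", lib), NA_character_)
  expect_error(match_element("ACGT", lib[0, ]), class = "mpra_validation_error")
})

test_that("association barcodes need both guides exactly 20 bases apart", {
  bc <- "ACGTACGTACGTACGTACGT"
  read <- paste0("TTAG", GL, bc, GR, "GGTT")
  expect_identical(extract_assoc_barcode(read), bc)
  # reverse-complemented read is searched too
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(read)))
  expect_identical(extract_assoc_barcode(rc), bc)
  # 19 bases between the guides -> no extraction
  expect_identical(extract_assoc_barcode(paste0(GL, substr(bc, 1, 19), GR)),
                   NA_character_)
  # N in the barcode -> no extraction
  bcn <- paste0(substr(bc, 1, 19), "N")
  expect_identical(extract_assoc_barcode(paste0(GL, bcn, GR)), NA_character_)
  expect_identical(extract_assoc_barcode("ACGTACGT"), NA_character_)
})

test_that("conflicted barcodes resolve by dominance or drop", {
  m <- build_barcode_map(rep("B1", 5), rep("e1", 5))
  expect_equal(m$support, 5L)
  expect_equal(m$element_id, "e1")
  # 9:1 split meets the 0.9 dominance default
  m <- build_barcode_map(rep("B1", 10), c(rep("e1", 9), "e2"))
  expect_equal(m$element_id, "e1")
  expect_equal(m$support, 9L)
  # 1:1 split has no majority
  m <- build_barcode_map(c("B1", "B1"), c("e1", "e2"))
  expect_equal(nrow(m), 0L)
  expect_equal(attr(m, "stats")$n_ambiguous, 1L)
})

test_that("raising the dominance threshold never maps more barcodes", {
  set.seed(1)
  bc <- sample(paste0("B", 1:40), 600, replace = TRUE)
  el <- sample(paste0("e", 1:4), 600, replace = TRUE)
  sizes <- vapply(c(0.5, 0.7, 0.9, 1.0),
                  function(d) nrow(build_barcode_map(bc, el, dominance = d)),
                  1L)
  expect_true(all(diff(sizes) <= 0L))
})

test_that("error-free association reads round-trip the exact barcode map", {
  sim <- tiny_sim(seed = 21L)
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  simulate_assoc_reads(sim$library, sim$truth, sim$config, r1, r2)
  map <- map_association_reads(r1, r2, sim$library)
  got <- paste(map$barcode, map$element_id)
  want <- paste(sim$truth$barcodes$barcode, sim$truth$barcodes$element_id)
  expect_setequal(got, want) # full recall, nothing fabricated
  s <- attr(map, "stats")
  expect_equal(s$n_element_matched, s$n_pairs)
  expect_equal(s$n_ambiguous, 0L)
})

test_that("read errors cost recall but never precision", {
  sim <- tiny_sim(seed = 22L, read_error_rate = 0.05)
  r1 <- tempfile(fileext = ".fastq"); r2 <- tempfile(fileext = ".fastq")
  simulate_assoc_reads(sim$library, sim$truth, sim$config, r1, r2)
  map <- map_association_reads(r1, r2, sim$library)
  tb <- sim$truth$barcodes
  # recall < 1: some true pairings are lost to corrupted reads
  recovered <- paste(map$barcode, map$element_id)
  expect_lt(sum(paste(tb$barcode, tb$element_id) %in% recovered), nrow(tb))
  # no misassignment: every recovered true barcode maps to its true element
  hit <- map[map$barcode %in% tb$barcode, ]
  expect_identical(hit$element_id,
                   tb$element_id[match(hit$barcode, tb$barcode)])
})
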