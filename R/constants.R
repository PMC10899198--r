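# Fixed sequences of the MPRA construct. All matching in this package is
# exact (no mismatches, no indels), so these literals are load-bearing.

# 15 bp amplification adapters flanking the 200 bp genomic insert
ADAPTER5 <- "ACTGGCCGCTTGACG"
ADAPTER3 <- "CACTGCGGCTCCTGC"

# 21-mer trimmed from the 5' end of association (oligo-sequencing) reads.
# Its last 15 bases equal ADAPTER5, so the trimmed read starts at the insert.
ASSOC_ADAPTER <- "GGCCTAACTGGCCGCTTGACG"

# Guides flanking the 20 bp barcode in association read 2
ASSOC_GUIDE_LEFT  <- "CGCCGAGGCCCGACGCTCTTCCGATCT"
ASSOC_GUIDE_RIGHT <- "TCTAGAGGTACCGCAGGAGCCGCAGTG"

# Guides used to locate barcodes in DNA/RNA count sequencing.
# Forward orientation (barcode read as cloned):
COUNT_FWD_LEFT  <- "CCGACGCTCTTCCGATCT"
COUNT_FWD_RIGHT <- "TCTAGAATTATTACACGG"
# Reverse orientation (barcode appears reverse-complemented):
DNA_REV_LEFT  <- "TCGCCGTGTAATAATTCTAGA"
DNA_REV_RIGHT <- "AGATCGGAAGAGCG"
RNA_REV_LEFT  <- "GTAATAATTCTAGA"
RNA_REV_RIGHT <- "AGATCGGAAGAGCGTC"

BARCODE_LEN <- 20L
INSERT_LEN <- 200L
ELEMENT_LEN <- 230L

#' Construct constants used by the pipeline
#'
#' Returns the fixed adapter and guide sequences assumed by the exact-match
#' read parsers: the 15 bp oligo adapters, the 21-mer association-read
#' adapter, and the barcode-flanking guide sequences for the association,
#' DNA and RNA libraries.
#'
#' @return Named list of character constants.
#' @export
mpra_constants <- function() {
  list(
    adapter5 = ADAPTER5, adapter3 = ADAPTER3,
    assoc_adapter = ASSOC_ADAPTER,
    assoc_guide_left = ASSOC_GUIDE_LEFT, assoc_guide_right = ASSOC_GUIDE_RIGHT,
    count_fwd_left = COUNT_FWD_LEFT, count_fwd_right = COUNT_FWD_RIGHT,
    dna_rev_left = DNA_REV_LEFT, dna_rev_right = DNA_REV_RIGHT,
    rna_rev_left = RNA_REV_LEFT, rna_rev_right = RNA_REV_RIGHT,
    barcode_len = BARCODE_LEN, insert_len = INSERT_LEN,
    element_len = ELEMENT_LEN
  )
}

# reverse complement of plain character vectors (NA-safe)
revcomp <- function(x) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(x[ok]))
    )
  }
  out
}

# vectorized single-capture regex extraction; NA where no match
regex_capture <- function(x, pattern) {
  m <- regexpr(pattern, x, perl = TRUE)
  st <- attr(m, "capture.start")[, 1L]
  len <- attr(m, "capture.length")[, 1L]
  ifelse(m > 0L, substr(x, st, st + len - 1L), NA_character_)
}

stop_mpra <- function(msg, class) {
  stop(structure(
    class = c(class, "mpra_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# round-half-up to `digits` decimals (report parity; R's round() is banker's)
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# coerce a genome given as FASTA path, DNAStringSet, or named character
as_genome <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome) &&
      is.null(names(genome))) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (methods::is(genome, "DNAStringSet")) {
    g <- as.character(genome)
    names(g) <- sub("\\s.*$", "", names(genome))
    return(g)
  }
  if (is.character(genome) && !is.null(names(genome))) return(genome)
  stop_mpra("genome must be a FASTA path, DNAStringSet, or named character vector",
            "mpra_validation_error")
}
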