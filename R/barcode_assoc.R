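#' Trim the association-library adapter
#'
#' Association (oligo-sequencing) read 1 starts with the fixed 21-mer
#' `GGCCTAACTGGCCGCTTGACG`. Reads beginning with it (exact match) are
#' trimmed to their suffix; all other reads are rejected (`NA`). The last
#' 15 bases of the adapter are the element 5' adapter, so a trimmed read
#' starts at the first base of the genomic insert.
#'
#' @param reads Character vector of read sequences.
#' @return Character vector: trimmed suffixes, `NA` where rejected.
#' @export
trim_assoc_adapter <- function(reads) {
  ok <- startsWith(reads, ASSOC_ADAPTER)
  ifelse(ok, substr(reads, nchar(ASSOC_ADAPTER) + 1L, nchar(reads)), NA_character_)
}

#' Match trimmed reads to library elements, exactly
#'
#' A trimmed read matches an element if it is an exact prefix of that
#' element's post-adapter reference (insert + 3' adapter): zero mismatches,
#' zero indels. Reads matching no element, or whose prefix is shared by
#' more than one element (e.g. an allele pair read too short to span the
#' variant base), return `NA`.
#'
#' @param trimmed Character vector of adapter-trimmed reads (`NA` allowed).
#' @param library An `mpra_library`.
#' @return Character vector of element IDs, `NA` where unmatched/ambiguous.
#' @export
match_element <- function(trimmed, library) {
  if (nrow(library) == 0L)
    stop_mpra("library is empty", "mpra_validation_error")
  refs <- paste0(library$insert, ADAPTER3)
  out <- rep(NA_character_, length(trimmed))
  keep <- !is.na(trimmed) & nzchar(trimmed)
  if (!any(keep)) return(out)
  # group reads by length; a length-L read matches iff it equals the
  # length-L prefix of exactly one reference
  lens <- nchar(trimmed[keep])
  for (L in unique(lens)) {
    i <- which(keep)[lens == L]
    valid <- nchar(refs) >= L
    keys <- substr(refs[valid], 1L, L)
    ids <- library$element_id[valid]
    # unique prefixes only: ambiguous prefixes resolve to NA
    tab <- table(keys)
    uniq <- names(tab)[tab == 1L]
    lut <- ids[match(uniq, keys)]
    names(lut) <- uniq
    hit <- lut[trimmed[i]]
    out[i] <- unname(hit)
  }
  out
}

#' Extract the barcode from an association read
#'
#' Finds the 20 bp barcode bounded immediately by the left guide
#' `CGCCGAGGCCCGACGCTCTTCCGATCT` and the right guide
#' `TCTAGAGGTACCGCAGGAGCCGCAGTG` (exact matches, exactly 20 A/C/G/T bases
#' apart). If the guides are not found in the read as given, its reverse
#' complement is searched. Barcodes containing N never match.
#'
#' @param reads Character vector of read-2 sequences.
#' @return Character vector of barcodes, `NA` where extraction fails.
#' @export
extract_assoc_barcode <- function(reads) {
  pat <- paste0(ASSOC_GUIDE_LEFT, "([ACGT]{", BARCODE_LEN, "})", ASSOC_GUIDE_RIGHT)
  bc <- regex_capture(reads, pat)
  miss <- is.na(bc)
  if (any(miss)) bc[miss] <- regex_capture(revcomp(reads[miss]), pat)
  bc
}

#' Aggregate barcode observations into a barcode map
#'
#' Tallies read support per (barcode, element) pair and resolves conflicts:
#' a barcode seen with more than one element is assigned to its majority
#' element when that element's support fraction is at least `dominance`
#' (default 0.9); otherwise it is dropped as ambiguous.
#'
#' @param barcode,element_id Parallel character vectors of observations
#'   (one entry per supporting read pair).
#' @param dominance Minimum majority support fraction to resolve a
#'   conflicted barcode.
#' @param min_support Minimum read support for a mapped barcode.
#' @return A `barcode_map`: data.frame (`barcode`, `element_id`, `support`)
#'   sorted by barcode, with a `stats` attribute.
#' @export
build_barcode_map <- function(barcode, element_id, dominance = 0.9,
                              min_support = 1L) {
  stopifnot(length(barcode) == length(element_id))
  if (length(barcode) == 0L) {
    map <- data.frame(barcode = character(), element_id = character(),
                      support = integer(), stringsAsFactors = FALSE)
    return(structure(map, stats = list(n_observations = 0L, n_ambiguous = 0L,
                                       n_low_support = 0L),
                     class = c("barcode_map", "data.frame")))
  }
  key <- paste(barcode, element_id, sep = "\t")
  tab <- table(key)
  kk <- strsplit(names(tab), "\t", fixed = TRUE)
  df <- data.frame(
    barcode = vapply(kk, `[`, "", 1L),
    element_id = vapply(kk, `[`, "", 2L),
    support = as.integer(tab),
    stringsAsFactors = FALSE
  )
  tot <- tapply(df$support, df$barcode, sum)
  # majority element per barcode (deterministic: ties keep first by order,
  # then fail the dominance check unless dominance <= 0.5)
  df <- df[order(df$barcode, -df$support, df$element_id), ]
  first <- !duplicated(df$barcode)
  map <- df[first, ]
  frac <- map$support / as.numeric(tot[map$barcode])
  tie <- duplicated(paste(df$barcode, df$support)) & !first
  ambiguous <- frac < dominance
  low <- !ambiguous & map$support < min_support
  n_amb <- sum(ambiguous)
  map <- map[!ambiguous & !low, ]
  rownames(map) <- NULL
  structure(map,
            stats = list(n_observations = length(barcode),
                         n_barcodes_seen = length(tot),
                         n_ambiguous = n_amb,
                         n_low_support = sum(low),
                         n_mapped = nrow(map)),
            class = c("barcode_map", "data.frame"))
}

#' @export
print.barcode_map <- function(x, ...) {
  s <- attr(x, "stats")
  cat("Barcode map:", nrow(x), "barcodes ->",
      length(unique(x$element_id)), "elements\n")
  cat("  observations:", s$n_observations,
      "| ambiguous dropped:", s$n_ambiguous,
      "| low support dropped:", s$n_low_support, "\n")
  invisible(x)
}

#' Recover the barcode map from association FASTQ files
#'
#' Runs the full association stage: trims the 5' adapter from read 1,
#' matches the trimmed read exactly against the library, extracts the
#' guide-flanked barcode from read 2 (searching its reverse complement if
#' needed), and aggregates pairs where both succeed into a barcode map.
#'
#' @param fastq1,fastq2 Paths to the paired FASTQ files (read 1 carries
#'   adapter + element; read 2 carries the barcode region).
#' @param library An `mpra_library` (or path to a library FASTA).
#' @param dominance,min_support Conflict-resolution parameters, see
#'   [build_barcode_map()].
#' @return A `barcode_map` whose `stats` attribute also tallies reads
#'   processed, adapter-trimmed, element-matched and barcode-found.
#' @export
map_association_reads <- function(fastq1, fastq2, library, dominance = 0.9,
                                  min_support = 1L) {
  if (is.character(library) && length(library) == 1L)
    library <- read_library_fasta(library)
  r1 <- as.character(Biostrings::readDNAStringSet(fastq1, format = "fastq"))
  r2 <- as.character(Biostrings::readDNAStringSet(fastq2, format = "fastq"))
  if (length(r1) != length(r2))
    stop_mpra("paired FASTQ files differ in read count", "mpra_validation_error")
  trimmed <- trim_assoc_adapter(unname(r1))
  el <- match_element(trimmed, library)
  bc <- extract_assoc_barcode(unname(r2))
  ok <- !is.na(el) & !is.na(bc)
  map <- build_barcode_map(bc[ok], el[ok], dominance = dominance,
                           min_support = min_support)
  s <- attr(map, "stats")
  s$n_pairs <- length(r1)
  s$n_trimmed <- sum(!is.na(trimmed))
  s$n_element_matched <- sum(!is.na(el))
  s$n_barcode_found <- sum(!is.na(bc))
  attr(map, "stats") <- s
  map
}

#' Write / read a barcode map as TSV
#'
#' @param map A `barcode_map`.
#' @param path TSV path (columns `barcode`, `element_id`, `support`).
#' @return `path` (writer) or a `barcode_map` (reader).
#' @export
write_barcode_map <- function(map, path) {
  utils::write.table(as.data.frame(map), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_barcode_map
#' @export
read_barcode_map <- function(path) {
  map <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer"))
  structure(map, class = c("barcode_map", "data.frame"))
}
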