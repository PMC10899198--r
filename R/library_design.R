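#' Read a variant table
#'
#' Reads a tab-separated variant table with columns `chrom`, `pos` (1-based),
#' `variant_id`, `ref`, `alt` and `category`, and validates it: IDs must be
#' unique, both alleles single nucleotides in A/C/G/T, `ref != alt`, and
#' `pos >= 1`. The `category` records how the variant was nominated
#' (e.g. GWAS linkage, intragenic, eQTL, cell-type functional, control).
#'
#' @param path Path to a TSV file. Lines starting with `#` are ignored.
#' @return A data.frame of validated variant records.
#' @export
read_variant_table <- function(path) {
  v <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chrom", "pos", "variant_id", "ref", "alt", "category")
  miss <- setdiff(need, names(v))
  if (length(miss))
    stop_mpra(paste("variant table missing columns:", paste(miss, collapse = ", ")),
              "mpra_validation_error")
  validate_variants(v[need])
}

validate_variants <- function(v) {
  v$pos <- as.integer(v$pos)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  if (anyDuplicated(v$variant_id))
    stop_mpra("duplicate variant_id in variant table", "mpra_validation_error")
  bad_allele <- !(v$ref %in% c("A", "C", "G", "T")) |
    !(v$alt %in% c("A", "C", "G", "T"))
  if (any(bad_allele))
    stop_mpra(paste("non-SNV or invalid alleles for:",
                    paste(utils::head(v$variant_id[bad_allele]), collapse = ", ")),
              "mpra_unsupported_variant")
  if (any(v$ref == v$alt))
    stop_mpra("ref and alt alleles identical for some variants",
              "mpra_validation_error")
  if (any(v$pos < 1L))
    stop_mpra("variant pos must be >= 1", "mpra_validation_error")
  v
}

#' Build one oligo element for a variant allele
#'
#' Extracts the 200 bp genomic window centred on the variant (99 bases
#' upstream, the allele base, 100 bases downstream; the variant sits at
#' 0-based offset 99 of the insert) and attaches the fixed 15 bp adapters,
#' giving the full 230 bp element. Genomic bases are uppercased; the genome
#' base at `pos` must equal the declared reference allele.
#'
#' @param variant A one-row data.frame (or list) with fields `variant_id`,
#'   `chrom`, `pos`, `ref`, `alt`.
#' @param genome Genome as FASTA path, `DNAStringSet`, or named character.
#' @param allele `"ref"` or `"alt"`.
#' @return A one-row data.frame with `element_id`, `variant_id`, `allele`,
#'   `chrom`, `pos`, `variant_offset`, `insert`, `full_sequence`.
#' @export
build_element <- function(variant, genome, allele = c("ref", "alt")) {
  allele <- match.arg(allele)
  genome <- as_genome(genome)
  build_elements_(as.data.frame(variant, stringsAsFactors = FALSE),
                  genome, allele)
}

# vectorized core shared by build_element()/build_library()
build_elements_ <- function(v, genome, allele) {
  if (any(nchar(v$ref) != 1L | nchar(v$alt) != 1L))
    stop_mpra("indel alleles are not supported", "mpra_unsupported_variant")
  if (nrow(v) == 0L)
    return(data.frame(element_id = character(), variant_id = character(),
                      allele = character(), chrom = character(),
                      pos = integer(), category = character(),
                      variant_offset = integer(), insert = character(),
                      full_sequence = character(), stringsAsFactors = FALSE))
  v$insert <- rep(NA_character_, nrow(v))
  for (chrom in unique(v$chrom)) {
    if (!chrom %in% names(genome))
      stop_mpra(paste("chromosome not in genome:", chrom),
                "mpra_validation_error")
    seq <- toupper(genome[[chrom]])
    i <- which(v$chrom == chrom)
    pos <- v$pos[i]
    if (any(pos - 100L < 1L | pos + 100L > nchar(seq)))
      stop_mpra(paste0("variant within 100 bp of contig end on ", chrom),
                "mpra_flank_error")
    gbase <- substr(rep(seq, length(i)), pos, pos)
    mism <- gbase != toupper(v$ref[i])
    if (any(mism))
      stop_mpra(paste("reference allele disagrees with genome base for:",
                      paste(utils::head(v$variant_id[i][mism]), collapse = ", ")),
                "mpra_ref_mismatch")
    up <- substr(rep(seq, length(i)), pos - 99L, pos - 1L)
    dn <- substr(rep(seq, length(i)), pos + 1L, pos + 100L)
    base <- if (allele == "ref") toupper(v$ref[i]) else toupper(v$alt[i])
    v$insert[i] <- paste0(up, base, dn)
  }
  data.frame(
    element_id = paste0(v$variant_id, "_", allele),
    variant_id = v$variant_id,
    allele = allele,
    chrom = v$chrom,
    pos = v$pos,
    category = if ("category" %in% names(v)) v$category else NA_character_,
    variant_offset = 99L,
    insert = v$insert,
    full_sequence = paste0(ADAPTER5, v$insert, ADAPTER3),
    stringsAsFactors = FALSE
  )
}

#' Build the allele-paired oligo library
#'
#' For every variant, builds the reference- and alternate-allele 230 bp
#' elements (adapter + 200 bp insert + adapter). Variants yielding identical
#' full sequences trigger a warning (both are kept); duplicate variant IDs
#' are an error.
#'
#' @param variants Data.frame of variant records
#'   (see [read_variant_table()]).
#' @param genome Genome as FASTA path, `DNAStringSet`, or named character.
#' @return An object of class `mpra_library`: a data.frame of elements with
#'   the adapter constants attached as attributes.
#' @seealso [design_report()], [write_library_fasta()]
#' @export
build_library <- function(variants, genome) {
  variants <- validate_variants(as.data.frame(variants,
                                              stringsAsFactors = FALSE))
  genome <- as_genome(genome)
  if (nrow(variants) == 0L) {
    el <- build_elements_(variants[0, ], genome, "ref")[0, ]
  } else {
    el <- rbind(build_elements_(variants, genome, "ref"),
                build_elements_(variants, genome, "alt"))
    el <- el[order(match(el$variant_id, variants$variant_id), el$allele), ]
    rownames(el) <- NULL
    dup <- duplicated(el$full_sequence) | duplicated(el$full_sequence,
                                                     fromLast = TRUE)
    if (any(dup))
      warning(sum(dup), " elements share identical full sequences; all kept")
  }
  structure(el,
            adapter5 = ADAPTER5, adapter3 = ADAPTER3,
            class = c("mpra_library", "data.frame"))
}

#' @export
print.mpra_library <- function(x, ...) {
  cat("MPRA oligo library:", nrow(x), "elements (",
      length(unique(x$variant_id)), "variants )\n")
  cat("  element length:", unique(nchar(x$full_sequence)), "bp;",
      "adapters", attr(x, "adapter5"), "/", attr(x, "adapter3"), "\n")
  invisible(x)
}

#' Summarise a designed library
#'
#' @param library An `mpra_library`.
#' @return List with element/variant counts and any duplicated full
#'   sequences.
#' @export
design_report <- function(library) {
  dup <- library$element_id[duplicated(library$full_sequence) |
                              duplicated(library$full_sequence, fromLast = TRUE)]
  list(
    n_variants = length(unique(library$variant_id)),
    n_elements = nrow(library),
    n_duplicate_sequences = length(dup),
    duplicate_elements = dup
  )
}

#' Write the library as FASTA
#'
#' Record IDs are element IDs; the description carries the variant ID,
#' allele, and `chrom:pos`. Output is byte-deterministic for identical
#' input.
#'
#' @param library An `mpra_library`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  x <- Biostrings::DNAStringSet(library$full_sequence)
  names(x) <- paste(library$element_id, library$variant_id, library$allele,
                    paste0(library$chrom, ":", library$pos))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read a library FASTA back into an `mpra_library`
#'
#' Inverse of [write_library_fasta()]; adapters are stripped from the full
#' sequence to recover the insert.
#'
#' @param path FASTA path written by [write_library_fasta()].
#' @return An `mpra_library` data.frame.
#' @export
read_library_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  parts <- strsplit(names(x), " ", fixed = TRUE)
  loc <- strsplit(vapply(parts, `[`, "", 4L), ":", fixed = TRUE)
  full <- as.character(x)
  el <- data.frame(
    element_id = vapply(parts, `[`, "", 1L),
    variant_id = vapply(parts, `[`, "", 2L),
    allele = vapply(parts, `[`, "", 3L),
    chrom = vapply(loc, `[`, "", 1L),
    pos = as.integer(vapply(loc, `[`, "", 2L)),
    category = NA_character_,
    variant_offset = 99L,
    insert = substr(full, nchar(ADAPTER5) + 1L,
                    nchar(full) - nchar(ADAPTER3)),
    full_sequence = full,
    stringsAsFactors = FALSE
  )
  structure(el, adapter5 = ADAPTER5, adapter3 = ADAPTER3,
            class = c("mpra_library", "data.frame"))
}
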