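count_guides <- function(assay) {
  switch(assay,
    DNA = list(
      fwd = paste0(COUNT_FWD_LEFT, "([ACGT]{", BARCODE_LEN, "})", COUNT_FWD_RIGHT),
      rev = paste0(DNA_REV_LEFT, "([ACGT]{", BARCODE_LEN, "})", DNA_REV_RIGHT)
    ),
    RNA = list(
      # RNA forward reads are anchored on the 3' guide attached at the end
      # of the barcode; the reverse-orientation pair flanks both sides
      fwd = paste0("([ACGT]{", BARCODE_LEN, "})", COUNT_FWD_RIGHT),
      rev = paste0(RNA_REV_LEFT, "([ACGT]{", BARCODE_LEN, "})", RNA_REV_RIGHT)
    ),
    stop_mpra("assay must be 'DNA' or 'RNA'", "mpra_validation_error")
  )
}

#' Extract barcodes from DNA/RNA count-sequencing read pairs
#'
#' Searches the forward read with the assay's forward-orientation guides,
#' and the reverse read with the reverse-orientation guides (the hit is
#' reverse-complemented back to the canonical orientation). If both reads
#' yield a barcode and they disagree, the pair is rejected (`NA`).
#'
#' @param read_fwd,read_rev Character vectors of forward/reverse read
#'   sequences (either may be `NULL` for single-ended input).
#' @param assay `"DNA"` or `"RNA"`.
#' @return Character vector of barcodes, `NA` where extraction fails.
#' @export
extract_count_barcode <- function(read_fwd, read_rev = NULL,
                                  assay = c("DNA", "RNA")) {
  assay <- match.arg(assay)
  g <- count_guides(assay)
  n <- max(length(read_fwd), length(read_rev))
  bf <- if (!is.null(read_fwd)) regex_capture(read_fwd, g$fwd)
        else rep(NA_character_, n)
  br <- if (!is.null(read_rev)) revcomp(regex_capture(read_rev, g$rev))
        else rep(NA_character_, n)
  inconsistent <- !is.na(bf) & !is.na(br) & bf != br
  out <- ifelse(is.na(bf), br, bf)
  out[inconsistent] <- NA_character_
  out
}

#' Count mapped barcodes per assay and replicate
#'
#' Extracts barcodes from every read pair and increments the corresponding
#' (assay, replicate, barcode) cell for barcodes present in the map;
#' extracted barcodes absent from the map are tallied as orphans, never
#' imputed.
#'
#' @param reads Nested list: `reads$DNA[[r]]` and `reads$RNA[[r]]` are
#'   lists with elements `fwd` and/or `rev`, each a character vector of
#'   read sequences (or a FASTQ path). Replicate names must agree between
#'   assays.
#' @param map A `barcode_map`.
#' @return A `barcode_counts` object: integer matrix (mapped barcodes x
#'   `dna_1..R, rna_1..R`) plus replicate names, orphan tallies and
#'   per-replicate stats.
#' @export
count_barcodes <- function(reads, map) {
  if (nrow(map) == 0L)
    stop_mpra("barcode map is empty", "mpra_validation_error")
  if (!all(c("DNA", "RNA") %in% names(reads)))
    stop_mpra("reads must have DNA and RNA components", "mpra_validation_error")
  reps <- names(reads$DNA)
  if (is.null(reps) || !identical(sort(reps), sort(names(reads$RNA))))
    stop_mpra("replicate labels inconsistent between DNA and RNA assays",
              "mpra_config_error")
  R <- length(reps)
  counts <- matrix(0L, nrow = nrow(map), ncol = 2L * R,
                   dimnames = list(map$barcode,
                                   c(paste0("dna_", seq_len(R)),
                                     paste0("rna_", seq_len(R)))))
  orphans <- stats_rows <- list()
  for (assay in c("DNA", "RNA")) {
    for (r in seq_len(R)) {
      rr <- reads[[assay]][[reps[r]]]
      fwd <- read_seqs(rr$fwd)
      rev <- read_seqs(rr$rev)
      bc <- extract_count_barcode(fwd, rev, assay)
      bc <- bc[!is.na(bc)]
      idx <- match(bc, map$barcode)
      n_orphan <- sum(is.na(idx))
      tab <- tabulate(idx[!is.na(idx)], nbins = nrow(map))
      col <- paste0(tolower(assay), "_", r)
      counts[, col] <- counts[, col] + as.integer(tab)
      key <- paste0(assay, "_", reps[r])
      orphans[[key]] <- n_orphan
      stats_rows[[key]] <- data.frame(
        assay = assay, replicate = reps[r],
        n_reads = max(length(fwd), length(rev)),
        n_extracted = length(bc), n_mapped = sum(!is.na(idx)),
        n_orphan = n_orphan, stringsAsFactors = FALSE)
    }
  }
  structure(
    list(counts = counts, replicates = reps, R = R,
         orphans = unlist(orphans),
         stats = do.call(rbind, c(stats_rows, list(make.row.names = FALSE)))),
    class = "barcode_counts")
}

read_seqs <- function(x) {
  if (is.null(x)) return(NULL)
  if (length(x) == 1L && file.exists(x) && grepl("\\.f(ast)?q(\\.gz)?$", x))
    return(unname(as.character(Biostrings::readDNAStringSet(x, format = "fastq"))))
  x
}

#' @export
print.barcode_counts <- function(x, ...) {
  cat("Barcode count table:", nrow(x$counts), "barcodes x", x$R,
      "replicates (DNA + RNA)\n")
  cat("  total counts:", sum(x$counts), "| orphan reads:", sum(x$orphans), "\n")
  invisible(x)
}

#' Aggregate barcode counts to element level
#'
#' A barcode contributes only if it is present (DNA count >= 1; optionally
#' RNA too) in every replicate. Contributing barcode counts are summed per
#' element and replicate, and elements represented by fewer than
#' `min_barcodes` contributing barcodes are dropped. Allele elements are
#' distinct elements and are filtered independently, so a variant can lose
#' one allele here.
#'
#' @param bc_counts A `barcode_counts` object.
#' @param map A `barcode_map`.
#' @param min_barcodes Minimum contributing barcodes per retained element.
#' @param require_rna_presence Also require RNA count >= 1 in every
#'   replicate for a barcode to contribute (default `FALSE`: a zero RNA
#'   count is a meaningful expression observation, while the DNA count
#'   witnesses plasmid delivery).
#' @return An `element_counts` data.frame (`element_id`, `n_barcodes`,
#'   `dna_1..R`, `rna_1..R`) with a `drop_log` attribute.
#' @export
aggregate_elements <- function(bc_counts, map, min_barcodes = 5L,
                               require_rna_presence = FALSE) {
  if (bc_counts$R < 2L)
    stop_mpra("at least 2 replicates required", "mpra_validation_error")
  cm <- bc_counts$counts
  R <- bc_counts$R
  dna <- cm[, paste0("dna_", seq_len(R)), drop = FALSE]
  present <- rowSums(dna >= 1L) == R
  if (require_rna_presence) {
    rna <- cm[, paste0("rna_", seq_len(R)), drop = FALSE]
    present <- present & rowSums(rna >= 1L) == R
  }
  el <- map$element_id[match(rownames(cm), map$barcode)]
  contrib <- present & !is.na(el)
  agg <- rowsum(cm[contrib, , drop = FALSE], el[contrib])
  nbc <- as.integer(table(el[contrib])[rownames(agg)])
  keep <- nbc >= min_barcodes
  all_el <- sort(unique(map$element_id))
  dropped <- setdiff(all_el, rownames(agg)[keep])
  reason <- ifelse(dropped %in% rownames(agg),
                   "fewer than min_barcodes contributing barcodes",
                   "no barcode present across all replicates")
  out <- data.frame(element_id = rownames(agg)[keep],
                    n_barcodes = nbc[keep],
                    agg[keep, , drop = FALSE],
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out,
            R = R,
            drop_log = data.frame(element_id = dropped, reason = reason,
                                  stringsAsFactors = FALSE),
            class = c("element_counts", "data.frame"))
}

#' Write / read element-level counts as TSV
#'
#' @param elements An `element_counts` data.frame.
#' @param path TSV path.
#' @return `path` (writer) or an `element_counts` (reader).
#' @export
write_element_counts <- function(elements, path) {
  utils::write.table(as.data.frame(elements), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_element_counts
#' @export
read_element_counts <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  R <- sum(grepl("^dna_", names(x)))
  structure(x, R = R, class = c("element_counts", "data.frame"))
}
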