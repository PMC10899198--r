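# shared in-code fixtures: tiny deterministic genomes, variant tables and
# simulated datasets used across test files

toy_genome <- function(len = 300L, base = "A", name = "chrT") {
  stats::setNames(paste(rep(base, len), collapse = ""), name)
}

toy_variants <- function(n = 3L, chrom = "chrT", start_pos = 150L,
                         spacing = 1L, ref = "A", alt = "C") {
  data.frame(
    chrom = rep(chrom, n),
    pos = start_pos + (seq_len(n) - 1L) * spacing,
    variant_id = sprintf("v%d", seq_len(n)),
    ref = rep(ref, n), alt = rep(alt, n), category = rep("gwas_ld", n),
    stringsAsFactors = FALSE
  )
}

# random genome + variants for property tests
random_library <- function(n = 10L, seed = 42L) {
  set.seed(seed)
  glen <- 150L + n * 250L
  genome <- stats::setNames(paste(
    sample(c("A", "C", "G", "T"), glen, replace = TRUE), collapse = ""), "chrR")
  pos <- 150L + (seq_len(n) - 1L) * 250L
  ref <- substring(genome, pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
  variants <- data.frame(chrom = "chrR", pos = pos,
                         variant_id = paste0("rv", seq_len(n)),
                         ref = ref, alt = unname(alt), category = "control",
                         stringsAsFactors = FALSE)
  list(genome = genome, variants = variants,
       library = build_library(variants, genome))
}

# element count table built directly from per-cell counts
make_element_counts <- function(dna, rna, ids = NULL) {
  R <- ncol(dna)
  if (is.null(ids)) ids <- paste0("e", seq_len(nrow(dna)))
  df <- data.frame(element_id = ids, n_barcodes = 5L,
                   stringsAsFactors = FALSE)
  for (r in seq_len(R)) df[[paste0("dna_", r)]] <- dna[, r]
  for (r in seq_len(R)) df[[paste0("rna_", r)]] <- rna[, r]
  structure(df, R = R, class = c("element_counts", "data.frame"))
}

# activity table with prescribed per-replicate activities (bypasses counts)
make_activity <- function(a, ids = rownames(a)) {
  structure(list(element_id = ids,
                 a = matrix(a, nrow = nrow(a),
                            dimnames = list(ids, paste0("rep", seq_len(ncol(a))))),
                 A = stats::setNames(rowMeans(a), ids), R = ncol(a)),
            class = "activity_table")
}

# paired activity table for n variants from a matrix of replicate
# differences D (ref activities all zero, alt = D)
activity_from_diffs <- function(D, prefix = "dv") {
  n <- nrow(D); R <- ncol(D)
  ids <- c(paste0(prefix, seq_len(n), "_ref"), paste0(prefix, seq_len(n), "_alt"))
  a <- rbind(matrix(0, n, R), D)
  rownames(a) <- ids
  make_activity(a, ids)
}

# tiny full simulation used by round-trip tests
tiny_sim <- function(seed = 11L, ...) {
  cfg <- sim_config_tiny(n_variants = 30L, barcode_mean = 8, depth = 3e4,
                         nb_dispersion = 0, replicate_sd = 0.05,
                         read_error_rate = 0, seed = seed, ...)
  c(simulate_library(cfg), list(config = cfg))
}
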