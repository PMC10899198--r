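#' Simulation configuration
#'
#' Collects the generative parameters for synthetic MPRA data. Defaults
#' emulate the scale and structure the analysis assumes: a minority of
#' variants with true enhancer activity, a smaller minority with
#' allele-specific effects, a long-tailed barcode complexity averaging 449
#' barcodes per element (truncated to 1-9333), and three replicates of
#' DNA/RNA counts with a shared within-replicate effect.
#'
#' @param n_variants Number of allele-paired variants.
#' @param frac_enhancer Fraction of variants with baseline enhancer
#'   activity (`alpha ~ Normal(2, 0.5)` on the log2 scale, shared by both
#'   alleles).
#' @param frac_allelic Fraction of variants with an allelic effect
#'   (`|beta| ~ Normal(1.5, 0.3)`, random sign, alt minus ref).
#' @param barcode_mean,barcode_range Mean and truncation bounds of the
#'   log-normal barcodes-per-element distribution.
#' @param replicates Number of technical replicates.
#' @param depth Sequencing depth per assay and replicate.
#' @param nb_dispersion Negative-binomial dispersion of RNA counts
#'   (0 gives multinomial sampling, for exact tests).
#' @param replicate_sd SD of the shared per-replicate log2 effect `u_r`.
#' @param read_error_rate Per-base substitution rate in simulated reads.
#' @param assoc_coverage Mean association read pairs per barcode (every
#'   barcode gets at least one pair).
#' @param read_length Association read-1 length.
#' @param seed Integer seed; one global seed drives a deterministic
#'   per-stage stream so stages can be regenerated independently.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 1000L, frac_enhancer = 0.03,
                       frac_allelic = 0.005, barcode_mean = 449,
                       barcode_range = c(1L, 9333L), replicates = 3L,
                       depth = 2e6, nb_dispersion = 0.05,
                       replicate_sd = 0.05, read_error_rate = 0,
                       assoc_coverage = 3, read_length = 150L,
                       seed = 1L) {
  cfg <- list(n_variants = as.integer(n_variants),
              frac_enhancer = frac_enhancer, frac_allelic = frac_allelic,
              barcode_mean = barcode_mean, barcode_range = barcode_range,
              replicates = as.integer(replicates), depth = depth,
              nb_dispersion = nb_dispersion, replicate_sd = replicate_sd,
              read_error_rate = read_error_rate,
              assoc_coverage = assoc_coverage,
              read_length = as.integer(read_length),
              seed = as.integer(seed))
  if (cfg$n_variants < 1L)
    stop_mpra("n_variants must be >= 1", "mpra_config_error")
  if (any(c(frac_enhancer, frac_allelic) < 0) ||
      any(c(frac_enhancer, frac_allelic) > 1))
    stop_mpra("fractions must lie in [0, 1]", "mpra_config_error")
  if (depth <= 0) stop_mpra("depth must be positive", "mpra_config_error")
  structure(cfg, class = "sim_config")
}

#' Tiny desk-test preset
#'
#' 200 variants, 20 barcodes per element on average, shallow depth:
#' enough structure to exercise every pipeline stage in seconds.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A `sim_config`.
#' @export
sim_config_tiny <- function(...) {
  args <- list(n_variants = 200L, barcode_mean = 20, depth = 2e5,
               assoc_coverage = 2)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

random_seq <- function(n, len) {
  if (n == 0L) return(character())
  m <- matrix(sample(c("A", "C", "G", "T"), n * len, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

#' Simulate an oligo library with planted ground truth
#'
#' Generates a random genome contig with variants on a regular grid,
#' builds the allele-paired library through the real design code, draws
#' per-element barcode complements (log-normal, truncated to the
#' configured range) with unique random 20-mer barcodes and log-normal
#' abundance weights, and plants baseline activities (enhancer variants)
#' and allelic effects (allelic variants) as ground truth.
#'
#' @param config A `sim_config`.
#' @return List with `library` (an `mpra_library`), `truth` (a
#'   `sim_truth`: per-element `alpha`, per-variant `beta`, per-barcode
#'   assignment and weight), `genome` (named character), and `variants`.
#' @export
simulate_library <- function(config) {
  set.seed(config$seed)
  n <- config$n_variants
  pos <- 150L + (seq_len(n) - 1L) * 250L
  glen <- max(pos) + 150L
  genome <- c(sim1 = random_seq(1L, glen))
  ref <- substr(rep(genome, n), pos, pos)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                "")
  variants <- data.frame(
    chrom = "sim1", pos = pos,
    variant_id = sprintf("sv%04d", seq_len(n)),
    ref = ref, alt = unname(alt),
    category = rep(c("gwas_ld", "park_intragenic", "park_eqtl", "microglia"),
                   length.out = n),
    stringsAsFactors = FALSE)
  library <- build_library(variants, genome)

  is_enh <- stats::runif(n) < config$frac_enhancer
  is_all <- stats::runif(n) < config$frac_allelic
  alpha_v <- ifelse(is_enh, stats::rnorm(n, 2, 0.5), 0)
  beta_v <- ifelse(is_all,
                   sample(c(-1, 1), n, replace = TRUE) *
                     stats::rnorm(n, 1.5, 0.3), 0)
  elements <- data.frame(
    element_id = library$element_id,
    variant_id = library$variant_id,
    allele = library$allele,
    alpha = alpha_v[match(library$variant_id, variants$variant_id)],
    beta = beta_v[match(library$variant_id, variants$variant_id)],
    stringsAsFactors = FALSE)

  # barcode complement per element: log-normal around barcode_mean,
  # truncated to the configured range
  sdlog <- 1
  nbc <- round(stats::rlnorm(nrow(library),
                             meanlog = log(config$barcode_mean) - sdlog^2 / 2,
                             sdlog = sdlog))
  nbc <- pmin(pmax(nbc, config$barcode_range[1L]), config$barcode_range[2L])
  total <- sum(nbc)
  if (total > 0.01 * 4^BARCODE_LEN)
    stop_mpra("barcode space exhausted (collision rate > 1%)",
              "mpra_config_error")
  bc <- random_seq(total, BARCODE_LEN)
  for (i in 1:10) {
    dup <- duplicated(bc)
    if (!any(dup)) break
    bc[dup] <- random_seq(sum(dup), BARCODE_LEN)
  }
  if (anyDuplicated(bc))
    stop_mpra("barcode space exhausted (collision rate > 1%)",
              "mpra_config_error")
  w <- stats::rlnorm(total, 0, 0.8)
  barcodes <- data.frame(
    barcode = bc,
    element_id = rep(library$element_id, nbc),
    weight = w / sum(w),
    stringsAsFactors = FALSE)

  truth <- structure(list(elements = elements, barcodes = barcodes,
                          config = config),
                     class = "sim_truth")
  list(library = library, truth = truth, genome = genome,
       variants = variants)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("Simulation ground truth:", nrow(x$elements), "elements,",
      nrow(x$barcodes), "barcodes\n")
  cat("  enhancer variants:", sum(x$elements$alpha != 0 &
                                    x$elements$allele == "ref"),
      "| allelic variants:", sum(x$elements$beta != 0 &
                                   x$elements$allele == "ref"), "\n")
  invisible(x)
}

inject_errors <- function(reads, rate) {
  if (rate <= 0) return(reads)
  nerr <- stats::rbinom(length(reads), nchar(reads), rate)
  idx <- which(nerr > 0L)
  for (i in idx) {
    p <- sample.int(nchar(reads[i]), nerr[i])
    s <- strsplit(reads[i], "")[[1L]]
    s[p] <- vapply(s[p],
                   function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L),
                   "")
    reads[i] <- paste(s, collapse = "")
  }
  reads
}

write_fastq <- function(seqs, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq")
  invisible(path)
}

#' Simulate association-library read pairs
#'
#' Read 1 is the association adapter followed by the element prefix;
#' read 2 carries the guide-flanked barcode. Per-base substitution errors
#' are injected at the configured rate; every barcode is covered by at
#' least one pair.
#'
#' @param library An `mpra_library`.
#' @param truth A `sim_truth`.
#' @param config A `sim_config`.
#' @param r1_path,r2_path Output FASTQ paths.
#' @return Invisible list of the two paths.
#' @export
simulate_assoc_reads <- function(library, truth, config, r1_path, r2_path) {
  set.seed(config$seed + 1L)
  b <- truth$barcodes
  if (nrow(b) == 0L) {
    write_fastq(character(), character(), r1_path)
    write_fastq(character(), character(), r2_path)
    return(invisible(list(r1 = r1_path, r2 = r2_path)))
  }
  cov <- 1L + stats::rpois(nrow(b), max(config$assoc_coverage - 1, 0))
  idx <- rep(seq_len(nrow(b)), cov)
  refs <- paste0(library$insert, ADAPTER3)
  names(refs) <- library$element_id
  ins_len <- config$read_length - nchar(ASSOC_ADAPTER)
  r1 <- paste0(ASSOC_ADAPTER, substr(refs[b$element_id[idx]], 1L, ins_len))
  pad <- random_seq(length(idx), 4L)
  r2 <- paste0(pad, ASSOC_GUIDE_LEFT, b$barcode[idx], ASSOC_GUIDE_RIGHT,
               substr(refs[b$element_id[idx]], 1L, 20L))
  r1 <- inject_errors(r1, config$read_error_rate)
  r2 <- inject_errors(r2, config$read_error_rate)
  ids <- sprintf("assoc_%07d", seq_along(idx))
  write_fastq(r1, ids, r1_path)
  write_fastq(r2, ids, r2_path)
  invisible(list(r1 = r1_path, r2 = r2_path))
}

#' Simulate DNA/RNA barcode counts (and optionally count FASTQ files)
#'
#' DNA counts per replicate are multinomial draws of the configured depth
#' over the barcode abundance weights. RNA expectations scale each weight
#' by `2^(alpha + beta*[allele == alt] + u_r)` with a per-replicate effect
#' `u_r ~ Normal(0, replicate_sd)` shared across all barcodes (and both
#' alleles) of the replicate; counts are negative-binomial around the
#' scaled expectations, or multinomial when `nb_dispersion = 0`.
#'
#' @param truth A `sim_truth`.
#' @param config A `sim_config`.
#' @param fastq_dir If non-`NULL`, also emit guide-flanked count reads as
#'   `<assay>_rep<r>_R1/R2.fastq` in this directory (one read pair per
#'   count unit).
#' @return A list: `counts` (a `barcode_counts` object), `u` (replicate
#'   effects), and `fastq` (nested file paths, or `NULL`).
#' @export
simulate_counts <- function(truth, config, fastq_dir = NULL) {
  set.seed(config$seed + 2L)
  b <- truth$barcodes
  el <- truth$elements
  R <- config$replicates
  i <- match(b$element_id, el$element_id)
  mu_log2 <- el$alpha[i] + el$beta[i] * (el$allele[i] == "alt")
  counts <- matrix(0L, nrow = nrow(b), ncol = 2L * R,
                   dimnames = list(b$barcode,
                                   c(paste0("dna_", seq_len(R)),
                                     paste0("rna_", seq_len(R)))))
  u <- stats::rnorm(R, 0, config$replicate_sd)
  for (r in seq_len(R)) {
    counts[, paste0("dna_", r)] <-
      as.integer(stats::rmultinom(1L, config$depth, b$weight))
    mu <- b$weight * 2^(mu_log2 + u[r])
    p <- mu / sum(mu)
    counts[, paste0("rna_", r)] <- if (config$nb_dispersion <= 0) {
      as.integer(stats::rmultinom(1L, config$depth, p))
    } else {
      as.integer(stats::rnbinom(nrow(b), mu = config$depth * p,
                                size = 1 / config$nb_dispersion))
    }
  }
  fastq <- NULL
  if (!is.null(fastq_dir)) {
    dir.create(fastq_dir, showWarnings = FALSE, recursive = TRUE)
    fastq <- list(DNA = list(), RNA = list())
    for (assay in c("DNA", "RNA")) {
      for (r in seq_len(R)) {
        k <- counts[, paste0(tolower(assay), "_", r)]
        fwd_t <- paste0(COUNT_FWD_LEFT, b$barcode, COUNT_FWD_RIGHT, "CGA")
        fwd <- rep(fwd_t, k)
        rev <- revcomp(fwd)
        ids <- sprintf("%s_r%d_%08d", tolower(assay), r, seq_along(fwd))
        p1 <- file.path(fastq_dir, sprintf("%s_rep%d_R1.fastq",
                                           tolower(assay), r))
        p2 <- file.path(fastq_dir, sprintf("%s_rep%d_R2.fastq",
                                           tolower(assay), r))
        write_fastq(inject_errors(fwd, config$read_error_rate), ids, p1)
        write_fastq(inject_errors(rev, config$read_error_rate), ids, p2)
        fastq[[assay]][[as.character(r)]] <- list(fwd = p1, rev = p2)
      }
    }
  }
  bc <- structure(list(counts = counts, replicates = as.character(seq_len(R)),
                       R = R, orphans = integer(), stats = NULL),
                  class = "barcode_counts")
  list(counts = bc, u = u, fastq = fastq)
}

#' Write simulation ground truth as TSV
#'
#' @param truth A `sim_truth`.
#' @param path TSV path (`element_id`, `alpha`, `beta`, `n_barcodes`).
#' @return `path`, invisibly.
#' @export
write_sim_truth <- function(truth, path) {
  nb <- table(truth$barcodes$element_id)
  el <- truth$elements
  el$n_barcodes <- as.integer(nb[el$element_id])
  utils::write.table(el, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
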