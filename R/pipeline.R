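default_params <- function() {
  list(min_barcodes = 5L, z_threshold = 3, dominance = 0.9, min_support = 1L,
       fdr_active = 0.05, fdr_suggestive = 0.1, flank = 100L,
       tfbs_cutoff = 0.8, require_rna_presence = FALSE, seed = 1L)
}

#' Read a pipeline run manifest
#'
#' The manifest is a YAML file declaring input paths (genome, variant
#' table, association FASTQ pair, DNA/RNA FASTQ sets per replicate,
#' optional annotation tracks), tunable parameters, and the output
#' directory. Missing parameters take the documented defaults.
#'
#' @param path YAML manifest path.
#' @return A validated `run_manifest` list.
#' @export
read_manifest <- function(path) {
  m <- yaml::read_yaml(path)
  validate_manifest(m, base_dir = dirname(path))
}

#' Validate a run manifest
#'
#' Checks that referenced files exist and parameters lie in their
#' documented ranges, collecting all failures into one error message.
#'
#' @param manifest Manifest as a list (paths relative to `base_dir`).
#' @param base_dir Directory against which relative paths are resolved.
#' @return The normalized `run_manifest`, with defaults filled in.
#' @export
validate_manifest <- function(manifest, base_dir = ".") {
  errs <- character()
  params <- default_params()
  over <- manifest$params
  unknown <- setdiff(names(over), names(params))
  if (length(unknown))
    errs <- c(errs, paste("unknown parameters:", paste(unknown, collapse = ", ")))
  params[intersect(names(over), names(params))] <-
    over[intersect(names(over), names(params))]
  if (params$min_barcodes < 1) errs <- c(errs, "min_barcodes must be >= 1")
  if (params$dominance < 0.5 || params$dominance > 1)
    errs <- c(errs, "dominance must lie in [0.5, 1]")
  if (params$fdr_active <= 0 || params$fdr_suggestive < params$fdr_active)
    errs <- c(errs, "fdr tiers must satisfy 0 < fdr_active <= fdr_suggestive")
  if (params$flank < 0) errs <- c(errs, "flank must be non-negative")
  if (abs(params$tfbs_cutoff) > 1) errs <- c(errs, "tfbs_cutoff must be in [0, 1]")

  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(file.exists(p), p, file.path(base_dir, p))
  }
  check_file <- function(p, what) {
    p <- resolve(p)
    if (!is.null(p) && !all(file.exists(p)))
      errs <<- c(errs, paste0(what, " file not found: ",
                              paste(p[!file.exists(p)], collapse = ", ")))
    p
  }
  manifest$genome <- check_file(manifest$genome, "genome")
  manifest$variants <- check_file(manifest$variants, "variant table")
  if (!is.null(manifest$assoc)) {
    manifest$assoc$r1 <- check_file(manifest$assoc$r1, "association R1")
    manifest$assoc$r2 <- check_file(manifest$assoc$r2, "association R2")
  }
  for (assay in c("dna", "rna")) {
    for (rep in names(manifest[[assay]])) {
      manifest[[assay]][[rep]] <-
        lapply(manifest[[assay]][[rep]], check_file,
               what = paste(assay, "replicate", rep))
    }
  }
  for (tr in c("dr_track", "tfbs_scores", "intervals")) {
    if (!is.null(manifest$annotation[[tr]]))
      manifest$annotation[[tr]] <- check_file(manifest$annotation[[tr]], tr)
  }
  if (is.null(manifest$outdir)) errs <- c(errs, "outdir is required")
  if (length(errs))
    stop_mpra(paste0("invalid manifest:\n  - ",
                     paste(errs, collapse = "\n  - ")),
              "mpra_validation_error")
  manifest$params <- params
  structure(manifest, class = c("run_manifest", "list"))
}

stage_log <- function(log_path, stage, ...) {
  line <- sprintf("[%s] %s", stage, paste(..., collapse = " "))
  message(line)
  cat(line, "\n", file = log_path, append = TRUE)
  invisible(line)
}

artifact <- function(manifest, name) file.path(manifest$outdir, name)

need_artifact <- function(manifest, name, producer) {
  p <- artifact(manifest, name)
  if (!file.exists(p))
    stop_mpra(paste0("missing upstream artifact '", name,
                     "': run stage '", producer, "' first"),
              "mpra_dependency_error")
  p
}

#' Run the MPRA pipeline
#'
#' Executes the requested stages in dependency order
#' (`design -> map -> count -> aggregate -> call -> annotate`), writing
#' column-documented TSV artifacts and a run log (input/output tallies per
#' stage) into the manifest's output directory. Re-running with identical
#' inputs reproduces identical outputs.
#'
#' Artifacts: `library.fasta`, `design_report.tsv`, `barcode_map.tsv`,
#' `assoc_stats.json`, `barcode_counts.tsv`, `element_counts.tsv`,
#' `drop_log.tsv`, `general_enhancers.tsv`, `allelic_results.tsv`, and
#' (with annotation inputs) `annotated_variants.tsv`.
#'
#' @param manifest A `run_manifest` (or YAML path).
#' @param stages Subset of
#'   `c("design", "map", "count", "aggregate", "call", "annotate")`.
#' @return Invisible named list of artifact paths.
#' @export
run_pipeline <- function(manifest,
                         stages = c("design", "map", "count", "aggregate",
                                    "call")) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!inherits(manifest, "run_manifest"))
    manifest <- validate_manifest(manifest)
  order_all <- c("design", "map", "count", "aggregate", "call", "annotate")
  bad <- setdiff(stages, order_all)
  if (length(bad))
    stop_mpra(paste("unknown stages:", paste(bad, collapse = ", ")),
              "mpra_validation_error")
  stages <- order_all[order_all %in% stages]
  dir.create(manifest$outdir, showWarnings = FALSE, recursive = TRUE)
  log <- artifact(manifest, "run_log.txt")
  cat("", file = log)
  p <- manifest$params
  out <- list()

  if ("design" %in% stages) {
    variants <- read_variant_table(manifest$variants)
    lib <- build_library(variants, manifest$genome)
    rep <- design_report(lib)
    out$library <- write_library_fasta(lib, artifact(manifest, "library.fasta"))
    utils::write.table(
      data.frame(metric = c("n_variants", "n_elements",
                            "n_duplicate_sequences"),
                 value = c(rep$n_variants, rep$n_elements,
                           rep$n_duplicate_sequences)),
      artifact(manifest, "design_report.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    stage_log(log, "design", "variants in:", rep$n_variants,
              "| elements out:", rep$n_elements)
  }

  if ("map" %in% stages) {
    libf <- need_artifact(manifest, "library.fasta", "design")
    map <- map_association_reads(manifest$assoc$r1, manifest$assoc$r2,
                                 libf, dominance = p$dominance,
                                 min_support = p$min_support)
    out$barcode_map <- write_barcode_map(map, artifact(manifest,
                                                       "barcode_map.tsv"))
    s <- attr(map, "stats")
    jsonlite::write_json(s, artifact(manifest, "assoc_stats.json"),
                         auto_unbox = TRUE)
    stage_log(log, "map", "pairs in:", s$n_pairs,
              "| mapped barcodes out:", s$n_mapped,
              "| dropped (untrimmed/unmatched/ambiguous):",
              s$n_pairs - s$n_mapped)
  }

  if ("count" %in% stages) {
    mapf <- need_artifact(manifest, "barcode_map.tsv", "map")
    map <- read_barcode_map(mapf)
    reads <- list(DNA = manifest$dna, RNA = manifest$rna)
    bc <- count_barcodes(reads, map)
    long <- data.frame(
      assay = rep(rep(c("DNA", "RNA"), each = bc$R), each = nrow(bc$counts)),
      replicate = rep(rep(bc$replicates, 2L), each = nrow(bc$counts)),
      barcode = rep(rownames(bc$counts), 2L * bc$R),
      count = as.integer(bc$counts), stringsAsFactors = FALSE)
    out$barcode_counts <- artifact(manifest, "barcode_counts.tsv")
    utils::write.table(long, out$barcode_counts, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage_log(log, "count", "reads in:", sum(bc$stats$n_reads),
              "| counted:", sum(bc$counts),
              "| orphans:", sum(bc$orphans))
  }

  if ("aggregate" %in% stages) {
    bcf <- need_artifact(manifest, "barcode_counts.tsv", "count")
    mapf <- need_artifact(manifest, "barcode_map.tsv", "map")
    map <- read_barcode_map(mapf)
    bc <- read_barcode_counts_tsv(bcf)
    el <- aggregate_elements(bc, map, min_barcodes = p$min_barcodes,
                             require_rna_presence = p$require_rna_presence)
    out$element_counts <- write_element_counts(
      el, artifact(manifest, "element_counts.tsv"))
    dl <- attr(el, "drop_log")
    utils::write.table(dl, artifact(manifest, "drop_log.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    stage_log(log, "aggregate", "elements in:", nrow(el) + nrow(dl),
              "| retained:", nrow(el), "| dropped:", nrow(dl))
  }

  if ("call" %in% stages) {
    elf <- need_artifact(manifest, "element_counts.tsv", "aggregate")
    el <- read_element_counts(elf)
    act <- compute_activity(el)
    gen <- call_general_enhancers(act, z_threshold = p$z_threshold)
    out$general <- artifact(manifest, "general_enhancers.tsv")
    utils::write.table(gen, out$general, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    fit <- fit_allelic(act, fdr_active = p$fdr_active,
                       fdr_suggestive = p$fdr_suggestive)
    out$allelic <- write_allelic_results(
      fit, artifact(manifest, "allelic_results.tsv"))
    stage_log(log, "call", "elements in:", nrow(el),
              "| general enhancers:", sum(gen$is_enhancer),
              "| variants tested:", nrow(fit$results),
              "| skipped:", length(fit$skipped),
              sprintf("| d0: %.4g s0_sq: %.4g", fit$d0, fit$s0_sq),
              "| active:", sum(fit$results$tier == "active"),
              "| suggestive:", sum(fit$results$tier == "suggestive"))
  }

  if ("annotate" %in% stages) {
    allf <- need_artifact(manifest, "allelic_results.tsv", "call")
    res <- utils::read.delim(allf, stringsAsFactors = FALSE)
    variants <- read_variant_table(manifest$variants)
    ann <- variants[variants$variant_id %in% res$variant_id, ]
    ann <- merge(ann, res, by = "variant_id", sort = TRUE)
    a <- manifest$annotation
    if (!is.null(a$dr_track)) {
      track <- utils::read.delim(a$dr_track, stringsAsFactors = FALSE)
      ann$dr_mean <- dr_mean(ann, track)
    }
    if (!is.null(a$tfbs_scores)) {
      sc <- utils::read.delim(a$tfbs_scores, stringsAsFactors = FALSE)
      fl <- filter_tfbs(sc, cutoff = p$tfbs_cutoff)$flags
      ann$disrupts_tfbs <- fl$disrupts_tfbs[match(ann$variant_id,
                                                  fl$variant_id)]
    }
    if (!is.null(a$intervals)) {
      iv <- utils::read.delim(a$intervals, stringsAsFactors = FALSE)
      ov <- as.matrix(overlap_flank(ann, iv, flank = p$flank))
      genf <- artifact(manifest, "general_enhancers.tsv")
      if (file.exists(genf)) {
        # group variants as allele-specific, general-only, or background
        # and summarize per-track overlap in the standard report layout
        gen <- utils::read.delim(genf, stringsAsFactors = FALSE)
        vid_of <- sub("_(ref|alt)$", "", gen$element_id)
        enh_vid <- unique(vid_of[gen$is_enhancer])
        grp <- ifelse(ann$tier == "active", "allele_specific",
                      ifelse(ann$variant_id %in% enh_vid, "general",
                             "background"))
        keep <- names(which(table(grp) > 0))
        if (length(keep) >= 2L && "background" %in% keep) {
          cnt <- rowsum(ov + 0L, grp)
          sizes <- as.integer(table(grp)[rownames(cnt)])
          names(sizes) <- rownames(cnt)
          osum <- summarize_overlaps(cnt, sizes,
                                     enhancer_groups = setdiff(rownames(cnt),
                                                               "background"))
          utils::write.table(merge(osum$summary, osum$tests, by = "class"),
                             artifact(manifest, "overlap_summary.tsv"),
                             sep = "\t", quote = FALSE, row.names = FALSE)
        }
      }
      colnames(ov) <- paste0("overlap_", colnames(ov))
      ann <- cbind(ann, ov)
    }
    out$annotated <- artifact(manifest, "annotated_variants.tsv")
    utils::write.table(ann, out$annotated, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    stage_log(log, "annotate", "variants in:", nrow(res),
              "| annotated out:", nrow(ann))
  }
  invisible(out)
}

# rebuild a barcode_counts object from the long-format TSV artifact
read_barcode_counts_tsv <- function(path) {
  long <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = c("character", "character",
                                           "character", "integer"))
  reps <- sort(unique(long$replicate))
  R <- length(reps)
  bcs <- unique(long$barcode)
  counts <- matrix(0L, nrow = length(bcs), ncol = 2L * R,
                   dimnames = list(bcs, c(paste0("dna_", seq_len(R)),
                                          paste0("rna_", seq_len(R)))))
  col <- paste0(tolower(long$assay), "_", match(long$replicate, reps))
  counts[cbind(match(long$barcode, bcs), match(col, colnames(counts)))] <-
    long$count
  structure(list(counts = counts, replicates = reps, R = R,
                 orphans = integer(), stats = NULL),
            class = "barcode_counts")
}
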