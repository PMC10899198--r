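#' Mean depletion-rank score at variant positions
#'
#' Depletion rank (DR) is a 0-1 constraint score assigned to overlapping
#' 500 bp genomic windows on a 50 bp grid (low = most depleted of
#' variation). A variant at 1-based position `pos` is covered by every
#' window whose 0-based half-open interval contains `pos - 1` (about ten
#' windows on the 50 bp grid); its DR annotation is the arithmetic mean of
#' those windows' scores, `NA` if no window covers it.
#'
#' @param variants Data.frame with `chrom` and `pos` (1-based) columns.
#' @param track Data.frame of windows: `chrom`, `start` (0-based),
#'   `end` (exclusive; `end - start` must be 500), `dr` in \[0, 1\].
#' @return Numeric vector of mean DR scores, parallel to `variants`.
#' @export
dr_mean <- function(variants, track) {
  if (any(track$end - track$start != 500L))
    stop_mpra("DR windows must be exactly 500 bp", "mpra_validation_error")
  if (any(track$dr < 0 | track$dr > 1))
    stop_mpra("DR scores must lie in [0, 1]", "mpra_validation_error")
  q <- GenomicRanges::GRanges(variants$chrom,
                              IRanges::IRanges(variants$pos, width = 1L))
  w <- GenomicRanges::GRanges(track$chrom,
                              IRanges::IRanges(track$start + 1L, track$end))
  hits <- GenomicRanges::findOverlaps(q, w)
  out <- rep(NA_real_, nrow(variants))
  if (length(hits)) {
    m <- tapply(track$dr[S4Vectors::subjectHits(hits)],
                S4Vectors::queryHits(hits), mean)
    out[as.integer(names(m))] <- as.numeric(m)
  }
  out
}

#' Filter TFBS delta scores to high-confidence calls
#'
#' Transcription-factor binding-site delta scores range from -1 (strongest
#' predicted disruption) to 1 (strongest predicted creation). Entries with
#' `|score| >= cutoff` (inclusive boundary, default 0.8) are kept and
#' labelled `disrupt` (negative) or `create` (positive); each variant is
#' flagged as TFBS-disrupting if it retains at least one entry.
#'
#' @param scores Data.frame with `variant_id`, `tf_name`, `score`.
#' @param cutoff High-confidence magnitude threshold.
#' @return List: `kept` (filtered rows plus `direction`) and `flags`
#'   (per-variant `disrupts_tfbs` logical).
#' @export
filter_tfbs <- function(scores, cutoff = 0.8) {
  if (any(abs(scores$score) > 1))
    stop_mpra("TFBS scores must lie in [-1, 1]", "mpra_validation_error")
  kept <- scores[abs(scores$score) >= cutoff, , drop = FALSE]
  kept$direction <- ifelse(kept$score < 0, "disrupt", "create")
  rownames(kept) <- NULL
  vids <- unique(scores$variant_id)
  flags <- data.frame(variant_id = vids,
                      disrupts_tfbs = vids %in% kept$variant_id,
                      stringsAsFactors = FALSE)
  list(kept = kept, flags = flags)
}

#' Flanked overlap of variants with annotation intervals
#'
#' A variant overlaps a track when the window of `flank` bases either side
#' of it (0-based `[pos-1-flank, pos+flank)`) intersects any interval of
#' the track. Intervals are 0-based half-open (BED convention).
#'
#' @param variants Data.frame with `chrom` and `pos` (1-based).
#' @param intervals Data.frame with `chrom`, `start`, `end`, and
#'   optionally `track` (annotation class label).
#' @param flank Bases of flank on each side (default 100).
#' @return If `intervals$track` exists, a logical matrix variants x
#'   tracks; otherwise a logical vector.
#' @export
overlap_flank <- function(variants, intervals, flank = 100L) {
  if (flank < 0) stop_mpra("flank must be non-negative", "mpra_validation_error")
  q <- GenomicRanges::GRanges(
    variants$chrom,
    IRanges::IRanges(pmax(1L, variants$pos - as.integer(flank)),
                     variants$pos + as.integer(flank)))
  tracks <- if ("track" %in% names(intervals)) unique(intervals$track) else NA
  res <- sapply(tracks, function(tr) {
    sub <- if (is.na(tr[1L])) intervals else intervals[intervals$track == tr, ]
    s <- GenomicRanges::GRanges(sub$chrom,
                                IRanges::IRanges(sub$start + 1L, sub$end))
    GenomicRanges::countOverlaps(q, s) > 0L
  })
  res <- matrix(res, nrow = nrow(variants),
                dimnames = list(variants$variant_id,
                                if (is.na(tracks[1L])) "overlap" else tracks))
  if (is.na(tracks[1L])) res[, 1L] else res
}

#' k-group proportion test
#'
#' Pearson chi-square test of equal proportions on a k x 2 table of
#' (overlap, no-overlap) counts. Yates continuity correction is applied
#' for the 2-group comparison only (the standard behaviour), which is
#' where it affects the result.
#'
#' @param successes Overlap counts per group.
#' @param sizes Group sizes.
#' @param correct Continuity correction; default `TRUE` (only applied when
#'   `k = 2`).
#' @return List with `statistic`, `df`, `p.value`, `estimate`
#'   (proportions).
#' @export
proportion_test <- function(successes, sizes, correct = TRUE) {
  if (length(successes) < 2L || length(successes) != length(sizes))
    stop_mpra("need matching counts for >= 2 groups", "mpra_validation_error")
  if (any(successes > sizes) || any(successes < 0) || any(sizes < 1))
    stop_mpra("counts must satisfy 0 <= count <= size", "mpra_validation_error")
  ht <- suppressWarnings(stats::prop.test(successes, sizes, correct = correct))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p.value = ht$p.value, estimate = unname(ht$estimate))
}

#' Summarise annotation overlaps across enhancer groups
#'
#' Builds the standard overlap report for a set of disjoint element groups
#' (e.g. allele-specific enhancers, general enhancers, background) against
#' one or more annotation classes: per-cell counts and percentages
#' (rounded half-up to 2 decimals), the k-group proportion test per class,
#' and the merged layout in which the enhancer groups are pooled and
#' tested against the background with continuity correction.
#'
#' @param counts Integer matrix, groups x annotation classes (row and
#'   column names required).
#' @param sizes Named group sizes (matching rownames of `counts`).
#' @param enhancer_groups Row names pooled for the merged-vs-background
#'   test; all remaining rows form the background.
#' @return An `overlap_summary`: list with `summary` (long data.frame:
#'   group, class, count, size, pct) and `tests` (per class: k-group
#'   p-value, merged 2-group p-value).
#' @export
summarize_overlaps <- function(counts, sizes,
                               enhancer_groups = rownames(counts)[-nrow(counts)]) {
  counts <- as.matrix(counts)
  groups <- rownames(counts)
  if (is.null(groups) || is.null(colnames(counts)))
    stop_mpra("counts must have group rownames and class colnames",
              "mpra_validation_error")
  sizes <- sizes[groups]
  if (any(counts > sizes))
    stop_mpra("counts exceed group sizes", "mpra_validation_error")
  summary <- data.frame(
    group = rep(groups, times = ncol(counts)),
    class = rep(colnames(counts), each = nrow(counts)),
    count = as.integer(counts),
    size = rep(unname(sizes), times = ncol(counts)),
    stringsAsFactors = FALSE
  )
  summary$pct <- round_half_up(100 * summary$count / summary$size, 2L)
  bg <- setdiff(groups, enhancer_groups)
  tests <- do.call(rbind, lapply(colnames(counts), function(cl) {
    p_groups <- proportion_test(counts[, cl], sizes)$p.value
    merged_counts <- c(sum(counts[enhancer_groups, cl]),
                       sum(counts[bg, cl]))
    merged_sizes <- c(sum(sizes[enhancer_groups]), sum(sizes[bg]))
    p_merged <- proportion_test(merged_counts, merged_sizes)$p.value
    data.frame(class = cl, p_groups = p_groups, p_merged = p_merged,
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, tests = tests),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("Annotation overlap summary\n")
  wide <- stats::reshape(x$summary[, c("group", "class", "pct")],
                         idvar = "group", timevar = "class",
                         direction = "wide")
  print(wide, row.names = FALSE)
  cat("\nProportion tests (p-values):\n")
  print(x$tests, row.names = FALSE, digits = 3)
  invisible(x)
}
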