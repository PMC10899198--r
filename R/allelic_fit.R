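#' Fit the moderated allelic-activity model
#'
#' Tests, for every variant with both alleles retained, whether the
#' alternate allele drives different reporter activity than the reference
#' allele. With replicate as the blocking factor the balanced two-allele
#' design reduces exactly to paired differences: per replicate
#' `d_r = a[alt, r] - a[ref, r]`, with effect estimate `beta = mean(d_r)`,
#' residual variance `s2 = var(d_r)` on `R - 1` degrees of freedom, and
#' unscaled variance `v = 1/R`. Variances are shrunk toward an
#' empirical-Bayes prior `(d0, s0^2)` estimated from the variance ensemble
#' (see [estimate_moderation()]):
#' `s2_post = (d0*s0^2 + (R-1)*s2) / (d0 + R - 1)`, and the moderated
#' statistic `t = beta / (sqrt(s2_post) * sqrt(v))` is referred to a t
#' distribution on `d0 + R - 1` degrees of freedom. P-values are
#' Benjamini-Hochberg adjusted and tiered: `active` below `fdr_active`,
#' `suggestive` between `fdr_active` and `fdr_suggestive`, otherwise `ns`.
#'
#' Variants missing one allele (e.g. lost to the minimum-barcode filter)
#' are skipped and recorded, not modeled.
#'
#' @param activity An `activity_table` from [compute_activity()], whose
#'   element IDs end in `_ref`/`_alt`, or an `element_counts` data.frame
#'   (activities are then computed with defaults).
#' @param d0,s0_sq Optional moderation hyperparameters; both default to
#'   ensemble estimates. `d0 = 0` gives the ordinary paired t-test.
#' @param fdr_active,fdr_suggestive Adjusted-p tier boundaries.
#' @param compute_b Also compute the B-statistic (log-odds of differential
#'   activity) with prior proportion `prior_prop`.
#' @param prior_prop Assumed proportion of truly differential variants.
#' @return An object of class `mpra_allelic_fit`; see Details. Methods:
#'   `print`, `summary`, `coef` (named logFC vector), `plot` (volcano).
#' @export
fit_allelic <- function(activity, d0 = NULL, s0_sq = NULL,
                        fdr_active = 0.05, fdr_suggestive = 0.1,
                        compute_b = FALSE, prior_prop = 0.01) {
  if (inherits(activity, "element_counts")) activity <- compute_activity(activity)
  R <- activity$R
  if (R < 2L)
    stop_mpra("at least 2 replicates required", "mpra_insufficient_replicates")
  ids <- activity$element_id
  allele <- sub("^.*_(ref|alt)$", "\\1", ids)
  variant <- sub("_(ref|alt)$", "", ids)
  if (any(allele == ids))
    stop_mpra("element IDs must end in _ref or _alt", "mpra_validation_error")
  iref <- match(paste0(unique(variant), "_ref"), ids)
  ialt <- match(paste0(unique(variant), "_alt"), ids)
  paired <- !is.na(iref) & !is.na(ialt)
  skipped <- unique(variant)[!paired]
  vid <- unique(variant)[paired]
  if (length(vid) == 0L)
    stop_mpra("no variant has both alleles retained", "mpra_validation_error")
  D <- activity$a[ialt[paired], , drop = FALSE] -
       activity$a[iref[paired], , drop = FALSE]
  beta <- rowMeans(D)
  s2 <- apply(D, 1L, stats::var)
  d_g <- R - 1L
  v <- 1 / R
  if (is.null(d0) || is.null(s0_sq)) {
    mod <- estimate_moderation(s2, d_g)
    if (is.null(d0)) d0 <- mod$d0
    if (is.null(s0_sq)) s0_sq <- mod$s0_sq
  }
  s2_post <- if (is.infinite(d0)) rep(s0_sq, length(s2))
             else if (d0 == 0) s2
             else (d0 * s0_sq + d_g * s2) / (d0 + d_g)
  df_total <- d0 + d_g
  tmod <- beta / (sqrt(s2_post) * sqrt(v))
  tmod[s2_post == 0 & beta == 0] <- 0
  p <- 2 * stats::pt(-abs(tmod), df = df_total)
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  adj <- adjust_fdr(p)
  tier <- ifelse(adj < fdr_active, "active",
                 ifelse(adj < fdr_suggestive, "suggestive", "ns"))
  res <- data.frame(variant_id = vid, logFC = unname(beta), t = unname(tmod),
                    p = unname(p), adj_p = unname(adj),
                    B = NA_real_, tier = tier, stringsAsFactors = FALSE)
  if (compute_b)
    res$B <- b_statistic(res$t, v, s2_post, df_total, prior_prop, beta)
  structure(list(results = res, d0 = d0, s0_sq = s0_sq, R = R,
                 df_total = df_total, v = v, s2 = unname(s2),
                 s2_post = unname(s2_post),
                 fdr_active = fdr_active, fdr_suggestive = fdr_suggestive,
                 skipped = skipped),
            class = "mpra_allelic_fit")
}

# log-odds of differential activity: posterior odds under a two-component
# mixture with prior proportion p1, where differential effects have extra
# variance V0. V0 is moment-matched on the strongest prior_prop fraction of
# effect estimates (excess of beta^2 over its null sampling variance).
b_statistic <- function(t, v, s2_post, df_total, p1, beta) {
  n <- length(t)
  ntop <- max(1L, ceiling(p1 * n))
  top <- order(abs(t), decreasing = TRUE)[seq_len(ntop)]
  V0 <- max(mean(beta[top]^2 - v * s2_post[top]), 0)
  r <- (v * s2_post + V0) / (v * s2_post) # variance inflation under H1
  t2 <- t^2
  kernel <- if (is.infinite(df_total)) t2 * (1 - 1 / r) / 2
            else ((1 + df_total) / 2) * log((t2 + df_total) / (t2 / r + df_total))
  log(p1 / (1 - p1)) - log(r) / 2 + kernel
}

#' @export
print.mpra_allelic_fit <- function(x, ...) {
  cat("Moderated allelic activity fit\n")
  cat("  variants tested:", nrow(x$results),
      "| replicates:", x$R,
      "| skipped (one allele):", length(x$skipped), "\n")
  cat(sprintf("  prior df d0 = %s, prior variance s0^2 = %.4g, df = %s\n",
              format(x$d0, digits = 4), x$s0_sq, format(x$df_total, digits = 4)))
  tc <- table(factor(x$results$tier, levels = c("active", "suggestive", "ns")))
  cat(sprintf("  tiers: %d active (adj.p < %s), %d suggestive (< %s), %d ns\n",
              tc[["active"]], format(x$fdr_active),
              tc[["suggestive"]], format(x$fdr_suggestive), tc[["ns"]]))
  invisible(x)
}

#' @method summary mpra_allelic_fit
#' @export
summary.mpra_allelic_fit <- function(object, n = 10L, ...) {
  print(object)
  res <- object$results[order(object$results$adj_p), ]
  cat("\nTop variants by adjusted p-value:\n")
  print(utils::head(res, n), row.names = FALSE, digits = 4)
  invisible(res)
}

#' @method coef mpra_allelic_fit
#' @export
coef.mpra_allelic_fit <- function(object, ...) {
  stats::setNames(object$results$logFC, object$results$variant_id)
}

#' @method plot mpra_allelic_fit
#' @export
plot.mpra_allelic_fit <- function(x, ...) {
  res <- x$results
  col <- c(active = "red3", suggestive = "grey40", ns = "grey75")[res$tier]
  graphics::plot(res$logFC, -log10(res$adj_p), col = col, pch = 16,
                 xlab = "logFC (alt - ref activity)",
                 ylab = "-log10 adjusted p", ...)
  graphics::abline(h = -log10(x$fdr_active), lty = 2)
  invisible(x)
}

#' @method as.data.frame mpra_allelic_fit
#' @export
as.data.frame.mpra_allelic_fit <- function(x, ...) x$results

#' Write allelic results as TSV
#'
#' Columns mirror the standard reporting layout: `variant_id`, `logFC`,
#' `t`, `p`, `adj_p`, `B`, `tier`.
#'
#' @param fit An `mpra_allelic_fit`.
#' @param path TSV path.
#' @return `path`, invisibly.
#' @export
write_allelic_results <- function(fit, path) {
  utils::write.table(fit$results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
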