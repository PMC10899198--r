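#' Compute per-replicate and pooled activity scores
#'
#' Activity is the log2 ratio of normalized RNA to normalized DNA counts.
#' With a pseudocount of 1 on both assays,
#' `a[e,r] = log2(((rna+1)/N_rna_r) / ((dna+1)/N_dna_r))`, where the
#' normalizers `N` are per-replicate assay totals over the retained
#' elements. The pooled activity `A[e]` applies the same formula to counts
#' summed over replicates.
#'
#' @param elements An `element_counts` data.frame (retained elements only).
#' @param pseudocount Added to each count before normalization (keeps
#'   activities finite).
#' @return An `activity_table`: list with `element_id`, per-replicate
#'   matrix `a`, pooled vector `A`, and `R`.
#' @export
compute_activity <- function(elements, pseudocount = 1) {
  R <- attr(elements, "R")
  if (is.null(R)) R <- sum(grepl("^dna_", names(elements)))
  dna <- as.matrix(elements[, paste0("dna_", seq_len(R)), drop = FALSE])
  rna <- as.matrix(elements[, paste0("rna_", seq_len(R)), drop = FALSE])
  Nd <- colSums(dna); Nr <- colSums(rna)
  if (any(Nd == 0) || any(Nr == 0))
    stop_mpra("a replicate has zero total counts in an assay",
              "mpra_degenerate_replicate")
  a <- log2(sweep(rna + pseudocount, 2L, Nr, "/") /
              sweep(dna + pseudocount, 2L, Nd, "/"))
  dp <- rowSums(dna); rp <- rowSums(rna)
  A <- log2(((rp + pseudocount) / sum(rp)) / ((dp + pseudocount) / sum(dp)))
  dimnames(a) <- list(elements$element_id, paste0("rep", seq_len(R)))
  structure(list(element_id = elements$element_id, a = a,
                 A = stats::setNames(A, elements$element_id), R = R),
            class = "activity_table")
}

#' @export
print.activity_table <- function(x, ...) {
  cat("Activity table:", length(x$element_id), "elements x", x$R,
      "replicates\n")
  cat("  pooled activity range:",
      paste(signif(range(x$A), 3), collapse = " .. "), "(log2 RNA/DNA)\n")
  invisible(x)
}

#' Call general enhancers by activity z-score
#'
#' Standardizes the pooled activities over all retained elements (sample
#' standard deviation) and flags elements whose z-score meets the
#' threshold. Calling is one-sided (`z >= z_threshold`) by default;
#' `two_sided = TRUE` flags `|z| >= z_threshold`. If the activities have
#' zero spread, all z-scores are defined as 0 and nothing is called.
#'
#' @param activity An `activity_table`.
#' @param z_threshold Standard-deviation threshold (default 3).
#' @param two_sided Flag strong negative (silencer-like) tails too.
#' @return Data.frame (`element_id`, `A`, `z`, `is_enhancer`).
#' @export
call_general_enhancers <- function(activity, z_threshold = 3,
                                   two_sided = FALSE) {
  A <- activity$A
  if (length(A) < 2L)
    stop_mpra("need at least 2 elements to standardize", "mpra_validation_error")
  s <- stats::sd(A)
  z <- if (s == 0) rep(0, length(A)) else (A - mean(A)) / s
  hit <- if (two_sided) abs(z) >= z_threshold else z >= z_threshold
  data.frame(element_id = activity$element_id, A = unname(A), z = unname(z),
             is_enhancer = hit & s > 0, stringsAsFactors = FALSE)
}

#' Estimate empirical-Bayes moderation hyperparameters
#'
#' Method-of-moments on log residual variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom `d0` solve
#' `trigamma(d0/2) = max(0, var(e)*n/(n-1) - mean(trigamma(d_g/2)))`
#' (monotone bisection; `d0 = Inf` when the right side is <= 0), and the
#' prior variance is `s0^2 = exp(mean(e) + digamma(d0/2) - log(d0/2))`
#' (limit `exp(mean(e))` as `d0 -> Inf`).
#'
#' @param s2 Per-variant residual variances (`s2 > 0`; zero variances are
#'   excluded with a warning).
#' @param df Residual degrees of freedom, scalar or per-variant.
#' @return List with `d0`, `s0_sq` and `n` (variances used).
#' @export
estimate_moderation <- function(s2, df) {
  df <- rep_len(df, length(s2))
  if (length(s2) && all(s2 == 0, na.rm = TRUE))
    stop_mpra("all residual variances are zero", "mpra_degenerate_variance")
  ok <- is.finite(s2) & s2 > 0 & df >= 1
  if (any(s2 == 0, na.rm = TRUE))
    warning(sum(s2 == 0, na.rm = TRUE), " zero variances excluded from moderation")
  s2 <- s2[ok]; df <- df[ok]
  n <- length(s2)
  if (n < 3L)
    stop_mpra("need at least 3 positive residual variances", "mpra_validation_error")
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  rhs <- max(0, stats::var(e) * n / (n - 1) - mean(trigamma(df / 2)))
  if (rhs <= 0) {
    d0 <- Inf
    s0_sq <- exp(mean(e))
  } else {
    d0 <- trigamma_inverse_half(rhs)
    s0_sq <- if (is.infinite(d0)) exp(mean(e))
             else exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  list(d0 = d0, s0_sq = s0_sq, n = n)
}

# solve trigamma(d0/2) = y for d0 by bisection on [1e-4, 1e6]
trigamma_inverse_half <- function(y, tol = 1e-8) {
  lo <- 1e-4; hi <- 1e6
  if (y <= trigamma(hi / 2)) return(Inf)
  if (y >= trigamma(lo / 2)) return(lo)
  while (hi - lo > tol * max(1, lo)) {
    mid <- (lo + hi) / 2
    if (trigamma(mid / 2) > y) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Sorts p-values ascending, computes `p_(i) * m / i`, enforces
#' monotonicity from the largest down, caps at 1, and restores the input
#' order.
#'
#' @param p P-values in (0, 1].
#' @return Adjusted p-values in the original order.
#' @export
adjust_fdr <- function(p) {
  if (length(p) == 0L) return(numeric())
  if (any(!is.finite(p) | p <= 0 | p > 1))
    stop_mpra("p-values must lie in (0, 1]", "mpra_validation_error")
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  adj <- pmin(rev(cummin(rev(q))), 1)
  out <- numeric(m)
  out[o] <- adj
  out
}
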