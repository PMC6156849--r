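#' Differential splicing statistics
#'
#' Sequencing counts are transformed with voom (log2-CPM plus observation
#' weights from the fitted mean-variance trend); array signals enter as log2
#' values with unit weights. Each alternative path is tested with a moderated
#' linear-model contrast; an event is significant when its two paths change
#' in opposite directions and the summarized p-value (by default the larger
#' of the two, an intersection-union reading) is below the significance
#' threshold.
#'
#' @name splicing_stats
#' @keywords internal
NULL

#' voom transformation of path-level counts
#'
#' log2 counts per million, y = log2((count + 0.5) / (library_size + 1) * 1e6),
#' with precision weights from the lowess mean-variance trend fitted under the
#' design. With fewer rows than needed for a stable trend (default 50), the
#' transform falls back to unit weights with a warning.
#'
#' @param counts non-negative integer matrix (rows = paths, cols = samples).
#' @param library_sizes total mapped reads per sample (defaults to column
#'   sums).
#' @param design design matrix (defaults to intercept only).
#' @param min_rows minimum number of rows for trend fitting.
#' @return list with \code{E} (log2-CPM matrix) and \code{weights}.
#' @export
voom_transform <- function(counts, library_sizes = NULL, design = NULL,
                           min_rows = 50L) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (is.null(library_sizes)) library_sizes <- colSums(counts)
  if (any(library_sizes <= 0)) stop("library sizes must be > 0")
  if (nrow(counts) < min_rows) {
    warning("fewer than ", min_rows,
            " rows; using unit precision weights")
    E <- t(log2(t(counts + 0.5) / (library_sizes + 1) * 1e6))
    return(list(E = E, weights = matrix(1, nrow(counts), ncol(counts))))
  }
  v <- limma::voom(counts, design = design, lib.size = library_sizes)
  list(E = v$E, weights = v$weights)
}

.check_design <- function(design, contrast = NULL) {
  design <- as.matrix(design)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    collinear <- colnames(design)[qr_d$pivot[-seq_len(qr_d$rank)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(collinear, collapse = ", "))
  }
  if (!is.null(contrast) && length(contrast) != ncol(design)) {
    stop("contrast length must equal the number of design columns")
  }
  design
}

#' Weighted least-squares contrast fit per row
#'
#' Fits the linear model row-wise with the given precision weights and
#' extracts the contrast estimate, its unscaled standard error, the residual
#' standard deviation and the residual degrees of freedom.
#'
#' @param E signal matrix (rows = paths).
#' @param weights precision-weight matrix of the same shape (or NULL).
#' @param design samples x covariates design matrix of full column rank.
#' @param contrast numeric contrast vector over the design columns.
#' @return data.frame with \code{logfc}, \code{stdev_unscaled}, \code{sigma},
#'   \code{df_residual}.
#' @export
fit_path_contrasts <- function(E, weights, design, contrast) {
  design <- .check_design(design, contrast)
  fit <- limma::lmFit(E, design, weights = weights)
  cf <- limma::contrasts.fit(fit, contrasts = matrix(contrast, ncol = 1L))
  data.frame(
    logfc = as.numeric(cf$coefficients[, 1L]),
    stdev_unscaled = as.numeric(cf$stdev.unscaled[, 1L]),
    sigma = cf$sigma,
    df_residual = cf$df.residual
  )
}

#' Empirical-Bayes moderated p-values
#'
#' Shrinks row-wise residual variances towards a common prior (limma's
#' squeezeVar) and computes moderated t statistics and two-sided p-values
#' with the augmented degrees of freedom.
#'
#' @param fit data.frame from [fit_path_contrasts()].
#' @return the fit with added \code{t}, \code{p} and \code{df_total}; rows
#'   with non-finite variances are dropped with a message.
#' @export
moderate <- function(fit) {
  ok <- is.finite(fit$sigma) & is.finite(fit$stdev_unscaled)
  if (!all(ok)) {
    message("dropping ", sum(!ok), " row(s) with non-finite variances")
    fit <- fit[ok, , drop = FALSE]
  }
  if (nrow(fit) < 10L) {
    warning("fewer than 10 rows; variance shrinkage may be unstable")
  }
  sq <- limma::squeezeVar(fit$sigma^2, fit$df_residual)
  df_total <- fit$df_residual + sq$df.prior
  se <- sqrt(sq$var.post) * fit$stdev_unscaled
  fit$t <- fit$logfc / se
  fit$df_total <- df_total
  fit$p <- 2 * stats::pt(-abs(fit$t), df = df_total)
  fit
}

#' Event-level decision rule
#'
#' Combines the two per-path tests: the summarized p-value (default: the
#' maximum of the two, so both paths must move), the opposite-sign requirement
#' on the fold changes, and the significance trichotomy -- significant when
#' the fold changes have opposite signs and the summarized p-value is below
#' \code{sig_threshold}; non-significant when the summarized p-value exceeds
#' \code{nonsig_threshold}; inconclusive otherwise.
#'
#' @param p1,p2 per-path p-values.
#' @param logfc1,logfc2 per-path contrast estimates (log fold changes).
#' @param sig_threshold significance cutoff (default 0.001).
#' @param nonsig_threshold non-significance cutoff (default 0.2).
#' @param combiner one of \code{"max"} (intersection-union), \code{"fisher"},
#'   \code{"irwin_hall"} (sum of the two p-values).
#' @return data.frame with \code{logfc1}, \code{logfc2}, \code{p1}, \code{p2},
#'   \code{p_summary}, \code{direction_ok} and \code{sig_class}.
#' @export
summarize_event <- function(p1, p2, logfc1, logfc2,
                            sig_threshold = 0.001, nonsig_threshold = 0.2,
                            combiner = c("max", "fisher", "irwin_hall")) {
  combiner <- match.arg(combiner)
  p_summary <- switch(
    combiner,
    max = pmax(p1, p2),
    fisher = stats::pchisq(-2 * (log(p1) + log(p2)), df = 4,
                           lower.tail = FALSE),
    irwin_hall = {
      s <- p1 + p2
      ifelse(s <= 1, s^2 / 2, 1 - (2 - s)^2 / 2)
    }
  )
  direction_ok <- sign(logfc1) * sign(logfc2) == -1
  sig_class <- ifelse(direction_ok & p_summary < sig_threshold, "significant",
               ifelse(p_summary > nonsig_threshold, "non_significant",
                      "inconclusive"))
  data.frame(logfc1 = logfc1, logfc2 = logfc2, p1 = p1, p2 = p2,
             p_summary = p_summary, direction_ok = direction_ok,
             sig_class = sig_class, stringsAsFactors = FALSE)
}

#' Estimate the null proportion and false discovery rate
#'
#' Storey's estimator at a single evaluation point (p > 0.5):
#' pi0 = #\{p > 0.5\} / (0.5 m), clipped to [0, 1]. FDR at a cutoff t is
#' pi0 * m * t / #\{p <= t\}; q-values follow by step-up monotonization.
#'
#' @param p p-value vector.
#' @param threshold cutoff at which to report the FDR (default 0.001).
#' @return list of class \code{fdr_result}: \code{pi0},
#'   \code{fdr_at_threshold}, \code{threshold}, \code{q} (per input p-value).
#' @export
estimate_pi0_fdr <- function(p, threshold = 0.001) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m < 100L) warning("pi0 estimation with fewer than 100 p-values")
  pi0 <- min(1, max(0, sum(p > 0.5) / (0.5 * m)))
  n_at <- sum(p <= threshold)
  fdr_at <- if (n_at > 0) min(1, pi0 * m * threshold / n_at) else NA_real_
  o <- order(p)
  q_sorted <- pi0 * m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  q <- numeric(m)
  q[o] <- q_sorted
  structure(list(pi0 = pi0, fdr_at_threshold = fdr_at, threshold = threshold,
                 q = q),
            class = "fdr_result")
}

#' @export
print.fdr_result <- function(x, ...) {
  cat(sprintf("pi0 = %.3f; FDR at p <= %g: %s (%d tests)\n", x$pi0,
              x$threshold,
              if (is.na(x$fdr_at_threshold)) "undefined"
              else sprintf("%.3g", x$fdr_at_threshold),
              length(x$q)))
  invisible(x)
}

#' Binomial thinning of counts
#'
#' Replaces each count by a binomial draw with the given success probability,
#' emulating a shallower sequencing run. Deterministic under a fixed seed.
#'
#' @param counts non-negative integer matrix or vector.
#' @param fraction thinning fraction in (0, 1].
#' @param library_sizes optional; when given, returned rescaled by
#'   \code{fraction} alongside the counts.
#' @param seed optional integer seed.
#' @return thinned counts (same shape); if \code{library_sizes} is supplied, a
#'   list with \code{counts} and \code{library_sizes}.
#' @export
subsample_counts <- function(counts, fraction, library_sizes = NULL,
                             seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  thinned <- counts
  if (fraction < 1) {
    thinned[] <- stats::rbinom(length(counts), size = as.integer(counts),
                               prob = fraction)
  }
  if (is.null(library_sizes)) return(thinned)
  list(counts = thinned, library_sizes = library_sizes * fraction)
}
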