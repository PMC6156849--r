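#' Differential splicing analysis of event-level measurements
#'
#' Runs the statistical pipeline for a set of events: voom transformation of
#' the two alternative paths' counts (sequencing) or log2 of linear signals
#' with unit weights (arrays), a moderated linear-model contrast per path,
#' the opposite-sign + summarized-p decision rule, pi0/FDR estimation, and
#' penalized-NNLS PSI per event.
#'
#' @param path1,path2 event x sample matrices of path measurements: counts for
#'   \code{platform = "rnaseq"}, linear-scale signals for \code{"array"}.
#'   Rownames are event ids.
#' @param design design matrix (samples x covariates), full column rank.
#' @param contrast numeric contrast vector over design columns.
#' @param platform \code{"rnaseq"} or \code{"array"}.
#' @param library_sizes per-sample totals (sequencing only; defaults to
#'   column sums of the stacked counts).
#' @param signals optional list with \code{S1}, \code{S2}, \code{SR} matrices
#'   on the linear scale used for PSI estimation (defaults: FPKM-like from
#'   counts for sequencing via \code{nominal_length}; the path signals
#'   themselves plus their sum for arrays).
#' @param condition optional factor used for the per-event delta PSI.
#' @param sig_threshold,nonsig_threshold,combiner decision-rule parameters,
#'   see [summarize_event()].
#' @param nominal_length effective path length used to convert counts to
#'   FPKM for PSI estimation.
#' @return data.frame of class \code{event_test_results}: per event, fold
#'   changes, p-values, summarized p, significance class, q-value, PSI model
#'   parameters (u, v, epsilon) and delta PSI. The pi0 estimate is attached
#'   as attribute \code{pi0}.
#' @export
test_splicing_events <- function(path1, path2, design, contrast,
                                 platform = c("rnaseq", "array"),
                                 library_sizes = NULL, signals = NULL,
                                 condition = NULL,
                                 sig_threshold = 0.001,
                                 nonsig_threshold = 0.2,
                                 combiner = "max",
                                 nominal_length = 99) {
  platform <- match.arg(platform)
  path1 <- as.matrix(path1); path2 <- as.matrix(path2)
  stopifnot(identical(dim(path1), dim(path2)))
  n_events <- nrow(path1)
  event_id <- rownames(path1)
  if (is.null(event_id)) event_id <- paste0("ev", seq_len(n_events))

  stacked <- rbind(path1, path2)
  if (platform == "rnaseq") {
    if (is.null(library_sizes)) library_sizes <- colSums(stacked)
    v <- voom_transform(stacked, library_sizes, design)
    E <- v$E; W <- v$weights
  } else {
    E <- log2(stacked + 1)
    W <- NULL
  }
  fit <- moderate(fit_path_contrasts(E, W, design, contrast))
  f1 <- fit[seq_len(n_events), ]
  f2 <- fit[n_events + seq_len(n_events), ]
  res <- summarize_event(f1$p, f2$p, f1$logfc, f2$logfc,
                         sig_threshold = sig_threshold,
                         nonsig_threshold = nonsig_threshold,
                         combiner = combiner)
  fdr <- estimate_pi0_fdr(res$p_summary, threshold = sig_threshold)

  if (is.null(signals)) {
    signals <- if (platform == "rnaseq") {
      to_fpkm <- function(cm) {
        sweep(cm * 1e9 / nominal_length, 2, library_sizes, "/")
      }
      list(S1 = to_fpkm(path1), S2 = to_fpkm(path2),
           SR = to_fpkm(path1 + path2))
    } else {
      list(S1 = path1, S2 = path2, SR = path1 + path2)
    }
  }
  u <- v_ <- eps <- dps <- rep(NA_real_, n_events)
  for (i in seq_len(n_events)) {
    pf <- estimate_psi(signals$S1[i, ], signals$S2[i, ], signals$SR[i, ],
                       condition = condition)
    u[i] <- pf$u; v_[i] <- pf$v; eps[i] <- pf$epsilon
    dps[i] <- pf$delta_psi
  }

  out <- data.frame(
    event_id = event_id,
    logfc1 = res$logfc1, logfc2 = res$logfc2,
    p1 = res$p1, p2 = res$p2, p_summary = res$p_summary,
    direction_ok = res$direction_ok, sig_class = res$sig_class,
    q_value = fdr$q, u = u, v = v_, epsilon = eps, delta_psi = dps,
    stringsAsFactors = FALSE
  )
  attr(out, "pi0") <- fdr$pi0
  attr(out, "fdr_at_threshold") <- fdr$fdr_at_threshold
  class(out) <- c("event_test_results", "data.frame")
  out
}

#' @export
print.event_test_results <- function(x, ...) {
  cat("Differential splicing results:", nrow(x), "events\n")
  cat("  significant:", sum(x$sig_class == "significant"),
      "| inconclusive:", sum(x$sig_class == "inconclusive"),
      "| non-significant:", sum(x$sig_class == "non_significant"), "\n")
  cat(sprintf("  pi0 = %.3f\n", attr(x, "pi0")))
  NextMethod()
}

#' Write a results table
#' @param results an \code{event_test_results} data.frame.
#' @param path output path.
#' @export
write_results_table <- function(results, path) {
  write_eventscope_tsv(as.data.frame(results), path)
}

#' Detection power and false-positive rate against a known truth
#'
#' @param results \code{event_test_results}.
#' @param truth data.frame with \code{event_id} and logical
#'   \code{differential}.
#' @return list with \code{power} (significant among true differential
#'   events) and \code{fpr} (significant among null events).
#' @export
detection_rates <- function(results, truth) {
  m <- match(results$event_id, truth$event_id)
  diff <- truth$differential[m]
  sig <- results$sig_class == "significant"
  list(power = mean(sig[diff]), fpr = mean(sig[!diff]))
}
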