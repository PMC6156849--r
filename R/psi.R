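#' Percent-spliced-in estimation by penalized non-negative least squares
#'
#' The signal of each path is modeled as the product of an affinity (probe
#' affinity on arrays, effective length for sequencing coverage) and the
#' concentration of the isoforms using the path: S_i = a_i * t_i. Because the
#' reference path carries all isoforms of the event, t_R = t_1 + t_2 and
#'
#'   S_R = u * S_1 + v * S_2,  u = a_R / a_1,  v = a_R / a_2.
#'
#' u and v are estimated by non-negative least squares on the stacked
#' per-sample signal rows with three penalty rows that pull u and v towards
#' each other and towards one:
#'
#'   A = rbind(cbind(S1, S2), c(l, -l), c(l, 0), c(0, l)),  b = c(SR, 0, l, l)
#'
#' with penalty weight l (lambda). PSI then follows without knowing the
#' affinities themselves:
#'
#'   PSI_j = u * S1_j / (u * S1_j + v * S2_j).
#'
#' @name psi_estimation
#' @keywords internal
NULL

#' Summarize per-edge signals into one path signal
#'
#' All measurements belonging to a path (junction/exon coverage, probe sets)
#' are summarized into one average value per sample.
#'
#' @param edge_signals numeric matrix, edges x samples (a vector is treated as
#'   a single sample's edge values).
#' @return Numeric vector: per-sample arithmetic mean across edges.
#' @export
summarize_path_signal <- function(edge_signals) {
  if (is.null(dim(edge_signals))) {
    edge_signals <- matrix(edge_signals, ncol = 1L)
  }
  if (nrow(edge_signals) == 0L) stop("path has no edges to summarize")
  colMeans(edge_signals)
}

## exact 2-D non-negative least squares: the problem is strictly convex for
## lambda > 0, so the minimizer is either the unconstrained solution or the
## best of the two single-coordinate boundary solutions.
.nnls2 <- function(A, b) {
  AtA <- crossprod(A)
  Atb <- drop(crossprod(A, b))
  obj <- function(x) drop(x %*% AtA %*% x) - 2 * sum(Atb * x)
  x <- tryCatch(drop(solve(AtA, Atb)), error = function(e) c(-1, -1))
  if (all(x >= 0)) return(pmax(x, 0))
  cand <- list(
    c(max(0, Atb[1L] / AtA[1L, 1L]), 0),
    c(0, max(0, Atb[2L] / AtA[2L, 2L])),
    c(0, 0)
  )
  vals <- vapply(cand, obj, numeric(1))
  cand[[which.min(vals)]]
}

#' Default penalty weight
#'
#' The penalty rows must be commensurate with the signal rows; the default is
#' one tenth of the root-mean-square reference signal.
#' @param SR reference-path signal vector.
#' @return Penalty weight (1 if the reference signal is identically zero).
#' @export
default_lambda <- function(SR) {
  rms <- sqrt(mean(SR^2))
  if (rms > 0) 0.1 * rms else 1
}

#' Estimate the affinity fractions u and v
#'
#' @param S1,S2,SR non-negative linear-scale signal vectors (one value per
#'   sample) for the two alternative paths and the reference path.
#' @param lambda penalty weight; defaults to [default_lambda()] of \code{SR}.
#' @return A list of class \code{uv_estimate}: \code{u}, \code{v},
#'   \code{lambda}, \code{epsilon} (relative residual error of the additive
#'   model) and \code{degenerate} (TRUE when all signals are zero, in which
#'   case the penalty rows force u = v = 1 and epsilon is 0).
#' @export
estimate_uv <- function(S1, S2, SR, lambda = NULL) {
  stopifnot(length(S1) == length(S2), length(S1) == length(SR),
            length(S1) >= 1L)
  if (any(c(S1, S2, SR) < 0)) stop("signals must be non-negative")
  degenerate <- all(S1 == 0) && all(S2 == 0) && all(SR == 0)
  if (is.null(lambda)) lambda <- default_lambda(SR)
  if (lambda <= 0) stop("lambda must be > 0")
  A <- rbind(cbind(S1, S2),
             c(lambda, -lambda),
             c(lambda, 0),
             c(0, lambda))
  b <- c(SR, 0, lambda, lambda)
  x <- unname(.nnls2(A, b))
  out <- structure(
    list(u = x[1L], v = x[2L], lambda = lambda, epsilon = NA_real_,
         degenerate = degenerate),
    class = "uv_estimate"
  )
  out$epsilon <- if (degenerate) 0 else relative_error(S1, S2, SR, out)
  out
}

#' @export
print.uv_estimate <- function(x, ...) {
  cat(sprintf("u = %.4f, v = %.4f (lambda = %.4g, epsilon = %.4g%s)\n",
              x$u, x$v, x$lambda, x$epsilon,
              if (isTRUE(x$degenerate)) ", degenerate" else ""))
  invisible(x)
}

#' Relative residual error of the additive signal model
#'
#' epsilon = ||(u*S1 + v*S2) - SR||_2 / ||SR||_2. Large values flag events
#' whose measurements are not internally coherent with the additive model
#' (e.g. bad-performing probe sets), whose estimates are less reliable.
#'
#' @inheritParams estimate_uv
#' @param uv a \code{uv_estimate}.
#' @return epsilon; \code{NA} (with a warning) when \code{SR} is identically
#'   zero, in which case the ratio is undefined.
#' @export
relative_error <- function(S1, S2, SR, uv) {
  denom <- sqrt(sum(SR^2))
  if (denom == 0) {
    warning("reference signal is identically zero; relative error undefined")
    return(NA_real_)
  }
  sqrt(sum((uv$u * S1 + uv$v * S2 - SR)^2)) / denom
}

#' Per-sample percent spliced in
#'
#' @inheritParams estimate_uv
#' @param uv a \code{uv_estimate} for the same event.
#' @return Numeric vector of PSI values in [0, 1]; \code{NA} where
#'   \code{u*S1 + v*S2} is zero (undefined).
#' @export
compute_psi <- function(S1, S2, uv) {
  if (any(c(S1, S2) < 0)) stop("signals must be non-negative")
  num <- uv$u * S1
  den <- uv$u * S1 + uv$v * S2
  psi <- ifelse(den > 0, num / den, NA_real_)
  pmin(pmax(psi, 0), 1)
}

#' Estimate PSI for one event
#'
#' Convenience wrapper: estimates u and v by penalized NNLS, computes
#' per-sample PSI and the model-coherence error.
#'
#' @inheritParams estimate_uv
#' @param condition optional factor of sample conditions with two levels;
#'   when given, \code{delta_psi} is the mean PSI difference (second level
#'   minus first, undefined samples excluded).
#' @return Object of class \code{psi_fit}: \code{psi}, \code{u}, \code{v},
#'   \code{lambda}, \code{epsilon}, \code{delta_psi}.
#' @examples
#' S1 <- c(30, 30, 10, 10); S2 <- c(10, 10, 30, 30); SR <- S1 + S2
#' fit <- estimate_psi(S1, S2, SR, condition = factor(c("a", "a", "b", "b")))
#' fit$psi
#' @export
estimate_psi <- function(S1, S2, SR, lambda = NULL, condition = NULL) {
  uv <- estimate_uv(S1, S2, SR, lambda)
  psi <- compute_psi(S1, S2, uv)
  delta <- NA_real_
  if (!is.null(condition)) {
    condition <- as.factor(condition)
    stopifnot(nlevels(condition) == 2L)
    g2 <- psi[condition == levels(condition)[2L]]
    g1 <- psi[condition == levels(condition)[1L]]
    delta <- mean(g2, na.rm = TRUE) - mean(g1, na.rm = TRUE)
  }
  structure(
    list(psi = psi, u = uv$u, v = uv$v, lambda = uv$lambda,
         epsilon = uv$epsilon, degenerate = uv$degenerate,
         delta_psi = delta),
    class = "psi_fit"
  )
}

#' @export
print.psi_fit <- function(x, ...) {
  cat("PSI fit:", length(x$psi), "sample(s)\n")
  cat(sprintf("  u = %.4f, v = %.4f, lambda = %.4g, epsilon = %.4g\n",
              x$u, x$v, x$lambda, x$epsilon))
  cat("  psi:", paste(sprintf("%.3f", x$psi), collapse = " "), "\n")
  if (!is.na(x$delta_psi)) cat(sprintf("  delta_psi = %.3f\n", x$delta_psi))
  invisible(x)
}

#' Write a PSI table
#'
#' TSV of event id x sample PSI, plus u, v, epsilon and delta_psi columns.
#' @param fits named list of \code{psi_fit} objects (names = event ids).
#' @param path output path.
#' @export
write_psi_table <- function(fits, path) {
  stopifnot(length(fits) > 0)
  ns <- length(fits[[1L]]$psi)
  tab <- do.call(rbind, lapply(names(fits), function(id) {
    f <- fits[[id]]
    row <- as.data.frame(as.list(stats::setNames(f$psi,
                                                 paste0("psi_", seq_len(ns)))))
    cbind(data.frame(event_id = id, stringsAsFactors = FALSE), row,
          data.frame(u = f$u, v = f$v, epsilon = f$epsilon,
                     delta_psi = f$delta_psi))
  }))
  write_eventscope_tsv(tab, path)
}
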