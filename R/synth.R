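#' Synthetic data generation
#'
#' Generators emulating the measurement model: path signals obey
#' S_i = a_i * t_i with multiplicative log-normal noise; junction counts obey
#' a count-noise model (Poisson by default, negative binomial optionally) at a
#' stated library size. All generators are deterministic under a fixed seed.
#'
#' @name synthetic_data
#' @keywords internal
NULL

.noise_sigma <- function(noise_cv) {
  # sd of log-signal for a log-normal with coefficient of variation noise_cv
  sqrt(log(1 + noise_cv^2))
}

#' Simulate path signals for one event
#'
#' Given per-sample true PSI and reference concentration, generates
#' S1 = a1 * t1, S2 = a2 * t2, SR = aR * (t1 + t2), each multiplied by
#' log-normal noise with coefficient of variation \code{noise_cv}.
#'
#' @param true_psi per-sample PSI values in [0, 1].
#' @param t_ref reference concentration (scalar or per-sample).
#' @param a1,a2,a_ref path affinities / equivalent lengths.
#' @param noise_cv multiplicative noise coefficient of variation (0 = exact).
#' @param seed optional integer seed.
#' @return list with \code{S1}, \code{S2}, \code{SR}, plus the generating
#'   \code{t1}, \code{t2} and \code{u_true = a_ref/a1}, \code{v_true =
#'   a_ref/a2}.
#' @export
simulate_signals <- function(true_psi, t_ref, a1 = 1, a2 = 1, a_ref = 1,
                             noise_cv = 0.1, seed = NULL) {
  stopifnot(all(true_psi >= 0 & true_psi <= 1), all(t_ref >= 0))
  if (!is.null(seed)) set.seed(seed)
  n <- length(true_psi)
  t_ref <- rep_len(t_ref, n)
  t1 <- true_psi * t_ref
  t2 <- (1 - true_psi) * t_ref
  sigma <- .noise_sigma(noise_cv)
  noise <- function() if (sigma > 0) exp(stats::rnorm(n, 0, sigma)) else 1
  list(
    S1 = a1 * t1 * noise(),
    S2 = a2 * t2 * noise(),
    SR = a_ref * t_ref * noise(),
    t1 = t1, t2 = t2,
    u_true = a_ref / a1, v_true = a_ref / a2
  )
}

#' Random multi-isoform gene annotation
#'
#' Draws a gene with up to \code{max_exons} exons and up to
#' \code{max_isoforms} isoforms; each isoform is a distinct subsequence of
#' the exons, occasionally with a trimmed 5'/3' exon boundary so that
#' alternative donor/acceptor structures arise. Uses the current RNG state.
#'
#' @param max_exons,max_isoforms upper bounds.
#' @param p_trim probability of trimming an exon boundary per isoform.
#' @return gene record (as for [build_graph_from_gtf()]).
#' @export
random_gene_annotation <- function(max_exons = 6L, max_isoforms = 4L,
                                   p_trim = 0.3) {
  n_exons <- sample(2:max_exons, 1L)
  widths <- sample(60:300, n_exons, replace = TRUE)
  gaps <- sample(80:500, n_exons, replace = TRUE)
  starts <- cumsum(gaps + c(0, widths[-n_exons])) + 1000L
  ends <- starts + widths
  n_iso <- sample(2:max_isoforms, 1L)
  iso <- list()
  guard <- 0L
  while (length(iso) < n_iso && guard < 50L) {
    guard <- guard + 1L
    k <- sample(seq_len(n_exons), 1L)
    use <- sort(sample(seq_len(n_exons), k))
    ex <- data.frame(start = starts[use], end = ends[use])
    if (stats::runif(1) < p_trim) {
      j <- sample(seq_len(nrow(ex)), 1L)
      w <- ex$end[j] - ex$start[j]
      d <- sample(10:(w - 20L), 1L)
      if (stats::runif(1) < 0.5) ex$start[j] <- ex$start[j] + d
      else ex$end[j] <- ex$end[j] - d
    }
    key <- paste(ex$start, ex$end, collapse = ";")
    if (!key %in% names(iso)) iso[[key]] <- ex
  }
  exons <- do.call(rbind, lapply(seq_along(iso), function(i) {
    cbind(data.frame(transcript_id = paste0("tx", i)), iso[[i]])
  }))
  list(gene_id = paste0("g", sample.int(1e6, 1L)), chrom = "chr1",
       strand = sample(c("+", "-"), 1L), exons = exons)
}

#' Simulate junction and coverage-bin count tables from an annotated gene
#'
#' Expected counts are proportional to the summed concentration of the
#' isoforms containing each junction (or exonic segment), its effective
#' length, and the library size; counts are drawn Poisson (default) or
#' negative binomial. Output uses the junction-table dialect of
#' [build_graph_from_junctions()].
#'
#' @param gene gene record (see [build_graph_from_gtf()]).
#' @param concentrations isoforms x samples matrix of concentrations (FPKM
#'   scale); rownames must be transcript ids.
#' @param library_sizes named vector of total mapped reads per sample.
#' @param read_length,min_anchor junction effective-length parameters.
#' @param count_model \code{"poisson"}, \code{"nb"} or \code{"exact"}
#'   (noise-free expected counts, rounded).
#' @param nb_dispersion negative-binomial dispersion (1/size).
#' @param seed optional integer seed.
#' @return list with \code{junctions}, \code{coverage_bins},
#'   \code{library_sizes} and the generating \code{graph}.
#' @export
simulate_reads_to_counts <- function(gene, concentrations, library_sizes,
                                     read_length = 100, min_anchor = 1,
                                     count_model = c("poisson", "nb", "exact"),
                                     nb_dispersion = 0.1, seed = NULL) {
  count_model <- match.arg(count_model)
  if (!is.null(seed)) set.seed(seed)
  graph <- build_graph_from_gtf(gene)
  samples <- names(library_sizes)
  stopifnot(!is.null(samples), ncol(concentrations) == length(samples))
  draw <- function(mu) {
    switch(count_model,
           exact = round(mu),
           poisson = stats::rpois(length(mu), mu),
           nb = stats::rnbinom(length(mu), mu = mu, size = 1 / nb_dispersion))
  }
  # concentration mapped to each edge: sum over isoforms whose path uses it
  edge_conc <- matrix(0, nrow(graph$edges), length(samples))
  for (tx in names(graph$isoform_edges)) {
    idx <- match(graph$isoform_edges[[tx]], graph$edges$edge_id)
    edge_conc[idx, ] <- sweep(edge_conc[idx, , drop = FALSE], 2,
                              concentrations[tx, ], "+")
  }
  eff_jn <- junction_effective_length(read_length, min_anchor)
  is_jn <- graph$edges$kind == "junction" & graph$edges$end > graph$edges$start
  is_ex <- graph$edges$kind == "exonic"

  jn_rows <- which(is_jn)
  mu_jn <- edge_conc[jn_rows, , drop = FALSE] * eff_jn
  mu_jn <- sweep(mu_jn, 2, library_sizes / 1e9, "*")
  junctions <- data.frame(
    chrom = rep(gene$chrom, length(jn_rows)),
    start = graph$edges$start[jn_rows],
    end = graph$edges$end[jn_rows],
    strand = rep(gene$strand, length(jn_rows))
  )
  jc <- matrix(draw(mu_jn), nrow = length(jn_rows))
  colnames(jc) <- samples
  junctions <- cbind(junctions, as.data.frame(jc))

  ex_rows <- which(is_ex)
  width <- graph$edges$end[ex_rows] - graph$edges$start[ex_rows]
  mu_ex <- edge_conc[ex_rows, , drop = FALSE] * width
  mu_ex <- sweep(mu_ex, 2, library_sizes / 1e9, "*")
  coverage_bins <- data.frame(
    chrom = rep(gene$chrom, length(ex_rows)),
    start = graph$edges$start[ex_rows],
    end = graph$edges$end[ex_rows],
    strand = rep(gene$strand, length(ex_rows))
  )
  ec <- matrix(draw(mu_ex), nrow = length(ex_rows))
  colnames(ec) <- samples
  coverage_bins <- cbind(coverage_bins, as.data.frame(ec))

  list(junctions = junctions, coverage_bins = coverage_bins,
       library_sizes = library_sizes, graph = graph)
}

#' Simulate a two-condition splicing cohort at the event level
#'
#' Generates per-event path measurements under the study conditions: two
#' conditions with \code{n_per_condition} replicates each; a fraction
#' \code{prop_differential} of events shifts its true PSI between conditions
#' by at least \code{delta_psi}; affinity fractions u*, v* are drawn uniformly
#' from \code{uv_range}; reference concentrations are log-normal on the FPKM
#' scale. The sequencing platform yields Poisson (or negative-binomial) path
#' counts at the given library size plus FPKM signal matrices; the array
#' platform yields linear-scale signals with platform-specific affinities and
#' multiplicative log-normal noise.
#'
#' @param n_events number of events.
#' @param n_per_condition replicates per condition.
#' @param prop_differential fraction of events with differential splicing.
#' @param delta_psi minimum true PSI shift for differential events.
#' @param library_size total mapped reads per sample.
#' @param noise_cv multiplicative noise CV for array signals.
#' @param uv_range range for the true affinity fractions u*, v*.
#' @param t_ref_meanlog,t_ref_sdlog log-normal parameters of the reference
#'   concentration (FPKM scale).
#' @param nominal_length nominal path effective length in bp (FPKM
#'   denominator).
#' @param count_model,nb_dispersion count noise model.
#' @param seed optional integer seed.
#' @return list of class \code{synthetic_cohort}: \code{truth} (data.frame),
#'   \code{condition}, \code{design}, \code{contrast}, \code{library_sizes},
#'   \code{counts} (list of path1/path2/ref matrices),
#'   \code{signals_rnaseq} and \code{signals_array} (lists of S1/S2/SR
#'   matrices).
#' @export
simulate_cohort <- function(n_events = 500L, n_per_condition = 5L,
                            prop_differential = 0.3, delta_psi = 0.3,
                            library_size = 2e7, noise_cv = 0.1,
                            uv_range = c(0.7, 1.4),
                            t_ref_meanlog = log(50), t_ref_sdlog = 0.7,
                            nominal_length = 99,
                            count_model = c("poisson", "nb"),
                            nb_dispersion = 0.1, seed = NULL) {
  count_model <- match.arg(count_model)
  if (!is.null(seed)) set.seed(seed)
  n <- 2L * n_per_condition
  condition <- factor(rep(c("control", "treated"), each = n_per_condition))
  design <- stats::model.matrix(~condition)
  contrast <- c(0, 1)
  n_diff <- round(prop_differential * n_events)
  differential <- seq_len(n_events) <= n_diff

  base_psi <- ifelse(differential,
                     stats::runif(n_events, 0.1, 0.9 - delta_psi),
                     stats::runif(n_events, 0.1, 0.9))
  shift <- numeric(n_events)
  if (n_diff > 0) {
    idx <- which(differential)
    shift[idx] <- stats::runif(n_diff, delta_psi,
                               pmin(0.9 - base_psi[idx], delta_psi + 0.3))
  }
  psi_control <- base_psi
  psi_treated <- base_psi + shift
  u_true <- stats::runif(n_events, uv_range[1L], uv_range[2L])
  v_true <- stats::runif(n_events, uv_range[1L], uv_range[2L])
  t_ref <- stats::rlnorm(n_events, t_ref_meanlog, t_ref_sdlog)

  psi <- cbind(matrix(psi_control, n_events, n_per_condition),
               matrix(psi_treated, n_events, n_per_condition))
  t1 <- psi * t_ref
  t2 <- (1 - psi) * t_ref
  a1 <- 1 / u_true   # a_ref = 1
  a2 <- 1 / v_true

  # sequencing platform: counts with effective length L_i = nominal * a_i
  depth <- library_size / 1e9
  draw <- function(mu) {
    m <- switch(count_model,
                poisson = stats::rpois(length(mu), mu),
                nb = stats::rnbinom(length(mu), mu = mu,
                                    size = 1 / nb_dispersion))
    matrix(m, nrow = nrow(mu))
  }
  counts <- list(
    path1 = draw(t1 * nominal_length * a1 * depth),
    path2 = draw(t2 * nominal_length * a2 * depth),
    ref = draw((t1 + t2) * nominal_length * depth)
  )
  library_sizes <- stats::setNames(rep(library_size, n),
                                   paste0("s", seq_len(n)))
  to_fpkm <- function(cm) cm * 1e9 / (library_size * nominal_length)
  signals_rnaseq <- lapply(counts, to_fpkm)
  names(signals_rnaseq) <- c("S1", "S2", "SR")

  # array platform: same truth, platform-specific affinities
  uM <- stats::runif(n_events, uv_range[1L], uv_range[2L])
  vM <- stats::runif(n_events, uv_range[1L], uv_range[2L])
  sigma <- .noise_sigma(noise_cv)
  lnoise <- function() {
    matrix(exp(stats::rnorm(n_events * n, 0, sigma)), n_events, n)
  }
  signals_array <- list(
    S1 = (t1 / uM) * lnoise(),
    S2 = (t2 / vM) * lnoise(),
    SR = (t1 + t2) * lnoise()
  )

  event_id <- paste0("ev", seq_len(n_events))
  for (nm in names(counts)) rownames(counts[[nm]]) <- event_id
  for (nm in names(signals_rnaseq)) rownames(signals_rnaseq[[nm]]) <- event_id
  for (nm in names(signals_array)) rownames(signals_array[[nm]]) <- event_id

  structure(list(
    truth = data.frame(event_id = event_id, differential = differential,
                       psi_control = psi_control, psi_treated = psi_treated,
                       delta_psi_true = psi_treated - psi_control,
                       u_true = u_true, v_true = v_true, t_ref = t_ref),
    condition = condition, design = design, contrast = contrast,
    library_sizes = library_sizes, counts = counts,
    signals_rnaseq = signals_rnaseq, signals_array = signals_array,
    nominal_length = nominal_length
  ), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic splicing cohort:", nrow(x$truth), "events,",
      length(x$condition), "samples (",
      sum(x$truth$differential), "differential )\n")
  invisible(x)
}
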