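test_that("voom fallback matches the log2-CPM formula for small matrices", {
  counts <- matrix(c(0, 10), nrow = 2, ncol = 4)
  expect_warning(v <- voom_transform(counts, library_sizes = rep(1e6, 4)),
                 "unit precision weights")
  expect_equal(v$E[1, 1], log2(0.5 / 1000001 * 1e6), tolerance = 1e-12)
  expect_equal(v$E[1, 1], -1.0, tolerance = 1e-3)
  expect_true(all(v$weights == 1))
})

test_that("voom weights decrease with decreasing mean count", {
  set.seed(100)
  n <- 8
  mu <- rep(c(5, 500), each = 100)
  counts <- matrix(rnbinom(200 * n, mu = mu, size = 10), ncol = n)
  design <- cbind(1, rep(0:1, each = n / 2))
  v <- voom_transform(counts, design = design)
  w_low <- mean(v$weights[1:100, ])
  w_high <- mean(v$weights[101:200, ])
  expect_lt(w_low, w_high)
})

test_that("contrast fit equals the group-mean difference with unit weights", {
  set.seed(3)
  n <- 10
  design <- cbind(intercept = 1, treated = rep(0:1, each = 5))
  E <- matrix(rnorm(60 * n), ncol = n)
  fit <- fit_path_contrasts(E, NULL, design, c(0, 1))
  manual <- apply(E, 1, function(y) mean(y[6:10]) - mean(y[1:5]))
  expect_equal(fit$logfc, manual, tolerance = 1e-10)
  # doubling all weights leaves estimates unchanged
  fit2 <- fit_path_contrasts(E, matrix(2, nrow(E), ncol(E)), design, c(0, 1))
  expect_equal(fit2$logfc, fit$logfc, tolerance = 1e-10)
})

test_that("rank-deficient designs are rejected naming the collinear column", {
  design <- cbind(a = rep(1, 6), b = rep(0:1, 3), dup = rep(0:1, 3))
  expect_error(fit_path_contrasts(matrix(rnorm(12), 2), NULL, design,
                                  c(0, 1, 0)),
               "dup")
})

test_that("moderated estimates recover a known simulated effect", {
  set.seed(17)
  n <- 20
  design <- cbind(1, rep(0:1, each = 10))
  beta <- 1
  E <- matrix(rnorm(100 * n, sd = 0.2), ncol = n) +
    matrix(rep(design[, 2] * beta, each = 100), ncol = n)
  fit <- moderate(fit_path_contrasts(E, NULL, design, c(0, 1)))
  se <- sqrt(fit$sigma^2) * fit$stdev_unscaled
  expect_true(all(abs(fit$logfc - beta) < 3 * se + 0.2))
  expect_true(mean(fit$p < 0.001) > 0.95)
})

test_that("moderated p-values are uniform under the null", {
  set.seed(23)
  n <- 10
  design <- cbind(1, rep(0:1, each = 5))
  E <- matrix(rnorm(5000 * n), ncol = n)
  fit <- moderate(fit_path_contrasts(E, NULL, design, c(0, 1)))
  ks <- suppressWarnings(ks.test(fit$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("the event decision rule implements the trichotomy", {
  r <- summarize_event(p1 = c(1e-5, 1e-5, 5e-4, 0.5),
                       p2 = c(1e-4, 1e-4, 5e-2, 0.9),
                       logfc1 = c(1, 1, 1, 1),
                       logfc2 = c(-1, 1, -1, -1))
  expect_equal(r$p_summary, c(1e-4, 1e-4, 5e-2, 0.9))
  # opposite signs + p < 0.001 -> significant
  expect_equal(r$sig_class[1], "significant")
  # same direction is never significant
  expect_false(r$sig_class[2] == "significant")
  # 0.001 < p < 0.2 -> inconclusive
  expect_equal(r$sig_class[3], "inconclusive")
  # p > 0.2 -> non-significant
  expect_equal(r$sig_class[4], "non_significant")
})

test_that("alternative p-value combiners are available and valid", {
  p1 <- runif(50); p2 <- runif(50)
  for (comb in c("fisher", "irwin_hall")) {
    r <- summarize_event(p1, p2, rep(1, 50), rep(-1, 50), combiner = comb)
    expect_true(all(r$p_summary >= 0 & r$p_summary <= 1))
  }
  # irwin-hall closed form at a known point
  r <- summarize_event(0.25, 0.25, 1, -1, combiner = "irwin_hall")
  expect_equal(r$p_summary, 0.5^2 / 2)
})

test_that("pi0 is recovered for pure null and mixture p-values", {
  set.seed(31)
  p_null <- runif(10000)
  expect_lt(abs(estimate_pi0_fdr(p_null)$pi0 - 1), 0.05)
  p_mix <- c(runif(5400), rbeta(4600, 0.1, 10))
  expect_lt(abs(estimate_pi0_fdr(p_mix)$pi0 - 0.54), 0.1)
})

test_that("q-values are monotone in p and FDR is non-decreasing in the cutoff", {
  set.seed(37)
  p <- c(rbeta(300, 0.2, 8), runif(700))
  fdr <- estimate_pi0_fdr(p)
  o <- order(p)
  expect_true(all(diff(fdr$q[o]) >= -1e-12))
  cuts <- c(0.001, 0.01, 0.05, 0.1, 0.2)
  fdrs <- vapply(cuts, function(t) estimate_pi0_fdr(p, t)$fdr_at_threshold,
                 numeric(1))
  # after monotonization via q-values this ordering holds on the q scale
  qcuts <- vapply(cuts, function(t) max(fdr$q[p <= t]), numeric(1))
  expect_true(all(diff(qcuts) >= -1e-12))
  expect_true(all(fdrs >= 0 & fdrs <= 1))
})

test_that("binomial thinning has the right moments and composes", {
  counts <- matrix(1000, 1, 1)
  expect_equal(subsample_counts(counts, 1), counts)
  set.seed(41)
  draws <- replicate(1000, subsample_counts(counts, 0.1)[1, 1])
  expect_lt(abs(mean(draws) - 100), 3 * sqrt(1000 * 0.1 * 0.9) / sqrt(1000))
  # thinning twice by 0.5 ~ once by 0.25 (mean and variance)
  twice <- replicate(2000, subsample_counts(
    subsample_counts(counts, 0.5), 0.5)[1, 1])
  once <- replicate(2000, subsample_counts(counts, 0.25)[1, 1])
  expect_lt(abs(mean(twice) - mean(once)), 4 * sqrt(var(once) / 2000) * 2)
  expect_lt(abs(var(twice) / var(once) - 1), 0.25)
  # library sizes rescale alongside
  out <- subsample_counts(counts, 0.5, library_sizes = c(s = 1e6), seed = 1)
  expect_equal(out$library_sizes, c(s = 5e5))
})

test_that("thinning is deterministic under a fixed seed", {
  counts <- matrix(rpois(100, 50), 10)
  a <- subsample_counts(counts, 0.3, seed = 7)
  b <- subsample_counts(counts, 0.3, seed = 7)
  expect_identical(a, b)
})
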