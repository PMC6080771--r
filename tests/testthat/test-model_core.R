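test_that("loglik_multinomial matches hand sums and the enumeration oracle", {
  # G = 1: every read has span probability 1
  cm1 <- coverage_matrix(0, "c", 100L, k = rep(1L, 4), l = rep(1L, 4))
  expect_identical(loglik_multinomial(cm1, 1), 0)

  # worked example at uniform p: span sums (.2,.4,.6,.4,.6,.2)
  hand <- log(0.2) + log(0.4) + log(0.6) + log(0.4) + log(0.6) + log(0.2)
  expect_equal(loglik_multinomial(fig1_cm(), rep(0.2, 5)), hand,
               tolerance = 1e-12)

  # enumeration oracle on random 3-site instances
  set.seed(31)
  for (rep in 1:10) {
    cm <- random_cm(3L, 4L)
    p <- as.numeric(stats::rexp(3)); p <- p / sum(p)
    oracle <- sum(log(mapply(function(k, l) enum_span_prob(p, k, l),
                             cm$k, cm$l)))
    expect_equal(loglik_multinomial(cm, p), oracle, tolerance = 1e-12)
  }

  # zero-probability span and dimension mismatch
  cm2 <- coverage_matrix(0, "c", c(10L, 50L), k = 1L, l = 1L)
  expect_identical(loglik_multinomial(cm2, c(0, 1)), -Inf)
  expect_error(loglik_multinomial(cm2, c(0.5, 0.3, 0.2)), "length")
})

test_that("one multinomial EM step reproduces the printed update formulas", {
  fit <- em_multinomial(fig1_cm(), max_iter = 1)
  expect_equal(fit$params,
               c(11 / 36, 5 / 36, 7 / 36, 5 / 36, 2 / 9),
               tolerance = 1e-12)
  # single-column matrix converges to p = 1 in one step
  cm1 <- coverage_matrix(0, "c", 100L, k = rep(1L, 3), l = rep(1L, 3))
  fit1 <- em_multinomial(cm1)
  expect_identical(fit1$params, 1)
  expect_true(fit1$converged)
})

test_that("converged multinomial EM maximises the observed likelihood", {
  fit <- em_multinomial(fig1_cm(), tol = 1e-10)
  expect_true(fit$converged)
  expect_equal(sum(fit$params), 1, tolerance = 1e-12)
  set.seed(55)
  mle <- optim_mle(fig1_cm())
  expect_true(max(abs(fit$params - mle)) < 1e-4)
  # one further iteration moves every coordinate less than tol
  again <- em_multinomial(fig1_cm(), init = fit$params, max_iter = 1)
  expect_true(max(abs(again$params - fit$params)) < 1e-8)
})

test_that("EM responsibilities are a proper soft assignment", {
  fit <- em_multinomial(fig1_cm(), tol = 1e-10)
  r <- fit$responsibilities
  expect_true(all(r >= 0 & r <= 1))
  expect_equal(rowSums(r), rep(1, 6), tolerance = 1e-12)
  # structural zeros outside each covered span
  expect_true(all(r[cbind(c(1, 1, 2, 4, 6), c(2, 5, 4, 1, 3))] == 0))
})

test_that("multinomial EM log-likelihood trace is non-decreasing", {
  set.seed(42)
  for (rep in 1:20) {
    cm <- random_cm(sample(2:5, 1), sample(0:8, 1))
    fit <- em_multinomial(cm, tol = 1e-8)
    expect_true(all(diff(fit$loglik_trace) >= -1e-10))
  }
})

test_that("multinomial EM fit does not depend on the starting value", {
  set.seed(7)
  fits <- replicate(10, {
    init <- as.numeric(stats::rexp(5)); init <- init / sum(init)
    em_multinomial(fig1_cm(), init = init, tol = 1e-10)$params
  })
  expect_lt(max(dist(t(fits))), 1e-6)
})

test_that("truncated-Bernoulli E-step matches the printed expressions", {
  # responsibilities at the initial q = 0.2 (no M-step yet)
  fit0 <- em_truncated_bernoulli(fig1_cm(), init = rep(0.2, 5),
                                 max_iter = 0)
  r <- fit0$responsibilities
  expect_equal(r[2, 1], 0.2 / (1 - 0.8^2), tolerance = 1e-12)  # = 5/9
  expect_equal(r[5, 5], 0.2 / (1 - 0.8^3), tolerance = 1e-12)
  expect_equal(r[1, 1], 1)        # singleton span is fully observed
  expect_true(all(r[1, 2:5] == 0))  # uncovered entries always 0
  expect_true(all(r[4, c(1, 2, 5)] == 0))
})

test_that("one truncated-Bernoulli M-step matches the printed update", {
  fit <- em_truncated_bernoulli(fig1_cm(), init = rep(0.2, 5),
                                max_iter = 1)
  t2 <- 1 - 0.8^2; t3 <- 1 - 0.8^3; t5 <- 1 - 0.8^5
  expect_equal(fit$params[5], (0.2 / t3 + 1) * t5 / 6, tolerance = 1e-12)
  expect_equal(fit$params[1], (1 + 0.2 / t2 + 0.2 / t3) * t5 / 6,
               tolerance = 1e-12)
  expect_equal(fit$params[2], (0.2 / t2 + 0.2 / t3) * t5 / 6,
               tolerance = 1e-12)
})

test_that("the degenerate all-zero Bernoulli fixed point is flagged", {
  fit <- em_truncated_bernoulli(fig1_cm(), tol = 1e-10)
  expect_false(fit$converged)
  expect_true(fit$degenerate)
  expect_true(max(fit$params) > 0)  # reported, not silently zeroed
})

test_that("allocate_counts rounds and conserves the read count", {
  mk_fit <- function(p, model = "multinomial")
    structure(list(model = model, params = p, n = NA), class = "em_fit")
  expect_equal(allocate_counts(mk_fit(c(1, 0, 0)), n = 6), c(6L, 0L, 0L))
  # half-even rounding with the residual sent to the lower index on ties
  expect_equal(allocate_counts(mk_fit(c(0.5, 0.5)), n = 5), c(3L, 2L))
  # conservation across random fitted regions
  set.seed(13)
  for (rep in 1:20) {
    cm <- random_cm(sample(2:5, 1), sample(1:10, 1))
    fit <- em_multinomial(cm, tol = 1e-8)
    counts <- allocate_counts(fit)
    expect_true(all(counts >= 0L))
    expect_identical(sum(counts), cm$n)
  }
  # bernoulli bracket: [n q / (1 - prod(1 - q))], no conservation fix
  q <- c(0.3, 0.2)
  fitb <- mk_fit(q, "bernoulli")
  expect_equal(allocate_counts(fitb, n = 10),
               as.integer(round(10 * q / (1 - 0.7 * 0.8))))
})

test_that("raw_counts credits a read to every covered site", {
  expect_equal(raw_counts(fig1_cm()), c(3L, 2L, 3L, 2L, 2L))
  cm <- coverage_matrix(0, "c", c(1L, 40L, 80L), k = 1L, l = 3L)
  expect_equal(raw_counts(cm), c(1L, 1L, 1L))
  set.seed(3)
  for (rep in 1:10) {
    cm <- random_cm(sample(2:6, 1), sample(0:10, 1))
    expect_equal(sum(raw_counts(cm)), sum(cm$l - cm$k + 1L))
  }
})

test_that("allocate_sample assembles per-site tables across regions", {
  idx <- segment_regions(read_cpg_table(toy_path("toy_sites.tsv")), 70)
  reads <- read_bed(toy_path("toy_reads.bed"))
  tab <- allocate_sample(reads, idx)
  expect_equal(nrow(tab), 5L)
  expect_equal(sum(tab$allocated), 6L)
  expect_equal(tab$raw, c(3L, 2L, 3L, 2L, 2L))
  expect_equal(unique(tab$n_region), 6L)
})
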