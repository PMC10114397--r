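test_that("Z-score standardization gives mean-0, sample-SD-1 columns", {
  expect_equal(standardize_columns(cbind(a = c(1, 2, 3), b = c(4, 5, 9)))[, "a"],
               c(-1, 0, 1))
  x <- cbind(a = c(10, 20, 40), b = c(1, 2, 3))
  std <- standardize_columns(x)
  expect_equal(std[, "a"], c(-0.8729, -0.2182, 1.0911), tolerance = 1e-4)
  # idempotence: standardizing a standardized matrix changes nothing
  expect_equal(standardize_columns(std), std, tolerance = 1e-12)
  set.seed(40)
  y <- standardize_columns(random_indicator_matrix(15, 4))
  expect_true(all(abs(colMeans(y)) < 1e-10))
  expect_true(all(abs(apply(y, 2, sd) - 1) < 1e-10))
  x[, "b"] <- 7
  expect_error(standardize_columns(x), class = "vc_degenerate_error")
  expect_error(standardize_columns(x), "b")
})

test_that("variation coefficients support both conventions and are reciprocal", {
  expect_equal(variation_coefficients(-0.38, 0.26, "table"), -1.461538,
               tolerance = 1e-6)
  expect_equal(variation_coefficients(-0.38, 0.26, "eq"), -0.684211,
               tolerance = 1e-6)
  expect_equal(variation_coefficients(2.5, 2.5, "table"), 1)
  expect_equal(variation_coefficients(2.5, 2.5, "eq"), 1)
  set.seed(41)
  m <- runif(6, -3, 3); s <- runif(6, 0.1, 2)
  expect_equal(variation_coefficients(m, s, "table") *
                 variation_coefficients(m, s, "eq"),
               rep(1, 6), tolerance = 1e-12)
  expect_error(variation_coefficients(0, 1, "eq"), class = "vc_degenerate_error")
  expect_error(variation_coefficients(1:3, 1:2), class = "vc_shape_error")
})

test_that("independence coefficients sum conflict over all indicators", {
  expect_equal(unname(independence_coefficients(diag(4))), rep(3, 4))
  ones <- matrix(1, 3, 3)
  expect_equal(unname(independence_coefficients(ones)), rep(0, 3))
  r <- reference_cohort()$correlation
  expect_equal(unname(independence_coefficients(r)),
               c(2.5199, 2.6737, 2.6979, 2.6149), tolerance = 1e-10)
  expect_error(independence_coefficients(matrix(2, 2, 2)),
               class = "vc_domain_error")
})

test_that("information volumes and weights follow the chain algebra", {
  expect_equal(information_volume(c(1, 1), c(2, 2)), c(2, 2))
  expect_equal(information_volume(-1.46, 2.5199, "abs"), 3.679054,
               tolerance = 1e-6)
  expect_equal(information_volume(-1.46, 2.5199, "signed"), -3.679054,
               tolerance = 1e-6)
  expect_equal(information_volume(c(1, -2), c(0, 0)), c(0, 0))
  expect_error(information_volume(1:2, 1:3), class = "vc_shape_error")

  expect_equal(critic_weights(c(1, 1, 1, 1)), rep(0.25, 4))
  expect_equal(critic_weights(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  expect_error(critic_weights(c(0, 0)), class = "vc_degenerate_error")
})

test_that("run_critic matches a naive full-chain oracle to 1e-10", {
  set.seed(42)
  for (i in 1:15) {
    x <- random_indicator_matrix(8, 4)
    for (conv in c("table", "eq")) {
      fit <- run_critic(x, convention = conv)
      expect_equal(unname(fit$weights),
                   naive_critic_weights(x, convention = conv),
                   tolerance = 1e-10)
    }
  }
})

test_that("weights are a normalized non-negative vector for arbitrary inputs", {
  set.seed(43)
  for (i in 1:25) {
    x <- random_indicator_matrix(sample(3:30, 1), sample(2:6, 1))
    w <- run_critic(x)$weights
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w >= 0))
  }
})

test_that("weights are permutation-equivariant and positive-scale invariant", {
  set.seed(44)
  x <- random_indicator_matrix(12, 4)
  w <- run_critic(x)$weights
  perm <- c(3, 1, 4, 2)
  expect_equal(unname(run_critic(x[, perm])$weights), unname(w[perm]),
               tolerance = 1e-12)
  y <- x
  y[, 2] <- 100 * x[, 2]
  expect_equal(run_critic(y)$weights, w, tolerance = 1e-10)
  # shifting a column moves its mean, hence its variation coefficient:
  # NOT invariant by construction
  z <- x
  z[, 2] <- x[, 2] + 5
  expect_gt(max(abs(run_critic(z)$weights - w)), 1e-4)
})

test_that("correlation dampens weights: a duplicated column loses weight", {
  # two uncorrelated columns with equal contrast share weight equally
  x <- cbind(a = c(1, 2, 1, 2), b = c(1, 1, 2, 2))
  expect_equal(unname(run_critic(x)$weights), c(0.5, 0.5))

  # duplicating a column shrinks its conflict term relative to an
  # independent column rescaled to identical mean and SD (equal contrast)
  set.seed(45)
  base <- rnorm(20, mean = 3)
  indep <- scale(rnorm(20))[, 1] * sd(base) + mean(base)
  fit <- run_critic(cbind(a = base, a_copy = base, c = indep))
  expect_lt(fit$weights[["a"]], fit$weights[["c"]])
})

test_that("the published cohort weights are not the summary-statistic chain output", {
  # Full chain evaluated on the published (two-decimal) summary table:
  # variation coefficients from mean/sd, conflict from the published
  # correlation matrix. The result differs substantially from the published
  # weights, which required the raw data.
  ref <- reference_cohort()
  v <- round(variation_coefficients(ref$means, ref$sds, "table"), 2)
  eta <- independence_coefficients(ref$correlation)
  w <- critic_weights(information_volume(v, eta, "abs"))
  expect_equal(unname(w), c(0.4266, 0.2263, 0.1439, 0.2032), tolerance = 1e-3)
  expect_gt(max(abs(w - ref$weights)), 0.1)
})

test_that("run_critic records coherent intermediates", {
  set.seed(46)
  x <- random_indicator_matrix(10, 4)
  fit <- run_critic(x)
  expect_s3_class(fit, "critic_fit")
  expect_equal(dim(fit$standardized), dim(x))
  expect_equal(fit$correlation, correlation_matrix(x), tolerance = 1e-12)
  expect_equal(unname(fit$information),
               abs(fit$summaries$variation_coefficient) *
                 unname(fit$independence), tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$weight, unname(fit$weights))
  expect_equal(nrow(glance(fit)), 1)
  expect_s3_class(autoplot(fit), "ggplot")
})
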