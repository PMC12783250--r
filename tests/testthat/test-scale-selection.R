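# Builds a value table directly: columns "<predictor>_<scale>m".
make_values <- function(cols) as.data.frame(cols, check.names = FALSE)

test_that("univariate scan picks the minimum-AIC scale with smallest-scale tie-break", {
  set.seed(10)
  n <- 400
  x <- rnorm(n)
  y <- rbinom(n, 1, plogis(-1 + 1.2 * x))
  # identical columns at all scales -> tie -> smallest scale chosen
  vals <- make_values(list(a_250m = x, a_1000m = x, a_16000m = x))
  res <- univariate_scale_scan(vals, y)
  expect_equal(res$chosen$scale, 250)
  expect_equal(nrow(res$table), 3)
  expect_true(all(res$table$aic == res$table$aic[1]))

  # informative column beats noise columns of the same predictor
  vals2 <- make_values(list(b_250m = rnorm(n), b_2000m = x, b_8000m = rnorm(n)))
  expect_equal(univariate_scale_scan(vals2, y)$chosen$scale, 2000)

  # pure-noise predictor: AIC close to the intercept-only model at every
  # scale. The upper bound null + 2 is exact (adding a term cannot lower the
  # likelihood); the downside deviance drop is chi-square(1) under the null,
  # so it is bounded by its 99.9% quantile and is small on average.
  vals3 <- make_values(list(c_250m = rnorm(n), c_1000m = rnorm(n), c_4000m = rnorm(n)))
  res3 <- univariate_scale_scan(vals3, y)
  expect_true(all(res3$table$aic <= res3$null_aic + 2 + 1e-8))
  expect_true(all(res3$table$aic >= res3$null_aic + 2 - qchisq(0.999, 1)))
  expect_lt(mean(res3$null_aic + 2 - res3$table$aic), 4)

  # AIC here is -2 logLik + 4 (two parameters)
  fit <- glm(y ~ x, family = binomial())
  res4 <- univariate_scale_scan(make_values(list(d_500m = x)), y)
  expect_equal(res4$chosen$aic, -2 * as.numeric(logLik(fit)) + 4, tolerance = 1e-8)
})

test_that("separated scales are flagged and excluded from the choice", {
  y <- rep(c(0, 1), each = 20)
  sep_col <- c(rnorm(20, -5), rnorm(20, 5))     # perfectly separating
  weak <- rnorm(40) + 0.3 * y
  vals <- make_values(list(e_250m = sep_col, e_2000m = weak))
  expect_warning(res <- univariate_scale_scan(vals, y), "separation")
  expect_true(res$table$separable[res$table$scale == 250])
  expect_equal(res$chosen$scale, 2000)
})

test_that("correlation pruning drops the higher-AIC member, severity-first, iteratively", {
  set.seed(20)
  n <- 500
  a <- rnorm(n)
  y <- rbinom(n, 1, plogis(a))
  # duplicated predictor (r = 1): lower-AIC copy retained
  vals <- make_values(list(a_250m = a, b_250m = a))
  res <- univariate_scale_scan(vals, y)
  cand <- prune_correlated(res, vals)
  expect_equal(nrow(cand$predictors), 1)
  expect_equal(cand$predictors$aic, min(res$chosen$aic))

  # |r| = 0.69 stays below the strict > 0.7 rule
  x1 <- scale(a)[, 1]
  resid <- rnorm(n); resid <- scale(stats::resid(lm(resid ~ x1)))[, 1]
  x2 <- 0.69 * x1 + sqrt(1 - 0.69^2) * resid
  vals2 <- make_values(list(a_250m = x1, c_250m = x2))
  expect_equal(abs(cor(x1, x2)), 0.69, tolerance = 1e-12)
  cand2 <- prune_correlated(univariate_scale_scan(vals2, y), vals2)
  expect_equal(nrow(cand2$predictors), 2)

  # triple with r(A,B)=0.9, r(A,C)=0.8 and AIC A < B < C -> only A retained:
  # B loses the worst pair against A, then C exceeds the threshold against A
  Sigma <- matrix(c(1, 0.9, 0.8, 0.9, 1, 0.58, 0.8, 0.58, 1), 3, 3)
  L <- chol(Sigma)
  Z <- matrix(rnorm(n * 3), n, 3) %*% L
  # strengthen signal A > B > C so univariate AIC orders A < B < C
  yy <- rbinom(n, 1, plogis(1.2 * Z[, 1]))
  vals3 <- make_values(list(A_250m = Z[, 1], B_250m = Z[, 2], C_250m = Z[, 3]))
  res3 <- univariate_scale_scan(vals3, yy)
  expect_equal(res3$chosen$predictor[order(res3$chosen$aic)][1], "A")
  cand3 <- prune_correlated(res3, vals3)
  # trace: drop B (|r|=.9 pair, higher AIC than A); then |r(A,C)|=.8 > .7 -> drop C
  expect_equal(cand3$predictors$predictor, "A")
  expect_equal(cand3$removed$reason, c("correlation", "correlation"))

  # constant column: correlation undefined -> dropped with log
  vals4 <- make_values(list(a_250m = a, k_250m = rep(1, n)))
  expect_message(cand4 <- prune_correlated(univariate_scale_scan(vals4, y), vals4),
                 "constant")
  expect_equal(cand4$predictors$predictor, "a")
})

test_that("VIF filtering removes the worst collinear column until all pass", {
  set.seed(30)
  n <- 1000
  A <- rnorm(n); B <- rnorm(n)
  # near-linear combination: pairwise |r| < 0.7 but VIF ~ 6
  C <- 0.55 * A + 0.55 * B + rnorm(n, sd = 0.35)
  y <- rbinom(n, 1, 0.5)
  vals <- make_values(list(A_250m = A, B_250m = B, C_250m = C))
  cand <- prune_correlated(univariate_scale_scan(vals, y), vals)
  expect_equal(nrow(cand$predictors), 3)  # pairwise screen does not fire
  filt <- vif_filter(cand, vals)
  expect_lt(nrow(filt$predictors), 3)
  expect_true("vif" %in% filt$removed$reason)
  # post-condition: every remaining VIF <= 5
  X <- vals[filt$predictors$column]
  if (ncol(X) >= 2) {
    vifs <- vapply(seq_len(ncol(X)), function(j)
      1 / (1 - summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared), 0)
    expect_true(all(vifs <= 5))
  }

  # orthogonal columns: all VIF = 1, nothing removed
  vals2 <- make_values(list(A_250m = A, B_250m = B))
  cand2 <- prune_correlated(univariate_scale_scan(vals2, y), vals2)
  filt2 <- vif_filter(cand2, vals2)
  expect_equal(nrow(filt2$predictors), 2)

  # single predictor passes vacuously
  vals3 <- make_values(list(A_250m = A))
  cand3 <- prune_correlated(univariate_scale_scan(vals3, y), vals3)
  expect_equal(nrow(vif_filter(cand3, vals3)$predictors), 1)

  # more predictors than rows is an error
  tiny <- vals[1:3, ]
  cand4 <- cand
  expect_error(vif_filter(cand4, tiny), "VIF is not estimable")
})

test_that("screening output satisfies both collinearity thresholds", {
  set.seed(40)
  n <- 600
  base <- matrix(rnorm(n * 3), n, 3)
  cols <- list(
    p1_250m = base[, 1],
    p2_250m = 0.95 * base[, 1] + 0.3 * rnorm(n),   # correlated with p1
    p3_250m = base[, 2],
    p4_250m = base[, 2] + base[, 3] + rnorm(n, sd = 0.05),  # collinear combo
    p5_250m = base[, 3])
  vals <- make_values(cols)
  y <- rbinom(n, 1, plogis(base[, 1] - base[, 2]))
  res <- univariate_scale_scan(vals, y)
  cand <- vif_filter(prune_correlated(res, vals), vals)
  expect_lt(nrow(cand$predictors), 5)          # violations strictly reduce cardinality
  X <- vals[cand$predictors$column]
  C <- abs(cor(X)); diag(C) <- 0
  expect_true(all(C <= 0.7))
  vifs <- vapply(seq_len(ncol(X)), function(j)
    1 / (1 - summary(lm(X[[j]] ~ ., data = X[-j]))$r.squared), 0)
  expect_true(all(vifs <= 5))
  # removals always cite a violating pair or VIF value
  expect_true(all(cand$removed$reason %in% c("correlation", "vif")))
})
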