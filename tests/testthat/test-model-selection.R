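test_that("intercept-only fit matches the closed-form Bernoulli MLE", {
  # 138 presences among 1455 stations
  y <- c(rep(1, 138), rep(0, 1317))
  fit <- fit_logistic(data.frame(row.names = seq_along(y)), y)
  phat <- 138 / 1455
  expect_equal(fit$coefficients$estimate, qlogis(phat), tolerance = 1e-8)
  expect_equal(fit$coefficients$estimate, -2.256, tolerance = 1e-3)
  # closed-form log-likelihood and AICc
  ll <- 1455 * (phat * log(phat) + (1 - phat) * log(1 - phat))
  expect_equal(fit$loglik, ll, tolerance = 1e-6)
  expect_equal(fit$aicc, (-2 * ll + 2) + 2 * 1 * 2 / (1455 - 2), tolerance = 1e-6)
})

test_that("tiny-fixture MLE matches a brute-force likelihood grid search", {
  x <- c(-1.5, -1.0, -0.5, -0.2, 0.3, 0.8, 1.2, 1.9)
  y <- c(0, 0, 1, 0, 1, 0, 1, 1)
  fit <- fit_logistic(data.frame(x = x), y)
  xz <- (x - mean(x)) / sd(x)
  X <- cbind(1, xz)
  # coarse-to-fine grid search over (b0, b1), independent of the fitting path
  best <- c(0, 0); width <- 8
  for (pass in 1:6) {
    b0s <- seq(best[1] - width, best[1] + width, length.out = 41)
    b1s <- seq(best[2] - width, best[2] + width, length.out = 41)
    ll <- outer(b0s, b1s, Vectorize(function(b0, b1)
      bernoulli_loglik(c(b0, b1), X, y)))
    w <- which(ll == max(ll), arr.ind = TRUE)[1, ]
    best <- c(b0s[w[1]], b1s[w[2]])
    width <- width / 8
  }
  expect_equal(fit$coefficients$estimate, best, tolerance = 1e-3)
  # score norm at the reported optimum honours the convergence contract
  pr <- plogis(drop(X %*% fit$coefficients$estimate))
  expect_lt(sqrt(sum(drop(crossprod(X, y - pr))^2)), 1e-8)
})

test_that("fitted model reports Wald inference and the AICc identities", {
  set.seed(50)
  n <- 300
  d <- data.frame(a = rnorm(n), b = rnorm(n))
  y <- rbinom(n, 1, plogis(0.5 * d$a))
  fit <- fit_logistic(d, y)
  co <- fit$coefficients
  expect_equal(co$z_value, co$estimate / co$std_error)
  expect_equal(co$p_value, 2 * pnorm(-abs(co$z_value)))
  expect_equal(fit$k, 3)
  expect_equal(fit$aicc, fit$aic + 2 * 3 * 4 / (n - 4))
  expect_gt(fit$aicc, fit$aic)
  # refitting is deterministic
  expect_identical(fit$coefficients, fit_logistic(d, y)$coefficients)
  # AICc converges to AIC for large n
  set.seed(51)
  big <- data.frame(a = rnorm(1e5))
  fy <- rbinom(1e5, 1, plogis(big$a))
  bf <- fit_logistic(big, fy)
  expect_lt(bf$aicc - bf$aic, 0.01)
  # agreement with glm as an independent route
  ref <- glm(y ~ scale(a) + scale(b), data = d, family = binomial())
  expect_equal(unname(co$estimate), unname(coef(ref)), tolerance = 1e-6)
})

test_that("zero-signal slopes stay within 2 SE of zero at the nominal rate", {
  set.seed(52)
  hits <- vapply(1:100, function(i) {
    d <- data.frame(x = rnorm(200))
    y <- rbinom(200, 1, 0.5)
    fit <- tryCatch(fit_logistic(d, y), error = function(e) NULL)
    if (is.null(fit)) return(NA)
    co <- fit$coefficients[fit$coefficients$term == "x", ]
    abs(co$estimate) < 2 * co$std_error
  }, TRUE)
  expect_gte(mean(hits, na.rm = TRUE), 0.9)  # nominal ~0.95
})

test_that("separation and degenerate designs are rejected with diagnostics", {
  y <- rep(c(0, 1), each = 15)
  d <- data.frame(x = c(rnorm(15, -8), rnorm(15, 8)))
  expect_error(fit_logistic(d, y), "separation")
  expect_error(fit_logistic(data.frame(x = rep(1, 30)), y), "rank-deficient|constant")
  expect_error(fit_logistic(data.frame(x = rnorm(3), z = rnorm(3), w = rnorm(3)),
                            c(0, 1, 0)), "n > k")
})

test_that("all-subsets ranking matches an independent brute-force re-fit", {
  set.seed(60)
  n <- 200
  vals <- data.frame(A_250m = rnorm(n), B_1000m = rnorm(n), C_4000m = rnorm(n))
  y <- rbinom(n, 1, plogis(0.9 * vals$A_250m - 0.7 * vals$B_1000m))
  cand <- vif_filter(prune_correlated(univariate_scale_scan(vals, y), vals), vals)
  expect_equal(nrow(cand$predictors), 3)
  ranking <- all_subsets(cand, vals, y)
  expect_equal(nrow(ranking$table), 8)  # 2^3 subsets including intercept-only
  expect_equal(ranking$table$delta_aicc[1], 0)
  expect_true(all(diff(ranking$table$aicc) >= 0))
  expect_true(all((ranking$table$delta_aicc < 2) == ranking$table$support))

  # oracle: refit every subset independently with glm + AICc arithmetic
  cols <- names(vals)
  oracle <- do.call(rbind, lapply(0:7, function(m) {
    inset <- cols[bitwAnd(m, c(1, 2, 4)) > 0]
    f <- if (length(inset) == 0) y ~ 1 else
      stats::reformulate(sprintf("scale(`%s`)", inset), response = "y")
    g <- glm(f, data = cbind(vals, y = y), family = binomial())
    k <- length(coef(g))
    data.frame(terms = if (length(inset) == 0) "(intercept only)" else
                 paste(sort(inset), collapse = " + "),
               aicc = g$aic + 2 * k * (k + 1) / (n - k - 1))
  }))
  oracle <- oracle[order(oracle$aicc), ]
  expect_equal(ranking$table$terms, oracle$terms)
  expect_equal(ranking$table$aicc, oracle$aicc, tolerance = 1e-8)

  # generative recovery: strong effects {A, B} always land in the top model
  top_terms <- ranking$models[[1]]$coefficients$term
  expect_true(all(c("A_250m", "B_1000m") %in% top_terms))

  # exhaustive-search guard
  cand_wide <- cand
  expect_error(all_subsets(cand_wide, vals, y, max_predictors = 2), "exhaustive")
})

test_that("suitability prediction applies the standardized inverse-logit response", {
  set.seed(70)
  cfg <- landscape_config(48, 48, 250, 1, 1500, seed = 2L)
  pred <- generate_predictor_stack(cfg)
  stack <- build_scaled_stack(pred, scales = c(250, 500))
  st <- make_stations(200,
                      x = runif(200, 100, 11900), y = runif(200, 100, 11900))
  vals <- extract_at_stations(stack, st)
  y <- rbinom(200, 1, plogis(vals$env1_500m))
  ti <- data.frame(column = "env1_500m", predictor = "env1", scale = 500)
  fit <- fit_logistic(vals["env1_500m"], y, term_info = ti)
  suit <- predict_suitability(fit, stack)
  expect_true(all(suit$values >= 0 & suit$values <= 1))
  # monotone in the underlying smoothed layer
  lyr <- stack_values <- focal_smooth(pred[[1]], 500)$values
  ord <- order(as.vector(lyr))
  expect_true(all(diff(as.vector(suit$values)[ord]) * sign(fit$coefficients$estimate[2]) >= 0))
  # a pixel at the training mean maps to plogis(intercept); the reported
  # intercept of a near-balanced fit maps back near 0.5
  mu <- fit$scaling$mean[["env1_500m"]]
  i <- which.min(abs(lyr - mu))
  expect_equal(as.vector(suit$values)[i],
               plogis(fit$coefficients$estimate[1] +
                        fit$coefficients$estimate[2] *
                          (as.vector(lyr)[i] - mu) / fit$scaling$sd[["env1_500m"]]),
               tolerance = 1e-12)
  expect_equal(plogis(-0.0563), 0.4859, tolerance = 1e-4)

  expect_error(predict_suitability(fit, build_scaled_stack(pred, scales = 250)),
               "scale 500|no layer")
})
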