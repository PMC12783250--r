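# Maximum-likelihood logistic modelling, AICc ranking and map prediction.

#' Small-sample corrected AIC
#'
#' `AICc = AIC + 2k(k+1)/(n - k - 1)`; infinite when `n <= k + 1`.
#'
#' @param aic Akaike information criterion value.
#' @param k number of estimated parameters (terms + intercept).
#' @param n number of observations.
#' @return AICc value.
#' @export
aicc <- function(aic, k, n) {
  if (n - k - 1 <= 0) return(Inf)
  aic + 2 * k * (k + 1) / (n - k - 1)
}

#' Fit a logistic regression with z-standardized predictors
#'
#' Maximum-likelihood presence/absence fit via iteratively reweighted least
#' squares, with a final Newton polish so the score (gradient) norm at the
#' reported optimum is below `1e-8`. Predictor columns are standardized to
#' the training mean 0 / SD 1 and the constants are retained on the fit for
#' later raster prediction, making coefficient magnitudes directly
#' comparable. Complete or quasi-complete separation is an error with a
#' diagnostic.
#'
#' @param design data frame of raw (unstandardized) predictor columns; zero
#'   columns give the intercept-only model.
#' @param response binary 0/1 vector.
#' @param term_info optional data frame (`column`, `predictor`, `scale`)
#'   binding columns to predictors and scales for map prediction.
#' @return object of class `hsm_fit`: `$coefficients` (term, estimate,
#'   std_error, z_value, p_value), `$loglik`, `$k`, `$n`, `$aic`, `$aicc`,
#'   `$scaling` (`mean`, `sd` per column), `$terms`.
#' @export
fit_logistic <- function(design, response, term_info = NULL) {
  stopifnot(all(response %in% c(0, 1)))
  design <- as.data.frame(design)
  cc <- if (ncol(design) > 0) stats::complete.cases(design, response) else !is.na(response)
  design <- design[cc, , drop = FALSE]
  y <- response[cc]
  n <- length(y)
  p <- ncol(design)
  if (n <= p + 1) stop("need n > k observations", call. = FALSE)
  mu <- vapply(design, mean, 0)
  sdev <- vapply(design, stats::sd, 0)
  if (any(sdev == 0 | !is.finite(sdev)))
    stop("constant predictor column: design is rank-deficient", call. = FALSE)
  X <- if (p == 0) matrix(1, n, 1, dimnames = list(NULL, "(Intercept)")) else
    cbind(`(Intercept)` = 1, as.matrix(scale(design, center = mu, scale = sdev)))
  if (qr(X)$rank < ncol(X)) stop("rank-deficient design", call. = FALSE)

  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  beta <- fit$coefficients
  # Newton polish to the score-norm convergence contract
  for (it in 1:50) {
    eta <- drop(X %*% beta)
    pr <- stats::plogis(eta)
    g <- drop(crossprod(X, y - pr))
    if (sqrt(sum(g^2)) < 1e-8) break
    W <- pr * (1 - pr)
    H <- crossprod(X * sqrt(W))
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    beta <- beta + step
  }
  eta <- drop(X %*% beta)
  pr <- stats::plogis(eta)
  g <- drop(crossprod(X, y - pr))
  if (max(abs(beta)) > 50 || (sep && max(abs(beta)) > 15))
    stop("complete or quasi-complete separation: estimates diverge (max |beta| = ",
         format(max(abs(beta)), digits = 3), ")", call. = FALSE)
  if (sqrt(sum(g^2)) >= 1e-8)
    stop("logistic fit failed to converge: score norm ",
         format(sqrt(sum(g^2)), digits = 3), call. = FALSE)

  W <- pr * (1 - pr)
  info <- crossprod(X * sqrt(W))
  se <- sqrt(diag(solve(info)))
  z <- beta / se
  pv <- 2 * stats::pnorm(-abs(z))
  ll <- sum(y * log(pr) + (1 - y) * log1p(-pr))
  k <- ncol(X)
  aic_val <- -2 * ll + 2 * k
  structure(list(
    coefficients = data.frame(term = colnames(X), estimate = unname(beta),
                              std_error = unname(se), z_value = unname(z),
                              p_value = unname(pv), stringsAsFactors = FALSE),
    loglik = ll, k = k, n = n, aic = aic_val, aicc = aicc(aic_val, k, n),
    scaling = list(mean = mu, sd = sdev),
    terms = term_info), class = "hsm_fit")
}

#' @export
print.hsm_fit <- function(x, digits = 4, ...) {
  cat(sprintf("<hsm_fit> %d term(s) + intercept, n = %d, logLik = %.3f, AIC = %.3f, AICc = %.3f\n",
              x$k - 1, x$n, x$loglik, x$aic, x$aicc))
  tab <- x$coefficients
  tab$sig <- ifelse(tab$p_value < 0.05, "*", "")
  print(format(tab, digits = digits), row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.hsm_fit <- function(x, ...) x$coefficients

#' Coefficient table in reporting layout
#'
#' The fitted model as a publication-style table: Estimate, Std. error,
#' z value, Pr(>|z|), with `*` marking strict `p < 0.05`.
#'
#' @param fit an `hsm_fit`.
#' @return data frame with an added `significant` column.
#' @export
coefficient_table <- function(fit) {
  stopifnot(inherits(fit, "hsm_fit"))
  tab <- fit$coefficients
  names(tab) <- c("term", "Estimate", "Std. error", "z value", "Pr(>|z|)")
  tab$significant <- ifelse(tab[["Pr(>|z|)"]] < 0.05, "*", "")
  tab
}

subset_term_label <- function(cols) {
  if (length(cols) == 0) "(intercept only)" else paste(sort(cols), collapse = " + ")
}

#' Exhaustive all-subsets logistic regression ranked by AICc
#'
#' Fits every subset of the candidate predictors (including the
#' intercept-only model) with [fit_logistic()] and ranks the `2^p` models by
#' AICc; ties break toward fewer parameters, then lexicographic term labels.
#' Models with `delta_aicc < 2` form the support set. Fits that fail (e.g.
#' separation) are excluded from the ranking with a message.
#'
#' @param candidates a `candidate_set` ([vif_filter()] output) binding
#'   predictors to their chosen scales.
#' @param values value table containing the candidate columns.
#' @param response binary 0/1 vector aligned with `values`.
#' @param max_predictors guard on the exhaustive search (default 20).
#' @return object of class `model_ranking`: `$table` (one row per fitted
#'   subset: terms, k, loglik, aic, aicc, delta_aicc, support) and `$models`
#'   (the `hsm_fit` objects, in ranked order).
#' @export
all_subsets <- function(candidates, values, response, max_predictors = 20) {
  stopifnot(inherits(candidates, "candidate_set"))
  cols <- candidates$predictors$column
  p <- length(cols)
  if (p > max_predictors)
    stop("more than ", max_predictors,
         " candidates: exhaustive search is infeasible; prune further", call. = FALSE)
  n_models <- 2^p
  fits <- vector("list", n_models)
  labels <- character(n_models)
  failed <- logical(n_models)
  for (m in seq_len(n_models) - 1L) {
    inset <- cols[bitwAnd(m, 2^(seq_len(p) - 1)) > 0]
    labels[m + 1] <- subset_term_label(inset)
    fits[[m + 1]] <- tryCatch(
      fit_logistic(values[inset], response,
                   term_info = candidates$predictors[candidates$predictors$column %in% inset, ,
                                                     drop = FALSE]),
      error = function(e) e)
    failed[m + 1] <- inherits(fits[[m + 1]], "error")
  }
  if (any(failed))
    message(sprintf("all_subsets: %d of %d subset fits failed and were excluded",
                    sum(failed), n_models))
  if (all(failed)) stop("every subset fit failed", call. = FALSE)
  keep <- which(!failed)
  tab <- data.frame(
    terms = labels[keep],
    k = vapply(fits[keep], `[[`, 0, "k"),
    loglik = vapply(fits[keep], `[[`, 0, "loglik"),
    aic = vapply(fits[keep], `[[`, 0, "aic"),
    aicc = vapply(fits[keep], `[[`, 0, "aicc"),
    stringsAsFactors = FALSE)
  ord <- order(tab$aicc, tab$k, tab$terms)
  tab <- tab[ord, , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  tab$support <- tab$delta_aicc < 2
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  structure(list(table = tab, models = fits[keep][ord]), class = "model_ranking")
}

#' @export
print.model_ranking <- function(x, n = 10, ...) {
  cat(sprintf("<model_ranking> %d models; %d with substantial support (delta AICc < 2)\n",
              nrow(x$table), sum(x$table$support)))
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}

#' Top-ranked model of a ranking
#' @param ranking a `model_ranking`.
#' @return the best `hsm_fit` (lowest AICc).
#' @export
top_model <- function(ranking) {
  stopifnot(inherits(ranking, "model_ranking"))
  ranking$models[[1]]
}

#' Predict a habitat-suitability raster from a fitted model
#'
#' Applies the fitted logistic model across the landscape: each term's
#' smoothed layer (at the term's chosen scale) is standardized with the
#' training constants stored on the fit, the linear predictor is assembled
#' per pixel and back-transformed through the inverse logit. Nodata
#' propagates.
#'
#' @param model an `hsm_fit` whose `$terms` binds columns to (predictor,
#'   scale).
#' @param stack a `scaled_stack` containing each required layer.
#' @param year optional target year for year-matched layers.
#' @return probability raster named `"suitability"`.
#' @export
predict_suitability <- function(model, stack, year = NA) {
  stopifnot(inherits(model, "hsm_fit"), inherits(stack, "scaled_stack"))
  co <- model$coefficients
  intercept <- co$estimate[co$term == "(Intercept)"]
  terms <- co$term[co$term != "(Intercept)"]
  ref <- stack$entries[[1]]$raster
  eta <- matrix(intercept, nrow(ref$values), ncol(ref$values))
  for (tm in terms) {
    ti <- model$terms[model$terms$column == tm, , drop = FALSE]
    if (nrow(ti) != 1)
      stop("no (predictor, scale) binding for term ", tm, call. = FALSE)
    lyr <- stack_get(stack, ti$predictor, ti$scale, year)
    z <- (lyr$values - model$scaling$mean[[tm]]) / model$scaling$sd[[tm]]
    eta <- eta + co$estimate[co$term == tm] * z
  }
  predictor_raster(stats::plogis(eta), ref$pixel_size, ref$origin, name = "suitability")
}
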