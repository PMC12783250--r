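# Univariate scale optimization and collinearity screening.
#
# Column naming convention throughout: "<predictor>_<scale>m", as produced by
# extract_at_stations().

parse_value_columns <- function(cols) {
  m <- regmatches(cols, regexec("^(.*)_([0-9]+)m$", cols))
  ok <- lengths(m) == 3
  data.frame(column = cols[ok],
             predictor = vapply(m[ok], `[[`, "", 2),
             scale = as.numeric(vapply(m[ok], `[[`, "", 3)),
             stringsAsFactors = FALSE)
}

# Intercept+slope logistic fit used by the scan; flags (quasi-)separation via
# glm's fitted-probability warning instead of failing.
scan_fit <- function(x, y) {
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  list(aic = fit$aic, separable = sep)
}

#' Univariate scale scan: pick each predictor's best smoothing scale
#'
#' For every predictor and every scale, fits the single-variable logistic
#' regression `detected ~ value` and records its AIC (`-2*logLik + 4`; with
#' two parameters throughout, ranking by AIC is ranking by likelihood). The
#' scale minimizing AIC is chosen per predictor; ties break toward the
#' smallest scale, and scales whose fit shows complete separation are flagged
#' and excluded from the minimum with a warning.
#'
#' @param values extracted value table (columns `"<predictor>_<scale>m"`),
#'   typically the training rows.
#' @param response binary 0/1 vector aligned with `values` rows.
#' @param scales optional scale ladder to restrict the scan to.
#' @return object of class `scale_selection_result`: `$table` (predictor,
#'   scale, aic, separable), `$chosen` (one row per predictor with the
#'   winning scale, its AIC and value column), `$null_aic` (intercept-only
#'   AIC for reference).
#' @export
univariate_scale_scan <- function(values, response, scales = NULL) {
  stopifnot(length(unique(response[!is.na(response)])) >= 2)
  info <- parse_value_columns(setdiff(names(values), "station_id"))
  if (!is.null(scales)) info <- info[info$scale %in% scales, , drop = FALSE]
  if (nrow(info) == 0) stop("no '<predictor>_<scale>m' value columns found", call. = FALSE)
  res <- info
  res$aic <- NA_real_; res$separable <- FALSE
  for (i in seq_len(nrow(info))) {
    x <- values[[info$column[i]]]
    cc <- stats::complete.cases(x, response)
    f <- scan_fit(x[cc], response[cc])
    res$aic[i] <- f$aic
    res$separable[i] <- f$separable
  }
  if (any(res$separable))
    warning("complete separation at ", sum(res$separable),
            " (predictor, scale) fit(s); excluded from scale choice", call. = FALSE)
  chosen <- do.call(rbind, lapply(split(res, res$predictor), function(d) {
    d <- d[order(d$scale), , drop = FALSE]
    ok <- !d$separable & is.finite(d$aic)
    if (!any(ok)) ok <- rep(TRUE, nrow(d))  # all separable: fall back, flagged above
    d[ok, , drop = FALSE][which.min(d$aic[ok]), c("predictor", "scale", "aic", "column")]
  }))
  rownames(chosen) <- NULL
  null_fit <- stats::glm(response ~ 1, family = stats::binomial())
  structure(list(table = res, chosen = chosen, null_aic = null_fit$aic),
            class = "scale_selection_result")
}

#' @export
print.scale_selection_result <- function(x, ...) {
  cat(sprintf("<scale_selection_result> %d predictors x %d scales (null AIC %.2f)\n",
              nrow(x$chosen), length(unique(x$table$scale)), x$null_aic))
  print(x$chosen, row.names = FALSE)
  invisible(x)
}

new_candidate_set <- function(predictors, removed) {
  structure(list(predictors = predictors, removed = removed), class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("<candidate_set> %d retained, %d removed\n",
              nrow(x$predictors), nrow(x$removed)))
  print(x$predictors, row.names = FALSE)
  if (nrow(x$removed)) {
    cat("removed:\n"); print(x$removed, row.names = FALSE)
  }
  invisible(x)
}

#' Prune pairwise-correlated predictors
#'
#' Computes Pearson correlations among the chosen-scale value columns and
#' repeatedly resolves the worst-offending pair: while any `|r| > threshold`,
#' the pair with the largest `|r|` loses its higher-AIC member (the weaker
#' univariate predictor). Correlations are recomputed after each drop.
#' Constant columns have undefined correlation and are removed first.
#'
#' @param result a [univariate_scale_scan()] result.
#' @param values the value table the scan used.
#' @param threshold correlation magnitude above which a pair is pruned
#'   (strict inequality; default 0.7).
#' @return a `candidate_set`: retained predictors bound to their scales plus
#'   a removal log.
#' @export
prune_correlated <- function(result, values, threshold = 0.7) {
  stopifnot(inherits(result, "scale_selection_result"))
  cand <- result$chosen
  removed <- data.frame(predictor = character(0), reason = character(0),
                        detail = character(0), stringsAsFactors = FALSE)
  sds <- vapply(cand$column, function(cl) stats::sd(values[[cl]], na.rm = TRUE), 0)
  for (i in which(!is.finite(sds) | sds == 0)) {
    removed <- rbind(removed, data.frame(predictor = cand$predictor[i],
                                         reason = "correlation",
                                         detail = "constant column"))
    message("prune_correlated: dropping constant column ", cand$column[i])
  }
  cand <- cand[is.finite(sds) & sds > 0, , drop = FALSE]
  repeat {
    if (nrow(cand) < 2) break
    C <- stats::cor(values[cand$column], use = "pairwise.complete.obs")
    diag(C) <- 0
    worst <- which(abs(C) == max(abs(C)), arr.ind = TRUE)[1, ]
    if (abs(C[worst[1], worst[2]]) <= threshold) break
    pair <- cand[c(worst[1], worst[2]), ]
    loser <- which.max(pair$aic)
    removed <- rbind(removed, data.frame(
      predictor = pair$predictor[loser], reason = "correlation",
      detail = sprintf("|r|=%.3f with %s (higher univariate AIC %.2f vs %.2f)",
                       abs(C[worst[1], worst[2]]), pair$predictor[3 - loser],
                       pair$aic[loser], pair$aic[3 - loser])))
    cand <- cand[cand$predictor != pair$predictor[loser], , drop = FALSE]
  }
  rownames(cand) <- NULL
  new_candidate_set(cand, removed)
}

#' Remove collinear predictors by variance inflation factor
#'
#' Iteratively computes `VIF_j = 1 / (1 - R^2_j)` from the linear regression
#' of each retained column on the others and removes the largest-VIF column
#' while any exceeds `threshold`. A single remaining predictor passes
#' vacuously.
#'
#' @param candidates a `candidate_set` from [prune_correlated()].
#' @param values the value table.
#' @param threshold VIF above which the worst column is removed (default 5).
#' @return the reduced `candidate_set` with removals appended to the log.
#' @export
vif_filter <- function(candidates, values, threshold = 5) {
  stopifnot(inherits(candidates, "candidate_set"))
  cand <- candidates$predictors
  removed <- candidates$removed
  while (nrow(cand) >= 2) {
    X <- values[cand$column]
    X <- X[stats::complete.cases(X), , drop = FALSE]
    if (nrow(X) <= ncol(X))
      stop("fewer rows than predictors; VIF is not estimable", call. = FALSE)
    vifs <- vapply(seq_len(ncol(X)), function(j) {
      r2 <- summary(stats::lm(X[[j]] ~ ., data = X[-j]))$r.squared
      1 / max(1 - r2, 1e-12)
    }, 0)
    if (max(vifs) <= threshold) break
    w <- which.max(vifs)
    removed <- rbind(removed, data.frame(
      predictor = cand$predictor[w], reason = "vif",
      detail = sprintf("VIF=%.2f", vifs[w])))
    cand <- cand[-w, , drop = FALSE]
  }
  rownames(cand) <- NULL
  new_candidate_set(cand, removed)
}
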