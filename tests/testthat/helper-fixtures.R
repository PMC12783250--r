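# Shared in-code fixtures: everything is generated at test time.

# Minimal station table builder.
make_stations <- function(n, survey = "SV01", detected = integer(n),
                          x = seq_len(n) * 1000, y = rep(0, n),
                          effort = rep(60L, n), year = rep(2015L, n),
                          prefix = survey) {
  station_table(data.frame(
    station_id = sprintf("%s-%03d", prefix, seq_len(n)),
    survey_id = survey, x = x, y = y, year = year,
    effort_days = effort, detected = as.integer(detected),
    stringsAsFactors = FALSE))
}

# Station table with a fixed presence/absence composition per survey.
make_survey_mix <- function(spec) {
  # spec: list(survey_id = c(presences, absences))
  tabs <- lapply(names(spec), function(sv) {
    np <- spec[[sv]][1]; na <- spec[[sv]][2]
    make_stations(np + na, survey = sv,
                  detected = c(rep(1L, np), rep(0L, na)),
                  x = seq_len(np + na) * 1000 + stats::runif(1, 0, 500),
                  y = rep(match(sv, names(spec)) * 1e5, np + na))
  })
  station_table(do.call(rbind, tabs))
}

# Constant-valued raster.
const_raster <- function(value, nr = 16, nc = 16, px = 250, name = "c") {
  predictor_raster(matrix(value, nr, nc), px, name = name)
}

# Empirical autocorrelation of a field at a given lag (in pixels), averaged
# over row and column shifts: the variogram-style oracle used to check the
# random-field generator.
lag_correlation <- function(mat, lag) {
  nr <- nrow(mat); nc <- ncol(mat)
  c_row <- stats::cor(as.vector(mat[1:(nr - lag), ]), as.vector(mat[(1 + lag):nr, ]))
  c_col <- stats::cor(as.vector(mat[, 1:(nc - lag)]), as.vector(mat[, (1 + lag):nc]))
  (c_row + c_col) / 2
}

# Independent brute-force logistic log-likelihood (used by grid-search and
# AICc oracles; no glm anywhere).
bernoulli_loglik <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  sum(y * eta - log1p(exp(eta)))
}
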