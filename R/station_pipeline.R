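#' Camera-station tables
#'
#' Validates and returns the canonical station table: one row per camera
#' station with survey membership, planar coordinates (meters), survey year,
#' operational effort in days and a binary detection flag.
#'
#' @param df data frame with columns `station_id`, `survey_id`, `x`, `y`,
#'   `year`, `effort_days`, `detected`.
#' @return the validated data frame (class unchanged).
#' @export
station_table <- function(df) {
  req <- c("station_id", "survey_id", "x", "y", "year", "effort_days", "detected")
  missing <- setdiff(req, names(df))
  if (length(missing))
    stop("station table lacks column(s): ", paste(missing, collapse = ", "), call. = FALSE)
  if (anyDuplicated(df$station_id))
    stop("station_id values must be unique", call. = FALSE)
  if (!all(df$detected %in% c(0L, 1L)))
    stop("detected must be 0/1", call. = FALSE)
  if (any(df$effort_days < 0))
    stop("effort_days must be non-negative", call. = FALSE)
  df
}

#' Detection prevalence of a station table
#'
#' Fraction of stations with a detection. Low prevalence (< 0.1) is the
#' regime in which presence/absence GLMs perform poorly and the pipeline
#' switches to bootstrap-balanced datasets.
#'
#' @param stations a station table.
#' @return a single number in `[0, 1]`.
#' @export
prevalence <- function(stations) mean(stations$detected)

#' Drop stations with insufficient survey effort
#'
#' Retains stations that operated at least `min_days` days (default 30,
#' inclusive).
#'
#' @param stations a station table.
#' @param min_days minimum operational days, inclusive.
#' @return filtered station table; logs "removed N of M".
#' @export
filter_min_effort <- function(stations, min_days = 30) {
  keep <- stations$effort_days >= min_days
  message(sprintf("filter_min_effort: removed %d of %d stations", sum(!keep), length(keep)))
  stations[keep, , drop = FALSE]
}

#' Remove duplicated stations within a circular buffer
#'
#' Greedy spatial thinning to limit spatial autocorrelation: stations are
#' visited presence-first (then by `station_id`), and a station is dropped
#' when an already-retained station lies strictly within `radius` meters.
#' Processing presences first means thinning never discards a detection in
#' favour of a non-detection — the conservative default for a rare species.
#'
#' @param stations a station table.
#' @param radius buffer radius in meters (default 500).
#' @return thinned station table in the original row order.
#' @export
dedupe_within_buffer <- function(stations, radius = 500) {
  n <- nrow(stations)
  if (n == 0) return(stations)
  ord <- order(-stations$detected, stations$station_id)
  keep <- logical(n)
  kx <- numeric(0); ky <- numeric(0)
  r2 <- radius^2
  for (i in ord) {
    if (length(kx) == 0 || !any((kx - stations$x[i])^2 + (ky - stations$y[i])^2 < r2)) {
      keep[i] <- TRUE
      kx <- c(kx, stations$x[i]); ky <- c(ky, stations$y[i])
    }
  }
  message(sprintf("dedupe_within_buffer: removed %d of %d stations", sum(!keep), n))
  stations[keep, , drop = FALSE]
}

#' Remove surveys that never detected the species
#'
#' Surveys with zero detections are taken as unsuited to detecting the
#' species (wrong design, placement or season) and all their stations are
#' removed, so that retained absences come from surveys demonstrably capable
#' of detection.
#'
#' @param stations a station table.
#' @return filtered station table; errors if no survey has a detection.
#' @export
drop_undetecting_surveys <- function(stations) {
  det <- tapply(stations$detected, stations$survey_id, sum)
  good <- names(det)[det > 0]
  if (length(good) == 0)
    stop("every survey failed to detect the species: no modellable data", call. = FALSE)
  keep <- stations$survey_id %in% good
  message(sprintf("drop_undetecting_surveys: removed %d of %d stations (%d survey(s))",
                  sum(!keep), length(keep), length(det) - length(good)))
  stations[keep, , drop = FALSE]
}

#' Bootstrap-balanced presence/absence datasets
#'
#' Builds `n_replicates` datasets, each containing every presence station
#' plus, per survey, a random draw of absences equal to that survey's
#' presence count — matching absences to presences within survey areas so
#' each replicate has equal class sizes (`2 * total presences` rows).
#' Absences are drawn without replacement when the survey has enough, with
#' replacement otherwise (logged). Replicates use successive draws from one
#' seeded stream, so the whole list is deterministic given `seed`.
#'
#' @param stations a filtered station table in which every survey has at
#'   least one presence (see [drop_undetecting_surveys()]).
#' @param n_replicates number of balanced datasets (default 10).
#' @param seed integer RNG seed.
#' @return list of `balanced_dataset` objects: `replicate_id`, `rows`
#'   (station rows), `seed`.
#' @export
bootstrap_balanced <- function(stations, n_replicates = 10, seed = 1L) {
  surveys <- split(seq_len(nrow(stations)), stations$survey_id)
  for (sv in names(surveys)) {
    idx <- surveys[[sv]]
    npres <- sum(stations$detected[idx] == 1)
    nabs <- sum(stations$detected[idx] == 0)
    if (npres == 0)
      stop("survey ", sv, " has no presences; drop it before balancing", call. = FALSE)
    if (nabs == 0)
      stop("survey ", sv, " has no absences to sample", call. = FALSE)
  }
  with_seed(seed, {
    lapply(seq_len(n_replicates), function(rep_i) {
      take <- integer(0)
      for (sv in names(surveys)) {
        idx <- surveys[[sv]]
        pres <- idx[stations$detected[idx] == 1]
        abs_ <- idx[stations$detected[idx] == 0]
        replace <- length(abs_) < length(pres)
        if (replace)
          message(sprintf("bootstrap_balanced: survey %s has %d absences for %d presences; sampling with replacement",
                          sv, length(abs_), length(pres)))
        take <- c(take, pres,
                  abs_[sample.int(length(abs_), length(pres), replace = replace)])
      }
      structure(list(replicate_id = rep_i,
                     rows = stations[sort(take), , drop = FALSE],
                     seed = as.integer(seed)),
                class = "balanced_dataset")
    })
  })
}

#' @export
print.balanced_dataset <- function(x, ...) {
  cat(sprintf("<balanced_dataset> replicate %d: %d rows (%d presences / %d absences)%s\n",
              x$replicate_id, nrow(x$rows), sum(x$rows$detected == 1),
              sum(x$rows$detected == 0),
              if (is.null(x$rows$split)) "" else " [partitioned]"))
  invisible(x)
}

#' Stratified train/test partition of a balanced dataset
#'
#' Tags each row `train` or `test` with a 4:1 ratio applied separately
#' within presences and absences, so both classes appear in both partitions.
#' Per class, `round(train_frac * n)` rows go to training.
#'
#' @param dataset a `balanced_dataset` from [bootstrap_balanced()].
#' @param train_frac training fraction (default 0.8, i.e. 4:1).
#' @param seed integer RNG seed.
#' @return the dataset with a `split` column added to `rows`.
#' @export
partition_train_test <- function(dataset, train_frac = 0.8, seed = 1L) {
  stopifnot(inherits(dataset, "balanced_dataset"))
  rows <- dataset$rows
  with_seed(seed, {
    split <- rep("test", nrow(rows))
    for (cls in c(0L, 1L)) {
      idx <- which(rows$detected == cls)
      if (length(idx) < 5)
        stop("fewer than 5 rows in class ", cls, "; cannot partition 4:1", call. = FALSE)
      n_train <- round(train_frac * length(idx))
      split[idx[sample.int(length(idx), n_train)]] <- "train"
    }
    dataset$rows$split <- split
    dataset
  })
}
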