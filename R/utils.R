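# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. Keeps every generator a pure function of its
# config + seed without clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = .GlobalEnv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = .GlobalEnv)
    } else if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# Spawn `n` independent sub-seeds from one master seed (all < 2^31).
spawn_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Percentage of a total, rounded for reporting
#'
#' Small reporting helper used when tabulating station counts by category
#' (e.g. landcover classes): `100 * n / total` rounded to `digits`.
#'
#' @param n count (vectorised).
#' @param total denominator.
#' @param digits decimal places to round to.
#' @return numeric vector of percentages.
#' @examples
#' pct_of_total(1080, 1455)        # 74.2
#' pct_of_total(248, 1455, 2)      # 17.04
#' @export
pct_of_total <- function(n, total, digits = 1) {
  stopifnot(total > 0)
  round(100 * n / total, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
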