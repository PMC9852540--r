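# shared internal helpers

#' Round half away from zero
#'
#' Percentages in reports are rounded half-up (0.05 -> 0.1), matching the
#' usual presentation of survey-style percentages, rather than R's default
#' round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Percent declining, presentation-rounded
#'
#' @param n_declining,n_total counts.
#' @param digits decimal places (default 1, as reported).
#' @return percent, rounded half-up; `NA` with a warning when `n_total` is 0.
#' @export
decline_percent <- function(n_declining, n_total, digits = 1) {
  k <- max(length(n_declining), length(n_total))
  num <- rep_len(n_declining, k)
  den <- rep_len(n_total, k)
  out <- rep(NA_real_, k)
  out[den > 0] <- round_half_up(100 * num[den > 0] / den[den > 0], digits)
  if (any(den == 0)) warning("empty group: percent undefined (NA)")
  out
}

# species_id <-> tip label normalisation: supertrees use underscores
normalize_label <- function(x) gsub(" ", "_", trimws(x))

# seeded evaluation that restores the caller's RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
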