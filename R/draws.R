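#' Scrambled Sobol points
#'
#' Generates `n` points of a Sobol low-discrepancy sequence in `dim`
#' dimensions with Matousek linear-matrix scrambling and a random digital
#' shift (32 bits).  Scrambling randomness is drawn from R's RNG, so results
#' are reproducible under [set.seed()] or via `seed`.
#'
#' @param n number of points.
#' @param dim dimension (at most 16).
#' @param seed optional integer seed for the scrambling; when `NULL` the
#'   current RNG state is used.
#' @param scramble set to `FALSE` for the raw (deterministic) sequence,
#'   whose first point is the origin.
#' @return An `n` x `dim` matrix of points in `[0, 1)`.
#' @export
sobol_points <- function(n, dim, seed = NULL, scramble = TRUE) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  nb <- 32L
  Lcols <- matrix(0, nb, dim)
  shift <- numeric(dim)
  if (scramble) {
    for (d in seq_len(dim)) {
      # column j of the GF(2) scrambling matrix: unit diagonal bit plus
      # uniformly random bits strictly below it
      diagbit <- 2^(nb - seq_len(nb))
      below <- floor(runif(nb) * diagbit)
      Lcols[, d] <- diagbit + below
      shift[d] <- floor(runif(1) * 2^32)
    }
  }
  cpp_sobol(as.integer(n), as.integer(dim), Lcols, shift, isTRUE(scramble))
}

#' Standard-normal quasi-random draw set for simulated likelihood
#'
#' Builds the fixed draw set used by the maximum simulated likelihood
#' estimator: one scrambled Sobol sequence of `n_respondents * n_draws`
#' points in `dim` dimensions (the random WTP coefficients plus the money
#' term), transformed to standard normal deviates by the inverse normal CDF.
#' Respondent `n` consumes rows `[(n-1) * n_draws + 1, n * n_draws]`, so each
#' respondent gets a distinct block of the sequence.  The draw set is
#' generated once per estimation run and never resampled between objective
#' evaluations.
#'
#' @param n_respondents number of respondents.
#' @param n_draws draws per respondent (2000 in the headline specification;
#'   tests and quick fits use fewer).
#' @param dim number of random dimensions.
#' @param seed integer scramble seed.
#' @return An object of class `draw_set`: list with the stacked matrix
#'   `draws` (`n_respondents * n_draws` rows) and metadata.
#' @export
make_draws <- function(n_respondents, n_draws, dim, seed = 1L) {
  u <- sobol_points(n_respondents * n_draws, dim, seed = seed)
  # guard the open interval before the normal quantile transform
  eps <- 2^-33
  z <- qnorm(pmin(pmax(u, eps), 1 - eps))
  structure(list(draws = z, n_respondents = as.integer(n_respondents),
                 n_draws = as.integer(n_draws), dim = as.integer(dim),
                 scramble_seed = as.integer(seed)),
            class = "draw_set")
}

#' @export
print.draw_set <- function(x, ...) {
  cat("Scrambled Sobol normal draw set: ", x$n_respondents, " respondents x ",
      x$n_draws, " draws x ", x$dim, " dims (seed ", x$scramble_seed, ")\n",
      sep = "")
  invisible(x)
}
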