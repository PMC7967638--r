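#' Numerically stable log(sum(exp(x)))
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Round half away from zero, the convention used for printed percentages
#' (base round() rounds half to even).
#' @noRd
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Run code with a fixed RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_prob_vector <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    abort(sprintf("%s must be a nonnegative vector summing to 1", what))
  }
  invisible(p)
}
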