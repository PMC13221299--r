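#' Derive a reproducible sub-seed for a named random stream
#'
#' All stochastic operations in the package draw from their own stream,
#' derived from a single user-facing seed and a short label.  Adding a new
#' generator call therefore never perturbs the draws of existing ones.
#'
#' @param seed Integer master seed.
#' @param label Character stream label, e.g. `"cohort"`.
#' @return An integer in `[1, 2^31 - 2]` usable with [set.seed()].
#' @export
derive_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, Mersenne prime used by Lehmer generators
  h <- as.double(seed %% m)
  for (ch in utf8ToInt(label)) {
    h <- (h * 131 + ch) %% m
  }
  h <- (h * 48271) %% m
  as.integer(h %% (m - 1L) + 1)
}

# evaluate polynomial with ascending-power coefficients at x (vectorised)
poly_eval <- function(coefs, x) {
  out <- rep(0, length(x))
  for (i in rev(seq_along(coefs))) {
    out <- out * x + coefs[[i]]
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_prob <- function(p, what) {
  if (!is.numeric(p) || any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop(sprintf("`%s` must be a probability in [0, 1]", what), call. = FALSE)
  }
  invisible(p)
}
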