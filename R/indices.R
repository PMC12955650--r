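#' Conventional equal-variance sensitivity d'
#'
#' Computes `d' = z(hit rate) - z(false-alarm rate)`, the sensitivity index of
#' the equal-variance Gaussian signal detection model, from a single ROC
#' point. `z` is the standard-normal quantile function.
#'
#' d' is computed from one (FA, hit) pair only and therefore inherits that
#' point's response bias: under an unequal-variance observer it overestimates
#' sensitivity at conservative criteria and underestimates it at lenient
#' ones. Use [d_a()] with a fitted model for a bias-robust index.
#'
#' @param hit_rate,fa_rate Hit and false-alarm rates, strictly inside (0, 1).
#'   Vectors are recycled to a common length.
#' @return Numeric vector of d' values.
#' @seealso [criterion_c()], [d_a()], [fit_evsdt_midpoint()]
#' @examples
#' d_prime(0.8413, 0.1587)   # z = +1 and -1, so d' = 2
#' @export
d_prime <- function(hit_rate, fa_rate) {
  check_rates(hit_rate, fa_rate)
  stats::qnorm(hit_rate) - stats::qnorm(fa_rate)
}

#' Unequal-variance sensitivity d_a
#'
#' Computes `d_a = mu * sqrt(2 / (1 + sigma^2))`: the separation between the
#' target-absent distribution (fixed N(0, 1)) and the target-present
#' distribution N(mu, sigma), standardized by the root-mean-square of the two
#' standard deviations. Unlike d', d_a does not depend on where the response
#' criterion happens to sit; when `sigma = 1` it reduces to conventional d'.
#'
#' @param mu Mean of the target-present evidence distribution.
#' @param sigma Standard deviation of the target-present distribution
#'   (target-absent SD is fixed at 1); must be > 0.
#' @return Numeric vector of d_a values.
#' @examples
#' d_a(1.5, 1.5)  # 1.18
#' d_a(2, 1)      # equals mu when sigma = 1
#' @export
d_a <- function(mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be finite and > 0", call. = FALSE)
  }
  mu * sqrt(2 / (1 + sigma^2))
}

#' Response criterion c
#'
#' Computes `c = -(z(hit rate) + z(fa rate)) / 2`, the equal-variance
#' response-bias index. Positive values indicate a conservative criterion
#' ("yes" requires strong evidence), negative values a lenient one.
#'
#' @inheritParams d_prime
#' @return Numeric vector of criterion values.
#' @examples
#' criterion_c(0.8413, 0.1587)  # symmetric rates: c = 0
#' @export
criterion_c <- function(hit_rate, fa_rate) {
  check_rates(hit_rate, fa_rate)
  -(stats::qnorm(hit_rate) + stats::qnorm(fa_rate)) / 2
}

# Rates at exactly 0 or 1 have infinite z; the sanctioned remedy is to pad
# the frequency table (pad_table) before computing rates.
check_rates <- function(hit_rate, fa_rate) {
  r <- c(hit_rate, fa_rate)
  if (any(!is.finite(r)) || any(r <= 0) || any(r >= 1)) {
    stop(
      "hit and false-alarm rates must lie strictly inside (0, 1); ",
      "pad the frequency table (see `pad_table()`) before computing rates",
      call. = FALSE
    )
  }
  invisible(NULL)
}
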