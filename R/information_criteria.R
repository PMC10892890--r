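#' Akaike information criteria
#'
#' `aic()` is the uncorrected criterion -2 log L + 2k. `aicc()` adds the
#' second-order small-sample correction 2k(k+1)/(n - k - 1), appropriate when
#' n/k is small, as with eight islands and up to six parameters. In both, k
#' counts every estimated parameter, including the negative binomial
#' dispersion or beta precision parameter.
#'
#' @param loglik Maximised log-likelihood.
#' @param k Number of estimated parameters.
#' @param n Number of observations (AICc only); must exceed `k + 1`.
#' @return The criterion value.
#' @examples
#' aicc(-50, k = 4, n = 8)  # 108 + 40/3
#' @export
aicc <- function(loglik, k, n) {
  if (!is.numeric(loglik) || !is.numeric(k) || !is.numeric(n) ||
      k < 0 || n <= 0)
    abort_validation("`loglik`, `k`, `n` must be numeric with k >= 0, n > 0")
  if (n <= k + 1)
    abort_domain("AICc correction is undefined unless n > k + 1")
  aic(loglik, k) + 2 * k * (k + 1) / (n - k - 1)
}

#' @rdname aicc
#' @export
aic <- function(loglik, k) {
  -2 * loglik + 2 * k
}
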