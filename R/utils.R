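#' Logit and inverse logit
#'
#' Convenience links used throughout the package. `logit()` maps a
#' probability to log-odds; `inv_logit()` is its inverse.
#'
#' @param p Probabilities in (0, 1).
#' @param x Real values (log-odds).
#' @return Numeric vector.
#' @examples
#' logit(0.37)
#' inv_logit(-0.5322)
#' @export
logit <- function(p) stats::qlogis(p)

#' @rdname logit
#' @export
inv_logit <- function(x) stats::plogis(x)

# numerically stable log(1 + exp(x))
log1pexp <- function(x) {
  out <- x
  small <- x <= 18
  out[small] <- log1p(exp(x[small]))
  big <- x > 18 & x < 33.3
  out[big] <- x[big] + exp(-x[big])
  out
}

# Bernoulli log-likelihood for linear predictor eta
bernoulli_loglik <- function(y, eta) {
  sum(y * eta) - sum(log1pexp(eta))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_ipdnmr <- function(msg, class) {
  rlang::abort(msg, class = c(class, "ipdnmr_error"))
}
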