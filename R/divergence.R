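# Distribution divergences used to compare a perceived (uniform-over-subset)
# consensus distribution with an observed PWM column.

check_prob_pair <- function(a, b) {
  if (length(a) != length(b)) {
    stop("probability vectors must have equal length", call. = FALSE)
  }
  if (any(a < 0) || any(b < 0)) {
    stop("probability vectors must be nonnegative", call. = FALSE)
  }
}

#' Kullback-Leibler divergence
#'
#' \eqn{KLD(A,B) = \sum_j A(j) \ln(A(j)/B(j))}, natural logarithm, with the
#' convention that terms with \eqn{A(j)=0} contribute 0. The information lost
#' when B is used to approximate A.
#'
#' @param a,b Probability vectors of equal length; `b` must be positive
#'   wherever `a` is.
#' @return A nonnegative scalar.
#' @examples
#' kl_divergence(c(1, 0), c(0.5, 0.5)) # log(2)
#' @export
kl_divergence <- function(a, b) {
  check_prob_pair(a, b)
  i <- a > 0
  if (any(b[i] == 0)) {
    stop("KL divergence undefined: a > 0 where b == 0", call. = FALSE)
  }
  sum(a[i] * log(a[i] / b[i]))
}

#' Jensen-Shannon divergence
#'
#' Symmetric, bounded divergence: the mean KL divergence of each argument to
#' their midpoint mixture \eqn{M = (A+B)/2}. With natural logarithms it lies
#' in \eqn{[0, \ln 2]} and is 0 iff the arguments are equal.
#'
#' @inheritParams kl_divergence
#' @return A scalar in `[0, log(2)]`.
#' @examples
#' js_divergence(c(1, 0, 0, 0), c(0, 1, 0, 0)) # log(2): disjoint supports
#' @export
js_divergence <- function(a, b) {
  check_prob_pair(a, b)
  m <- (a + b) / 2
  0.5 * kl_divergence(a, m) + 0.5 * kl_divergence(b, m)
}

#' Mean squared error between probability vectors
#'
#' \eqn{MSE(A,B) = \frac{1}{n}\sum_j (A(j)-B(j))^2}.
#'
#' @inheritParams kl_divergence
#' @return A nonnegative scalar.
#' @export
mean_squared_error <- function(a, b) {
  check_prob_pair(a, b)
  mean((a - b)^2)
}
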