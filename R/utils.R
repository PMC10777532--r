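#' @importFrom stats pnorm qnorm rnorm rbinom runif coef lm glm quantile
#'   binomial plogis qlogis cor sd var setNames predict
#' @importFrom utils head
NULL

# numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) for a >= b; returns -Inf when the difference underflows
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

is_palindromic <- function(ea, oa) {
  (ea == "A" & oa == "T") | (ea == "T" & oa == "A") |
    (ea == "C" & oa == "G") | (ea == "G" & oa == "C")
}

# two-sided normal tail probability for a z statistic, guarded away from 0
z_to_p <- function(z) {
  p <- 2 * pnorm(-abs(z))
  pmax(p, .Machine$double.xmin)
}
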