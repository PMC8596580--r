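#' Borel distribution of optical crosstalk cascade size
#'
#' When a SPAD fires, infrared photons emitted by the avalanche can trigger
#' neighbouring SPADs nearly instantaneously, each of which can trigger
#' further SPADs. The total number of triggers in such a cascade (including
#' the initiating one) follows the Borel distribution
#' \deqn{P(n) = \frac{(\lambda n)^{n-1} e^{-\lambda n}}{n!}, \quad n \ge 1,}
#' where \eqn{\lambda} is the mean number of directly succeeding triggers
#' per trigger. The pmf is evaluated in log space so large \eqn{n} stay
#' finite.
#'
#' @param n Cascade sizes (positive integers).
#' @param lambda Crosstalk parameter, in \[0, 1).
#' @param log Return log probabilities?
#' @return Probabilities (or log probabilities) of the same length as `n`.
#' @examples
#' dborel(1, 0.2)            # exp(-0.2)
#' sum(dborel(1:1000, 0.4))  # 1
#' @export
dborel <- function(n, lambda, log = FALSE) {
  .check_lambda(lambda)
  if (any(n < 1 | n != floor(n))) {
    stop("Borel cascade sizes must be integers >= 1")
  }
  if (lambda == 0) {
    lp <- ifelse(n == 1, 0, -Inf)
  } else {
    lp <- (n - 1) * base::log(lambda * n) - lambda * n - lgamma(n + 1)
  }
  if (log) lp else exp(lp)
}

#' Generalized Poisson distribution of the total trigger count
#'
#' With a Poisson-distributed number of primary (scintillation
#' photon-induced) triggers with mean `mean_primary` and Borel-distributed
#' crosstalk cascades with parameter `lambda`, the total number of triggers
#' follows the generalized Poisson distribution
#' \deqn{P(n) = \frac{\bar n (\bar n + \lambda n)^{n-1}
#'   e^{-\bar n - \lambda n}}{n!}.}
#' Its mean is \eqn{\bar n/(1-\lambda)} and its variance
#' \eqn{\bar n/(1-\lambda)^3}: crosstalk inflates the variance faster than
#' the mean.
#'
#' @param n Total trigger counts (non-negative integers).
#' @param mean_primary Mean number of primary triggers, > 0.
#' @param lambda Crosstalk parameter, in \[0, 1). `lambda >= 1`
#'   (supercritical crosstalk) is a domain error.
#' @param log Return log probabilities?
#' @return Probabilities of the same length as `n`.
#' @examples
#' all.equal(dgpois(0:50, 10, 0), dpois(0:50, 10))
#' @export
dgpois <- function(n, mean_primary, lambda, log = FALSE) {
  .check_lambda(lambda)
  stopifnot(mean_primary > 0)
  if (any(n < 0 | n != floor(n))) {
    stop("counts must be non-negative integers")
  }
  lp <- base::log(mean_primary) +
    (n - 1) * base::log(mean_primary + lambda * n) -
    (mean_primary + lambda * n) - lgamma(n + 1)
  lp[n == 0] <- -mean_primary
  if (log) lp else exp(lp)
}

#' @rdname dgpois
#' @param nn Number of draws.
#' @details `rgpois()` samples by inverse-transform over the tabulated pmf
#'   (the table is truncated where the cdf exceeds 1 - 1e-12).
#' @export
rgpois <- function(nn, mean_primary, lambda) {
  tab <- .gpois_table(mean_primary, lambda)
  findInterval(stats::runif(nn), tab$cdf)
}

#' @rdname dborel
#' @param nn Number of draws.
#' @export
rborel <- function(nn, lambda) {
  .check_lambda(lambda)
  if (lambda == 0) return(rep.int(1L, nn))
  nmax <- 10
  repeat {
    cdf <- cumsum(dborel(seq_len(nmax), lambda))
    if (1 - cdf[nmax] < 1e-12) break
    nmax <- nmax * 2
    if (nmax > 1e7) stop("Borel cdf did not close; lambda too close to 1")
  }
  findInterval(stats::runif(nn), cdf) + 1L
}

# pmf table of the generalized Poisson up to cdf >= 1 - 1e-12
.gpois_table <- function(mean_primary, lambda) {
  m <- mean_primary / (1 - lambda)
  s <- sqrt(mean_primary / (1 - lambda)^3)
  nmax <- ceiling(m + 12 * s + 30)
  p <- dgpois(0:nmax, mean_primary, lambda)
  cdf <- cumsum(p)
  while (1 - cdf[length(cdf)] > 1e-12) {
    extra <- dgpois((nmax + 1):(2 * nmax), mean_primary, lambda)
    cdf <- c(cdf, cdf[length(cdf)] + cumsum(extra))
    p <- c(p, extra)
    nmax <- 2 * nmax
  }
  list(n = seq_along(p) - 1L, pmf = p, cdf = cdf)
}

#' Mean and variance of the total trigger count
#'
#' First two moments of the generalized Poisson trigger statistics for a
#' given mean primary-trigger count and crosstalk parameter.
#'
#' @param mean_primary Mean number of primary triggers
#'   (see [mean_primary_triggers()]).
#' @param lambda Crosstalk parameter.
#' @return A list of class `"trigger_statistics"` with `mean_primary`,
#'   `mean_total`, `var_total` and `lambda`.
#' @examples
#' trigger_statistics(78.07, 0.184)
#' @export
trigger_statistics <- function(mean_primary, lambda) {
  .check_lambda(lambda)
  stopifnot(mean_primary > 0)
  structure(list(
    mean_primary = mean_primary,
    mean_total = mean_primary / (1 - lambda),
    var_total = mean_primary / (1 - lambda)^3,
    lambda = lambda
  ), class = "trigger_statistics")
}

#' @export
print.trigger_statistics <- function(x, ...) {
  cat(sprintf(
    "Trigger statistics: primary %.4g -> total mean %.4g, sd %.4g (lambda = %g)\n",
    x$mean_primary, x$mean_total, sqrt(x$var_total), x$lambda))
  invisible(x)
}

.check_lambda <- function(lambda) {
  if (!is.numeric(lambda) || length(lambda) != 1 || lambda < 0 || lambda >= 1) {
    stop("crosstalk parameter lambda must lie in [0, 1); got ",
         format(lambda), " (lambda >= 1 means supercritical crosstalk)")
  }
  invisible(lambda)
}
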