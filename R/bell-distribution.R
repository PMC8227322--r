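# The one-parameter Bell distribution:
#   P(Z = z) = theta^z exp(-(e^theta - 1)) B_z / z!,   z = 0, 1, 2, ...
# Overdispersed (Var/E = 1 + theta), infinitely divisible, Poisson-like for
# small theta.  All pmf work is done on the log scale through the cached
# log Bell numbers.

.check_theta <- function(theta) {
  if (!is.numeric(theta) || length(theta) != 1 || is.na(theta) || theta <= 0)
    stop("'theta' must be a single positive number", call. = FALSE)
  theta
}

#' The Bell distribution
#'
#' Density (pmf), distribution function, random generation and moments for
#' the Bell distribution with parameter `theta`:
#' \deqn{P(Z=z) = \frac{\theta^z e^{-(e^\theta - 1)} B_z}{z!},}
#' where \eqn{B_z} is the \eqn{z}-th Bell number.  The distribution has mean
#' \eqn{\theta e^\theta} and variance \eqn{\theta(1+\theta)e^\theta}, so the
#' variance-to-mean ratio is \eqn{1+\theta > 1}: always overdispersed, and
#' approaching Poisson\eqn{(\theta e^\theta)} as \eqn{\theta \to 0}.
#'
#' @param x,q vector of non-negative integer quantiles.
#' @param theta positive distribution parameter.
#' @param log,log.p logical; return log probabilities?
#' @param lower.tail logical; if `TRUE` (default), probabilities are
#'   \eqn{P(Z \le q)}.
#' @param n number of random draws.
#' @param method sampling algorithm: `"compound"` (default) draws
#'   \eqn{N \sim} Poisson\eqn{(e^\theta - 1)} and sums \eqn{N} zero-truncated
#'   Poisson\eqn{(\theta)} variables, which is the compound-Poisson
#'   representation of the law; `"inversion"` inverts the cdf.
#' @return `dbell` and `pbell` return numeric vectors; `rbell` an integer
#'   vector; `bell_moments` a list with `mean` and `variance`.
#' @examples
#' dbell(0:5, theta = 1)
#' sum(dbell(0:100, theta = 1.5))   # 1
#' bell_moments(1)                  # mean e, variance 2e
#' set.seed(1); mean(rbell(1e4, 0.5))
#' @name bell
NULL

#' @rdname bell
#' @export
dbell <- function(x, theta, log = FALSE) {
  .check_theta(theta)
  out <- rep(-Inf, length(x))
  bad <- !is.finite(x) | x < 0 | x != floor(x)
  if (any(bad & is.finite(x))) warning("non-integer or negative x; returning 0")
  ok <- !bad
  if (any(ok)) {
    z <- as.integer(x[ok])
    out[ok] <- z * log(theta) - expm1(theta) + log_bell_number(z) - lgamma(z + 1)
  }
  if (log) out else exp(out)
}

#' @rdname bell
#' @export
pbell <- function(q, theta, lower.tail = TRUE, log.p = FALSE) {
  .check_theta(theta)
  cdf <- cumsum(.bell_pmf_table(theta, max(0, floor(max(q[is.finite(q)], 0)))))
  p <- ifelse(q < 0, 0, cdf[pmin(floor(pmax(q, 0)), length(cdf) - 1) + 1])
  p <- pmin(p, 1)
  if (!lower.tail) p <- 1 - p
  if (log.p) log(p) else p
}

# pmf over 0..z_max (at least); extends until the remaining tail mass,
# bounded by a geometric majorant on successive pmf ratios, is < 1e-14.
.bell_pmf_table <- function(theta, z_max) {
  z_hi <- max(as.integer(z_max), 10L)
  repeat {
    pmf <- dbell(0:z_hi, theta)
    last <- pmf[length(pmf)]
    ratio <- theta * exp(log_bell_number(z_hi + 1L) - log_bell_number(z_hi)) /
      (z_hi + 1L)
    if ((ratio < 1 && last * ratio / (1 - ratio) < 1e-14) || z_hi > 100000L)
      return(pmf)
    z_hi <- z_hi + 25L
  }
}

#' @rdname bell
#' @export
rbell <- function(n, theta, method = c("compound", "inversion")) {
  .check_theta(theta)
  if (length(n) != 1 || is.na(n) || n < 1) stop("'n' must be a positive count")
  n <- as.integer(n)
  method <- match.arg(method)
  if (method == "compound") {
    N <- stats::rpois(n, expm1(theta))
    tot <- integer(n)
    m <- sum(N)
    if (m > 0) {
      # zero-truncated Poisson via cdf-slice inversion
      u <- stats::runif(m, stats::ppois(0, theta), 1)
      draws <- stats::qpois(u, theta)
      s <- rowsum(draws, rep.int(seq_len(n), N))
      tot[as.integer(rownames(s))] <- as.integer(s)
    }
    tot
  } else {
    mv <- bell_moments(theta)
    z_max <- ceiling(mv$mean + 12 * sqrt(mv$variance)) + 30
    cdf <- cumsum(.bell_pmf_table(theta, z_max))
    findInterval(stats::runif(n), cdf)
  }
}

#' @rdname bell
#' @export
bell_moments <- function(theta) {
  .check_theta(theta)
  list(mean = theta * exp(theta), variance = theta * (1 + theta) * exp(theta))
}

# first three cumulants; kappa3 feeds the third-moment recursion of the process
.bell_cumulants <- function(theta) {
  e <- exp(theta)
  c(k1 = theta * e, k2 = theta * (1 + theta) * e,
    k3 = theta * (1 + 3 * theta + theta^2) * e)
}

#' Probability generating function of the Bell distribution
#'
#' \eqn{G(s) = E s^Z = \exp(e^{s\theta} - e^\theta)} for \eqn{|s| \le 1}.
#'
#' @param s evaluation points with \eqn{|s| \le 1}.
#' @inheritParams bell
#' @return numeric vector \eqn{G(s)}.
#' @export
bell_pgf <- function(s, theta) {
  .check_theta(theta)
  if (any(abs(s) > 1)) stop("'s' must satisfy |s| <= 1", call. = FALSE)
  exp(exp(s * theta) - exp(theta))
}

#' Invert the Bell mean
#'
#' Solves \eqn{\theta e^\theta = m} for \eqn{\theta > 0} via the principal
#' branch of the Lambert W function with one Newton polish step, so the
#' round-trip error \eqn{|\theta e^\theta - m|} stays below
#' \eqn{10^{-10}\max(1, m)}.  This is the map from a fitted innovation mean
#' to the Bell parameter used by the moment-based estimators.
#'
#' @param m positive mean value(s).
#' @return numeric vector of \eqn{\theta} values.
#' @examples
#' theta_from_mean(exp(1))   # 1
#' @export
theta_from_mean <- function(m) {
  if (!is.numeric(m) || any(is.na(m)) || any(m <= 0))
    stop("'m' must be positive", call. = FALSE)
  th <- vapply(m, function(mi) pracma::lambertWp(mi), numeric(1))
  th - (th * exp(th) - m) / ((1 + th) * exp(th))   # Newton polish
}
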