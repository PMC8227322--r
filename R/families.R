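# Pluggable innovation families for INAR(1) conditional maximum likelihood.
# A family supplies its log-pmf, moments, sampler, moment-based starting
# values, and an unconstrained reparameterisation for the optimiser.  The
# CML engine below is shared by fit_blinar(method = "cml"), the comparison
# table, and the overdispersion bootstrap.

#' Innovation family constructor
#'
#' Bundles everything the conditional-likelihood machinery needs to know
#' about an innovation distribution \eqn{\epsilon_t}.  Three families ship
#' with the package: [bell_family()], [poisson_family()] and
#' [geometric_family()]; user-defined families plug into [fit_inar()] and
#' [compare_models()] through this constructor.
#'
#' @param name short model label (e.g. `"BL-INAR"`).
#' @param par_names character vector naming the innovation parameters.
#' @param logpmf function `(k, par)` returning the log pmf on `k = 0, 1, ...`.
#' @param mean,variance functions `(par)` giving innovation moments.
#' @param sample function `(n, par)` drawing `n` innovations.
#' @param init function `(mu_eps, var_eps)` mapping method-of-moments
#'   innovation mean/variance to a starting parameter vector.
#' @param to_unconstrained,from_unconstrained transform between the natural
#'   parameter space and an unconstrained optimisation scale.
#' @return object of class `inar_family`.
#' @export
inar_family <- function(name, par_names, logpmf, mean, variance, sample,
                        init, to_unconstrained, from_unconstrained) {
  structure(list(name = name, n_params = length(par_names),
                 par_names = par_names, logpmf = logpmf, mean = mean,
                 variance = variance, sample = sample, init = init,
                 to_unconstrained = to_unconstrained,
                 from_unconstrained = from_unconstrained),
            class = "inar_family")
}

#' @export
print.inar_family <- function(x, ...) {
  cat("INAR(1) innovation family:", x$name,
      "(", paste(x$par_names, collapse = ", "), ")\n")
  invisible(x)
}

#' Built-in innovation families
#'
#' * `bell_family()`: Bell\eqn{(\theta)} innovations — the BL-INAR(1) model;
#'   overdispersed, variance/mean \eqn{= 1+\theta}.
#' * `poisson_family()`: Poisson\eqn{(\lambda)} innovations — the classical
#'   equidispersed model.
#' * `geometric_family()`: geometric innovations with success probability
#'   \eqn{\pi} on \eqn{\{0,1,2,\dots\}}, pmf \eqn{\pi(1-\pi)^k}; mean
#'   \eqn{(1-\pi)/\pi}.
#'
#' @return an [inar_family()] object.
#' @name builtin_families
NULL

#' @rdname builtin_families
#' @export
bell_family <- function() {
  inar_family(
    name = "BL-INAR", par_names = "theta",
    logpmf = function(k, par) dbell(k, par[1], log = TRUE),
    mean = function(par) par[1] * exp(par[1]),
    variance = function(par) par[1] * (1 + par[1]) * exp(par[1]),
    sample = function(n, par) rbell(n, par[1]),
    init = function(mu_eps, var_eps) theta_from_mean(max(mu_eps, 1e-3)),
    to_unconstrained = function(par) log(par),
    from_unconstrained = function(v) exp(v))
}

#' @rdname builtin_families
#' @export
poisson_family <- function() {
  inar_family(
    name = "P-INAR", par_names = "lambda",
    logpmf = function(k, par) stats::dpois(k, par[1], log = TRUE),
    mean = function(par) par[1],
    variance = function(par) par[1],
    sample = function(n, par) stats::rpois(n, par[1]),
    init = function(mu_eps, var_eps) max(mu_eps, 1e-3),
    to_unconstrained = function(par) log(par),
    from_unconstrained = function(v) exp(v))
}

#' @rdname builtin_families
#' @export
geometric_family <- function() {
  inar_family(
    name = "G-INAR", par_names = "pi",
    logpmf = function(k, par) stats::dgeom(k, par[1], log = TRUE),
    mean = function(par) (1 - par[1]) / par[1],
    variance = function(par) (1 - par[1]) / par[1]^2,
    sample = function(n, par) stats::rgeom(n, par[1]),
    init = function(mu_eps, var_eps) min(max(1 / (1 + mu_eps), 1e-3), 1 - 1e-3),
    to_unconstrained = function(par) stats::qlogis(par),
    from_unconstrained = function(v) stats::plogis(v))
}

# ---- conditional log-likelihood engine --------------------------------------
# For each transition (x_t -> x_{t+1}) the likelihood term is
#   sum_{m=0}^{min(x_t, x_{t+1})} C(x_t, m) a^m (1-a)^{x_t - m} p_eps(x_{t+1} - m).
# All transitions are laid out as (T-1) x (M+1) matrices over the thinning
# count m, with parameter-free parts precomputed once per series, so one
# likelihood evaluation is a handful of vectorised matrix operations plus a
# row-wise log-sum-exp.

.cml_structure <- function(x) {
  x <- .check_counts(x, min_len = 2)
  xt <- x[-length(x)]
  xt1 <- x[-1]
  M <- max(pmin(xt, xt1))
  m <- matrix(0:M, nrow = length(xt), ncol = M + 1, byrow = TRUE)
  valid <- m <= pmin(xt, xt1)
  k <- xt1 - m                      # innovation count; >= 0 wherever valid
  k[!valid] <- 0L
  lch <- lchoose(xt, m)
  lch[!valid] <- -Inf
  list(xt = xt, xt1 = xt1, m = m, k = k, lch = lch, valid = valid,
       n_trans = length(xt), k_max = max(xt1))
}

.cml_loglik <- function(st, alpha, log_pmf_eps) {
  # log_pmf_eps: vector over 0:k_max
  z <- st$lch + st$m * log(alpha) + (st$xt - st$m) * log1p(-alpha) +
    matrix(log_pmf_eps[st$k + 1L], nrow = st$n_trans)
  mx <- z[cbind(seq_len(nrow(z)), max.col(z, ties.method = "first"))]
  sum(mx + log(rowSums(exp(z - mx))))
}

#' Conditional log-likelihood of a BL-INAR(1) model
#'
#' \eqn{L(\alpha, \theta) = \sum_{t=1}^{T-1} \ln P(X_{t+1} = x_{t+1} \mid
#' X_t = x_t)}: the likelihood conditional on the first observation, built
#' from the one-step transition probabilities.
#'
#' @inheritParams blinar_joint_loglik
#' @return a single number.
#' @export
conditional_loglik <- function(x, alpha, theta) {
  .check_alpha(alpha); .check_theta(theta)
  st <- .cml_structure(x)
  lp <- dbell(0:st$k_max, theta, log = TRUE)
  .cml_loglik(st, alpha, lp)
}

#' Conditional maximum likelihood for a general innovation family
#'
#' Maximises the conditional log-likelihood of an INAR(1) model with
#' innovations from `family` over \eqn{(\alpha,} family parameters\eqn{)}
#' using BFGS with numerical derivatives on an unconstrained scale
#' (\eqn{logit\,\alpha} and the family's own transform).  Starting values
#' come from the Yule–Walker moment fit (clipped into the interior) unless
#' `init` is supplied.
#'
#' @param x count series, length at least 3.
#' @param family an [inar_family()].
#' @param init optional list with `alpha` and `par` starting values.
#' @param se logical; compute the observed-information covariance from a
#'   numerical Hessian?
#' @return object of class `blinar_fit`.
#' @examples
#' set.seed(7)
#' x <- rblinar(300, 0.5, 1)
#' fit_inar(x, bell_family())
#' @export
fit_inar <- function(x, family, init = NULL, se = FALSE) {
  stopifnot(inherits(family, "inar_family"))
  x <- .check_counts(x, min_len = 3)
  st <- .cml_structure(x)

  if (is.null(init)) {
    yw <- fit_blinar(x, method = "yw")
    a0 <- min(max(yw$alpha_hat, 0.001), 0.999)
    mu_eps0 <- max(mean(x) * (1 - a0), 1e-3)
    var_eps0 <- max(stats::var(x) * (1 - a0^2) - a0 * (1 - a0) * mean(x), 1e-3)
    p0 <- family$init(mu_eps0, var_eps0)
  } else {
    a0 <- min(max(init$alpha, 0.001), 0.999)
    p0 <- init$par
  }
  v0 <- c(stats::qlogis(a0), family$to_unconstrained(p0))

  negll <- function(v) {
    a <- stats::plogis(v[1])
    par <- family$from_unconstrained(v[-1])
    if (any(!is.finite(par))) return(1e10)       # line-search excursions
    a <- min(max(a, 1e-8), 1 - 1e-8)
    lp <- tryCatch(family$logpmf(0:st$k_max, par), error = function(e) NULL)
    if (is.null(lp)) return(1e10)
    ll <- .cml_loglik(st, a, lp)
    if (!is.finite(ll)) 1e10 else -ll
  }
  opt <- stats::optim(v0, negll, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-10))
  alpha_hat <- stats::plogis(opt$par[1])
  par_hat <- family$from_unconstrained(opt$par[-1])
  names(par_hat) <- family$par_names
  mu_eps <- family$mean(par_hat)

  fit <- structure(list(
    method = "CML", family = family$name,
    alpha_hat = alpha_hat, par = par_hat,
    theta_hat = if (family$name == "BL-INAR") unname(par_hat[1]) else NA_real_,
    mu_hat = mu_eps / (1 - alpha_hat),
    loglik = -opt$value, converged = opt$convergence == 0,
    n_used = st$n_trans, flags = character(0)), class = "blinar_fit")

  if (se) {
    H <- stats::optimHess(opt$par, negll)
    V <- tryCatch(solve(H), error = function(e) NULL)
    if (!is.null(V)) {
      # delta back to the natural scale (transforms are elementwise)
      jd <- vapply(seq_along(opt$par[-1]), function(i) {
        h <- 1e-6; vp <- vm <- opt$par[-1]
        vp[i] <- vp[i] + h; vm[i] <- vm[i] - h
        (family$from_unconstrained(vp)[i] - family$from_unconstrained(vm)[i]) /
          (2 * h)
      }, numeric(1))
      J <- diag(c(alpha_hat * (1 - alpha_hat), jd))
      fit$cov <- J %*% V %*% t(J)
      dimnames(fit$cov) <- list(c("alpha", family$par_names),
                                c("alpha", family$par_names))
      fit$se <- sqrt(pmax(diag(fit$cov), 0))
    } else fit$flags <- c(fit$flags, "singular_hessian")
  }
  fit
}

#' @export
print.blinar_fit <- function(x, ...) {
  cat(sprintf("INAR(1) fit [%s, %s]\n", x$family %||% "BL-INAR", x$method))
  cat(sprintf("  alpha = %.6g", x$alpha_hat))
  if (!is.null(x$par)) {
    for (nm in names(x$par)) cat(sprintf("  %s = %.6g", nm, x$par[[nm]]))
  } else if (!is.na(x$theta_hat)) cat(sprintf("  theta = %.6g", x$theta_hat))
  cat("\n")
  if (!is.null(x$loglik) && !is.na(x$loglik))
    cat(sprintf("  conditional loglik = %.4f on %d transitions\n",
                x$loglik, x$n_used))
  if (!is.null(x$se))
    cat("  se:", sprintf("%.4g", x$se), "\n")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
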