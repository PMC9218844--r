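#' Distribution specification
#'
#' A light container for the sampling distribution attached to a model
#' parameter: one of beta, gamma (shape/scale), lognormal (meanlog/sdlog),
#' normal, Dirichlet, uniform, Poisson, or a point mass. Optional truncation
#' bounds are honoured by [dist_sample()] and [dist_quantile()] via
#' inverse-CDF restriction.
#'
#' @param family distribution family name.
#' @param params named numeric parameters: beta `(shape1, shape2)`; gamma
#'   `(shape, scale)`; lognormal `(meanlog, sdlog)`; normal `(mean, sd)`;
#'   dirichlet `alpha` vector; uniform `(min, max)`; poisson `lambda`;
#'   point `value`.
#' @param truncation optional numeric `c(lower, upper)`.
#' @return an object of class `dist_spec`.
#' @export
dist_spec <- function(family = c("beta", "gamma", "lognormal", "normal",
                                 "dirichlet", "uniform", "poisson", "point"),
                      params, truncation = NULL) {
  family <- match.arg(family)
  params <- unlist(params)
  if (!is.numeric(params) || any(!is.finite(params)))
    stop("distribution parameters must be finite numerics", call. = FALSE)
  switch(family,
    beta = {
      stopifnot(length(params) == 2)
      if (any(params <= 0)) stop("beta shapes must be > 0", call. = FALSE)
      names(params) <- c("shape1", "shape2")
    },
    gamma = {
      stopifnot(length(params) == 2)
      if (any(params <= 0)) stop("gamma shape/scale must be > 0", call. = FALSE)
      names(params) <- c("shape", "scale")
    },
    lognormal = {
      stopifnot(length(params) == 2)
      if (params[2] < 0) stop("lognormal sdlog must be >= 0", call. = FALSE)
      names(params) <- c("meanlog", "sdlog")
    },
    normal = {
      stopifnot(length(params) == 2)
      if (params[2] < 0) stop("normal sd must be >= 0", call. = FALSE)
      names(params) <- c("mean", "sd")
    },
    dirichlet = {
      if (length(params) < 2 || any(params <= 0))
        stop("dirichlet needs >= 2 positive concentrations", call. = FALSE)
      names(params) <- paste0("alpha", seq_along(params))
    },
    uniform = {
      stopifnot(length(params) == 2)
      if (params[1] > params[2]) stop("uniform min > max", call. = FALSE)
      names(params) <- c("min", "max")
    },
    poisson = {
      stopifnot(length(params) == 1)
      if (params <= 0) stop("poisson lambda must be > 0", call. = FALSE)
      names(params) <- "lambda"
    },
    point = {
      stopifnot(length(params) == 1)
      names(params) <- "value"
    }
  )
  if (!is.null(truncation)) {
    stopifnot(is.numeric(truncation), length(truncation) == 2,
              truncation[1] <= truncation[2])
    truncation <- as.numeric(truncation)
  }
  structure(list(family = family, params = params, truncation = truncation),
            class = "dist_spec")
}

#' @export
print.dist_spec <- function(x, ...) {
  p <- paste(names(x$params), signif(x$params, 5), sep = "=", collapse = ", ")
  tr <- if (is.null(x$truncation)) "" else
    sprintf(" truncated to [%g, %g]", x$truncation[1], x$truncation[2])
  cat(sprintf("<dist_spec %s(%s)%s>\n", x$family, p, tr))
  invisible(x)
}

#' Analytic mean of a distribution specification
#'
#' Truncation is ignored (the registry uses truncation only for the age
#' distribution, whose truncated mean is handled by the cohort module).
#'
#' @param spec a [dist_spec()].
#' @return numeric mean (vector for dirichlet).
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    beta = unname(p[1] / (p[1] + p[2])),
    gamma = unname(p[1] * p[2]),
    lognormal = unname(exp(p[1] + p[2]^2 / 2)),
    normal = unname(p[1]),
    dirichlet = unname(p / sum(p)),
    uniform = unname((p[1] + p[2]) / 2),
    poisson = unname(p[1]),
    point = unname(p[1])
  )
}

# CDF / quantile pairs used for truncation and common-random-number sampling.
dist_cdf <- function(spec, q) {
  p <- spec$params
  switch(spec$family,
    beta = stats::pbeta(q, p[1], p[2]),
    gamma = stats::pgamma(q, shape = p[1], scale = p[2]),
    lognormal = if (p[2] == 0) as.numeric(q >= exp(p[1]))
                else stats::plnorm(q, p[1], p[2]),
    normal = if (p[2] == 0) as.numeric(q >= p[1]) else stats::pnorm(q, p[1], p[2]),
    uniform = stats::punif(q, p[1], p[2]),
    poisson = stats::ppois(q, p[1]),
    point = as.numeric(q >= p[1]),
    stop("no scalar CDF for family ", spec$family, call. = FALSE)
  )
}

#' Quantile function of a distribution specification
#'
#' Honours truncation bounds by mapping `u` into the retained probability
#' mass. This is the primitive the simulation engine uses to convert shared
#' uniform draws into outcome draws (common random numbers across strategies).
#'
#' @param spec a [dist_spec()].
#' @param u probabilities in \[0, 1\].
#' @return quantiles, same length as `u`.
#' @export
dist_quantile <- function(spec, u) {
  stopifnot(inherits(spec, "dist_spec"), all(u >= 0 & u <= 1))
  p <- spec$params
  if (!is.null(spec$truncation)) {
    lo <- dist_cdf(spec, spec$truncation[1])
    hi <- dist_cdf(spec, spec$truncation[2])
    # for discrete families include the lower bound's own mass
    if (spec$family == "poisson")
      lo <- if (spec$truncation[1] <= 0) 0 else
        stats::ppois(spec$truncation[1] - 1, p[1])
    u <- lo + u * (hi - lo)
  }
  out <- switch(spec$family,
    beta = stats::qbeta(u, p[1], p[2]),
    gamma = stats::qgamma(u, shape = p[1], scale = p[2]),
    lognormal = if (p[2] == 0) rep(exp(p[1]), length(u))
                else stats::qlnorm(u, p[1], p[2]),
    normal = if (p[2] == 0) rep(p[1], length(u)) else stats::qnorm(u, p[1], p[2]),
    uniform = stats::qunif(u, p[1], p[2]),
    poisson = stats::qpois(u, p[1]),
    point = rep(unname(p[1]), length(u)),
    stop("no scalar quantile for family ", spec$family, call. = FALSE)
  )
  if (!is.null(spec$truncation))
    out <- pmin(pmax(out, spec$truncation[1]), spec$truncation[2])
  unname(out)
}

#' Sample from a distribution specification
#'
#' Uses the current RNG state. Dirichlet draws are returned as an `n` x `k`
#' matrix whose rows sum to 1.
#'
#' @param spec a [dist_spec()].
#' @param n number of draws.
#' @return numeric vector of length `n` (matrix for dirichlet).
#' @export
dist_sample <- function(spec, n = 1) {
  stopifnot(inherits(spec, "dist_spec"), n >= 0)
  if (n == 0) return(numeric(0))
  if (spec$family == "dirichlet") {
    a <- spec$params
    g <- matrix(stats::rgamma(n * length(a), shape = rep(a, each = n)), nrow = n)
    return(g / rowSums(g))
  }
  if (spec$family == "point") return(rep(unname(spec$params[1]), n))
  dist_quantile(spec, stats::runif(n))
}

# Return a copy of a gamma/poisson/normal/lognormal/point spec rescaled so
# its analytic mean equals `new_mean` (shape preserved for gamma; sdlog
# preserved for lognormal). Used when a PSA draw perturbs a utilization mean.
dist_rescale_mean <- function(spec, new_mean) {
  stopifnot(inherits(spec, "dist_spec"))
  p <- spec$params
  switch(spec$family,
    gamma = dist_spec("gamma", c(p[1], new_mean / p[1]), spec$truncation),
    poisson = dist_spec("poisson", new_mean, spec$truncation),
    normal = dist_spec("normal", c(new_mean, p[2]), spec$truncation),
    lognormal = dist_spec("lognormal",
                          c(p[1] + log(new_mean / dist_mean(spec)), p[2]),
                          spec$truncation),
    point = dist_spec("point", new_mean),
    stop("cannot rescale family ", spec$family, call. = FALSE)
  )
}

# Sampling distribution of the mean of n_eff iid gamma observations:
# Gamma(shape * n_eff, scale / n_eff). One draw, current RNG state.
sample_gamma_mean <- function(spec, n_eff) {
  stopifnot(inherits(spec, "dist_spec"), spec$family == "gamma", n_eff > 0)
  p <- spec$params
  stats::rgamma(1, shape = p[1] * n_eff, scale = p[2] / n_eff)
}

#' Fit a gamma distribution to a printed mean and 95% interval
#'
#' Summary utilization and cost quantities are published as a mean with a
#' 95% interval and a gamma family. The fit constrains the analytic mean to
#' equal the printed mean exactly (scale = mean/shape) and chooses the shape
#' by least squares on the 2.5th and 97.5th percentiles against the printed
#' interval. When the lower bound is 0 the lower constraint is dropped and
#' the shape is the one whose 97.5th percentile equals the printed upper
#' bound exactly (the larger of the two roots, avoiding the degenerate
#' near-zero-shape solution); if the bound exceeds what any mean-preserving
#' gamma can reach, the closest attainable shape is used.
#'
#' @param mean printed mean (> 0 unless the interval is degenerate).
#' @param ci_low printed 2.5th percentile (>= 0).
#' @param ci_high printed 97.5th percentile.
#' @return a gamma [dist_spec()], or a point spec for a zero-width interval.
#' @export
fit_gamma_from_summary <- function(mean, ci_low, ci_high) {
  assert_scalar_num(mean, "mean", lower = 0)
  assert_scalar_num(ci_low, "ci_low", lower = 0)
  assert_scalar_num(ci_high, "ci_high", lower = 0)
  if (!(ci_low <= mean && mean <= ci_high))
    stop("require ci_low <= mean <= ci_high", call. = FALSE)
  if (ci_low == ci_high) return(dist_spec("point", mean))
  if (mean <= 0) stop("mean must be > 0 for a non-degenerate gamma", call. = FALSE)
  rng <- c(log(1e-4), log(1e6))
  qk <- function(p, logk) stats::qgamma(p, shape = exp(logk),
                                        scale = mean / exp(logk))
  if (ci_low == 0) {
    # mean-preserving q97.5 is unimodal in the shape: rises from `mean`
    # (shape -> Inf) to a peak, then collapses as the shape -> 0
    peak <- stats::optimize(function(lk) -qk(0.975, lk), rng, tol = 1e-10)
    logk <- if (-peak$objective <= ci_high) peak$minimum
      else stats::uniroot(function(lk) qk(0.975, lk) - ci_high,
                          c(peak$minimum, rng[2]), tol = 1e-12)$root
  } else {
    obj <- function(lk) (qk(0.025, lk) - ci_low)^2 + (qk(0.975, lk) - ci_high)^2
    logk <- stats::optimize(obj, interval = rng, tol = 1e-10)$minimum
  }
  k <- exp(logk)
  dist_spec("gamma", c(k, mean / k))
}

#' Fit a lognormal distribution to a ratio estimate with 95% CI
#'
#' For hazard ratios reported as `point (ci_low-ci_high)`: location is
#' `log(point)` and the log-scale spread is the CI width on the log scale
#' divided by 2 * 1.959964.
#'
#' @param point point estimate (> 0).
#' @param ci_low,ci_high 95% confidence bounds (> 0).
#' @return a lognormal [dist_spec()] (sdlog 0 for a zero-width interval).
#' @export
fit_lognormal_from_ratio <- function(point, ci_low, ci_high) {
  for (v in c(point = point, ci_low = ci_low, ci_high = ci_high))
    if (!is.finite(v) || v <= 0)
      stop("ratio and CI bounds must be positive finite", call. = FALSE)
  if (!(ci_low <= point && point <= ci_high))
    stop("require ci_low <= point <= ci_high", call. = FALSE)
  sdlog <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  dist_spec("lognormal", c(log(point), sdlog))
}

#' Fit a beta distribution to a mean and 95% interval
#'
#' Constrains the mean exactly (shape1 = mean * c, shape2 = (1 - mean) * c)
#' and chooses the concentration c by least squares on the 2.5th/97.5th
#' percentiles. Used for the EQ-5D utilities published as mean (95% CI).
#'
#' @param mean mean in (0, 1).
#' @param ci_low,ci_high 95% bounds in \[0, 1\].
#' @return a beta [dist_spec()].
#' @export
fit_beta_from_mean_ci <- function(mean, ci_low, ci_high) {
  assert_scalar_num(mean, "mean", lower = 0, upper = 1)
  assert_scalar_num(ci_low, "ci_low", lower = 0, upper = 1)
  assert_scalar_num(ci_high, "ci_high", lower = 0, upper = 1)
  if (!(ci_low <= mean && mean <= ci_high))
    stop("require ci_low <= mean <= ci_high", call. = FALSE)
  if (ci_low == ci_high) return(dist_spec("point", mean))
  obj <- function(logc) {
    cc <- exp(logc)
    (stats::qbeta(0.025, mean * cc, (1 - mean) * cc) - ci_low)^2 +
      (stats::qbeta(0.975, mean * cc, (1 - mean) * cc) - ci_high)^2
  }
  opt <- stats::optimize(obj, interval = c(log(2), log(1e8)), tol = 1e-10)
  cc <- exp(opt$minimum)
  dist_spec("beta", c(mean * cc, (1 - mean) * cc))
}

# Normal from mean and symmetric 95% CI.
fit_normal_from_ci <- function(mean, ci_low, ci_high) {
  stopifnot(ci_low <= mean, mean <= ci_high)
  dist_spec("normal", c(mean, (ci_high - ci_low) / (2 * stats::qnorm(0.975))))
}
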