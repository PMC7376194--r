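#' Ornstein-Uhlenbeck parameters for per-CpG methylation dynamics
#'
#' The methylation level M of a CpG is modelled as a mean-reverting
#' diffusion dM = theta (mu - M) dt + sigma dW, with `mu` the equilibrium
#' methylation, `theta` the restoring force (high in normal tissue, low
#' after a carcinogenic event) and `sigma` the noise level in
#' methylation-fraction units (0.04 = "4%"). Trajectories are clipped to
#' `[0, 1]` after each step, since methylation is a fraction.
#'
#' @param theta restoring force, `> 0` (1/time).
#' @param mu equilibrium methylation in `[0, 1]`.
#' @param sigma diffusion coefficient, `>= 0` (per sqrt(time)).
#' @param dt Euler-Maruyama time step, `> 0`.
#' @param n_steps number of steps, `>= 1`.
#' @param m0 initial methylation in `[0, 1]`.
#' @param seed RNG seed for the Wiener increments.
#' @return an `ou_params` list.
#' @export
ou_params <- function(theta = 2, mu = 0.5, sigma = 0.04, dt = 0.01,
                      n_steps = 1e4, m0 = mu, seed = 1) {
  if (theta <= 0) stopf("theta must be > 0")
  if (sigma < 0) stopf("sigma must be >= 0")
  if (dt <= 0) stopf("dt must be > 0")
  if (n_steps < 1) stopf("n_steps must be >= 1")
  if (mu < 0 || mu > 1) stopf("mu must be in [0,1]")
  if (m0 < 0 || m0 > 1) stopf("m0 must be in [0,1]")
  structure(list(theta = theta, mu = mu, sigma = sigma, dt = dt,
                 n_steps = as.integer(n_steps), m0 = m0, seed = seed),
            class = "ou_params")
}

#' Simulate a bounded OU methylation trajectory (Euler-Maruyama)
#'
#' Integrates `M_{k+1} = M_k + theta (mu - M_k) dt + sigma sqrt(dt) Z_k`
#' with iid standard normal `Z_k` from a locally seeded generator, clipping
#' into `[0, 1]` after every step. Deterministic given the seed in `params`.
#'
#' @param params an [ou_params()] object.
#' @return an `ou_trace`: list with `times` (length `n_steps + 1`) and
#'   `values` (clipped methylation levels).
#' @export
simulate_ou <- function(params) {
  stopifnot(inherits(params, "ou_params"))
  p <- params
  if (p$theta * p$dt >= 2)
    stopf("theta*dt = %.3g >= 2: explicit Euler scheme unstable; reduce dt",
          p$theta * p$dt)
  z <- with_seed(p$seed, rnorm(p$n_steps))
  values <- numeric(p$n_steps + 1L)
  values[1] <- p$m0
  a <- 1 - p$theta * p$dt
  b <- p$theta * p$mu * p$dt
  s <- p$sigma * sqrt(p$dt)
  m <- p$m0
  for (k in seq_len(p$n_steps)) {
    m <- a * m + b + s * z[k]
    m <- min(max(m, 0), 1)
    values[k + 1L] <- m
  }
  structure(list(times = seq(0, by = p$dt, length.out = p$n_steps + 1L),
                 values = values, params = p),
            class = "ou_trace")
}

#' Stationary mean and variance of the (unbounded) OU process
#'
#' Returns `(mu, sigma^2 / (2 theta))`, ignoring the `[0, 1]` truncation;
#' accurate whenever `mu +- 4 sd` stays inside the unit interval.
#'
#' @inheritParams simulate_ou
#' @return named numeric vector `c(mean, variance)`.
#' @export
stationary_moments <- function(params) {
  stopifnot(inherits(params, "ou_params"))
  if (params$theta <= 0) stopf("theta must be > 0")
  c(mean = params$mu, variance = params$sigma^2 / (2 * params$theta))
}

#' Recover OU parameters from a trajectory by an AR(1) fit
#'
#' Fits `M_{k+1} = a M_k + b + eps` by least squares and maps back:
#' `theta = (1 - a) / dt`, `mu = b / (1 - a)`, `sigma = sd(eps) / sqrt(dt)`.
#' This discrete-time estimator is the recovery oracle for the simulator;
#' it is biased near the `[0, 1]` boundary where clipping distorts the
#' linear dynamics.
#'
#' @param trace an `ou_trace` (or numeric vector of levels).
#' @param dt time step used to generate the trace.
#' @return named vector `c(theta, mu, sigma)`.
#' @export
estimate_ou_params <- function(trace, dt = NULL) {
  values <- if (inherits(trace, "ou_trace")) trace$values else as.numeric(trace)
  dt <- dt %||% (if (inherits(trace, "ou_trace")) trace$params$dt else
    stopf("dt required for a bare numeric trace"))
  if (length(values) < 101) stopf("need at least 100 steps to estimate")
  if (sd(values) == 0) stopf("constant trace: parameters unidentifiable")
  x <- values[-length(values)]
  y <- values[-1]
  fit <- stats::lm.fit(cbind(1, x), y)
  a <- fit$coefficients[2]
  b <- fit$coefficients[1]
  eps <- fit$residuals
  c(theta = unname((1 - a) / dt),
    mu = unname(b / (1 - a)),
    sigma = sd(eps) / sqrt(dt))
}

#' Draw stationary OU methylation levels
#'
#' Marginal shortcut used by the synthetic cohort generator: samples are
#' drawn directly from the stationary law `N(mu, sigma^2 / (2 theta))`
#' clipped to `[0, 1]`, equivalent in distribution to integrating long
#' trajectories per CpG.
#'
#' @param n number of draws.
#' @param mu equilibrium level(s), recycled to `n`.
#' @param theta restoring force.
#' @param sigma noise level.
#' @return numeric vector in `[0, 1]`. Uses the caller's RNG stream.
#' @export
rstationary_ou <- function(n, mu, theta, sigma) {
  sdv <- sigma / sqrt(2 * theta)
  pmin(pmax(rnorm(n, mean = mu, sd = sdv), 0), 1)
}

#' @rdname simulate_ou
#' @param x an `ou_trace`.
#' @param ... unused.
#' @export
print.ou_trace <- function(x, ...) {
  cat(sprintf("ou_trace: %d steps, dt=%g, theta=%g, mu=%g, sigma=%g\n",
              length(x$values) - 1L, x$params$dt, x$params$theta,
              x$params$mu, x$params$sigma))
  invisible(x)
}
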