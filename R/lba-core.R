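# Analytic LBA race model: single-accumulator distribution functions,
# defective (choice, RT) densities, choice probabilities, and the race
# sampler. All functions are vectorized over decision time t.
#
# Conventions: t is DECISION time (nondecision time t0 already removed);
# the defective density and the sampler work on observed RT = t + t0.
# Numerical guards: standard-normal arguments are clipped to +/- 38 and
# densities floored at 1e-290 before any log.

.Z_CLIP <- 38
.DENS_FLOOR <- 1e-290

.clip <- function(z) pmin(pmax(z, -.Z_CLIP), .Z_CLIP)

#' Single-accumulator finishing-time CDF
#'
#' Probability that accumulator `i`, starting at `U(0, A)` and drifting
#' at `N(v[i], s)`, has crossed the threshold `b` by decision time `t`.
#' The distribution is defective: as `t` grows it approaches
#' `P(drift > 0) = 1 - pnorm(-v[i]/s)`, not 1. The point-start limit
#' `A = 0` is handled explicitly as `pnorm((v[i] - b/t)/s)`.
#'
#' @param t decision time(s) in seconds (nondecision time excluded).
#' @param i response-option index (1-based).
#' @param params an [lba_params] object.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
accumulator_cdf <- function(t, i, params) {
  stopifnot(inherits(params, "lba_params"),
            length(i) == 1, i >= 1, i <= length(params$v))
  v <- params$v[i]; s <- params$s; A <- params$A; b <- params$b
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tt <- t[pos]
  if (A == 0) {
    F <- stats::pnorm(.clip((v - b / tt) / s))
  } else {
    ts <- tt * s
    z1 <- .clip((b - A - tt * v) / ts)
    z2 <- .clip((b - tt * v) / ts)
    F <- 1 + ((b - A - tt * v) / A) * stats::pnorm(z1) -
      ((b - tt * v) / A) * stats::pnorm(z2) +
      (ts / A) * (stats::dnorm(z1) - stats::dnorm(z2))
  }
  out[pos] <- pmin(pmax(F, 0), 1)
  out
}

#' Single-accumulator finishing-time density
#'
#' Density of the threshold-crossing time of accumulator `i`; the
#' defective counterpart of [accumulator_cdf]. Integrates to
#' `1 - pnorm(-v[i]/s)` over `(0, Inf)`. The point-start limit `A = 0`
#' uses `f(t) = (b / (s t^2)) * dnorm((b/t - v)/s)`.
#'
#' @inheritParams accumulator_cdf
#' @return numeric vector of densities (1/s), floored at 0.
#' @export
accumulator_pdf <- function(t, i, params) {
  stopifnot(inherits(params, "lba_params"),
            length(i) == 1, i >= 1, i <= length(params$v))
  v <- params$v[i]; s <- params$s; A <- params$A; b <- params$b
  out <- numeric(length(t))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  tt <- t[pos]
  if (A == 0) {
    f <- (b / (s * tt^2)) * stats::dnorm(.clip((b / tt - v) / s))
  } else {
    ts <- tt * s
    z1 <- .clip((b - A - tt * v) / ts)
    z2 <- .clip((b - tt * v) / ts)
    f <- (1 / A) * (-v * stats::pnorm(z1) + s * stats::dnorm(z1) +
                      v * stats::pnorm(z2) - s * stats::dnorm(z2))
  }
  out[pos] <- pmax(f, 0)
  out
}

#' Defective density of an observed (choice, RT) pair
#'
#' Winner-takes-all density: the chosen accumulator finishes at decision
#' time `rt - t0` while every other accumulator is still below
#' threshold. Zero for `rt <= t0`. Integrating over `rt` gives the
#' probability of that choice (not 1), hence "defective".
#'
#' @param rt observed response time(s), seconds.
#' @param choice index of the winning response option.
#' @param params an [lba_params] object.
#' @return numeric vector of densities, floored at `1e-290` where
#'   positive support exists (use `log = TRUE` callers downstream).
#' @export
defective_pdf <- function(rt, choice, params) {
  stopifnot(inherits(params, "lba_params"),
            length(choice) == 1, choice >= 1, choice <= length(params$v))
  t <- rt - params$t0
  out <- numeric(length(rt))
  pos <- which(t > 0)
  if (!length(pos)) return(out)
  dens <- accumulator_pdf(t[pos], choice, params)
  for (j in seq_along(params$v)) {
    if (j == choice) next
    dens <- dens * (1 - accumulator_cdf(t[pos], j, params))
  }
  out[pos] <- dens
  out
}

#' Choice probability by adaptive quadrature
#'
#' Integrates the defective density of `choice` over all response times.
#' The values over choices sum to the probability that at least one
#' accumulator has positive drift, `1 - prod(pnorm(-v/s))`, which is
#' below 1 when negative-drift trials can fail to terminate.
#'
#' @inheritParams defective_pdf
#' @param choice index of the response option.
#' @return scalar probability.
#' @export
choice_probability <- function(choice, params) {
  stopifnot(inherits(params, "lba_params"))
  f <- function(rt) defective_pdf(rt, choice, params)
  q <- stats::integrate(f, lower = params$t0, upper = Inf,
                        rel.tol = 1e-8, abs.tol = 1e-10,
                        stop.on.error = FALSE)
  if (q$message != "OK" && q$abs.error > 1e-4) {
    stop("choice_probability: quadrature did not converge (",
         q$message, ", abs.error = ", signif(q$abs.error, 3), ")")
  }
  min(max(q$value, 0), 1)
}

#' Simulate the LBA race
#'
#' Draws `n` trials: start points uniform on `[0, A]`, drifts normal
#' `N(v[i], s)` per option, finishing times `(b - start)/drift` for
#' positive drifts. The winner is the fastest accumulator; observed
#' `rt = t0 +` winning decision time. Trials on which every drift is
#' negative never terminate and are resampled, i.e. the sampler
#' conditions on race termination (the induced mismatch with the
#' unnormalized defective density is `prod(pnorm(-v/s))`, negligible for
#' the parameter ranges used here).
#'
#' @param params an [lba_params] object.
#' @param n number of trials.
#' @param seed optional integer seed for reproducibility.
#' @return a `data.frame` of class `choice_data` with columns `choice`
#'   (integer option index) and `rt` (seconds).
#' @export
sample_race <- function(params, n, seed = NULL) {
  stopifnot(inherits(params, "lba_params"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- length(params$v)
  out_choice <- integer(n)
  out_rt <- numeric(n)
  need <- seq_len(n)
  guard <- 0
  while (length(need)) {
    m <- length(need)
    start <- matrix(stats::runif(m * K, 0, params$A), m, K)
    drift <- matrix(stats::rnorm(m * K, mean = rep(params$v, each = m),
                                 sd = params$s), m, K)
    finish <- (params$b - start) / drift
    finish[drift <= 0] <- Inf
    win <- max.col(-finish, ties.method = "first")
    tmin <- finish[cbind(seq_len(m), win)]
    ok <- is.finite(tmin)
    out_choice[need[ok]] <- win[ok]
    out_rt[need[ok]] <- tmin[ok] + params$t0
    need <- need[!ok]
    guard <- guard + 1
    if (guard > 1000) stop("sample_race: race fails to terminate")
  }
  structure(data.frame(choice = out_choice, rt = out_rt),
            class = c("choice_data", "data.frame"))
}

#' Analytic defective CDF of the observed RT for one choice
#'
#' `P(choice = c, RT <= rt)` obtained by quadrature of [defective_pdf];
#' used for sampler-vs-analytic agreement checks and posterior
#' predictive overlays.
#'
#' @inheritParams defective_pdf
#' @return numeric vector, same length as `rt`.
#' @export
defective_cdf <- function(rt, choice, params) {
  vapply(rt, function(r) {
    if (r <= params$t0) return(0)
    stats::integrate(function(u) defective_pdf(u, choice, params),
                     lower = params$t0, upper = r,
                     rel.tol = 1e-7, stop.on.error = FALSE)$value
  }, numeric(1))
}
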