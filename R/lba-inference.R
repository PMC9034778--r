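# Bayesian estimation of LBA parameters by Hamiltonian Monte Carlo.
# The log posterior and its analytic gradient live in src/ (see
# lba_logpost.cpp); this file owns the sampler loop, adaptation,
# diagnostics (split R-hat, autocorrelation ESS) and the per-zone
# fitting front end.

#' Prior specification for LBA inference
#'
#' Defaults follow the standard Bayesian LBA setup: truncated-normal
#' (lower bound 0) priors on each drift rate (mean 2, SD 1), on the
#' maximum start point `A` (mean 0.5, SD 1) and on the relative
#' threshold `k` (mean 0.5, SD 1); uniform prior on the nondecision
#' time over `(0, t0_upper)` with `t0_upper = 1` s. The between-trial
#' drift SD `s` is the fixed scaling constant, 1.
#'
#' @param n_options number of response options (accumulators).
#' @param v_mean,v_sd drift-rate prior location and scale.
#' @param A_mean,A_sd start-point prior location and scale.
#' @param k_mean,k_sd relative-threshold prior location and scale.
#' @param t0_upper upper bound of the uniform nondecision-time prior, s.
#' @param s fixed between-trial drift SD.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(n_options = 2, v_mean = 2, v_sd = 1,
                       A_mean = 0.5, A_sd = 1, k_mean = 0.5, k_sd = 1,
                       t0_upper = 1, s = 1) {
  stopifnot(n_options >= 2, v_sd > 0, A_sd > 0, k_sd > 0,
            t0_upper > 0, s > 0)
  structure(list(n_options = n_options, v_mean = v_mean, v_sd = v_sd,
                 A_mean = A_mean, A_sd = A_sd, k_mean = k_mean,
                 k_sd = k_sd, t0_upper = t0_upper, s = s),
            class = "prior_spec")
}

#' Sampler configuration
#'
#' Defaults mirror the conventional HMC setup for this model: 1000
#' warmup iterations out of 2000 total per chain, no thinning, target
#' acceptance (delta) 0.8, three chains.
#'
#' @param warmup adaptation iterations discarded from each chain.
#' @param iterations total iterations per chain (including warmup).
#' @param thinning keep every `thinning`-th post-warmup draw.
#' @param target_accept dual-averaging target acceptance probability.
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(warmup = 1000, iterations = 2000,
                           thinning = 1, target_accept = 0.8,
                           chains = 3, seed = 1) {
  stopifnot(iterations > warmup, warmup >= 0, thinning >= 1,
            target_accept > 0, target_accept < 1, chains >= 1)
  structure(list(warmup = warmup, iterations = iterations,
                 thinning = thinning, target_accept = target_accept,
                 chains = chains, seed = seed),
            class = "sampler_config")
}

#' LBA log likelihood of choice-RT data
#'
#' Sum of log defective densities over trials. RTs at or below `t0`
#' contribute the guarded floor density so the result stays finite.
#'
#' @param data a `choice_data` data.frame (columns `choice`, `rt`).
#' @param params an [lba_params] object.
#' @return scalar log density.
#' @export
lba_log_likelihood <- function(data, params) {
  stopifnot(inherits(params, "lba_params"))
  if (is.null(data) || nrow(data) == 0) stop("empty data")
  ll <- 0
  for (c in sort(unique(data$choice))) {
    rts <- data$rt[data$choice == c]
    dens <- pmax(defective_pdf(rts, c, params), .DENS_FLOOR)
    ll <- ll + sum(log(dens))
  }
  ll
}

# unconstrained xi -> named constrained parameter vector
.xi_to_params <- function(xi, K, t0_upper) {
  v <- exp(xi[seq_len(K)])
  A <- exp(xi[K + 1]); k <- exp(xi[K + 2])
  t0 <- t0_upper * stats::plogis(xi[K + 3])
  c(stats::setNames(v, paste0("v", seq_len(K))), A = A, k = k, t0 = t0)
}

.logpost <- function(xi, rt, choice, priors, t0_upper, use_lik,
                     normalize = TRUE) {
  .lba_logpost_grad(xi, rt, choice, priors$n_options,
                    priors$v_mean, priors$v_sd,
                    priors$A_mean, priors$A_sd,
                    priors$k_mean, priors$k_sd,
                    t0_upper, priors$s, use_lik, normalize)
}

# One HMC chain (C++ driver): dual-averaging step size, diagonal mass
# matrix estimated mid-warmup, jittered path length. Draws are on the
# unconstrained scale.
.hmc_chain <- function(xi0, rt, choice, priors, t0_upper, use_lik,
                       warmup, iterations, target_accept, L_base = 32,
                       normalize = TRUE) {
  .lba_hmc_chain(xi0, rt, choice, priors$n_options,
                 priors$v_mean, priors$v_sd, priors$A_mean, priors$A_sd,
                 priors$k_mean, priors$k_sd, t0_upper, priors$s,
                 use_lik, normalize, warmup, iterations, target_accept,
                 L_base)
}

#' Sample the LBA posterior by Hamiltonian Monte Carlo
#'
#' Runs `config$chains` independent HMC chains on the unconstrained
#' scale (log transforms for `v`, `A`, `k`; scaled logit for `t0`) with
#' Jacobian correction, dual-averaging step-size adaptation toward
#' `target_accept`, and a diagonal mass matrix estimated during warmup.
#' The nondecision-time prior is uniform on `(0, u)` with
#' `u = min(priors$t0_upper, min(rt))`; the scaled-logit transform
#' keeps every draw strictly below the smallest observed RT, so the
#' likelihood stays finite while the admissible range still contains
#' any true nondecision time.
#'
#' @param data a `choice_data` data.frame (columns `choice`, `rt`), or
#'   `NULL` for a prior-only run (the likelihood term is dropped and
#'   draws target the prior; used for prior-recovery checks).
#' @param priors a [prior_spec].
#' @param config a [sampler_config].
#' @param normalize condition the likelihood on race termination
#'   (default `TRUE`): each trial's defective density is divided by
#'   `1 - prod(pnorm(-v/s))`, matching a data-generating race that
#'   resamples trials on which no accumulator has positive drift. Set
#'   `FALSE` for the unnormalized defective likelihood.
#' @return object of class `posterior_samples`: list with `draws` (3-d
#'   array iterations x chains x parameters, including derived `b` and
#'   `caution`), `diagnostics` (from [lba_diagnostics]), `n_divergent`,
#'   `config`, `priors`, `t0_upper`.
#' @export
sample_posterior <- function(data, priors = prior_spec(),
                             config = sampler_config(),
                             normalize = TRUE) {
  stopifnot(inherits(priors, "prior_spec"),
            inherits(config, "sampler_config"))
  use_lik <- !is.null(data)
  if (use_lik) {
    stopifnot(nrow(data) > 0, all(data$rt > 0),
              all(data$choice >= 1), all(data$choice <= priors$n_options))
    rt <- as.numeric(data$rt); choice <- as.integer(data$choice)
    t0_upper <- min(priors$t0_upper, min(rt))
  } else {
    rt <- numeric(0); choice <- integer(0)
    t0_upper <- priors$t0_upper
  }
  K <- priors$n_options
  d <- K + 3
  base <- c(rep(log(max(priors$v_mean, 0.5)), K),
            log(max(priors$A_mean, 0.2)), log(max(priors$k_mean, 0.2)), 0)
  # start every chain near the posterior mode (short BFGS ascent) so
  # step-size/metric adaptation sees the same geometry in each chain
  if (use_lik) {
    neglp <- function(x) -.logpost(x, rt, choice, priors, t0_upper,
                                   use_lik, normalize)$lp
    neggr <- function(x) -.logpost(x, rt, choice, priors, t0_upper,
                                   use_lik, normalize)$grad
    opt <- try(stats::optim(base, neglp, neggr, method = "BFGS",
                            control = list(maxit = 200)), silent = TRUE)
    if (!inherits(opt, "try-error") && all(is.finite(opt$par)) &&
          is.finite(opt$value)) {
      base <- opt$par
    }
  }
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    set.seed(config$seed + ch - 1)
    xi0 <- base + stats::rnorm(d, 0, 0.1)
    chains[[ch]] <- .hmc_chain(xi0, rt, choice, priors, t0_upper, use_lik,
                               config$warmup, config$iterations,
                               config$target_accept,
                               normalize = normalize)
  }
  thin_idx <- seq(1, config$iterations - config$warmup, by = config$thinning)
  pnames <- c(paste0("v", seq_len(K)), "A", "k", "t0", "b", "caution")
  draws <- array(NA_real_, c(length(thin_idx), config$chains, d + 2),
                 dimnames = list(NULL, NULL, pnames))
  for (ch in seq_len(config$chains)) {
    xi <- chains[[ch]]$draws[thin_idx, , drop = FALSE]
    v <- exp(xi[, seq_len(K), drop = FALSE])
    A <- exp(xi[, K + 1]); k <- exp(xi[, K + 2])
    t0 <- t0_upper * stats::plogis(xi[, K + 3])
    draws[, ch, seq_len(K)] <- v
    draws[, ch, "A"] <- A; draws[, ch, "k"] <- k; draws[, ch, "t0"] <- t0
    draws[, ch, "b"] <- k + A
    draws[, ch, "caution"] <- (k + A) - A / 2
  }
  out <- structure(
    list(draws = draws,
         n_divergent = sum(vapply(chains, `[[`, 0, "n_divergent")),
         config = config, priors = priors, t0_upper = t0_upper),
    class = "posterior_samples")
  out$diagnostics <- lba_diagnostics(out)
  out
}

#' @export
print.posterior_samples <- function(x, ...) {
  s <- posterior_summary(x)
  cat("LBA posterior:", dim(x$draws)[1], "draws x", dim(x$draws)[2],
      "chains;", x$n_divergent, "divergent transitions\n")
  print(s, digits = 3)
  invisible(x)
}

#' Posterior summary table
#'
#' @param samples a `posterior_samples` object.
#' @param probs credible-interval probabilities.
#' @return data.frame with mean, median, CI bounds, R-hat and ESS per
#'   parameter.
#' @export
posterior_summary <- function(samples, probs = c(0.025, 0.975)) {
  dr <- samples$draws
  pn <- dimnames(dr)[[3]]
  flat <- apply(dr, 3, identity) # (iter*chain) x param
  data.frame(
    parameter = pn,
    mean = colMeans(flat),
    median = apply(flat, 2, stats::median),
    ci_lo = apply(flat, 2, stats::quantile, probs[1]),
    ci_hi = apply(flat, 2, stats::quantile, probs[2]),
    rhat = samples$diagnostics$rhat[pn],
    n_eff = samples$diagnostics$n_eff[pn],
    row.names = NULL)
}

# split R-hat for a draws matrix (iterations x chains)
.split_rhat <- function(m) {
  n <- nrow(m); half <- floor(n / 2)
  if (half < 2) return(NA_real_)
  sm <- cbind(m[seq_len(half), , drop = FALSE],
              m[(n - half + 1):n, , drop = FALSE])
  W <- mean(apply(sm, 2, stats::var))
  B <- half * stats::var(colMeans(sm))
  if (!is.finite(W) || W == 0) return(NA_real_)
  sqrt(((half - 1) / half * W + B / half) / W)
}

# multichain autocorrelation-based effective sample size (initial
# monotone positive sequence truncation)
.ess <- function(m) {
  n <- nrow(m); nc <- ncol(m)
  if (n < 4) return(NA_real_)
  W <- mean(apply(m, 2, stats::var))
  B <- if (nc > 1) n * stats::var(colMeans(m)) else 0
  var_plus <- (n - 1) / n * W + B / n
  if (!is.finite(var_plus) || var_plus == 0) return(NA_real_)
  max_lag <- min(n - 1, 2000)
  acov <- matrix(0, max_lag + 1, nc)
  for (ch in seq_len(nc)) {
    x <- m[, ch] - mean(m[, ch])
    ac <- stats::acf(x, lag.max = max_lag, plot = FALSE,
                     type = "covariance", demean = FALSE)$acf[, 1, 1]
    acov[, ch] <- ac
  }
  rho <- 1 - (W - rowMeans(acov)) / var_plus
  rho[1] <- 1
  # Geyer initial monotone positive sequence on paired sums
  tmax <- 1; sum_rho <- 0; prev_pair <- Inf
  t <- 1
  while (t + 1 <= length(rho) - 1) {
    pair <- rho[t + 1] + rho[t + 2]
    if (!is.finite(pair) || pair < 0) break
    pair <- min(pair, prev_pair)
    sum_rho <- sum_rho + pair
    prev_pair <- pair
    t <- t + 2
  }
  ess <- n * nc / (1 + 2 * sum_rho)
  max(ess, 1)
}

#' Convergence diagnostics for posterior draws
#'
#' Split Gelman-Rubin R-hat and autocorrelation-based effective sample
#' size (ESS, a.k.a. Neff) per parameter, with the conventional pass
#' rule: every R-hat < 1.1 and every Neff > 100.
#'
#' @param samples a `posterior_samples` object, or a 3-d draws array
#'   (iterations x chains x parameters).
#' @return list with named vectors `rhat`, `n_eff`, logical `pass`, and
#'   `flags` naming parameters with undefined diagnostics.
#' @export
lba_diagnostics <- function(samples) {
  dr <- if (inherits(samples, "posterior_samples")) samples$draws
        else samples
  stopifnot(length(dim(dr)) == 3)
  if (dim(dr)[2] < 2) stop("diagnostics require at least 2 chains")
  pn <- dimnames(dr)[[3]]
  if (is.null(pn)) pn <- paste0("p", seq_len(dim(dr)[3]))
  rhat <- vapply(seq_along(pn), function(j) .split_rhat(dr[, , j]),
                 numeric(1))
  ess <- vapply(seq_along(pn), function(j) .ess(dr[, , j]), numeric(1))
  names(rhat) <- names(ess) <- pn
  flags <- pn[!is.finite(rhat) | !is.finite(ess)]
  pass <- length(flags) == 0 && all(rhat < 1.1) && all(ess > 100)
  list(rhat = rhat, n_eff = ess, pass = pass, flags = flags)
}

#' Posterior predictive check
#'
#' Simulates races from thinned posterior draws and compares the
#' predicted RT distribution with the observed one: reports the
#' sup-distance between the predicted mean RT CDF and the observed
#' empirical CDF (pooled over choices), plus predicted and observed
#' choice-1 proportions.
#'
#' @param samples a `posterior_samples` object.
#' @param data observed `choice_data`.
#' @param n_draws number of posterior draws to simulate from.
#' @param n_per_draw trials simulated per draw (defaults to `nrow(data)`).
#' @param seed integer seed.
#' @return list with `distance` (sup-distance in `[0, 1]`), `p_choice1`
#'   predicted and observed, and the simulated RT pool.
#' @export
posterior_predictive <- function(samples, data, n_draws = 100,
                                 n_per_draw = NULL, seed = 1) {
  stopifnot(inherits(samples, "posterior_samples"), nrow(data) > 0)
  if (is.null(n_per_draw)) n_per_draw <- nrow(data)
  set.seed(seed)
  dr <- samples$draws
  K <- sum(grepl("^v[0-9]+$", dimnames(dr)[[3]]))
  ni <- dim(dr)[1]; nc <- dim(dr)[2]
  idx <- cbind(sample(ni, n_draws, replace = n_draws > ni),
               sample(nc, n_draws, replace = TRUE))
  sims <- vector("list", n_draws)
  for (i in seq_len(n_draws)) {
    pv <- dr[idx[i, 1], idx[i, 2], ]
    pp <- lba_params(v = pv[seq_len(K)], A = pv[["A"]], k = pv[["k"]],
                     t0 = pv[["t0"]])
    sims[[i]] <- sample_race(pp, n_per_draw)
  }
  sim <- do.call(rbind, sims)
  grid <- sort(unique(data$rt))
  pred_cdf <- stats::ecdf(sim$rt)(grid)
  obs_cdf <- stats::ecdf(data$rt)(grid)
  list(distance = max(abs(pred_cdf - obs_cdf)),
       p_choice1 = c(predicted = mean(sim$choice == 1),
                     observed = mean(data$choice == 1)),
       sim = sim)
}

#' Fit the LBA independently per subject and zone
#'
#' Approach decisions are response option 1, avoid decisions option 2.
#' Fits are fully independent across subject x zone cells; cells with
#' fewer than `min_trials` pauses are skipped with a logged reason.
#'
#' @param pauses data.frame of pause events with columns `subject`,
#'   `zone`, `outcome` ("approach"/"avoid") and `rt`.
#' @param priors a [prior_spec].
#' @param config a [sampler_config]; chain seeds are offset per cell so
#'   cells are independent but the whole fit is reproducible.
#' @param min_trials minimum pauses per cell (default 20).
#' @return object of class `lba_zone_fits`: list with `fits` (named
#'   list of `posterior_samples`), `estimates` (data.frame of posterior
#'   means per cell) and `skipped`.
#' @export
fit_per_zone <- function(pauses, priors = prior_spec(),
                         config = sampler_config(), min_trials = 20) {
  if (!"rt" %in% names(pauses) && "rt_s" %in% names(pauses)) {
    pauses[["rt"]] <- pauses[["rt_s"]]
  }
  stopifnot(all(c("subject", "zone", "outcome", "rt") %in% names(pauses)))
  cells <- unique(pauses[, c("subject", "zone")])
  cells <- cells[order(cells$subject, cells$zone), , drop = FALSE]
  fits <- list(); skipped <- character(0); rows <- list()
  for (r in seq_len(nrow(cells))) {
    sb <- cells$subject[r]; zn <- cells$zone[r]
    sel <- pauses$subject == sb & pauses$zone == zn
    dat <- data.frame(
      choice = ifelse(pauses$outcome[sel] == "approach", 1L, 2L),
      rt = pauses$rt[sel])
    key <- paste(sb, zn, sep = ":")
    if (nrow(dat) < min_trials) {
      skipped <- c(skipped, sprintf("%s: %d trials < %d", key,
                                    nrow(dat), min_trials))
      next
    }
    cfg <- config
    cfg$seed <- config$seed + 1000L * r
    fit <- sample_posterior(dat, priors, cfg)
    fits[[key]] <- fit
    sm <- posterior_summary(fit)
    est <- stats::setNames(sm$mean, sm$parameter)
    rows[[key]] <- data.frame(
      subject = sb, zone = zn, n_trials = nrow(dat),
      v_approach = est[["v1"]], v_avoid = est[["v2"]],
      A = est[["A"]], k = est[["k"]], t0 = est[["t0"]],
      b = est[["b"]], caution = est[["caution"]],
      rhat_max = max(fit$diagnostics$rhat),
      n_eff_min = min(fit$diagnostics$n_eff),
      converged = fit$diagnostics$pass)
  }
  structure(list(fits = fits,
                 estimates = if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE)) else NULL,
                 skipped = skipped),
            class = "lba_zone_fits")
}
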