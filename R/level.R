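#' Interval-censored estimate of current foreign-crop usage
#'
#' Fits the intercept-only interval-censored Normal model for one country's
#' current usage: the latent usage in each observation year follows
#' \eqn{y_i \sim N(\theta, \sigma^2)} but is observed only as the interval
#' `[min_use, max_use]` computed by [usage_interval()]. This is the model
#' behind "mean of the most recent 3 years" current-use estimates: the
#' posterior for \eqn{\theta} carries the min/max uncertainty forward
#' instead of picking a point inside the interval.
#'
#' Priors are non-informative: \eqn{\theta \sim N(0, 10^6)},
#' \eqn{\sigma \sim U(0, 100)}. A data-augmented Gibbs sampler alternates
#' truncated-Normal draws of the latent usages with conjugate updates of
#' \eqn{\theta} and a slice update of \eqn{\sigma}. Observations with
#' `min_use == max_use` are exact data: their latents are fixed, so the
#' degenerate all-exact case reduces to ordinary Normal conjugate updates.
#'
#' @param data data frame with columns `min_use`, `max_use` (percent), one
#'   row per observation (typically 3 years for one country).
#' @param chains number of chains (>= 2 for diagnostics).
#' @param iter iterations per chain.
#' @param burnin burn-in iterations discarded per chain.
#' @param seed integer seed; required, no silent default.
#' @param level credible level for reported intervals.
#' @return an object of class `usage_level` with elements `summary`
#'   (posterior mean/sd/CI for `theta` and `sigma`), `rhat`, `draws`
#'   (per-chain matrices), and the sampler settings.
#' @seealso [fit_usage_trend()] for the hierarchical 50-year trend model.
#' @export
fit_usage_level <- function(data, chains = 3, iter = 5000, burnin = 1000,
                            seed, level = 0.95) {
  if (missing(seed)) stop("seed is required (no silent default)")
  if (!all(c("min_use", "max_use") %in% names(data))) {
    stop("data needs columns 'min_use' and 'max_use'")
  }
  L <- as.numeric(data$min_use)
  U <- as.numeric(data$max_use)
  if (!length(L)) stop("need at least one observation")
  if (any(L > U) || any(L < 0) || any(U > 100)) {
    stop("bounds must satisfy 0 <= min_use <= max_use <= 100")
  }
  if (iter <= burnin) stop("iter must exceed burnin")
  n <- length(L)
  mid <- (L + U) / 2
  prior_prec <- 1e-6        # N(0, 1e6) on theta
  sigma_max <- 100          # U(0, 100) on sigma
  sigma_floor <- 1e-4       # numerical floor when the data are exact and equal

  run_chain <- function(chain_id) {
    set.seed(seed + 1000 * chain_id)
    ## dispersed starts
    theta <- mean(mid) + stats::rnorm(1, 0, max(stats::sd(mid), 5))
    sigma <- max(stats::runif(1, 1, 20), sigma_floor)
    y <- mid
    keep <- iter - burnin
    out <- matrix(NA_real_, keep, 2, dimnames = list(NULL, c("theta", "sigma")))
    for (it in seq_len(iter)) {
      y <- rtruncnorm_vec(rep(theta, n), sigma, L, U)
      prec <- n / sigma^2 + prior_prec
      theta <- stats::rnorm(1, sum(y) / sigma^2 / prec, sqrt(1 / prec))
      ss <- sum((y - theta)^2)
      logf <- function(s) {
        if (s <= sigma_floor || s >= sigma_max) return(-Inf)
        -n * log(s) - ss / (2 * s^2)
      }
      sigma <- slice_sample1(sigma, logf, w = max(sigma, 0.5),
                             lower = sigma_floor, upper = sigma_max)
      if (it > burnin) out[it - burnin, ] <- c(theta, sigma)
    }
    out
  }
  draws <- lapply(seq_len(chains), run_chain)

  summ <- rbind(
    summarize_posterior(lapply(draws, function(d) d[, "theta"]), level,
                        name = "theta"),
    summarize_posterior(lapply(draws, function(d) d[, "sigma"]), level,
                        name = "sigma"))
  rhat <- if (chains >= 2) gelman_rubin(draws) else
    stats::setNames(rep(NA_real_, 2), c("theta", "sigma"))

  structure(list(summary = summ, rhat = rhat, draws = draws,
                 data = data.frame(min_use = L, max_use = U),
                 settings = list(chains = chains, iter = iter,
                                 burnin = burnin, seed = seed,
                                 level = level)),
            class = "usage_level")
}

#' @export
print.usage_level <- function(x, ...) {
  s <- x$summary
  th <- s[s$parameter == "theta", ]
  cat("Interval-censored current-usage model\n")
  cat(sprintf("  observations: %d   chains: %d x %d (burn-in %d)\n",
              nrow(x$data), x$settings$chains, x$settings$iter,
              x$settings$burnin))
  cat(sprintf("  mean usage: %.1f%% +/- %.1f  [%.1f, %.1f] (%.0f%% CI)\n",
              th$mean, th$sd, th$lower, th$upper, 100 * x$settings$level))
  invisible(x)
}

#' @export
summary.usage_level <- function(object, ...) {
  out <- object$summary
  out$rhat <- object$rhat[out$parameter]
  out
}

#' @export
coef.usage_level <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}
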