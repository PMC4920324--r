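#' Interval-censored hierarchical trend model for foreign-crop usage
#'
#' Fits the 50-year trend model: each country's latent foreign-crop usage
#' follows a country-specific line,
#' \deqn{y_{ct} \sim N(\alpha_c + \beta_c t,\ \sigma^2),}
#' observed only as the interval `[min_use, max_use]` produced by
#' [usage_table()]. Country intercepts and slopes are correlated random
#' effects,
#' \deqn{(\alpha_c, \beta_c) \sim N_2((\mu_\alpha, \mu_\beta), \Sigma),}
#' with \eqn{\Sigma} parameterized by standard deviations
#' \eqn{\tau_\alpha, \tau_\beta} and correlation \eqn{\rho}. The slope
#' hyper-mean \eqn{\mu_\beta} is the global change in usage (percentage
#' points per year) across countries; the correlation allows countries
#' with high usage to show weaker time trends. Time is measured in years
#' since `origin_year`, so \eqn{\mu_\alpha} is the usage level at the
#' origin (1961 for the historical panels).
#'
#' Priors are non-informative: \eqn{N(0, 10^6)} on the hyper-means,
#' \eqn{U(0, 100)} on \eqn{\sigma, \tau_\alpha, \tau_\beta}, and
#' \eqn{U(-1, 1)} on \eqn{\rho}. Sampling is a data-augmented Gibbs
#' sampler: latent usages are drawn from Normals truncated to their
#' observation intervals, \eqn{(\alpha_c, \beta_c)}, the hyper-means and
#' \eqn{\sigma^2} have conjugate updates, and the scale/correlation
#' parameters are updated by univariate slice sampling. Zero-width
#' intervals (exact data) are handled exactly, so the model reduces to an
#' ordinary hierarchical linear model when censoring vanishes.
#'
#' Predicted usage in the first and last observed year is computed per
#' posterior draw, per country and averaged across countries (derived
#' parameters), and clipped to `[0, 100]` only at report time (the number
#' of clipped summaries is recorded).
#'
#' @param data data frame with columns `country`, `year`, `min_use`,
#'   `max_use` (percent scale). Unbalanced panels are allowed; countries
#'   contribute their available years.
#' @param chains number of chains (>= 2; dispersed starting points).
#' @param iter iterations per chain.
#' @param burnin burn-in iterations discarded per chain.
#' @param seed integer seed; required, no silent default.
#' @param level credible level for reported intervals.
#' @param origin_year year mapped to t = 0 (default: earliest year in
#'   `data`).
#' @param rhat_threshold convergence alarm threshold for split-\eqn{\hat R}
#'   (default 1.1); exceeding it triggers a warning and is flagged in the
#'   diagnostics, never silent.
#' @return an object of class `usage_trend`; see [summary.usage_trend()],
#'   [coef.usage_trend()], [predict.usage_trend()], [plot.usage_trend()].
#' @examples
#' \donttest{
#' w <- generate_world(world_spec(n_regions = 5, n_countries = 8,
#'                                n_crops = 12, years = 1961:1990,
#'                                seed = 1))
#' u <- usage_table(generate_panel(w), w$crop_map, w$country_map)
#' fit <- fit_usage_trend(u, chains = 2, iter = 1000, burnin = 300,
#'                        seed = 1)
#' summary(fit)
#' }
#' @export
fit_usage_trend <- function(data, chains = 3, iter = 5000, burnin = 1000,
                            seed, level = 0.95, origin_year = NULL,
                            rhat_threshold = 1.1) {
  if (missing(seed)) stop("seed is required (no silent default)")
  need <- c("country", "year", "min_use", "max_use")
  if (!all(need %in% names(data))) {
    stop("data needs columns ", paste(need, collapse = ", "))
  }
  if (iter <= burnin) stop("iter must exceed burnin")
  L <- as.numeric(data$min_use)
  U <- as.numeric(data$max_use)
  if (any(L > U) || any(L < 0) || any(U > 100)) {
    stop("bounds must satisfy 0 <= min_use <= max_use <= 100")
  }
  countries <- sort(unique(data$country))
  C <- length(countries)
  if (C < 2) stop("need at least 2 countries")
  ci <- match(data$country, countries)
  if (is.null(origin_year)) origin_year <- min(data$year)
  t <- as.numeric(data$year - origin_year)
  if (min(tapply(t, ci, function(z) length(unique(z)))) < 3) {
    stop("every country needs at least 3 time points")
  }
  N <- length(L)
  t_end <- max(t)
  mid <- (L + U) / 2

  ## fixed per-country sufficient statistics of the design
  n_c <- as.numeric(tabulate(ci, C))
  St <- as.numeric(rowsum(t, ci))
  Stt <- as.numeric(rowsum(t^2, ci))

  ## per-country OLS on interval midpoints for starting points
  ols <- t(vapply(seq_len(C), function(k) {
    i <- ci == k
    if (sum(i) >= 2 && stats::sd(t[i]) > 0) {
      f <- stats::lm.fit(cbind(1, t[i]), mid[i])
      f$coefficients
    } else c(mean(mid[i]), 0)
  }, numeric(2)))

  prior_prec_mu <- 1e-6
  sd_max <- 100
  sd_floor <- 1e-4
  keep <- iter - burnin
  hyper_names <- c("mu_alpha", "mu_beta", "sigma", "tau_alpha", "tau_beta",
                   "rho")

  run_chain <- function(chain_id) {
    set.seed(seed + 1000 * chain_id)
    disperse <- chain_id - (chains + 1) / 2
    alpha <- ols[, 1] + stats::rnorm(C, 0, 1)
    beta <- ols[, 2] + stats::rnorm(C, 0, 0.05)
    mu <- c(mean(alpha) + 5 * disperse, mean(beta) + 0.1 * disperse)
    sigma <- max(5 * 2^disperse, 0.5)
    tau_a <- max(stats::sd(alpha), 1)
    tau_b <- max(stats::sd(beta), 0.02)
    rho <- 0

    hyper <- matrix(NA_real_, keep, 6, dimnames = list(NULL, hyper_names))
    alpha_d <- matrix(NA_real_, keep, C)
    beta_d <- matrix(NA_real_, keep, C)

    for (it in seq_len(iter)) {
      ## 1. latent usages, truncated to observation intervals
      fit_obs <- alpha[ci] + beta[ci] * t
      y <- rtruncnorm_vec(fit_obs, sigma, L, U)

      ## 2. country lines: conjugate bivariate normal, vectorized over c
      omd <- tau_a^2 * tau_b^2 * (1 - rho^2)
      O11 <- tau_b^2 / omd
      O12 <- -rho * tau_a * tau_b / omd
      O22 <- tau_a^2 / omd
      Sy <- as.numeric(rowsum(y, ci))
      Sty <- as.numeric(rowsum(y * t, ci))
      s2 <- sigma^2
      ab <- rbvn_prec_vec(n_c / s2 + O11, St / s2 + O12, Stt / s2 + O22,
                          Sy / s2 + O11 * mu[1] + O12 * mu[2],
                          Sty / s2 + O12 * mu[1] + O22 * mu[2])
      alpha <- ab[, 1]
      beta <- ab[, 2]

      ## 3. hyper-means
      mu_draw <- rbvn_prec_vec(C * O11 + prior_prec_mu, C * O12,
                               C * O22 + prior_prec_mu,
                               O11 * sum(alpha) + O12 * sum(beta),
                               O12 * sum(alpha) + O22 * sum(beta))
      mu <- as.numeric(mu_draw)

      ## 4. residual scale: truncated inverse-gamma from the U(0,100) prior
      ss <- sum((y - alpha[ci] - beta[ci] * t)^2)
      for (try in 1:100) {
        s2new <- (ss / 2) / stats::rgamma(1, (N - 1) / 2)
        if (sqrt(s2new) < sd_max) break
      }
      sigma <- min(sqrt(s2new), sd_max - 1e-9)
      sigma <- max(sigma, sd_floor)

      ## 5. random-effect scales and correlation: slice updates
      d1 <- alpha - mu[1]
      d2 <- beta - mu[2]
      S11 <- sum(d1^2); S22 <- sum(d2^2); S12 <- sum(d1 * d2)
      re_loglik <- function(ta, tb, r) {
        -C * (log(ta) + log(tb) + 0.5 * log1p(-r^2)) -
          (S11 / ta^2 - 2 * r * S12 / (ta * tb) + S22 / tb^2) /
          (2 * (1 - r^2))
      }
      tau_a <- slice_sample1(tau_a,
                             function(x) re_loglik(x, tau_b, rho),
                             w = max(tau_a / 2, 0.1),
                             lower = sd_floor, upper = sd_max)
      tau_b <- slice_sample1(tau_b,
                             function(x) re_loglik(tau_a, x, rho),
                             w = max(tau_b / 2, 0.01),
                             lower = sd_floor, upper = sd_max)
      rho <- slice_sample1(rho,
                           function(x) re_loglik(tau_a, tau_b, x),
                           w = 0.3, lower = -0.999, upper = 0.999)

      if (it > burnin) {
        k <- it - burnin
        hyper[k, ] <- c(mu, sigma, tau_a, tau_b, rho)
        alpha_d[k, ] <- alpha
        beta_d[k, ] <- beta
      }
    }
    list(hyper = hyper, alpha = alpha_d, beta = beta_d)
  }

  chains_out <- lapply(seq_len(chains), run_chain)

  hyper_by_chain <- lapply(chains_out, `[[`, "hyper")
  summ <- do.call(rbind, lapply(hyper_names, function(p) {
    summarize_posterior(lapply(hyper_by_chain, function(h) h[, p]), level,
                        name = p)
  }))

  ## derived endpoints: predicted usage at t = 0 and t = t_end, per draw
  first_by_chain <- lapply(chains_out, function(chn) rowMeans(chn$alpha))
  last_by_chain <- lapply(chains_out, function(chn)
    rowMeans(chn$alpha + chn$beta * t_end))
  derived <- rbind(
    summarize_posterior(first_by_chain, level, name = "mean_usage_first"),
    summarize_posterior(last_by_chain, level, name = "mean_usage_last"))

  alpha_all <- do.call(rbind, lapply(chains_out, `[[`, "alpha"))
  beta_all <- do.call(rbind, lapply(chains_out, `[[`, "beta"))
  ep_first <- alpha_all
  ep_last <- alpha_all + beta_all * t_end
  clip_n <- sum(ep_first < 0 | ep_first > 100) + sum(ep_last < 0 |
                                                       ep_last > 100)
  mk_ep <- function(m, when) {
    data.frame(country = countries, when = when,
               mean = pmin(pmax(colMeans(m), 0), 100),
               sd = apply(m, 2, stats::sd),
               lower = pmin(pmax(apply(m, 2, stats::quantile,
                                       (1 - level) / 2), 0), 100),
               upper = pmin(pmax(apply(m, 2, stats::quantile,
                                       1 - (1 - level) / 2), 0), 100),
               stringsAsFactors = FALSE)
  }
  endpoints <- rbind(mk_ep(ep_first, origin_year),
                     mk_ep(ep_last, origin_year + t_end))

  diag_draws <- lapply(chains_out, `[[`, "hyper")
  rhat <- gelman_rubin(diag_draws)
  converged <- all(rhat < rhat_threshold, na.rm = TRUE)
  if (!converged) {
    warning("convergence alarm: split-Rhat > ", rhat_threshold, " for ",
            paste(names(rhat)[rhat >= rhat_threshold], collapse = ", "))
  }

  structure(list(
    summary = summ, derived = derived, endpoints = endpoints,
    rhat = rhat,
    diagnostics = list(rhat = rhat, converged = converged,
                       threshold = rhat_threshold, chains = chains,
                       iter = iter, burnin = burnin, thin = 1, seed = seed,
                       clipped_predictions = clip_n),
    draws = list(hyper = hyper_by_chain, alpha = alpha_all,
                 beta = beta_all),
    countries = countries, origin_year = origin_year, t_end = t_end,
    data = data.frame(country = data$country, year = data$year,
                      min_use = L, max_use = U, stringsAsFactors = FALSE),
    settings = list(chains = chains, iter = iter, burnin = burnin,
                    seed = seed, level = level)),
    class = "usage_trend")
}

#' @export
print.usage_trend <- function(x, ...) {
  s <- x$summary
  g <- function(p, col) s[s$parameter == p, col]
  cat("Interval-censored hierarchical trend model\n")
  cat(sprintf("  %d countries, %d interval observations, years %d-%d\n",
              length(x$countries), nrow(x$data), x$origin_year,
              x$origin_year + x$t_end))
  cat(sprintf("  global slope (mu_beta): %.3f +/- %.3f %%/yr  [%.3f, %.3f]\n",
              g("mu_beta", "mean"), g("mu_beta", "sd"),
              g("mu_beta", "lower"), g("mu_beta", "upper")))
  d <- x$derived
  cat(sprintf("  mean usage %d: %.1f%% +/- %.1f   %d: %.1f%% +/- %.1f\n",
              x$origin_year, d$mean[1], d$sd[1], x$origin_year + x$t_end,
              d$mean[2], d$sd[2]))
  if (!x$diagnostics$converged) {
    cat("  WARNING: split-Rhat above", x$diagnostics$threshold,
        "- chains have not converged\n")
  }
  invisible(x)
}

#' Posterior summary table for a fitted trend model
#'
#' @param object a `usage_trend` fit.
#' @param ... unused.
#' @return data frame of hyperparameters and derived all-country endpoint
#'   means with posterior mean, sd, credible bounds, effective draws and
#'   split-\eqn{\hat R}.
#' @export
summary.usage_trend <- function(object, ...) {
  out <- rbind(object$summary, object$derived)
  out$rhat <- object$rhat[out$parameter]
  out
}

#' @export
coef.usage_trend <- function(object, ...) {
  stats::setNames(object$summary$mean, object$summary$parameter)
}

#' Posterior predicted usage for fitted countries
#'
#' Evaluates \eqn{\alpha_c + \beta_c (year - origin)} per retained draw and
#' summarizes. Point summaries are clipped to the percent scale `[0, 100]`
#' at report time.
#'
#' @param object a `usage_trend` fit.
#' @param newdata data frame with columns `country`, `year`; default: the
#'   first and last modelled year for every fitted country.
#' @param level credible level.
#' @param ... unused.
#' @return `newdata` with columns `mean`, `sd`, `lower`, `upper` appended.
#' @export
predict.usage_trend <- function(object, newdata = NULL, level = 0.95, ...) {
  if (is.null(newdata)) {
    newdata <- expand.grid(country = object$countries,
                           year = object$origin_year + c(0, object$t_end),
                           stringsAsFactors = FALSE)
  }
  k <- match(newdata$country, object$countries)
  if (anyNA(k)) {
    stop("country not in fitted model: ",
         paste(unique(newdata$country[is.na(k)]), collapse = ", "))
  }
  tt <- newdata$year - object$origin_year
  a <- (1 - level) / 2
  stats_m <- vapply(seq_len(nrow(newdata)), function(i) {
    dr <- object$draws$alpha[, k[i]] + object$draws$beta[, k[i]] * tt[i]
    c(mean(dr), stats::sd(dr), stats::quantile(dr, c(a, 1 - a)))
  }, numeric(4))
  newdata$mean <- pmin(pmax(stats_m[1, ], 0), 100)
  newdata$sd <- stats_m[2, ]
  newdata$lower <- pmin(pmax(stats_m[3, ], 0), 100)
  newdata$upper <- pmin(pmax(stats_m[4, ], 0), 100)
  newdata
}

#' @export
fitted.usage_trend <- function(object, ...) {
  k <- match(object$data$country, object$countries)
  tt <- object$data$year - object$origin_year
  am <- colMeans(object$draws$alpha)
  bm <- colMeans(object$draws$beta)
  am[k] + bm[k] * tt
}

#' @export
residuals.usage_trend <- function(object, ...) {
  ## residuals relative to interval midpoints (the data are intervals)
  (object$data$min_use + object$data$max_use) / 2 - fitted(object)
}

#' Trajectories and global trend of a fitted usage model
#'
#' Draws each country's observed interval midpoints as grey lines and
#' overlays the posterior mean global trajectory
#' \eqn{\mu_\alpha + \mu_\beta t} with its credible ribbon.
#'
#' @param x a `usage_trend` fit.
#' @param level credible level for the ribbon.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.usage_trend <- function(x, level = 0.95, ...) {
  d <- x$data
  yrs <- sort(unique(d$year))
  graphics::plot(NA, xlim = range(yrs), ylim = c(0, 100), xlab = "year",
                 ylab = "foreign crop use (%)", ...)
  for (ct in x$countries) {
    i <- d$country == ct
    graphics::lines(d$year[i], (d$min_use[i] + d$max_use[i]) / 2,
                    col = grDevices::adjustcolor("grey40", 0.4))
  }
  tt <- yrs - x$origin_year
  hyper <- do.call(rbind, x$draws$hyper)
  a <- (1 - level) / 2
  traj <- vapply(tt, function(z) {
    dr <- hyper[, "mu_alpha"] + hyper[, "mu_beta"] * z
    c(mean(dr), stats::quantile(dr, c(a, 1 - a)))
  }, numeric(3))
  graphics::polygon(c(yrs, rev(yrs)), c(traj[2, ], rev(traj[3, ])),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(yrs, traj[1, ], col = "steelblue", lwd = 2)
  invisible(x)
}
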