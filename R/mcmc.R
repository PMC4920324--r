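## Sampling primitives shared by the interval-censored models.

## Vectorized truncated-normal draw by inverse-CDF. Bounds here are the
## observation intervals (percent scale), so extreme-tail pathologies are
## mild; probabilities are clamped away from 0/1 and results clamped into
## the interval to be safe. Zero-width intervals return the bound exactly.
rtruncnorm_vec <- function(mean, sd, lower, upper) {
  n <- length(mean)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- plo + stats::runif(n) * (phi - plo)
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  x <- stats::qnorm(u, mean, sd)
  x <- pmin(pmax(x, lower), upper)
  fixed <- upper - lower <= 0
  x[fixed] <- lower[fixed]
  x
}

## Univariate slice sampler (stepping-out + shrinkage; Neal 2003) for the
## non-conjugate scale/correlation updates. logf must be finite at x0.
slice_sample1 <- function(x0, logf, w = 0.5, lower = -Inf, upper = Inf,
                          max_steps = 50) {
  ly <- logf(x0) + log(stats::runif(1))
  u <- stats::runif(1)
  L <- max(x0 - w * u, lower)
  R <- min(L + w, upper)
  j <- floor(stats::runif(1) * max_steps)
  k <- max_steps - 1 - j
  while (j > 0 && L > lower && logf(L) > ly) {
    L <- max(L - w, lower); j <- j - 1
  }
  while (k > 0 && R < upper && logf(R) > ly) {
    R <- min(R + w, upper); k <- k - 1
  }
  repeat {
    x1 <- stats::runif(1, L, R)
    if (logf(x1) >= ly) return(x1)
    if (x1 < x0) L <- x1 else R <- x1
    if (R - L < 1e-12) return(x0)
  }
}

## Draw from a bivariate normal given 2x2 precision P and b = P %*% mean,
## vectorized over rows (each row one unit). Returns cbind(x1, x2).
rbvn_prec_vec <- function(P11, P12, P22, b1, b2) {
  det <- P11 * P22 - P12^2
  s11 <- P22 / det
  s22 <- P11 / det
  s12 <- -P12 / det
  m1 <- s11 * b1 + s12 * b2
  m2 <- s12 * b1 + s22 * b2
  l11 <- sqrt(s11)
  l21 <- s12 / l11
  l22 <- sqrt(pmax(s22 - l21^2, 1e-300))
  z1 <- stats::rnorm(length(m1))
  z2 <- stats::rnorm(length(m1))
  cbind(m1 + l11 * z1, m2 + l21 * z1 + l22 * z2)
}

#' Gelman-Rubin potential scale reduction statistic
#'
#' Split-\eqn{\hat R}: each chain is halved, and the usual
#' between/within-chain variance ratio is computed over the resulting
#' 2m half-chains. Values near 1 indicate the chains have mixed; the
#' conventional alarm threshold is 1.1. Estimates below 1 can only arise
#' from Monte-Carlo noise and are reported as exactly 1.
#'
#' @param chains a list of numeric vectors (one parameter), a list of equal
#'   size matrices (iterations x parameters), or a 3-d array
#'   (iterations x chains x parameters).
#' @return named numeric vector of \eqn{\hat R} values, one per parameter.
#' @examples
#' set.seed(1)
#' gelman_rubin(list(rnorm(200), rnorm(200)))          # ~1: mixed
#' gelman_rubin(list(rnorm(200), rnorm(200, 10)))      # >> 1.1: divergent
#' @export
gelman_rubin <- function(chains) {
  if (is.array(chains) && length(dim(chains)) == 3) {
    chains <- lapply(seq_len(dim(chains)[2]), function(j) chains[, j, ])
  }
  if (!is.list(chains) || length(chains) < 2) {
    stop("need at least 2 chains")
  }
  chains <- lapply(chains, function(ch) {
    if (is.null(dim(ch))) matrix(ch, ncol = 1) else as.matrix(ch)
  })
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1) stop("chains must have equal length")
  if (n < 10) stop("chains too short (need >= 10 iterations)")
  p <- ncol(chains[[1]])

  half <- floor(n / 2)
  splits <- list()
  for (ch in chains) {
    splits <- c(splits, list(ch[seq_len(half), , drop = FALSE],
                             ch[(n - half + 1):n, , drop = FALSE]))
  }
  m <- length(splits)
  rhat <- numeric(p)
  for (j in seq_len(p)) {
    means <- vapply(splits, function(s) mean(s[, j]), numeric(1))
    vars <- vapply(splits, function(s) stats::var(s[, j]), numeric(1))
    W <- mean(vars)
    B <- half * stats::var(means)
    if (W <= 0) {
      rhat[j] <- if (B <= 0) 1 else Inf
    } else {
      ## values below 1 are Monte-Carlo noise; report the floor
      rhat[j] <- max(1, sqrt(((half - 1) / half * W + B / half) / W))
    }
  }
  names(rhat) <- colnames(chains[[1]])
  rhat
}

## Effective sample size via Geyer's initial monotone positive sequence on
## the chain-averaged autocorrelations.
ess <- function(draws_by_chain) {
  chains <- lapply(draws_by_chain, as.numeric)
  n <- length(chains[[1]])
  m <- length(chains)
  if (n < 4) return(n * m)
  maxlag <- min(n - 2, 500)
  acfs <- vapply(chains, function(x) {
    if (stats::sd(x) == 0) return(rep(0, maxlag + 1))
    as.numeric(stats::acf(x, lag.max = maxlag, plot = FALSE,
                          demean = TRUE)$acf)
  }, numeric(maxlag + 1))
  rho <- rowMeans(acfs)
  ## sum consecutive pairs while positive and non-increasing
  s <- 0
  prev <- Inf
  k <- 2
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair < 0) break
    pair <- min(pair, prev)
    s <- s + pair
    prev <- pair
    k <- k + 2
  }
  max(1, round(n * m / (1 + 2 * s)))
}

#' Summarize posterior draws
#'
#' Posterior mean, standard deviation, a central credible interval, and an
#' autocorrelation-adjusted effective draw count.
#'
#' @param draws numeric vector of retained draws, or a list of per-chain
#'   vectors (used for the effective-size calculation).
#' @param level credible level (default 0.95).
#' @param name optional parameter name.
#' @return one-row data frame: `parameter`, `mean`, `sd`, `lower`, `upper`,
#'   `n_eff`.
#' @export
summarize_posterior <- function(draws, level = 0.95, name = "parameter") {
  by_chain <- if (is.list(draws)) draws else list(draws)
  all <- unlist(by_chain, use.names = FALSE)
  if (length(all) < 100) stop("need at least 100 retained draws")
  a <- (1 - level) / 2
  q <- as.numeric(stats::quantile(all, c(a, 1 - a)))
  data.frame(parameter = name, mean = mean(all), sd = stats::sd(all),
             lower = q[1], upper = q[2], n_eff = ess(by_chain),
             stringsAsFactors = FALSE)
}
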