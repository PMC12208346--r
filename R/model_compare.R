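# Generalized-Pareto fit to exceedances by the Zhang & Stephens (2009)
# profile-likelihood method, with the weak prior regularisation of the
# shape that standard PSIS practice applies at small tail sizes.
gpd_fit <- function(x) {
  x <- sort(x)
  n <- length(x)
  m <- 30L + floor(sqrt(n))
  jj <- seq_len(m) - 0.5
  xstar <- x[max(1L, floor(n / 4 + 0.5))]
  theta <- 1 / x[n] + (1 - sqrt(m / jj)) / (3 * xstar)
  k_of <- function(th) mean(log1p(-th * x))
  ll <- vapply(theta, function(th) {
    k <- k_of(th)
    n * (log(-th / k) - k - 1)
  }, numeric(1))
  w <- 1 / vapply(seq_len(m), function(j) sum(exp(ll - ll[j])), numeric(1))
  theta_hat <- sum(theta * w)
  k <- k_of(theta_hat)
  sigma <- -k / theta_hat
  k <- (n * k + 10 * 0.5) / (n + 10)   # weak prior pulls the shape toward 0.5
  list(k = k, sigma = sigma)
}

qgpd <- function(p, k, sigma) {
  if (abs(k) < 1e-12) return(-sigma * log1p(-p))
  sigma * expm1(-k * log1p(-p)) / k
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

psis_smooth_lw <- function(lw) {
  S <- length(lw)
  lw <- lw - max(lw)
  M <- ceiling(0.2 * S)
  ord <- order(lw)
  tail_ids <- ord[(S - M + 1L):S]
  cut_lw <- lw[ord[S - M]]
  exceed <- exp(lw[tail_ids]) - exp(cut_lw)
  khat <- Inf
  if (length(unique(exceed)) >= 5L && any(exceed > 0)) {
    fit <- gpd_fit(exceed[exceed > 0])
    khat <- fit$k
    if (is.finite(khat)) {
      p <- (rank(lw[tail_ids], ties.method = "first") - 0.5) / M
      smoothed <- log(exp(cut_lw) + qgpd(p, fit$k, fit$sigma))
      lw[tail_ids] <- pmin(smoothed, 0)  # never exceed the raw maximum
    }
  } else {
    khat <- -Inf   # (near-)constant tail: nothing to smooth
  }
  list(lw = lw - log_sum_exp(lw), khat = khat)
}

#' Pareto-smoothed importance-sampling leave-one-out cross-validation
#'
#' Estimates the expected log pointwise predictive density (elpd) from the
#' posterior draws of a fitted model. For each observation the importance
#' ratios `1 / p(y_i | theta_s)` are stabilised by fitting a generalized
#' Pareto distribution to the largest 20% of ratios and replacing them with
#' their expected order statistics (capped at the raw maximum); the
#' observation's elpd contribution is the log of the smoothed-weighted mean
#' predictive density. Observations with Pareto shape `k > 0.7` trigger a
#' reliability warning.
#'
#' @param log_lik S x N pointwise log-likelihood matrix (draws x
#'   observations), e.g. from [pointwise_log_likelihood()], or an
#'   `affect_fit`.
#' @param k_threshold Pareto-shape warning threshold (default 0.7).
#' @return Object of class `loo_estimate`: `elpd`, its standard error `se`,
#'   the `pointwise` contributions, and `pareto_k` per observation.
#' @export
psis_loo <- function(log_lik, k_threshold = 0.7) {
  if (inherits(log_lik, "affect_fit")) log_lik <- pointwise_log_likelihood(log_lik)
  log_lik <- as.matrix(log_lik)
  if (!all(is.finite(log_lik))) stop("log-likelihood matrix must be finite")
  S <- nrow(log_lik)
  if (S < 100L) stop("need at least 100 draws for PSIS (have ", S, ")")
  N <- ncol(log_lik)
  pointwise <- numeric(N)
  pareto_k <- numeric(N)
  for (i in seq_len(N)) {
    sm <- psis_smooth_lw(-log_lik[, i])
    pointwise[i] <- log_sum_exp(sm$lw + log_lik[, i])
    pareto_k[i] <- sm$khat
  }
  n_bad <- sum(is.finite(pareto_k) & pareto_k > k_threshold)
  if (n_bad > 0) {
    warning(n_bad, " observation(s) with Pareto k > ", k_threshold,
            "; PSIS-LOO estimate may be unreliable for them", call. = FALSE)
  }
  structure(list(elpd = sum(pointwise),
                 se = sqrt(N * stats::var(pointwise)),
                 pointwise = pointwise, pareto_k = pareto_k),
            class = "loo_estimate")
}

#' @export
print.loo_estimate <- function(x, ...) {
  cat(sprintf("PSIS-LOO elpd: %.2f (se %.2f) over %d observations\n",
              x$elpd, x$se, length(x$pointwise)))
  cat(sprintf("Pareto k: max %.2f, %d > 0.7\n",
              suppressWarnings(max(x$pareto_k[is.finite(x$pareto_k)], -Inf)),
              sum(is.finite(x$pareto_k) & x$pareto_k > 0.7)))
  invisible(x)
}

#' Differences in elpd from the best model
#'
#' @param loos List of `loo_estimate` objects on identical observations.
#' @return Numeric vector (named like `loos`): 0 for the best model,
#'   `elpd - max(elpd)` (non-positive) for the rest.
#' @export
delta_elpd <- function(loos) {
  if (inherits(loos, "loo_estimate")) loos <- list(loos)
  stopifnot(length(loos) >= 1L,
            all(vapply(loos, inherits, logical(1), "loo_estimate")))
  ns <- vapply(loos, function(l) length(l$pointwise), integer(1))
  if (length(unique(ns)) != 1L) {
    stop("models were evaluated on different numbers of observations")
  }
  elpds <- vapply(loos, `[[`, numeric(1), "elpd")
  elpds - max(elpds)
}

#' Classify models by their elpd deficit
#'
#' Models within 2 elpd of the best are `"strong"`, models more than 10
#' behind are `"poor"`, the rest `"intermediate"`.
#'
#' @param deltas Non-positive vector from [delta_elpd()].
#' @return Character vector of labels.
#' @export
classify_models <- function(deltas) {
  stopifnot(all(deltas <= 0))
  ifelse(deltas > -2, "strong", ifelse(deltas < -10, "poor", "intermediate"))
}

#' Bayesian stacking weights of predictive distributions
#'
#' Finds the simplex weights maximising the pooled leave-one-out log score
#' `sum_i log sum_k w_k exp(lpd[i, k])` (a concave problem, solved by
#' quasi-Newton ascent on a softmax parametrisation from a uniform start, so
#' flat optima return the symmetric solution). The `"mse"` method instead
#' minimises the leave-one-out mean squared error of the stacked point
#' predictions and requires `mu` and `y`.
#'
#' @param lpd N x K matrix of pointwise elpd contributions per model
#'   (columns), e.g. `cbind(loo_a$pointwise, loo_b$pointwise)`.
#' @param method `"log"` (default, stacking of predictive distributions) or
#'   `"mse"`.
#' @param mu N x K matrix of leave-one-out predictive means (only for
#'   `"mse"`).
#' @param y Length-N outcome vector (only for `"mse"`).
#' @return Object of class `stacking_result` with `weights` (non-negative,
#'   summing to 1) and the attained objective `value`.
#' @export
stacking_weights <- function(lpd, method = c("log", "mse"), mu = NULL, y = NULL) {
  method <- match.arg(method)
  lpd <- as.matrix(lpd)
  K <- ncol(lpd)
  stopifnot(K >= 2L)
  if (method == "log") {
    obj <- function(alpha) {
      w <- softmax(c(0, alpha))
      -sum(apply(lpd, 1, function(r) log_sum_exp(log(w) + r)))
    }
    grad <- function(alpha) {
      w <- softmax(c(0, alpha))
      p <- exp(lpd - apply(lpd, 1, max))
      num <- p %*% w
      dw <- -colSums(p / as.numeric(num))          # d(-obj)/dw
      g <- w * (dw - sum(w * dw))                  # chain rule through softmax
      g[-1]
    }
  } else {
    if (is.null(mu) || is.null(y)) stop("method 'mse' needs `mu` and `y`")
    mu <- as.matrix(mu)
    stopifnot(ncol(mu) == K, length(y) == nrow(mu))
    obj <- function(alpha) {
      w <- softmax(c(0, alpha))
      mean((y - mu %*% w)^2)
    }
    grad <- function(alpha) {
      w <- softmax(c(0, alpha))
      r <- as.numeric(mu %*% w - y)
      dw <- 2 * colMeans(mu * r)
      g <- w * (dw - sum(w * dw))
      g[-1]
    }
  }
  # boundary solutions (a weight of exactly 0) sit at alpha -> -Inf; the
  # box keeps the search finite (exp(-30) is zero at double precision)
  opt <- stats::optim(rep(0, K - 1L), obj, grad, method = "L-BFGS-B",
                      lower = -30, upper = 30,
                      control = list(maxit = 1000, factr = 1e4))
  if (opt$convergence != 0) {
    stop("stacking optimisation did not converge: code ", opt$convergence,
         " (", opt$message, ")")
  }
  w <- softmax(c(0, opt$par))
  names(w) <- colnames(lpd)
  structure(list(weights = w, value = if (method == "log") -opt$value else opt$value,
                 method = method),
            class = "stacking_result")
}

softmax <- function(a) {
  e <- exp(a - max(a))
  e / sum(e)
}

#' @export
print.stacking_result <- function(x, ...) {
  cat("Bayesian stacking weights (", x$method, " score):\n", sep = "")
  print(round(x$weights, 3))
  invisible(x)
}

#' Compare a set of fitted candidate models
#'
#' Runs PSIS-LOO on each fit, computes stacking weights, elpd deficits,
#' strong/poor classification and marginal/conditional Bayesian R-squared,
#' mirroring the usual model-comparison report table.
#'
#' @param fits Named list of `affect_fit` objects fitted to the same
#'   observations.
#' @return List with `table` (one row per model: stacking weight, delta
#'   elpd, classification, R-squared summaries) and the underlying `loos`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 2L,
            all(vapply(fits, inherits, logical(1), "affect_fit")))
  if (is.null(names(fits))) {
    names(fits) <- vapply(fits, function(f) f$spec$variant, character(1))
  }
  loos <- lapply(fits, psis_loo)
  deltas <- delta_elpd(loos)
  lpd <- do.call(cbind, lapply(loos, `[[`, "pointwise"))
  colnames(lpd) <- names(fits)
  w <- stacking_weights(lpd)$weights
  fmt_r2 <- function(r2) sprintf("%.2f [%.2f, %.2f]", r2$mean, r2$ci_low, r2$ci_high)
  tab <- data.frame(
    model = names(fits),
    stacking_weight = as.numeric(w),
    delta_elpd = as.numeric(deltas),
    classification = classify_models(deltas),
    elpd = vapply(loos, `[[`, numeric(1), "elpd"),
    elpd_se = vapply(loos, `[[`, numeric(1), "se"),
    r2_conditional = vapply(fits, function(f) fmt_r2(bayes_r2(f, "conditional")), character(1)),
    r2_marginal = vapply(fits, function(f) fmt_r2(bayes_r2(f, "marginal")), character(1)),
    row.names = NULL)
  list(table = tab, loos = loos)
}
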