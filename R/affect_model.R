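AFFECT_OUTCOMES <- c("hap", "lap", "hana", "lana")

#' MCMC sampler settings
#'
#' Desk defaults (4 chains, 500 warmup + 500 sampling draws per chain) keep
#' fits in the seconds range; the study-scale configuration (8 chains, 1000
#' warmup, 5000 sampling, 40 000 post-warmup draws) is available by passing
#' the corresponding values.
#'
#' @param chains Number of chains.
#' @param warmup Warmup (adaptation + burn-in) iterations per chain.
#' @param sampling Saved post-warmup iterations per chain.
#' @return List with class `mcmc_control`; `$total_draws` is
#'   `chains * sampling`.
#' @export
mcmc_control <- function(chains = 4, warmup = 500, sampling = 500) {
  stopifnot(chains >= 1, warmup >= 0, sampling >= 1)
  structure(list(chains = as.integer(chains), warmup = as.integer(warmup),
                 sampling = as.integer(sampling),
                 total_draws = as.integer(chains * sampling)),
            class = "mcmc_control")
}

#' Weakly informative prior settings
#'
#' Scales are resolved against the observed data at fit time: regression
#' coefficients get Normal(0, (`beta_scale_mult` * sd(y)/sd(x_j))^2), the
#' intercept a Student-t(`intercept_df`, median(y), `intercept_scale_mult` *
#' mad(y)), residual and group standard deviations half-Student-t(`sd_df`,
#' 0, `sd_scale_mult` * sd(y)). The covariance of correlated random effects
#' gets an inverse-Wishart prior with identity-times-sd(y)^2 scale and
#' dimension + 1 degrees of freedom (heavy-tailed, weakly informative).
#'
#' @param beta_scale_mult Multiplier for coefficient prior SDs.
#' @param intercept_df,intercept_scale_mult Intercept Student-t settings.
#' @param sd_df,sd_scale_mult Half-t settings for scale parameters.
#' @return List with class `prior_spec`.
#' @export
prior_spec <- function(beta_scale_mult = 5, intercept_df = 3,
                       intercept_scale_mult = 2.5, sd_df = 3,
                       sd_scale_mult = 2.5) {
  stopifnot(beta_scale_mult > 0, intercept_df > 0, intercept_scale_mult > 0,
            sd_df > 0, sd_scale_mult > 0)
  structure(list(beta_scale_mult = beta_scale_mult,
                 intercept_df = intercept_df,
                 intercept_scale_mult = intercept_scale_mult,
                 sd_df = sd_df, sd_scale_mult = sd_scale_mult),
            class = "prior_spec")
}

#' Specify one of the four candidate affect models
#'
#' The candidate set, shared across all four affect outcomes:
#' * `"a"` — covariates only, random person intercept;
#' * `"b"` — model a + the 3 between-person ilr coordinates;
#' * `"c"` — model a + the 3 within-person ilr coordinates, with correlated
#'   random slopes on the within coordinates;
#' * `"d"` — model a + both coordinate sets, with the variant-c random
#'   structure.
#'
#' All variants adjust for time in bed, the matched previous-night pre-sleep
#' affect, weekend, circadian misalignment (`cpd`), age, gender, ethnicity,
#' subjective social status and BMI.
#'
#' @param outcome One of `"hap"`, `"lap"`, `"hana"`, `"lana"`.
#' @param variant One of `"a"`, `"b"`, `"c"`, `"d"`.
#' @param include_tib_interaction Add time-in-bed-by-composition interaction
#'   columns (used to test moderation by sleep opportunity)?
#' @param covariates Covariate column names; the pre-sleep score matched to
#'   `outcome` is added automatically.
#' @param priors A [prior_spec()].
#' @param mcmc An [mcmc_control()].
#' @return List with class `model_spec`.
#' @export
model_spec <- function(outcome = c("hap", "lap", "hana", "lana"),
                       variant = c("a", "b", "c", "d"),
                       include_tib_interaction = FALSE,
                       covariates = c("tib_min", "weekend", "cpd", "age",
                                      "gender", "ethnicity", "sss", "bmi"),
                       priors = prior_spec(),
                       mcmc = mcmc_control()) {
  outcome <- match.arg(outcome)
  variant <- match.arg(variant)
  structure(list(outcome = outcome, variant = variant,
                 include_tib_interaction = isTRUE(include_tib_interaction),
                 covariates = covariates, priors = priors, mcmc = mcmc),
            class = "model_spec")
}

ilr_cols_for_variant <- function(variant) {
  list(between = if (variant %in% c("b", "d")) paste0("b", 1:3) else character(),
       within  = if (variant %in% c("c", "d")) paste0("w", 1:3) else character())
}

#' Build the fixed- and random-effects design for a model specification
#'
#' Rows with a missing outcome or missing covariates are dropped
#' (complete-case, per outcome). Numeric covariates are mean-centred (the
#' centres are returned so new rows can be placed on the same scale);
#' categorical covariates enter as dummy indicators against their most
#' frequent level. When `include_tib_interaction` is set, products of
#' centred time in bed with every ilr column are appended.
#'
#' @param data A decomposed table from [decompose_bw()].
#' @param spec A [model_spec()].
#' @return List with the fixed design `X`, random design `Z` (intercept, plus
#'   the within-person ilr columns for variants c/d), outcome `y`, person
#'   index `group`, person labels `persons`, and metadata (`centers`,
#'   `factor_levels`, column roles).
#' @export
build_design <- function(data, spec) {
  stopifnot(inherits(spec, "model_spec"))
  ilr_cols <- ilr_cols_for_variant(spec$variant)
  need_ilr <- c(ilr_cols$between, ilr_cols$within)
  if (length(need_ilr) && !all(need_ilr %in% names(data))) {
    stop("data lacks ilr coordinate columns; run decompose_bw() first")
  }
  presleep <- paste0("presleep_", spec$outcome)
  covs <- unique(c(spec$covariates, presleep))
  missing_cols <- setdiff(c(spec$outcome, covs), names(data))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(data[, c(spec$outcome, covs, need_ilr)])
  df <- data[keep, , drop = FALSE]
  if (nrow(df) < 10L) stop("too few complete rows to fit (", nrow(df), ")")

  is_cat <- vapply(covs, function(v) is.character(df[[v]]) || is.factor(df[[v]]),
                   logical(1))
  is_bin <- vapply(covs, function(v) !is_cat[v] && all(df[[v]] %in% c(0, 1)),
                   logical(1))
  centers <- numeric(0)
  factor_levels <- list()
  cols <- list(`(Intercept)` = rep(1, nrow(df)))
  for (cc in c(ilr_cols$between, ilr_cols$within)) cols[[cc]] <- df[[cc]]
  for (v in covs) {
    if (is_cat[v]) {
      f <- as.factor(df[[v]])
      if (nlevels(f) < 2L) stop("constant column: ", v)
      ref <- names(sort(table(f), decreasing = TRUE))[1]
      f <- stats::relevel(f, ref = ref)
      factor_levels[[v]] <- levels(f)
      for (lev in levels(f)[-1]) cols[[paste0(v, lev)]] <- as.numeric(f == lev)
    } else if (is_bin[v]) {
      cols[[v]] <- df[[v]]
    } else {
      centers[v] <- mean(df[[v]])
      cols[[v]] <- df[[v]] - centers[v]
    }
  }
  interaction_cols <- character()
  if (spec$include_tib_interaction) {
    if (!length(need_ilr)) {
      stop("tib interaction requested but the variant has no ilr columns")
    }
    tib_c <- df$tib_min - centers["tib_min"]
    for (cc in need_ilr) {
      nm <- paste0("tib_min:", cc)
      cols[[nm]] <- tib_c * df[[cc]]
      interaction_cols <- c(interaction_cols, nm)
    }
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  sds <- apply(X[, -1, drop = FALSE], 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant column: ", paste(names(sds)[sds == 0], collapse = ", "))
  }
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dep <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    stop("rank-deficient design; offending column(s): ",
         paste(dep, collapse = ", "))
  }
  Z <- if (length(ilr_cols$within)) {
    cbind(`(Intercept)` = 1, as.matrix(df[, ilr_cols$within, drop = FALSE]))
  } else {
    matrix(1, nrow(df), 1, dimnames = list(NULL, "(Intercept)"))
  }
  persons <- unique(df$id)
  list(X = X, Z = Z, y = df[[spec$outcome]],
       group = match(df$id, persons), persons = persons,
       centers = centers, factor_levels = factor_levels,
       between_cols = ilr_cols$between, within_cols = ilr_cols$within,
       interaction_cols = interaction_cols,
       rows = df[, c("id", "day")])
}

jags_model_string <- function(Q) {
  random_block <- if (Q == 1L) {
    "  for (j in 1:J) { u[j,1] ~ dnorm(0, tau_u) }
  tau_u <- pow(sd_u, -2)
  sd_u ~ dt(0, prec_sd, sd_df) T(0,)"
  } else {
    "  for (j in 1:J) { u[j,1:Q] ~ dmnorm(zeroQ[1:Q], Omega[1:Q,1:Q]) }
  Omega[1:Q,1:Q] ~ dwish(RQ[1:Q,1:Q], Q + 1)
  Sigma_u[1:Q,1:Q] <- inverse(Omega[1:Q,1:Q])"
  }
  paste0("model {
  for (i in 1:N) {
    mu[i] <- inprod(X[i,], beta) + inprod(Z[i,], u[g[i],])
    y[i] ~ dnorm(mu[i], tau)
  }
", random_block, "
  # Student-t intercept prior as a normal-gamma scale mixture: keeps the
  # fixed-effect block conjugate so the glm module can sample it jointly.
  beta[1] ~ dnorm(int_loc, int_prec * lambda_int)
  lambda_int ~ dgamma(int_df / 2, int_df / 2)
  for (p in 2:P) { beta[p] ~ dnorm(0, prec_beta[p]) }
  tau <- pow(sigma, -2)
  sigma ~ dt(0, prec_sd, sd_df) T(0,)
}
")
}

#' Fit a Bayesian multilevel affect model by MCMC
#'
#' Gaussian likelihood with identity link; person random intercept (variants
#' a/b) or correlated random intercept + within-composition slopes (variants
#' c/d). Sampling runs in JAGS with block updating; priors are resolved from
#' the [prior_spec()] against the observed outcome and design scales.
#' Convergence is summarised per monitored parameter by the potential
#' scale-reduction factor and effective sample size; the fit is flagged
#' `converged` iff max R-hat < 1.05 and min ESS > 400. A non-converged fit
#' is returned (never silently discarded) with a warning.
#'
#' @param data A decomposed table from [decompose_bw()].
#' @param spec A [model_spec()].
#' @param seed Integer seed; the same data, spec and seed reproduce the
#'   draws exactly.
#' @return An object of class `affect_fit`: posterior draws (`beta` with one
#'   named column per fixed effect, person effects `u`, residual `sigma`),
#'   the design, per-parameter diagnostics, and the convergence flag.
#' @export
fit_affect_model <- function(data, spec, seed = 1L) {
  stopifnot(inherits(spec, "model_spec"))
  des <- build_design(data, spec)
  y <- des$y
  X <- des$X
  Z <- des$Z
  Q <- ncol(Z)
  P <- ncol(X)
  pr <- spec$priors
  sd_y <- stats::sd(y)
  if (!is.finite(sd_y) || sd_y == 0) sd_y <- 1
  sd_x <- apply(X, 2, stats::sd)
  prec_beta <- 1 / (pr$beta_scale_mult * sd_y / pmax(sd_x, 1e-12))^2
  prec_beta[1] <- NA_real_  # intercept has its own prior
  mad_y <- stats::mad(y)
  if (!is.finite(mad_y) || mad_y == 0) mad_y <- sd_y
  jdata <- list(y = y, X = X, Z = Z, g = des$group, N = length(y),
                J = length(des$persons), P = P,
                prec_beta = prec_beta,
                int_loc = stats::median(y),
                int_prec = 1 / (pr$intercept_scale_mult * mad_y)^2,
                int_df = pr$intercept_df,
                prec_sd = 1 / (pr$sd_scale_mult * sd_y)^2,
                sd_df = pr$sd_df)
  if (Q > 1L) {
    jdata$Q <- Q
    jdata$zeroQ <- rep(0, Q)
    jdata$RQ <- diag(sd_y^2, Q)
  }
  mc <- spec$mcmc
  inits <- lapply(seq_len(mc$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = (as.integer(seed) %% 100000L) * 1000L + ch)
  })
  rjags::load.module("glm", quiet = TRUE)
  jm <- rjags::jags.model(textConnection(jags_model_string(Q)), data = jdata,
                          inits = inits, n.chains = mc$chains, quiet = TRUE)
  if (mc$warmup > 0) stats::update(jm, mc$warmup, progress.bar = "none")
  monitors <- c("beta", "sigma", if (Q == 1L) "sd_u" else "Sigma_u", "u")
  samp <- rjags::coda.samples(jm, monitors, mc$sampling, progress.bar = "none")

  vnames <- colnames(samp[[1]])
  M <- do.call(rbind, lapply(samp, as.matrix))
  beta_idx <- grep("^beta\\[", vnames)
  beta <- M[, beta_idx, drop = FALSE]
  colnames(beta) <- colnames(X)
  sigma <- M[, vnames == "sigma"]
  S <- nrow(M)
  J <- length(des$persons)
  u <- array(0, dim = c(S, J, Q))
  for (j in seq_len(J)) {
    for (q in seq_len(Q)) {
      u[, j, q] <- M[, vnames == sprintf("u[%d,%d]", j, q)]
    }
  }
  sd_u <- if (Q == 1L) {
    matrix(M[, vnames == "sd_u"], ncol = 1,
           dimnames = list(NULL, colnames(Z)))
  } else {
    out <- sapply(seq_len(Q), function(q) sqrt(M[, vnames == sprintf("Sigma_u[%d,%d]", q, q)]))
    colnames(out) <- colnames(Z)
    out
  }

  # diagnostics on the structural parameters (fixed effects + scales)
  diag_names <- c(vnames[beta_idx], "sigma",
                  if (Q == 1L) "sd_u" else sprintf("Sigma_u[%d,%d]", 1:Q, 1:Q))
  sub <- samp[, diag_names, drop = FALSE]
  rhat <- tryCatch(
    coda::gelman.diag(sub, autoburnin = FALSE, multivariate = FALSE)$psrf[, 1],
    error = function(e) rep(NA_real_, length(diag_names)))
  ess <- coda::effectiveSize(sub)
  pretty <- c(colnames(X), "sigma", paste0("sd_u.", colnames(Z))[seq_len(
    if (Q == 1L) 1L else Q)])
  diagnostics <- data.frame(parameter = pretty, rhat = as.numeric(rhat),
                            ess = as.numeric(ess[diag_names]),
                            row.names = NULL)
  converged <- all(is.finite(diagnostics$rhat)) &&
    max(diagnostics$rhat) < 1.05 && min(diagnostics$ess) > 400
  if (!converged) {
    warning("fit did not meet convergence gates (max R-hat ",
            sprintf("%.3f", suppressWarnings(max(diagnostics$rhat))),
            ", min ESS ", sprintf("%.0f", min(diagnostics$ess)),
            "); inspect $diagnostics", call. = FALSE)
  }
  structure(list(spec = spec, design = des,
                 draws = list(beta = beta, u = u, sigma = sigma, sd_u = sd_u),
                 diagnostics = diagnostics, converged = converged,
                 sd_y = stats::sd(y), seed = as.integer(seed),
                 data_hash = sum(abs(y)) + sum(abs(X)),
                 basis = attr(data, "basis")),
            class = "affect_fit")
}

#' @export
print.affect_fit <- function(x, ...) {
  cat("Bayesian multilevel affect model (variant ", x$spec$variant, ", outcome ",
      x$spec$outcome, ")\n", sep = "")
  cat(nrow(x$draws$beta), "post-warmup draws;",
      length(x$design$persons), "persons;", length(x$design$y), "nights\n")
  cat("converged:", x$converged,
      sprintf("(max R-hat %.3f, min ESS %.0f)\n",
              max(x$diagnostics$rhat), min(x$diagnostics$ess)))
  est <- cbind(mean = colMeans(x$draws$beta),
               t(apply(x$draws$beta, 2, stats::quantile, c(0.025, 0.975))))
  print(round(est, 3))
  invisible(x)
}

random_effect_contribution <- function(fit, rows = NULL) {
  Z <- fit$design$Z
  g <- fit$design$group
  if (!is.null(rows)) {
    Z <- Z[rows, , drop = FALSE]
    g <- g[rows]
  }
  S <- dim(fit$draws$u)[1]
  out <- matrix(0, S, length(g))
  for (q in seq_len(ncol(Z))) {
    out <- out + fit$draws$u[, g, q, drop = TRUE] *
      matrix(Z[, q], S, length(g), byrow = TRUE)
  }
  out
}

#' Posterior draws of the expected outcome
#'
#' Evaluates the linear predictor on new design rows for every posterior
#' draw. Population level by default (random effects at their zero mean);
#' with `include_person_effects = TRUE` and `newdata = NULL` the fitted
#' person effects of the training rows are added.
#'
#' @param fit An `affect_fit`.
#' @param newdata Matrix or data frame whose columns are exactly the fit's
#'   fixed-effect design columns (see `colnames(fit$draws$beta)`), in any
#'   order; `NULL` uses the training design.
#' @param include_person_effects Add the person-specific effects? Only
#'   available for the training rows.
#' @return S x M matrix of expected-outcome draws (S posterior draws, M
#'   rows of `newdata`).
#' @export
posterior_expectation <- function(fit, newdata = NULL,
                                  include_person_effects = FALSE) {
  stopifnot(inherits(fit, "affect_fit"))
  if (is.null(newdata)) {
    Xn <- fit$design$X
  } else {
    Xn <- as.matrix(newdata)
    want <- colnames(fit$draws$beta)
    unknown <- setdiff(colnames(Xn), want)
    if (length(unknown)) {
      stop("unknown column(s): ", paste(unknown, collapse = ", "))
    }
    if (!setequal(colnames(Xn), want)) {
      stop("newdata must supply every design column; missing: ",
           paste(setdiff(want, colnames(Xn)), collapse = ", "))
    }
    Xn <- Xn[, want, drop = FALSE]
    if (include_person_effects) {
      stop("person effects are only defined for the training rows (newdata = NULL)")
    }
  }
  eta <- fit$draws$beta %*% t(Xn)
  if (include_person_effects) eta <- eta + random_effect_contribution(fit)
  eta
}

#' Pointwise log-likelihood matrix
#'
#' Gaussian log density of each training observation under each posterior
#' draw, conditional on the draw's person effects (the likelihood the model
#' was fitted with). Input to [psis_loo()].
#'
#' @param fit An `affect_fit`.
#' @return S x N matrix of log densities.
#' @export
pointwise_log_likelihood <- function(fit) {
  stopifnot(inherits(fit, "affect_fit"))
  mu <- posterior_expectation(fit, include_person_effects = TRUE)
  y <- fit$design$y
  S <- nrow(mu)
  ym <- matrix(y, S, length(y), byrow = TRUE)
  stats::dnorm(ym, mu, fit$draws$sigma, log = TRUE)
}

#' Bayesian R-squared for a multilevel fit
#'
#' Per posterior draw, the proportion of outcome variance attributed to the
#' modelled effects. The conditional version uses the full linear predictor
#' (fixed + person effects) against the residual variance,
#' `var(mu) / (var(mu) + sigma^2)`. The marginal version credits only the
#' fixed effects and counts person-level variation as unexplained,
#' `var(Xb) / (var(Xb) + var(Zu) + sigma^2)`, so conditional >= marginal up
#' to Monte Carlo error.
#'
#' @param fit An `affect_fit`.
#' @param kind `"marginal"` or `"conditional"`.
#' @return List with `mean`, `ci_low`, `ci_high` (equal-tailed 95%), and the
#'   per-draw values in `draws`.
#' @export
bayes_r2 <- function(fit, kind = c("marginal", "conditional")) {
  kind <- match.arg(kind)
  fixed <- posterior_expectation(fit, include_person_effects = FALSE)
  ranef <- random_effect_contribution(fit)
  var_f <- apply(fixed, 1, stats::var)
  var_c <- apply(fixed + ranef, 1, stats::var)
  var_z <- apply(ranef, 1, stats::var)
  s2 <- fit$draws$sigma^2
  r2 <- if (kind == "conditional") var_c / (var_c + s2)
        else var_f / (var_f + var_z + s2)
  qs <- stats::quantile(r2, c(0.025, 0.975), names = FALSE)
  list(mean = mean(r2), ci_low = qs[1], ci_high = qs[2], draws = r2)
}
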