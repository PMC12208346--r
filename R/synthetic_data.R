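#' Configuration for the synthetic sleep-affect generator
#'
#' Defaults emulate the study conditions the pipeline is designed for:
#' 96 persons by 15 nights; nightly compositions are logistic-normal around
#' a grand geometric mean of 13% wake in bed, 43% light, 21% SWS, 23% REM,
#' with between-/within-person variance split so composition coordinates
#' have ICC ~ 0.35 (within-dominant); time in bed is Normal(448.66, 95.47)
#' minutes truncated at 180; affect outcomes (1-5 scale) have a person
#' random intercept SD of 0.45 against a residual SD of 0.35 (ICC ~ 0.6,
#' between-dominant) plus small covariate and composition effects; 4% of
#' sleep nights and 19% of morning-affect reports are missing completely
#' at random.
#'
#' @param n_persons,n_days Panel dimensions.
#' @param target_proportions Grand geometric-mean composition (closed).
#' @param sigma_b,sigma_w 3x3 between-/within-person covariance of the ilr
#'   coordinates (symmetric positive definite).
#' @param tib_mean_min,tib_sd_min,tib_min_floor Time-in-bed distribution,
#'   minutes.
#' @param betas Per-outcome list of true effects: each element has
#'   `between` and `within` (length-3, on the ilr scale), `presleep`,
#'   `weekend`, `cpd`.
#' @param intercept Outcome grand intercept on the 1-5 scale.
#' @param random_intercept_sd,random_slope_sds,residual_sd Outcome variance
#'   components (slopes apply to the within-person ilr coordinates).
#' @param missing_sleep_rate,missing_affect_rate MCAR masking rates.
#' @param basis `ilr_basis` the truth is expressed in.
#' @param seed Integer; `generate_sleep_data()` is bit-reproducible under
#'   the same config and seed.
#' @return List with class `generator_config`.
#' @export
generator_config <- function(n_persons = 96, n_days = 15,
                             target_proportions = c(twt = 0.13, light = 0.43,
                                                    sws = 0.21, rem = 0.23),
                             sigma_b = diag(0.0315, 3),
                             sigma_w = diag(0.0585, 3),
                             tib_mean_min = 448.66, tib_sd_min = 95.47,
                             tib_min_floor = 180,
                             betas = default_true_betas(),
                             intercept = 2.5,
                             random_intercept_sd = 0.45,
                             random_slope_sds = c(0.05, 0.05, 0.05),
                             residual_sd = 0.35,
                             missing_sleep_rate = 0.04,
                             missing_affect_rate = 0.19,
                             basis = build_ilr_basis(default_sbp()),
                             seed = 1L) {
  stopifnot(n_persons >= 1, n_days >= 1,
            length(target_proportions) == 4, all(target_proportions > 0),
            isSymmetric(sigma_b), isSymmetric(sigma_w),
            all(eigen(sigma_b, only.values = TRUE)$values > 0),
            all(eigen(sigma_w, only.values = TRUE)$values >= 0),
            tib_mean_min > 0, tib_sd_min >= 0,
            random_intercept_sd >= 0, residual_sd > 0,
            missing_sleep_rate >= 0, missing_sleep_rate <= 1,
            missing_affect_rate >= 0, missing_affect_rate <= 1)
  structure(list(n_persons = as.integer(n_persons),
                 n_days = as.integer(n_days),
                 target_proportions = close_comp(target_proportions),
                 mu_b = ilr_transform(close_comp(target_proportions), basis),
                 sigma_b = sigma_b, sigma_w = sigma_w,
                 tib_mean_min = tib_mean_min, tib_sd_min = tib_sd_min,
                 tib_min_floor = tib_min_floor,
                 betas = betas, intercept = intercept,
                 random_intercept_sd = random_intercept_sd,
                 random_slope_sds = random_slope_sds,
                 residual_sd = residual_sd,
                 missing_sleep_rate = missing_sleep_rate,
                 missing_affect_rate = missing_affect_rate,
                 basis = basis, seed = as.integer(seed)),
            class = "generator_config")
}

#' Default true fixed effects per affect outcome
#'
#' Modest composition effects on the ilr scale (order: wake-vs-sleep,
#' light-vs-deep, SWS-vs-REM balances), a positive carry-over from the
#' matched pre-sleep affect, and small daily-covariate effects.
#'
#' @param between,within Length-3 effects shared by all outcomes.
#' @return Named list over `hap`, `lap`, `hana`, `lana`.
#' @export
default_true_betas <- function(between = c(0.20, -0.15, 0.10),
                               within = c(0.08, -0.05, 0.06)) {
  one <- list(between = between, within = within,
              presleep = 0.15, weekend = 0.05, cpd = 0.03)
  stats::setNames(rep(list(one), 4), AFFECT_OUTCOMES)
}

rmvnorm_chol <- function(n, mu, Sigma) {
  L <- chol(Sigma + diag(1e-12, nrow(Sigma)))
  matrix(stats::rnorm(n * length(mu)), n) %*% L +
    matrix(mu, n, length(mu), byrow = TRUE)
}

#' Generate a synthetic multilevel sleep-affect dataset
#'
#' Person-level ilr means are multivariate normal around the grand mean;
#' daily deviations are multivariate normal around each person's mean;
#' nightly minutes are the inverse ilr composition scaled by a truncated-
#' normal time in bed (positivity holds by construction). Affect is the
#' linear multilevel model: intercept + between/within composition effects
#' + covariate effects + person intercept and within-slopes + Gaussian
#' noise, clipped to the 1-5 response scale. MCAR missingness is applied
#' at the configured rates. The generating truth (realised person effects
#' included) is returned alongside the table.
#'
#' @param config A [generator_config()].
#' @param seed Optional override of `config$seed`.
#' @return List of class `synthetic_sleep_data` with elements `table` (the
#'   long-format data frame, see [sleep_table_columns()]) and `truth`.
#' @export
generate_sleep_data <- function(config = generator_config(), seed = NULL) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  set.seed(config$seed)
  np <- config$n_persons
  nd <- config$n_days
  n <- np * nd
  id <- rep(seq_len(np), each = nd)
  day <- rep(seq_len(nd), np)

  b <- rmvnorm_chol(np, config$mu_b, config$sigma_b)
  w <- rmvnorm_chol(n, c(0, 0, 0), config$sigma_w)
  z <- b[id, , drop = FALSE] + w
  if (config$tib_sd_min > 0 &&
      stats::pnorm(config$tib_min_floor, config$tib_mean_min,
                   config$tib_sd_min) > 0.01) {
    stop("infeasible config: more than 1% of time-in-bed draws would fall ",
         "below the ", config$tib_min_floor, "-minute floor")
  }
  tib <- stats::rnorm(n, config$tib_mean_min, config$tib_sd_min)
  tib <- pmax(tib, config$tib_min_floor)
  comp <- ilr_inverse(z, config$basis) * tib

  # baseline covariates (per person); binary demographics hit the target
  # proportions exactly (with both levels present from 2 persons up) so
  # that contrasts stay estimable even in small panels
  age <- round(stats::rnorm(np, 20.55, 1.65), 1)
  n_fem <- if (np >= 2) min(np - 1L, max(1L, round(0.773 * np))) else np
  gender <- sample(rep(c("female", "male"), c(n_fem, np - n_fem)))
  n_asi <- if (np >= 2) min(np - 1L, max(1L, round(0.845 * np))) else np
  ethnicity <- sample(rep(c("asian", "other"), c(n_asi, np - n_asi)))
  sss <- pmin(10, pmax(1, round(stats::rnorm(np, 6, 1.5))))
  bmi <- round(stats::rnorm(np, 21.92, 3.49), 1)

  # staggered study start: person i begins on weekday (i - 1) mod 7
  dow <- (id - 1L + day - 1L) %% 7L
  weekend <- as.integer(dow %in% c(5L, 6L))
  cpd <- stats::rnorm(n, 0, 1)

  u0 <- stats::rnorm(np, 0, config$random_intercept_sd)
  us <- sapply(config$random_slope_sds, function(s) stats::rnorm(np, 0, s))

  clip15 <- function(x) pmin(5, pmax(1, x))
  df <- data.frame(id = id, day = day,
                   twt_min = comp[, 1], light_min = comp[, 2],
                   sws_min = comp[, 3], rem_min = comp[, 4],
                   tib_min = tib)
  presleep_person <- stats::rnorm(np, config$intercept, 0.5)
  for (oc in AFFECT_OUTCOMES) {
    be <- config$betas[[oc]]
    presleep <- clip15(presleep_person[id] + stats::rnorm(n, 0, 0.4))
    zb <- b[id, , drop = FALSE]
    eta <- config$intercept +
      drop(zb %*% be$between) + drop(w %*% be$within) +
      be$presleep * (presleep - config$intercept) +
      be$weekend * weekend + be$cpd * cpd +
      u0[id] + rowSums(w * us[id, , drop = FALSE]) +
      stats::rnorm(n, 0, config$residual_sd)
    df[[oc]] <- clip15(eta)
    df[[paste0("presleep_", oc)]] <- presleep
  }
  df$weekend <- weekend
  df$cpd <- cpd
  df$age <- age[id]
  df$gender <- gender[id]
  df$ethnicity <- ethnicity[id]
  df$sss <- sss[id]
  df$bmi <- bmi[id]
  df <- df[, sleep_table_columns()]

  truth <- list(config = config, person_ilr_means = b,
                person_intercepts = u0, person_slopes = us)
  out <- structure(list(table = df, truth = truth),
                   class = "synthetic_sleep_data")
  apply_missingness(out, sleep_rate = config$missing_sleep_rate,
                    affect_rate = config$missing_affect_rate)
}

#' Mask sleep nights and morning-affect reports completely at random
#'
#' Whole nights (all four stage columns plus time in bed) are masked at
#' `sleep_rate`; whole morning-affect reports (the four outcome columns
#' jointly) at `affect_rate`. Masking is driven by the current RNG state,
#' so calling inside [generate_sleep_data()] is seed-reproducible.
#'
#' @param dataset A `synthetic_sleep_data` or a plain table.
#' @param sleep_rate,affect_rate Masking probabilities in \[0, 1\].
#' @return Same type as `dataset`, with masked values set to `NA`.
#' @export
apply_missingness <- function(dataset, sleep_rate = 0, affect_rate = 0) {
  stopifnot(sleep_rate >= 0, sleep_rate <= 1, affect_rate >= 0, affect_rate <= 1)
  df <- if (inherits(dataset, "synthetic_sleep_data")) dataset$table else dataset
  n <- nrow(df)
  if (sleep_rate > 0) {
    mask <- stats::runif(n) < sleep_rate
    df[mask, c(part_cols(), "tib_min")] <- NA_real_
  }
  if (affect_rate > 0) {
    mask <- stats::runif(n) < affect_rate
    df[mask, AFFECT_OUTCOMES] <- NA_real_
  }
  if (inherits(dataset, "synthetic_sleep_data")) {
    dataset$table <- df
    dataset
  } else {
    df
  }
}

#' Intraclass correlation of a longitudinal variable
#'
#' Between-person variance over total variance from the variance components
#' of a random-intercept model (REML, via lme4). `variable` may be any
#' column of the table, or `"ilr1"`, `"ilr2"`, `"ilr3"` to use the nightly
#' ilr coordinates of the composition.
#'
#' @param dataset A `synthetic_sleep_data` or a table per
#'   [sleep_table_columns()].
#' @param variable Column name or `"ilr<k>"`.
#' @param basis Basis used when `variable` is an ilr coordinate.
#' @return Proportion in \[0, 1\].
#' @export
compute_icc <- function(dataset, variable,
                        basis = build_ilr_basis(default_sbp())) {
  df <- if (inherits(dataset, "synthetic_sleep_data")) dataset$table else dataset
  if (grepl("^ilr[123]$", variable)) {
    comp <- as.matrix(df[, part_cols()])
    keep <- stats::complete.cases(comp)
    comp <- comp[keep, , drop = FALSE]
    comp[comp == 0] <- 0.5
    z <- ilr_transform(comp, basis)
    value <- z[, as.integer(sub("ilr", "", variable))]
    id <- df$id[keep]
  } else {
    if (!variable %in% names(df)) stop("unknown variable: ", variable)
    keep <- !is.na(df[[variable]])
    value <- df[[variable]][keep]
    id <- df$id[keep]
  }
  counts <- table(id)
  if (sum(counts >= 2) < 2) {
    stop("degenerate grouping: need at least 2 persons with 2+ records")
  }
  if (stats::var(value) < 1e-12) {
    stop("ICC undefined: '", variable, "' has no variance")
  }
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ 1 + (1 | id), data = data.frame(value = value, id = id),
               control = lme4::lmerControl(check.conv.singular = "ignore"))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  vb <- vc$vcov[vc$grp == "id"]
  vw <- vc$vcov[vc$grp == "Residual"]
  vb / (vb + vw)
}
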