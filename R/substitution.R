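#' Reallocate minutes between two sleep stages
#'
#' Moves `minutes` from the `donor` stage to the `recipient` stage, leaving
#' the other stages and the total time in bed untouched. Negative `minutes`
#' reallocate in the opposite direction:
#' `reallocate_minutes(x, a, b, t) == reallocate_minutes(x, b, a, -t)`.
#'
#' @param comp Named 4-vector of stage minutes (names from [sleep_parts()]).
#' @param donor,recipient Distinct stage names.
#' @param minutes Minutes to move (may be negative).
#' @return The reallocated composition in minutes.
#' @examples
#' x <- c(twt = 58, light = 193, sws = 94, rem = 103)
#' reallocate_minutes(x, "light", "sws", 30)
#' @export
reallocate_minutes <- function(comp, donor, recipient, minutes) {
  stopifnot(donor %in% SLEEP_PARTS, recipient %in% SLEEP_PARTS)
  if (donor == recipient) stop("donor and recipient must differ")
  if (is.null(names(comp))) names(comp) <- SLEEP_PARTS
  out <- comp
  out[donor] <- out[donor] - minutes
  out[recipient] <- out[recipient] + minutes
  if (out[donor] <= 0 || out[recipient] <= 0) {
    stop("infeasible reallocation: moving ", minutes, " min from ", donor,
         " to ", recipient, " exhausts a stage")
  }
  out
}

#' Grid of pairwise reallocations
#'
#' All ordered donor/recipient stage pairs at 1-minute increments up to
#' `max_minutes` (each unordered pair appears in both directions, matching
#' an evaluation from `-max_minutes` to `+max_minutes` per pair).
#'
#' @param max_minutes Largest reallocation, minutes (default 60).
#' @param minutes Optional explicit vector of positive minute values.
#' @return Data frame with columns `donor`, `recipient`, `minutes`.
#' @export
reallocation_grid <- function(max_minutes = 60, minutes = seq_len(max_minutes)) {
  pairs <- expand.grid(donor = SLEEP_PARTS, recipient = SLEEP_PARTS,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$donor != pairs$recipient, ]
  out <- merge(pairs, data.frame(minutes = minutes))
  out[order(out$donor, out$recipient, out$minutes),
      c("donor", "recipient", "minutes")]
}

#' Summarise posterior draws of an affect difference
#'
#' @param draws Vector of posterior draws.
#' @return List with the posterior `mean`, equal-tailed 95% interval
#'   (`ci_low`, `ci_high`) and `significant` (TRUE iff the interval
#'   excludes zero).
#' @export
summarize_draws <- function(draws) {
  stopifnot(length(draws) >= 100L || length(unique(draws)) == 1L)
  qs <- stats::quantile(draws, c(0.025, 0.975), names = FALSE)
  list(mean = mean(draws), ci_low = qs[1], ci_high = qs[2],
       significant = qs[1] > 0 || qs[2] < 0)
}

#' Standardize a mean affect difference
#'
#' @param mean_diff Unstandardized difference, affect points.
#' @param scale Positive standard deviation to divide by.
#' @return Dimensionless standardized difference.
#' @export
standardize_difference <- function(mean_diff, scale) {
  if (!is.numeric(scale) || any(scale <= 0)) stop("scale must be positive")
  mean_diff / scale
}

#' Standardization scale for substitution estimates
#'
#' The divisor used for standardized differences: the observed outcome SD
#' (default), the model's between-person SD (random-intercept SD), or the
#' model's within-person (residual) SD.
#'
#' @param fit An `affect_fit`.
#' @param type `"observed"`, `"between"`, or `"within"`.
#' @return Positive scalar.
#' @export
substitution_scale <- function(fit, type = c("observed", "between", "within")) {
  type <- match.arg(type)
  switch(type,
         observed = fit$sd_y,
         between = mean(fit$draws$sd_u[, 1]),
         within = mean(fit$draws$sigma))
}

# Design row at the covariate reference: centred numeric covariates at 0
# (their sample means), binary and categorical covariates at the reference
# level, all ilr columns 0. Interaction columns are products of centred tib
# with ilr columns, hence 0 at the reference.
reference_design_row <- function(fit) {
  cols <- colnames(fit$draws$beta)
  row <- matrix(0, 1, length(cols), dimnames = list(NULL, cols))
  row[1, "(Intercept)"] <- 1
  row
}

substitute_level <- function(fit, reference, grid, level,
                             covariate_row = NULL, scale_type = "observed") {
  stopifnot(inherits(fit, "affect_fit"), level %in% c("between", "within"))
  cols <- if (level == "between") fit$design$between_cols else fit$design$within_cols
  if (!length(cols)) {
    stop("fit variant '", fit$spec$variant, "' has no ", level,
         "-person composition terms")
  }
  basis <- fit$basis
  if (is.null(basis)) basis <- build_ilr_basis(default_sbp())
  ref_min <- reference$minutes
  if (any(ref_min <= 0)) stop("reference composition must be strictly positive")
  z_ref <- ilr_transform(ref_min, basis)
  if (is.null(covariate_row)) covariate_row <- reference_design_row(fit)
  base_row <- covariate_row
  if (level == "between") base_row[1, fit$design$between_cols] <- z_ref
  eta_ref <- posterior_expectation(fit, base_row)
  scale <- substitution_scale(fit, scale_type)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    new_min <- tryCatch(
      reallocate_minutes(ref_min, g$donor, g$recipient, g$minutes),
      error = function(e) NULL)
    if (is.null(new_min)) {
      message("skipping infeasible reallocation: ", g$donor, " -> ",
              g$recipient, " ", g$minutes, " min")
      next
    }
    z_new <- ilr_transform(new_min, basis)
    row <- base_row
    if (level == "between") {
      row[1, fit$design$between_cols] <- z_new
    } else {
      row[1, fit$design$within_cols] <- z_new - z_ref
    }
    diff_draws <- posterior_expectation(fit, row)[, 1] - eta_ref[, 1]
    s <- summarize_draws(diff_draws)
    rows[[i]] <- data.frame(level = level, donor = g$donor,
                            recipient = g$recipient, minutes = g$minutes,
                            mean = s$mean, ci_low = s$ci_low,
                            ci_high = s$ci_high,
                            std = standardize_difference(s$mean, scale),
                            significant = s$significant)
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(level = character(), donor = character(),
                      recipient = character(), minutes = numeric(),
                      mean = numeric(), ci_low = numeric(),
                      ci_high = numeric(), std = numeric(),
                      significant = logical())
  }
  rownames(out) <- NULL
  out
}

#' Between-person compositional substitution analysis
#'
#' For each grid point, the posterior difference in expected affect between
#' a hypothetical person whose average composition is the reallocated
#' reference and one at the reference itself: the between-person ilr
#' coordinates move from `ilr(reference)` to `ilr(reallocated)`, the
#' within-person deviation stays 0, covariates sit at the reference row,
#' and person effects are excluded (population level). Infeasible grid
#' points (donor exhausted) are skipped with a message, never clamped.
#'
#' @param fit An `affect_fit` whose variant includes between-person terms
#'   (b or d).
#' @param reference Reference composition from [reference_composition()].
#' @param grid Data frame from [reallocation_grid()].
#' @param covariate_row Optional 1-row design matrix overriding the default
#'   covariate reference.
#' @param scale_type Divisor for standardized differences
#'   (see [substitution_scale()]).
#' @return Data frame: `level`, `donor`, `recipient`, `minutes`, `mean`,
#'   `ci_low`, `ci_high`, `std`, `significant`.
#' @export
substitute_between <- function(fit, reference, grid = reallocation_grid(),
                               covariate_row = NULL, scale_type = "observed") {
  substitute_level(fit, reference, grid, "between", covariate_row, scale_type)
}

#' Within-person compositional substitution analysis
#'
#' As [substitute_between()], but the reallocation perturbs the daily
#' deviation: the between-person coordinates are held at the reference and
#' the within-person coordinates move from 0 to
#' `ilr(reallocated) - ilr(reference)`. Differences are evaluated through
#' the within-person fixed effects (random slopes at their zero mean).
#'
#' @inheritParams substitute_between
#' @param fit An `affect_fit` whose variant includes within-person terms
#'   (c or d).
#' @return Data frame as in [substitute_between()].
#' @export
substitute_within <- function(fit, reference, grid = reallocation_grid(),
                              covariate_row = NULL, scale_type = "observed") {
  stopifnot(inherits(fit, "affect_fit"))
  if (!length(fit$design$within_cols)) {
    stop("fit variant '", fit$spec$variant, "' has no within-person composition terms")
  }
  covariate_row <- if (is.null(covariate_row)) reference_design_row(fit) else covariate_row
  if (length(fit$design$between_cols)) {
    basis <- if (is.null(fit$basis)) build_ilr_basis(default_sbp()) else fit$basis
    covariate_row[1, fit$design$between_cols] <-
      ilr_transform(reference$minutes, basis)
  }
  substitute_level(fit, reference, grid, "within", covariate_row, scale_type)
}
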