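# One small fitted model is shared across the MCMC-dependent assertions to
# keep the suite fast; analytic operations are checked on hand-built fits.

test_that("design matrices have the variant's composition columns", {
  dec <- decompose_bw(small_table())
  d_a <- build_design(dec, model_spec("hap", "a"))
  d_b <- build_design(dec, model_spec("hap", "b"))
  d_c <- build_design(dec, model_spec("hap", "c"))
  d_d <- build_design(dec, model_spec("hap", "d"))
  has_ilr <- function(d) sum(colnames(d$X) %in% c(paste0("b", 1:3), paste0("w", 1:3)))
  expect_equal(has_ilr(d_a), 0)
  expect_equal(has_ilr(d_b), 3)
  expect_equal(has_ilr(d_c), 3)
  expect_equal(has_ilr(d_d), 6)
  # random structure: intercept only for a/b, intercept + within slopes for c/d
  expect_equal(ncol(d_a$Z), 1)
  expect_equal(ncol(d_d$Z), 4)
  # covariates present: centred numerics, dummy factors, matched pre-sleep score
  expect_true(all(c("tib_min", "weekend", "cpd", "age", "sss", "bmi",
                    "presleep_hap") %in% colnames(d_a$X)))
  expect_lt(abs(mean(d_a$X[, "age"])), 1e-10)
  expect_true(any(grepl("^gender", colnames(d_a$X))))
  d_i <- build_design(dec, model_spec("hap", "d", include_tib_interaction = TRUE))
  expect_equal(length(d_i$interaction_cols), 6)
  expect_true(all(grepl("^tib_min:", d_i$interaction_cols)))
})

test_that("mean-centring makes the design invariant to covariate shifts", {
  df <- small_table()
  dec <- decompose_bw(df)
  shifted <- dec
  shifted$age <- shifted$age + 10
  d1 <- build_design(dec, model_spec("lap", "b"))
  d2 <- build_design(shifted, model_spec("lap", "b"))
  expect_equal(d1$X, d2$X)
  expect_equal(d2$centers[["age"]], d1$centers[["age"]] + 10)
})

test_that("degenerate designs fail loudly, naming the column", {
  dec <- decompose_bw(small_table())
  dec$cpd <- 0
  expect_error(build_design(dec, model_spec("hap", "a")), "cpd")
  dec2 <- decompose_bw(small_table())
  dec2$bmi <- dec2$age   # collinear copy
  expect_error(build_design(dec2, model_spec("hap", "a")), "bmi|age")
})

test_that("posterior expectation reproduces X beta draw by draw", {
  B <- cbind(`(Intercept)` = c(1, 2, 3), x = c(0.5, -0.5, 0))
  B <- B[rep(1:3, each = 40), ]  # 120 draws
  fit <- fake_fit(B)
  nd <- rbind(c(1, 2), c(1, 2))
  colnames(nd) <- colnames(B)
  eta <- posterior_expectation(fit, nd)
  expect_equal(eta[, 1], drop(B %*% c(1, 2)))
  expect_equal(eta[, 1], eta[, 2])  # identical rows give identical draws
  bad <- cbind(nd, junk = 1)
  expect_error(posterior_expectation(fit, bad), "unknown column")
})

test_that("pointwise log-likelihood matches the closed-form normal density", {
  dec <- decompose_bw(small_table(n_persons = 12, n_days = 4))
  spec <- model_spec("hana", "b", mcmc = quick_mcmc())
  fit <- suppressWarnings(fit_affect_model(dec, spec, seed = 3))
  ll <- pointwise_log_likelihood(fit)
  expect_equal(dim(ll), c(500, length(fit$design$y)))
  # independent recomputation for one draw and one observation
  s <- 57; i <- 11
  mu_si <- sum(fit$draws$beta[s, ] * fit$design$X[i, ]) +
    fit$draws$u[s, fit$design$group[i], 1]
  expect_equal(ll[s, i],
               -0.5 * log(2 * pi) - log(fit$draws$sigma[s]) -
                 (fit$design$y[i] - mu_si)^2 / (2 * fit$draws$sigma[s]^2),
               tolerance = 1e-10)
  # additivity: row sums are the total log-likelihood per draw
  mu <- posterior_expectation(fit, include_person_effects = TRUE)
  tot <- rowSums(stats::dnorm(matrix(fit$design$y, nrow(mu), ncol(mu), byrow = TRUE),
                              mu, fit$draws$sigma, log = TRUE))
  expect_equal(rowSums(ll), tot, tolerance = 1e-8)
})

test_that("fits are reproducible under a fixed seed", {
  dec <- decompose_bw(small_table(n_persons = 8, n_days = 4))
  spec <- model_spec("lap", "a", mcmc = mcmc_control(2, 150, 150))
  f1 <- suppressWarnings(fit_affect_model(dec, spec, seed = 11))
  f2 <- suppressWarnings(fit_affect_model(dec, spec, seed = 11))
  expect_identical(f1$draws$beta, f2$draws$beta)
  expect_identical(f1$draws$sigma, f2$draws$sigma)
  f3 <- suppressWarnings(fit_affect_model(dec, spec, seed = 12))
  expect_false(identical(f1$draws$beta, f3$draws$beta))
})

test_that("draw count is chains times sampling iterations", {
  expect_equal(mcmc_control(8, 1000, 5000)$total_draws, 40000)
  dec <- decompose_bw(small_table(n_persons = 8, n_days = 3))
  fit <- suppressWarnings(fit_affect_model(dec,
    model_spec("hap", "a", mcmc = mcmc_control(3, 100, 120)), seed = 1))
  expect_equal(nrow(fit$draws$beta), 360)
})

test_that("Bayesian R2 behaves at the signal limits and orders correctly", {
  # zero signal: outcome is pure noise, marginal R2 near 0
  cfg0 <- generator_config(n_persons = 40, n_days = 5,
                           betas = default_true_betas(between = rep(0, 3),
                                                      within = rep(0, 3)),
                           random_intercept_sd = 0, random_slope_sds = rep(0, 3),
                           residual_sd = 0.4,
                           missing_sleep_rate = 0, missing_affect_rate = 0)
  d0 <- generate_sleep_data(cfg0, seed = 5)
  # outcome must not carry covariate signal either
  d0$table$hap <- pmin(5, pmax(1, 2.5 + stats::rnorm(nrow(d0$table), 0, 0.4)))
  dec0 <- decompose_bw(d0$table)
  fit0 <- suppressWarnings(fit_affect_model(dec0,
    model_spec("hap", "b", mcmc = quick_mcmc()), seed = 5))
  expect_lt(bayes_r2(fit0, "marginal")$mean, 0.2)
  # strong clustered signal: conditional above marginal, near 1 when noiseless
  cfg1 <- generator_config(n_persons = 12, n_days = 6,
                           random_intercept_sd = 0.6, random_slope_sds = rep(0, 3),
                           residual_sd = 0.02,
                           missing_sleep_rate = 0, missing_affect_rate = 0)
  d1 <- generate_sleep_data(cfg1, seed = 6)
  dec1 <- decompose_bw(d1$table)
  fit1 <- suppressWarnings(fit_affect_model(dec1,
    model_spec("hap", "b", mcmc = quick_mcmc()), seed = 6))
  r2c <- bayes_r2(fit1, "conditional")
  r2m <- bayes_r2(fit1, "marginal")
  expect_gt(r2c$mean, 0.95)
  expect_gt(r2c$mean, r2m$mean)
  expect_true(r2m$ci_low <= r2m$mean && r2m$mean <= r2m$ci_high)
})
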