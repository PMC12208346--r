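test_that("reallocation moves minutes exactly and is antisymmetric", {
  x <- c(twt = 58, light = 193, sws = 94, rem = 103)
  y <- reallocate_minutes(x, "light", "sws", 30)
  expect_equal(unname(y), c(58, 163, 124, 103))
  expect_equal(sum(y), sum(x))
  expect_equal(reallocate_minutes(x, "light", "sws", 0), x)
  expect_equal(reallocate_minutes(x, "sws", "light", -30), y)
  expect_error(reallocate_minutes(x, "sws", "sws", 10), "differ")
  expect_error(reallocate_minutes(x, "twt", "rem", 60), "infeasible")
})

test_that("the reallocation grid covers all ordered pairs at 1-min steps", {
  g <- reallocation_grid(60)
  expect_equal(nrow(g), 12 * 60)
  expect_equal(sort(unique(g$minutes)), 1:60)
  expect_true(all(g$donor != g$recipient))
})

test_that("draw summaries report equal-tailed intervals and CI-exclusion", {
  s <- summarize_draws(rep(2.5, 200))
  expect_equal(s[c("mean", "ci_low", "ci_high")], list(mean = 2.5, ci_low = 2.5,
                                                       ci_high = 2.5))
  expect_true(s$significant)
  expect_false(summarize_draws(c(rep(-1, 100), rep(1, 100)))$significant)
  set.seed(8)
  z <- stats::rnorm(10000)
  sz <- summarize_draws(z)
  expect_equal(sz$ci_low, -1.96, tolerance = 0.05)
  expect_equal(sz$ci_high, 1.96, tolerance = 0.05)
})

test_that("standardization divides by the chosen positive scale", {
  expect_equal(standardize_difference(0, 2), 0)
  expect_equal(standardize_difference(0.38, 1.09), 0.3486, tolerance = 1e-4)
  expect_error(standardize_difference(1, 0), "positive")
  B <- cbind(`(Intercept)` = rep(1, 150), b1 = 0, b2 = 0, b3 = 0)
  f <- fake_fit(B, sigma = rep(0.4, 150), sd_y = 1.2)
  expect_equal(substitution_scale(f, "observed"), 1.2)
  expect_equal(substitution_scale(f, "within"), 0.4)
  expect_equal(substitution_scale(f, "between"), 1)
})

test_that("substitution reproduces the analytic effect under a linear truth", {
  basis <- build_ilr_basis(default_sbp())
  beta <- c(0.8, -0.5, 0.3)
  S <- 150
  B <- cbind(`(Intercept)` = rep(2.5, S),
             b1 = beta[1], b2 = beta[2], b3 = beta[3],
             w1 = 2 * beta[1], w2 = 2 * beta[2], w3 = 2 * beta[3])
  fit <- fake_fit(B, sigma = rep(1e-8, S))
  ref <- make_reference()
  grid <- reallocation_grid(60)
  res_b <- substitute_between(fit, ref, grid)
  z_ref <- ilr_transform(ref$minutes, basis)
  for (i in seq_len(nrow(res_b))) {
    dz <- ilr_transform(reallocate_minutes(ref$minutes, res_b$donor[i],
                                           res_b$recipient[i], res_b$minutes[i]),
                        basis) - z_ref
    expect_equal(res_b$mean[i], sum(beta * dz), tolerance = 1e-10)
    expect_equal(res_b$ci_low[i], res_b$mean[i])  # degenerate draws
  }
  # within level: same geometry through the within coefficients
  res_w <- substitute_within(fit, ref, grid[grid$minutes == 30, ])
  for (i in seq_len(nrow(res_w))) {
    dz <- ilr_transform(reallocate_minutes(ref$minutes, res_w$donor[i],
                                           res_w$recipient[i], 30), basis) - z_ref
    expect_equal(res_w$mean[i], sum(2 * beta * dz), tolerance = 1e-10)
  }
  # zero-minute reallocation: exactly zero with a zero-width interval
  z0 <- substitute_between(fit, ref, data.frame(donor = "twt",
                                                recipient = "sws", minutes = 0))
  expect_identical(z0$mean, 0)
  expect_identical(z0$ci_low, 0)
  expect_identical(z0$ci_high, 0)
  expect_false(z0$significant)
})

test_that("reallocation curves are asymmetric and monotone under a linear truth", {
  S <- 120
  B <- cbind(`(Intercept)` = rep(0, S), b1 = 0.6, b2 = -0.4, b3 = 0.2)
  fit <- fake_fit(B, sigma = rep(1e-8, S))
  ref <- make_reference()
  g_pos <- data.frame(donor = "light", recipient = "sws", minutes = 1:60)
  g_neg <- data.frame(donor = "sws", recipient = "light", minutes = 1:60)
  up <- substitute_between(fit, ref, g_pos)$mean
  down <- substitute_between(fit, ref, g_neg)$mean
  # the inverse-ilr map is non-linear in minutes: +t and -t do not mirror
  expect_gt(max(abs(up + down)), 1e-6)
  # but each curve is monotone in t for a linear-in-ilr effect
  expect_true(all(diff(up) > 0) || all(diff(up) < 0))
  expect_true(all(diff(down) > 0) || all(diff(down) < 0))
})

test_that("infeasible grid points are skipped, not fabricated", {
  S <- 120
  B <- cbind(`(Intercept)` = rep(0, S), b1 = 0.1, b2 = 0.1, b3 = 0.1)
  fit <- fake_fit(B, sigma = rep(1e-8, S))
  ref <- make_reference(proportions = c(twt = 0.05, light = 0.5,
                                        sws = 0.25, rem = 0.2), tib = 400)
  # twt holds only 20 minutes: donations of 20+ are impossible
  g <- data.frame(donor = "twt", recipient = "sws", minutes = c(10, 19, 25, 40))
  expect_message(res <- substitute_between(fit, ref, g), "infeasible")
  expect_equal(res$minutes, c(10, 19))
  # empty grid gives an empty, well-formed table
  e <- substitute_between(fit, ref, reallocation_grid(60)[0, ])
  expect_equal(nrow(e), 0)
  expect_true(all(c("level", "donor", "recipient", "minutes", "mean",
                    "ci_low", "ci_high", "std", "significant") %in% names(e)))
})

test_that("substitution requires the matching composition terms in the fit", {
  S <- 120
  B_a <- cbind(`(Intercept)` = rep(0, S))
  expect_error(substitute_between(fake_fit(B_a), make_reference(),
                                  reallocation_grid(10)), "between")
  B_b <- cbind(`(Intercept)` = rep(0, S), b1 = 0.1, b2 = 0.1, b3 = 0.1)
  expect_error(substitute_within(fake_fit(B_b), make_reference(),
                                 reallocation_grid(10)), "within")
})
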