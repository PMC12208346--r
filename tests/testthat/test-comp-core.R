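test_that("closure rescales to the requested total and preserves ratios", {
  expect_equal(close_comp(c(1, 1, 1, 1)), rep(0.25, 4))
  x <- c(71.77, 190.78, 86.58, 98.35)
  cl <- close_comp(x)
  expect_equal(sum(cl), 1)
  expect_equal(cl, x / 447.48, tolerance = 1e-10)
  expect_equal(cl[2] / cl[3], x[2] / x[3])
  # scale invariance: closing twice is the same as scaling once
  expect_equal(close_comp(close_comp(x), 448.66), 448.66 * close_comp(x))
  # matrix form closes row-wise
  m <- rbind(x, 2 * x)
  expect_equal(close_comp(m)[1, ], close_comp(m)[2, ])
})

test_that("closure rejects degenerate and negative input", {
  expect_error(close_comp(c(0, 0, 0, 0)), "degenerate")
  expect_error(close_comp(c(-1, 2, 3, 4)), "non-negative")
})

test_that("geometric-mean composition matches the per-part oracle", {
  x <- close_comp(c(0.2, 0.3, 0.4, 0.1))
  expect_equal(gmean_comp(rbind(x, x, x)), x)
  a <- c(0.1, 0.4, 0.2, 0.3)
  b <- c(0.4, 0.1, 0.3, 0.2)
  expect_equal(gmean_comp(rbind(a, b)), close_comp(sqrt(a * b)))
  # consistency: gmean in the simplex == arithmetic mean in ilr space
  basis <- build_ilr_basis(default_sbp())
  X <- random_comps(25)
  expect_equal(gmean_comp(X),
               unname(ilr_inverse(colMeans(ilr_transform(X, basis)), basis)),
               tolerance = 1e-10)
  expect_error(gmean_comp(rbind(c(0, 1, 1, 1))), "replace_zeros")
})

test_that("ilr basis rows have the closed-form balance coefficients", {
  basis <- build_ilr_basis(default_sbp())
  # 1 vs 3 split
  expect_equal(unname(basis$contrast[1, ]),
               c(sqrt(3 / 4), -sqrt(1 / 12), -sqrt(1 / 12), -sqrt(1 / 12)))
  # 1 vs 1 split
  expect_equal(unname(basis$contrast[3, ]), c(0, 0, 1 / sqrt(2), -1 / sqrt(2)))
})

test_that("every enumerated 4-part SBP yields an orthonormal zero-sum basis", {
  sbps <- enumerate_sbps()
  expect_gt(length(sbps), 50)
  for (sbp in sbps) {
    V <- build_ilr_basis(sbp)$contrast
    expect_lt(max(abs(V %*% t(V) - diag(3))), 1e-12)
    expect_lt(max(abs(rowSums(V))), 1e-12)
  }
})

test_that("invalid SBP hierarchies are rejected", {
  # row 2 straddles both sides of row 1
  bad <- rbind(c(1, 1, -1, -1), c(1, -1, 1, -1), c(0, 0, 1, -1))
  expect_error(build_ilr_basis(bad), "SBP")
  # a row without a negative side
  bad2 <- rbind(c(1, 1, 1, 1), c(0, 1, -1, -1), c(0, 0, 1, -1))
  expect_error(build_ilr_basis(bad2), "SBP")
  # unresolved pair: only 2 rows for 4 parts
  expect_error(build_ilr_basis(rbind(c(1, -1, -1, -1), c(0, 1, -1, -1))),
               "rows")
})

test_that("ilr transform is zero at the barycentre and round-trips", {
  basis <- build_ilr_basis(default_sbp())
  expect_equal(ilr_transform(rep(0.25, 4), basis), c(z1 = 0, z2 = 0, z3 = 0))
  X <- random_comps(50)
  Z <- ilr_transform(X, basis)
  back <- ilr_inverse(Z, basis)
  expect_lt(max(abs(back - X)), 1e-12)
  # scale invariance in the input total
  expect_equal(ilr_transform(X[1, ] * 448.66, basis), ilr_transform(X[1, ], basis))
  expect_error(ilr_transform(c(0, 0.5, 0.3, 0.2), basis), "positive")
})

test_that("ilr is an isometry onto Aitchison geometry", {
  basis <- build_ilr_basis(default_sbp())
  X <- random_comps(20, seed = 3)
  for (i in 1:10) {
    x <- X[2 * i - 1, ]
    y <- X[2 * i, ]
    d_ilr <- sqrt(sum((ilr_transform(x, basis) - ilr_transform(y, basis))^2))
    expect_equal(d_ilr, aitchison_dist_oracle(x, y), tolerance = 1e-10)
  }
})

test_that("ilr inverse closes, handles extreme coordinates, scales to minutes", {
  basis <- build_ilr_basis(default_sbp())
  expect_equal(unname(ilr_inverse(c(0, 0, 0), basis)), rep(0.25, 4))
  big <- ilr_inverse(c(500, -400, 300), basis)
  expect_true(all(is.finite(big)))
  expect_equal(sum(big), 1)
  x <- close_comp(c(58, 193, 94, 103))
  mins <- ilr_inverse(ilr_transform(x, basis), basis, total = 448)
  expect_equal(sum(mins), 448)
  expect_equal(unname(mins), 448 * x, tolerance = 1e-12)
})

test_that("basis change is the expected orthogonal rotation", {
  V1 <- build_ilr_basis(default_sbp())
  x <- close_comp(c(0.18, 0.4, 0.22, 0.2))
  z1 <- ilr_transform(x, V1)
  for (sbp in enumerate_sbps()[c(1, 7, 20, 33, 50)]) {
    V2 <- build_ilr_basis(sbp)
    R <- V2$contrast %*% t(V1$contrast)
    expect_lt(max(abs(R %*% t(R) - diag(3))), 1e-12)
    expect_equal(unname(ilr_transform(x, V2)), drop(R %*% z1),
                 tolerance = 1e-12)
  }
})

test_that("multiplicative zero replacement preserves totals and ratios", {
  x <- c(0, 300, 100, 50)
  out <- replace_zeros(x, total = 450, delta = 0.5)
  expect_equal(sum(out), 450)
  expect_equal(out[1], 0.5)
  expect_equal(out[2], 300 * 449.5 / 450)
  expect_equal(out[3] / out[4], 2)  # observed ratios unchanged
  # no zeros: identity
  expect_equal(replace_zeros(c(60, 190, 95, 105)), c(60, 190, 95, 105))
  # two zeros handled symmetrically
  sym <- replace_zeros(c(0, 200, 0, 200), total = 400, delta = 0.5)
  expect_equal(sym[1], sym[3])
  expect_equal(sym[2], sym[4])
  expect_equal(sum(sym), 400)
  expect_error(replace_zeros(c(0, 0, 0, 1), total = 1, delta = 0.5), "delta")
})
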