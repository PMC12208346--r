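# Shared fixtures: all of them built in code at test time.

# Enumerate every ordered sequential binary partition of `parts` as a list
# of sign matrices (first row splits the full set; each side is recursively
# resolved). Used to exercise basis properties exhaustively for D = 4.
enumerate_sbps <- function(parts = 1:4, D = max(parts)) {
  n <- length(parts)
  if (n == 1L) return(list(matrix(0L, 0, D)))
  out <- list()
  for (mask in 1:(2^n - 2)) {
    pos <- parts[bitwAnd(mask, 2^(seq_len(n) - 1)) > 0]
    neg <- setdiff(parts, pos)
    row <- rep(0L, D)
    row[pos] <- 1L
    row[neg] <- -1L
    for (sub_p in enumerate_sbps(pos, D)) {
      for (sub_n in enumerate_sbps(neg, D)) {
        out[[length(out) + 1L]] <- rbind(row, sub_p, sub_n,
                                         deparse.level = 0)
      }
    }
  }
  out
}

# Random strictly positive compositions (rows sum to 1)
random_comps <- function(n, d = 4, seed = 42) {
  set.seed(seed)
  close_comp(matrix(stats::rexp(n * d) + 0.01, n, d))
}

# clr transform: the independent route to Aitchison distance
clr_oracle <- function(x) log(x) - mean(log(x))

aitchison_dist_oracle <- function(x, y) {
  sqrt(sum((clr_oracle(x) - clr_oracle(y))^2))
}

# Small longitudinal table with fully observed outcomes; deterministic.
small_table <- function(n_persons = 12, n_days = 6, seed = 7, ...) {
  cfg <- generator_config(n_persons = n_persons, n_days = n_days,
                          missing_sleep_rate = 0, missing_affect_rate = 0,
                          ...)
  generate_sleep_data(cfg, seed = seed)$table
}

# Hand-built affect_fit with known coefficient draws, for analytic oracles.
# `beta_draws` is an S x P named matrix; columns named b1..b3 / w1..w3 are
# wired up as the composition terms.
fake_fit <- function(beta_draws, sigma = rep(1, nrow(beta_draws)),
                     basis = build_ilr_basis(default_sbp()), sd_y = 1) {
  cols <- colnames(beta_draws)
  S <- nrow(beta_draws)
  structure(list(
    spec = model_spec("hap", if (all(c("b1", "w1") %in% cols)) "d"
                             else if ("b1" %in% cols) "b"
                             else if ("w1" %in% cols) "c" else "a"),
    design = list(
      X = matrix(0, 0, ncol(beta_draws), dimnames = list(NULL, cols)),
      Z = matrix(1, 0, 1), y = numeric(0), group = integer(0),
      persons = 1L, centers = numeric(0), factor_levels = list(),
      between_cols = intersect(paste0("b", 1:3), cols),
      within_cols = intersect(paste0("w", 1:3), cols),
      interaction_cols = character(),
      rows = data.frame(id = integer(0), day = integer(0))),
    draws = list(beta = beta_draws, u = array(0, c(S, 1, 1)),
                 sigma = sigma, sd_u = matrix(1, S, 1)),
    diagnostics = data.frame(parameter = cols, rhat = 1, ess = S),
    converged = TRUE, sd_y = sd_y, seed = 0L,
    data_hash = 0, basis = basis), class = "affect_fit")
}

# Reference composition object without running the data path
make_reference <- function(proportions = c(twt = 0.13, light = 0.43,
                                           sws = 0.21, rem = 0.23),
                           tib = 448.66) {
  p <- close_comp(proportions)
  list(minutes = p * tib, proportions = p, tib = tib)
}

quick_mcmc <- function() mcmc_control(chains = 2, warmup = 250, sampling = 250)
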