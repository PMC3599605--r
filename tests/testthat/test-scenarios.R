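beta_low <- 1.99e-7
beta_high <- 4.33e-7

test_that("a unit multiplier reproduces the baseline prevalence for every target", {
  p <- model_params(beta = beta_low)
  base <- solve_equilibria(p)[[1]]$prevalence
  for (tg in c("epsilon", "beta", "inverse_gamma", "sigma")) {
    sw <- univariate_sweep(tg, 1, p)
    expect_equal(sw$prevalence, base, tolerance = 1e-10)
  }
  expect_error(univariate_sweep("nonsense", 1, p), "unknown sweep target")
})

test_that("sweep cells agree with the dense-scan equilibrium oracle", {
  p <- model_params(beta = beta_low)
  mults <- c(0.25, 0.5, 0.75, 1)
  for (tg in c("epsilon", "beta", "inverse_gamma", "sigma")) {
    sw <- univariate_sweep(tg, mults, p)
    for (k in seq_along(mults)) {
      p_k <- obesitysir:::rescale_param(p, tg, mults[k])
      orc <- oracle_equilibria(p_k)
      expect_lt(min(abs(orc$prevalence - sw$prevalence[k])), 1e-6)
    }
  }
})

test_that("at low transmissibility the non-contagious hazard dominates the response", {
  p <- model_params(beta = beta_low)
  mults <- seq(0.1, 0.9, by = 0.2)
  prev <- sapply(c("epsilon", "beta", "inverse_gamma", "sigma"),
                 function(tg) univariate_sweep(tg, mults, p)$prevalence)
  # reducing epsilon yields the lowest prevalence at every reduction level
  for (k in seq_along(mults))
    expect_equal(which.min(prev[k, ]), c(epsilon = 1L))
})

test_that("combined sweep reduces to the baseline at unit factors and is monotone in alpha", {
  p <- model_params(beta = beta_high)
  base <- solve_equilibria(p)[[1]]$prevalence
  sw <- combined_sweep(1, 1, p)
  expect_equal(sw$prevalence, rep(base, 2), tolerance = 1e-10)
  alphas <- seq(0, 1, by = 0.1)
  swa <- combined_sweep(alphas, numeric(0), p)
  expect_true(all(diff(swa$prevalence) >= -1e-9))
  expect_equal(swa$prevalence[1], 0)  # alpha = 0: no entry into obesity
  # primary vs secondary gap at high beta: reported, finite, in [0, 1]
  grid <- seq(0.2, 1, by = 0.2)
  both <- combined_sweep(grid, grid, p)
  gap <- max(abs(both$prevalence[both$factor == "alpha"] -
                   both$prevalence[both$factor == "kappa"]))
  expect_true(is.finite(gap) && gap >= 0 && gap <= 1)
})

test_that("transmission and recovery panels behave as the model predicts", {
  p <- model_params()
  hr <- hazard_recovery_sweep(
    p,
    beta_grid = seq(0, 6e-7, length.out = 41),
    epsilon_multipliers = c(0, 1),
    inverse_gamma_grid = seq(5, 65, length.out = 13),
    sigma_multipliers = c(0.1, 1, 10))
  tr <- hr$transmission
  # no hazard at all: prevalence zero
  z <- tr[tr$epsilon_multiplier == 0 & tr$beta == 0, ]
  expect_equal(z$prevalence, 0)
  # headline rows are unique per cell and on stable branches
  hd <- tr[tr$headline, ]
  expect_equal(nrow(hd), 41 * 2)
  expect_true(all(hd$stable))
  # prevalence non-decreasing in the mean duration of obesity at fixed sigma
  rc <- hr$recovery[hr$recovery$headline, ]
  for (sm in c(0.1, 1, 10)) {
    cur <- rc[rc$sigma_multiplier == sm, ]
    expect_true(all(diff(cur$prevalence[order(cur$inverse_gamma)]) >= -1e-9))
  }
  # abrupt rise on the pure-contagion curve: the largest jump dwarfs the
  # median slope
  e0 <- hd[hd$epsilon_multiplier == 0, ]
  e0 <- e0[order(e0$beta), ]
  slopes <- abs(diff(e0$prevalence))
  expect_gt(max(slopes), 0.3)
  expect_gte(max(slopes), 10 * median(slopes))
})

test_that("late-outcome risk obeys its limiting and scaling laws", {
  lam <- 0.03; mu <- 1 / 69.4
  ages <- c(0, 15, 40, 70, 100)
  # delta delay at zero: risk is p times the ever-obese probability
  d0 <- delay_density("pointmass", location = 0)
  expect_equal(late_outcome_risk(ages, 0.3, d0, lam, mu),
               0.3 * (1 - exp(-(lam + mu) * ages)))
  # linear in p
  dg <- delay_density("gamma", shape = 4, rate = 0.4)
  w1 <- late_outcome_risk(ages, 0.25, dg, lam, mu)
  w2 <- late_outcome_risk(ages, 0.5, dg, lam, mu)
  expect_equal(w2, 2 * w1, tolerance = 1e-8)
  # monotone in age and bounded by p
  aa <- seq(0, 120, by = 5)
  w <- late_outcome_risk(aa, 0.3, dg, lam, mu)
  expect_true(all(diff(w) >= 0))
  expect_true(all(w <= 0.3 + 1e-12))
  # gamma-delay quadrature agrees with Monte-Carlo marginalization
  set.seed(71)
  s <- rgamma(1e6, shape = 4, rate = 0.4)
  for (a in c(40, 80)) {
    draw <- 0.3 * ifelse(s >= a, 0, 1 - exp(-(lam + mu) * (a - s)))
    mc_se <- sd(draw) / sqrt(length(draw))
    expect_lt(abs(late_outcome_risk(a, 0.3, dg, lam, mu) - mean(draw)),
              3 * mc_se)
  }
  # a non-normalized density is rejected
  expect_error(delay_density("custom", pdf = function(s) dexp(s) * 2),
               "integrate to 1")
})

test_that("CSV export round-trips at full precision and is deterministic", {
  p <- model_params()
  traj <- integrate_model(p, horizon = 50)
  f1 <- file.path(tempdir(), "traj1.csv")
  f2 <- file.path(tempdir(), "traj2.csv")
  export_csv(traj, f1)
  export_csv(traj, f2)
  expect_identical(readLines(f1), readLines(f2))
  back <- read_model_csv(f1)
  expect_equal(names(back), c("t", "S", "I", "R"))
  expect_identical(back$S, traj$S)
  expect_identical(back$I, traj$I)
  expect_equal(unlist(back[1, ]), c(t = 0, S = p$N, I = 0, R = 0))
  expect_equal(attr(back, "metadata")[["type"]], "trajectory")
  # sweep export: one row per grid point
  sw <- univariate_sweep("beta", c(0.5, 0.75, 1), p)
  fs <- file.path(tempdir(), "sweep.csv")
  export_csv(sw, fs)
  expect_equal(nrow(read_model_csv(fs)), 3)
  # household export carries the ids
  hh <- simulate_households(1, 3, 25, p, seed = 81)
  fh <- file.path(tempdir(), "hh.csv")
  export_csv(hh, fh)
  hb <- read_model_csv(fh)
  expect_equal(names(hb), c("household_id", "m", "secondary_count"))
  expect_equal(nrow(hb), 25)
})

test_that("parameter configs round-trip and drive the table regeneration", {
  p <- model_params(beta = 3.1e-7, sigma = 6)
  cfg <- file.path(tempdir(), "params.cfg")
  write_params_config(p, cfg)
  p2 <- read_params_config(cfg)
  expect_equal(unclass(p2), unclass(p))
  expect_error(read_params_config(file.path(tempdir(), "nope.cfg")),
               "no such config")
  bad <- file.path(tempdir(), "bad.cfg")
  writeLines("zeta = 3", bad)
  expect_error(read_params_config(bad), "unknown config key")
})
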