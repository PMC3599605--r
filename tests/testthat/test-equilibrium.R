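test_that("stationary prevalence at fixed lambda matches a direct linear solve", {
  p <- model_params()
  expect_equal(prevalence_given_lambda(0, p), 0)
  # freeze lambda = epsilon (the beta = 0 case) and solve the full linear
  # stationary system independently
  p0 <- model_params(beta = 0)
  exact <- oracle_linear_stationary(p0, lambda = p0$epsilon)
  expect_equal(prevalence_given_lambda(p0$epsilon, p0),
               exact[2] / p0$N, tolerance = 1e-12)
  # a few more lambdas, against the linear solve
  for (lam in c(0.005, 0.03, 0.2)) {
    exact <- oracle_linear_stationary(p, lambda = lam)
    expect_equal(prevalence_given_lambda(lam, p), exact[2] / p$N,
                 tolerance = 1e-12)
  }
})

test_that("the baseline system has a single endemic equilibrium near 61%", {
  p <- model_params()
  eqs <- solve_equilibria(p)
  expect_length(eqs, 1)
  eq <- eqs[[1]]
  expect_equal(eq$prevalence, 0.608, tolerance = 0.001 / 0.608)
  expect_true(eq$stable)
  # stationarity and self-consistency
  st <- c(eq$S_star, eq$I_star, eq$R_star)
  expect_lt(max(abs(rhs_baseline(st, p))), 1e-9 * p$N)
  expect_equal(eq$lambda_star, p$beta * eq$I_star + p$epsilon,
               tolerance = 1e-10)
  expect_equal(eq$S_star + eq$I_star + eq$R_star, p$N,
               tolerance = 1e-9 * p$N)
})

test_that("with no non-contagious hazard and weak contagion only the free state remains", {
  p <- model_params(beta = 1.5e-7, epsilon = 0)
  eqs <- solve_equilibria(p)
  expect_length(eqs, 1)
  expect_equal(eqs[[1]]$I_star, 0)
  expect_equal(eqs[[1]]$S_star, p$N)
  expect_true(eqs[[1]]$stable)
})

test_that("strong relapse opens a bistable window below the classical threshold", {
  p <- model_params(beta = 3.5e-7, epsilon = 0)  # R0 ~ 0.83 < 1
  expect_lt(beta_to_R0(p$beta, p), 1)
  eqs <- solve_equilibria(p)
  expect_length(eqs, 3)
  # dense-scan oracle agrees on count and roots
  orc <- oracle_equilibria(p)
  expect_equal(nrow(orc), 3)
  expect_equal(vapply(eqs, function(e) e$lambda_star, numeric(1)),
               orc$lambda, tolerance = 1e-8)
  cls <- vapply(eqs, function(e) e$classification, character(1))
  expect_equal(cls, c("stable", "unstable", "stable"))
  # cross-check by perturbed forward integration off the unstable branch
  low <- eqs[[2]]
  up_state <- c(low$S_star - 0.1 * low$I_star, 1.1 * low$I_star,
                low$R_star)
  term <- unlist(tail(integrate_model(p, init = up_state, horizon = 3000),
                      1)[c("S", "I", "R")])
  expect_equal(unname(term[2]), eqs[[3]]$I_star,
               tolerance = 1e-3 * p$N / eqs[[3]]$I_star)
  dn_state <- c(low$S_star + 0.1 * low$I_star, 0.9 * low$I_star,
                low$R_star)
  term2 <- unlist(tail(integrate_model(p, init = dn_state, horizon = 5000),
                       1)[c("S", "I", "R")])
  expect_lt(term2[2], 0.02 * p$N)  # collapses toward the free state
})

test_that("the obesity-free state loses stability once R0 exceeds one", {
  p <- model_params(beta = 5e-7, epsilon = 0)  # R0 ~ 1.18
  eqs <- solve_equilibria(p)
  free <- eqs[[1]]
  expect_equal(free$I_star, 0)
  expect_false(free$stable)
  # analytic leading eigenvalue of the linearization at the free state
  expect_equal(max(Re(free$eigenvalues)),
               p$beta * p$N - (p$gamma + p$mu), tolerance = 1e-10)
})

test_that("stability rejects states that are not stationary", {
  p <- model_params()
  expect_error(stability(c(p$N, 0, 0), p), "not stationary")
  eq <- solve_equilibria(p)[[1]]
  s <- stability(eq, p)
  expect_true(s$stable)
  expect_equal(s$classification, "stable")
})

test_that("forward integration lands on a solved stable equilibrium", {
  p <- model_params()
  eq <- solve_equilibria(p)[[1]]
  term <- unlist(tail(integrate_model(p, horizon = 1000),
                      1)[c("S", "I", "R")])
  expect_equal(unname(term), c(eq$S_star, eq$I_star, eq$R_star),
               tolerance = 1e-3)
})

test_that("equilibria of the intervention-modified systems are stationary", {
  p <- model_params()
  for (fac in list(intervention_factors(alpha = 0.4),
                   intervention_factors(kappa = 2.5),
                   intervention_factors(alpha = 0.7, kappa = 0.5))) {
    eqs <- solve_equilibria(p, fac)
    expect_length(eqs, 1)
    e <- eqs[[1]]
    st <- c(e$S_star, e$I_star, e$R_star)
    resid <- obesitysir:::rhs_general(st, p, fac$alpha, fac$kappa)
    expect_lt(max(abs(resid)), 1e-9 * p$N)
  }
})

test_that("the scan recovers monotone prevalence and the bistable interval", {
  p <- model_params()
  scan <- bifurcation_scan(p, beta_grid = seq(0.5e-7, 5e-7, by = 0.25e-7),
                           epsilon_multipliers = c(0, 1))
  expect_true(all(scan$prevalence >= 0 & scan$prevalence <= 1))
  # with the baseline non-contagious hazard there is a unique equilibrium,
  # non-decreasing in beta
  base <- scan[scan$epsilon_multiplier == 1, ]
  expect_true(all(table(base$beta) == 1))
  expect_true(all(diff(base$prevalence[order(base$beta)]) >= -1e-9))
  # with epsilon = 0 some betas carry two stable equilibria
  free <- scan[scan$epsilon_multiplier == 0 & scan$stable, ]
  n_stable <- table(free$beta)
  expect_true(any(n_stable == 2))
})

test_that("the equilibrium force of infection reproduces the lifetime risk", {
  p <- model_params()
  eq <- solve_equilibria(p)[[1]]
  expect_equal(lifetime_risk(eq$lambda_star, p$mu),
               cumulative_risk(1e6, eq$lambda_star, p$mu),
               tolerance = 1e-12)
})
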