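# Independent oracles used across the suite.

# Dense-scan equilibrium oracle: the stationary prevalence at fixed lambda
# is written out with the unsimplified denominator (a different algebraic
# route from the package), and all self-consistent roots are located by a
# dense sign-change scan followed by bracketed refinement.
oracle_equilibria <- function(params, n_grid = 1e5) {
  mu <- params$mu; sg <- params$sigma; g0 <- params$gamma
  ifun <- function(l)
    l * mu * (sg * l + mu) /
      ((l + mu) * ((mu + g0) * (sg * l + mu) - sg * l * g0))
  gfun <- function(l)
    params$beta * params$N * ifun(l) + params$epsilon - l
  upper <- params$beta * params$N + params$epsilon
  roots <- if (params$epsilon == 0) 0 else numeric(0)
  if (upper > 0) {
    grid <- seq(0, upper, length.out = n_grid)
    gv <- gfun(grid)
    for (k in which(gv[-1] * gv[-n_grid] < 0))
      roots <- c(roots, uniroot(gfun, grid[k + 0:1], tol = 1e-14)$root)
  }
  roots <- sort(roots)
  data.frame(lambda = roots, prevalence = ifun(roots))
}

# Exact stationary state of the linear system obtained when the force of
# infection is frozen at lambda (e.g. beta = 0 so lambda = epsilon),
# computed by a direct linear solve -- independent of any closed form.
oracle_linear_stationary <- function(params, lambda) {
  mu <- params$mu; sg <- params$sigma; g0 <- params$gamma
  A <- matrix(c(-(lambda + mu), 0, 0,
                lambda, -(mu + g0), sg * lambda,
                0, g0, -(sg * lambda + mu)),
              nrow = 3, byrow = TRUE)
  as.numeric(solve(A, c(-mu * params$N, 0, 0)))
}

# Random valid states on the simplex S + I + R = N.
random_states <- function(n, N, seed) {
  set.seed(seed)
  t(replicate(n, {
    w <- runif(3)
    N * w / sum(w)
  }))
}
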