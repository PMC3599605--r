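# Rescale one named parameter of a model_params object by a multiplier.
# "inverse_gamma" scales the mean duration of obesity 1/gamma.
rescale_param <- function(params, target, multiplier) {
  v <- list(N = params$N, mu = params$mu, beta = params$beta,
            epsilon = params$epsilon, sigma = params$sigma,
            gamma = params$gamma)
  switch(target,
         epsilon = { v$epsilon <- v$epsilon * multiplier },
         beta = { v$beta <- v$beta * multiplier },
         sigma = { v$sigma <- v$sigma * multiplier },
         inverse_gamma = {
           if (multiplier <= 0)
             stop("'inverse_gamma' multiplier must be positive",
                  call. = FALSE)
           v$gamma <- v$gamma / multiplier
         },
         stop("unknown sweep target '", target, "'", call. = FALSE))
  do.call(model_params, v)
}

sweep_row <- function(eq, extra) {
  cbind(extra,
        data.frame(prevalence = eq$prevalence,
                   lambda_star = eq$lambda_star, stable = eq$stable))
}

new_sweep_result <- function(df, target, params, branches = NULL) {
  rownames(df) <- NULL
  structure(df, target = target, params = params, branches = branches,
            class = c("sweep_result", "data.frame"))
}

#' Equilibrium prevalence under a single rescaled parameter
#'
#' For each multiplier, rescales one parameter (`epsilon`, `beta`, the mean
#' obesity duration `inverse_gamma`, or `sigma`) away from its baseline
#' value, keeps the others fixed, and records the headline equilibrium
#' prevalence. The headline is the unique stable equilibrium, or -- in
#' bistable cells (pure contagion with strong relapse) -- the stable branch
#' reached by forward integration from the all-never-obese state; all
#' branches are retained in the `branches` attribute.
#'
#' Reductions correspond to multipliers below 1; multipliers above 1
#' (worsening scenarios) are also accepted.
#'
#' @param target one of `"epsilon"`, `"beta"`, `"inverse_gamma"`,
#'   `"sigma"`.
#' @param multipliers non-negative multipliers applied to the baseline
#'   value (strictly positive for `"inverse_gamma"`).
#' @param params baseline [model_params()].
#' @return A data frame of class `sweep_result` with columns `target`,
#'   `multiplier`, `value` (the rescaled absolute parameter value),
#'   `prevalence`, `lambda_star`, `stable`, `n_equilibria`, `bistable`.
#' @export
#' @examples
#' univariate_sweep("epsilon", c(0.5, 1), model_params(beta = 1.99e-7))
univariate_sweep <- function(target, multipliers, params = model_params()) {
  params <- as_model_params(params)
  if (!is.character(target) || length(target) != 1L)
    stop("'target' must be a single string", call. = FALSE)
  if (length(multipliers) == 0L || any(multipliers < 0))
    stop("'multipliers' must be non-negative", call. = FALSE)
  rows <- list()
  branches <- list()
  for (mlt in multipliers) {
    p <- rescale_param(params, target, mlt)
    eqs <- solve_equilibria(p)
    hd <- headline_equilibrium(p)
    nst <- sum(vapply(eqs, function(e) e$stable, logical(1)))
    val <- switch(target, epsilon = p$epsilon, beta = p$beta,
                  sigma = p$sigma, inverse_gamma = 1 / p$gamma)
    rows[[length(rows) + 1L]] <- sweep_row(
      hd, data.frame(target = target, multiplier = mlt, value = val))
    rows[[length(rows)]]$n_equilibria <- length(eqs)
    rows[[length(rows)]]$bistable <- nst > 1L
    for (j in seq_along(eqs))
      branches[[length(branches) + 1L]] <- sweep_row(
        eqs[[j]], data.frame(target = target, multiplier = mlt,
                             value = val, branch = j))
  }
  new_sweep_result(do.call(rbind, rows), target, params,
                   branches = do.call(rbind, branches))
}

#' Compare primary and secondary prevention programs
#'
#' Equilibrium prevalence of the primary-prevention system for each value
#' of `alpha` (with `kappa = 1`) and of the secondary-prevention system for
#' each value of `kappa` (with `alpha = 1`). Reducing `alpha` below 1
#' weakens all hazards on the never-obese; values above 1 describe
#' worsening hazards and are allowed. `kappa` scales the recovery rate and
#' the ex-obese re-infection hazard jointly.
#'
#' @param alpha_grid,kappa_grid non-negative factor values; either may be
#'   empty.
#' @param params baseline [model_params()].
#' @return A `sweep_result` data frame with columns `factor`
#'   (`"alpha"`/`"kappa"`), `value`, `prevalence`, `lambda_star`, `stable`,
#'   `bistable`.
#' @export
combined_sweep <- function(alpha_grid, kappa_grid,
                           params = model_params()) {
  params <- as_model_params(params)
  if (any(c(alpha_grid, kappa_grid) < 0))
    stop("factor grids must be non-negative", call. = FALSE)
  rows <- list()
  add <- function(name, value, fac) {
    eqs <- solve_equilibria(params, fac)
    hd <- headline_equilibrium(params, fac)
    nst <- sum(vapply(eqs, function(e) e$stable, logical(1)))
    r <- sweep_row(hd, data.frame(factor = name, value = value))
    r$bistable <- nst > 1L
    rows[[length(rows) + 1L]] <<- r
  }
  for (a in alpha_grid) add("alpha", a, intervention_factors(alpha = a))
  for (k in kappa_grid) add("kappa", k, intervention_factors(kappa = k))
  new_sweep_result(do.call(rbind, rows), "combined", params)
}

#' Prevalence sensitivity to transmission and recovery parameters
#'
#' Two panels of equilibrium data. The transmission panel scans the
#' transmission coefficient with the non-contagious hazard at several
#' multiples of baseline (including 0, where the backward bifurcation and
#' the abrupt rise of prevalence appear). The recovery panel scans the mean
#' duration of obesity `1/gamma` with the relapse hazard `sigma` at several
#' multiples of baseline. Every equilibrium branch is reported with its
#' stability flag; the branch the epidemic actually reaches from the
#' all-never-obese state is marked `headline`.
#'
#' @param params baseline [model_params()].
#' @param beta_grid transmission coefficients for the transmission panel.
#' @param epsilon_multipliers multipliers on baseline `epsilon`
#'   (default `c(0, 0.1, 1, 10)`).
#' @param inverse_gamma_grid mean durations of obesity (years) for the
#'   recovery panel.
#' @param sigma_multipliers multipliers on baseline `sigma`
#'   (default `c(0.1, 1, 10)`).
#' @return A list of class `hazard_recovery_sweep` with data-frame
#'   components `transmission` and `recovery`.
#' @export
hazard_recovery_sweep <- function(params = model_params(),
                                  beta_grid,
                                  epsilon_multipliers = c(0, 0.1, 1, 10),
                                  inverse_gamma_grid,
                                  sigma_multipliers = c(0.1, 1, 10)) {
  params <- as_model_params(params)
  if (length(beta_grid) == 0L || length(epsilon_multipliers) == 0L ||
      length(inverse_gamma_grid) == 0L || length(sigma_multipliers) == 0L)
    stop("all grids must be non-empty", call. = FALSE)

  cell <- function(p, id) {
    eqs <- solve_equilibria(p)
    hd <- headline_equilibrium(p)
    out <- list()
    for (j in seq_along(eqs)) {
      e <- eqs[[j]]
      r <- sweep_row(e, cbind(id, data.frame(branch = j)))
      r$headline <- abs(e$lambda_star - hd$lambda_star) <=
        1e-9 * max(1, hd$lambda_star)
      out[[j]] <- r
    }
    out
  }

  trans <- list()
  for (em in epsilon_multipliers) for (b in beta_grid) {
    p <- model_params(N = params$N, mu = params$mu, beta = b,
                      epsilon = params$epsilon * em, sigma = params$sigma,
                      gamma = params$gamma)
    trans <- c(trans, cell(p, data.frame(beta = b, epsilon_multiplier = em,
                                         epsilon = p$epsilon)))
  }
  recov <- list()
  for (sm in sigma_multipliers) for (d in inverse_gamma_grid) {
    p <- model_params(N = params$N, mu = params$mu, beta = params$beta,
                      epsilon = params$epsilon, sigma = params$sigma * sm,
                      gamma = 1 / d)
    recov <- c(recov, cell(p, data.frame(inverse_gamma = d,
                                         sigma_multiplier = sm,
                                         sigma = p$sigma)))
  }
  tdf <- do.call(rbind, trans); rownames(tdf) <- NULL
  rdf <- do.call(rbind, recov); rownames(rdf) <- NULL
  structure(list(transmission = tdf, recovery = rdf, params = params),
            class = "hazard_recovery_sweep")
}

#' Delay distribution from obesity onset to a late outcome
#'
#' Constructs the delay density `f(s)` used by [late_outcome_risk()]. The
#' gamma family is the default choice for onset-to-outcome delays; an
#' exponential and a point mass (fixed delay) are provided, and any custom
#' density on `[0, Inf)` can be supplied (it is checked to integrate to 1).
#'
#' @param family `"gamma"`, `"exponential"`, `"pointmass"` or `"custom"`.
#' @param shape,rate gamma/exponential parameters (rate in 1/year).
#' @param location point-mass delay (years, >= 0).
#' @param pdf density function for `family = "custom"`.
#' @return An object of class `delay_density`.
#' @export
#' @examples
#' delay_density("gamma", shape = 4, rate = 0.4)  # mean delay 10 y
delay_density <- function(family = c("gamma", "exponential", "pointmass",
                                     "custom"),
                          shape = NULL, rate = NULL, location = NULL,
                          pdf = NULL) {
  family <- match.arg(family)
  obj <- switch(family,
    gamma = {
      if (is.null(shape) || is.null(rate) || shape <= 0 || rate <= 0)
        stop("gamma delay needs positive 'shape' and 'rate'", call. = FALSE)
      list(pdf = function(s) stats::dgamma(s, shape = shape, rate = rate),
           mean = shape / rate, pars = list(shape = shape, rate = rate))
    },
    exponential = {
      if (is.null(rate) || rate <= 0)
        stop("exponential delay needs a positive 'rate'", call. = FALSE)
      list(pdf = function(s) stats::dexp(s, rate = rate),
           mean = 1 / rate, pars = list(rate = rate))
    },
    pointmass = {
      if (is.null(location) || location < 0)
        stop("point-mass delay needs a non-negative 'location'",
             call. = FALSE)
      list(pdf = NULL, mean = location, pars = list(location = location))
    },
    custom = {
      if (!is.function(pdf))
        stop("custom delay needs a 'pdf' function", call. = FALSE)
      tot <- stats::integrate(pdf, 0, Inf)$value
      if (abs(tot - 1) > 1e-6)
        stop(sprintf(
          "delay density must integrate to 1 over [0, Inf) (got %.6g)",
          tot), call. = FALSE)
      list(pdf = pdf, mean = NA_real_, pars = list())
    })
  structure(c(list(family = family), obj), class = "delay_density")
}

#' Age-specific risk of a late outcome of obesity
#'
#' Convolves the probability of having ever become obese by a given age,
#' `1 - x(a)` with `x(a) = exp(-(lambda* + mu) a)`, with a delay density
#' `f(s)` from obesity onset to the outcome (for example a heart attack),
#' scaled by the overall outcome risk `p`:
#' \deqn{w(a) = p \int_0^\infty f(s)\,(1 - x(a - s))\, ds,}
#' with `1 - x(u) = 0` for `u < 0`. The cohort-survival interpretation of
#' `1 - x(a)` is used (not an individual's own obesity history). `w` is
#' non-decreasing in age, linear in `p`, and bounded by `p`.
#'
#' @param a age(s) in years (>= 0); vectorized.
#' @param p overall scaling risk of the outcome, in `[0, 1]`.
#' @param delay a [delay_density()] object.
#' @param lambda_star equilibrium force of infection (1/year).
#' @param mu birth/death rate (1/year).
#' @param abs_tol absolute quadrature tolerance (default 1e-8).
#' @return Risk values on the probability scale.
#' @export
#' @examples
#' d <- delay_density("gamma", shape = 4, rate = 0.4)
#' late_outcome_risk(c(40, 60, 80), p = 0.3, d, 0.03, 1 / 69.4)
late_outcome_risk <- function(a, p, delay, lambda_star, mu,
                              abs_tol = 1e-8) {
  if (!inherits(delay, "delay_density"))
    stop("'delay' must come from delay_density()", call. = FALSE)
  if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1)
    stop("'p' must be a probability in [0, 1]", call. = FALSE)
  if (any(a < 0)) stop("'a' must be non-negative", call. = FALSE)
  onset <- function(u) ifelse(u <= 0, 0, 1 - exp(-(lambda_star + mu) * u))
  if (delay$family == "pointmass") {
    s0 <- delay$pars$location
    return(p * onset(a - s0))
  }
  vapply(a, function(ai) {
    if (ai <= 0) return(0)
    p * stats::integrate(function(s) delay$pdf(s) * onset(ai - s),
                         lower = 0, upper = ai, abs.tol = abs_tol,
                         subdivisions = 400L)$value
  }, numeric(1))
}
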