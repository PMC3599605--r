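#' Force of infection (overall hazard of obesity)
#'
#' The per-capita hazard at which never-obese individuals acquire obesity is
#' additive in two independent routes: a contagious route proportional to the
#' current number of obese individuals, \eqn{\lambda_1 = \beta I}, and a
#' constant non-contagious route \eqn{\lambda_2 = \epsilon} (genetics,
#' lifestyle, diet). Ex-obese individuals experience \eqn{\sigma} times this
#' hazard.
#'
#' @param I number of obese individuals (>= 0); vectorized.
#' @param params a [model_params()] object.
#' @param parts if `TRUE`, return a two-column matrix with the contagious and
#'   non-contagious components instead of their sum.
#' @return Hazard in 1/year: a numeric vector, or a matrix with columns
#'   `contagious`, `noncontagious` when `parts = TRUE`.
#' @export
#' @examples
#' force_of_infection(0, model_params())       # = epsilon
#' force_of_infection(60800, model_params())   # ~ 0.030 per year
force_of_infection <- function(I, params, parts = FALSE) {
  params <- as_model_params(params)
  if (!is.numeric(I) || any(!is.finite(I)) || any(I < 0))
    stop("'I' must be finite and non-negative", call. = FALSE)
  l1 <- params$beta * I
  if (parts)
    cbind(contagious = l1, noncontagious = rep(params$epsilon, length(I)))
  else
    l1 + params$epsilon
}

# Validate and name a compartment state (S, I, R).
as_state <- function(state) {
  if (is.list(state)) state <- unlist(state)
  if (!is.numeric(state) || length(state) != 3L || any(!is.finite(state)))
    stop("a state must be three finite numbers (S, I, R)", call. = FALSE)
  if (any(state < 0))
    stop("compartment counts must be non-negative", call. = FALSE)
  names(state) <- c("S", "I", "R")
  state
}

# Shared derivative of the general (intervention-modified) system.
# alpha multiplies the hazard acting on S; kappa multiplies both the
# recovery rate and the ex-obese re-infection hazard. alpha = kappa = 1
# is the baseline system.
rhs_general <- function(state, params, alpha = 1, kappa = 1) {
  S <- state[[1L]]; I <- state[[2L]]; R <- state[[3L]]
  lam <- params$beta * I + params$epsilon
  dS <- params$mu * params$N - alpha * lam * S - params$mu * S
  dI <- alpha * lam * S + kappa * params$sigma * lam * R -
    (params$mu + kappa * params$gamma) * I
  dR <- kappa * params$gamma * I - kappa * params$sigma * lam * R -
    params$mu * R
  c(dS = dS, dI = dI, dR = dR)
}

#' Time derivatives of the baseline transmission system
#'
#' The baseline model tracks never-obese (`S`), obese (`I`) and ex-obese
#' (`R`) individuals:
#' \deqn{dS/dt = \mu N - (\beta I + \epsilon) S - \mu S}
#' \deqn{dI/dt = (\beta I + \epsilon) S + \sigma(\beta I + \epsilon) R - (\mu + \gamma) I}
#' \deqn{dR/dt = \gamma I - \sigma(\beta I + \epsilon) R - \mu R}
#' Ex-obese individuals are assumed non-contagious; they relapse at
#' \eqn{\sigma} times the hazard of the never-obese. The three derivatives
#' always sum to zero, so \eqn{S + I + R = N} is conserved.
#'
#' @param state numeric vector `c(S, I, R)` of non-negative counts.
#' @param params a [model_params()] object.
#' @return Named numeric vector `c(dS, dI, dR)` in individuals/year.
#' @seealso [rhs_primary()], [rhs_secondary()], [integrate_model()]
#' @export
#' @examples
#' p <- model_params()
#' rhs_baseline(c(p$N, 0, 0), p)  # dI/dt = epsilon * N
rhs_baseline <- function(state, params) {
  params <- as_model_params(params)
  rhs_general(as_state(state), params)
}

#' Time derivatives under primary prevention
#'
#' Primary prevention (interventions on social contact and on weight gain
#' among never-obese individuals) reduces both the contagious and
#' non-contagious hazards acting on never-obese individuals equally by the
#' factor `alpha`; the hazard terms acting on ex-obese individuals are
#' unchanged.
#'
#' @inheritParams rhs_baseline
#' @param alpha hazard multiplier on the never-obese (>= 0); `alpha = 1`
#'   recovers the baseline system.
#' @return Named numeric vector `c(dS, dI, dR)` in individuals/year.
#' @export
rhs_primary <- function(state, params, alpha) {
  params <- as_model_params(params)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha < 0)
    stop("'alpha' must be a single finite non-negative number", call. = FALSE)
  rhs_general(as_state(state), params, alpha = alpha)
}

#' Time derivatives under secondary prevention
#'
#' Secondary prevention (dietary restriction among obese individuals and
#' follow-up of ex-obese individuals) multiplies by `kappa` both the
#' recovery rate \eqn{\gamma} and the overall re-infection hazard
#' \eqn{\sigma(\beta I + \epsilon)} of ex-obese individuals.
#'
#' @inheritParams rhs_baseline
#' @param kappa enhancement factor on the secondary-prevention rates (>= 0);
#'   `kappa = 1` recovers the baseline system.
#' @return Named numeric vector `c(dS, dI, dR)` in individuals/year.
#' @export
rhs_secondary <- function(state, params, kappa) {
  params <- as_model_params(params)
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa < 0)
    stop("'kappa' must be a single finite non-negative number", call. = FALSE)
  rhs_general(as_state(state), params, kappa = kappa)
}

integration_error <- function(msg) {
  stop(errorCondition(msg, class = c("obesitysir_integration_error", "error")))
}

#' Integrate the transmission system over time
#'
#' Adaptive-step integration (via \pkg{deSolve}'s `lsoda`) of the baseline
#' or intervention-modified system. Conservation of the population size is
#' verified on the returned grid (never enforced by renormalization); a
#' violation beyond `1e-6 * N`, or any compartment below `-1e-9 * N`, is
#' reported as an integration failure (condition class
#' `obesitysir_integration_error`), distinct from invalid-input errors.
#'
#' @param params a [model_params()] object.
#' @param init initial state `c(S, I, R)`, non-negative, summing to `N`.
#'   Defaults to the conventional all-never-obese population `(N, 0, 0)`.
#' @param horizon final time (years), > 0.
#' @param factors an [intervention_factors()] object; the default
#'   (`alpha = 1, kappa = 1`) integrates the baseline system.
#' @param times optional output time grid (strictly increasing, starting
#'   at 0); by default roughly one point per year, at least 201 points.
#' @param rtol,atol relative and absolute integration tolerances; the
#'   defaults (1e-8, 1e-10 N) hold comfortably for relapse hazards up to an
#'   order of magnitude above baseline.
#' @return An object of class `obesity_trajectory`: a data frame with
#'   columns `t`, `S`, `I`, `R`, carrying the parameters and factors as
#'   attributes.
#' @export
#' @examples
#' traj <- integrate_model(model_params(), horizon = 300)
#' tail(traj, 1)  # prevalence I/N approaching its equilibrium value
integrate_model <- function(params, init = c(params$N, 0, 0), horizon = 1000,
                            factors = intervention_factors(), times = NULL,
                            rtol = 1e-8, atol = 1e-10 * params$N) {
  params <- as_model_params(params)
  factors <- as_factors(factors)
  init <- as_state(init)
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0)
    stop("'horizon' must be a single positive number", call. = FALSE)
  if (abs(sum(init) - params$N) > 1e-6 * params$N)
    stop("initial state must sum to N", call. = FALSE)
  if (is.null(times)) {
    npt <- max(201L, min(2001L, as.integer(ceiling(horizon)) + 1L))
    times <- seq(0, horizon, length.out = npt)
  }
  if (any(diff(times) <= 0) || times[1L] != 0)
    stop("'times' must be strictly increasing and start at 0", call. = FALSE)

  deriv <- function(t, y, parms)
    list(rhs_general(y, params, factors$alpha, factors$kappa))
  sol <- deSolve::ode(y = init, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    integration_error("ODE solver failed to meet the requested tolerance")
  out <- as.data.frame(sol)
  names(out) <- c("t", "S", "I", "R")
  cons <- max(abs(out$S + out$I + out$R - params$N)) / params$N
  if (cons > 1e-6)
    integration_error(sprintf(
      "population conservation violated (max relative drift %.3g)", cons))
  if (min(out$S, out$I, out$R) < -1e-9 * params$N)
    integration_error("a compartment became negative beyond tolerance")
  structure(out, params = params, factors = factors,
            class = c("obesity_trajectory", "data.frame"))
}

#' Time taken to settle at an equilibrium
#'
#' First time after which every compartment of a trajectory stays within
#' `rel_tol * N` (sup norm over compartments, relative to the population
#' size) of the given equilibrium through the end of the horizon. With the
#' default 0.5% band, the baseline epidemic started from an all-never-obese
#' population settles on the order of two centuries.
#'
#' @param traj an `obesity_trajectory` from [integrate_model()].
#' @param eq an `equilibrium_point` (see [solve_equilibria()]), or a numeric
#'   vector `c(S, I, R)`.
#' @param rel_tol convergence band relative to `N` (default 0.005).
#' @return Time in years, rounded to the nearest year.
#' @export
time_to_equilibrium <- function(traj, eq, rel_tol = 0.005) {
  if (!inherits(traj, "obesity_trajectory"))
    stop("'traj' must come from integrate_model()", call. = FALSE)
  if (!is.numeric(rel_tol) || length(rel_tol) != 1L || rel_tol <= 0)
    stop("'rel_tol' must be a single positive number", call. = FALSE)
  N <- attr(traj, "params")$N
  tgt <- if (inherits(eq, "equilibrium_point"))
    c(eq$S_star, eq$I_star, eq$R_star) else as_state(eq)
  dev <- pmax(abs(traj$S - tgt[1L]), abs(traj$I - tgt[2L]),
              abs(traj$R - tgt[3L])) / N
  ok <- dev <= rel_tol
  if (!ok[length(ok)])
    stop(errorCondition(
      "trajectory has not converged to the equilibrium within its horizon",
      class = c("obesitysir_no_convergence", "error")))
  # first index from which the band is never left again
  stays <- rev(cumprod(rev(ok))) > 0
  round(traj$t[which(stays)[1L]])
}
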