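#' Stationary age profile at a fixed force of infection
#'
#' In an endemic equilibrium, the numbers of never-obese `X(a)`, obese
#' `Y(a)` and ex-obese `Z(a)` individuals at age `a` obey a linear system
#' with constant coefficients,
#' \deqn{dX/da = -(\lambda^* + \mu) X,}
#' \deqn{dY/da = \lambda^* X + \sigma\lambda^* Z - (\mu + \gamma) Y,}
#' \deqn{dZ/da = -(\sigma\lambda^* + \mu) Z + \gamma Y,}
#' started from the birth-cohort inflow `(Nc(0), 0, 0)` with
#' `Nc(0) = mu * N` (newborns are never obese). Because life expectancy is
#' exponentially distributed, the cohort size decays as
#' `Nc(a) = Nc(0) exp(-mu a)`, and the never-obese occupancy has the closed
#' form `X(a) = Nc(0) exp(-(lambda* + mu) a)`.
#'
#' The force of infection is a fixed input here (typically `lambda_star`
#' from [solve_equilibria()]): the age structure does not feed back on
#' transmission.
#'
#' @param lambda_star equilibrium force of infection (1/year, >= 0).
#' @param params a [model_params()] object.
#' @param max_age oldest age on the grid (years; default 110).
#' @param step output grid step (years; default 0.1).
#' @param rtol,atol integration tolerances (same adaptive contract as
#'   [integrate_model()]).
#' @return An object of class `age_profile`: a data frame with columns
#'   `age`, `X`, `Y`, `Z`, with `lambda_star`, `Nc0` and the parameters
#'   attached as attributes.
#' @export
#' @examples
#' prof <- solve_age_profile(0.03, model_params(), max_age = 90)
#' head(prof)
solve_age_profile <- function(lambda_star, params, max_age = 110, step = 0.1,
                              rtol = 1e-8, atol = NULL) {
  params <- as_model_params(params)
  if (!is.numeric(lambda_star) || length(lambda_star) != 1L ||
      !is.finite(lambda_star) || lambda_star < 0)
    stop("'lambda_star' must be a single finite non-negative number",
         call. = FALSE)
  if (!is.numeric(max_age) || length(max_age) != 1L || max_age <= 0)
    stop("'max_age' must be a single positive number", call. = FALSE)
  Nc0 <- params$mu * params$N
  if (is.null(atol)) atol <- 1e-10 * Nc0
  ages <- seq(0, max_age, by = step)
  deriv <- function(a, y, parms) {
    lam <- lambda_star
    list(c(-(lam + params$mu) * y[1L],
           lam * y[1L] + params$sigma * lam * y[3L] -
             (params$mu + params$gamma) * y[2L],
           -(params$sigma * lam + params$mu) * y[3L] +
             params$gamma * y[2L]))
  }
  sol <- deSolve::ode(y = c(Nc0, 0, 0), times = ages, func = deriv,
                      parms = NULL, method = "lsoda", rtol = rtol,
                      atol = atol)
  if (attr(sol, "istate")[1L] < 0)
    integration_error("age-profile integration failed to meet tolerance")
  out <- data.frame(age = ages, X = sol[, 2L], Y = sol[, 3L], Z = sol[, 4L])
  structure(out, lambda_star = lambda_star, Nc0 = Nc0, params = params,
            class = c("age_profile", "data.frame"))
}

# Closed-form occupancies of the constant-coefficient age system via
# eigen-decomposition; used for fast repeated evaluation when locating the
# peak-risk age. Falls back to numerical integration if the spectrum is
# (near-)degenerate.
age_occupancy <- function(ages, lambda_star, params) {
  mu <- params$mu; sg <- params$sigma; g <- params$gamma
  l <- lambda_star
  A <- matrix(c(-(l + mu),          0,            0,
                l,          -(mu + g),     sg * l,
                0,                  g, -(sg * l + mu)),
              nrow = 3L, byrow = TRUE)
  Nc0 <- mu * params$N
  es <- eigen(A)
  ev <- es$values
  gap <- min(Mod(outer(ev, ev, "-")[lower.tri(diag(3))]))
  if (is.complex(ev) || gap < 1e-10 * max(Mod(ev))) {
    prof <- solve_age_profile(lambda_star, params,
                              max_age = max(ages, 1), step = 0.05)
    idx <- vapply(ages, function(a) which.min(abs(prof$age - a)), integer(1))
    return(as.matrix(prof[idx, c("X", "Y", "Z")]))
  }
  co <- solve(es$vectors, c(Nc0, 0, 0))
  t(vapply(ages,
           function(a) as.numeric(es$vectors %*% (co * exp(es$values * a))),
           numeric(3L))) |>
    `colnames<-`(c("X", "Y", "Z"))
}

#' Probability of remaining never-obese by a given age
#'
#' `x(a) = exp(-(lambda* + mu) a)`, the closed-form survivor function of the
#' never-obese state in the stationary age system (jointly escaping obesity
#' onset and death).
#'
#' @param a age (years, >= 0); vectorized.
#' @param lambda_star force of infection (1/year).
#' @param mu birth/death rate (1/year).
#' @return Probability in `[0, 1]`.
#' @export
never_obese_fraction <- function(a, lambda_star, mu) {
  if (any(a < 0)) stop("'a' must be non-negative", call. = FALSE)
  exp(-(lambda_star + mu) * a)
}

#' Cumulative risk of obesity by a given age
#'
#' The probability of having left the never-obese state by age `a`,
#' \deqn{q(a) = \int_0^a \lambda^* x(s) ds
#'   = \frac{\lambda^*}{\lambda^* + \mu}\left(1 - e^{-(\lambda^*+\mu)a}\right).}
#' It increases monotonically to the lifetime risk
#' \eqn{\lambda^*/(\lambda^*+\mu)} as `a` grows.
#'
#' @inheritParams never_obese_fraction
#' @return Probability in `[0, 1)`; vectorized over `a`.
#' @export
#' @examples
#' cumulative_risk(c(20, 40, 80), 0.03, 1 / 69.4)
cumulative_risk <- function(a, lambda_star, mu) {
  if (any(a < 0)) stop("'a' must be non-negative", call. = FALSE)
  if (lambda_star < 0) stop("'lambda_star' must be non-negative",
                            call. = FALSE)
  if (lambda_star == 0) return(rep(0, length(a)))
  lambda_star / (lambda_star + mu) * (1 - exp(-(lambda_star + mu) * a))
}

#' Lifetime risk of experiencing obesity
#'
#' The limiting cumulative risk \eqn{q(\infty) = \lambda^*/(\lambda^*+\mu)}:
#' the probability of ever leaving the never-obese state during life. It is
#' monotone increasing in the force of infection, so a larger equilibrium
#' prevalence always implies a larger lifetime risk.
#'
#' @inheritParams never_obese_fraction
#' @return Probability in `[0, 1)`.
#' @export
lifetime_risk <- function(lambda_star, mu) {
  if (any(lambda_star < 0)) stop("'lambda_star' must be non-negative",
                                 call. = FALSE)
  lambda_star / (lambda_star + mu)
}

#' Age at which the birth-cohort risk of obesity peaks
#'
#' The risk of being obese at age `a` for a newborn, `Y(a)/Nc(0)`, rises
#' while the force of infection recruits the cohort into obesity and then
#' falls as natural mortality thins it; the maximizing age is located by a
#' coarse grid followed by golden-section refinement (via
#' `stats::optimize`), to within 0.05 years. Flat maxima resolve to the
#' smallest age. The alternative normalization by the survivors of age `a`,
#' `Y(a)/Nc(a)`, is exposed through `normalization = "current"`.
#'
#' @param lambda_star equilibrium force of infection (1/year, > 0; the risk
#'   curve is identically zero at 0, where the peak is undefined).
#' @param params a [model_params()] object.
#' @param normalization `"birth"` (default) divides by the cohort inflow
#'   `Nc(0)`; `"current"` divides by the survivors `Nc(a)`.
#' @param max_age upper end of the search range (years).
#' @param grid_step coarse bracketing grid step (years).
#' @return The peak age in years.
#' @export
#' @examples
#' peak_obesity_age(0.03, model_params())
peak_obesity_age <- function(lambda_star, params,
                             normalization = c("birth", "current"),
                             max_age = 110, grid_step = 0.5) {
  params <- as_model_params(params)
  normalization <- match.arg(normalization)
  if (!is.numeric(lambda_star) || length(lambda_star) != 1L ||
      !is.finite(lambda_star) || lambda_star <= 0)
    stop("peak age is undefined for lambda_star <= 0 (Y is identically zero)",
         call. = FALSE)
  Nc0 <- params$mu * params$N
  risk <- function(a) {
    y <- age_occupancy(a, lambda_star, params)[, "Y"]
    if (normalization == "current") y / (Nc0 * exp(-params$mu * a))
    else y / Nc0
  }
  grid <- seq(0, max_age, by = grid_step)
  rv <- risk(grid)
  k <- which.max(rv)  # which.max takes the first (smallest-age) maximum
  lo <- grid[max(1L, k - 1L)]
  hi <- grid[min(length(grid), k + 1L)]
  if (lo == hi) return(lo)
  opt <- stats::optimize(function(a) risk(a), interval = c(lo, hi),
                         maximum = TRUE, tol = 0.01)
  if (rv[k] > opt$objective) grid[k] else opt$maximum
}
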