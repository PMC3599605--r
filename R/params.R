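#' Parameters of the obesity transmission model
#'
#' Bundle the six epidemiological constants that define the compartmental
#' model: never-obese individuals acquire obesity at the force of infection
#' \eqn{\lambda(t) = \beta I(t) + \epsilon} (a contagious route proportional
#' to the number of obese individuals plus a constant non-contagious hazard),
#' recover at rate \eqn{\gamma}, and, once ex-obese, relapse at
#' \eqn{\sigma \lambda(t)} with \eqn{\sigma > 1} reflecting the elevated risk
#' of weight regain. Births and deaths occur at the common rate \eqn{\mu},
#' keeping the population size \eqn{N} constant.
#'
#' Defaults are the baseline values used throughout the package:
#' a hypothetical randomly mixing population of 100,000 with life expectancy
#' 69.4 years, transmission coefficient 2.96e-7 per individual per year
#' (calibrated from household secondary attack proportions, see
#' [sap_to_R0()]), non-contagious hazard 0.012 per year, relative relapse
#' hazard 8.0, and mean duration of obesity 35.8 years.
#'
#' @param N population size (individuals); constant over time.
#' @param mu per-capita birth and death rate (1/year). Must be positive:
#'   the stationary age structure requires demographic turnover.
#' @param beta transmission coefficient (per individual per year); may be 0.
#' @param epsilon non-contagious hazard of obesity (1/year); may be 0.
#' @param sigma relative hazard of obesity among ex-obese individuals
#'   (dimensionless, typically > 1); any non-negative value is accepted.
#' @param gamma recovery rate from obesity (1/year).
#'
#' @return An object of class `model_params`: a named list with components
#'   `N`, `mu`, `beta`, `epsilon`, `sigma`, `gamma`.
#' @seealso [rhs_baseline()], [solve_equilibria()], [integrate_model()]
#' @export
#' @examples
#' p <- model_params()
#' p
#' # transmission switched off:
#' model_params(beta = 0)
model_params <- function(N = 1e5, mu = 1 / 69.4, beta = 2.96e-7,
                         epsilon = 0.012, sigma = 8.0, gamma = 1 / 35.8) {
  vals <- list(N = N, mu = mu, beta = beta, epsilon = epsilon,
               sigma = sigma, gamma = gamma)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (N <= 0) stop("'N' must be positive", call. = FALSE)
  if (mu <= 0) stop("'mu' must be positive (demographic turnover required)",
                    call. = FALSE)
  if (gamma <= 0) stop("'gamma' must be positive", call. = FALSE)
  if (beta < 0) stop("'beta' must be non-negative", call. = FALSE)
  if (epsilon < 0) stop("'epsilon' must be non-negative", call. = FALSE)
  if (sigma < 0) stop("'sigma' must be non-negative", call. = FALSE)
  structure(vals, class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("Obesity transmission model parameters\n")
  cat(sprintf("  N       = %g individuals\n", x$N))
  cat(sprintf("  mu      = %.6g /y   (life expectancy %.4g y)\n", x$mu, 1 / x$mu))
  cat(sprintf("  beta    = %.6g per individual per y\n", x$beta))
  cat(sprintf("  epsilon = %.6g /y\n", x$epsilon))
  cat(sprintf("  sigma   = %.6g\n", x$sigma))
  cat(sprintf("  gamma   = %.6g /y   (mean duration %.4g y)\n", x$gamma, 1 / x$gamma))
  invisible(x)
}

as_model_params <- function(params) {
  if (!inherits(params, "model_params"))
    stop("'params' must be created by model_params()", call. = FALSE)
  params
}

#' Intervention factors for prevention programs
#'
#' Two dimensionless multipliers describe the intervention variants of the
#' baseline system. Primary prevention reduces both the contagious and
#' non-contagious hazards acting on never-obese individuals by the factor
#' `alpha` (hazards on ex-obese individuals are untouched). Secondary
#' prevention multiplies by `kappa` both the recovery rate (dietary
#' restriction among the obese) and the overall re-infection hazard of
#' ex-obese individuals (follow-up programs). `alpha = 1, kappa = 1`
#' reproduces the baseline system exactly.
#'
#' @param alpha multiplier on the never-obese hazards (>= 0).
#' @param kappa multiplier on recovery and ex-obese re-infection (>= 0).
#' @return An object of class `intervention_factors`.
#' @seealso [rhs_primary()], [rhs_secondary()]
#' @export
#' @examples
#' intervention_factors(alpha = 0.5)
intervention_factors <- function(alpha = 1, kappa = 1) {
  for (nm in c("alpha", "kappa")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0)
      stop("'", nm, "' must be a single finite non-negative number",
           call. = FALSE)
  }
  structure(list(alpha = alpha, kappa = kappa),
            class = "intervention_factors")
}

#' @export
print.intervention_factors <- function(x, ...) {
  cat(sprintf("Intervention factors: alpha = %g, kappa = %g\n",
              x$alpha, x$kappa))
  invisible(x)
}

as_factors <- function(factors) {
  if (!inherits(factors, "intervention_factors"))
    stop("'factors' must be created by intervention_factors()", call. = FALSE)
  factors
}
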