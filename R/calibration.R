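#' Translate a household secondary attack proportion into R0
#'
#' In a confined household with a single index case and `m`
#' susceptible-and-exposed members, a generalized stochastic epidemic in
#' which the index's sojourn competes with per-susceptible transmission
#' gives the secondary attack proportion
#' \deqn{SAP = \frac{R_0}{R_0 + m},}
#' so the basic reproduction number is recovered exactly as
#' `R0 = m * sap / (1 - sap)`.
#'
#' @param sap secondary attack proportion, in `[0, 1)`; vectorized.
#' @param m number of susceptible-and-exposed household members (>= 1).
#' @return The basic reproduction number (dimensionless).
#' @seealso [R0_to_beta()], [simulate_households()]
#' @export
#' @examples
#' sap_to_R0(0.25, m = 3)   # 1
#' sap_to_R0(c(0.135, 0.254), m = 3)
sap_to_R0 <- function(sap, m) {
  if (!is.numeric(sap) || any(!is.finite(sap)) || any(sap < 0) ||
      any(sap >= 1))
    stop("'sap' must lie in [0, 1): sap = 1 has no finite R0", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  m * sap / (1 - sap)
}

#' Convert a basic reproduction number to a transmission coefficient
#'
#' Uses the special-case relation `R0 = beta * N / (gamma + mu)`, which is
#' exact only when the non-contagious hazard is zero -- the natural
#' assumption for household observations collected over periods short
#' relative to the life expectancy. The conversion therefore uses only
#' `N`, `gamma` and `mu` from `params` and does not gate on `epsilon`.
#'
#' @param R0 basic reproduction number (>= 0); vectorized.
#' @param params a [model_params()] object supplying `N`, `gamma`, `mu`.
#' @return Transmission coefficient in per individual per year.
#' @export
#' @examples
#' p <- model_params()
#' R0_to_beta(sap_to_R0(0.135, 3), p)  # ~ 1.99e-7
#' R0_to_beta(sap_to_R0(0.254, 3), p)  # ~ 4.33e-7
R0_to_beta <- function(R0, params) {
  params <- as_model_params(params)
  if (!is.numeric(R0) || any(!is.finite(R0)) || any(R0 < 0))
    stop("'R0' must be finite and non-negative", call. = FALSE)
  R0 * (params$gamma + params$mu) / params$N
}

#' Convert a transmission coefficient to a basic reproduction number
#'
#' Exact inverse of [R0_to_beta()]: `R0 = beta * N / (gamma + mu)`.
#'
#' @param beta transmission coefficient (>= 0); vectorized.
#' @inheritParams R0_to_beta
#' @return The basic reproduction number.
#' @export
beta_to_R0 <- function(beta, params) {
  params <- as_model_params(params)
  if (!is.numeric(beta) || any(!is.finite(beta)) || any(beta < 0))
    stop("'beta' must be finite and non-negative", call. = FALSE)
  beta * params$N / (params$gamma + params$mu)
}
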