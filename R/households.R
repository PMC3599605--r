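# Run an expression with a private, seeded RNG stream, restoring any
# pre-existing global state afterwards.
with_private_seed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  expr
}

#' Simulate household outbreaks with a single index case
#'
#' Generative counterpart of the secondary-attack-proportion relation
#' `SAP = R0 / (R0 + m)`: in each household the index case's sojourn in the
#' obese state is `T ~ Exponential(gamma + mu)` (recovery competing with
#' death), and each of the `m` susceptible members independently becomes
#' obese with probability `1 - exp(-b T)`, where `b = R0 (gamma + mu) / m`
#' is the per-susceptible transmission rate. Marginalizing over `T`, each
#' susceptible is infected with probability `b / (b + gamma + mu)
#' = R0 / (R0 + m)` exactly. Only first-generation transmission is
#' simulated -- no tertiary chains -- which is what makes the identity exact
#' and mirrors the definition of a secondary attack proportion.
#'
#' @param R0 generating basic reproduction number (>= 0).
#' @param m susceptible-and-exposed members per household (integer >= 1).
#' @param n_households number of households (integer >= 1).
#' @param params a [model_params()] object (supplies `gamma` and `mu`).
#' @param seed integer seed; mandatory, so samples are reproducible
#'   bit-for-bit. The generator state is private: the caller's global RNG
#'   stream is left untouched.
#' @return An object of class `household_sample`: a list with `m`,
#'   `n_households`, `secondary_counts` (one count in `0..m` per
#'   household), `sojourns` (the index sojourn times, years), `seed` and
#'   `true_R0`.
#' @seealso [estimate_sap()], [recover_beta()]
#' @export
#' @examples
#' hh <- simulate_households(R0 = 1, m = 3, n_households = 1000,
#'                           params = model_params(), seed = 1)
#' mean(hh$secondary_counts) / hh$m  # ~ 0.25 = R0/(R0+m)
simulate_households <- function(R0, m, n_households, params, seed) {
  params <- as_model_params(params)
  if (!is.numeric(R0) || length(R0) != 1L || !is.finite(R0) || R0 < 0)
    stop("'R0' must be a single finite non-negative number", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'m' must be a positive integer", call. = FALSE)
  if (!is.numeric(n_households) || length(n_households) != 1L ||
      n_households < 1 || n_households != round(n_households))
    stop("'n_households' must be a positive integer", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      !is.finite(seed))
    stop("'seed' is mandatory (single integer)", call. = FALSE)
  rate <- params$gamma + params$mu
  b <- R0 * rate / m
  sims <- with_private_seed(seed, {
    sojourns <- stats::rexp(n_households, rate = rate)
    counts <- stats::rbinom(n_households, size = m,
                            prob = -expm1(-b * sojourns))
    list(sojourns = sojourns, counts = counts)
  })
  structure(list(m = as.integer(m), n_households = as.integer(n_households),
                 secondary_counts = sims$counts, sojourns = sims$sojourns,
                 seed = seed, true_R0 = R0, index_rate = rate,
                 transmission_rate = b),
            class = "household_sample")
}

#' @export
print.household_sample <- function(x, ...) {
  cat(sprintf(
    "Household outbreak sample: %d households, m = %d, generating R0 = %g\n",
    x$n_households, x$m, x$true_R0))
  cat(sprintf("  pooled secondary attack proportion: %.4f (seed %s)\n",
              sum(x$secondary_counts) / (x$n_households * x$m),
              format(x$seed)))
  invisible(x)
}

# Wilson score interval for a proportion.
wilson_interval <- function(p_hat, n, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) /
    (1 + z^2 / n)
  c(lower = max(0, centre - half), upper = min(1, centre + half))
}

#' Estimate the secondary attack proportion from a household sample
#'
#' Pooled estimate `sum(counts) / (n * m)` with a Wilson score interval.
#' Because all susceptibles in a household share the index's sojourn time,
#' within-household outcomes are positively correlated; with
#' `cluster_adjust = TRUE` (the default) the interval is computed on an
#' effective number of trials deflated by the estimated design effect
#' (household-level variance of the per-household proportions), which
#' restores close-to-nominal coverage. `cluster_adjust = FALSE` gives the
#' plain binomial Wilson interval, which under-covers for clustered data.
#'
#' @param sample a `household_sample` from [simulate_households()].
#' @param conf_level confidence level (default 0.95).
#' @param cluster_adjust adjust the interval for within-household
#'   correlation (default `TRUE`).
#' @return An object of class `sap_estimate`: a list with `estimate`,
#'   `lower`, `upper`, `conf_level`, `n_trials`, `n_effective`.
#' @export
estimate_sap <- function(sample, conf_level = 0.95, cluster_adjust = TRUE) {
  if (!inherits(sample, "household_sample"))
    stop("'sample' must come from simulate_households()", call. = FALSE)
  if (sample$n_households < 1L || length(sample$secondary_counts) == 0L)
    stop("empty sample", call. = FALSE)
  n <- sample$n_households
  m <- sample$m
  n_trials <- n * m
  p_hat <- sum(sample$secondary_counts) / n_trials
  n_eff <- n_trials
  if (cluster_adjust && n > 1L) {
    v <- stats::var(sample$secondary_counts / m)
    if (v > 0) n_eff <- min(n_trials, n * p_hat * (1 - p_hat) / v)
  }
  ci <- wilson_interval(p_hat, n_eff, conf_level)
  structure(list(estimate = p_hat, lower = ci[["lower"]],
                 upper = ci[["upper"]], conf_level = conf_level,
                 n_trials = n_trials, n_effective = n_eff,
                 cluster_adjust = cluster_adjust),
            class = "sap_estimate")
}

#' @export
print.sap_estimate <- function(x, ...) {
  cat(sprintf("SAP estimate: %.4f (%g%% CI %.4f-%.4f, %s trials)\n",
              x$estimate, 100 * x$conf_level, x$lower, x$upper,
              format(x$n_trials, big.mark = ",")))
  invisible(x)
}

#' Recover the transmission coefficient from household data
#'
#' Propagates the pooled SAP estimate and its confidence limits through the
#' exact monotone maps `sap -> R0 -> beta` ([sap_to_R0()] then
#' [R0_to_beta()]). Since both maps are strictly increasing, the interval
#' endpoints map to interval endpoints.
#'
#' @inheritParams estimate_sap
#' @param params a [model_params()] object supplying `N`, `gamma`, `mu`.
#' @return A list with `beta` (point estimate), `lower`, `upper`, `R0` and
#'   the underlying `sap_estimate`.
#' @export
#' @examples
#' p <- model_params()
#' hh <- simulate_households(beta_to_R0(p$beta, p), m = 3,
#'                           n_households = 1e4, params = p, seed = 11)
#' recover_beta(hh, p)$beta
recover_beta <- function(sample, params, conf_level = 0.95,
                         cluster_adjust = TRUE) {
  params <- as_model_params(params)
  sap <- estimate_sap(sample, conf_level = conf_level,
                      cluster_adjust = cluster_adjust)
  if (sap$estimate >= 1)
    stop("SAP estimate of 1 implies an infinite R0", call. = FALSE)
  to_beta <- function(s) {
    if (s >= 1) Inf else R0_to_beta(sap_to_R0(s, sample$m), params)
  }
  list(beta = to_beta(sap$estimate),
       lower = to_beta(sap$lower),
       upper = to_beta(sap$upper),
       R0 = sap_to_R0(sap$estimate, sample$m),
       sap = sap)
}
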