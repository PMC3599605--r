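#' Equilibrium prevalence consistent with a fixed force of infection
#'
#' Setting the time derivatives of the (possibly intervention-modified)
#' system to zero at a fixed force of infection \eqn{\lambda} and solving the
#' resulting linear relations gives the unique stationary prevalence
#' \deqn{i(\lambda) = \frac{\alpha\lambda(\kappa\sigma\lambda + \mu)}
#'   {(\alpha\lambda + \mu)(\kappa\sigma\lambda + \mu + \kappa\gamma)}.}
#' With `alpha = kappa = 1` this is the steady-state reduction of the
#' baseline system; a genuine equilibrium additionally requires the
#' self-consistency \eqn{\lambda = \beta N i(\lambda) + \epsilon}, which
#' [solve_equilibria()] enforces by root finding.
#'
#' @param lambda force of infection (1/year, >= 0); vectorized.
#' @param params a [model_params()] object.
#' @param factors an [intervention_factors()] object.
#' @return Prevalence fraction(s) `I*/N` in `[0, 1]`.
#' @export
#' @examples
#' prevalence_given_lambda(0.03, model_params())
prevalence_given_lambda <- function(lambda, params,
                                    factors = intervention_factors()) {
  params <- as_model_params(params)
  factors <- as_factors(factors)
  if (!is.numeric(lambda) || any(!is.finite(lambda)) || any(lambda < 0))
    stop("'lambda' must be finite and non-negative", call. = FALSE)
  a <- factors$alpha; k <- factors$kappa
  mu <- params$mu; sg <- params$sigma; g <- params$gamma
  a * lambda * (k * sg * lambda + mu) /
    ((a * lambda + mu) * (k * sg * lambda + mu + k * g))
}

# Expand a self-consistent lambda root into full compartment counts.
equilibrium_from_lambda <- function(lambda, params, factors) {
  i <- prevalence_given_lambda(lambda, params, factors)
  I <- params$N * i
  S <- params$mu * params$N / (factors$alpha * lambda + params$mu)
  R <- params$N - S - I
  list(S = S, I = I, R = max(R, 0))
}

# Analytic Jacobian of the reduced (S, I) system with R = N - S - I
# substituted; eliminating R removes the spurious zero eigenvalue of the
# conserved three-dimensional system.
reduced_jacobian <- function(S, I, params, factors) {
  a <- factors$alpha; k <- factors$kappa
  b <- params$beta; mu <- params$mu; sg <- params$sigma; g <- params$gamma
  lam <- b * I + params$epsilon
  R <- params$N - S - I
  matrix(c(-a * lam - mu,                      -a * b * S,
           (a - k * sg) * lam,
           a * b * S + k * sg * (b * R - lam) - (mu + k * g)),
         nrow = 2L, byrow = TRUE)
}

classify_eigenvalues <- function(ev, marginal_tol = 1e-10) {
  maxre <- max(Re(ev))
  if (maxre < -marginal_tol) "stable"
  else if (abs(maxre) <= marginal_tol) "marginal"
  else "unstable"
}

new_equilibrium_point <- function(lambda, params, factors) {
  st <- equilibrium_from_lambda(lambda, params, factors)
  J <- reduced_jacobian(st$S, st$I, params, factors)
  ev <- eigen(J, only.values = TRUE)$values
  cls <- classify_eigenvalues(ev)
  structure(list(S_star = st$S, I_star = st$I, R_star = st$R,
                 lambda_star = lambda,
                 prevalence = st$I / params$N,
                 eigenvalues = ev,
                 stable = identical(cls, "stable"),
                 classification = cls,
                 factors = factors),
            class = "equilibrium_point")
}

#' @export
print.equilibrium_point <- function(x, ...) {
  cat(sprintf(
    "Equilibrium point: S* = %.4g, I* = %.4g, R* = %.4g\n",
    x$S_star, x$I_star, x$R_star))
  cat(sprintf("  prevalence I*/N = %.4f, lambda* = %.6g /y, %s\n",
              x$prevalence, x$lambda_star, x$classification))
  cat("  eigenvalues:", paste(format(x$eigenvalues, digits = 4),
                              collapse = ", "), "\n")
  invisible(x)
}

#' Find all stationary states of the transmission system
#'
#' Reduces the stationarity conditions to the scalar self-consistency
#' \eqn{g(\lambda) = \beta N\, i(\lambda) + \epsilon - \lambda = 0} on the
#' bracket \eqn{[0, \beta N + \epsilon]}, isolates every sign change by a
#' dense pre-scan, and polishes each root by bracketed root finding
#' (`uniroot`, tolerance 1e-12 relative in \eqn{\lambda}). The dense scan is
#' what captures the multiple roots arising under backward bifurcation
#' (pure contagion, \eqn{\epsilon = 0}, with strong relapse). Each root is
#' expanded to compartment counts and classified for stability from the
#' analytic Jacobian of the reduced two-dimensional system.
#'
#' With a positive non-contagious hazard the obesity-free state is not
#' stationary at all, and around the baseline parameter values exactly one
#' (stable, endemic) equilibrium exists. With \eqn{\epsilon = 0} the
#' obesity-free state is always stationary and, inside the bifurcation
#' window, coexists with a stable upper and an unstable lower endemic
#' branch.
#'
#' @param params a [model_params()] object.
#' @param factors an [intervention_factors()] object; equilibria of the
#'   primary/secondary-prevention systems use the correspondingly modified
#'   closed form.
#' @param n_scan number of pre-scan points on the bracket (default 10,000).
#' @return A list of `equilibrium_point` objects, ordered by `I_star`.
#' @export
#' @examples
#' eqs <- solve_equilibria(model_params())
#' eqs[[1]]
solve_equilibria <- function(params, factors = intervention_factors(),
                             n_scan = 10000L) {
  params <- as_model_params(params)
  factors <- as_factors(factors)
  upper <- params$beta * params$N + params$epsilon
  g <- function(l) params$beta * params$N *
    prevalence_given_lambda(l, params, factors) + params$epsilon - l

  roots <- numeric(0)
  if (params$epsilon == 0) roots <- 0  # obesity-free state
  if (upper > 0) {
    grid <- seq(0, upper, length.out = n_scan + 1L)
    gv <- g(grid)
    # exact zeros on the grid (beyond lambda = 0)
    hit <- which(gv == 0 & grid > 0)
    roots <- c(roots, grid[hit])
    sgn <- which(gv[-length(gv)] * gv[-1L] < 0)
    for (k in sgn) {
      r <- stats::uniroot(g, lower = grid[k], upper = grid[k + 1L],
                          tol = 1e-12 * max(upper, 1))$root
      roots <- c(roots, r)
    }
  }
  roots <- sort(unique(roots))
  if (length(roots) > 1L) {
    keep <- c(TRUE, diff(roots) > 1e-9 * max(upper, 1))
    roots <- roots[keep]
  }
  pts <- lapply(roots, new_equilibrium_point, params = params,
                factors = factors)
  pts[order(vapply(pts, function(p) p$I_star, numeric(1)))]
}

#' Stability of a stationary state
#'
#' Linearizes the system about a stationary point and reports the
#' eigenvalues of the analytic Jacobian of the reduced `(S, I)` system
#' (with `R = N - S - I` substituted to eliminate the zero eigenvalue that
#' conservation would otherwise force). The point is classified `"stable"`
#' if every real part is negative, `"unstable"` if any is positive, and
#' `"marginal"` when the leading real part is within 1e-10 of zero.
#'
#' @param point an `equilibrium_point`, or a numeric state `c(S, I, R)`
#'   that is stationary to tolerance.
#' @param params a [model_params()] object.
#' @param factors an [intervention_factors()] object.
#' @return A list with `eigenvalues`, `stable` (logical) and
#'   `classification`.
#' @export
stability <- function(point, params, factors = intervention_factors()) {
  params <- as_model_params(params)
  factors <- as_factors(factors)
  st <- if (inherits(point, "equilibrium_point"))
    c(point$S_star, point$I_star, point$R_star) else as_state(point)
  resid <- rhs_general(st, params, factors$alpha, factors$kappa)
  if (max(abs(resid)) > 1e-6 * params$N)
    stop("'point' is not stationary to tolerance", call. = FALSE)
  J <- reduced_jacobian(st[[1L]], st[[2L]], params, factors)
  ev <- eigen(J, only.values = TRUE)$values
  cls <- classify_eigenvalues(ev)
  list(eigenvalues = ev, stable = identical(cls, "stable"),
       classification = cls)
}

# Headline equilibrium: the unique stable point, or -- in bistable cells --
# the stable point reached by forward integration from (N, 0, 0).
headline_equilibrium <- function(params, factors = intervention_factors(),
                                 horizon = 4000) {
  eqs <- solve_equilibria(params, factors)
  st <- Filter(function(p) p$stable, eqs)
  if (length(st) == 0L) st <- eqs  # marginal threshold cases
  if (length(st) == 1L) return(st[[1L]])
  traj <- integrate_model(params, horizon = horizon, factors = factors,
                          times = seq(0, horizon, length.out = 401L))
  term <- unlist(utils::tail(traj, 1L)[c("S", "I", "R")])
  d <- vapply(st, function(p)
    max(abs(term - c(p$S_star, p$I_star, p$R_star))), numeric(1))
  st[[which.min(d)]]
}

#' Scan equilibria over a transmission-coefficient grid
#'
#' For every combination of `beta` on `beta_grid` and the baseline
#' non-contagious hazard rescaled by each of `epsilon_multipliers`, records
#' all equilibria with their stability classification. With
#' `epsilon_multipliers` containing 0 and strong relapse, the scan exhibits
#' the backward bifurcation: an interval of `beta` where a stable endemic
#' branch coexists with the stable obesity-free state, so prevalence has no
#' simple threshold in `beta`.
#'
#' @param params a [model_params()] object (its `beta` and `epsilon` are
#'   the values being rescaled).
#' @param beta_grid transmission coefficients to scan (per individual per
#'   year).
#' @param epsilon_multipliers multipliers applied to the baseline
#'   `epsilon` (default `c(0, 0.1, 1, 10)`).
#' @return A data frame of class `bifurcation_scan` with columns `beta`,
#'   `epsilon_multiplier`, `epsilon`, `branch`, `lambda_star`, `prevalence`,
#'   `stable`, `classification`.
#' @export
bifurcation_scan <- function(params, beta_grid,
                             epsilon_multipliers = c(0, 0.1, 1, 10)) {
  params <- as_model_params(params)
  if (length(beta_grid) == 0L || length(epsilon_multipliers) == 0L)
    stop("grids must be non-empty", call. = FALSE)
  rows <- list()
  for (em in epsilon_multipliers) {
    eps <- params$epsilon * em
    for (b in beta_grid) {
      p <- model_params(N = params$N, mu = params$mu, beta = b,
                        epsilon = eps, sigma = params$sigma,
                        gamma = params$gamma)
      eqs <- solve_equilibria(p)
      for (j in seq_along(eqs)) {
        e <- eqs[[j]]
        rows[[length(rows) + 1L]] <- data.frame(
          beta = b, epsilon_multiplier = em, epsilon = eps, branch = j,
          lambda_star = e$lambda_star, prevalence = e$prevalence,
          stable = e$stable, classification = e$classification)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, params = params,
            class = c("bifurcation_scan", "data.frame"))
}
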