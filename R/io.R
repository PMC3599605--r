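# CSV output: '#'-prefixed metadata header lines, then an RFC-4180 table.
# Numeric columns are formatted with %.17g so a re-read restores them to
# full double precision; no timestamps, so repeated exports of the same
# object are bit-identical.
write_csv_with_meta <- function(df, path, meta) {
  con <- tryCatch(file(path, open = "wt"),
                  error = function(e)
                    stop("cannot open '", path, "' for writing: ",
                         conditionMessage(e), call. = FALSE))
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", vapply(meta, format, "")), con)
  out <- df
  for (j in seq_along(out))
    if (is.double(out[[j]])) out[[j]] <- sprintf("%.17g", out[[j]])
  utils::write.table(out, con, sep = ",", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

params_meta <- function(params)
  list(N = params$N, mu = params$mu, beta = params$beta,
       epsilon = params$epsilon, sigma = params$sigma, gamma = params$gamma)

#' Export a model object to CSV
#'
#' Writes a headered CSV with the generating parameters and settings echoed
#' as `#`-prefixed metadata lines. Output is deterministic (bit-identical
#' across repeated exports of the same object) and numeric columns
#' round-trip at full double precision through [read_model_csv()].
#'
#' @param x a trajectory, age profile, sweep result, bifurcation scan,
#'   household sample, or plain data frame.
#' @param path output file path.
#' @param ... unused.
#' @return The path, invisibly.
#' @export
export_csv <- function(x, path, ...) UseMethod("export_csv")

#' @export
export_csv.data.frame <- function(x, path, ...) {
  write_csv_with_meta(as.data.frame(x), path, list(type = "table"))
}

#' @export
export_csv.obesity_trajectory <- function(x, path, ...) {
  p <- attr(x, "params"); f <- attr(x, "factors")
  meta <- c(list(type = "trajectory"), params_meta(p),
            list(alpha = f$alpha, kappa = f$kappa))
  write_csv_with_meta(as.data.frame(x), path, meta)
}

#' @export
export_csv.age_profile <- function(x, path, ...) {
  meta <- c(list(type = "age_profile",
                 lambda_star = attr(x, "lambda_star"),
                 Nc0 = attr(x, "Nc0")),
            params_meta(attr(x, "params")))
  write_csv_with_meta(as.data.frame(x), path, meta)
}

#' @export
export_csv.sweep_result <- function(x, path, ...) {
  meta <- c(list(type = "sweep", target = attr(x, "target")),
            params_meta(attr(x, "params")))
  write_csv_with_meta(as.data.frame(x), path, meta)
}

#' @export
export_csv.bifurcation_scan <- function(x, path, ...) {
  meta <- c(list(type = "bifurcation_scan"),
            params_meta(attr(x, "params")))
  write_csv_with_meta(as.data.frame(x), path, meta)
}

#' @export
export_csv.household_sample <- function(x, path, ...) {
  df <- data.frame(household_id = seq_len(x$n_households),
                   m = x$m, secondary_count = x$secondary_counts)
  meta <- list(type = "household_sample", seed = x$seed,
               true_R0 = x$true_R0, m = x$m,
               n_households = x$n_households)
  write_csv_with_meta(df, path, meta)
}

#' Read a CSV written by [export_csv()]
#'
#' @param path file path.
#' @return A data frame; the metadata header is attached as a named
#'   character vector in the `"metadata"` attribute.
#' @export
read_model_csv <- function(path) {
  if (!file.exists(path))
    stop("no such file: '", path, "'", call. = FALSE)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- character(0)
  if (length(hdr)) {
    kv <- sub("^#\\s*", "", hdr)
    keys <- sub(":.*$", "", kv)
    vals <- trimws(sub("^[^:]*:", "", kv))
    meta <- stats::setNames(vals, keys)
  }
  df <- utils::read.csv(path, comment.char = "#")
  attr(df, "metadata") <- meta
  df
}

#' Read model parameters from a flat key-value config file
#'
#' The config format is plain text, one `key = value` pair per line, with
#' keys matching the model notation (`N`, `mu`, `beta`, `epsilon`, `sigma`,
#' `gamma`); blank lines and `#` comments are ignored. Keys left out fall
#' back to the baseline values.
#'
#' @param path config file path.
#' @return A [model_params()] object.
#' @export
read_params_config <- function(path) {
  if (!file.exists(path))
    stop("no such config file: '", path, "'", call. = FALSE)
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  args <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(parts) != 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(parts[1L])
    if (!key %in% c("N", "mu", "beta", "epsilon", "sigma", "gamma"))
      stop("unknown config key: '", key, "'", call. = FALSE)
    val <- suppressWarnings(as.numeric(trimws(parts[2L])))
    if (is.na(val))
      stop("non-numeric value for '", key, "'", call. = FALSE)
    args[[key]] <- val
  }
  do.call(model_params, args)
}

#' Write model parameters to a flat key-value config file
#'
#' @param params a [model_params()] object.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_params_config <- function(params, path) {
  params <- as_model_params(params)
  writeLines(sprintf("%s = %.17g", names(params_meta(params)),
                     unlist(params_meta(params))), path)
  invisible(path)
}

#' Regenerate the package's full table set from one parameter config
#'
#' Produces, deterministically, every data table behind the package's
#' standard outputs: the baseline epidemic trajectory, the stationary age
#' profile at the baseline equilibrium, the transmission/recovery
#' sensitivity scans (including the backward-bifurcation region), and the
#' single-parameter and combined intervention sweeps at both the low and
#' high calibrated transmission coefficients.
#'
#' @param out_dir output directory (created if missing).
#' @param params baseline [model_params()]; ignored when `config` is given.
#' @param config optional path to a key-value config file
#'   (see [read_params_config()]).
#' @param beta_low,beta_high the two calibration endpoints of the
#'   transmission coefficient used for the intervention sweeps.
#' @return Named character vector of the files written, invisibly.
#' @export
regenerate_tables <- function(out_dir, params = model_params(),
                              config = NULL,
                              beta_low = 1.99e-7, beta_high = 4.33e-7) {
  if (!is.null(config)) params <- read_params_config(config)
  params <- as_model_params(params)
  if (!dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  files <- c()

  # baseline epidemic and age profile
  traj <- integrate_model(params, horizon = 1000)
  files["trajectory"] <- export_csv(traj, path("baseline_trajectory.csv"))
  eq <- headline_equilibrium(params)
  prof <- solve_age_profile(eq$lambda_star, params)
  files["age_profile"] <- export_csv(prof, path("baseline_age_profile.csv"))

  # sensitivity of prevalence to transmission and recovery parameters
  hr <- hazard_recovery_sweep(
    params,
    beta_grid = seq(0, 6e-7, length.out = 61L),
    inverse_gamma_grid = seq(2, 70, length.out = 35L))
  files["transmission_scan"] <- write_csv_with_meta(
    hr$transmission, path("prevalence_vs_beta.csv"),
    c(list(type = "transmission_scan"), params_meta(params)))
  files["recovery_scan"] <- write_csv_with_meta(
    hr$recovery, path("prevalence_vs_duration.csv"),
    c(list(type = "recovery_scan"), params_meta(params)))

  # intervention comparison at the low and high calibrated beta
  mults <- seq(0, 1, by = 0.05)
  for (side in c("low", "high")) {
    b <- if (side == "low") beta_low else beta_high
    pb <- model_params(N = params$N, mu = params$mu, beta = b,
                       epsilon = params$epsilon, sigma = params$sigma,
                       gamma = params$gamma)
    uni <- do.call(rbind, lapply(
      c("epsilon", "beta", "inverse_gamma", "sigma"),
      function(tg) {
        mm <- if (tg == "inverse_gamma") mults[mults > 0] else mults
        as.data.frame(univariate_sweep(tg, mm, pb))
      }))
    files[paste0("univariate_", side)] <- write_csv_with_meta(
      uni, path(sprintf("intervention_univariate_beta_%s.csv", side)),
      c(list(type = "univariate_sweep", beta_setting = side),
        params_meta(pb)))
    comb <- combined_sweep(mults, mults, pb)
    files[paste0("combined_", side)] <- export_csv(
      comb, path(sprintf("intervention_combined_beta_%s.csv", side)))
  }
  invisible(files)
}
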