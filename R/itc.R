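# Single-site ("one set of sites") ITC isotherm: displacement bookkeeping,
# the Wiseman cumulative-heat closed form, per-injection heats with the
# standard displacement correction, and deterministic least-squares fitting.
#
# Internal units: volumes in liters, concentrations molar, dH in cal/mol,
# heats in microcalories. dH is reported in kcal/mol at the interface.

#' Construct an ITC experiment
#'
#' @param injection_volumes Injection volumes in liters (all > 0).
#' @param observed_heats Integrated heats per injection in microcal, or `NULL`
#'   for a design-only object.
#' @param V0 Cell volume (liters).
#' @param Mt0 Initial macromolecule concentration in the cell (molar).
#' @param Xs Titrant concentration in the syringe (molar).
#' @param temperature Temperature in kelvin (metadata).
#' @return A list of class `ItcExperiment`.
#' @export
itc_experiment <- function(injection_volumes, observed_heats = NULL,
                           V0, Mt0, Xs, temperature = 298.15) {
  if (any(injection_volumes <= 0)) {
    stop("injection volumes must be positive", call. = FALSE)
  }
  if (!is.null(observed_heats) &&
      length(observed_heats) != length(injection_volumes)) {
    stop("observed_heats and injection_volumes differ in length",
         call. = FALSE)
  }
  stopifnot(V0 > 0, Mt0 > 0, Xs > 0)
  structure(list(injection_volumes = as.numeric(injection_volumes),
                 observed_heats = observed_heats,
                 V0 = V0, Mt0 = Mt0, Xs = Xs, temperature = temperature),
            class = "ItcExperiment")
}

#' Standard titration design
#'
#' One 0.2 ul purge injection followed by 19 injections of 2 ul into a 200 ul
#' cell holding 300 uM macromolecule, titrated with 3 mM ligand at 25 C.
#'
#' @param Mt0,Xs Cell and syringe concentrations (molar).
#' @return A design-only `ItcExperiment` (no observed heats).
#' @export
default_itc_design <- function(Mt0 = 300e-6, Xs = 3e-3) {
  itc_experiment(injection_volumes = c(0.2e-6, rep(2e-6, 19L)),
                 V0 = 200e-6, Mt0 = Mt0, Xs = Xs, temperature = 298.15)
}

#' Cell concentrations after i injections
#'
#' Perfusion-displacement bookkeeping: with cumulative injected volume `dV`,
#' `Mt = Mt0 (1 - dV/2V0) / (1 + dV/2V0)` and
#' `Xt = Xs (dV/V0) / (1 + dV/2V0)`.
#'
#' @param experiment An `ItcExperiment`.
#' @param i Injection index (0 = before any injection).
#' @return Named vector `c(Mt, Xt, dV)`.
#' @export
titration_state <- function(experiment, i) {
  i <- as.integer(i)
  if (i < 0L || i > length(experiment$injection_volumes)) {
    stop("injection index out of range", call. = FALSE)
  }
  dV <- if (i == 0L) 0 else sum(experiment$injection_volumes[seq_len(i)])
  V0 <- experiment$V0
  f <- dV / (2 * V0)
  c(Mt = experiment$Mt0 * (1 - f) / (1 + f),
    Xt = experiment$Xs * (dV / V0) / (1 + f),
    dV = dV)
}

#' Cumulative heat of the single-site isotherm
#'
#' Fractional saturation `theta` is the smaller root of
#' `theta^2 - theta (1 + Xt/(n Mt) + 1/(n Ka Mt)) + Xt/(n Mt) = 0`;
#' cumulative heat is `Q = n theta Mt dH V0` (returned in microcal).
#'
#' @param Xt,Mt Total titrant and macromolecule concentrations (molar).
#' @param n Stoichiometry.
#' @param Ka Association constant (1/molar).
#' @param dH Enthalpy (cal/mol).
#' @param V0 Cell volume (liters).
#' @return Cumulative heat in microcal (vectorized over `Xt`/`Mt`).
#' @export
cumulative_heat <- function(Xt, Mt, n, Ka, dH, V0) {
  stopifnot(n > 0, Ka > 0, V0 > 0, all(Mt > 0), all(Xt >= 0))
  b <- 1 + Xt / (n * Mt) + 1 / (n * Ka * Mt)
  disc <- b^2 - 4 * Xt / (n * Mt)
  if (any(disc < 0)) stop("negative discriminant", call. = FALSE)
  theta <- (b - sqrt(disc)) / 2
  n * theta * Mt * dH * V0 * 1e6
}

#' Per-injection heats
#'
#' `dQ_i = Q_i - Q_{i-1} + (dV_i / V0) (Q_i + Q_{i-1}) / 2`, with `Q`
#' evaluated at each injection's [titration_state()]. This is the standard
#' correction for heat carried out of the cell by displaced volume.
#'
#' @param experiment An `ItcExperiment`.
#' @param n Stoichiometry.
#' @param Ka Association constant (1/molar).
#' @param dH Enthalpy (cal/mol).
#' @return Numeric vector of heats (microcal), one per injection.
#' @export
injection_heats <- function(experiment, n, Ka, dH) {
  k <- length(experiment$injection_volumes)
  V0 <- experiment$V0
  states <- vapply(0:k, function(i) titration_state(experiment, i),
                   numeric(3))
  Q <- cumulative_heat(states["Xt", ], states["Mt", ], n, Ka, dH, V0)
  dv <- experiment$injection_volumes
  idx <- 2:(k + 1)
  Q[idx] - Q[idx - 1L] + (dv / V0) * (Q[idx] + Q[idx - 1L]) / 2
}

#' Fit the single-site binding model to an ITC experiment
#'
#' Weighted least squares of [injection_heats()] over `(n, Ka, dH)` (and an
#' optional per-injection baseline). Fitting is on `log(Ka)` and `log(n)` for
#' conditioning and positivity; initialization is a fixed log-spaced `Ka`
#' grid, so fits are fully deterministic. The first injection (the purge) is
#' excluded from the objective by default.
#'
#' @param experiment An `ItcExperiment` with observed heats.
#' @param exclude_first Drop the first injection from the objective.
#' @param weights Optional per-injection weights (after exclusion), default
#'   uniform.
#' @param baseline Also fit a constant per-injection heat offset.
#' @param ka_grid Association-constant starting grid (1/molar).
#' @return A list of class `SingleSiteFit`: `n`, `Kd` (molar), `dH_kcal`
#'   (kcal/mol), `baseline` (microcal), `residual_norm`, `converged`,
#'   `c_value` (= n Ka Mt0), and `low_information` (`c_value < 1`, the
#'   weak-binding regime where Kd is poorly determined).
#' @export
fit_single_site <- function(experiment, exclude_first = TRUE, weights = NULL,
                            baseline = FALSE,
                            ka_grid = 10^seq(2, 9, by = 0.5)) {
  obs <- experiment$observed_heats
  if (is.null(obs)) stop("experiment has no observed heats", call. = FALSE)
  k <- length(obs)
  use <- if (exclude_first) seq.int(2L, k) else seq_len(k)
  if (length(use) < 5L) stop("need at least 5 usable injections",
                             call. = FALSE)
  if (is.null(weights)) weights <- rep(1, length(use))
  sw <- sqrt(weights)

  resid_fn <- function(par) {
    model <- injection_heats(experiment, n = exp(par[2L]), Ka = exp(par[1L]),
                             dH = par[3L])[use]
    if (baseline) model <- model + par[4L]
    (obs[use] - model) * sw
  }

  # Crude dH scale: saturating the cell converts ~ n Mt0 V0 moles.
  dh0 <- sum(obs[use]) / (experiment$Mt0 * experiment$V0 * 1e6)
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1e4

  ssr0 <- vapply(ka_grid, function(ka) {
    sum(resid_fn(c(log(ka), 0, dh0, 0)[seq_len(3L + baseline)])^2)
  }, numeric(1))
  starts <- ka_grid[order(ssr0)][seq_len(min(3L, length(ka_grid)))]

  best <- NULL
  for (ka0 in starts) {
    par0 <- c(log(ka0), 0, dh0)
    if (baseline) par0 <- c(par0, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par = par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all fit starts failed", call. = FALSE)

  par <- best$par
  ka <- exp(par[1L])
  n_fit <- exp(par[2L])
  structure(list(
    n = n_fit,
    Kd = 1 / ka,
    dH_kcal = par[3L] / 1000,
    baseline = if (baseline) par[4L] else 0,
    residual_norm = sqrt(best$deviance),
    converged = best$info %in% 1:4,
    c_value = n_fit * ka * experiment$Mt0,
    low_information = n_fit * ka * experiment$Mt0 < 1,
    n_injections_used = length(use)),
    class = "SingleSiteFit")
}

#' @export
print.SingleSiteFit <- function(x, ...) {
  cat(sprintf(
    "Single-site fit: n = %.4g, Kd = %.4g uM, dH = %.4g kcal/mol%s\n",
    x$n, x$Kd * 1e6, x$dH_kcal,
    if (x$low_information) "  [low c-value: Kd poorly determined]" else ""))
  cat(sprintf("  residual norm %.4g ucal over %d injections; converged: %s\n",
              x$residual_norm, x$n_injections_used, x$converged))
  invisible(x)
}

#' Write an ITC injection table
#'
#' Header block (`# key=value`: `V0_ul`, `Mt0_uM`, `Xs_uM`, `temperature_K`)
#' followed by tab-separated columns `injection_volume_ul`, `heat_ucal`.
#'
#' @param experiment An `ItcExperiment` with observed heats.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_itc_table <- function(experiment, path) {
  if (is.null(experiment$observed_heats)) {
    stop("experiment has no observed heats", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# V0_ul=%.10g", experiment$V0 * 1e6),
               sprintf("# Mt0_uM=%.10g", experiment$Mt0 * 1e6),
               sprintf("# Xs_uM=%.10g", experiment$Xs * 1e6),
               sprintf("# temperature_K=%.10g", experiment$temperature)), con)
  writeLines("injection_volume_ul\theat_ucal", con)
  writeLines(sprintf("%.10g\t%.17g", experiment$injection_volumes * 1e6,
                     experiment$observed_heats), con)
  invisible(path)
}

#' Read an ITC injection table written by [write_itc_table()]
#' @param path Path to the table.
#' @return An `ItcExperiment` with observed heats.
#' @export
read_itc_table <- function(path) {
  lines <- readLines(path)
  hdr <- sub("^#\\s*", "", grep("^#", lines, value = TRUE))
  keys <- sub("=.*$", "", hdr)
  vals <- as.numeric(sub("^[^=]*=", "", hdr))
  need <- c("V0_ul", "Mt0_uM", "Xs_uM", "temperature_K")
  if (!all(need %in% keys)) {
    stop("ITC table header lacks: ",
         paste(setdiff(need, keys), collapse = ", "), call. = FALSE)
  }
  get <- function(k) vals[match(k, keys)]
  body <- utils::read.delim(text = lines[!grepl("^#", lines)])
  itc_experiment(injection_volumes = body$injection_volume_ul * 1e-6,
                 observed_heats = body$heat_ucal,
                 V0 = get("V0_ul") * 1e-6, Mt0 = get("Mt0_uM") * 1e-6,
                 Xs = get("Xs_uM") * 1e-6,
                 temperature = get("temperature_K"))
}
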