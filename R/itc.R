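#' Define an ITC titration schedule
#'
#' Units are fixed throughout the module: concentrations in uM, volumes in
#' uL, enthalpies in kcal/mol, heats in ucal.
#'
#' @param V0 Cell volume (uL).
#' @param M0 Initial macromolecule concentration in the cell (uM).
#' @param X0 Ligand concentration in the syringe (uM).
#' @param injection_volumes Vector of injection volumes (uL), length >= 5.
#' @param temperature Temperature (K), default 298.15.
#' @return An `itc_schedule` tibble with one row per injection and the
#'   instrument constants as attributes.
#' @export
itc_schedule <- function(V0, M0, X0, injection_volumes,
                         temperature = 298.15) {
  if (any(c(V0, M0, X0, injection_volumes, temperature) <= 0)) {
    abort("volumes, concentrations and temperature must be positive")
  }
  if (length(injection_volumes) < 5L) abort("need at least 5 injections")
  out <- tibble(injection = seq_along(injection_volumes),
                volume = injection_volumes)
  attr(out, "V0") <- V0
  attr(out, "M0") <- M0
  attr(out, "X0") <- X0
  attr(out, "temperature") <- temperature
  class(out) <- c("itc_schedule", class(out))
  out
}

# Dilution-corrected total concentrations after each injection, using the
# continuous-displacement (exponential) convention: injecting total volume
# Vi into a constant-volume cell dilutes existing contents by exp(-Vi/V0)
# while delivered ligand accumulates to X0 * (1 - exp(-Vi/V0)).
itc_concentrations <- function(schedule) {
  V0 <- attr(schedule, "V0"); M0 <- attr(schedule, "M0")
  X0 <- attr(schedule, "X0")
  Vi <- cumsum(schedule$volume)
  tibble(injection = schedule$injection,
         M = M0 * exp(-Vi / V0),
         X = X0 * (1 - exp(-Vi / V0)))
}

#' One-set-of-sites ITC forward model
#'
#' Computes per-injection heats for N identical independent sites. After
#' injection i, with dilution-corrected totals `M_i`, `X_i`, the bound
#' fraction `theta_i` is the root in \[0, 1\] of
#' `theta^2 - theta * (1 + X/(N M) + K_D/(N M)) + X/(N M) = 0`;
#' cumulative heat `Q_i = N * theta_i * M_i * dH * V0` (converted to ucal)
#' and the observed injection heat is
#' `dQ_i = Q_i - Q_{i-1} + (v_i/V0) * (Q_i + Q_{i-1})/2 + baseline`,
#' the middle term being the standard displaced-volume correction.
#'
#' @param params List or one-row tibble with `K_D` (uM), `dH` (kcal/mol),
#'   `N` (sites per macromolecule), optional `baseline` (ucal/injection,
#'   default 0). See [binding_params()].
#' @param schedule An [itc_schedule()].
#' @return Tibble: `injection`, `molar_ratio` (X/M), `heat` (ucal).
#' @export
itc_forward <- function(params, schedule) {
  params <- as.list(params)
  if (is.null(params$baseline)) params$baseline <- 0
  if (params$K_D <= 0 || params$N <= 0) abort("K_D and N must be positive")
  conc <- itc_concentrations(schedule)
  V0 <- attr(schedule, "V0")
  r <- conc$X / (params$N * conc$M)
  k <- params$K_D / (params$N * conc$M)
  b <- 1 + r + k
  disc <- b^2 - 4 * r
  if (any(disc < 0)) abort("negative discriminant in binding quadratic")
  theta <- (b - sqrt(disc)) / 2
  # uM * uL * kcal/mol = 1e-12 mol * kcal/mol = 1e-12 kcal = 1e-3 ucal
  Q <- params$N * theta * conc$M * V0 * params$dH * 1e-3
  Qprev <- c(0, head(Q, -1))
  dQ <- Q - Qprev + (schedule$volume / V0) * (Q + Qprev) / 2 +
    params$baseline
  tibble(injection = schedule$injection,
         molar_ratio = conc$X / conc$M,
         heat = dQ)
}

#' Bundle one-set-of-sites binding parameters
#'
#' @param K_D Dissociation constant (uM).
#' @param dH Binding enthalpy (kcal/mol).
#' @param N Sites per macromolecule.
#' @param baseline Constant per-injection offset (ucal), default 0.
#' @return Named list.
#' @export
binding_params <- function(K_D, dH, N = 1, baseline = 0) {
  if (K_D <= 0 || N <= 0) abort("K_D and N must be positive")
  list(K_D = K_D, dH = dH, N = N, baseline = baseline)
}

#' Simulate an ITC titration
#'
#' Forward-model heats plus i.i.d. Gaussian noise.
#'
#' @inheritParams itc_forward
#' @param noise_sd Standard deviation of additive heat noise (ucal).
#' @param seed Optional seed.
#' @return Tibble as [itc_forward()], with noisy `heat`.
#' @export
simulate_itc <- function(params, schedule, noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  local_seed_if(seed)
  out <- itc_forward(params, schedule)
  if (noise_sd > 0) out$heat <- out$heat + rnorm(nrow(out), 0, noise_sd)
  out
}

itc_init <- function(heats, schedule) {
  V0 <- attr(schedule, "V0"); M0 <- attr(schedule, "M0")
  X0 <- attr(schedule, "X0")
  # dH guess: heat per mole injected over the first 3 injections, assuming
  # complete binding early in the titration (ucal vs uM*uL*1e-3 kcal/mol)
  dH0 <- mean(heats[1:3] / (X0 * schedule$volume[1:3] * 1e-3))
  # steepest-slope heuristic for the c-value: for the Wiseman isotherm the
  # normalized slope at the equivalence point grows with sqrt(c)
  ratio <- itc_forward(binding_params(1, -1, 1), schedule)$molar_ratio
  h <- heats - heats[length(heats)]
  if (max(abs(h)) > 0) h <- h / max(abs(h))
  sl <- abs(diff(h) / diff(ratio))
  c0 <- max(1, (2 * max(sl, na.rm = TRUE))^2)
  K0 <- M0 / c0
  list(K_D = K0, dH = dH0, N = 1, baseline = 0)
}

#' Fit the one-set-of-sites model to injection heats
#'
#' Nonlinear least squares (Levenberg-Marquardt) over `(log K_D, dH, N,
#' baseline)`; K_D is fitted on the log scale for stability. Default
#' initialization: `N = 1`, `dH` from the mean of the first three heats,
#' `K_D` from a steepest-slope heuristic on the normalized isotherm.
#'
#' @param heats Numeric vector of per-injection heats (ucal), or the
#'   tibble returned by [simulate_itc()].
#' @param schedule An [itc_schedule()].
#' @param init Optional list overriding the default initialization
#'   (`K_D`, `dH`, `N`, `baseline`).
#' @return An `itc_fit` object; see [tidy.itc_fit()] and
#'   [glance.itc_fit()]. Non-convergence is flagged in `$converged`, never
#'   silently ignored.
#' @export
itc_fit <- function(heats, schedule, init = NULL) {
  if (is.data.frame(heats)) heats <- heats$heat
  if (length(heats) != nrow(schedule)) {
    abort("heats length must match the schedule")
  }
  init0 <- itc_init(heats, schedule)
  if (!is.null(init)) init0[names(init)] <- init
  start <- c(logK = log(init0$K_D), dH = init0$dH, N = init0$N,
             baseline = init0$baseline)
  resid_fn <- function(par) {
    p <- binding_params(exp(par[["logK"]]), par[["dH"]],
                        abs(par[["N"]]), par[["baseline"]])
    itc_forward(p, schedule)$heat - heats
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = start, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(
                         maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- list(params = init0, converged = FALSE, residual_norm = NA_real_,
                heats = heats, schedule = schedule,
                message = "optimizer error")
  } else {
    par <- fit$par
    params <- binding_params(exp(par[["logK"]]), par[["dH"]],
                             abs(par[["N"]]), par[["baseline"]])
    out <- list(params = params,
                converged = fit$info %in% 1:4,
                residual_norm = sqrt(sum(fit$fvec^2)),
                heats = heats, schedule = schedule,
                message = fit$message)
  }
  class(out) <- "itc_fit"
  out
}

#' @export
print.itc_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<itc_fit> K_D = %.4g uM, dH = %.4g kcal/mol, N = %.4g, baseline = %.3g ucal\n",
    p$K_D, p$dH, p$N, p$baseline))
  cat(sprintf("  converged: %s, residual norm %.3g ucal\n",
              x$converged, x$residual_norm))
  invisible(x)
}

#' Tidy an ITC fit
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return Tibble with one row per parameter (`term`, `estimate`).
#' @method tidy itc_fit
#' @export
tidy.itc_fit <- function(x, ...) {
  tibble(term = c("K_D", "dH", "N", "baseline"),
         estimate = unlist(x$params, use.names = FALSE))
}

#' One-row summary of an ITC fit
#' @param x An `itc_fit`.
#' @param ... Unused.
#' @return Tibble: `K_D`, `dH`, `N`, `baseline`, `residual_norm`,
#'   `converged`.
#' @method glance itc_fit
#' @export
glance.itc_fit <- function(x, ...) {
  tibble(K_D = x$params$K_D, dH = x$params$dH, N = x$params$N,
         baseline = x$params$baseline,
         residual_norm = x$residual_norm, converged = x$converged)
}

#' Isotherm plot of an ITC fit
#' @param object An `itc_fit`.
#' @param ... Unused.
#' @return A ggplot of observed and fitted heats versus molar ratio.
#' @method autoplot itc_fit
#' @export
autoplot.itc_fit <- function(object, ...) {
  fitted <- itc_forward(object$params, object$schedule)
  df <- fitted |> mutate(observed = object$heats)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$molar_ratio)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$heat), color = "red") +
    ggplot2::labs(x = "molar ratio (ligand/protein)",
                  y = "heat per injection (ucal)") +
    ggplot2::theme_minimal()
}

#' Thermodynamic quantities from binding parameters
#'
#' `dG = R T ln(K_D)` with K_D in molar (negative for sub-molar
#' affinities) and `dS = (dH - dG) / T`; the identity `dG = dH - T dS`
#' holds to machine precision.
#'
#' @param params [binding_params()] or an `itc_fit`.
#' @param temperature Temperature (K), default 298.15.
#' @return Tibble: `dG` (kcal/mol), `dS` (cal/mol/K), `temperature`.
#' @export
derive_thermo <- function(params, temperature = 298.15) {
  if (inherits(params, "itc_fit")) params <- params$params
  if (temperature <= 0) abort("temperature must be positive")
  R <- 1.98720425864083e-3  # kcal / (mol K)
  dG <- R * temperature * log(params$K_D * 1e-6)
  dS <- (params$dH - dG) / temperature * 1000  # cal/mol/K
  tibble(dG = dG, dS = dS, temperature = temperature)
}
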