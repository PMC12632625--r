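#' Define an ITC titration protocol
#'
#' Captures the experimental design of a one-site ITC titration: host in
#' the cell, guest in the syringe, a sequence of injection volumes, and
#' the cell temperature. A typical experiment titrates 20 x 2 uL aliquots
#' of guest (1.25-30 mM) into a ~200 uL cell containing the host
#' (0.25-4 mM) at 25 C.
#'
#' @param cell_volume_ul active cell volume in uL.
#' @param cell_conc host concentration in the cell, molar.
#' @param syringe_conc guest concentration in the syringe, molar.
#' @param injection_volumes_ul vector of injection volumes in uL.
#' @param temperature cell temperature in K.
#' @return object of class \code{titration_protocol}.
#' @examples
#' titration_protocol(200, 1e-3, 1e-2, rep(2, 20))
#' @export
titration_protocol <- function(cell_volume_ul, cell_conc, syringe_conc,
                               injection_volumes_ul, temperature = 298.15) {
  if (!is.finite(cell_volume_ul) || cell_volume_ul <= 0)
    stop("cell volume must be > 0")
  if (!is.finite(cell_conc) || cell_conc <= 0)
    stop("cell concentration must be > 0")
  if (!is.finite(syringe_conc) || syringe_conc <= 0)
    stop("syringe concentration must be > 0")
  if (length(injection_volumes_ul) < 1 ||
      any(!is.finite(injection_volumes_ul)) || any(injection_volumes_ul <= 0))
    stop("injection volumes must be a non-empty positive vector")
  if (!is.finite(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  structure(list(cell_volume_ul = cell_volume_ul,
                 cell_conc = cell_conc,
                 syringe_conc = syringe_conc,
                 injection_volumes_ul = injection_volumes_ul,
                 temperature = temperature),
            class = "titration_protocol")
}

#' @export
print.titration_protocol <- function(x, ...) {
  cat("ITC titration protocol\n")
  cat(sprintf("  cell: %.1f uL of %.3g M host at %.2f K\n",
              x$cell_volume_ul, x$cell_conc, x$temperature))
  cat(sprintf("  syringe: %.3g M guest, %d injections (%.3g uL total)\n",
              x$syringe_conc, length(x$injection_volumes_ul),
              sum(x$injection_volumes_ul)))
  invisible(x)
}

# Concentration bookkeeping for an overflow cell: after a cumulative
# injected volume v, the host is diluted and the injected guest partially
# displaced, following the standard mean-displacement forms
#   [M]_i = M0 (1 - v/2V0) / (1 + v/2V0)
#   [X]_i = Xs (v/V0) / (1 + v/2V0).
.itc_concentrations <- function(protocol) {
  v0 <- protocol$cell_volume_ul
  v <- cumsum(protocol$injection_volumes_ul)
  list(M = protocol$cell_conc * (1 - v / (2 * v0)) / (1 + v / (2 * v0)),
       X = protocol$syringe_conc * (v / v0) / (1 + v / (2 * v0)))
}

# Cumulative binding heat content of the cell (J) after each injection,
# from the 1:1 mass-balance quadratic in the bound fraction.
.itc_cumulative_heat <- function(n, K_a, dH_kj, protocol) {
  conc <- .itc_concentrations(protocol)
  M <- conc$M
  X <- conc$X
  v0_l <- protocol$cell_volume_ul * 1e-6
  r <- X / (n * M)
  k <- 1 / (n * K_a * M)
  b <- 1 + r + k
  disc <- b^2 - 4 * r
  if (any(disc < 0)) stop("internal: negative discriminant in mass balance")
  theta <- (b - sqrt(disc)) / 2
  n * M * theta * dH_kj * 1000 * v0_l
}

#' Predict per-injection heats for a one-site titration
#'
#' Forward model for a 1:1 binding isotherm in an overflow titration
#' cell. The cumulative heat content after injection \eqn{i} follows from
#' the mass-balance quadratic for the bound fraction; the observed heat of
#' injection \eqn{i} is the difference of cumulative heats plus the
#' mean-displacement correction
#' \eqn{q_i = Q_i - Q_{i-1} + (dV_i/V_0)(Q_i + Q_{i-1})/2},
#' which accounts for bound complex pushed out of the active volume.
#'
#' @param params list with \code{n} (sites), \code{K_a} (1/M) and
#'   \code{dH} (kJ/mol). \code{K_D} may be given instead of \code{K_a}.
#' @param protocol a \code{\link{titration_protocol}}.
#' @return numeric vector of injection heats in J.
#' @export
predict_injection_heats <- function(params, protocol) {
  stopifnot(inherits(protocol, "titration_protocol"))
  if (is.null(params$K_a) && !is.null(params$K_D)) params$K_a <- 1 / params$K_D
  vals <- c(params$n, params$K_a, params$dH)
  if (length(vals) != 3 || any(!is.finite(vals)))
    stop("params must supply finite n, K_a (or K_D) and dH")
  if (params$K_a <= 0) stop("K_a must be > 0")
  if (params$n <= 0) stop("n must be > 0")
  Q <- .itc_cumulative_heat(params$n, params$K_a, params$dH, protocol)
  Qprev <- c(0, Q[-length(Q)])
  dv <- protocol$injection_volumes_ul / protocol$cell_volume_ul
  Q - Qprev + dv * (Q + Qprev) / 2
}

#' Subtract a blank (heat-of-dilution) titration
#'
#' Elementwise subtraction of a blank titration (guest injected into
#' buffer alone) from a sample titration. If per-injection uncertainties
#' are supplied for both, they are propagated in quadrature.
#'
#' @param sample_heats,blank_heats equal-length heat vectors (same unit).
#' @param sample_se,blank_se optional per-injection standard errors.
#' @return corrected heat vector; with uncertainties, a list with
#'   \code{heats} and \code{se}.
#' @export
subtract_blank <- function(sample_heats, blank_heats,
                           sample_se = NULL, blank_se = NULL) {
  if (length(sample_heats) != length(blank_heats))
    stop("sample and blank must have the same number of injections")
  out <- sample_heats - blank_heats
  if (!is.null(sample_se) || !is.null(blank_se)) {
    if (is.null(sample_se)) sample_se <- 0
    if (is.null(blank_se)) blank_se <- 0
    return(list(heats = out, se = sqrt(sample_se^2 + blank_se^2)))
  }
  out
}

#' Fit a one-site binding isotherm to injection heats
#'
#' Weighted least-squares fit of \code{\link{predict_injection_heats}} to
#' observed per-injection heats, estimating the stoichiometry \eqn{n},
#' the dissociation constant \eqn{K_D} and the binding enthalpy
#' \eqn{\Delta H}. For weak binders the stoichiometry can be fixed at 1
#' (\code{fix_n = TRUE}), leaving only \eqn{(K_a, \Delta H)} free, as is
#' standard practice when the isotherm has no resolvable inflection.
#'
#' The association constant is fitted on a log scale (guaranteeing
#' \eqn{K_a > 0}); standard errors come from the local curvature of the
#' weighted least-squares surface, with the \eqn{K_D} error obtained by
#' the delta method. Initialisation uses the integral heat for
#' \eqn{\Delta H} and a mid-range Wiseman \eqn{c} value for \eqn{K_a},
#' refined by a small multi-start over \eqn{\log K_a} if the first
#' attempt stalls. Non-convergence is reported in the result, never as an
#' error. A Wiseman \eqn{c = n K_a [M]_0} outside the informative range
#' (1-1000) attaches a warning string to the fit.
#'
#' @param heats per-injection heats in J.
#' @param protocol a \code{\link{titration_protocol}}.
#' @param fix_n fix the stoichiometry at exactly 1.
#' @param init optional list with starting \code{n}, \code{K_a},
#'   \code{dH}.
#' @param weights optional per-injection weights (default uniform).
#' @return object of class \code{binding_fit}: fields \code{n},
#'   \code{n_se}, \code{K_D}, \code{K_D_se}, \code{dH}, \code{dH_se},
#'   \code{fixed_n}, \code{converged}, \code{residual_norm},
#'   \code{c_value}, \code{uninformative} and \code{warnings}.
#' @export
fit_one_site <- function(heats, protocol, fix_n = FALSE, init = NULL,
                         weights = NULL) {
  stopifnot(inherits(protocol, "titration_protocol"))
  if (length(heats) < 5) stop("need at least 5 injections to fit")
  if (length(heats) != length(protocol$injection_volumes_ul))
    stop("heats and protocol injection count differ")
  if (any(!is.finite(heats))) stop("heats must be finite")
  if (is.null(weights)) weights <- rep(1, length(heats))
  w <- sqrt(weights)

  warnings_out <- character(0)
  M0 <- protocol$cell_conc
  v0_l <- protocol$cell_volume_ul * 1e-6

  if (all(heats == 0)) {
    fit <- structure(list(n = if (fix_n) 1 else NA_real_, n_se = NA_real_,
                          K_D = NA_real_, K_D_se = NA_real_,
                          dH = 0, dH_se = 0, fixed_n = fix_n,
                          converged = FALSE, residual_norm = 0,
                          c_value = NA_real_, uninformative = TRUE,
                          warnings = "all heats are zero; fit uninformative"),
                     class = "binding_fit")
    return(fit)
  }

  # starting values: integral heat ~ n dH M0 V0; c ~ 30 for K_a
  dH0 <- if (!is.null(init$dH)) init$dH else sum(heats) / (M0 * v0_l) / 1000
  if (dH0 == 0) dH0 <- -1
  Ka0 <- if (!is.null(init$K_a)) init$K_a else 30 / M0
  n0 <- if (!is.null(init$n)) init$n else 1

  resid_fun <- function(par) {
    n <- if (fix_n) 1 else exp(par[["log_n"]])
    pred <- predict_injection_heats(
      list(n = n, K_a = exp(par[["log_Ka"]]), dH = par[["dH"]]), protocol)
    w * (heats - pred)
  }

  make_start <- function(lKa) {
    if (fix_n) c(log_Ka = lKa, dH = dH0)
    else c(log_Ka = lKa, dH = dH0, log_n = log(n0))
  }

  run <- function(start) {
    tryCatch(minpack.lm::nls.lm(par = start, fn = resid_fun,
                                control = minpack.lm::nls.lm.control(
                                  maxiter = 500, ftol = 1e-14,
                                  ptol = 1e-14)),
             error = function(e) NULL)
  }

  best <- run(make_start(log(Ka0)))
  # multi-start over log10(Ka) if the first attempt failed or stalled
  if (is.null(best) || best$info %in% c(0, 5)) {
    for (lk in log(10^seq(2, 8, by = 1.5))) {
      cand <- run(make_start(lk))
      if (!is.null(cand) &&
          (is.null(best) || cand$deviance < best$deviance)) best <- cand
    }
  }
  if (is.null(best)) {
    return(structure(list(n = NA_real_, n_se = NA_real_, K_D = NA_real_,
                          K_D_se = NA_real_, dH = NA_real_, dH_se = NA_real_,
                          fixed_n = fix_n, converged = FALSE,
                          residual_norm = NA_real_, c_value = NA_real_,
                          uninformative = TRUE,
                          warnings = "optimizer failed to evaluate"),
                     class = "binding_fit"))
  }

  par <- best$par
  converged <- best$info %in% 1:4
  n_hat <- if (fix_n) 1 else exp(par[["log_n"]])
  Ka_hat <- exp(par[["log_Ka"]])
  dH_hat <- par[["dH"]]

  ses <- tryCatch({
    s <- summary(best)
    se <- s$coefficients[, "Std. Error"]
    names(se) <- rownames(s$coefficients)
    se
  }, error = function(e) NULL)
  se_of <- function(nm) if (!is.null(ses) && nm %in% names(ses)) ses[[nm]] else NA_real_
  K_D_hat <- 1 / Ka_hat
  K_D_se <- K_D_hat * se_of("log_Ka")       # delta method on log K_a
  n_se <- if (fix_n) NA_real_ else n_hat * se_of("log_n")

  c_value <- n_hat * Ka_hat * M0
  if (is.finite(c_value) && (c_value < 1 || c_value > 1000))
    warnings_out <- c(warnings_out, sprintf(
      "Wiseman c = %.3g outside the informative range [1, 1000]", c_value))

  structure(list(n = n_hat, n_se = n_se,
                 K_D = K_D_hat, K_D_se = K_D_se,
                 dH = dH_hat, dH_se = se_of("dH"),
                 fixed_n = fix_n, converged = converged,
                 residual_norm = sqrt(best$deviance),
                 c_value = c_value, uninformative = FALSE,
                 warnings = warnings_out),
            class = "binding_fit")
}

#' @export
print.binding_fit <- function(x, ...) {
  cat("One-site binding fit\n")
  if (x$fixed_n) cat("  n fixed at 1\n")
  else cat(sprintf("  n    = %.3f (se %.3g)\n", x$n, x$n_se))
  cat(sprintf("  K_D  = %.4g M (se %.3g)\n", x$K_D, x$K_D_se))
  cat(sprintf("  dH   = %.3f kJ/mol (se %.3g)\n", x$dH, x$dH_se))
  cat(sprintf("  converged: %s; residual norm %.3g; c = %.3g\n",
              x$converged, x$residual_norm, x$c_value))
  for (wmsg in x$warnings) cat("  warning: ", wmsg, "\n", sep = "")
  invisible(x)
}

#' Read and write per-injection heat files
#'
#' Heats travel as a two-column CSV (\code{injection}, \code{heat_J} or
#' \code{heat_uJ}); the column name declares the unit and values are
#' returned in J.
#'
#' @param path file path.
#' @param heats numeric heats in J (for writing).
#' @param unit output unit, \code{"J"} or \code{"uJ"}.
#' @return \code{read_heats}: numeric vector of heats in J.
#' @export
read_heats <- function(path) {
  df <- utils::read.csv(path)
  col <- intersect(c("heat_J", "heat_uJ"), names(df))
  if (length(col) != 1)
    stop("heat file must have exactly one of: heat_J, heat_uJ")
  scale <- if (col == "heat_uJ") 1e-6 else 1
  df[[col]][order(df$injection)] * scale
}

#' @rdname read_heats
#' @export
write_heats <- function(heats, path, unit = c("J", "uJ")) {
  unit <- match.arg(unit)
  scale <- if (unit == "uJ") 1e6 else 1
  df <- data.frame(injection = seq_along(heats), heat = heats * scale)
  names(df)[2] <- paste0("heat_", unit)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
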