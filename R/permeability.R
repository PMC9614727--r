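## Hydraulic and osmotic permeability.
##
## Darcy-law form: J_v = L_P dP (volume flux per membrane area, zero
## intercept). With an impermeable solute, J_m = P_f dC, and the two driving
## forces are equivalent through dP = R T dC, so the permeabilities are
## related by the constant factor P_f = L_P R T / V_W with V_W the molar
## volume of water.

#' Fit the hydraulic permeability from flux--pressure data
#'
#' Weighted least-squares slope of `jv` against `dp` *through the origin*
#' (the linear law has zero intercept: no flux without a driving force).
#' Weights are inverse-variance from the per-point standard errors when
#' available, else unweighted. A free-intercept fit is also reported as a
#' linearity diagnostic, not as the estimator.
#'
#' @param dp Pressure differences, MPa (at least 2 distinct positive values).
#' @param jv Volume fluxes, nm/ns (as from [net_flux()]`$J_v_nm_ns`).
#' @param jv_se Optional per-point standard errors of `jv`.
#' @param A Optional membrane area (nm^2) used to express the single-channel
#'   hydraulic permeability in the cgs-style unit cm^5 N^-1 s^-1.
#' @param T Temperature, K (used for the osmotic conversion when `A` is given).
#' @param V_W Molar volume of water, cm^3 mol^-1.
#' @return An object of class `pf_lpfit`: list with
#'   \describe{
#'     \item{slope, slope_se}{L_P in (nm/ns)/MPa: volume flux per membrane
#'       area and pressure. With per-point SEs, `slope_se` is the propagated
#'       error times the standard scale factor `max(1, sqrt(chi2/dof))`;
#'       without them it is residual-based. The unscaled components are
#'       reported as `slope_se_prop` / `slope_se_resid`.}
#'     \item{LP_m_Pa_s}{Per-area hydraulic permeability, m Pa^-1 s^-1.}
#'     \item{LP_cm5_N_s, LP_cm5_N_s_se}{Single-channel hydraulic permeability
#'       (slope x A), cm^5 N^-1 s^-1; `NA` without `A`.}
#'     \item{Pf_cm3_s, Pf_cm3_s_se}{Osmotic permeability from Eq-3 style
#'       conversion; `NA` without `A`.}
#'     \item{intercept_fit}{Free-intercept diagnostic: slope, intercept and
#'       their SEs.}
#'     \item{residuals}{Residuals of the through-origin fit.}
#'   }
#' @export
fit_LP <- function(dp, jv, jv_se = NULL, A = NULL, T = 300,
                   V_W = pf_constants$V_W) {
  dp <- as.numeric(dp); jv <- as.numeric(jv)
  if (length(dp) < 2L || length(unique(dp)) < 2L)
    stop("insufficient data: need at least 2 distinct pressures")
  if (length(jv) != length(dp)) stop("'dp' and 'jv' lengths differ")
  if (!all(is.finite(dp)) || !all(is.finite(jv)))
    stop("non-finite input in 'dp' or 'jv'")
  if (any(dp <= 0)) stop("pressures must be > 0")
  have_se <- !is.null(jv_se)
  if (have_se) {
    jv_se <- as.numeric(jv_se)
    if (length(jv_se) != length(dp) || !all(is.finite(jv_se)) || any(jv_se < 0))
      stop("'jv_se' must be finite nonnegative, one per point")
    if (any(jv_se == 0)) have_se <- FALSE  # cannot inverse-variance weight
  }
  w <- if (have_se) 1 / jv_se^2 else rep(1, length(dp))
  sxx <- sum(w * dp^2)
  slope <- sum(w * dp * jv) / sxx
  res <- jv - slope * dp
  se_prop <- if (have_se) sqrt(1 / sxx) else NA_real_
  se_resid <- if (length(dp) > 1L) sqrt(sum(w * res^2) / (length(dp) - 1L) / sxx)
              else NA_real_
  ## primary SE: with per-point errors, propagate and apply the standard
  ## error-scaling factor max(1, sqrt(chi2/dof)) so understated per-point
  ## errors cannot understate the slope error; else residual-based
  slope_se <- if (have_se) se_prop * max(1, se_resid / se_prop) else se_resid

  ## an exactly linear input makes lm warn about a perfect fit; that is a
  ## legitimate use here (the diagnostic then shows intercept ~ 0, SE 0)
  ifit <- suppressWarnings(stats::lm(jv ~ dp, weights = w))
  ico <- suppressWarnings(summary(ifit))$coefficients
  intercept_fit <- list(intercept = ico[1, 1], intercept_se = ico[1, 2],
                        slope = ico[2, 1], slope_se = ico[2, 2])

  LP_cm5 <- if (is.null(A)) NA_real_ else slope * A * .CM5_PER_SLOPE_AREA
  LP_cm5_se <- if (is.null(A)) NA_real_ else slope_se * A * .CM5_PER_SLOPE_AREA
  structure(list(
    slope = slope, slope_se = slope_se,
    slope_se_prop = se_prop, slope_se_resid = se_resid,
    LP_m_Pa_s = slope * 1e-6,
    LP_cm5_N_s = LP_cm5, LP_cm5_N_s_se = LP_cm5_se,
    Pf_cm3_s = if (is.na(LP_cm5)) NA_real_ else Pf_from_LP(LP_cm5, T, V_W),
    Pf_cm3_s_se = if (is.na(LP_cm5)) NA_real_ else Pf_from_LP(LP_cm5_se, T, V_W),
    T = T, V_W = V_W, A = A,
    intercept_fit = intercept_fit,
    residuals = res, dp = dp, jv = jv, jv_se = if (have_se) jv_se else NULL),
    class = "pf_lpfit")
}

#' @export
print.pf_lpfit <- function(x, ...) {
  cat(sprintf("<pf_lpfit> L_P = %g +/- %g (nm/ns)/MPa  [%g m Pa^-1 s^-1]\n",
              x$slope, x$slope_se, x$LP_m_Pa_s))
  if (!is.na(x$LP_cm5_N_s))
    cat(sprintf("  channel: L_P = %g +/- %g cm^5 N^-1 s^-1; P_f = %g +/- %g cm^3 s^-1 (T = %g K)\n",
                x$LP_cm5_N_s, x$LP_cm5_N_s_se, x$Pf_cm3_s, x$Pf_cm3_s_se, x$T))
  cat(sprintf("  free-intercept diagnostic: slope %g +/- %g, intercept %g +/- %g\n",
              x$intercept_fit$slope, x$intercept_fit$slope_se,
              x$intercept_fit$intercept, x$intercept_fit$intercept_se))
  invisible(x)
}

#' Convert hydraulic to osmotic permeability
#'
#' `P_f = L_P R T / V_W`, with exact unit handling: `L_P` in
#' cm^5 N^-1 s^-1 (= 1e-10 m^3 Pa^-1 s^-1), `V_W` in cm^3 mol^-1, result in
#' cm^3 s^-1. The standard error propagates by the same constant factor.
#'
#' @param LP Hydraulic permeability, cm^5 N^-1 s^-1.
#' @param T Temperature, K (> 0).
#' @param V_W Molar volume of water, cm^3 mol^-1 (> 0; default 18.07).
#' @return Osmotic permeability, cm^3 s^-1.
#' @examples
#' Pf_from_LP(7.3e-18, T = 300)   # ~1.0e-13 cm^3/s
#' @export
Pf_from_LP <- function(LP, T = 300, V_W = pf_constants$V_W) {
  if (T <= 0) stop("'T' must be > 0")
  if (V_W <= 0) stop("'V_W' must be > 0")
  ## 1 cm^5/N/s = 1e-10 m^3/Pa/s; V_W cm^3/mol = 1e-6 m^3/mol;
  ## result m^3/s -> 1e6 cm^3/s. Net factor 1e2.
  LP * pf_constants$R * T / V_W * 1e2
}

#' @rdname Pf_from_LP
#' @param Pf Osmotic permeability, cm^3 s^-1.
#' @return `LP_from_Pf`: hydraulic permeability, cm^5 N^-1 s^-1.
#' @export
LP_from_Pf <- function(Pf, T = 300, V_W = pf_constants$V_W) {
  if (T <= 0) stop("'T' must be > 0")
  if (V_W <= 0) stop("'V_W' must be > 0")
  Pf * V_W / (pf_constants$R * T) / 1e2
}

#' Osmotic--hydrostatic driving-force equivalence
#'
#' A solute concentration difference `delta_C` drives the same water flux as
#' a hydrostatic pressure difference `delta_P = R T delta_C`. Supply exactly
#' one of the pair; the other is filled in.
#'
#' @param delta_C Concentration difference, mol m^-3.
#' @param delta_P Pressure difference, MPa.
#' @param T Temperature, K (> 0).
#' @return A list of class `pf_osmotic_equiv` with both `delta_C` (mol m^-3)
#'   and `delta_P` (MPa).
#' @examples
#' pressure_concentration_equiv(delta_P = 10)   # ~4.0e3 mol/m^3 at 300 K
#' @export
pressure_concentration_equiv <- function(delta_C = NULL, delta_P = NULL,
                                         T = 300) {
  if (T <= 0) stop("'T' must be > 0")
  if (is.null(delta_C) == is.null(delta_P))
    stop("supply exactly one of 'delta_C' or 'delta_P'")
  if (is.null(delta_P)) {
    delta_P <- pf_constants$R * T * delta_C / 1e6   # Pa -> MPa
  } else {
    delta_C <- delta_P * 1e6 / (pf_constants$R * T)
  }
  structure(list(delta_C = delta_C, delta_P = delta_P, T = T),
            class = "pf_osmotic_equiv")
}

#' @export
print.pf_osmotic_equiv <- function(x, ...) {
  cat(sprintf("<pf_osmotic_equiv> dP = %g MPa <-> dC = %g mol/m^3 at %g K\n",
              x$delta_P, x$delta_C, x$T))
  invisible(x)
}
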