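# Quantitative assay computations behind the packaged constants:
# fast-exchange NMR titrations, combined amide chemical shift perturbation,
# ITC one-site isotherms, and the chymotrypsin-coupled PPIase assay.

#' Container for fit outputs
#'
#' @param estimates named numeric point estimates (units per name: `kd_uM`,
#'   `delta_bound_ppm`, `n`, `dH_kcal_mol`, `turnover_s1`, `k0_s1`).
#' @param stderr named numeric standard errors (same names).
#' @param converged logical.
#' @param residual_rms root-mean-square residual, units of the observable.
#' @param flags character vector of quality flags (`"non_binding"`,
#'   `"low_confidence_kd"`, `"poor_saturation_coverage"`, `"no_activity"`).
#' @return An object of class `fit_result`.
#' @export
fit_result <- function(estimates = numeric(0), stderr = numeric(0),
                       converged = FALSE, residual_rms = NA_real_,
                       flags = character(0)) {
  stopifnot(all(stderr >= 0 | is.na(stderr)))
  structure(list(estimates = estimates, stderr = stderr,
                 converged = converged, residual_rms = residual_rms,
                 flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", if (x$converged) "converged" else "NOT converged",
      if (length(x$flags)) paste0("[", paste(x$flags, collapse = ", "), "]")
      else "", "\n")
  if (length(x$estimates)) {
    for (nm in names(x$estimates))
      cat(sprintf("  %-16s %g +/- %g\n", nm, x$estimates[[nm]],
                  if (nm %in% names(x$stderr)) x$stderr[[nm]] else NA))
  }
  cat(sprintf("  residual rms     %g\n", x$residual_rms))
  invisible(x)
}

# shared Levenberg-Marquardt driver: multi-start over supplied parameter
# vectors, numerical-Jacobian covariance at the best optimum
lm_multistart <- function(resid_fn, starts, lower = NULL, upper = NULL) {
  best <- NULL
  for (p0 in starts) {
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0, fn = resid_fn, lower = lower,
                         upper = upper,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-12, ptol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(NULL)
  p <- best$par
  r <- resid_fn(p)
  n <- length(r); k <- length(p)
  J <- matrix(0, n, k)
  for (j in seq_len(k)) {
    h <- max(1e-7, 1e-7 * abs(p[[j]]))
    pp <- p; pp[[j]] <- pp[[j]] + h
    J[, j] <- (resid_fn(pp) - r) / h
  }
  s2 <- sum(r^2) / max(n - k, 1)
  cov <- tryCatch(solve(crossprod(J)) * s2,
                  error = function(e) matrix(NA_real_, k, k))
  # info 1-4: gradient/step criteria met; 5: iteration cap reached, which the
  # fitters treat as termination and convey quality through stderr and flags
  list(par = p, deviance = best$deviance, converged = best$info %in% 1:5,
       stderr = sqrt(pmax(diag(cov), 0)), rms = sqrt(mean(r^2)))
}

# ---- NMR titration ---------------------------------------------------------

#' Observed chemical shift under fast exchange
#'
#' In the fast-exchange regime the observed resonance is the population
#' average of the free and bound states, so the shift tracks the bound
#' fraction of the observed species directly:
#' `delta_obs = delta_free + (delta_bound - delta_free) * f_bound`.
#'
#' @param p_total total observed species, uM.
#' @param l_total total titrated ligand, uM; vectorised.
#' @param kd dissociation constant, uM.
#' @param delta_free,delta_bound limiting shifts, ppm.
#' @return Observed shift(s), ppm.
#' @export
predict_shift <- function(p_total, l_total, kd, delta_free, delta_bound) {
  delta_free + (delta_bound - delta_free) *
    bound_fraction_1to1(p_total, l_total, kd)
}

#' One fast-exchange titration series
#'
#' @param p_total total observed species, uM (scalar, or one value per point).
#' @param l_totals ligand totals per titration point, uM; at least 4 points.
#' @param shifts observed shifts, ppm.
#' @param delta_free shift of the free species, ppm (usually the first point).
#' @param meta optional named list of metadata (generator parameters travel
#'   here).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(p_total, l_totals, shifts,
                             delta_free = shifts[which.min(l_totals)],
                             meta = list()) {
  stopifnot(length(l_totals) >= 4, all(l_totals >= 0),
            length(shifts) == length(l_totals), all(is.finite(shifts)))
  p_total <- rep_len(p_total, length(l_totals))
  structure(list(p_total = p_total, l_totals = l_totals, shifts = shifts,
                 delta_free = delta_free, meta = meta),
            class = "titration_series")
}

#' Fit a 1:1 fast-exchange titration
#'
#' Nonlinear least squares of [predict_shift()] over the dissociation
#' constant and the bound-state shift, with the free-state shift fixed from
#' the series. The fit is multi-started over dissociation-constant decades
#' from 0.1 to 1e5 uM to avoid local minima. Series whose total shift range
#' is below three times the point-scatter estimate are declared non-binding.
#' A warning flag is raised when the design never leaves the < 10% or > 90%
#' saturation window, where the constant is poorly identified.
#'
#' @param series a [titration_series()].
#' @return A [fit_result()] with estimates `kd_uM` and `delta_bound_ppm`.
#' @export
fit_titration <- function(series) {
  stopifnot(inherits(series, "titration_series"))
  obs <- series$shifts
  span <- diff(range(obs))
  noise <- stats::sd(diff(obs)) / sqrt(2)
  if (span < 3 * max(noise, 1e-12))
    return(fit_result(flags = "non_binding",
                      residual_rms = stats::sd(obs)))

  dfree <- series$delta_free
  resid_fn <- function(p) {
    predict_shift(series$p_total, series$l_totals, exp(p[["log_kd"]]),
                  dfree, p[["delta_bound"]]) - obs
  }
  starts <- lapply(10^seq(-1, 5), function(kd0) {
    fb <- bound_fraction_1to1(series$p_total, max(series$l_totals), kd0)
    fb <- max(fb[length(fb)], 0.05)
    c(log_kd = log(kd0),
      delta_bound = dfree + (obs[which.max(series$l_totals)] - dfree) / fb)
  })
  fit <- lm_multistart(resid_fn, starts)
  if (is.null(fit) || !fit$converged)
    return(fit_result(converged = FALSE, residual_rms = NA_real_))

  kd <- exp(fit$par[["log_kd"]])
  flags <- character(0)
  fb <- bound_fraction_1to1(series$p_total, series$l_totals, kd)
  if (max(fb) < 0.10 || min(fb[series$l_totals > 0]) > 0.90)
    flags <- "poor_saturation_coverage"
  fit_result(
    estimates = c(kd_uM = kd, delta_bound_ppm = fit$par[["delta_bound"]]),
    stderr = c(kd_uM = kd * fit$stderr[1], delta_bound_ppm = fit$stderr[2]),
    converged = TRUE, residual_rms = fit$rms, flags = flags)
}

#' Combined amide chemical shift perturbation
#'
#' Scalar combination of the proton and nitrogen shift changes of a backbone
#' amide, `sqrt(dH^2 + (w * dN)^2)`, with the conventional nitrogen scaling
#' of 0.2 by default.
#'
#' @param delta_H,delta_N shift changes, ppm; vectorised.
#' @param weight nitrogen weight, > 0.
#' @return Combined perturbation, ppm.
#' @export
csp_combined <- function(delta_H, delta_N, weight = 0.2) {
  stopifnot(weight > 0)
  sqrt(delta_H^2 + (weight * delta_N)^2)
}

# ---- ITC -------------------------------------------------------------------

#' ITC thermogram container
#'
#' @param cell_vol_uL working cell volume, uL.
#' @param cell_uM initial cell (macromolecule) concentration, uM.
#' @param syringe_uM syringe (ligand) concentration, uM.
#' @param inj_vol_uL injection volumes, uL.
#' @param heats measured injection heats, ucal (baseline-subtracted).
#' @param meta optional named metadata list.
#' @return An object of class `itc_thermogram`.
#' @export
itc_thermogram <- function(cell_vol_uL, cell_uM, syringe_uM, inj_vol_uL,
                           heats, meta = list()) {
  stopifnot(cell_vol_uL > 0, cell_uM > 0, syringe_uM > 0,
            all(inj_vol_uL > 0), length(heats) == length(inj_vol_uL))
  structure(list(cell_vol_uL = cell_vol_uL, cell_uM = cell_uM,
                 syringe_uM = syringe_uM, inj_vol_uL = inj_vol_uL,
                 heats = heats, meta = meta),
            class = "itc_thermogram")
}

#' Sequential-injection heats of a one-site binding isotherm
#'
#' Models an incremental-titration ITC run with displacement dilution: each
#' injection of volume `v` into working volume `V0` dilutes the prior cell
#' contents by `(1 - v/V0)` and adds ligand `syringe * v/V0`. The heat of
#' injection i is the enthalpy of the newly formed complex,
#' `V0 * dH * ([PL]_i - [PL]_{i-1} * (1 - v/V0))`, in ucal.
#'
#' @param n binding stoichiometry (sites per cell molecule).
#' @param kd dissociation constant, uM.
#' @param dH binding enthalpy, kcal/mol.
#' @param cell_vol_uL,cell_uM,syringe_uM,inj_vol_uL geometry as in
#'   [itc_thermogram()].
#' @return Numeric vector of injection heats, ucal.
#' @export
itc_heats <- function(n, kd, dH, cell_vol_uL, cell_uM, syringe_uM,
                      inj_vol_uL) {
  stopifnot(n > 0, kd > 0, cell_vol_uL > 0, all(inj_vol_uL > 0))
  V0 <- cell_vol_uL
  P <- cell_uM
  L <- 0
  pl_prev <- 0
  heats <- numeric(length(inj_vol_uL))
  for (i in seq_along(inj_vol_uL)) {
    v <- inj_vol_uL[i]
    d <- 1 - v / V0
    P <- P * d
    L <- L * d + syringe_uM * v / V0
    sites <- n * P
    pl <- bound_fraction_1to1(sites, L, kd) * sites
    # uM * uL * kcal/mol -> 1e-3 ucal
    heats[i] <- V0 * dH * (pl - pl_prev * d) * 1e-3
    pl_prev <- pl
  }
  heats
}

#' Fit a one-site ITC isotherm
#'
#' Least squares of [itc_heats()] over stoichiometry, dissociation constant
#' and enthalpy, multi-started over dissociation-constant decades. The first
#' injection (routinely corrupted by syringe diffusion) can be excluded.
#' When the Wiseman c-value `n * [cell] / kd` of the fit leaves the
#' informative window \[0.1, 1e4\], the dissociation constant is flagged low
#' confidence.
#'
#' @param tg an [itc_thermogram()] with at least 10 usable injections.
#' @param discard_first drop injection 1 before fitting.
#' @return A [fit_result()] with estimates `n`, `kd_uM`, `dH_kcal_mol`.
#' @export
fit_itc <- function(tg, discard_first = FALSE) {
  stopifnot(inherits(tg, "itc_thermogram"))
  keep <- seq_along(tg$heats)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 10)
    stop("at least 10 usable injections are required", call. = FALSE)
  obs <- tg$heats[keep]

  noise <- stats::sd(diff(obs)) / sqrt(2)
  if (max(abs(obs)) < 3 * max(noise, 1e-12))
    return(fit_result(flags = "non_binding", residual_rms = stats::sd(obs)))

  model <- function(n, kd, dH)
    itc_heats(n, kd, dH, tg$cell_vol_uL, tg$cell_uM, tg$syringe_uM,
              tg$inj_vol_uL)[keep]
  resid_fn <- function(p)
    model(p[["n"]], exp(p[["log_kd"]]), p[["dH"]]) - obs
  # rough enthalpy scale: total heat over cell-content moles
  dH0 <- sum(obs) / (tg$cell_vol_uL * tg$cell_uM * 1e-3)
  starts <- lapply(10^seq(-1, 5), function(kd0)
    c(n = 1, log_kd = log(kd0), dH = dH0))
  fit <- lm_multistart(resid_fn, starts,
                       lower = c(n = 0.05, log_kd = log(1e-4), dH = -Inf),
                       upper = c(n = 20, log_kd = log(1e7), dH = Inf))
  if (is.null(fit) || !fit$converged)
    return(fit_result(converged = FALSE))

  n_hat <- fit$par[["n"]]
  kd <- exp(fit$par[["log_kd"]])
  cval <- n_hat * tg$cell_uM / kd
  kd_se <- kd * fit$stderr[2]
  # outside the informative c window, or when the linearised uncertainty
  # rivals the estimate itself, the constant is not trustworthy
  flags <- if (cval < 0.1 || cval > 1e4 || !is.finite(kd_se) || kd_se > kd)
    "low_confidence_kd" else character(0)
  fit_result(
    estimates = c(n = n_hat, kd_uM = kd, dH_kcal_mol = fit$par[["dH"]]),
    stderr = c(n = fit$stderr[1], kd_uM = kd * fit$stderr[2],
               dH_kcal_mol = fit$stderr[3]),
    converged = TRUE, residual_rms = fit$rms, flags = flags)
}

# ---- PPIase ----------------------------------------------------------------

#' Observed rate of the chymotrypsin-coupled isomerisation assay
#'
#' The coupled assay follows the disappearance of the cis substrate isomer as
#' a pseudo-first-order process. The observed rate is the uncatalysed
#' background plus the enzymatic contribution, with the turnover number
#' defined as initial enzymatic velocity per enzyme at the assay substrate
#' concentration: `k_obs = k0 + turnover * [E] / [S_cis0]`.
#'
#' @param k0 uncatalysed isomerisation rate, s^-1.
#' @param turnover turnover number, s^-1.
#' @param enzyme enzyme concentration, uM; vectorised.
#' @param substrate_cis0 initial cis-substrate concentration, uM; > 0.
#' @return Observed rate(s), s^-1.
#' @export
ppiase_kobs <- function(k0, turnover, enzyme, substrate_cis0) {
  stopifnot(substrate_cis0 > 0, all(enzyme >= 0))
  k0 + turnover * enzyme / substrate_cis0
}

#' One absorbance progress curve of the coupled assay
#'
#' @param enzyme_uM enzyme concentration, uM (0 for the blank).
#' @param s_cis0_uM initial cis-substrate concentration, uM.
#' @param times sampling times, s; strictly increasing.
#' @param signal absorbance-proportional readings (arbitrary units).
#' @param meta optional named metadata list.
#' @return An object of class `progress_curve`.
#' @export
progress_curve <- function(enzyme_uM, s_cis0_uM, times, signal,
                           meta = list()) {
  stopifnot(enzyme_uM >= 0, s_cis0_uM > 0, all(diff(times) > 0),
            length(signal) == length(times))
  structure(list(enzyme_uM = enzyme_uM, s_cis0_uM = s_cis0_uM,
                 times = times, signal = signal, meta = meta),
            class = "progress_curve")
}

# single-exponential fit of one progress curve; returns k_obs and its se
fit_progress_exponential <- function(curve) {
  y <- curve$signal
  t <- curve$times
  a_inf0 <- mean(utils::tail(y, max(3L, length(y) %/% 10)))
  da0 <- max(a_inf0 - y[1], 1e-8)
  # crude rate from the early log-linear segment
  z <- a_inf0 + 0.05 * da0 - y
  ok <- which(z > 0)[seq_len(min(length(y) %/% 2, sum(z > 0)))]
  k0_init <- if (length(ok) > 2)
    max(-stats::coef(stats::lm(log(z[ok]) ~ t[ok]))[2], 1e-4) else 0.05
  resid_fn <- function(p)
    p[["a_inf"]] - p[["da"]] * exp(-exp(p[["log_k"]]) * t) - y
  fit <- lm_multistart(resid_fn,
                       list(c(a_inf = a_inf0, da = da0, log_k = log(k0_init)),
                            c(a_inf = a_inf0, da = da0,
                              log_k = log(10 * k0_init))))
  if (is.null(fit) || !fit$converged) return(NULL)
  k <- exp(fit$par[["log_k"]])
  list(k_obs = k, se = k * fit$stderr[3], rms = fit$rms)
}

#' Estimate the PPIase turnover number from progress curves
#'
#' Each curve is fit as a single exponential approach to completion,
#' `signal = A_inf - dA * exp(-k_obs * t)`; curves that are not monotone
#' after light smoothing are excluded with a warning. The observed rates are
#' then regressed (weighted by their inverse variance) on
#' `enzyme / substrate_cis0`: the slope is the turnover number and the
#' intercept the uncatalysed rate. The slope is invariant to the arbitrary
#' absorbance scale of the signal.
#'
#' @param curves list of [progress_curve()] objects covering at least 3
#'   enzyme concentrations (a blank or low point included).
#' @return A [fit_result()] with estimates `turnover_s1` and `k0_s1`.
#' @export
fit_ppiase <- function(curves) {
  stopifnot(is.list(curves),
            all(vapply(curves, inherits, logical(1), "progress_curve")))
  if (length(unique(vapply(curves, `[[`, numeric(1), "enzyme_uM"))) < 3)
    stop("at least 3 enzyme concentrations are required", call. = FALSE)

  rows <- list()
  for (i in seq_along(curves)) {
    cv <- curves[[i]]
    sm <- stats::filter(cv$signal, rep(1 / 5, 5), sides = 2)
    sm <- sm[!is.na(sm)]
    amp <- max(diff(range(sm)), 1e-12)
    # a rising curve may flatten, but must never dip far below its running max
    if (max(cummax(sm) - sm) > 0.2 * amp) {
      warning("excluding non-monotone progress curve ", i, call. = FALSE)
      next
    }
    ef <- fit_progress_exponential(cv)
    if (is.null(ef)) {
      warning("excluding progress curve ", i, " (exponential fit failed)",
              call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <-
      data.frame(x = cv$enzyme_uM / cv$s_cis0_uM, k_obs = ef$k_obs,
                 se = ef$se, rms = ef$rms)
  }
  if (length(rows) < 3)
    stop("fewer than 3 usable progress curves", call. = FALSE)
  dat <- do.call(rbind, rows)

  w <- if (all(is.finite(dat$se)) && all(dat$se > 0)) 1 / dat$se^2
       else rep(1, nrow(dat))
  lmfit <- stats::lm(k_obs ~ x, data = dat, weights = w)
  co <- summary(lmfit)$coefficients
  slope <- co["x", "Estimate"]
  flags <- if (!is.finite(slope) || slope < 1e-6 ||
               slope < 3 * co["x", "Std. Error"])
    "no_activity" else character(0)
  fit_result(
    estimates = c(turnover_s1 = slope, k0_s1 = co["(Intercept)", "Estimate"]),
    stderr = c(turnover_s1 = co["x", "Std. Error"],
               k0_s1 = co["(Intercept)", "Std. Error"]),
    converged = TRUE,
    residual_rms = sqrt(mean(stats::residuals(lmfit)^2)), flags = flags)
}
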