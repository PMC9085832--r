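FARADAY <- 96485.33212      # C / mol
GAS_CONSTANT <- 8.31446262  # J / (mol K)

#' Boltzmann model of steady-state activation
#'
#' I/Imax = amp / (1 + exp(z_delta * F * (V - V_half) / (R * T))) with V
#' in mV. With positive `z_delta` activation grows toward hyperpolarised
#' voltages; at V = V_half the model equals amp/2.
#'
#' @param V command voltage, mV
#' @param V_half half-activation voltage, mV
#' @param z_delta effective gating charge (dimensionless, > 0)
#' @param amp relative amplitude at saturating voltage
#' @param temperature Kelvin
#' @export
boltzmann_model <- function(V, V_half, z_delta, amp = 1,
                            temperature = 293.15) {
  amp / (1 + exp(z_delta * FARADAY * (V - V_half) / 1000 /
                   (GAS_CONSTANT * temperature)))
}

#' Normalise tail-current amplitudes
#'
#' Divides by the amplitude of largest magnitude, so the saturated level
#' maps to 1 regardless of current sign (inward currents are negative);
#' monotonicity of the activation curve is preserved.
#'
#' @param amplitudes numeric vector, not all zero
#' @export
normalize_tail_currents <- function(amplitudes) {
  m <- amplitudes[which.max(abs(amplitudes))]
  if (abs(m) == 0) stop("all-zero tail amplitudes cannot be normalised")
  amplitudes / m
}

#' Fit the Boltzmann activation model to one recording
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' [boltzmann_model()] to relative tail currents of a single recording.
#' The recording temperature is not part of the data; the fitted
#' `z_delta` equals slope x RT/F and therefore scales proportionally
#' with the assumed temperature, so the value used is recorded in the
#' fit.
#'
#' @param voltages command voltages, mV
#' @param rel_current I/Imax values (normalise first via
#'   [normalize_tail_currents()])
#' @param temperature Kelvin (default 293.15)
#' @return list of class `boltzmann_fit`: V_half (mV), z_delta,
#'   amp_satV, temperature, residual_sd, fit (nls object)
#' @export
fit_boltzmann <- function(voltages, rel_current, temperature = 293.15) {
  stopifnot(length(voltages) == length(rel_current),
            length(voltages) >= 5)
  if (cor(voltages, rel_current) > 0.5)
    warning("current increases with depolarisation; ",
            "check the sign convention of the recording")
  df <- data.frame(V = voltages, y = rel_current)
  amp0 <- max(rel_current)
  # crude half-point from linear interpolation on the sorted curve
  o <- order(voltages)
  Vh0 <- tryCatch(
    approx(rel_current[o], voltages[o], xout = amp0 / 2, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(Vh0)) Vh0 <- median(voltages)
  fit <- minpack.lm::nlsLM(
    y ~ amp / (1 + exp(zd * FARADAY * (V - Vh) / 1000 /
                         (GAS_CONSTANT * temperature))),
    data = df, start = list(amp = amp0, zd = 4, Vh = Vh0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(V_half = unname(cf["Vh"]), z_delta = unname(cf["zd"]),
                 amp_satV = unname(cf["amp"]), temperature = temperature,
                 residual_sd = sd(residuals(fit)), fit = fit),
            class = "boltzmann_fit")
}

#' @export
print.boltzmann_fit <- function(x, ...) {
  cat(sprintf("Boltzmann fit: V1/2 = %.2f mV, z_delta = %.2f, amp = %.3f (T = %.2f K)\n",
              x$V_half, x$z_delta, x$amp_satV, x$temperature))
  invisible(x)
}

#' Ligand-induced shift of half-activation voltage
#'
#' Difference of mean V_half between a saturating-ligand and a
#' ligand-free fit set, with the SEM propagated as
#' sqrt(sem_sat^2 + sem_zero^2).
#'
#' @param fits_zero,fits_sat lists of `boltzmann_fit` objects (or bare
#'   numeric V_half vectors)
#' @return list(delta_mV, sem, n_zero, n_sat)
#' @export
delta_v12 <- function(fits_zero, fits_sat) {
  vh <- function(x) {
    if (is.numeric(x)) return(x)
    vapply(x, function(f) f$V_half, numeric(1))
  }
  a <- vh(fits_zero); b <- vh(fits_sat)
  if (length(a) == 0 || length(b) == 0) stop("empty fit set")
  list(delta_mV = mean(b) - mean(a),
       sem = sqrt(sem(a)^2 + sem(b)^2),
       n_zero = length(a), n_sat = length(b))
}

#' Fit a delayed single exponential to a current time course
#'
#' Model I(t) = I_inf + A * exp(-(t - delay)/tau) on points with
#' t >= delay. The delay is either given, or detected automatically as
#' the first crossing of 10 percent of the signal span, then refined by
#' back-extrapolating the fitted exponential to the pre-delay baseline.
#'
#' @param time,current numeric vectors (time units are preserved in tau)
#' @param delay numeric fixed delay, or `"auto"` (default), or 0 for
#'   none
#' @return list of class `exp_fit`: A, tau, delay, I_inf, fit
#' @export
fit_exponential <- function(time, current, delay = "auto") {
  stopifnot(length(time) == length(current), length(time) >= 4)
  o <- order(time); time <- time[o]; current <- current[o]
  span <- max(time) - min(time)
  baseline <- current[1]
  final <- mean(current[time >= max(time) - 0.05 * span])
  auto <- identical(delay, "auto")
  if (auto) {
    thr <- baseline + 0.1 * (final - baseline)
    crossed <- if (final >= baseline) current >= thr else current <= thr
    k <- which(crossed)[1]
    delay <- if (is.na(k) || k == 1) min(time) else time[k - 1]
  } else {
    delay <- as.numeric(delay)
  }
  keep <- time >= delay
  if (sum(keep) < 4) stop("fewer than 4 points after the delay")
  tt <- time[keep] - delay; yy <- current[keep]
  tau0 <- max(span / 5, diff(range(time)) / length(time))
  fit <- minpack.lm::nlsLM(
    yy ~ yinf + A * exp(-tt / tau),
    data = data.frame(tt = tt, yy = yy),
    start = list(yinf = final, A = yy[1] - final, tau = tau0),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  A <- unname(cf["A"]); tau <- unname(cf["tau"]); yinf <- unname(cf["yinf"])
  if (tau <= 0) stop("exponential fit returned non-positive tau")
  if (auto) {
    # back-extrapolate to the baseline level to undo the threshold lag
    arg <- (baseline - yinf) / A
    if (is.finite(arg) && arg > 0) {
      d2 <- delay - tau * log(arg)
      if (is.finite(d2) && d2 >= min(time) && d2 <= delay) delay <- d2
    }
  }
  structure(list(A = A, tau = tau, delay = delay, I_inf = yinf, fit = fit),
            class = "exp_fit")
}

#' Hill model of the concentration-binding relationship
#'
#' F/Fmax = 1 / (1 + (BC50 / conc)^H); equals 0.5 at conc = BC50 by
#' construction.
#'
#' @param conc agonist concentration (same units as BC50)
#' @param BC50 concentration of half-maximum binding
#' @param H Hill coefficient
#' @export
hill_model <- function(conc, BC50, H) 1 / (1 + (BC50 / conc)^H)

#' Fit the Hill equation to averaged binding data
#'
#' Fitted once to the averaged F/Fmax relationship (not per patch), with
#' the saturating amplitude fixed at 1 as in [hill_model()].
#'
#' @param concentrations agonist concentrations (> 0), micromolar by
#'   convention
#' @param F_over_Fmax averaged relative fluorescence at each
#'   concentration
#' @return list of class `hill_fit`: BC50, H, fit
#' @export
fit_hill <- function(concentrations, F_over_Fmax) {
  stopifnot(length(concentrations) == length(F_over_Fmax),
            all(concentrations > 0), length(concentrations) >= 3)
  if (sd(F_over_Fmax) == 0) stop("all responses equal; Hill fit undefined")
  o <- order(concentrations)
  bc0 <- tryCatch(
    approx(F_over_Fmax[o], concentrations[o], xout = 0.5, ties = mean)$y,
    error = function(e) NA_real_)
  if (!is.finite(bc0)) bc0 <- exp(mean(log(concentrations)))
  fit <- minpack.lm::nlsLM(
    y ~ 1 / (1 + (BC50 / conc)^H),
    data = data.frame(conc = concentrations, y = F_over_Fmax),
    start = list(BC50 = bc0, H = 1.5),
    lower = c(BC50 = 1e-9, H = 1e-3),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  structure(list(BC50 = unname(cf["BC50"]), H = unname(cf["H"]), fit = fit),
            class = "hill_fit")
}

#' Reference-dye background subtraction for cPCF images
#'
#' The red reference-dye image is scaled so that it matches the green
#' (ligand) image over the free-dye regions (bath and pipette interior),
#' then subtracted; the mean of the corrected green signal over the
#' patch dome, relative to `f_max`, quantifies the bound-ligand
#' fraction. The result is invariant to rescaling the red channel (the
#' scale factor compensates) and to adding any multiple of the red image
#' to the green one.
#'
#' @param green,red 2-D intensity matrices of equal size
#' @param roi_dome,roi_bath,roi_pipette logical masks (disjoint) of the
#'   same size
#' @param f_max dome intensity at a saturating ligand concentration
#'   (> 0)
#' @return list of class `cpcf_result`: F_over_Fmax, bound (mean
#'   corrected dome intensity), scale (red-to-green factor), clipped
#'   (TRUE when the raw ratio was negative and reported as 0;
#'   `F_over_Fmax_raw` keeps the unclipped value)
#' @export
cpcf_subtract <- function(green, red, roi_dome, roi_bath, roi_pipette,
                          f_max) {
  stopifnot(all(dim(green) == dim(red)), f_max > 0)
  if (any(roi_dome & (roi_bath | roi_pipette)) || any(roi_bath & roi_pipette))
    stop("ROIs must be disjoint")
  free <- roi_bath | roi_pipette
  if (!any(free)) stop("empty bath/pipette scaling region")
  red_free <- mean(red[free])
  if (abs(red_free) < 1e-12)
    stop("zero red signal in the scaling ROIs; cannot scale reference dye")
  s <- mean(green[free]) / red_free
  corrected <- green - s * red
  bound <- mean(corrected[roi_dome])
  raw <- bound / f_max
  structure(list(F_over_Fmax = max(0, raw), F_over_Fmax_raw = raw,
                 bound = bound, scale = s, clipped = raw < 0),
            class = "cpcf_result")
}
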