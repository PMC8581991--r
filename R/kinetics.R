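# Forward kinetic models for the pCASL difference signal: Buxton general
# kinetic model tissue compartment, an optional macrovascular compartment,
# and a Gamma flow-dispersion kernel applied to the delivery functions of
# both compartments.
#
# Time convention: model time t runs from the start of labeling, so a
# protocol post-labeling delay (PLD) maps to sample time t = tau + PLD.

#' Physiological state of one simulated voxel
#'
#' Bundles the ground-truth tissue and vascular parameters that drive the
#' forward signal model.  CBF is given in the conventional ml/100g/min and
#' internally converted to the `f` used by the kinetic equations
#' (ml blood / ml tissue / s) by dividing by 6000, with the partition
#' coefficient `lam` treated as ml/g.
#'
#' @param cbf Cerebral blood flow, ml/100 g/min.
#' @param att Arterial transit time of the tissue compartment (Delta t), s.
#' @param abv Arterial blood volume fraction (0.002 = 0.2%).
#' @param att_macro Transit time of the macrovascular compartment
#'   (Delta t_a), s.  Defaults to `att - 0.5`, the coupling used throughout
#'   the simulation study; must not exceed `att`.
#' @param lam Blood-tissue partition coefficient of water, ml/g.
#' @param t1b Longitudinal relaxation time of arterial blood, s.
#' @param t1t Longitudinal relaxation time of tissue, s.
#' @return An object of class `asl_state`.
#' @examples
#' st <- asl_state(cbf = 60, att = 1.4)
#' st$f        # 0.01 s^-1
#' @export
asl_state <- function(cbf = 60, att = 1.4, abv = 0.002,
                      att_macro = att - 0.5,
                      lam = 0.9, t1b = 1.65, t1t = 1.3) {
  stopifnot(is.numeric(cbf), length(cbf) == 1L, cbf >= 0)
  if (!(is.numeric(att) && length(att) == 1L && att > 0))
    stop("`att` must be a single positive number", call. = FALSE)
  if (!(abv >= 0 && abv <= 1))
    stop("`abv` must be a fraction in [0, 1]", call. = FALSE)
  if (att_macro > att + 1e-12)
    stop("`att_macro` must not exceed `att`", call. = FALSE)
  if (att_macro < 0)
    stop("`att_macro` must be nonnegative", call. = FALSE)
  if (any(c(lam, t1b, t1t) <= 0))
    stop("`lam`, `t1b` and `t1t` must be positive", call. = FALSE)
  structure(list(cbf = cbf, f = cbf / 6000, att = att, abv = abv,
                 att_macro = att_macro, lam = lam, t1b = t1b, t1t = t1t),
            class = "asl_state")
}

#' Labeling configuration
#'
#' @param alpha Labeling efficiency, dimensionless in (0, 1].
#' @param tau Label duration, s.
#' @param m0b Equilibrium magnetization of arterial blood (arbitrary
#'   units); all signals are expressed in units of `m0b`, so the default of
#'   1 makes signal values directly relative.
#' @return An object of class `asl_labeling`.
#' @export
labeling_config <- function(alpha = 0.85, tau = 1.4, m0b = 1) {
  stopifnot(alpha > 0, alpha <= 1, tau > 0, m0b > 0)
  structure(list(alpha = alpha, tau = tau, m0b = m0b),
            class = "asl_labeling")
}

#' Gamma dispersion kernel specification
#'
#' The kernel is a Gamma density `k(t) = s^(1+sp)/Gamma(1+sp) t^(sp)
#' e^(-st)` with sharpness `s` (1/s) and time-to-peak `p` (s); its mode is
#' at `t = p` and lower `s` means broader dispersion.  `dispersion_off()`
#' gives the identity (Dirac) kernel, i.e. no dispersion.
#'
#' @param s Sharpness, s^-1; default 1/0.13.
#' @param p Time-to-peak, s; default 0.17.
#' @param enabled Logical; if `FALSE` the kernel is the identity.
#' @return An object of class `asl_dispersion`.
#' @examples
#' dispersion_spec()            # reference sharpness s0
#' dispersion_spec(s = (1/0.13) / 4)  # heavy dispersion
#' @export
dispersion_spec <- function(s = 1 / 0.13, p = 0.17, enabled = TRUE) {
  if (enabled) {
    if (!(is.numeric(s) && length(s) == 1L && s > 0))
      stop("dispersion sharpness `s` must be positive", call. = FALSE)
    if (!(is.numeric(p) && length(p) == 1L && p >= 0))
      stop("dispersion time-to-peak `p` must be nonnegative", call. = FALSE)
  }
  structure(list(s = s, p = p, enabled = isTRUE(enabled)),
            class = "asl_dispersion")
}

#' @rdname dispersion_spec
#' @export
dispersion_off <- function() dispersion_spec(enabled = FALSE)

#' ASL difference-signal curve
#'
#' A light container for signal values sampled at given model times
#' (seconds from start of labeling).
#'
#' @param times Strictly increasing (or protocol-ordered) sample times, s.
#' @param values Signal values in units of M0B.
#' @param meta Named list of free-form metadata (protocol, signal class,
#'   repeat index, ...).
#' @return An object of class `asl_signal`.
#' @export
asl_signal <- function(times, values, meta = list()) {
  stopifnot(length(times) == length(values), all(is.finite(times)))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 meta = meta),
            class = "asl_signal")
}

#' @export
print.asl_signal <- function(x, ...) {
  cls <- x$meta$signal_class
  cat("<asl_signal> ", length(x$times), " samples",
      if (!is.null(cls)) paste0(" [", cls, "]"), "\n", sep = "")
  print(utils::head(data.frame(time = x$times, value = x$values), 10))
  if (length(x$times) > 10) cat("...\n")
  invisible(x)
}

#' @export
as.data.frame.asl_signal <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

# ---- delivery and dispersion ------------------------------------------------

#' Undispersed pCASL delivery function
#'
#' The ideal pCASL arterial input at the tissue voxel: zero before the
#' bolus arrives at `att`, a plateau of height `alpha * exp(-att/t1b)`
#' during the bolus window `(att, att + tau)`, zero after.
#'
#' @param t Time(s) since start of labeling, s; must be nonnegative.
#' @param state An [asl_state()].
#' @param label A [labeling_config()].
#' @return Delivery-function value(s) (units of alpha).
#' @export
delivery_function <- function(t, state, label = labeling_config()) {
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  plateau <- label$alpha * exp(-state$att / state$t1b)
  ifelse(t > state$att & t <= state$att + label$tau, plateau, 0)
}

#' Gamma dispersion kernel density
#'
#' @param t Time(s), s; nonnegative.
#' @param disp A [dispersion_spec()] with `enabled = TRUE`.
#' @return Kernel density value(s), s^-1.  A unit-mass Gamma density with
#'   shape `1 + s*p` and rate `s`; its mode is at `t = p`.
#' @export
dispersion_kernel <- function(t, disp = dispersion_spec()) {
  if (!disp$enabled)
    stop("dispersion kernel requested but dispersion is disabled", call. = FALSE)
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  stats::dgamma(t, shape = 1 + disp$s * disp$p, rate = disp$s)
}

#' Dispersed delivery function
#'
#' Convolution of the pCASL boxcar delivery with the Gamma dispersion
#' kernel.  Because the kernel is a Gamma density, the convolution with a
#' boxcar has the exact form `plateau * (F(t - att) - F(t - att - tau))`
#' with `F` the Gamma CDF; no numerical grid is involved.
#'
#' @inheritParams delivery_function
#' @param disp A [dispersion_spec()]; when disabled this equals
#'   [delivery_function()].
#' @return Dispersed delivery value(s).
#' @export
dispersed_delivery <- function(t, state, label = labeling_config(),
                               disp = dispersion_spec()) {
  if (any(t < 0)) stop("`t` must be nonnegative", call. = FALSE)
  if (!disp$enabled) return(delivery_function(t, state, label))
  plateau <- label$alpha * exp(-state$att / state$t1b)
  a <- 1 + disp$s * disp$p
  plateau * (stats::pgamma(t - state$att, shape = a, rate = disp$s) -
               stats::pgamma(t - state$att - label$tau, shape = a,
                             rate = disp$s))
}

# Integral H(x) = int_0^x (k * exp(-R u))(v) dv for the Gamma kernel,
# i.e. the bolus-window building block of the dispersed tissue signal.
# Closed form via regularized incomplete gamma functions when s > R;
# numerical fallback (fine-grid trapezoid) otherwise.
.H_disp <- function(x, R, s, p) {
  a <- 1 + s * p
  b <- s - R
  out <- numeric(length(x))
  pos <- x > 0
  if (!any(pos)) return(out)
  xp <- x[pos]
  if (b > 1e-2) {
    # log-space second term avoids overflow of (s/b)^a for small b
    term2 <- exp(a * log(s / b) - R * xp +
                   stats::pgamma(xp, shape = a, rate = b, log.p = TRUE))
    out[pos] <- (stats::pgamma(xp, shape = a, rate = s) - term2) / R
  } else {
    out[pos] <- .H_disp_numeric(xp, R, s, p)
  }
  out
}

.H_disp_numeric <- function(x, R, s, p, h = 5e-4) {
  a <- 1 + s * p
  tg <- seq(0, max(x) + h, by = h)
  # g(v) = exp(-R v) * int_0^v k(u) exp(R u) du  (trapezoid cumulative)
  integrand <- stats::dgamma(tg, shape = a, rate = s) * exp(R * tg)
  cum <- c(0, cumsum((integrand[-1] + integrand[-length(integrand)]) / 2)) * h
  g <- exp(-R * tg) * cum
  Hg <- c(0, cumsum((g[-1] + g[-length(g)]) / 2)) * h
  stats::approx(tg, Hg, xout = x, rule = 2)$y
}

# Undispersed building block: H(x) = (1 - exp(-R x))/R for x > 0.
.H_undisp <- function(x, R) {
  out <- numeric(length(x))
  pos <- x > 0
  out[pos] <- (1 - exp(-R * x[pos])) / R
  out
}

# ---- compartment signals ----------------------------------------------------

# Internal vectorised forward model used by both the user-facing signal
# functions and the fitting engine.  `t` are model times (tau + PLD).
.tissue_values <- function(t, f, att, lam, t1b, t1t, alpha, tau, m0b,
                           disp_on, s, p) {
  R <- 1 / t1t + f / lam
  plateau <- alpha * exp(-att / t1b)
  H <- if (disp_on) function(x) .H_disp(x, R, s, p) else function(x) .H_undisp(x, R)
  2 * m0b * f * plateau * (H(t - att) - H(t - att - tau))
}

.macro_values <- function(t, abv, att_macro, t1b, alpha, tau, m0b,
                          disp_on, s, p) {
  height <- 2 * alpha * m0b * exp(-att_macro / t1b) * abv
  if (!disp_on) {
    height * (t > att_macro & t <= att_macro + tau)
  } else {
    a <- 1 + s * p
    height * (stats::pgamma(t - att_macro, shape = a, rate = s) -
                stats::pgamma(t - att_macro - tau, shape = a, rate = s))
  }
}

#' Tissue-compartment difference signal
#'
#' The Buxton general kinetic model signal `2 M0B f (c * (r m))(t)` with
#' residue function `r(t) = exp(-f t / lam)` and relaxation
#' `m(t) = exp(-t / t1t)`, so the effective clearance rate is
#' `R = 1/t1t + f/lam`.  With dispersion the delivery is first convolved
#' with the Gamma kernel; both cases are evaluated in closed form
#' (`method = "closed"`, via regularized incomplete gamma functions when
#' dispersed) or by numerical convolution on a uniform grid
#' (`method = "numeric"`), which serves as an internal cross-check.
#'
#' @param times Sample times since start of labeling, s.
#' @inheritParams dispersed_delivery
#' @param method `"closed"` (default, exact) or `"numeric"` (uniform-grid
#'   convolution with step `grid_dt`).
#' @param grid_dt Grid step for `method = "numeric"`, s.
#' @return An [asl_signal()].
#' @export
tissue_signal <- function(times, state, label = labeling_config(),
                          disp = dispersion_off(),
                          method = c("closed", "numeric"), grid_dt = 1e-3) {
  if (any(times < 0)) stop("`times` must be nonnegative", call. = FALSE)
  method <- match.arg(method)
  if (method == "closed") {
    v <- .tissue_values(times, state$f, state$att, state$lam, state$t1b,
                        state$t1t, label$alpha, label$tau, label$m0b,
                        disp$enabled, disp$s, disp$p)
  } else {
    v <- .tissue_numeric(times, state, label, disp, grid_dt)
  }
  asl_signal(times, v, meta = list(compartment = "tissue"))
}

# Numerical double-convolution route on a uniform grid.  The boxcar is
# rasterised by cell-overlap fractions so the Riemann sums keep second-order
# accuracy despite the discontinuous delivery.
.tissue_numeric <- function(times, state, label, disp, h) {
  R <- 1 / state$t1t + state$f / state$lam
  tmax <- max(times)
  tg <- seq(0, tmax + h, by = h)
  n <- length(tg)
  plateau <- label$alpha * exp(-state$att / state$t1b)
  # fraction of cell [t-h/2, t+h/2] inside the bolus window
  lo <- state$att; hi <- state$att + label$tau
  frac <- pmax(0, pmin(tg + h / 2, hi) - pmax(tg - h / 2, lo)) / h
  cg <- plateau * frac
  if (disp$enabled) {
    kg <- stats::dgamma(tg, shape = 1 + disp$s * disp$p, rate = disp$s)
    cg <- .conv_grid(cg, kg, h)[seq_len(n)]
  }
  rm_g <- exp(-R * tg)
  sig <- 2 * label$m0b * state$f * .conv_grid(cg, rm_g, h)[seq_len(n)]
  stats::approx(tg, sig, xout = times, rule = 2)$y
}

# discrete convolution with trapezoid end-correction
.conv_grid <- function(x, y, h) {
  n <- length(x)
  full <- stats::convolve(x, rev(y), type = "open")[seq_len(n)] * h
  full - (h / 2) * (x[1] * y + x * y[1])
}

#' Macrovascular-compartment difference signal
#'
#' Labeled blood still residing in large vessels: a boxcar of height
#' `2 alpha M0B exp(-att_macro/t1b) * abv` on `(att_macro, att_macro +
#' tau)`.  With dispersion enabled the boxcar is convolved with the same
#' Gamma kernel as the tissue delivery.  The trailing edge of the bolus is
#' taken at `att_macro + tau`.
#'
#' @inheritParams tissue_signal
#' @return An [asl_signal()].
#' @export
macrovascular_signal <- function(times, state, label = labeling_config(),
                                 disp = dispersion_off()) {
  if (any(times < 0)) stop("`times` must be nonnegative", call. = FALSE)
  v <- .macro_values(times, state$abv, state$att_macro, state$t1b,
                     label$alpha, label$tau, label$m0b,
                     disp$enabled, disp$s, disp$p)
  asl_signal(times, v, meta = list(compartment = "macrovascular"))
}

#' Total voxel difference signal
#'
#' Sum of the tissue and (optionally) macrovascular compartments.  The
#' four simulated signal classes map onto the two switches: D-M-
#' (`disp` disabled, `include_mvc = FALSE`), D-M+, D+M-, D+M+.
#'
#' @inheritParams tissue_signal
#' @param include_mvc Logical; add the macrovascular compartment?
#' @return An [asl_signal()] with `meta$signal_class` set.
#' @examples
#' lab <- labeling_config()
#' st <- asl_state(cbf = 60, att = 1.4, abv = 0.002)
#' total_signal(lab$tau + c(0.5, 1.0, 1.8), st, lab, include_mvc = TRUE)
#' @export
total_signal <- function(times, state, label = labeling_config(),
                         disp = dispersion_off(), include_mvc = FALSE) {
  sig <- tissue_signal(times, state, label, disp)
  if (include_mvc) {
    sig$values <- sig$values +
      macrovascular_signal(times, state, label, disp)$values
  }
  cls <- paste0(if (disp$enabled) "D+" else "D-",
                if (include_mvc) "M+" else "M-")
  sig$meta <- list(signal_class = cls)
  sig
}

#' Signal-class code helpers
#'
#' Signal classes are written `"D-M-"`, `"D-M+"`, `"D+M-"`, `"D+M+"`
#' (dispersion / macrovascular component present or absent); the
#' file-name-safe aliases `"DmMm"`, `"DmMp"`, `"DpMm"`, `"DpMp"` are also
#' accepted everywhere.
#'
#' @param x A signal-class code.
#' @return `normalize_signal_class()` returns the canonical `"D?M?"` form;
#'   `signal_class_flags()` returns a list with logical `disp` and `mvc`.
#' @export
normalize_signal_class <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  map <- c("DmMm" = "D-M-", "DmMp" = "D-M+", "DpMm" = "D+M-", "DpMp" = "D+M+",
           "D-M-" = "D-M-", "D-M+" = "D-M+", "D+M-" = "D+M-", "D+M+" = "D+M+")
  if (!x %in% names(map))
    stop("unknown signal class: ", x, call. = FALSE)
  unname(map[x])
}

#' @rdname normalize_signal_class
#' @export
signal_class_flags <- function(x) {
  x <- normalize_signal_class(x)
  list(disp = substr(x, 2, 2) == "+", mvc = substr(x, 4, 4) == "+")
}
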