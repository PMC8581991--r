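# Voxelwise model fitting.  Four nested kinetic model variants are fit by
# maximum a posteriori (MAP) estimation under truncated-Gaussian priors,
# with parameter uncertainties taken from the curvature (inverse Hessian)
# of the negative log-posterior at the optimum.  The single-PLD protocol
# is quantified by exact closed-form inversion at an assumed ATT.

.free_params <- list(
  "gkm" = c("cbf", "att"),
  "gkm+mvc" = c("cbf", "att", "abv", "datt"),
  "gkm+disp" = c("cbf", "att", "s", "p"),
  "gkm+disp+mvc" = c("cbf", "att", "abv", "datt", "s", "p")
)

#' Default estimation priors and bounds
#'
#' Truncated-Gaussian priors, weakly informative: CBF half-normal with SD
#' 100 ml/100 g/min on \[0, 400\] (zero-centered, the convention of
#' variational ASL toolkits, so that a curve carrying no perfusion signal
#' is quantified as zero flow rather than pulled to a nominal value);
#' ATT ~ N(1.3, 1.0) s on \[0.05, 4\]; aBV half-normal with SD 1% on
#' \[0, 5%\]; the macrovascular lead time `datt = att - att_macro`
#' ~ N(0.5, 0.5) s on \[0, 2\] (which bounds `att_macro <= att` by
#' construction); dispersion sharpness s ~ N(s0, s0) with s0 = 1/0.13 on
#' \[1, 60\] s^-1; time-to-peak p ~ N(0.17, 0.1) s on \[0, 1\].
#'
#' @return Named list of `c(mean, sd)` (priors) or `c(lower, upper)`
#'   (bounds) per parameter.
#' @export
default_priors <- function() {
  list(cbf = c(0, 100), att = c(1.3, 1.0), abv = c(0, 0.01),
       datt = c(0.5, 0.5), s = c(1 / 0.13, 1 / 0.13), p = c(0.17, 0.1))
}

#' @rdname default_priors
#' @export
default_bounds <- function() {
  list(cbf = c(0, 400), att = c(0.05, 4), abv = c(0, 0.05),
       datt = c(0, 2), s = c(1, 60), p = c(0, 1))
}

# optimizer works on scaled parameters of order ~1
.param_scale <- c(cbf = 10, att = 1, abv = 0.01, datt = 1, s = 10, p = 0.1)

#' Kinetic model specification for fitting
#'
#' The variant determines the model structure and the free parameters:
#' `"gkm"` frees CBF and ATT; `"+mvc"` adds the macrovascular aBV and
#' transit-time lead `datt` (so `att_macro = att - datt`); `"+disp"` adds
#' the Gamma-kernel sharpness `s` and time-to-peak `p`.  Fixed parameters
#' take their prior means.  `"single-pld"` selects closed-form single-PLD
#' quantification at `assumed_att` instead of an optimization.
#'
#' @param variant One of `"gkm"`, `"gkm+mvc"`, `"gkm+disp"`,
#'   `"gkm+disp+mvc"`, `"single-pld"`.
#' @param priors,bounds Named lists overriding entries of
#'   [default_priors()] / [default_bounds()].
#' @param known_sd Optional known noise SD (units of M0B, per fitted
#'   sample).  Default `NULL` profiles the noise SD out of the Gaussian
#'   likelihood (it is estimated from the residuals).
#' @param n_starts Number of deterministic multi-start initializations
#'   (>= 1); the best (lowest objective) solution is kept.  Defaults to 3
#'   for `"gkm"` and 4 for the extended variants.
#' @param assumed_att Assumed ATT (s) for `"single-pld"` quantification.
#' @return An object of class `asl_model_spec`.
#' @examples
#' model_spec("gkm+mvc")
#' model_spec("gkm", priors = list(att = c(1.5, 0.5)))
#' @export
model_spec <- function(variant = c("gkm", "gkm+mvc", "gkm+disp",
                                   "gkm+disp+mvc", "single-pld"),
                       priors = list(), bounds = list(),
                       known_sd = NULL, n_starts = NULL, assumed_att = 1.25) {
  variant <- match.arg(variant)
  pr <- utils::modifyList(default_priors(), priors)
  bd <- utils::modifyList(default_bounds(), bounds)
  if (is.null(n_starts))
    n_starts <- if (variant %in% c("gkm", "single-pld")) 3L else 4L
  stopifnot(n_starts >= 1L)
  structure(list(variant = variant,
                 free = if (variant == "single-pld") character(0)
                        else .free_params[[variant]],
                 priors = pr, bounds = bd, known_sd = known_sd,
                 n_starts = as.integer(n_starts),
                 assumed_att = assumed_att,
                 disp_on = grepl("disp", variant),
                 mvc_on = grepl("mvc", variant)),
            class = "asl_model_spec")
}

#' @export
print.asl_model_spec <- function(x, ...) {
  cat("<asl_model_spec> ", x$variant,
      if (length(x$free)) paste0(" | free: ", paste(x$free, collapse = ", ")),
      "\n", sep = "")
  invisible(x)
}

# Build a fast single-curve fitter closed over the protocol times and spec.
# Returns function(y) -> list(estimates, sd, converged, objective).
.make_fitter <- function(times, spec, label, uncertainty = TRUE,
                         physio = asl_state()) {
  free <- spec$free
  npar <- length(free)
  scale <- .param_scale[free]
  lower <- vapply(spec$bounds[free], `[`, numeric(1), 1L) / scale
  upper <- vapply(spec$bounds[free], `[`, numeric(1), 2L) / scale
  pmean <- vapply(spec$priors[free], `[`, numeric(1), 1L)
  psd <- vapply(spec$priors[free], `[`, numeric(1), 2L)
  n <- length(times)
  lam <- physio$lam; t1b <- physio$t1b; t1t <- physio$t1t
  alpha <- label$alpha; tau <- label$tau; m0b <- label$m0b
  disp_on <- spec$disp_on; mvc_on <- spec$mvc_on
  fixed <- vapply(spec$priors, `[`, numeric(1), 1L)

  # specialized predictors by position in `free` (cbf, att[, abv, datt][, s, p])
  # keep the hot Monte-Carlo paths (undispersed variants) allocation-lean
  invt1t <- 1 / t1t
  two_m0b <- 2 * m0b
  predict_free <- if (!disp_on && !mvc_on) {
    function(theta) {
      f <- theta[1] / 6000
      R <- invt1t + f / lam
      x1 <- times - theta[2]
      x1 <- x1 * (x1 > 0)
      x2 <- x1 - tau
      x2 <- x2 * (x2 > 0)
      two_m0b * f * alpha * exp(-theta[2] / t1b) *
        ((exp(-R * x2) - exp(-R * x1)) / R)
    }
  } else if (!disp_on && mvc_on) {
    function(theta) {
      f <- theta[1] / 6000
      R <- invt1t + f / lam
      x1 <- times - theta[2]
      x1 <- x1 * (x1 > 0)
      x2 <- x1 - tau
      x2 <- x2 * (x2 > 0)
      am <- max(theta[2] - theta[4], 0)
      two_m0b * f * alpha * exp(-theta[2] / t1b) *
        ((exp(-R * x2) - exp(-R * x1)) / R) +
        (two_m0b * alpha * exp(-am / t1b) * theta[3]) *
          (times > am & times <= am + tau)
    }
  } else if (disp_on && !mvc_on) {
    function(theta) {
      f <- theta[1] / 6000
      R <- invt1t + f / lam
      sv <- theta[3]; pv <- theta[4]
      two_m0b * f * alpha * exp(-theta[2] / t1b) *
        (.H_disp(times - theta[2], R, sv, pv) -
           .H_disp(times - theta[2] - tau, R, sv, pv))
    }
  } else {
    function(theta) {
      f <- theta[1] / 6000
      R <- invt1t + f / lam
      sv <- theta[5]; pv <- theta[6]
      am <- max(theta[2] - theta[4], 0)
      a <- 1 + sv * pv
      two_m0b * f * alpha * exp(-theta[2] / t1b) *
        (.H_disp(times - theta[2], R, sv, pv) -
           .H_disp(times - theta[2] - tau, R, sv, pv)) +
        (two_m0b * alpha * exp(-am / t1b) * theta[3]) *
          (stats::pgamma(times - am, shape = a, rate = sv) -
             stats::pgamma(times - am - tau, shape = a, rate = sv))
    }
  }

  # analytic model Jacobian for the undispersed variants (the hot
  # Monte-Carlo paths); dispersed variants fall back to finite differences
  grad_free <- if (!disp_on) {
    function(theta) {
      f <- theta[1] / 6000
      R <- invt1t + f / lam
      att <- theta[2]
      x1 <- times - att
      x1 <- x1 * (x1 > 0)
      x2 <- x1 - tau
      x2 <- x2 * (x2 > 0)
      e1 <- exp(-R * x1)
      e2 <- exp(-R * x2)
      A_unit <- two_m0b * alpha * exp(-att / t1b)  # = A / f, finite at f = 0
      A <- f * A_unit
      D <- (e2 - e1) / R
      dD_dR <- (x1 * e1 - x2 * e2) / R - D / R
      dmu_dcbf <- (A_unit * D + A * dD_dR / lam) / 6000
      dmu_datt <- -A * D / t1b + A * (e2 * (x2 > 0) - e1 * (x1 > 0))
      if (!mvc_on) return(cbind(dmu_dcbf, dmu_datt, deparse.level = 0))
      am <- max(att - theta[4], 0)
      ind <- (times > am & times <= am + tau)
      B2 <- two_m0b * alpha * exp(-am / t1b)
      live <- (att - theta[4]) > 0  # clamped att_macro has zero derivative
      mvc <- B2 * theta[3] * ind
      cbind(dmu_dcbf,
            dmu_datt - if (live) mvc / t1b else 0,
            B2 * ind,
            if (live) mvc / t1b else rep(0, length(times)),
            deparse.level = 0)
    }
  } else NULL

  known_sd <- spec$known_sd
  # clamped to bounds so derivative-free polishing can evaluate anywhere
  objective <- function(theta_s, y) {
    theta <- pmin.int(pmax.int(theta_s, lower), upper) * scale
    mu <- predict_free(theta)
    rss <- sum((y - mu)^2)
    nll <- if (is.null(known_sd)) 0.5 * n * log(rss / n + 1e-300)
           else rss / (2 * known_sd^2)
    nll + 0.5 * sum(((theta - pmean) / psd)^2)
  }
  gradient <- if (!is.null(grad_free)) {
    function(theta_s, y) {
      theta <- pmin.int(pmax.int(theta_s, lower), upper) * scale
      mu <- predict_free(theta)
      resid <- y - mu
      J <- grad_free(theta)
      drss <- -2 * as.numeric(crossprod(resid, J))
      dnll <- if (is.null(known_sd)) {
        0.5 * n * drss / (sum(resid^2) + n * 1e-300)
      } else {
        drss / (2 * known_sd^2)
      }
      (dnll + (theta - pmean) / psd^2) * scale
    }
  } else NULL

  # deterministic multi-start: a prior-centered start plus the best points
  # of a coarse candidate grid over ATT (and aBV / sharpness for the
  # extended variants), with CBF set by linear projection of the data on
  # the unit-CBF model shape.  Retained grid starts are deduplicated by
  # ATT so the optimizer explores distinct basins.
  att_grid <- seq(0.6, 3.0, by = 0.3)
  abv_grid <- if ("abv" %in% free) c(0.001, 0.01) else 0
  s_grid <- if ("s" %in% free) c(1 / 0.13, 1 / 0.13 / 4) else NA_real_
  base_start <- fixed[free]
  base_start["cbf"] <- 60
  base_start["att"] <- 1.3
  if ("abv" %in% free) base_start["abv"] <- 0.003
  cand_df <- expand.grid(att = att_grid, abv = abv_grid, s = s_grid,
                         KEEP.OUT.ATTRS = FALSE)

  starts_for <- function(y) {
    cand <- lapply(seq_len(nrow(cand_df)), function(i) {
      th <- base_start
      th["att"] <- cand_df$att[i]
      if ("abv" %in% free) th["abv"] <- cand_df$abv[i]
      if ("s" %in% free) th["s"] <- cand_df$s[i]
      shape <- predict_free(replace(th, "cbf", 60)) / 60
      denom <- sum(shape^2)
      if (denom > 0) {
        th["cbf"] <- min(max(sum(y * shape) / denom,
                             lower[["cbf"]] * scale[["cbf"]]),
                         upper[["cbf"]] * scale[["cbf"]])
      }
      th
    })
    obj <- vapply(cand, function(th) objective(th / scale, y), numeric(1))
    ord <- order(obj)
    starts <- list(base_start)
    for (j in ord) {
      if (length(starts) >= spec$n_starts) break
      atts_used <- vapply(starts[-1], `[[`, numeric(1), "att")
      if (!length(atts_used) || min(abs(atts_used - cand[[j]][["att"]])) > 0.15)
        starts[[length(starts) + 1L]] <- cand[[j]]
    }
    starts
  }

  function(y) {
    starts <- starts_for(y)
    best <- NULL
    for (th0 in starts) {
      res <- tryCatch(
        stats::optim(pmin(pmax(th0 / scale, lower), upper), objective,
                     gr = gradient, y = y, method = "L-BFGS-B",
                     lower = lower, upper = upper,
                     control = list(maxit = 300)),
        error = function(e) NULL)
      if (is.null(res)) next
      if (npar > 1L && (res$convergence != 0 || !is.null(known_sd))) {
        # line-search failures near curved valleys: derivative-free polish
        pol <- tryCatch(
          stats::optim(res$par, objective, y = y, method = "Nelder-Mead",
                       control = list(maxit = 1000, reltol = 1e-12)),
          error = function(e) NULL)
        if (!is.null(pol) && pol$value <= res$value) {
          pol$par <- pmin(pmax(pol$par, lower), upper)
          pol$convergence <- 0
          res <- pol
        }
      }
      if (is.null(best) || res$value < best$value)
        best <- res
    }
    if (is.null(best)) {
      return(list(estimates = stats::setNames(rep(NA_real_, npar), free),
                  sd = stats::setNames(rep(NA_real_, npar), free),
                  converged = FALSE, objective = NA_real_))
    }
    est <- best$par * scale
    names(est) <- free
    sds <- stats::setNames(rep(NA_real_, npar), free)
    cov_mat <- NULL
    if (uncertainty) {
      H <- tryCatch(stats::optimHess(best$par, objective, gr = gradient,
                                     y = y),
                    error = function(e) NULL)
      if (!is.null(H)) {
        cv <- tryCatch(solve(H), error = function(e) NULL)
        if (!is.null(cv)) {
          d <- diag(cv)
          ok <- is.finite(d) & d >= 0
          sds[ok] <- sqrt(d[ok]) * scale[ok]
          cov_mat <- cv * tcrossprod(scale)
        }
      }
    }
    list(estimates = est, sd = sds, converged = best$convergence == 0,
         objective = best$value, cov = cov_mat)
  }
}

# Coerce the accepted signal inputs to a numeric value vector aligned with
# the protocol's (nondecreasing) PLD order.
.signal_values <- function(signal, protocol) {
  if (inherits(signal, "asl_signal")) {
    v <- signal$values
    if (length(v) != length(protocol$plds))
      stop("signal length does not match the protocol's PLD schedule",
           call. = FALSE)
    return(v[order(signal$times)])
  }
  if (is.data.frame(signal)) {
    col <- intersect(c("value", "values"), names(signal))[1]
    key <- intersect(c("pld", "time"), names(signal))[1]
    if (is.na(col) || is.na(key))
      stop("signal data frame needs a `pld` (or `time`) and `value` column",
           call. = FALSE)
    if (nrow(signal) != length(protocol$plds))
      stop("signal length does not match the protocol's PLD schedule",
           call. = FALSE)
    return(signal[[col]][order(signal[[key]])])
  }
  if (is.numeric(signal)) {
    if (length(signal) != length(protocol$plds))
      stop("signal length does not match the protocol's PLD schedule",
           call. = FALSE)
    return(signal)
  }
  stop("unsupported signal input", call. = FALSE)
}

#' Fit a kinetic model to one averaged signal curve
#'
#' MAP estimation under the model specification's truncated-Gaussian priors,
#' bounded quasi-Newton optimization with deterministic multi-start
#' initialization; ties are broken by the lowest objective.  Failed
#' optimizations are flagged in the result, never raised.
#'
#' @param signal An [asl_signal()], a data frame with `pld` (or `time`)
#'   and `value` columns, or a bare numeric vector in protocol PLD order.
#'   Values are the per-PLD averaged difference signal in units of M0B.
#' @param protocol The [asl_protocol()] the signal was sampled with.
#' @param spec A [model_spec()].
#' @param label A [labeling_config()].
#' @param uncertainty Compute curvature-based parameter SDs (inverse
#'   Hessian of the negative log-posterior)?
#' @return An object of class `asl_fit`: list with `estimates` (named:
#'   `cbf` ml/100 g/min, `att` s, and for the extended variants `abv`,
#'   `att_macro`, `s`, `p`), `sd` (same names), `variant`, `converged`,
#'   `objective`, `flags`.
#' @examples
#' prot <- builtin_protocol("cbf-opt")
#' truth <- asl_state(cbf = 60, att = 1.4)
#' y <- total_signal(protocol_times(prot), truth)
#' fit(y, prot, model_spec("gkm"))$estimates
#' @export
fit <- function(signal, protocol, spec = model_spec("gkm"),
                label = labeling_config(), uncertainty = TRUE) {
  stopifnot(inherits(protocol, "asl_protocol"),
            inherits(spec, "asl_model_spec"))
  if (spec$variant == "single-pld")
    return(fit_single_pld(signal, protocol, assumed_att = spec$assumed_att,
                          label = label))
  y <- .signal_values(signal, protocol)
  fitter <- .make_fitter(protocol_times(protocol), spec, label)
  res <- fitter(y)
  .as_asl_fit(res, spec)
}

.as_asl_fit <- function(res, spec) {
  est <- res$estimates
  sds <- res$sd
  if ("datt" %in% names(est)) {
    est <- c(est, att_macro = unname(est[["att"]] - est[["datt"]]))
    am_sd <- NA_real_
    if (!is.null(res$cov)) {
      i <- match(c("att", "datt"), spec$free)
      v <- res$cov[i[1], i[1]] + res$cov[i[2], i[2]] - 2 * res$cov[i[1], i[2]]
      if (is.finite(v) && v >= 0) am_sd <- sqrt(v)
    }
    sds <- c(sds, att_macro = am_sd)
  }
  structure(list(estimates = est, sd = sds, variant = spec$variant,
                 converged = res$converged, objective = res$objective,
                 flags = if (res$converged) character(0) else "no_convergence"),
            class = "asl_fit")
}

#' @export
print.asl_fit <- function(x, ...) {
  cat("<asl_fit> ", x$variant,
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  print(round(rbind(estimate = x$estimates,
                    sd = x$sd[names(x$estimates)]), 4))
  invisible(x)
}

#' Single-PLD closed-form CBF quantification
#'
#' Inverts the (undispersed) general-kinetic-model tissue signal at
#' `t = tau + PLD` with ATT fixed to `assumed_att`, by root finding on
#' CBF (the model is monotone in CBF).  The provided signal values are
#' averaged first.  Exact on noiseless input generated at
#' `att = assumed_att`.  Non-positive signals give CBF 0 with a
#' `"clipped_at_zero"` flag.
#'
#' @inheritParams fit
#' @param assumed_att Assumed ATT, s (default 1.25).
#' @return An `asl_fit` with estimates `cbf` and `att` (the assumption).
#' @export
fit_single_pld <- function(signal, protocol, assumed_att = 1.25,
                           label = labeling_config()) {
  stopifnot(inherits(protocol, "asl_protocol"))
  if (length(unique(protocol$plds)) != 1L)
    stop("single-PLD quantification requires a protocol with one distinct PLD",
         call. = FALSE)
  y <- mean(.signal_values(signal, protocol))
  t0 <- protocol$tau + protocol$plds[1]
  st_at <- function(cbf) asl_state(cbf = cbf, att = assumed_att, abv = 0,
                                   att_macro = max(assumed_att - 0.5, 0))
  model_at <- function(cbf) {
    tissue_signal(t0, st_at(cbf), label)$values
  }
  flags <- character(0)
  if (y <= 0) {
    cbf <- 0
    flags <- "clipped_at_zero"
  } else {
    upper <- 2000
    if (model_at(upper) < y) {
      cbf <- upper
      flags <- "clipped_at_upper_bound"
    } else {
      cbf <- stats::uniroot(function(cc) model_at(cc) - y,
                            interval = c(0, upper), tol = 1e-10)$root
    }
  }
  structure(list(estimates = c(cbf = cbf, att = assumed_att),
                 sd = c(cbf = NA_real_, att = NA_real_),
                 variant = "single-pld", converged = TRUE,
                 objective = NA_real_, flags = flags),
            class = "asl_fit")
}

#' Fit a kinetic model to every repeat of an ensemble
#'
#' Batch wrapper over [fit()] (or [fit_single_pld()] for the
#' `"single-pld"` variant).  Results are independent of row order: rows
#' are canonically sorted by condition, repeat and PLD before fitting, and
#' the optimizer initialization is deterministic.
#'
#' @param ensemble Data frame from [simulate_ensemble()] (columns `att`,
#'   `abv`, `s`, `rep`, `pld`, `value`; extra columns are carried along).
#' @param protocol The generating [asl_protocol()].
#' @param spec A [model_spec()].
#' @param label A [labeling_config()].
#' @param uncertainty Compute curvature SDs for every fit (slower;
#'   default `FALSE` for Monte-Carlo ensembles).
#' @return A data frame with one row per (condition, repeat): the
#'   condition columns, `variant`, estimate columns (`cbf_est`,
#'   `att_est`, and `abv_est`/`att_macro_est`/`s_est`/`p_est` where
#'   free), optional `*_sd` columns, and `converged`.
#' @export
fit_ensemble <- function(ensemble, protocol, spec = model_spec("gkm"),
                         label = labeling_config(), uncertainty = FALSE) {
  stopifnot(is.data.frame(ensemble))
  need <- c("att", "abv", "s", "rep", "pld", "value")
  miss <- setdiff(need, names(ensemble))
  if (length(miss))
    stop("ensemble is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(ensemble) == 0L) {
    return(data.frame(att = numeric(0), abv = numeric(0), s = numeric(0),
                      rep = integer(0), variant = character(0),
                      cbf_est = numeric(0), att_est = numeric(0),
                      converged = logical(0)))
  }
  skey <- ensemble$s
  skey[is.na(skey)] <- -1
  ord <- order(ensemble$att, ensemble$abv, skey, ensemble$rep, ensemble$pld)
  ens <- ensemble[ord, , drop = FALSE]
  nt <- length(protocol$plds)
  grp <- paste(ens$att, ens$abv, ens$s, ens$rep, sep = "\r")
  grp <- factor(grp, levels = unique(grp))
  if (any(tabulate(grp) != nt))
    stop("each (condition, repeat) group must contain exactly one value per ",
         "protocol PLD", call. = FALSE)
  ngrp <- nlevels(grp)
  vals <- matrix(ens$value, nrow = nt)
  head_rows <- ens[!duplicated(grp), c("att", "abv", "s", "rep"), drop = FALSE]

  single <- spec$variant == "single-pld"
  if (!single)
    fitter <- .make_fitter(protocol_times(protocol), spec, label,
                           uncertainty = uncertainty)
  free <- spec$free
  res_list <- vector("list", ngrp)
  for (i in seq_len(ngrp)) {
    y <- vals[, i]
    if (single) {
      fr <- fit_single_pld(y, protocol, assumed_att = spec$assumed_att,
                           label = label)
      row <- list(cbf_est = unname(fr$estimates[["cbf"]]),
                  att_est = unname(fr$estimates[["att"]]),
                  converged = fr$converged)
    } else {
      fr <- fitter(y)
      row <- as.list(stats::setNames(unname(fr$estimates),
                                     paste0(free, "_est")))
      if ("datt" %in% free) {
        row$att_macro_est <- row$att_est - row$datt_est
        row$datt_est <- NULL
      }
      if (uncertainty) {
        row <- c(row, as.list(stats::setNames(unname(fr$sd),
                                              paste0(free, "_sd"))))
      }
      row$converged <- fr$converged
    }
    res_list[[i]] <- row
  }
  res <- do.call(rbind, lapply(res_list, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- cbind(head_rows, variant = spec$variant, res,
               row.names = NULL)
  out
}
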