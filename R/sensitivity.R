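# Error metrics and protocol comparisons: signed percent errors,
# macrovascular-contamination sensitivity slopes, dispersion-bias
# summaries, voxel exclusion rules, binning, and one-tailed Welch t-tests
# with Bonferroni correction.

#' Signed percent estimation error
#'
#' `(estimate - reference) / reference * 100`.
#'
#' @param estimate Estimated value(s).
#' @param reference Ground-truth or reference value(s); must be nonzero.
#' @return Percent error(s), signed.
#' @examples
#' estimation_error(66, 60)   # +10
#' estimation_error(30, 60)   # -50
#' @export
estimation_error <- function(estimate, reference) {
  if (any(reference == 0))
    stop("`reference` must be nonzero", call. = FALSE)
  (estimate - reference) / reference * 100
}

#' Percent-error table from an ensemble fit table
#'
#' Adds `cbf_error_pct` (and `att_error_pct` where an ATT estimate is
#' present and the truth column is usable) to a [fit_ensemble()] result,
#' using the generating condition columns as ground truth.
#'
#' @param fits Data frame from [fit_ensemble()].
#' @param cbf_true Ground-truth CBF, ml/100 g/min.
#' @return The input with error columns appended.
#' @export
error_table <- function(fits, cbf_true = 60) {
  stopifnot(is.data.frame(fits), "cbf_est" %in% names(fits))
  fits$cbf_error_pct <- estimation_error(fits$cbf_est, cbf_true)
  if ("att_est" %in% names(fits) && all(fits$att > 0))
    fits$att_error_pct <- estimation_error(fits$att_est, fits$att)
  fits
}

#' Sensitivity to macrovascular contamination
#'
#' Ordinary least-squares slope of the mean percent error against aBV
#' (expressed in %), restricted to conditions with aBV strictly above
#' `threshold`.  The slope unit is therefore % error per 1% aBV.  Errors
#' are first averaged per aBV value (set `on_means = FALSE` to regress on
#' raw repeats instead).
#'
#' @param errors Data frame with columns `abv` (fraction) and the error
#'   column named by `parameter` (`"cbf_error_pct"` or
#'   `"att_error_pct"`).
#' @param parameter Which error column to use.
#' @param threshold aBV threshold (fraction); default 0.005 (= 0.5%).
#' @param on_means Regress on per-aBV mean errors (default) or raw rows.
#' @return A data frame row with `parameter`, `slope`, `intercept`,
#'   `n_points`, `abv_threshold`.
#' @examples
#' d <- data.frame(abv = c(0.005, 0.01, 0.015),
#'                 cbf_error_pct = c(10, 20, 30))
#' mvc_sensitivity(d, threshold = 0.004)$slope  # 20
#' @export
mvc_sensitivity <- function(errors, parameter = c("cbf_error_pct",
                                                  "att_error_pct"),
                            threshold = 0.005, on_means = TRUE) {
  parameter <- match.arg(parameter)
  stopifnot(is.data.frame(errors), "abv" %in% names(errors),
            parameter %in% names(errors))
  sub <- errors[errors$abv > threshold & is.finite(errors[[parameter]]), ]
  if (length(unique(sub$abv)) < 2L)
    stop("need at least 2 distinct aBV values above the threshold",
         call. = FALSE)
  if (on_means) {
    agg <- stats::aggregate(sub[[parameter]], by = list(abv = sub$abv), mean)
    x <- agg$abv * 100
    y <- agg$x
  } else {
    x <- sub$abv * 100
    y <- sub[[parameter]]
  }
  co <- stats::coef(stats::lm(y ~ x))
  data.frame(parameter = parameter, slope = unname(co[2]),
             intercept = unname(co[1]), n_points = length(unique(x)),
             abv_threshold = threshold)
}

#' Increase in peak overestimation under stronger dispersion
#'
#' For two error tables sharing the same ATT grid (one at a stronger
#' dispersion level, one at the baseline), computes the mean error curve
#' over ATT in each table and returns the difference of the curve maxima
#' (`"peak"`, default) or the maximum pointwise difference
#' (`"pointwise"`).
#'
#' @param errors_hi,errors_ref Data frames with columns `att` and the
#'   error column named by `parameter`.
#' @param parameter Error column to summarize.
#' @param method `"peak"` or `"pointwise"`.
#' @return Increase in peak overestimation, percentage points.
#' @export
dispersion_bias <- function(errors_hi, errors_ref,
                            parameter = c("cbf_error_pct", "att_error_pct"),
                            method = c("peak", "pointwise")) {
  parameter <- match.arg(parameter)
  method <- match.arg(method)
  curve <- function(d) {
    stopifnot(is.data.frame(d), all(c("att", parameter) %in% names(d)))
    agg <- stats::aggregate(d[[parameter]], by = list(att = d$att), mean)
    agg[order(agg$att), ]
  }
  a <- curve(errors_hi)
  b <- curve(errors_ref)
  if (!isTRUE(all.equal(a$att, b$att)))
    stop("the two error tables must share the same ATT grid", call. = FALSE)
  if (method == "peak") max(a$x) - max(b$x) else max(a$x - b$x)
}

#' Quality-control exclusion filter for fit tables
#'
#' Removes rows whose curvature SDs exceed the CBF / ATT limits or whose
#' estimates fall outside the parameter range of interest, and reports how
#' many rows each rule removed.
#'
#' @param fits Data frame with columns `cbf_est`, `att_est`, `cbf_sd`,
#'   `att_sd` (and `abv_est` if an aBV range is enforced).
#' @param cbf_sd_max Maximum allowed CBF SD, ml/100 g/min.
#' @param att_sd_max Maximum allowed ATT SD, s.
#' @param att_range Open interval of admissible ATT estimates, s.
#' @param abv_range Open interval of admissible aBV estimates (fraction);
#'   only applied when `abv_est` is present.
#' @return List with `kept` (filtered data frame) and `removed` (named
#'   counts per rule; a row violating several rules is counted once per
#'   rule).
#' @export
exclusion_filter <- function(fits, cbf_sd_max = 15, att_sd_max = 1.0,
                             att_range = c(0.5, 3.0),
                             abv_range = c(0, 0.02)) {
  stopifnot(is.data.frame(fits))
  need <- c("cbf_est", "att_est", "cbf_sd", "att_sd")
  miss <- setdiff(need, names(fits))
  if (length(miss))
    stop("fit table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad_cbf_sd <- !is.na(fits$cbf_sd) & fits$cbf_sd > cbf_sd_max
  bad_att_sd <- !is.na(fits$att_sd) & fits$att_sd > att_sd_max
  bad_att <- fits$att_est <= att_range[1] | fits$att_est >= att_range[2]
  bad_abv <- if ("abv_est" %in% names(fits))
    fits$abv_est <= abv_range[1] | fits$abv_est >= abv_range[2]
  else rep(FALSE, nrow(fits))
  drop <- bad_cbf_sd | bad_att_sd | bad_att | bad_abv
  list(kept = fits[!drop, , drop = FALSE],
       removed = c(cbf_sd = sum(bad_cbf_sd), att_sd = sum(bad_att_sd),
                   att_range = sum(bad_att), abv_range = sum(bad_abv),
                   total = sum(drop)))
}

#' Bin and average estimates on a regular grid
#'
#' Half-open bins `[lo, lo + width)` anchored at multiples of `width`;
#' empty bins are omitted.
#'
#' @param data Data frame.
#' @param key Name of the binning column (e.g. `"att"` or `"abv"`).
#' @param value Name of the column to average.
#' @param width Bin width (same units as `key`); default 0.05.
#' @return Data frame with columns `bin` (left edge), `mean`, `n`.
#' @export
bin_estimates <- function(data, key, value, width = 0.05) {
  stopifnot(is.data.frame(data), key %in% names(data),
            value %in% names(data), width > 0)
  bin <- floor(data[[key]] / width + 1e-9) * width
  agg <- stats::aggregate(data[[value]], by = list(bin = bin),
                          function(v) c(mean(v), length(v)))
  data.frame(bin = agg$bin, mean = agg$x[, 1], n = as.integer(agg$x[, 2]))
}

#' One-tailed Welch comparison of two error samples
#'
#' Two-sample Welch t-test with a one-tailed alternative; the p-value is
#' Bonferroni-adjusted by multiplying by `m` and capping at 1.  Two
#' identical zero-variance samples are reported with `t = 0`, adjusted
#' p = 1 and a `degenerate` flag instead of an error.
#'
#' @param errors_a,errors_b Numeric samples (e.g. absolute errors of two
#'   protocols); both of length >= 2.
#' @param alternative `"less"` or `"greater"` (direction of `a` vs `b`).
#' @param m Number of comparisons in the family (Bonferroni factor).
#' @return Data frame row with `t`, `df`, `p`, `p_adjusted`,
#'   `significant` (at 0.05), `degenerate`.
#' @export
compare_protocols <- function(errors_a, errors_b,
                              alternative = c("less", "greater"),
                              m = 1L) {
  alternative <- match.arg(alternative)
  stopifnot(length(errors_a) >= 2L, length(errors_b) >= 2L, m >= 1)
  degenerate <- (stats::sd(errors_a) == 0 && stats::sd(errors_b) == 0)
  if (degenerate) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = 1)
  } else {
    tt <- stats::t.test(errors_a, errors_b, alternative = alternative,
                        var.equal = FALSE)
  }
  p_adj <- min(1, tt$p.value * m)
  data.frame(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value, p_adjusted = p_adj,
             significant = p_adj < 0.05, degenerate = degenerate)
}
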