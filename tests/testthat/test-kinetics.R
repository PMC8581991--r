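lab <- labeling_config()

test_that("delivery function is a decayed boxcar over the bolus window", {
  st <- asl_state(cbf = 60, att = 1.4)
  expect_equal(delivery_function(1.0, st, lab), 0)
  expect_equal(delivery_function(2.0, st, lab), 0.85 * exp(-1.4 / 1.65),
               tolerance = 1e-12)
  expect_equal(delivery_function(3.0, st, lab), 0)  # 3.0 > tau + att = 2.8
  # plateau is constant within the window
  inside <- delivery_function(seq(1.5, 2.7, by = 0.2), st, lab)
  expect_true(all(inside == inside[1]))
  expect_error(delivery_function(-0.1, st, lab), "nonnegative")
})

test_that("Gamma kernel is unit mass with mode at p for all sharpness levels", {
  for (s in c(s0_ref, s0_ref / 2, s0_ref / 4)) {
    d <- dispersion_spec(s = s, p = 0.17)
    mass <- stats::integrate(function(t) dispersion_kernel(t, d), 0, Inf,
                             rel.tol = 1e-10)$value
    expect_lt(abs(mass - 1), 1e-6)
    mode <- stats::optimize(function(t) -dispersion_kernel(t, d),
                            c(0, 2), tol = 1e-9)$minimum
    expect_equal(mode, 0.17, tolerance = 1e-4)
  }
  expect_error(dispersion_spec(s = 0), "positive")
  expect_error(dispersion_spec(s = -1), "positive")
})

test_that("dispersed delivery preserves bolus area and reduces to the boxcar", {
  st <- asl_state(cbf = 60, att = 1.4)
  tt <- seq(0, 6, by = 0.25)
  expect_equal(dispersed_delivery(tt, st, lab, dispersion_off()),
               delivery_function(tt, st, lab))
  area_expected <- 0.85 * exp(-1.4 / 1.65) * 1.4
  for (s in c(s0_ref, s0_ref / 2, s0_ref / 4)) {
    d <- dispersion_spec(s = s)
    area <- stats::integrate(function(t) dispersed_delivery(t, st, lab, d),
                             0, 80, rel.tol = 1e-10, subdivisions = 1000L)$value
    expect_lt(abs(area / area_expected - 1), 1e-6)
  }
})

test_that("dispersed delivery matches brute-force quadrature of boxcar * kernel", {
  st <- asl_state(cbf = 60, att = 1.4)
  d <- dispersion_spec()
  a <- 1 + d$s * d$p
  for (t0 in c(1.6, 2.0, 2.8, 3.2)) {
    oracle <- stats::integrate(function(w)
      stats::dgamma(w, shape = a, rate = d$s) *
        delivery_function(pmax(t0 - w, 0), st, lab),
      0, t0, rel.tol = 1e-10, subdivisions = 500L)$value
    expect_lt(abs(dispersed_delivery(t0, st, lab, d) / oracle - 1), 1e-6)
  }
})

test_that("undispersed tissue signal matches the closed-form hand value and scales", {
  st <- asl_state(cbf = 60, att = 1.4)
  # independent: R = 1/1.3 + 0.01/0.9; plateau formula on the bolus window
  R <- 1 / 1.3 + 0.01 / 0.9
  expected <- 2 * 0.01 * 0.85 * exp(-1.4 / 1.65) * (1 - exp(-R * 0.6)) / R
  expect_equal(tissue_signal(2.0, st, lab)$values, expected, tolerance = 1e-12)
  expect_equal(expected, 3.49e-3, tolerance = 2e-3)
  # causality and zero-flow limits
  expect_equal(tissue_signal(c(0.5, 1.0, 1.39), st, lab)$values, rep(0, 3))
  st0 <- asl_state(cbf = 0, att = 1.4)
  expect_equal(tissue_signal(seq(0, 5, 0.5), st0, lab)$values, rep(0, 11))
})

test_that("closed-form tissue signal agrees with quadrature oracle on random draws", {
  set.seed(101)
  tt <- seq(0.2, 4.6, by = 0.55)
  for (i in 1:20) {
    st <- draw_state()
    rel <- abs(tissue_signal(tt, st, lab)$values - quad_tissue(tt, st, lab)) /
      pmax(quad_tissue(tt, st, lab), 1e-12)
    keep <- quad_tissue(tt, st, lab) > 1e-8  # relative error where signal exists
    expect_lt(max(rel[keep]), 1e-6)
  }
})

test_that("dispersed tissue signal agrees with nested quadrature and grid convolution", {
  st <- asl_state(cbf = 60, att = 1.4)
  tt <- c(1.7, 2.2, 2.9, 3.6)
  for (s in c(s0_ref, s0_ref / 4)) {
    d <- dispersion_spec(s = s)
    closed <- tissue_signal(tt, st, lab, d)$values
    oracle <- quad_tissue(tt, st, lab, d)
    expect_lt(max(abs(closed / oracle - 1)), 1e-6)
    numeric <- tissue_signal(tt, st, lab, d, method = "numeric",
                             grid_dt = 2.5e-4)$values
    expect_lt(max(abs(numeric / closed - 1)), 1e-4)
  }
})

test_that("macrovascular signal is the expected boxcar and vanishes correctly", {
  st <- asl_state(cbf = 60, att = 1.4, abv = 0.002, att_macro = 0.9)
  expect_equal(macrovascular_signal(1.2, st, lab)$values,
               2 * 0.85 * exp(-0.9 / 1.65) * 0.002, tolerance = 1e-12)
  expect_equal(macrovascular_signal(c(0.1, 0.5, 0.89), st, lab)$values,
               rep(0, 3))
  st0 <- asl_state(cbf = 60, att = 1.4, abv = 0)
  expect_equal(macrovascular_signal(seq(0, 4, 0.5), st0, lab)$values,
               rep(0, 9))
})

test_that("dispersed macrovascular signal preserves area and matches quadrature", {
  st <- asl_state(cbf = 60, att = 1.4, abv = 0.01, att_macro = 0.9)
  height <- 2 * 0.85 * exp(-0.9 / 1.65) * 0.01
  for (s in c(s0_ref, s0_ref / 4)) {
    d <- dispersion_spec(s = s)
    area <- stats::integrate(function(t)
      macrovascular_signal(t, st, lab, d)$values, 0, 80,
      rel.tol = 1e-10, subdivisions = 1000L)$value
    expect_lt(abs(area / (height * 1.4) - 1), 1e-6)
    tt <- c(1.1, 1.8, 2.5)
    expect_equal(macrovascular_signal(tt, st, lab, d)$values,
                 quad_macro(tt, st, lab, d), tolerance = 1e-7)
  }
})

test_that("total signal is additive and the class flags map onto components", {
  st <- table2_state()
  tt <- protocol_times(builtin_protocol("cbf-opt"))
  dmm <- total_signal(tt, st, lab, include_mvc = FALSE)
  dmp <- total_signal(tt, st, lab, include_mvc = TRUE)
  expect_equal(dmm$values, tissue_signal(tt, st, lab)$values)
  expect_equal(dmp$values - dmm$values,
               macrovascular_signal(tt, st, lab)$values)
  expect_identical(dmm$meta$signal_class, "D-M-")
  expect_identical(total_signal(tt, st, lab, dispersion_spec(),
                                include_mvc = TRUE)$meta$signal_class, "D+M+")
  # all four classes finite and nonnegative at the nominal condition
  for (cls in c("D-M-", "D-M+", "D+M-", "D+M+")) {
    fl <- signal_class_flags(cls)
    d <- if (fl$disp) dispersion_spec() else dispersion_off()
    v <- total_signal(tt, st, lab, d, include_mvc = fl$mvc)$values
    expect_true(all(is.finite(v)))
    expect_true(all(v >= 0))
  }
})

test_that("dispersion raises the trailing edge of the tissue curve", {
  st <- asl_state(cbf = 60, att = 1.4)
  # well past the bolus (tau + att = 2.8) but still within sampled times:
  # dispersed signals exceed the undispersed one
  t_trail <- 3.4
  undisp <- tissue_signal(t_trail, st, lab)$values
  vals <- vapply(c(s0_ref, s0_ref / 2, s0_ref / 4), function(s)
    tissue_signal(t_trail, st, lab, dispersion_spec(s = s))$values, numeric(1))
  expect_true(all(vals > undisp))
  # deep in the tail the effect is monotone in the degree of dispersion
  tail_vals <- vapply(c(s0_ref, s0_ref / 2, s0_ref / 4), function(s)
    tissue_signal(4.0, st, lab, dispersion_spec(s = s))$values, numeric(1))
  expect_true(all(diff(tail_vals) > 0))
})

test_that("signal scales linearly in M0B and, at small flow, in CBF", {
  st <- asl_state(cbf = 60, att = 1.4, abv = 0.002, att_macro = 0.9)
  tt <- seq(1.5, 3.5, by = 0.5)
  v1 <- total_signal(tt, st, labeling_config(m0b = 1), include_mvc = TRUE)$values
  v3 <- total_signal(tt, st, labeling_config(m0b = 3), include_mvc = TRUE)$values
  expect_equal(v3, 3 * v1, tolerance = 1e-12)
  # tissue part linear in f in the r(t) ~ 1 regime (tiny f)
  sa <- asl_state(cbf = 0.5, att = 1.4)
  sb <- asl_state(cbf = 1.0, att = 1.4)
  ra <- tissue_signal(tt, sa, lab)$values
  rb <- tissue_signal(tt, sb, lab)$values
  expect_equal(rb / ra, rep(2, length(tt)), tolerance = 1e-3)
})

test_that("state and signal validation reject inadmissible inputs", {
  expect_error(asl_state(att = 0), "positive")
  expect_error(asl_state(abv = 1.5), "fraction")
  expect_error(asl_state(att = 1.0, att_macro = 1.2), "exceed")
  expect_error(tissue_signal(-1, asl_state(), lab), "nonnegative")
  expect_error(dispersion_kernel(1, dispersion_off()), "disabled")
  expect_error(normalize_signal_class("DxMy"), "unknown")
  expect_identical(normalize_signal_class("DpMm"), "D+M-")
})
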