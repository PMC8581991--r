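# Recovery tests run in the near-maximum-likelihood regime: the noise SD
# is supplied (known-SD switch) and shrinkage priors are broadened, with
# the transit-coupling prior datt ~ N(0.5, 0.5) kept, since it encodes the
# generating design att_macro = att - 0.5 and resolves the aBV/att_macro
# height degeneracy of undispersed macrovascular boxcars whose edges fall
# between sampled PLDs.
recovery_priors <- list(cbf = c(60, 100), abv = c(0, 0.1), att = c(1.3, 3))

lab <- labeling_config()

test_that("noiseless self-generated data is recovered by every model variant", {
  st <- asl_state(cbf = 60, att = 1.4, abv = 0.01, att_macro = 0.9)
  truth <- c(cbf = 60, att = 1.4, abv = 0.01, att_macro = 0.9,
             s = s0_ref, p = 0.17)
  for (pn in c("ref-multi", "cbf-att-opt", "cbf-opt")) {
    prot <- builtin_protocol(pn)
    sdp <- noise_sd_for_protocol(prot)
    for (v in c("gkm", "gkm+mvc", "gkm+disp", "gkm+disp+mvc")) {
      disp <- if (grepl("disp", v)) dispersion_spec() else dispersion_off()
      y <- total_signal(protocol_times(prot), st, lab, disp,
                        include_mvc = grepl("mvc", v))
      ff <- fit(y, prot, model_spec(v, known_sd = sdp,
                                    priors = recovery_priors),
                uncertainty = FALSE)
      expect_true(ff$converged, info = paste(pn, v))
      est <- ff$estimates[intersect(names(ff$estimates), names(truth))]
      rel <- abs(est - truth[names(est)]) / truth[names(est)]
      expect_lt(max(rel), 0.005, label = paste(pn, v, "max rel error"))
    }
  }
})

test_that("random admissible truths are recovered when priors center on them", {
  set.seed(202)
  prot <- builtin_protocol("cbf-opt")
  sdp <- noise_sd_for_protocol(prot)
  for (v in c("gkm", "gkm+mvc", "gkm+disp", "gkm+disp+mvc")) {
    for (i in 1:5) {
      st <- draw_state()
      sv <- stats::runif(1, s0_ref / 4, s0_ref)
      pv <- stats::runif(1, 0.12, 0.22)
      disp <- if (grepl("disp", v)) dispersion_spec(s = sv, p = pv)
              else dispersion_off()
      y <- total_signal(protocol_times(prot), st, lab, disp,
                        include_mvc = grepl("mvc", v))
      pri <- list(cbf = c(st$cbf, 30), att = c(st$att, 3),
                  abv = c(st$abv, 0.1), s = c(sv, s0_ref), p = c(pv, 0.1))
      ff <- fit(y, prot, model_spec(v, known_sd = sdp, priors = pri),
                uncertainty = FALSE)
      truth <- c(cbf = st$cbf, att = st$att, abv = st$abv,
                 att_macro = st$att - 0.5, s = sv, p = pv)
      est <- ff$estimates[intersect(names(ff$estimates), names(truth))]
      rel <- abs(est - truth[names(est)]) / truth[names(est)]
      expect_lt(max(rel), 0.005, label = paste(v, "draw", i))
    }
  }
})

test_that("uncorrected macrovascular contamination inflates CBF and deflates ATT", {
  prot <- builtin_protocol("cbf-opt")
  st <- asl_state(cbf = 60, att = 1.4, abv = 0.01, att_macro = 0.9)
  y <- total_signal(protocol_times(prot), st, lab, include_mvc = TRUE)
  fg <- fit(y, prot, model_spec("gkm"), uncertainty = FALSE)
  expect_gt(fg$estimates[["cbf"]], 60)
  expect_lt(fg$estimates[["att"]], 1.4)
  # the two-compartment model corrects most of the bias
  fm <- fit(y, prot, model_spec("gkm+mvc",
                                known_sd = noise_sd_for_protocol(prot),
                                priors = recovery_priors),
            uncertainty = FALSE)
  expect_lt(abs(fm$estimates[["cbf"]] - 60), abs(fg$estimates[["cbf"]] - 60))
  expect_lt(abs(fm$estimates[["abv"]] - 0.01) / 0.01,
            abs(fg$estimates[["cbf"]] - 60) / 60)
})

test_that("with the aBV prior massed at zero, gkm+mvc collapses to gkm", {
  prot <- builtin_protocol("cbf-opt")
  st <- asl_state(cbf = 60, att = 1.4, abv = 0)
  sdn <- noise_sd_for_protocol(prot)
  set.seed(7)
  y <- tissue_signal(protocol_times(prot), st, lab)$values + rnorm(34, sd = sdn)
  f1 <- fit(y, prot, model_spec("gkm"), uncertainty = FALSE)
  f2 <- fit(y, prot, model_spec("gkm+mvc",
                                priors = list(abv = c(0, 1e-9))),
            uncertainty = FALSE)
  expect_equal(f2$estimates[["cbf"]], f1$estimates[["cbf"]], tolerance = 1e-3)
  expect_equal(f2$estimates[["att"]], f1$estimates[["att"]], tolerance = 1e-3)
})

test_that("curvature uncertainties are positive and shrink with noise", {
  prot <- builtin_protocol("cbf-opt")
  st <- asl_state(cbf = 60, att = 1.4)
  y <- tissue_signal(protocol_times(prot), st, lab)$values
  f_hi <- fit(y, prot, model_spec("gkm", known_sd = 1e-3))
  f_lo <- fit(y, prot, model_spec("gkm", known_sd = 1e-4))
  expect_true(all(f_hi$sd > 0))
  expect_lt(f_lo$sd[["cbf"]], f_hi$sd[["cbf"]])
})

test_that("single-PLD inversion is exact at the assumed ATT and degrades off it", {
  prot <- builtin_protocol("single-pld")
  tms <- protocol_times(prot)
  y <- tissue_signal(tms, asl_state(cbf = 60, att = 1.25, abv = 0), lab)$values
  f <- fit_single_pld(y, prot, assumed_att = 1.25)
  expect_equal(f$estimates[["cbf"]], 60, tolerance = 1e-7)
  # generation at long ATT: strong underestimation
  y2 <- tissue_signal(tms, asl_state(cbf = 60, att = 3.0, abv = 0), lab)$values
  expect_lt(fit_single_pld(y2, prot)$estimates[["cbf"]], 30)
  # scaling the signal scales CBF nearly proportionally (weak R(f) coupling)
  f2 <- fit_single_pld(2 * y, prot, assumed_att = 1.25)
  expect_equal(f2$estimates[["cbf"]] / 60, 2, tolerance = 0.05)
  # non-positive signal clips to zero with a flag
  f0 <- fit_single_pld(-abs(y), prot)
  expect_equal(f0$estimates[["cbf"]], 0)
  expect_true("clipped_at_zero" %in% f0$flags)
  expect_error(fit_single_pld(y, builtin_protocol("ref-multi")),
               "one distinct PLD")
})

test_that("the single-pld model spec routes through fit()", {
  prot <- builtin_protocol("single-pld")
  y <- tissue_signal(protocol_times(prot),
                     asl_state(cbf = 45, att = 1.25, abv = 0), lab)$values
  f <- fit(y, prot, model_spec("single-pld"))
  expect_equal(f$estimates[["cbf"]], 45, tolerance = 1e-6)
})

test_that("ensemble fitting is stateless: order-independent and repeat-stable", {
  prot <- builtin_protocol("ref-multi")
  g <- condition_grid("abv", abvs = c(0.002, 0.01), repeats = 3, seed = 5)
  ens <- simulate_ensemble(prot, g, "D-M+")
  ft <- fit_ensemble(ens, prot, model_spec("gkm"))
  expect_equal(nrow(ft), 6L)
  # shuffled rows give identical per-repeat results
  set.seed(1)
  shuf <- ens[sample(nrow(ens)), ]
  ft2 <- fit_ensemble(shuf, prot, model_spec("gkm"))
  expect_equal(ft2, ft)
  # identical noiseless repeats give identical fits
  g0 <- condition_grid("abv", abvs = 0.005, repeats = 1, seed = 5)
  e0 <- simulate_ensemble(prot, g0, "D-M+", noiseless = TRUE)
  e0 <- do.call(rbind, lapply(1:4, function(r) transform(e0, rep = r)))
  f0 <- fit_ensemble(e0, prot, model_spec("gkm"))
  expect_equal(length(unique(f0$cbf_est)), 1L)
  # empty ensemble gives an empty table
  expect_equal(nrow(fit_ensemble(ens[0, ], prot, model_spec("gkm"))), 0L)
})

test_that("fit input validation catches mismatched signals", {
  prot <- builtin_protocol("ref-multi")
  expect_error(fit(1:3, prot), "does not match")
  expect_error(fit_ensemble(data.frame(att = 1), prot), "missing columns")
  bad <- simulate_ensemble(builtin_protocol("ref-multi"),
                           condition_grid("abv", abvs = 0.005, repeats = 1,
                                          seed = 1), "D-M+")[-1, ]
  expect_error(fit_ensemble(bad, prot), "exactly one value per")
})
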