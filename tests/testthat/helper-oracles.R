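# Independent quadrature oracles for the closed-form kinetic model, plus
# shared fixtures.  The oracles only use the piecewise delivery function,
# dgamma and adaptive quadrature -- none of the package's closed-form
# incomplete-gamma machinery.

s0_ref <- 1 / 0.13

table2_state <- function(abv = 0.002)
  asl_state(cbf = 60, att = 1.4, abv = abv, att_macro = 0.9)

# tissue signal by adaptive quadrature of c'(u) * exp(-R (t - u)).
# Integration intervals are split at the bolus-window breakpoints so the
# quadrature only ever sees smooth integrands.
quad_tissue <- function(t, state, label = labeling_config(),
                        disp = dispersion_off()) {
  R <- 1 / state$t1t + state$f / state$lam
  lo <- state$att
  hi <- state$att + label$tau
  cprime <- if (!disp$enabled) {
    function(u) delivery_function(u, state, label)
  } else {
    a <- 1 + disp$s * disp$p
    plateau <- label$alpha * exp(-state$att / state$t1b)
    # c'(u) = plateau * integral of the kernel over w in (u - hi, u - lo)
    function(u) {
      vapply(u, function(ui) {
        w1 <- max(ui - hi, 0)
        w2 <- max(ui - lo, 0)
        if (w2 <= w1) return(0)
        plateau * stats::integrate(function(w)
          stats::dgamma(w, shape = a, rate = disp$s),
          w1, w2, rel.tol = 1e-11, subdivisions = 500L)$value
      }, numeric(1))
    }
  }
  vapply(t, function(ti) {
    if (ti <= 0) return(0)
    cuts <- sort(unique(c(0, pmin(pmax(c(lo, hi), 0), ti), ti)))
    segs <- vapply(seq_len(length(cuts) - 1L), function(k)
      stats::integrate(function(u) cprime(u) * exp(-R * (ti - u)),
                       cuts[k], cuts[k + 1L], rel.tol = 1e-10,
                       subdivisions = 500L)$value, numeric(1))
    2 * label$m0b * state$f * sum(segs)
  }, numeric(1))
}

# macrovascular signal by quadrature of the dispersed boxcar
quad_macro <- function(t, state, label = labeling_config(),
                       disp = dispersion_off()) {
  height <- 2 * label$alpha * label$m0b *
    exp(-state$att_macro / state$t1b) * state$abv
  if (!disp$enabled) {
    return(height * (t > state$att_macro & t <= state$att_macro + label$tau))
  }
  a <- 1 + disp$s * disp$p
  vapply(t, function(ti) {
    w1 <- max(ti - state$att_macro - label$tau, 0)
    w2 <- max(ti - state$att_macro, 0)
    if (w2 <= w1) return(0)
    height * stats::integrate(function(w)
      stats::dgamma(w, shape = a, rate = disp$s),
      w1, w2, rel.tol = 1e-11, subdivisions = 500L)$value
  }, numeric(1))
}

# random admissible physiological draws for property suites
draw_state <- function() {
  att <- stats::runif(1, 0.8, 1.8)
  asl_state(cbf = stats::runif(1, 40, 80), att = att,
            abv = stats::runif(1, 0.003, 0.02), att_macro = att - 0.5)
}
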