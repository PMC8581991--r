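# Monte-Carlo signal generator: noisy pCASL difference-signal ensembles
# over grids of ATT, aBV and dispersion sharpness, with reproducible
# per-condition random streams.

#' Gaussian noise model anchored to a reference condition
#'
#' Noise is white Gaussian with a standard deviation tied to the maximum
#' noiseless signal a protocol samples in a typical condition
#' (ATT = 1.4 s, aBV = 0.2%, macrovascular component included, no
#' dispersion): `sd_noise = max sampled signal / snr`.  Noise is applied
#' per acquisition; averaging the `averages` repeats of a PLD leaves an
#' effective per-PLD SD of `sd_noise / sqrt(averages)`.
#'
#' @param snr Signal-to-noise ratio at the reference condition; default
#'   9.37, representative of a common 2D acquisition.
#' @param reference State describing the reference condition (an
#'   [asl_state()]).
#' @return An object of class `asl_noise`.
#' @export
noise_model <- function(snr = 9.37,
                        reference = asl_state(cbf = 60, att = 1.4,
                                              abv = 0.002, att_macro = 0.9)) {
  stopifnot(is.numeric(snr), snr > 0)
  structure(list(snr = snr, reference = reference), class = "asl_noise")
}

#' Per-acquisition noise SD for a protocol
#'
#' Evaluates the noiseless total signal (tissue + macrovascular, no
#' dispersion) at the protocol's own sample times under the noise model's
#' reference condition, takes the maximum, and divides by the SNR.
#'
#' @param protocol An [asl_protocol()].
#' @param noise An [noise_model()].
#' @param label A [labeling_config()].
#' @return Noise SD in units of M0B (per acquisition, before averaging).
#' @export
noise_sd_for_protocol <- function(protocol, noise = noise_model(),
                                  label = labeling_config()) {
  stopifnot(inherits(protocol, "asl_protocol"))
  sig <- total_signal(protocol_times(protocol), noise$reference, label,
                      dispersion_off(), include_mvc = TRUE)
  smax <- max(sig$values)
  if (smax <= 0)
    stop("protocol samples no signal at the reference condition; ",
         "noise SD would be zero", call. = FALSE)
  smax / noise$snr
}

#' Condition grid for a simulation sweep
#'
#' Describes which parameter is swept and which are held fixed.  Defaults
#' follow the simulation design of the study: ATT swept 0.5-3.0 s in
#' 0.05 s steps with aBV fixed at 0.2%, or aBV swept 0-2% in 0.05% steps
#' with ATT fixed at 1.4 s; the macrovascular transit time is always
#' coupled as `att_macro = att - 0.5` (floored at 0); 2000 Monte-Carlo
#' repeats per condition.  Dispersion sharpness values enter only for
#' D+ signal classes.
#'
#' @param vary `"att"` or `"abv"`: the swept parameter.
#' @param atts ATT values, s.
#' @param abvs aBV fractions.
#' @param s_values Dispersion sharpness values (s^-1) for dispersed
#'   classes; `NULL` for no dispersion.
#' @param p Dispersion time-to-peak, s.
#' @param cbf Ground-truth CBF, ml/100 g/min.
#' @param repeats Monte-Carlo repeats per condition.
#' @param seed Root random seed (integer).
#' @return An object of class `asl_grid`: a list with a `conditions`
#'   data frame (columns `att`, `abv`, `s`) plus `repeats`, `seed`, `cbf`,
#'   `p`.
#' @examples
#' g <- condition_grid("abv", repeats = 100, seed = 1)
#' nrow(g$conditions)  # 41 aBV values
#' @export
condition_grid <- function(vary = c("att", "abv"),
                           atts = NULL, abvs = NULL,
                           s_values = NULL, p = 0.17,
                           cbf = 60, repeats = 2000L, seed = 1L) {
  vary <- match.arg(vary)
  if (is.null(atts))
    atts <- if (vary == "att") seq(0.5, 3.0, by = 0.05) else 1.4
  if (is.null(abvs))
    abvs <- if (vary == "abv") seq(0, 0.02, by = 0.0005) else 0.002
  repeats <- as.integer(repeats)
  if (is.na(repeats) || repeats < 1L)
    stop("`repeats` must be a positive integer", call. = FALSE)
  seed <- as.integer(seed)
  if (is.na(seed)) stop("`seed` must be an integer", call. = FALSE)
  s_grid <- if (is.null(s_values)) NA_real_ else as.numeric(s_values)
  conditions <- expand.grid(att = atts, abv = abvs, s = s_grid,
                            KEEP.OUT.ATTRS = FALSE)
  structure(list(vary = vary, conditions = conditions, p = p, cbf = cbf,
                 repeats = repeats, seed = seed),
            class = "asl_grid")
}

# Deterministic per-condition child seed: a fixed LCG-style mix of the
# root seed and the 1-based condition index, kept inside 32-bit range so
# subsets of the grid reproduce in isolation.
.child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 214748357) %% 2147483647)
}

#' Simulate a noisy signal ensemble over a condition grid
#'
#' For every condition (row of `grid$conditions`) and repeat, Gaussian
#' noise of SD [noise_sd_for_protocol()] is added to each acquisition and
#' the protocol's averages are averaged per PLD, giving an effective
#' per-PLD SD of `sd_noise / sqrt(averages)`.  Conditions use independent
#' child random streams derived from the root seed, so identical seeds
#' reproduce identical ensembles and any subset of conditions is
#' reproducible in isolation.
#'
#' @param protocol An [asl_protocol()].
#' @param grid An [condition_grid()].
#' @param signal_class One of `"D-M-"`, `"D-M+"`, `"D+M-"`, `"D+M+"` (or
#'   the aliases `"DmMm"`, ...).  M- classes force aBV to 0; an aBV sweep
#'   therefore requires an M+ class.  D+ classes require `s` values in the
#'   grid.
#' @param noise An [noise_model()]; `noiseless = TRUE` skips noise
#'   entirely (repeats collapse to one).
#' @param label A [labeling_config()].
#' @param noiseless Logical, generate noise-free curves only.
#' @return A tidy data frame with columns `protocol`, `signal_class`,
#'   `att`, `abv`, `s`, `rep`, `pld`, `value`.  `value` is the per-PLD
#'   averaged signal in units of M0B.
#' @export
simulate_ensemble <- function(protocol, grid, signal_class,
                              noise = noise_model(),
                              label = labeling_config(),
                              noiseless = FALSE) {
  stopifnot(inherits(protocol, "asl_protocol"), inherits(grid, "asl_grid"))
  flags <- signal_class_flags(signal_class)
  cls <- normalize_signal_class(signal_class)
  conds <- grid$conditions
  if (flags$disp && anyNA(conds$s))
    stop("signal class ", cls, " needs dispersion sharpness values in the grid",
         call. = FALSE)
  if (!flags$mvc && grid$vary == "abv" && length(unique(conds$abv)) > 1L)
    stop("an aBV sweep requires a macrovascular (M+) signal class",
         call. = FALSE)
  times <- protocol_times(protocol)
  sd_eff <- if (noiseless) 0 else
    noise_sd_for_protocol(protocol, noise, label) / sqrt(protocol$averages)
  repeats <- if (noiseless) 1L else grid$repeats
  nt <- length(times)

  out <- vector("list", nrow(conds))
  for (i in seq_len(nrow(conds))) {
    att <- conds$att[i]
    abv <- if (flags$mvc) conds$abv[i] else 0
    st <- asl_state(cbf = grid$cbf, att = att, abv = abv,
                    att_macro = max(att - 0.5, 0))
    disp <- if (flags$disp) dispersion_spec(s = conds$s[i], p = grid$p)
            else dispersion_off()
    mu <- total_signal(times, st, label, disp, include_mvc = flags$mvc)$values
    if (sd_eff > 0) {
      set.seed(.child_seed(grid$seed, i))
      vals <- mu + stats::rnorm(nt * repeats, sd = sd_eff)
    } else {
      vals <- rep(mu, repeats)
    }
    out[[i]] <- data.frame(
      protocol = protocol$name, signal_class = cls,
      att = att, abv = conds$abv[i], s = conds$s[i],
      rep = rep(seq_len(repeats), each = nt),
      pld = rep(protocol$plds, repeats),
      value = vals)
  }
  do.call(rbind, out)
}

#' Write / read a simulated ensemble as CSV
#'
#' @param ensemble A data frame from [simulate_ensemble()].
#' @param path Output file; `.gz` suffix enables compression via R's
#'   built-in gzfile connection.
#' @return `write_ensemble()` returns `path` invisibly;
#'   `read_ensemble()` returns the data frame.
#' @export
write_ensemble <- function(ensemble, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.csv(ensemble, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
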