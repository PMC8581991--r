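# Canonical 2D-readout PLD schedules and a YAML loader for user-defined
# protocols.  The four builtin schedules were designed for an ATT range of
# 0.5-1.8 s: a consensus-style single-PLD protocol, an evenly spaced
# reference multi-PLD protocol, and two optimized schedules (one for joint
# CBF+ATT accuracy, one for CBF accuracy alone).  All protocols use equal
# total scan time: 33, 42, 40 and 34 label-control acquisitions.

.builtin_plds <- list(
  "single-pld" = 1.8,
  "ref-multi" = c(0.25, 0.5, 0.75, 1, 1.25, 1.5),
  "cbf-att-opt" = c(0.2, 0.2, 0.225, 0.3, 0.375, 0.45, 0.5, 0.55, 0.6, 0.6,
                    0.625, 0.625, 0.65, 0.65, 0.675, 0.675, 0.7, 0.7, 0.7,
                    0.7, 1.25, 1.275, 1.3, 1.35, 1.375, 1.4, 1.425, 1.425,
                    1.475, 1.5, 1.675, 1.75, 1.8, 1.825, 1.85, 1.875, 1.9,
                    1.925, 1.95, 1.975),
  # 34 delays; heavy sampling of the late (post-bolus) window with
  # increasing multiplicity towards the longest delay
  "cbf-opt" = c(0.2, 0.7, 0.825, 1, 1.125, 1.25, 1.325, 1.4, 1.475, 1.55,
                1.625, 1.675, 1.7, 1.725, 1.75, 1.775, 1.8, 1.825, 1.85,
                1.85, 1.875, 1.9, 1.925, 1.925, 1.95, 1.975, 1.975, 2,
                2.025, 2.025, 2.05, 2.075, 2.075, 2.075)
)
.builtin_averages <- c("single-pld" = 33L, "ref-multi" = 7L,
                       "cbf-att-opt" = 1L, "cbf-opt" = 1L)

#' Construct a PLD sampling protocol
#'
#' @param name Protocol identifier.
#' @param plds Ordered (nondecreasing) vector of post-labeling delays, s.
#'   Repeated values are genuine repeated acquisitions.
#' @param averages Number of label-control averages acquired at every PLD
#'   (uniform across the schedule).
#' @param tau Label duration, s.
#' @return An object of class `asl_protocol`.
#' @export
asl_protocol <- function(name, plds, averages = 1L, tau = 1.4) {
  plds <- as.numeric(plds)
  if (length(plds) < 1L)
    stop("protocol must contain at least one PLD", call. = FALSE)
  if (any(diff(plds) < 0))
    stop("PLDs must be nondecreasing", call. = FALSE)
  if (any(plds < 0)) stop("PLDs must be nonnegative", call. = FALSE)
  averages <- as.integer(averages)
  if (length(averages) != 1L || is.na(averages) || averages < 1L)
    stop("`averages` must be a single integer >= 1", call. = FALSE)
  stopifnot(tau > 0)
  structure(list(name = as.character(name), plds = plds,
                 averages = averages, tau = tau),
            class = "asl_protocol")
}

#' @export
print.asl_protocol <- function(x, ...) {
  cat("<asl_protocol> ", x$name, ": ", length(x$plds), " PLDs x ",
      x$averages, " averages (tau = ", x$tau, " s)\n", sep = "")
  cat("  PLDs: ", paste(format(x$plds, trim = TRUE), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Total number of label-control acquisitions in a protocol
#' @param protocol An [asl_protocol()].
#' @return Integer count `length(plds) * averages`.
#' @export
n_acquisitions <- function(protocol) {
  length(protocol$plds) * protocol$averages
}

#' Model sample times of a protocol
#'
#' Maps each PLD to model time `tau + PLD` (time since start of labeling),
#' the standard pCASL readout convention.
#'
#' @param protocol An [asl_protocol()].
#' @return Numeric vector of sample times, s.
#' @export
protocol_times <- function(protocol) protocol$tau + protocol$plds

#' Builtin 2D-readout protocols
#'
#' Returns one of the four canonical equal-scan-time schedules:
#' `"single-pld"` (PLD 1.8 s, 33 averages), `"ref-multi"` (6 evenly spaced
#' PLDs, 7 averages), `"cbf-att-opt"` (40 PLDs optimized for joint CBF and
#' ATT estimation) or `"cbf-opt"` (34 PLDs optimized for CBF only).
#'
#' @param name One of `"single-pld"`, `"ref-multi"`, `"cbf-att-opt"`,
#'   `"cbf-opt"`.
#' @return An [asl_protocol()].
#' @examples
#' builtin_protocol("cbf-opt")
#' @export
builtin_protocol <- function(name = c("single-pld", "ref-multi",
                                      "cbf-att-opt", "cbf-opt")) {
  name <- match.arg(name)
  asl_protocol(name, .builtin_plds[[name]], .builtin_averages[[name]])
}

#' Load / write a protocol definition file
#'
#' Protocol files are plain-text YAML with keys `name`, `tau`, `plds`
#' and `averages`, e.g.
#' \preformatted{
#' name: my-protocol
#' tau: 1.4
#' averages: 3
#' plds: [0.5, 1.0, 1.5, 2.0]
#' }
#'
#' @param path File path.
#' @return `load_protocol()` returns an [asl_protocol()];
#'   `write_protocol()` returns `path` invisibly.
#' @export
load_protocol <- function(path) {
  if (!file.exists(path)) stop("no such protocol file: ", path, call. = FALSE)
  spec <- tryCatch(yaml::read_yaml(path),
                   error = function(e) stop("cannot parse protocol file '",
                                            path, "': ", conditionMessage(e),
                                            call. = FALSE))
  for (key in c("name", "plds")) {
    if (is.null(spec[[key]]))
      stop("protocol file '", path, "' is missing key '", key, "'",
           call. = FALSE)
  }
  if (length(spec$plds) < 1L)
    stop("protocol file '", path, "' has an empty PLD list", call. = FALSE)
  tryCatch(
    asl_protocol(spec$name, spec$plds,
                 averages = spec$averages %||% 1L,
                 tau = spec$tau %||% 1.4),
    error = function(e) stop("invalid protocol in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
}

#' @rdname load_protocol
#' @param protocol An [asl_protocol()] to serialize.
#' @export
write_protocol <- function(protocol, path) {
  stopifnot(inherits(protocol, "asl_protocol"))
  yaml::write_yaml(list(name = protocol$name, tau = protocol$tau,
                        averages = protocol$averages,
                        plds = as.list(protocol$plds)),
                   path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
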