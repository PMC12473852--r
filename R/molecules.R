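#' Specification of one signaling compound
#'
#' One stress-specific volatile compound of the modulation alphabet: its
#' diffusion coefficient, detection threshold at the receiver, per-slot
#' transmit probability, and the stress label it encodes. Within a
#' [stress_alphabet()] the compound names and stress labels are unique, so
#' the stress-to-compound mapping is one-to-one.
#'
#' @param name Compound label, e.g. `"MeJA"` (methyl jasmonate, the pest
#'   stress marker) or `"ethanol"` (the heat stress marker).
#' @param D Diffusion coefficient in air (m^2/s), > 0.
#' @param threshold Detection threshold on absorbed mass, > 0 (same units
#'   as the absorbed masses it is compared against).
#' @param p Per-slot transmit probability, in `[0, 1]`; default 0.5.
#' @param stress Stress label encoded by this compound.
#' @return An object of class `"molecule_spec"`.
#' @examples
#' molecule_spec("MeJA", D = 0.007, threshold = 2e-4, stress = "pest")
#' @export
molecule_spec <- function(name, D, threshold, p = 0.5, stress = name) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_cfg("`name` must be a non-empty string")
  }
  check_scalar(D, "D", lower = 0, allow_lower = FALSE)
  check_scalar(threshold, "threshold", lower = 0, allow_lower = FALSE)
  check_scalar(p, "p", lower = 0, upper = 1)
  if (!is.character(stress) || length(stress) != 1L || !nzchar(stress)) {
    stop_cfg("`stress` must be a non-empty string")
  }
  structure(list(name = name, D = D, threshold = threshold, p = p,
                 stress = stress),
            class = "molecule_spec")
}

#' Stress-to-compound modulation alphabet
#'
#' An ordered collection of [molecule_spec()]s with unique compound names
#' and unique stress labels, defining the one-to-one mapping used for
#' modulation at the transmitter and threshold demodulation at the receiver.
#'
#' @param ... [molecule_spec()] objects (or a single list of them).
#' @return An object of class `"stress_alphabet"` (a named list of
#'   molecule specs, named by compound).
#' @export
stress_alphabet <- function(...) {
  mols <- list(...)
  if (length(mols) == 1L && !inherits(mols[[1L]], "molecule_spec")) {
    mols <- mols[[1L]]
  }
  if (!length(mols) ||
      !all(vapply(mols, inherits, logical(1), "molecule_spec"))) {
    stop_cfg("supply one or more `molecule_spec` objects")
  }
  nms <- vapply(mols, `[[`, character(1), "name")
  stresses <- vapply(mols, `[[`, character(1), "stress")
  if (anyDuplicated(nms)) stop_cfg("compound names must be unique")
  if (anyDuplicated(stresses)) stop_cfg("stress labels must be unique")
  names(mols) <- nms
  structure(mols, class = "stress_alphabet")
}

#' @export
print.stress_alphabet <- function(x, ...) {
  cat(sprintf("<stress_alphabet> %d compound(s)\n", length(x)))
  for (m in x) {
    cat(sprintf("  %s -> %s: D = %g m^2/s, threshold = %g, p = %g\n",
                m$stress, m$name, m$D, m$threshold, m$p))
  }
  invisible(x)
}

#' Thresholds of an alphabet as a named vector
#'
#' @param alphabet A [stress_alphabet()].
#' @return Named numeric vector of detection thresholds.
#' @export
alphabet_thresholds <- function(alphabet) {
  if (!inherits(alphabet, "stress_alphabet")) {
    stop_cfg("expected a `stress_alphabet`")
  }
  vapply(alphabet, `[[`, numeric(1), "threshold")
}

#' Replace the thresholds of an alphabet
#'
#' @param alphabet A [stress_alphabet()].
#' @param thresholds Named numeric vector (names are compound names).
#' @return The alphabet with updated thresholds.
#' @export
set_thresholds <- function(alphabet, thresholds) {
  if (!inherits(alphabet, "stress_alphabet")) {
    stop_cfg("expected a `stress_alphabet`")
  }
  bad <- setdiff(names(thresholds), names(alphabet))
  if (length(bad)) stop_cfg("unknown compound(s): %s", paste(bad, collapse = ", "))
  for (nm in names(thresholds)) {
    check_scalar(thresholds[[nm]], nm, lower = 0, allow_lower = FALSE)
    alphabet[[nm]]$threshold <- thresholds[[nm]]
  }
  alphabet
}

#' Two-compound reference alphabet
#'
#' The alphabet used in the package's detection examples: methyl jasmonate
#' (pest stress, D = 0.007 m^2/s) and ethanol (heat stress,
#' D = 0.009 m^2/s), with equal per-slot transmit probability 0.5.
#' Thresholds default to placeholders of 1 unit and are normally replaced by
#' [optimal_thresholds()] for the configuration under study.
#'
#' @param thresholds Optional named numeric vector of thresholds.
#' @return A [stress_alphabet()] with compounds `"MeJA"` and `"ethanol"`.
#' @export
default_alphabet <- function(thresholds = NULL) {
  ab <- stress_alphabet(
    molecule_spec("MeJA", D = 0.007, threshold = 1, stress = "pest"),
    molecule_spec("ethanol", D = 0.009, threshold = 1, stress = "heat")
  )
  if (!is.null(thresholds)) ab <- set_thresholds(ab, thresholds)
  ab
}
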