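# Model parameters for the reduced four-variable ventricular AP model.
#
# All parameters follow the 1991 Luo-Rudy (LR-I) formulation except the
# maximal ICa-L conductance (raised to 0.112 mS/cm^2 so that window-region
# manipulations can elicit EADs) and the Ca2+ reversal potential, which is a
# fixed constant here because the intracellular Ca2+ variable of LR-I is
# dropped. Units: ms, mV, uA/cm^2, mS/cm^2, uF/cm^2, mM.

# Physical constants for the K+ Nernst potentials (LR-I values)
.RTF  <- 8.314472 * 310.15 / 96.4853415  # mV at 37 C
.Ki   <- 145   # mM intracellular K+
.Nao  <- 140   # mM extracellular Na+
.Nai  <- 18    # mM intracellular Na+
.PRNaK <- 0.01833  # Na/K permeability ratio in the IK Nernst potential
.gK_ref  <- 0.282   # mS/cm^2 at [K+]o = 5.4 mM
.gK1_ref <- 0.6047  # mS/cm^2 at [K+]o = 5.4 mM
.Ko_ref  <- 5.4     # mM reference extracellular K+

.param_names <- c("Cm", "gCa", "gK", "gK1", "gKp", "gb", "VCa", "VK", "VK1",
                  "Vb", "Ko", "dV_d", "dV_f", "alpha", "beta", "f_pedestal",
                  "stim_amp", "stim_dur", "stim_onset", "stim_smooth")

.nernst_VK  <- function(Ko) .RTF * log((Ko + .PRNaK * .Nao) / (.Ki + .PRNaK * .Nai))
.nernst_VK1 <- function(Ko) .RTF * log(Ko / .Ki)

#' Construct a model parameter set
#'
#' Returns the full parameter set of the reduced Luo-Rudy I action potential
#' model, with any field overridden by name. The K+-sensitive fields
#' (\code{gK}, \code{gK1}, \code{VK}, \code{VK1}) default to their values at
#' the supplied \code{Ko}; overriding \code{Ko} recomputes them unless they
#' are also overridden explicitly.
#'
#' @param ... named overrides of parameter fields. Recognised names:
#'   \code{Cm} (membrane capacitance, uF/cm^2), \code{gCa} (maximal ICa-L
#'   conductance, mS/cm^2), \code{gK}, \code{gK1}, \code{gKp}, \code{gb}
#'   (maximal conductances, mS/cm^2), \code{VCa}, \code{VK}, \code{VK1},
#'   \code{Vb} (reversal potentials, mV), \code{Ko} (extracellular K+, mM),
#'   \code{dV_d}, \code{dV_f} (half-activation/inactivation shifts of the
#'   ICa-L steady-state curves, mV), \code{alpha}, \code{beta} (scalings of
#'   tau_d and tau_f), \code{f_pedestal} (inactivation floor in [0,1)),
#'   \code{stim_amp} (uA/cm^2), \code{stim_dur}, \code{stim_onset},
#'   \code{stim_smooth} (ms).
#' @return an object of class \code{ead_params}: a named list of numeric
#'   scalars.
#' @examples
#' p <- ead_params()                   # default AP-producing cell
#' p2 <- ead_params(dV_d = -2.08, dV_f = 2.08)  # symmetric window broadening
#' @export
ead_params <- function(...) {
  over <- list(...)
  if (length(over) && (is.null(names(over)) || any(names(over) == "")))
    stop("all overrides must be named")
  bad <- setdiff(names(over), .param_names)
  if (length(bad))
    stop("unknown parameter field(s): ", paste(bad, collapse = ", "))
  Ko <- if (!is.null(over$Ko)) over$Ko else .Ko_ref
  if (!is.finite(Ko) || Ko <= 0) stop("Ko must be positive")
  p <- list(
    Cm = 1, gCa = 0.112,
    gK  = .gK_ref  * sqrt(Ko / .Ko_ref),
    gK1 = .gK1_ref * sqrt(Ko / .Ko_ref),
    gKp = 0.0183, gb = 0.03921,
    VCa = 80, VK = .nernst_VK(Ko), VK1 = .nernst_VK1(Ko),
    Vb = -59.87, Ko = Ko,
    dV_d = 0, dV_f = 0, alpha = 1, beta = 1, f_pedestal = 0,
    stim_amp = 70, stim_dur = 2, stim_onset = 20, stim_smooth = 0.1
  )
  for (nm in names(over)) p[[nm]] <- over[[nm]]
  p <- lapply(p, as.numeric)
  class(p) <- "ead_params"
  validate_params(p)
  p
}

validate_params <- function(p) {
  stopifnot(inherits(p, "ead_params"))
  num1 <- function(v) is.numeric(v) && length(v) == 1 && is.finite(v)
  for (nm in .param_names)
    if (!num1(p[[nm]])) stop("parameter ", nm, " must be a finite scalar")
  if (p$Cm <= 0) stop("Cm must be positive")
  for (nm in c("gCa", "gK", "gK1", "gKp", "gb"))
    if (p[[nm]] < 0) stop(nm, " must be non-negative")
  if (p$Ko <= 0) stop("Ko must be positive")
  if (p$alpha <= 0 || p$beta <= 0) stop("alpha and beta must be positive")
  if (p$f_pedestal < 0 || p$f_pedestal >= 1)
    stop("f_pedestal must lie in [0, 1)")
  if (p$stim_dur <= 0) stop("stim_dur must be positive")
  if (p$stim_smooth <= 0) stop("stim_smooth must be positive")
  invisible(p)
}

# flat numeric vector in the fixed order the C++ layer expects
.pvec <- function(p) {
  validate_params(p)
  vapply(.param_names, function(nm) p[[nm]], numeric(1))
}

#' @export
print.ead_params <- function(x, ...) {
  cat("Reduced Luo-Rudy I parameter set\n")
  v <- .pvec(x)
  for (nm in names(v)) cat(sprintf("  %-12s %g\n", nm, v[[nm]]))
  invisible(x)
}

#' Set the extracellular K+ concentration
#'
#' Recomputes the K+-sensitive fields for a new [K+]o: the maximal
#' conductances \code{gK} and \code{gK1} scale as sqrt(Ko/5.4) relative to
#' their reference values and the Nernst potentials \code{VK} and \code{VK1}
#' are recomputed; all other fields are unchanged. Lowering Ko (hypokalemia)
#' therefore weakens the repolarising K+ currents while raising (making less
#' negative) their reversal potentials.
#'
#' @param params an \code{ead_params} object.
#' @param Ko new extracellular K+ concentration (mM, > 0).
#' @return a new \code{ead_params} object.
#' @export
apply_Ko <- function(params, Ko) {
  validate_params(params)
  if (!is.numeric(Ko) || length(Ko) != 1 || !is.finite(Ko) || Ko <= 0)
    stop("Ko must be a positive finite scalar")
  params$Ko <- as.numeric(Ko)
  params$gK  <- .gK_ref  * sqrt(Ko / .Ko_ref)
  params$gK1 <- .gK1_ref * sqrt(Ko / .Ko_ref)
  params$VK  <- .nernst_VK(Ko)
  params$VK1 <- .nernst_VK1(Ko)
  validate_params(params)
  params
}

# named presets encoding the figure markers of the study this model family
# comes from (window-shift ray, asymmetric shifts, hypokalemia, gCa rescue)
.preset_table <- list(
  default       = list(),
  fig3_1.04     = list(dV_d = -1.04, dV_f = 1.04),
  fig3_2.08     = list(dV_d = -2.08, dV_f = 2.08),
  fig3_3.12     = list(dV_d = -3.12, dV_f = 3.12),
  fig7a         = list(dV_d = -1.83, dV_f = 1.83),
  fig7b         = list(dV_d = -2.08, dV_f = 2.08),
  fig7c         = list(dV_d = -2.33, dV_f = 2.33),
  fig9a         = list(dV_d = -3.35, dV_f = 0),
  fig9b         = list(dV_d = -3.6,  dV_f = 0),
  fig9c         = list(dV_d = -3.85, dV_f = 0),
  hypokalemia_b2 = list(Ko = 2.0),
  fig11_red     = list(gCa = 0.18),
  fig11_orange  = list(gCa = 0.18, dV_d = 1, dV_f = -1)
)

#' Named parameter presets
#'
#' @param name preset name; see \code{preset_names()}.
#' @return an \code{ead_params} object.
#' @export
preset_params <- function(name) {
  if (!name %in% names(.preset_table))
    stop("unknown preset '", name, "'; see preset_names()")
  do.call(ead_params, .preset_table[[name]])
}

#' @rdname preset_params
#' @export
preset_names <- function() names(.preset_table)

#' Load a parameter configuration from a JSON file
#'
#' The file holds a flat JSON object of parameter overrides (possibly empty)
#' and, optionally, a \code{"preset"} key naming a base preset to overlay
#' them on. Unknown keys are rejected.
#'
#' @param path path to a JSON file.
#' @return an \code{ead_params} object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  over <- if (nzchar(trimws(txt))) jsonlite::fromJSON(txt) else list()
  if (!is.list(over)) stop("config must be a JSON object")
  base <- list()
  if (!is.null(over$preset)) {
    if (!over$preset %in% names(.preset_table))
      stop("unknown preset '", over$preset, "'")
    base <- .preset_table[[over$preset]]
    over$preset <- NULL
  }
  bad <- setdiff(names(over), .param_names)
  if (length(bad))
    stop("unknown parameter field(s) in config: ", paste(bad, collapse = ", "))
  do.call(ead_params, utils::modifyList(base, over))
}

#' Serialize a parameter set to JSON
#'
#' Round-trips through \code{load_config()} unchanged.
#'
#' @param params an \code{ead_params} object.
#' @param path output file path.
#' @export
save_config <- function(params, path) {
  validate_params(params)
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
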