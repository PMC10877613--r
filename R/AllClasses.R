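#' @import methods
NULL

#' ReactionNetwork: a mass-action chemical reaction network
#'
#' Container for a well-mixed reaction network of DNA strands: a species
#' table (name, strandedness, initial concentration in nM, free-text role)
#' and a reaction table of reversible bimolecular exchanges and irreversible
#' unimolecular decays. Rates are in 1/(nM*s) for bimolecular and 1/s for
#' unimolecular steps. An optional set of named rate "modes" (e.g. blue-light
#' vs ultraviolet irradiation) overrides per-reaction rate constants.
#'
#' @slot species data.frame with columns \code{name}, \code{strandedness}
#'   (\code{"single"} or \code{"double"}), \code{init} (nM, >= 0),
#'   \code{role}.
#' @slot reactions data.frame with columns \code{label}, \code{r1},
#'   \code{r2}, \code{p1}, \code{p2} (species names, \code{NA} when a slot is
#'   unused), \code{kf}, \code{kb}. A degradation has one reactant, no
#'   products and \code{kb = 0}; its products are implicit waste.
#' @slot modeRates named list; each element is a data.frame with columns
#'   \code{label}, \code{kf}, \code{kb} overriding the base rates while that
#'   mode is active.
#'
#' @seealso [reactionNetwork()], [simulateNetwork()], [massActionRHS()]
#' @export
setClass("ReactionNetwork",
  representation(species = "data.frame", reactions = "data.frame",
                 modeRates = "list"),
  prototype(modeRates = list()))

setValidity("ReactionNetwork", function(object) {
  sp <- object@species
  rx <- object@reactions
  msgs <- character(0)
  need <- c("name", "strandedness", "init", "role")
  if (!all(need %in% names(sp)))
    return(paste("species must have columns", paste(need, collapse = ", ")))
  if (anyDuplicated(sp$name)) msgs <- c(msgs, "species names must be unique")
  if (any(sp$init < 0)) msgs <- c(msgs, "initial concentrations must be >= 0")
  if (!all(sp$strandedness %in% c("single", "double")))
    msgs <- c(msgs, "strandedness must be 'single' or 'double'")
  needr <- c("label", "r1", "r2", "p1", "p2", "kf", "kb")
  if (!all(needr %in% names(rx)))
    return(paste("reactions must have columns", paste(needr, collapse = ", ")))
  if (nrow(rx)) {
    if (anyDuplicated(rx$label)) msgs <- c(msgs, "reaction labels must be unique")
    if (any(rx$kf < 0) || any(rx$kb < 0)) msgs <- c(msgs, "rate constants must be >= 0")
    used <- stats::na.omit(unlist(rx[, c("r1", "r2", "p1", "p2")]))
    miss <- setdiff(used, sp$name)
    if (length(miss))
      msgs <- c(msgs, paste("unknown species in reactions:", paste(miss, collapse = ", ")))
    if (any(is.na(rx$r1))) msgs <- c(msgs, "every reaction needs at least one reactant")
    deg <- is.na(rx$p1)
    if (any(deg & (rx$kb != 0 | !is.na(rx$r2))))
      msgs <- c(msgs, "a degradation must be unimolecular and irreversible")
  }
  for (m in object@modeRates) {
    if (!all(c("label", "kf", "kb") %in% names(m)) ||
        !all(m$label %in% rx$label))
      msgs <- c(msgs, "modeRates entries must reference existing reaction labels")
  }
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' DoseSchedule: timed instantaneous input additions
#'
#' Administration of input strands is modeled as instantaneous concentration
#' increments: at each event time the stated amount (nM) is added to the
#' named species and the integrator is restarted.
#'
#' @slot events data.frame with columns \code{time} (s, >= 0),
#'   \code{species}, \code{amount} (nM, > 0), sorted by time.
#' @slot horizon numeric(1), end of simulation in seconds; must exceed the
#'   last event time.
#' @seealso [doseSchedule()], [simulateNetwork()]
#' @export
setClass("DoseSchedule",
  representation(events = "data.frame", horizon = "numeric"))

setValidity("DoseSchedule", function(object) {
  ev <- object@events
  if (!all(c("time", "species", "amount") %in% names(ev)))
    return("events must have columns time, species, amount")
  msgs <- character(0)
  if (nrow(ev)) {
    if (any(ev$time < 0)) msgs <- c(msgs, "event times must be >= 0")
    if (any(ev$amount <= 0)) msgs <- c(msgs, "dose amounts must be > 0")
    if (is.unsorted(ev$time)) msgs <- c(msgs, "events must be sorted by time")
    if (object@horizon <= max(ev$time))
      msgs <- c(msgs, "horizon must exceed the last event time")
  }
  if (length(object@horizon) != 1 || object@horizon <= 0)
    msgs <- c(msgs, "horizon must be a positive scalar")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Trajectory: simulated concentration time courses
#'
#' @slot times numeric, strictly increasing (s).
#' @slot concentrations matrix [time x species] in nM, clipped at 0 for
#'   reporting; column names are the species roster.
#' @slot eventTimes numeric, dose times (markers for window extraction).
#' @seealso [simulateNetwork()], [windowMetrics()]
#' @export
setClass("Trajectory",
  representation(times = "numeric", concentrations = "matrix",
                 eventTimes = "numeric"))

setValidity("Trajectory", function(object) {
  if (length(object@times) != nrow(object@concentrations))
    return("times and concentration rows must match")
  if (is.unsorted(object@times, strictly = TRUE))
    return("times must be strictly increasing")
  if (is.null(colnames(object@concentrations)))
    return("concentration columns must be named by species")
  TRUE
})

#' CircuitParams: parameters of the conditioned-reflex circuit
#'
#' Holds the shared strand-displacement rate constants, the two input
#' degradation rates, the initial concentrations and the per-event dose.
#' Defaults are the estimated operating point: all five displacement
#' reactions at 5.32e-4 1/(nM*s) forward and backward, degradation at
#' 0.01 1/s, gates M1/M2p/S/R2 at 100 nM, R1 at 50 nM, 100 nM doses.
#'
#' @slot kf,kb numeric, forward/backward displacement rates, 1/(nM*s);
#'   length 1 (shared) or 5 (per reaction, in builder order).
#' @slot kd1,kd2 numeric(1), degradation rates of free I1 / I2, 1/s.
#' @slot init named numeric, initial concentrations (nM); unnamed species
#'   default to 0.
#' @slot doseAmount numeric(1), nM added per dosed input per event.
#' @seealso [circuitParams()], [buildTwoInputCircuit()]
#' @export
setClass("CircuitParams",
  representation(kf = "numeric", kb = "numeric", kd1 = "numeric",
                 kd2 = "numeric", init = "numeric", doseAmount = "numeric"))

setValidity("CircuitParams", function(object) {
  msgs <- character(0)
  if (any(c(object@kf, object@kb, object@kd1, object@kd2) < 0))
    msgs <- c(msgs, "rates must be >= 0")
  if (!length(object@kf) %in% c(1L, 5L) || !length(object@kb) %in% c(1L, 5L))
    msgs <- c(msgs, "kf and kb must have length 1 or 5")
  if (any(object@init < 0)) msgs <- c(msgs, "initial concentrations must be >= 0")
  if (is.null(names(object@init)) && length(object@init))
    msgs <- c(msgs, "init must be named")
  if (object@doseAmount < 0) msgs <- c(msgs, "doseAmount must be >= 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' InputPattern: an ordered sequence of F / B / FB input events
#'
#' Tokens name which inputs are dosed at each event: \code{F} the
#' unconditioned ("feed") input I1, \code{B} the neutral ("bell") input I2,
#' \code{FB} both simultaneously. Events are spaced by a fixed interval
#' (default 5 h = 18000 s) with a trailing observation window.
#'
#' @slot tokens character vector over {F, B, FB}.
#' @slot interval numeric(1), seconds between consecutive events.
#' @slot postWindow numeric(1), seconds simulated after the last event.
#' @seealso [parsePattern()], [runPattern()]
#' @export
setClass("InputPattern",
  representation(tokens = "character", interval = "numeric",
                 postWindow = "numeric"))

setValidity("InputPattern", function(object) {
  msgs <- character(0)
  if (!length(object@tokens)) msgs <- c(msgs, "token list must be non-empty")
  if (!all(object@tokens %in% c("F", "B", "FB")))
    msgs <- c(msgs, "tokens must be F, B or FB")
  if (object@interval <= 0) msgs <- c(msgs, "interval must be > 0")
  if (object@postWindow <= 0) msgs <- c(msgs, "postWindow must be > 0")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' MetricsReport: per-event response metrics of a pattern run
#'
#' @slot perEvent data.frame with one row per input event: \code{token},
#'   \code{doseTime} (s), \code{outputPeak} and \code{outputEnd} (nM) of the
#'   output strand O over that event's window.
#' @slot memoryLevels numeric, memory-gate M2 concentration (nM) at the end
#'   of each inter-event window.
#' @slot learningEfficiency numeric(1), percent, or NA when not applicable.
#' @seealso [runPattern()], [learningEfficiency()]
#' @export
setClass("MetricsReport",
  representation(perEvent = "data.frame", memoryLevels = "numeric",
                 learningEfficiency = "numeric"))

setValidity("MetricsReport", function(object) {
  pe <- object@perEvent
  if (!all(c("token", "doseTime", "outputPeak", "outputEnd") %in% names(pe)))
    return("perEvent must have columns token, doseTime, outputPeak, outputEnd")
  if (nrow(pe) && any(pe$outputPeak < 0 | pe$outputEnd < 0))
    return("metrics must be >= 0")
  TRUE
})

#' SeesawParams: rates and loading of the seesaw threshold gate
#'
#' The gate binarizes the circuit output O into Z through a fast
#' thresholding reaction (O absorbed by threshold duplex Tt) and a
#' catalytic amplification pair (gate Tg releases Z, fuel Tf regenerates O).
#' Azobenzene photoswitching is modeled as a second rate mode: under UV the
#' forward (duplex-invading) rates are suppressed by a multiplier so every
#' gate reaction relaxes back toward its initial state.
#'
#' @slot kThresholdF,kThresholdB numeric(1), thresholding rates, 1/(nM*s).
#' @slot kAmplifyF,kAmplifyB numeric(1), amplification rates, 1/(nM*s).
#' @slot uvForwardFactor numeric(1), multiplier applied to forward rates in
#'   UV mode (default 1e-3).
#' @slot init named numeric, gate loadings (default Tt = Tg = Tf = 100 nM).
#' @seealso [seesawParams()], [buildThresholdGate()], [runPhotoswitched()]
#' @export
setClass("SeesawParams",
  representation(kThresholdF = "numeric", kThresholdB = "numeric",
                 kAmplifyF = "numeric", kAmplifyB = "numeric",
                 uvForwardFactor = "numeric", init = "numeric"))

setValidity("SeesawParams", function(object) {
  r <- c(object@kThresholdF, object@kThresholdB, object@kAmplifyF,
         object@kAmplifyB, object@uvForwardFactor)
  if (any(r < 0)) return("rates and multipliers must be >= 0")
  if (any(object@init < 0)) return("initial concentrations must be >= 0")
  TRUE
})

#' IrradiationSchedule: alternating light-mode segments
#'
#' @slot modes character, alternating mode labels (e.g. BL, UV).
#' @slot durations numeric, segment durations in seconds (> 0); the sequence
#'   repeats cyclically to tile any horizon.
#' @seealso [irradiationSchedule()], [runPhotoswitched()]
#' @export
setClass("IrradiationSchedule",
  representation(modes = "character", durations = "numeric"))

setValidity("IrradiationSchedule", function(object) {
  if (length(object@modes) != length(object@durations))
    return("modes and durations must have equal length")
  if (!length(object@modes)) return("schedule must have at least one segment")
  if (any(object@durations <= 0)) return("durations must be > 0")
  TRUE
})
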