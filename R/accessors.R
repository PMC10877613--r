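# Accessors and show methods. Slot access stays internal; user code goes
# through these.

#' Construct a ReactionNetwork
#'
#' @param species data.frame (or list coercible to one) with columns
#'   \code{name}, \code{strandedness}, \code{init}, \code{role}; missing
#'   \code{strandedness}/\code{role} default to \code{"single"} / \code{""}.
#' @param reactions data.frame with columns \code{label}, \code{r1},
#'   \code{r2}, \code{p1}, \code{p2}, \code{kf}, \code{kb}.
#' @param modeRates optional named list of per-mode rate overrides.
#' @return a validated \code{ReactionNetwork}
#' @examples
#' net <- reactionNetwork(
#'   species = data.frame(name = c("A", "B"), init = c(100, 0)),
#'   reactions = data.frame(label = "iso", r1 = "A", r2 = NA, p1 = "B",
#'                          p2 = NA, kf = 0.01, kb = 0.01))
#' speciesNames(net)
#' @export
reactionNetwork <- function(species, reactions, modeRates = list()) {
  species <- as.data.frame(species)
  if (is.null(species$strandedness)) species$strandedness <- "single"
  if (is.null(species$role)) species$role <- ""
  species <- species[, c("name", "strandedness", "init", "role")]
  reactions <- as.data.frame(reactions)
  for (col in c("r1", "r2", "p1", "p2"))
    reactions[[col]] <- as.character(reactions[[col]])
  new("ReactionNetwork", species = species, reactions = reactions,
      modeRates = modeRates)
}

#' Construct a DoseSchedule
#'
#' @param events data.frame with columns \code{time} (s), \code{species},
#'   \code{amount} (nM); rows are sorted by time.
#' @param horizon end of simulation, seconds.
#' @return a validated \code{DoseSchedule}
#' @export
doseSchedule <- function(events, horizon) {
  events <- as.data.frame(events)
  if (nrow(events)) {
    events$species <- as.character(events$species)
    events <- events[order(events$time), , drop = FALSE]
    rownames(events) <- NULL
  }
  new("DoseSchedule", events = events, horizon = as.numeric(horizon))
}

#' @rdname ReactionNetwork-class
#' @export
setMethod("speciesNames", "ReactionNetwork", function(x) x@species$name)

#' @rdname ReactionNetwork-class
#' @export
setMethod("initialConcentrations", "ReactionNetwork", function(x)
  stats::setNames(x@species$init, x@species$name))

#' @rdname ReactionNetwork-class
#' @export
setMethod("reactionTable", "ReactionNetwork", function(x) x@reactions)

#' @rdname ReactionNetwork-class
#' @export
setMethod("stoichiometricMatrix", "ReactionNetwork",
  function(x, includeDegradation = TRUE) {
    N <- compileNetwork(x)$N
    if (!includeDegradation) N <- N[, !is.na(x@reactions$p1), drop = FALSE]
    N
  })

#' @rdname Trajectory-class
#' @export
setMethod("timePoints", "Trajectory", function(x) x@times)

#' @rdname Trajectory-class
#' @export
setMethod("concentrations", "Trajectory", function(x) x@concentrations)

#' @rdname Trajectory-class
#' @export
setMethod("eventMarkers", "Trajectory", function(x) x@eventTimes)

#' @rdname DoseSchedule-class
#' @export
setMethod("doseEvents", "DoseSchedule", function(x) x@events)

#' @rdname DoseSchedule-class
#' @export
setMethod("horizon", "DoseSchedule", function(x) x@horizon)

#' @rdname MetricsReport-class
#' @export
setMethod("perEventMetrics", "MetricsReport", function(x) x@perEvent)

#' @rdname MetricsReport-class
#' @export
setMethod("memoryLevels", "MetricsReport", function(x) x@memoryLevels)

setMethod("show", "ReactionNetwork", function(object) {
  rx <- object@reactions
  deg <- sum(is.na(rx$p1))
  cat("ReactionNetwork with", nrow(object@species), "species and",
      nrow(rx), "reactions\n")
  cat(" ", nrow(rx) - deg, "strand-displacement,", deg, "degradation\n")
  if (length(object@modeRates))
    cat("  rate modes:", paste(names(object@modeRates), collapse = ", "), "\n")
  nz <- object@species[object@species$init > 0, ]
  if (nrow(nz))
    cat("  loaded species:",
        paste(sprintf("%s=%g nM", nz$name, nz$init), collapse = ", "), "\n")
})

setMethod("show", "DoseSchedule", function(object) {
  cat("DoseSchedule:", nrow(object@events), "events, horizon",
      object@horizon, "s\n")
  if (nrow(object@events)) print(utils::head(object@events, 10))
})

setMethod("show", "Trajectory", function(object) {
  cat("Trajectory:", length(object@times), "time points over [",
      min(object@times), ",", max(object@times), "] s;",
      ncol(object@concentrations), "species\n")
  if (length(object@eventTimes))
    cat("  dose events at:", paste(object@eventTimes, collapse = ", "), "s\n")
})

setMethod("show", "CircuitParams", function(object) {
  cat("CircuitParams: kf =", paste(object@kf, collapse = "/"),
      "kb =", paste(object@kb, collapse = "/"), "1/(nM*s); kd =",
      object@kd1, "/", object@kd2, "1/s; dose =", object@doseAmount, "nM\n")
  nz <- object@init[object@init > 0]
  cat("  init:", paste(sprintf("%s=%g", names(nz), nz), collapse = ", "),
      "nM\n")
})

setMethod("show", "InputPattern", function(object) {
  cat("InputPattern:", paste(object@tokens, collapse = "-"),
      sprintf("(interval %g h, post-window %g h)\n",
              object@interval / 3600, object@postWindow / 3600))
})

setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport over", nrow(object@perEvent), "events\n")
  print(object@perEvent)
  cat("M2 at window ends (nM):",
      paste(round(object@memoryLevels, 3), collapse = ", "), "\n")
  if (!is.na(object@learningEfficiency))
    cat("learning efficiency:", round(object@learningEfficiency, 1), "%\n")
})

setMethod("show", "IrradiationSchedule", function(object) {
  cat("IrradiationSchedule:",
      paste(sprintf("%s %g h", object@modes, object@durations / 3600),
            collapse = " -> "), "(repeating)\n")
})
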