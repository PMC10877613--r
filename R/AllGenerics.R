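#' @rdname ReactionNetwork-class
#' @param object,x a \code{ReactionNetwork}, \code{Trajectory} or related
#'   object
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname ReactionNetwork-class
#' @export
setGeneric("initialConcentrations",
           function(x) standardGeneric("initialConcentrations"))

#' @rdname ReactionNetwork-class
#' @export
setGeneric("reactionTable", function(x) standardGeneric("reactionTable"))

#' @rdname ReactionNetwork-class
#' @param includeDegradation logical; keep the irreversible decay columns?
#' @export
setGeneric("stoichiometricMatrix",
           function(x, includeDegradation = TRUE)
             standardGeneric("stoichiometricMatrix"))

#' @rdname Trajectory-class
#' @export
setGeneric("timePoints", function(x) standardGeneric("timePoints"))

#' @rdname Trajectory-class
#' @export
setGeneric("concentrations", function(x) standardGeneric("concentrations"))

#' @rdname Trajectory-class
#' @export
setGeneric("eventMarkers", function(x) standardGeneric("eventMarkers"))

#' @rdname DoseSchedule-class
#' @export
setGeneric("doseEvents", function(x) standardGeneric("doseEvents"))

#' @rdname DoseSchedule-class
#' @export
setGeneric("horizon", function(x) standardGeneric("horizon"))

#' @rdname MetricsReport-class
#' @export
setGeneric("perEventMetrics", function(x) standardGeneric("perEventMetrics"))

#' @rdname MetricsReport-class
#' @export
setGeneric("memoryLevels", function(x) standardGeneric("memoryLevels"))
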