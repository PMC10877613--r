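# The two-input conditioned-reflex circuit: builder, input-pattern parsing
# and the learning / forgetting / synchronization experiments.

.twoInputSpecies <- c("I1", "I2", "Y1", "Y2", "Y2p", "O", "M1", "M2",
                      "M2p", "W1", "W2", "S", "R1", "R2")

#' Parameters of the two-input conditioned-reflex circuit
#'
#' @param kf,kb strand-displacement forward/backward rate constants,
#'   1/(nM*s); a single shared value (default 5.32e-4) or one per reaction.
#' @param kd1,kd2 degradation rates of the free inputs I1 / I2, 1/s.
#' @param init named initial concentrations, nM; unnamed species are 0.
#' @param doseAmount nM of each dosed input per event.
#' @return a [CircuitParams-class]
#' @export
circuitParams <- function(kf = 5.32e-4, kb = 5.32e-4, kd1 = 0.01,
                          kd2 = 0.01,
                          init = c(M1 = 100, M2p = 100, S = 100,
                                   R2 = 100, R1 = 50),
                          doseAmount = 100) {
  new("CircuitParams", kf = kf, kb = kb, kd1 = kd1, kd2 = kd2,
      init = init, doseAmount = doseAmount)
}

#' The high-capacity / fast-turnover parameter variant
#'
#' Gate loadings doubled to 200 nM (R1 kept at 50 nM) and both degradation
#' rates increased tenfold, the setting under which the memory gate steps
#' from about 19 to about 30 nM over three coincident trainings and
#' forgetting is roughly twice as fast.
#'
#' @return a [CircuitParams-class]
#' @export
highCapacityParams <- function() {
  circuitParams(kd1 = 0.1, kd2 = 0.1,
                init = c(M1 = 200, M2p = 200, S = 200, R2 = 200, R1 = 50))
}

#' Build the two-input conditioned-reflex network
#'
#' Fourteen species and seven reactions. The five reversible
#' strand-displacement reactions: I1+M1 <-> Y1+W1 (input 1 excites),
#' Y1+S <-> O+R1 (reservoir releases output), Y2+S <-> O+R2 (run backward,
#' output regenerates the excitation strand Y2), I2+M2 <-> Y2+W2 (run
#' backward, coincidence of Y2 and W2 writes the memory gate M2),
#' I2+M2p <-> Y2p+W2 (pseudomemory absorbs input 2 pre-learning). Two
#' irreversible degradations remove free I1 and I2 and make the circuit
#' renewable; degradation products are implicit waste.
#'
#' @param params a [CircuitParams-class].
#' @return a [ReactionNetwork-class]
#' @examples
#' net <- buildTwoInputCircuit(circuitParams())
#' net
#' @export
buildTwoInputCircuit <- function(params) {
  validObject(params)
  net <- buildNInputCircuit(2L, params)
  stopifnot(identical(speciesNames(net), .twoInputSpecies))
  net
}

#' Parse an input-pattern string
#'
#' Tokens \code{F} (dose I1), \code{B} (dose I2) and \code{FB} (both at the
#' same instant) joined by \code{"-"} or an en dash.
#'
#' @param pattern e.g. \code{"B-FB-B"}.
#' @param interval seconds between consecutive events (default 5 h).
#' @param postWindow seconds simulated after the last event (default 5 h).
#' @return an [InputPattern-class]
#' @examples
#' parsePattern("B-FB-B")
#' @export
parsePattern <- function(pattern, interval = 18000, postWindow = 18000) {
  tokens <- strsplit(pattern, "[-–]")[[1]]
  tokens <- tokens[nzchar(tokens)]
  bad <- setdiff(tokens, c("F", "B", "FB"))
  if (length(bad))
    stop("unknown input token(s): ", paste(unique(bad), collapse = ", "))
  new("InputPattern", tokens = tokens, interval = interval,
      postWindow = postWindow)
}

#' Dose schedule of an input pattern
#'
#' Event k is dosed at (k-1)*interval; F doses I1, B doses I2, FB doses
#' both at the same instant, each at \code{doseAmount} nM.
#'
#' @param pattern an [InputPattern-class] (or a pattern string).
#' @param doseAmount nM per dosed input.
#' @return a [DoseSchedule-class]
#' @export
scheduleFromPattern <- function(pattern, doseAmount = 100) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  tok <- pattern@tokens
  ev <- do.call(rbind, lapply(seq_along(tok), function(k) {
    t <- (k - 1) * pattern@interval
    sp <- switch(tok[k], F = "I1", B = "I2", FB = c("I1", "I2"))
    data.frame(time = t, species = sp, amount = doseAmount)
  }))
  if (doseAmount <= 0) ev <- ev[0, , drop = FALSE]
  doseSchedule(ev, horizon = (length(tok) - 1) * pattern@interval +
                 pattern@postWindow)
}

# Event windows: [t_k, t_{k+1}) with the last window closed at the horizon.
eventWindows <- function(pattern) {
  tok <- pattern@tokens
  starts <- (seq_along(tok) - 1) * pattern@interval
  ends <- c(starts[-1], starts[length(tok)] + pattern@postWindow)
  data.frame(token = tok, start = starts, end = ends)
}

#' Run an input pattern through the circuit
#'
#' Simulates the circuit under the pattern's dose schedule and extracts,
#' per event, the output-strand O peak and end value over the window
#' [event time, next event time), plus the memory-gate M2 concentration at
#' each inter-event boundary (read just before the next dose).
#'
#' @param params a [CircuitParams-class].
#' @param pattern an [InputPattern-class] or pattern string.
#' @param control a [solverControl()] list.
#' @param network optional prebuilt network (defaults to
#'   [buildTwoInputCircuit()]); metrics always read species O and M2.
#' @return list with elements \code{trajectory} ([Trajectory-class]) and
#'   \code{metrics} ([MetricsReport-class])
#' @examples
#' \donttest{
#' res <- runPattern(circuitParams(), "B-F-B")
#' perEventMetrics(res$metrics)
#' }
#' @export
runPattern <- function(params, pattern, control = solverControl(),
                       network = NULL) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  validObject(pattern)
  if (is.null(network)) network <- buildTwoInputCircuit(params)
  sch <- scheduleFromPattern(pattern, params@doseAmount)
  traj <- simulateNetwork(network, sch, control)
  win <- eventWindows(pattern)
  mets <- lapply(seq_len(nrow(win)), function(k)
    windowMetrics(traj, "O", c(win$start[k], win$end[k])))
  perEvent <- data.frame(token = win$token,
                         doseTime = win$start,
                         outputPeak = vapply(mets, `[[`, 0, "peak"),
                         outputEnd = vapply(mets, `[[`, 0, "endValue"))
  m2 <- vapply(seq_len(nrow(win)), function(k)
    windowMetrics(traj, "M2", c(win$start[k], win$end[k]))$endValue, 0)
  report <- new("MetricsReport", perEvent = perEvent, memoryLevels = m2,
                learningEfficiency = NA_real_)
  list(trajectory = traj, metrics = report)
}

#' Learning efficiency
#'
#' Peak of the I2-induced output in the post-learning condition divided by
#' the I1-induced output in the pre-learning condition, as a percentage.
#'
#' @param postPeak post-learning I2-induced output peak, nM.
#' @param prePeak pre-learning I1-induced output peak, nM; must be > 0.
#' @return percent
#' @examples
#' learningEfficiency(3.8, 17.3)  # ~22.0
#' @export
learningEfficiency <- function(postPeak, prePeak) {
  if (!is.finite(prePeak) || prePeak <= 0)
    stop("learning efficiency undefined: pre-learning peak must be > 0")
  100 * postPeak / prePeak
}

#' Forgetting experiment
#'
#' Runs the pattern FB followed by nine B events and returns the ten
#' output-response peaks normalized by the first (FB) peak. With a learned
#' memory gate and no further coincident input, the response decays.
#'
#' @param params a [CircuitParams-class].
#' @param nRepeats number of trailing B events (default 9).
#' @param control a [solverControl()] list.
#' @return numeric vector of normalized peaks, first element 1
#' @export
forgettingExperiment <- function(params, nRepeats = 9,
                                 control = solverControl()) {
  pat <- new("InputPattern", tokens = c("FB", rep("B", nRepeats)),
             interval = 18000, postWindow = 18000)
  res <- runPattern(params, pat, control)
  peaks <- perEventMetrics(res$metrics)$outputPeak
  if (peaks[1] <= 0)
    stop("normalization undefined: first FB event produced no output")
  peaks / peaks[1]
}

#' Synchronization-window experiment
#'
#' Pattern F-B-B where the gap between the first (I1) and second (I2)
#' events is swept; the gap between the second and third events stays at
#' 5 h. Returns the memory-gate level after the second event and the output
#' peak at the third event, both normalized by the simultaneous
#' (zero-interval) case.
#'
#' @param params a [CircuitParams-class].
#' @param intervals seconds between the first and second inputs (0 to 10 h).
#' @param control a [solverControl()] list.
#' @return data.frame with columns \code{interval}, \code{M2}, \code{peak}
#'   (raw nM) and \code{M2norm}, \code{peakNorm}
#' @export
synchronizationExperiment <- function(params,
                                      intervals = seq(0, 36000, by = 3600),
                                      control = solverControl()) {
  stopifnot(all(intervals >= 0), all(intervals <= 36000))
  gap <- 18000
  one <- function(d) {
    ev <- rbind(
      data.frame(time = 0, species = "I1", amount = params@doseAmount),
      data.frame(time = d, species = "I2", amount = params@doseAmount),
      data.frame(time = d + gap, species = "I2", amount = params@doseAmount))
    sch <- doseSchedule(ev, horizon = d + 2 * gap)
    traj <- simulateNetwork(buildTwoInputCircuit(params), sch, control)
    c(M2 = windowMetrics(traj, "M2", c(d, d + gap))$endValue,
      peak = windowMetrics(traj, "O", c(d + gap, d + 2 * gap))$peak)
  }
  base <- one(0)
  res <- t(vapply(intervals, one, c(M2 = 0, peak = 0)))
  data.frame(interval = intervals, M2 = res[, "M2"], peak = res[, "peak"],
             M2norm = res[, "M2"] / base["M2"],
             peakNorm = res[, "peak"] / base["peak"])
}
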