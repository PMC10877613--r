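# Seesaw threshold gate with azobenzene-style photoswitching: binarizes the
# circuit output O into Z under blue light, resets under UV.

#' Seesaw threshold-gate parameters
#'
#' Blue-light (BL) rates follow standard seesaw practice: the thresholding
#' reaction is 10x faster than the catalytic amplification pair and its
#' equilibrium is 10:1 forward-biased, so small outputs are mostly absorbed
#' while larger ones leak through and are catalytically amplified. Under UV
#' the azobenzene-modified invading strands (O, Tt, Tg, Tf carry the
#' modified domains) no longer displace efficiently, so every forward rate
#' is multiplied by \code{uvForwardFactor} while the reverse rates keep
#' their BL values; all gate reactions then relax toward the initial state.
#'
#' @param kThresholdF,kThresholdB thresholding rates, 1/(nM*s).
#' @param kAmplifyF,kAmplifyB amplification rates, 1/(nM*s).
#' @param uvForwardFactor forward-rate multiplier in UV mode.
#' @param init named gate loadings, nM.
#' @return a [SeesawParams-class]
#' @export
seesawParams <- function(kThresholdF = 5.32e-3, kThresholdB = 5.32e-4,
                         kAmplifyF = 5.32e-4, kAmplifyB = 5.32e-4,
                         uvForwardFactor = 1e-3,
                         init = c(Tt = 100, Tg = 100, Tf = 100)) {
  new("SeesawParams", kThresholdF = kThresholdF, kThresholdB = kThresholdB,
      kAmplifyF = kAmplifyF, kAmplifyB = kAmplifyB,
      uvForwardFactor = uvForwardFactor, init = init)
}

#' Alternating irradiation schedule
#'
#' @param blDuration blue-light segment duration, seconds (default 1 h).
#' @param uvDuration UV segment duration, seconds (default 4 h).
#' @param firstMode which mode starts the sequence.
#' @return an [IrradiationSchedule-class] (the BL/UV pair repeats)
#' @export
irradiationSchedule <- function(blDuration = 3600, uvDuration = 14400,
                                firstMode = c("BL", "UV")) {
  firstMode <- match.arg(firstMode)
  modes <- if (firstMode == "BL") c("BL", "UV") else c("UV", "BL")
  durs <- if (firstMode == "BL") c(blDuration, uvDuration) else
    c(uvDuration, blDuration)
  new("IrradiationSchedule", modes = modes, durations = durs)
}

#' Tile an irradiation schedule over a horizon
#'
#' @param irr an [IrradiationSchedule-class].
#' @param horizon seconds.
#' @return data.frame with columns \code{mode}, \code{start}, \code{end}
#' @export
tileIrradiation <- function(irr, horizon) {
  starts <- numeric(0); modes <- character(0); ends <- numeric(0)
  t <- 0; i <- 1L
  nseg <- length(irr@modes)
  while (t < horizon) {
    starts <- c(starts, t)
    modes <- c(modes, irr@modes[i])
    t <- min(t + irr@durations[i], horizon)
    ends <- c(ends, t)
    i <- i %% nseg + 1L
  }
  data.frame(mode = modes, start = starts, end = ends)
}

#' Build the seesaw threshold-gate network fragment
#'
#' Species O (shared with the reflex circuit), Tp, Tf, Z, Tt, Tq, Tg, Ti,
#' Tw. Reactions: thresholding T1: O + Tt <-> Tp + Tq (fast, absorbs O up
#' to the Tt loading); gate release T2: O + Tg <-> Z + Ti; fuel turnover
#' T3: Tf + Ti <-> O + Tw, which regenerates O so that a supra-threshold
#' pulse is catalytically amplified into Z. The fragment carries BL/UV rate
#' modes (see [seesawParams()]).
#'
#' @param params a [SeesawParams-class].
#' @return a [ReactionNetwork-class] fragment (O at initial concentration 0)
#' @export
buildThresholdGate <- function(params) {
  validObject(params)
  sp <- c("O", "Tp", "Tf", "Z", "Tt", "Tq", "Tg", "Ti", "Tw")
  strand <- ifelse(sp %in% c("O", "Tp", "Tf", "Z"), "single", "double")
  init <- stats::setNames(numeric(length(sp)), sp)
  init[names(params@init)] <- params@init
  role <- rep("threshold-gate component", length(sp))
  role[sp == "O"] <- "output"
  role[sp == "Z"] <- "binarized output"
  bl <- data.frame(label = c("T1", "T2", "T3"),
                   kf = c(params@kThresholdF, params@kAmplifyF,
                          params@kAmplifyF),
                   kb = c(params@kThresholdB, params@kAmplifyB,
                          params@kAmplifyB))
  uv <- bl
  uv$kf <- uv$kf * params@uvForwardFactor
  reactions <- data.frame(
    label = c("T1", "T2", "T3"),
    r1 = c("O", "O", "Tf"), r2 = c("Tt", "Tg", "Ti"),
    p1 = c("Tp", "Z", "O"), p2 = c("Tq", "Ti", "Tw"),
    kf = bl$kf, kb = bl$kb)
  reactionNetwork(
    species = data.frame(name = sp, strandedness = strand,
                         init = as.numeric(init), role = role),
    reactions = reactions,
    modeRates = list(BL = bl, UV = uv))
}

#' Combine two reaction networks sharing species
#'
#' Species present in both (e.g. the output strand O) are merged; their
#' initial concentrations must agree. Reaction labels must not clash.
#'
#' @param a,b [ReactionNetwork-class] objects.
#' @return a combined [ReactionNetwork-class]
#' @export
combineNetworks <- function(a, b) {
  shared <- intersect(a@species$name, b@species$name)
  for (s in shared) {
    ia <- a@species$init[a@species$name == s]
    ib <- b@species$init[b@species$name == s]
    if (abs(ia - ib) > 1e-9)
      stop("shared species ", s, " has conflicting initial concentrations")
  }
  if (length(intersect(a@reactions$label, b@reactions$label)))
    stop("reaction labels clash between the networks")
  species <- rbind(a@species,
                   b@species[!b@species$name %in% shared, , drop = FALSE])
  modes <- union(names(a@modeRates), names(b@modeRates))
  modeRates <- stats::setNames(lapply(modes, function(m)
    rbind(a@modeRates[[m]], b@modeRates[[m]])), modes)
  reactionNetwork(species = species,
                  reactions = rbind(a@reactions, b@reactions),
                  modeRates = modeRates)
}

#' Run the photoswitched circuit + threshold gate
#'
#' Couples the two-input conditioned-reflex circuit to the seesaw gate
#' through the shared output strand O and simulates the pattern under an
#' alternating BL/UV irradiation schedule: at each mode switch the gate
#' reactions' rate constants are swapped and integration continues. Under
#' BL the gate binarizes O into Z; under UV it relaxes back toward its
#' initial loading, making the thresholding renewable across events.
#'
#' @param params a [CircuitParams-class].
#' @param gate a [SeesawParams-class].
#' @param pattern an [InputPattern-class] or pattern string.
#' @param irr an [IrradiationSchedule-class].
#' @param control a [solverControl()] list.
#' @return list with \code{trajectory} (including the gate species and Z),
#'   \code{modeSchedule} and \code{metrics} (per-event Z and O peaks)
#' @export
runPhotoswitched <- function(params, gate = seesawParams(), pattern,
                             irr = irradiationSchedule(),
                             control = solverControl()) {
  if (is.character(pattern)) pattern <- parsePattern(pattern)
  net <- combineNetworks(buildTwoInputCircuit(params),
                         buildThresholdGate(gate))
  sch <- scheduleFromPattern(pattern, params@doseAmount)
  ms <- tileIrradiation(irr, horizon(sch))
  traj <- simulateNetwork(net, sch, control, modeSchedule = ms)
  win <- eventWindows(pattern)
  perEvent <- data.frame(
    token = win$token, doseTime = win$start,
    zPeak = vapply(seq_len(nrow(win)), function(k)
      windowMetrics(traj, "Z", c(win$start[k], win$end[k]))$peak, 0),
    oPeak = vapply(seq_len(nrow(win)), function(k)
      windowMetrics(traj, "O", c(win$start[k], win$end[k]))$peak, 0))
  list(trajectory = traj, modeSchedule = ms, metrics = perEvent)
}
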