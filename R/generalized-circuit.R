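# n-input generalization: one unconditioned channel (I1) plus n-1 neutral
# channels, each with its own memory / pseudomemory gate pair and reward
# strand, all sharing the reservoir S and output O.

#' Build the n-input generalized conditioned-reflex network
#'
#' Channel 1 (unconditioned): I1 + M1 <-> Y1 + W1 and Y1 + S <-> O + R1.
#' Each neutral channel k = 2..n adds Yk + S <-> O + Rk (backward: output
#' regenerates Yk), Ik + Mk <-> Yk + Wk (backward: coincidence writes Mk)
#' and Ik + Mkp <-> Ykp + Wk, plus degradation of free Ik. Gate loadings
#' follow the two-input defaults: M1, every Mkp, S and every Rk (k >= 2) at
#' the \code{M1}/\code{M2p}/\code{S}/\code{R2} levels of \code{params},
#' R1 at the \code{R1} level.
#'
#' For n = 2 this reproduces the two-input circuit exactly (same species
#' order, same reactions).
#'
#' @param n number of input channels, >= 2.
#' @param params a [CircuitParams-class]; \code{kd2} is applied to every
#'   neutral input, \code{kd1} to I1.
#' @return a [ReactionNetwork-class]
#' @export
buildNInputCircuit <- function(n, params = circuitParams()) {
  n <- as.integer(n)
  if (n < 2) stop("n must be >= 2")
  validObject(params)
  ks <- seq(2L, n)
  sp <- c(paste0("I", 1:n), paste0("Y", 1:n), paste0("Y", ks, "p"), "O",
          paste0("M", 1:n), paste0("M", ks, "p"), paste0("W", 1:n), "S",
          paste0("R", 1:n))
  strand <- ifelse(sp %in% c(paste0("I", 1:n), paste0("Y", 1:n),
                             paste0("Y", ks, "p"), "O"), "single", "double")
  role <- rep("", length(sp))
  role[grep("^I", sp)] <- "input"
  role[sp %in% paste0("Y", 1:n)] <- "excitation"
  role[sp %in% paste0("Y", ks, "p")] <- "pseudoexcitation"
  role[sp == "O"] <- "output"
  role[sp %in% paste0("M", 1:n)] <- "memory gate"
  role[sp %in% paste0("M", ks, "p")] <- "pseudomemory gate"
  role[grep("^W", sp)] <- "waiting"
  role[sp == "S"] <- "reservoir"
  role[grep("^R", sp)] <- "reward"
  lvl <- function(key) if (key %in% names(params@init)) params@init[[key]] else 0
  init <- stats::setNames(numeric(length(sp)), sp)
  init["M1"] <- lvl("M1")
  init[paste0("M", ks, "p")] <- lvl("M2p")
  init["S"] <- lvl("S")
  init[paste0("R", ks)] <- lvl("R2")
  init["R1"] <- lvl("R1")

  kf <- rep(params@kf, length.out = 5)
  kb <- rep(params@kb, length.out = 5)
  rx <- function(label, r1, r2, p1, p2, kf, kb)
    data.frame(label = label, r1 = r1, r2 = r2, p1 = p1, p2 = p2,
               kf = kf, kb = kb)
  reactions <- rbind(
    rx("R1", "I1", "M1", "Y1", "W1", kf[1], kb[1]),
    rx("R2", "Y1", "S", "O", "R1", kf[2], kb[2]))
  lab <- 2L
  for (k in ks) {
    reactions <- rbind(reactions,
      rx(paste0("R", lab + 1L), paste0("Y", k), "S", "O", paste0("R", k),
         kf[3], kb[3]),
      rx(paste0("R", lab + 2L), paste0("I", k), paste0("M", k),
         paste0("Y", k), paste0("W", k), kf[4], kb[4]),
      rx(paste0("R", lab + 3L), paste0("I", k), paste0("M", k, "p"),
         paste0("Y", k, "p"), paste0("W", k), kf[5], kb[5]))
    lab <- lab + 3L
  }
  degs <- do.call(rbind, lapply(1:n, function(k)
    rx(paste0("D", k), paste0("I", k), NA, NA, NA,
       if (k == 1) params@kd1 else params@kd2, 0)))
  reactionNetwork(
    species = data.frame(name = sp, strandedness = strand,
                         init = as.numeric(init), role = role),
    reactions = rbind(reactions, degs))
}

#' Expected responsiveness of a trained circuit
#'
#' After a first (training) combination containing the unconditioned input
#' I1, the circuit should respond to a second combination iff it contains
#' I1 or any channel trained by the first combination.
#'
#' @param first,second 0/1 (or logical) vectors of equal length n; entry k
#'   marks input Ik as present.
#' @return logical(1)
#' @examples
#' expectedTruth(c(1, 0, 1, 0), c(0, 0, 1, 0))  # TRUE: channel 3 trained
#' expectedTruth(c(1, 0, 0, 0), c(0, 1, 0, 0))  # FALSE: channel 2 untrained
#' @export
expectedTruth <- function(first, second) {
  stopifnot(length(first) == length(second))
  first <- as.logical(first); second <- as.logical(second)
  trained <- unique(c(1L, which(first)))
  any(second[trained])
}

#' Enumerate two-event input histories
#'
#' First inputs are all 2^(n-1) combinations containing the unconditioned
#' stimulus I1; second inputs are either the n singletons
#' (\code{"single_second"}) or all 2^n - 1 non-empty combinations
#' (\code{"all_second"}). For n = 4 this yields 32 and 120 histories.
#'
#' @param n number of input channels.
#' @param mode \code{"single_second"} or \code{"all_second"}.
#' @return list of \code{list(first =, second =)} 0/1 vectors
#' @export
enumerateHistories <- function(n, mode = c("single_second", "all_second")) {
  mode <- match.arg(mode)
  n <- as.integer(n)
  stopifnot(n >= 2)
  bits <- function(x) as.integer(intToBits(x))[seq_len(n)]
  firsts <- lapply(0:(2^(n - 1) - 1), function(x) {
    v <- bits(x * 2L); v[1] <- 1L; v
  })
  seconds <- if (mode == "single_second") {
    lapply(seq_len(n), function(k) { v <- integer(n); v[k] <- 1L; v })
  } else {
    lapply(seq_len(2^n - 1), bits)
  }
  out <- vector("list", length(firsts) * length(seconds))
  i <- 0L
  for (f in firsts) for (s in seconds) {
    i <- i + 1L
    out[[i]] <- list(first = f, second = s)
  }
  out
}

#' Default responsiveness threshold
#'
#' 5% of the pre-learning I1-induced output peak of the two-input circuit
#' under the same parameters. With the net-response classification the
#' responsive / non-responsive split of the enumerated histories is
#' insensitive to this choice over a wide band (anywhere below about 8% of
#' the pre-learning peak at four channels; see the \code{band} element of
#' [truthTableExperiment()]).
#'
#' @param params a [CircuitParams-class].
#' @param control a [solverControl()] list.
#' @return nM
#' @export
responsivenessThreshold <- function(params, control = solverControl()) {
  res <- runPattern(params, "F", control)
  0.05 * perEventMetrics(res$metrics)$outputPeak[1]
}

#' Truth-table experiment on the generalized circuit
#'
#' Simulates every enumerated two-event history (first event at t = 0,
#' second one interval later, every member of a combination dosed at the
#' full amount) and classifies the second-event response against the
#' threshold, comparing with [expectedTruth()]. The response is the net
#' rise of the output above its level at the window start: the output
#' carries a slowly decaying tail from the first event, so the raw window
#' maximum would score that relaxation, not the second input.
#'
#' @param n number of input channels.
#' @param params a [CircuitParams-class].
#' @param threshold responsiveness threshold, nM; default
#'   [responsivenessThreshold()].
#' @param mode history enumeration mode, see [enumerateHistories()].
#' @param interval seconds between the two events (default 5 h).
#' @param control a [solverControl()] list.
#' @return list with \code{results} (data.frame: first, second, peak,
#'   response = peak minus window-start baseline, responsive, expected),
#'   \code{threshold}, \code{nResponsive}, \code{nExpected},
#'   \code{nNonTrivialResponsive} (responsive histories whose second input
#'   does not contain I1), \code{allAgree}, and \code{band}: the open
#'   interval of thresholds over which the classification is unchanged
#'   (largest non-responsive response, smallest responsive response)
#' @export
truthTableExperiment <- function(n, params = circuitParams(),
                                 threshold = NULL,
                                 mode = c("single_second", "all_second"),
                                 interval = 18000,
                                 control = solverControl()) {
  mode <- match.arg(mode)
  if (is.null(threshold)) threshold <- responsivenessThreshold(params, control)
  stopifnot(threshold > 0)
  histories <- enumerateHistories(n, mode)
  net <- buildNInputCircuit(n, params)
  fmt <- function(v) paste(v, collapse = "")
  rows <- lapply(histories, function(h) {
    ev <- rbind(
      data.frame(time = 0, species = paste0("I", which(h$first == 1)),
                 amount = params@doseAmount),
      data.frame(time = interval, species = paste0("I", which(h$second == 1)),
                 amount = params@doseAmount))
    sch <- doseSchedule(ev, horizon = 2 * interval)
    traj <- simulateNetwork(net, sch, control)
    wm <- windowMetrics(traj, "O", c(interval, 2 * interval))
    base <- stats::approx(traj@times, traj@concentrations[, "O"],
                          xout = interval)$y
    response <- max(wm$peak - base, 0)
    data.frame(first = fmt(h$first), second = fmt(h$second),
               peak = wm$peak, response = response,
               responsive = response >= threshold,
               expected = expectedTruth(h$first, h$second))
  })
  results <- do.call(rbind, rows)
  secondHasI1 <- substr(results$second, 1, 1) == "1"
  list(results = results, threshold = threshold,
       nResponsive = sum(results$responsive),
       nExpected = sum(results$expected),
       nNonTrivialResponsive = sum(results$responsive & !secondHasI1),
       allAgree = all(results$responsive == results$expected),
       band = c(low = max(results$response[!results$expected], 0),
                high = min(results$response[results$expected])))
}
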