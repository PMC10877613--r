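# Core mass-action machinery: right-hand side construction, piecewise stiff
# integration with instantaneous doses, conservation analysis and window
# metrics.

#' Solver configuration
#'
#' Tolerances and output density for the stiff integrator. The defaults
#' (relative 1e-8, absolute 1e-10 nM, one output point per 10 s) resolve
#' the circuit's fastest time scale (input degradation, 0.1 1/s in the
#' high-turnover variant) with large margin.
#'
#' @param rtol relative tolerance.
#' @param atol absolute tolerance, nM.
#' @param dtOut output grid spacing, seconds.
#' @param method a \pkg{deSolve} integration method; \code{"lsoda"} switches
#'   automatically between stiff and non-stiff regimes.
#' @return a list of class \code{solverControl}
#' @export
solverControl <- function(rtol = 1e-8, atol = 1e-10, dtOut = 10,
                          method = "lsoda") {
  stopifnot(rtol > 0, atol > 0, dtOut > 0)
  structure(list(rtol = rtol, atol = atol, dtOut = dtOut, method = method),
            class = "solverControl")
}

# Index-compiled form of a network: integer reactant/product indices and
# rate vectors, plus the stoichiometric matrix, for fast RHS evaluation.
# `mode` selects a modeRates override set by name.
compileNetwork <- function(network, mode = NULL) {
  sp <- network@species$name
  rx <- network@reactions
  if (!is.null(mode)) {
    if (!mode %in% names(network@modeRates))
      stop("unknown rate mode: ", mode)
    ov <- network@modeRates[[mode]]
    i <- match(ov$label, rx$label)
    rx$kf[i] <- ov$kf
    rx$kb[i] <- ov$kb
  }
  nrx <- nrow(rx)
  nsp <- length(sp)
  idx <- function(col) {
    i <- match(rx[[col]], sp)
    i[is.na(i)] <- 0L
    i
  }
  ir1 <- idx("r1"); ir2 <- idx("r2"); ip1 <- idx("p1"); ip2 <- idx("p2")
  N <- matrix(0, nsp, nrx, dimnames = list(sp, rx$label))
  for (j in seq_len(nrx)) {
    for (i in c(ir1[j], ir2[j])) if (i > 0) N[i, j] <- N[i, j] - 1
    for (i in c(ip1[j], ip2[j])) if (i > 0) N[i, j] <- N[i, j] + 1
  }
  # safe indices: unused slots point at 1 but contribute a factor of 1 / 0
  list(nsp = nsp, species = sp, N = N, kf = rx$kf, kb = rx$kb,
       ir1 = pmax(ir1, 1L), hasR2 = ir2 > 0L, ir2 = pmax(ir2, 1L),
       hasP1 = ip1 > 0L, ip1 = pmax(ip1, 1L),
       hasP2 = ip2 > 0L, ip2 = pmax(ip2, 1L))
}

rhsFromCompiled <- function(cn) {
  force(cn)
  function(t, y, parms) {
    f2 <- rep(1, length(cn$kf))
    f2[cn$hasR2] <- y[cn$ir2[cn$hasR2]]
    b1 <- as.numeric(cn$hasP1)
    b1[cn$hasP1] <- y[cn$ip1[cn$hasP1]]
    b2 <- rep(1, length(cn$kb))
    b2[cn$hasP2] <- y[cn$ip2[cn$hasP2]]
    flux <- cn$kf * y[cn$ir1] * f2 - cn$kb * b1 * b2
    list(as.vector(cn$N %*% flux))
  }
}

#' Mass-action time derivatives of a reaction network
#'
#' Evaluates d[X]/dt for every species at a given state: each reaction with
#' reactants A (+ B) and products C (+ D) contributes a net flux
#' kf*[A]*[B] - kb*[C]*[D] (unimolecular terms drop the second factor),
#' subtracted from its reactants and added to its products.
#'
#' @param network a [ReactionNetwork-class].
#' @param state numeric concentration vector, one entry per species (nM),
#'   in roster order or named.
#' @param mode optional rate-mode name (see \code{modeRates}).
#' @return named numeric vector of derivatives, nM/s
#' @export
massActionRHS <- function(network, state, mode = NULL) {
  sp <- network@species$name
  if (!is.null(names(state))) {
    miss <- setdiff(sp, names(state))
    if (length(miss)) stop("state is missing species: ",
                           paste(miss, collapse = ", "))
    state <- state[sp]
  }
  if (length(state) != length(sp))
    stop("state length must equal the species count")
  if (!all(is.finite(state))) stop("state must be finite")
  cn <- compileNetwork(network, mode)
  d <- rhsFromCompiled(cn)(0, as.numeric(state), NULL)[[1]]
  stats::setNames(d, sp)
}

#' Simulate a reaction network under a dose schedule
#'
#' Deterministic mass-action integration with a stiff-capable solver.
#' The trajectory is integrated piecewise between dose times (and rate-mode
#' switches, when a \code{modeSchedule} is given); at each dose time the
#' dosed amount is added to the species' concentration instantaneously and
#' integration restarts. Values stored at an event time are post-dose.
#'
#' @param network a [ReactionNetwork-class].
#' @param schedule a [DoseSchedule-class].
#' @param control a [solverControl()] list.
#' @param modeSchedule optional data.frame with columns \code{mode},
#'   \code{start}, \code{end} (seconds) tiling \code{[0, horizon]} without
#'   gaps or overlaps; the named \code{modeRates} set is active per segment.
#' @return a [Trajectory-class] over \code{[0, horizon]}
#' @examples
#' net <- reactionNetwork(
#'   species = data.frame(name = "A", init = 0),
#'   reactions = data.frame(label = "deg", r1 = "A", r2 = NA, p1 = NA,
#'                          p2 = NA, kf = 0.01, kb = 0))
#' sch <- doseSchedule(data.frame(time = 0, species = "A", amount = 100),
#'                     horizon = 300)
#' traj <- simulateNetwork(net, sch)
#' windowMetrics(traj, "A", c(0, 300))
#' @export
simulateNetwork <- function(network, schedule, control = solverControl(),
                            modeSchedule = NULL) {
  ev <- schedule@events
  hz <- schedule@horizon
  sp <- network@species$name
  if (nrow(ev)) {
    bad <- setdiff(ev$species, sp)
    if (length(bad)) stop("dose schedule names unknown species: ",
                          paste(bad, collapse = ", "))
  }
  breaks <- sort(unique(c(0, ev$time, hz)))
  if (!is.null(modeSchedule)) {
    ms <- modeSchedule[order(modeSchedule$start), , drop = FALSE]
    if (ms$start[1] != 0 || any(abs(ms$start[-1] - ms$end[-nrow(ms)]) > 1e-9) ||
        ms$end[nrow(ms)] < hz)
      stop("modeSchedule segments must tile [0, horizon] without gaps or overlaps")
    breaks <- sort(unique(c(breaks, ms$start[ms$start < hz])))
  }
  breaks <- breaks[breaks <= hz]
  y <- stats::setNames(network@species$init, sp)
  rows <- NULL
  times <- NULL
  compiled <- list()  # cache per mode
  for (i in seq_len(length(breaks) - 1)) {
    t0 <- breaks[i]; t1 <- breaks[i + 1]
    here <- ev[abs(ev$time - t0) < 1e-9, , drop = FALSE]
    for (j in seq_len(nrow(here)))
      y[here$species[j]] <- y[here$species[j]] + here$amount[j]
    mode <- NULL
    if (!is.null(modeSchedule)) {
      k <- which(ms$start <= t0 + 1e-9 & ms$end > t0 + 1e-9)[1]
      mode <- ms$mode[k]
      if (!mode %in% names(network@modeRates)) mode <- NULL
    }
    key <- if (is.null(mode)) ".base" else mode
    if (is.null(compiled[[key]]))
      compiled[[key]] <- compileNetwork(network, mode)
    tt <- unique(c(seq(t0, t1, by = control$dtOut), t1))
    if (length(tt) < 2) tt <- c(t0, t1)
    out <- deSolve::ode(y = y, times = tt, func = rhsFromCompiled(compiled[[key]]),
                        parms = NULL, method = control$method,
                        rtol = control$rtol, atol = control$atol)
    if (attr(out, "istate")[1] < 0)
      stop(sprintf("solver failure on interval [%g, %g] s", t0, t1))
    y <- stats::setNames(out[nrow(out), -1], sp)
    seg <- out[, -1, drop = FALSE]
    segt <- out[, 1]
    if (!is.null(times)) {           # drop pre-dose duplicate at boundary
      keepPrev <- times < t0 - 1e-9
      times <- times[keepPrev]
      rows <- rows[keepPrev, , drop = FALSE]
    }
    times <- c(times, segt)
    rows <- rbind(rows, seg)
  }
  if (min(rows) < -100 * control$rtol * max(abs(rows)))
    warning("solver produced concentrations below -100*rtol; check tolerances")
  rows[rows < 0] <- 0
  colnames(rows) <- sp
  new("Trajectory", times = as.numeric(times), concentrations = rows,
      eventTimes = sort(unique(ev$time)))
}

# Minimal nonnegative conservation relations (P-semiflows) of a
# stoichiometric matrix, by the Farkas elimination algorithm: cancel one
# reaction column at a time by combining rows of opposite sign, keep
# minimal-support rows. Sizes here are small (tens of species) so the
# combinatorial growth is harmless.
minimalSemiflows <- function(N) {
  n <- nrow(N)
  B <- cbind(diag(n), N)
  for (j in seq_len(ncol(N))) {
    col <- n + j
    v <- B[, col]
    keep <- B[v == 0, , drop = FALSE]
    pos <- B[v > 0, , drop = FALSE]
    neg <- B[v < 0, , drop = FALSE]
    if (nrow(pos) && nrow(neg)) {
      combos <- vector("list", nrow(pos) * nrow(neg))
      idx <- 0L
      for (ip in seq_len(nrow(pos))) for (im in seq_len(nrow(neg))) {
        idx <- idx + 1L
        r <- abs(neg[im, col]) * pos[ip, ] + pos[ip, col] * neg[im, ]
        g <- Reduce(function(a, b) if (b == 0) a else Recall(b, a %% b),
                    abs(r[r != 0]))
        combos[[idx]] <- r / g
      }
      keep <- rbind(keep, do.call(rbind, combos))
    }
    keep <- unique(keep)
    # minimal support only
    supp <- lapply(seq_len(nrow(keep)), function(i) which(keep[i, 1:n] != 0))
    minimal <- rep(TRUE, nrow(keep))
    for (a in seq_len(nrow(keep))) for (b in seq_len(nrow(keep)))
      if (a != b && minimal[a] && length(supp[[b]]) < length(supp[[a]]) &&
          all(supp[[b]] %in% supp[[a]])) minimal[a] <- FALSE
    B <- keep[minimal, , drop = FALSE]
  }
  t(B[, seq_len(n), drop = FALSE])            # species x groups
}

#' Conservation groups of a reaction network
#'
#' Computes the minimal nonnegative weighted species sums (P-semiflows)
#' left invariant by all non-degradation (reversible strand-displacement)
#' reactions, i.e. vectors in the left null space of the stoichiometric
#' matrix restricted to those reactions. Each group is flagged when an
#' irreversible degradation breaks it.
#'
#' @param network a [ReactionNetwork-class].
#' @return list of groups; each has \code{weights} (named numeric over
#'   species, zeros dropped), \code{total} (the conserved value at the
#'   initial state, nM) and \code{broken} (TRUE when degradation changes it)
#' @examples
#' net <- reactionNetwork(
#'   species = data.frame(name = c("A", "B"), init = c(100, 0)),
#'   reactions = data.frame(label = "iso", r1 = "A", r2 = NA, p1 = "B",
#'                          p2 = NA, kf = 1e-3, kb = 1e-3))
#' conservationGroups(net)[[1]]$weights  # A + B conserved
#' @export
conservationGroups <- function(network) {
  cn <- compileNetwork(network)
  deg <- is.na(network@reactions$p1)
  Nnd <- cn$N[, !deg, drop = FALSE]
  Nd <- cn$N[, deg, drop = FALSE]
  B <- minimalSemiflows(Nnd)
  init <- network@species$init
  out <- vector("list", ncol(B))
  for (k in seq_len(ncol(B))) {
    w <- stats::setNames(B[, k], cn$species)
    broken <- ncol(Nd) > 0 && any(abs(as.vector(w %*% Nd)) > 1e-9)
    out[[k]] <- list(weights = w[abs(w) > 1e-9],
                     total = sum(w * init), broken = broken)
  }
  out
}

#' Peak and end-point metrics over a trajectory window
#'
#' @param traj a [Trajectory-class].
#' @param species species name.
#' @param window numeric(2), \code{c(tStart, tEnd)} in seconds, inside the
#'   trajectory span.
#' @return list with \code{peak} (nM, max over the window), \code{peakTime}
#'   (s) and \code{endValue} (nM at \code{tEnd}, the steady-state proxy read
#'   just before any subsequent dose)
#' @export
windowMetrics <- function(traj, species, window) {
  if (!species %in% colnames(traj@concentrations))
    stop("unknown species: ", species)
  if (length(window) != 2 || window[2] <= window[1])
    stop("window must be c(tStart, tEnd) with tEnd > tStart")
  tt <- traj@times
  if (window[1] < min(tt) - 1e-9 || window[2] > max(tt) + 1e-9)
    stop("window outside trajectory span")
  sel <- tt >= window[1] - 1e-9 & tt <= window[2] + 1e-9
  if (!any(sel)) stop("empty window")
  y <- traj@concentrations[sel, species]
  ts <- tt[sel]
  i <- which.max(y)
  endValue <- stats::approx(ts, y, xout = min(window[2], max(ts)))$y
  list(peak = max(y[i], 0), peakTime = ts[i], endValue = max(endValue, 0))
}
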