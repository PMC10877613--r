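# Parameter estimation: response statistics, cost function, a seeded
# real-coded genetic algorithm and a local-sensitivity utility.

#' Response statistics used by the estimation cost
#'
#' Two probe simulations: (a) simultaneous I1 + I2 at the pre-learning
#' state, giving the peak and steady-state (window-end) output Jpk12 /
#' Jss12; (b) I2 alone at the post-learning state, reached by one FB
#' training event followed by one reset interval, giving Jpk2 / Jss2.
#'
#' @param params a [CircuitParams-class].
#' @param control a [solverControl()] list.
#' @return named numeric: \code{Jpk12}, \code{Jss12}, \code{Jpk2},
#'   \code{Jss2} (nM)
#' @export
responseStatistics <- function(params, control = solverControl()) {
  pre <- perEventMetrics(runPattern(params, "FB", control)$metrics)
  post <- perEventMetrics(runPattern(params, "FB-B", control)$metrics)
  c(Jpk12 = pre$outputPeak[1], Jss12 = pre$outputEnd[1],
    Jpk2 = post$outputPeak[2], Jss2 = post$outputEnd[2])
}

#' Cost specification
#'
#' Default form J = -Jpk2 + alpha * (Jss12 + Jss2): maximize the
#' conditioned (post-learning I2-induced) response while penalizing
#' non-zero steady states, which enforces renewability. A custom
#' \code{form} function(stats) may replace it.
#'
#' @param alpha steady-state penalty weight.
#' @param form optional function of the statistics vector returning a
#'   scalar cost.
#' @return list of class \code{costSpec}
#' @export
costSpec <- function(alpha = 1, form = NULL) {
  stopifnot(is.finite(alpha))
  structure(list(alpha = alpha, form = form), class = "costSpec")
}

#' Evaluate the estimation cost
#'
#' @param spec a [costSpec()].
#' @param stats named statistics from [responseStatistics()].
#' @return scalar cost
#' @examples
#' evaluateCost(costSpec(), c(Jpk12 = 17, Jss12 = 0, Jpk2 = 3.8, Jss2 = 0))
#' @export
evaluateCost <- function(spec, stats) {
  stopifnot(all(is.finite(stats)))
  if (!is.null(spec$form)) return(spec$form(stats))
  unname(-stats["Jpk2"] + spec$alpha * (stats["Jss12"] + stats["Jss2"]))
}

#' Toehold-length to rate-constant lookup table
#'
#' Strand-displacement rates grow steeply with toehold length before
#' saturating. Only the 5-nt entry is anchored by the estimated operating
#' point (5.32e-4 1/(nM*s)); the others are placeholder values on a
#' roughly-tenfold-per-nucleotide ramp that saturates at 6 nt, and matter
#' only for exploration during estimation.
#'
#' @return named numeric, lengths "3".."6" -> 1/(nM*s)
#' @export
toeholdRateTable <- function() {
  c(`3` = 5.32e-6, `4` = 5.32e-5, `5` = 5.32e-4, `6` = 1.06e-3)
}

#' Define the circuit estimation problem
#'
#' Decision vector: the five non-zero initial concentrations (M1, M2p, S,
#' R2, R1; 0-200 nM), log10 of the shared degradation rate (1e-3 to 1e-1
#' 1/s) and one toehold-length gene (integer 3-6) setting the shared
#' displacement rate through [toeholdRateTable()].
#'
#' @param spec a [costSpec()].
#' @param rateTable toehold-length lookup, see [toeholdRateTable()].
#' @param control a [solverControl()] list used inside the fitness.
#' @return list with \code{lower}, \code{upper}, \code{integerIdx},
#'   \code{decode} (vector -> [CircuitParams-class]) and \code{fitness}
#'   (vector -> cost, minimized)
#' @export
estimationProblem <- function(spec = costSpec(),
                              rateTable = toeholdRateTable(),
                              control = solverControl()) {
  decode <- function(x) {
    th <- as.character(round(x[7]))
    k <- unname(rateTable[th])
    circuitParams(kf = k, kb = k, kd1 = 10^x[6], kd2 = 10^x[6],
                  init = c(M1 = x[1], M2p = x[2], S = x[3], R2 = x[4],
                           R1 = x[5]))
  }
  list(lower = c(0, 0, 0, 0, 0, -3, 3),
       upper = c(200, 200, 200, 200, 200, -1, 6),
       integerIdx = 7L,
       decode = decode,
       fitness = function(x)
         evaluateCost(spec, responseStatistics(decode(x), control)))
}

#' Seeded real-coded genetic algorithm
#'
#' Minimizes \code{fitness} over a box. Tournament selection, blend
#' crossover, gaussian mutation, elitism; genes listed in
#' \code{integerIdx} are rounded to integers throughout. Runs are
#' bit-reproducible for a fixed seed.
#'
#' @param fitness function(numeric vector) -> scalar to minimize.
#' @param lower,upper bounds.
#' @param integerIdx indices of integer-valued genes.
#' @param popSize population size.
#' @param generations number of generations.
#' @param seed integer RNG seed.
#' @param mutationSd gaussian mutation scale, as a fraction of the range.
#' @return list with \code{par}, \code{value} and per-generation
#'   \code{trace} of the incumbent cost
#' @export
runGA <- function(fitness, lower, upper, integerIdx = integer(0),
                  popSize = 24, generations = 40, seed = 1,
                  mutationSd = 0.1) {
  stopifnot(length(lower) == length(upper), all(upper >= lower))
  nvar <- length(lower)
  rng <- upper - lower
  set.seed(seed)
  snap <- function(x) {
    x <- pmin(pmax(x, lower), upper)
    x[integerIdx] <- round(x[integerIdx])
    x
  }
  pop <- t(replicate(popSize, snap(lower + stats::runif(nvar) * rng)))
  fit <- apply(pop, 1, fitness)
  trace <- numeric(generations)
  for (g in seq_len(generations)) {
    newPop <- matrix(0, popSize, nvar)
    best <- which.min(fit)
    newPop[1, ] <- pop[best, ]                         # elitism
    for (i in 2:popSize) {
      pick <- function() {
        c2 <- sample.int(popSize, 2)
        c2[which.min(fit[c2])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      a <- stats::runif(nvar, -0.25, 1.25)             # BLX-alpha blend
      child <- a * p1 + (1 - a) * p2
      mut <- stats::runif(nvar) < 0.15
      child[mut] <- child[mut] + stats::rnorm(sum(mut), 0,
                                              mutationSd * rng[mut])
      newPop[i, ] <- snap(child)
    }
    pop <- newPop
    fit <- apply(pop, 1, fitness)
    trace[g] <- min(fit)
  }
  best <- which.min(fit)
  list(par = pop[best, ], value = fit[best], trace = trace)
}

#' Estimate circuit parameters with the genetic algorithm
#'
#' @param problem an [estimationProblem()].
#' @param popSize,generations,seed GA settings (kept deliberately small by
#'   default; each fitness call runs two circuit simulations).
#' @return list with the best decoded [CircuitParams-class]
#'   (\code{params}), raw vector (\code{par}), \code{value},
#'   \code{rounded} (estimates rounded to one significant digit) and
#'   \code{trace}
#' @export
estimateCircuit <- function(problem = estimationProblem(), popSize = 12,
                            generations = 10, seed = 1) {
  res <- runGA(problem$fitness, problem$lower, problem$upper,
               problem$integerIdx, popSize = popSize,
               generations = generations, seed = seed)
  res$params <- problem$decode(res$par)
  res$rounded <- signif(res$par, 1)
  res
}

#' Local sensitivity of a response statistic
#'
#' Central finite-difference sensitivities of one named response statistic
#' with respect to every rate constant and non-zero initial concentration,
#' reported as normalized log-log coefficients d log(metric) / d log(p)
#' (absolute derivative when the metric is 0).
#'
#' @param params a [CircuitParams-class].
#' @param metric one of \code{"Jpk12"}, \code{"Jss12"}, \code{"Jpk2"},
#'   \code{"Jss2"}, or a function([CircuitParams-class]) -> scalar.
#' @param relStep relative perturbation, in (0, 0.5).
#' @param control a [solverControl()] list.
#' @return named numeric of sensitivity coefficients
#' @export
localSensitivity <- function(params, metric = "Jpk2", relStep = 0.01,
                             control = solverControl()) {
  stopifnot(relStep > 0, relStep < 0.5)
  mfun <- if (is.function(metric)) metric else
    function(p) unname(responseStatistics(p, control)[metric])
  get <- function(p, name) switch(name,
    kf = p@kf[1], kb = p@kb[1], kd1 = p@kd1, kd2 = p@kd2,
    p@init[[name]])
  set <- function(p, name, v) {
    switch(name,
           kf = p@kf <- rep(v, length(p@kf)),
           kb = p@kb <- rep(v, length(p@kb)),
           kd1 = p@kd1 <- v,
           kd2 = p@kd2 <- v,
           p@init[[name]] <- v)
    p
  }
  pnames <- c("kf", "kb", "kd1", "kd2",
              names(params@init)[params@init > 0])
  m0 <- mfun(params)
  out <- stats::setNames(numeric(length(pnames)), pnames)
  for (nm in pnames) {
    v <- get(params, nm)
    if (v == 0) { out[nm] <- 0; next }
    mUp <- mfun(set(params, nm, v * (1 + relStep)))
    mDn <- mfun(set(params, nm, v * (1 - relStep)))
    dmdp <- (mUp - mDn) / (2 * v * relStep)
    out[nm] <- if (m0 != 0) dmdp * v / m0 else dmdp
  }
  out
}
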