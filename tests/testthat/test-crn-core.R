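test_that("mass-action derivatives match hand evaluation", {
  # no reactions -> no flux
  net0 <- reactionNetwork(
    species = data.frame(name = c("A", "B"), init = c(1, 2)),
    reactions = data.frame(label = character(0), r1 = character(0),
                           r2 = character(0), p1 = character(0),
                           p2 = character(0), kf = numeric(0),
                           kb = numeric(0)))
  expect_equal(unname(massActionRHS(net0, c(10, 20))), c(0, 0))

  # linear decay: d[A]/dt = -kd [A]
  expect_equal(unname(massActionRHS(degradationNet(0.01), 100)), -1.0)

  # A+B <-> C+D at kf = kb = 5.32e-4, [A]=[B]=100, [C]=[D]=0:
  # d[A]/dt = -(5.32e-4 * 100 * 100) = -5.32
  d <- massActionRHS(exchangeNet(), c(A = 100, B = 100, C = 0, D = 0))
  expect_equal(unname(d), c(-5.32, -5.32, 5.32, 5.32))

  # named state in arbitrary order is aligned to the roster
  d2 <- massActionRHS(exchangeNet(), c(D = 0, C = 0, B = 100, A = 100))
  expect_equal(d, d2)
})

test_that("mass-action RHS rejects malformed states and networks", {
  expect_error(massActionRHS(exchangeNet(), c(1, 2, 3)), "length")
  expect_error(massActionRHS(exchangeNet(), c(A = 1, B = 2, C = 3, X = 4)),
               "missing species")
  expect_error(massActionRHS(exchangeNet(), c(NaN, 1, 1, 1)), "finite")
  expect_error(
    reactionNetwork(
      species = data.frame(name = "A", init = 1),
      reactions = data.frame(label = "r", r1 = "A", r2 = NA, p1 = "Zz",
                             p2 = NA, kf = 1, kb = 0)),
    "unknown species")
})

test_that("simulated decay follows the closed-form exponential", {
  net <- degradationNet(kd = 0.01)
  sch <- doseSchedule(data.frame(time = 0, species = "A", amount = 100),
                      horizon = 300)
  traj <- simulateNetwork(net, sch, solverControl(dtOut = 1))
  tt <- timePoints(traj)
  expect_equal(unname(concentrations(traj)[, "A"]), 100 * exp(-0.01 * tt),
               tolerance = 1e-6)
  # t=0 value is post-dose
  expect_equal(unname(concentrations(traj)[1, "A"]), 100)
  # half-life: [A](69.3 s) ~ 50 nM
  a <- approx(tt, concentrations(traj)[, "A"], xout = log(2) / 0.01)$y
  expect_equal(a, 50, tolerance = 1e-4)
})

test_that("empty schedule with zero initial state stays identically zero", {
  net <- degradationNet()
  traj <- simulateNetwork(net, emptySchedule(100))
  expect_true(all(concentrations(traj) == 0))
  expect_equal(range(timePoints(traj)), c(0, 100))
})

test_that("reversible exchange reaches the detailed-balance equilibrium", {
  # symmetric case: [A]=[B]=[C]=[D]=50 by symmetry
  traj <- simulateNetwork(exchangeNet(), emptySchedule(2e5))
  final <- concentrations(traj)[length(timePoints(traj)), ]
  expect_equal(unname(final), rep(50, 4), tolerance = 1e-6)

  # asymmetric rates against the quadratic root-finding oracle
  for (kb in c(5.32e-4, 1e-3, 2e-4)) {
    net <- exchangeNet(kf = 5.32e-4, kb = kb,
                       init = c(A = 80, B = 120, C = 0, D = 0))
    traj <- simulateNetwork(net, emptySchedule(5e5))
    fin <- concentrations(traj)[length(timePoints(traj)), ]
    x <- equilibriumExtentOracle(5.32e-4, kb, 80, 120)
    expect_equal(unname(fin),
                 c(80 - x, 120 - x, x, x), tolerance = 1e-6)
    # detailed balance kf [A][B] = kb [C][D]
    expect_equal(5.32e-4 * fin["A"] * fin["B"], kb * fin["C"] * fin["D"],
                 ignore_attr = TRUE, tolerance = 1e-6)
  }
})

test_that("dosing a+b at once equals dosing a then b at the same time", {
  net <- exchangeNet()
  one <- doseSchedule(data.frame(time = 50, species = "A", amount = 30),
                      horizon = 1000)
  two <- doseSchedule(data.frame(time = c(50, 50), species = c("A", "A"),
                                 amount = c(10, 20)), horizon = 1000)
  t1 <- simulateNetwork(net, one)
  t2 <- simulateNetwork(net, two)
  expect_equal(concentrations(t1), concentrations(t2))
  expect_equal(timePoints(t1), timePoints(t2))
})

test_that("halving solver tolerances leaves peak metrics unchanged to 0.1%", {
  p <- circuitParams()
  c1 <- solverControl()
  c2 <- solverControl(rtol = c1$rtol / 2, atol = c1$atol / 2)
  pk1 <- perEventMetrics(runPattern(p, "B-F", c1)$metrics)$outputPeak[2]
  pk2 <- perEventMetrics(runPattern(p, "B-F", c2)$metrics)$outputPeak[2]
  expect_lt(abs(pk1 - pk2) / pk1, 1e-3)
})

test_that("window metrics report peaks, end values and errors", {
  net <- degradationNet()
  flat <- simulateNetwork(net, emptySchedule(100))
  m <- windowMetrics(flat, "A", c(10, 90))
  expect_equal(m$peak, 0)
  expect_equal(m$peakTime, 10)
  expect_equal(m$endValue, 0)

  sch <- doseSchedule(data.frame(time = 0, species = "A", amount = 100),
                      horizon = 500)
  dec <- simulateNetwork(net, sch)
  m <- windowMetrics(dec, "A", c(0, 500))
  expect_equal(m$peak, 100)         # monotone decay peaks at the dose
  expect_equal(m$peakTime, 0)
  expect_equal(m$endValue, 100 * exp(-0.01 * 500), tolerance = 1e-5)

  expect_error(windowMetrics(dec, "A", c(90, 10)), "tEnd > tStart")
  expect_error(windowMetrics(dec, "A", c(0, 1e5)), "span")
  expect_error(windowMetrics(dec, "nope", c(0, 10)), "unknown species")
})

test_that("trajectories stay non-negative and conserve unbroken groups", {
  net <- exchangeNet(init = c(A = 100, B = 40, C = 0, D = 10))
  traj <- simulateNetwork(net, emptySchedule(1e5))
  expect_true(all(concentrations(traj) >= 0))
  # {A+C}, {B+C}-type semiflow totals constant to 10x solver tolerance
  expect_true(all(groupDrift(net, traj) < 10 * solverControl()$rtol))
})

test_that("conservation analysis recovers the circuit's invariant groups", {
  net <- buildTwoInputCircuit(circuitParams())
  groups <- conservationGroups(net)
  keyOf <- function(w) paste(sort(names(w)), collapse = "+")
  keys <- vapply(groups, function(g) keyOf(g$weights), "")
  expected <- list(
    c("M1", "W1"), c("O", "S"), c("M1", "R1", "Y1"), c("M2", "R2", "Y2"),
    c("M2p", "Y2p"), c("M2", "M2p", "W2"), c("R1", "R2", "S"))
  for (e in expected) {
    i <- match(paste(sort(e), collapse = "+"), keys)
    expect_false(is.na(i), info = paste("missing group", paste(e, collapse = "+")))
    expect_false(groups[[i]]$broken)
    expect_true(all(groups[[i]]$weights == 1))
  }
  # memory redistribution pool starts at the pseudomemory loading
  i <- match("M2+M2p+W2", keys)
  expect_equal(groups[[i]]$total, 100)
  # groups containing a degradable free input are broken
  for (g in groups)
    expect_equal(g$broken, any(c("I1", "I2") %in% names(g$weights)))
  # a pure-degradation network conserves nothing containing the substrate
  dg <- conservationGroups(degradationNet())
  expect_true(all(vapply(dg, function(g) g$broken, TRUE)))
})

test_that("simple isomerization conserves total mass", {
  net <- reactionNetwork(
    species = data.frame(name = c("A", "B"), init = c(100, 0)),
    reactions = data.frame(label = "iso", r1 = "A", r2 = NA, p1 = "B",
                           p2 = NA, kf = 1e-3, kb = 1e-3))
  g <- conservationGroups(net)
  expect_length(g, 1)
  expect_equal(sort(names(g[[1]]$weights)), c("A", "B"))
  expect_equal(g[[1]]$total, 100)
})
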