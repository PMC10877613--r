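test_that("the two-input circuit has the expected roster and topology", {
  net <- buildTwoInputCircuit(circuitParams())
  expect_setequal(speciesNames(net),
                  c("I1", "I2", "Y1", "Y2", "Y2p", "O", "M1", "M2", "M2p",
                    "W1", "W2", "S", "R1", "R2"))
  expect_length(speciesNames(net), 14)
  rx <- reactionTable(net)
  expect_equal(nrow(rx), 7)
  expect_equal(sum(is.na(rx$p1)), 2)          # two degradations
  expect_equal(sum(rx$kb > 0), 5)             # five reversible exchanges
  # six single- and eight double-stranded DNAs
  expect_equal(sum(net@species$strandedness == "single"), 6)
  expect_equal(sum(net@species$strandedness == "double"), 8)
  init <- initialConcentrations(net)
  expect_equal(unname(init[c("M1", "M2p", "S", "R2", "R1")]),
               c(100, 100, 100, 100, 50))
  expect_true(all(init[setdiff(names(init),
                               c("M1", "M2p", "S", "R2", "R1"))] == 0))
})

test_that("zero rates freeze the circuit at its initial state", {
  p <- circuitParams(kf = 0, kb = 0, kd1 = 0, kd2 = 0)
  net <- buildTwoInputCircuit(p)
  traj <- simulateNetwork(net, emptySchedule(1000))
  cc <- concentrations(traj)
  for (s in speciesNames(net))
    expect_true(all(cc[, s] == initialConcentrations(net)[s]))
})

test_that("pattern strings parse with both dash dialects", {
  p <- parsePattern("B-FB-B")
  expect_equal(p@tokens, c("B", "FB", "B"))
  expect_equal(parsePattern("B–FB–B")@tokens, c("B", "FB", "B"))
  expect_equal(parsePattern("F")@tokens, "F")
  long <- parsePattern("FB-B-B-B-B-B-B-B-B-B")
  expect_length(long@tokens, 10)
  expect_equal(long@tokens, c("FB", rep("B", 9)))
  expect_error(parsePattern("B-X-B"), "X")
  expect_error(parsePattern(""), "non-empty")
})

test_that("pattern schedules dose the right inputs at the right times", {
  sch <- scheduleFromPattern(parsePattern("B-FB-B"), doseAmount = 100)
  ev <- doseEvents(sch)
  expect_equal(ev$time, c(0, 18000, 18000, 36000))
  expect_equal(ev$species, c("I2", "I1", "I2", "I2"))
  expect_true(all(ev$amount == 100))
  expect_equal(horizon(sch), 54000)
})

test_that("zero-dose patterns give identically zero metrics", {
  p <- circuitParams(doseAmount = 0)
  res <- runPattern(p, "F-B")
  pe <- perEventMetrics(res$metrics)
  expect_true(all(pe$outputPeak == 0))
  expect_true(all(pe$outputEnd == 0))
  expect_true(all(memoryLevels(res$metrics) == 0))
})

test_that("learning requires coincident inputs (specificity)", {
  p <- circuitParams()
  m2NoLearn <- memoryLevels(runPattern(p, "B-F-B")$metrics)[2]
  m2Learn <- memoryLevels(runPattern(p, "B-FB-B")$metrics)[2]
  expect_lt(m2NoLearn, 0.25 * m2Learn)
})

test_that("memory accumulation saturates over repeated coincident inputs", {
  p <- circuitParams()
  m1 <- memoryLevels(runPattern(p, "FB")$metrics)[1]
  m2 <- memoryLevels(runPattern(p, "FB-FB")$metrics)[2]
  m3 <- memoryLevels(runPattern(p, "FB-FB-FB")$metrics)[3]
  expect_true(m1 <= m2 + 1e-6 && m2 <= m3 + 1e-6)
  expect_lt((m3 - m1) / m1, 0.1)              # nearly saturating
})

test_that("the circuit renews after a single non-learning event", {
  p <- circuitParams()
  net <- buildTwoInputCircuit(p)
  init <- initialConcentrations(net)
  for (tok in c("F", "B")) {
    pat <- parsePattern(tok, postWindow = 27000)  # ~7.5 h of relaxation
    traj <- runPattern(p, pat)$trajectory
    final <- concentrations(traj)[length(timePoints(traj)), ]
    # within 2% of the initial loading (scaled by the largest loading)
    expect_true(all(abs(final - init) <= 0.02 * max(init)),
                info = paste("renewability after", tok))
  }
})

test_that("learning efficiency is the post/pre peak ratio in percent", {
  expect_equal(round(learningEfficiency(3.8, 17.3), 1), 22.0)
  expect_equal(learningEfficiency(0, 5), 0)
  expect_equal(learningEfficiency(7, 7), 100)
  expect_error(learningEfficiency(1, 0), "undefined")
  expect_error(learningEfficiency(1, -2), "undefined")
})

test_that("forgetting is monotone and normalized to the first event", {
  series <- forgettingExperiment(circuitParams())
  expect_length(series, 10)
  expect_equal(series[1], 1)
  expect_true(all(diff(series[-1]) <= 1e-9))  # non-increasing from event 2
  expect_error(forgettingExperiment(circuitParams(doseAmount = 0)),
               "undefined")
})

test_that("forgetting accelerates in the high-capacity variant", {
  s <- forgettingExperiment(circuitParams())
  v <- forgettingExperiment(highCapacityParams())
  # the first post-learning peak is roughly halved
  expect_gt(s[2] / v[2], 1.6)
  expect_lt(s[2] / v[2], 2.6)
})

test_that("memory accumulation narrows with the input interval", {
  sy <- synchronizationExperiment(circuitParams(),
                                  intervals = c(0, 3600, 7200, 18000, 36000))
  expect_equal(sy$M2norm[1], 1)
  expect_equal(sy$peakNorm[1], 1)
  expect_true(all(diff(sy$M2norm) < 0))       # strictly decreasing
  expect_true(all(diff(sy$peakNorm) < 0))
  expect_lt(sy$M2norm[nrow(sy)], 0.2)         # long-gap residual is small
})

test_that("conservation groups hold along a learning experiment", {
  p <- circuitParams()
  net <- buildTwoInputCircuit(p)
  traj <- runPattern(p, "B-FB-B")$trajectory
  expect_true(all(groupDrift(net, traj) < 1e-6))
})
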