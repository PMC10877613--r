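# Small fixture networks built in code.

# single irreversible decay A -> waste
degradationNet <- function(kd = 0.01, a0 = 0) {
  reactionNetwork(
    species = data.frame(name = "A", init = a0),
    reactions = data.frame(label = "deg", r1 = "A", r2 = NA, p1 = NA,
                           p2 = NA, kf = kd, kb = 0))
}

# reversible bimolecular exchange A + B <-> C + D
exchangeNet <- function(kf = 5.32e-4, kb = 5.32e-4,
                        init = c(A = 100, B = 100, C = 0, D = 0)) {
  reactionNetwork(
    species = data.frame(name = names(init), init = as.numeric(init)),
    reactions = data.frame(label = "x", r1 = "A", r2 = "B", p1 = "C",
                           p2 = "D", kf = kf, kb = kb))
}

emptySchedule <- function(horizon = 100) {
  doseSchedule(data.frame(time = numeric(0), species = character(0),
                          amount = numeric(0)), horizon = horizon)
}

# independent oracle: equilibrium extent x of A+B <-> C+D from the
# quadratic detailed-balance condition kf (A0-x)(B0-x) = kb (C0+x)(D0+x),
# found by root bracketing (no reliance on the ODE path)
equilibriumExtentOracle <- function(kf, kb, A0, B0, C0 = 0, D0 = 0) {
  f <- function(x) kf * (A0 - x) * (B0 - x) - kb * (C0 + x) * (D0 + x)
  stats::uniroot(f, c(0, min(A0, B0)), tol = 1e-12)$root
}

# conservation totals of every unbroken group along a trajectory, as the
# worst drift relative to the trajectory's own first time point (doses at
# t = 0 legitimately shift totals relative to the undosed network)
groupDrift <- function(network, traj) {
  cc <- concentrations(traj)
  vapply(Filter(function(g) !g$broken, conservationGroups(network)),
         function(g) {
           tot <- as.vector(cc[, names(g$weights), drop = FALSE] %*%
                              g$weights)
           max(abs(tot - tot[1])) / max(abs(tot[1]), 1)
         }, 0)
}
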