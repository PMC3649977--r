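# A tiny search problem built on the cascade fixture: the observed behavior
# is that the end product crosses 30 molecules within 6 h ("PC" true), which
# the reference parameters achieve; mis-setting the middle rate k2 breaks it.
cascadeProblem <- function(k2Factor = 1) {
  fx <- makeFixture("mini-cascade")
  net <- fx$network
  parameters(net) <- c(k2 = parameters(net)[["k2"]] * k2Factor)
  fB <- parseFormula("ev(Ba > 30)")
  fC <- parseFormula("ev(Ca > 30)")
  predict <- function(params) {
    tr <- simulateNetwork(net, horizon = 6, gridStep = 0.5,
                          paramOverrides = params)
    rB <- robustnessAt(fB, tr, 0)
    rC <- robustnessAt(fC, tr, 0)
    data.frame(line = "toy", property = c("PB", "PC"),
               robustness = c(rB, rC), satisfied = c(rB, rC) > 0,
               stringsAsFactors = FALSE)
  }
  # both the intermediate and the end product are observed to accumulate;
  # only restoring k2 can reproduce both
  obs <- toyObservations(list(list("toy", "PB", "true"),
                              list("toy", "PC", "true")))
  list(net = net, predict = predict, obs = obs)
}

test_that("penalty components reproduce their closed-form arithmetic", {
  obs <- observationTable()
  sc <- scoreableEntries(obs)
  pred <- data.frame(line = sc$line, property = sc$property,
                     robustness = ifelse(sc$observed, 0.3, -0.3),
                     satisfied = sc$observed)
  expect_equal(booleanPenalty(pred, obs), -16)
  allWrong <- pred
  allWrong$satisfied <- !pred$satisfied
  expect_equal(booleanPenalty(allWrong, obs), 0)
  threeOff <- pred
  threeOff$satisfied[1:3] <- !threeOff$satisfied[1:3]
  expect_equal(booleanPenalty(threeOff, obs), -13)

  # an entry observed true with rho 0.3 contributes -0.3; observed false
  # with rho -0.3 also contributes -0.3 (rewarded)
  w1 <- c(P1 = 1, P2 = 1, P3 = 1)
  expect_equal(continuousPenalty(pred, obs, w1), -16 * 0.3)
  # flipping one robustness sign changes the total by 2 w |rho|
  flip <- pred
  flip$robustness[5] <- -flip$robustness[5]
  expect_equal(continuousPenalty(flip, obs, w1) - continuousPenalty(pred, obs, w1),
               2 * 0.3)
  # Boolean penalty ignores magnitudes; continuous ignores Boolean flips
  bigger <- pred
  bigger$robustness <- bigger$robustness * 100
  expect_equal(booleanPenalty(bigger, obs), booleanPenalty(pred, obs))
  flippedBool <- pred
  flippedBool$satisfied <- !flippedBool$satisfied
  expect_equal(continuousPenalty(flippedBool, obs, w1),
               continuousPenalty(pred, obs, w1))
})

test_that("the parameter penalty is an absolute log10 fold-change sum with bounds", {
  ref <- c(a = 2, b = 0.5, c = 1)
  expect_equal(parameterPenalty(ref, ref), 0)
  expect_equal(parameterPenalty(c(a = 20, b = 0.5, c = 1), ref), 1)
  p <- c(a = 2 * 2.71, b = 0.5 / 55.6, c = 1)
  expect_equal(parameterPenalty(p, ref), abs(log10(2.71)) + abs(log10(55.6)),
               tolerance = 1e-12)
  expect_equal(parameterPenalty(p, ref), 2.178, tolerance = 1e-3)
  expect_error(parameterPenalty(c(a = 300, b = 0.5, c = 1), ref,
                                foldBound = 100), "outside")
})

test_that("the cost decomposes exactly into its weighted components", {
  pr <- cascadeProblem(k2Factor = 0.02)
  cs <- costSpec(pr$predict, pr$obs, parameters(pr$net),
                 freeParams = c("k1", "k2", "k3"))
  for (fac in list(c(k2 = 1), c(k2 = 10), c(k1 = 0.5, k3 = 2))) {
    params <- parameters(pr$net)
    params[names(fac)] <- params[names(fac)] * fac
    cv <- evaluateCost(params, cs)
    expect_equal(cv$total, cs$wB * cv$B + cs$wC * cv$C + cs$wP * cv$P)
  }
  # weight calibration puts the components near the 50/30/20 shares at start:
  # the Boolean range (2 entries) maps to 0.5, the box-expected parameter
  # penalty to 0.2
  expect_equal(cs$wB * 2, 0.5, tolerance = 1e-9)
  expect_equal(cs$wP * 3 * log10(100) / 2, 0.2, tolerance = 1e-9)
})

test_that("the search restores consistency of a mis-set cascade within 200 evaluations", {
  pr <- cascadeProblem(k2Factor = 0.02)   # fifty-fold too slow
  cs <- costSpec(pr$predict, pr$obs, parameters(pr$net),
                 freeParams = c("k1", "k2", "k3"))
  refCost <- evaluateCost(parameters(pr$net), cs)
  expect_false(refCost$consistent)
  res <- phase1Search(cs, budget = 200, seed = 7)
  expect_true(res$cost$consistent)
  expect_lte(res$consistentAt, 200)
  expect_lt(res$cost$total, refCost$total)
  # the best-so-far trace is monotone
  expect_true(all(diff(res$trace) <= 0))
  # seeded repeatability: identical trajectory
  res2 <- phase1Search(cs, budget = 200, seed = 7)
  expect_identical(res$trace, res2$trace)
  expect_identical(res$par, res2$par)
  expect_false(identical(phase1Search(cs, budget = 200, seed = 8)$trace,
                         res$trace))
})

test_that("phase 2 returns a minimal single-parameter revision for the cascade", {
  pr <- cascadeProblem(k2Factor = 0.02)
  cs <- costSpec(pr$predict, pr$obs, parameters(pr$net),
                 freeParams = c("k1", "k2", "k3"))
  p1 <- phase1Search(cs, budget = 300, seed = 3)
  expect_true(p1$cost$consistent)
  p2 <- phase2MinimalSubset(cs, p1, foldThreshold = 5, budget = 120, seed = 3)
  expect_true(p2$consistent)
  expect_length(p2$subset, 1)
  expect_equal(p2$subset, "k2")
  # never a superset of the phase-1 changed parameters
  expect_true(all(p2$subset %in% p2$candidates))
  expect_true(all(p2$candidates %in% names(which(abs(p1$foldChanges) > log10(5)))))
  # the recovered rate moves up substantially toward the reference value
  expect_gt(p2$foldChanges[["k2"]], log10(5))
})

test_that("candidate pairs are enumerated after singletons", {
  cand <- c("kc9", "kc25", "kc20", "k7", "k24")
  subsets <- c(lapply(cand, identity), utils::combn(cand, 2L, simplify = FALSE))
  expect_length(subsets, 5 + 10)   # C(5,2) = 10 pairs
  sizes <- lengths(subsets)
  expect_true(!is.unsorted(sizes))
})
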