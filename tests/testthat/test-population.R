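test_that("lognormal draws reproduce the nominal means and stated CVs", {
  net <- buildEarm()
  H <- earmCellLines(net)$H
  pop <- samplePopulation(net, H, n = 5000, seed = 11)
  d <- populationDraws(pop)
  # arithmetic-mean convention: mean = nominal within 3 standard errors
  seXIAP <- 30000 * 0.52 / sqrt(5000)
  expect_lt(abs(mean(d[, "XIAP"]) - 30000), 3 * seXIAP)
  expect_equal(sd(d[, "pC3"]) / mean(d[, "pC3"]), 0.32, tolerance = 0.05)
  # unstated CVs fall back to 25%
  expect_equal(sd(d[, "Bid"]) / mean(d[, "Bid"]), 0.25, tolerance = 0.05)
  expect_true(all(d > 0))
})

test_that("zero-nominal species stay exactly zero and seeds give bit-identical draws", {
  net <- buildEarm()
  HX <- earmCellLines(net)$HX
  pop <- samplePopulation(net, HX, n = 50, seed = 3)
  expect_true(all(populationDraws(pop)[, "XIAP"] == 0))
  pop2 <- samplePopulation(net, HX, n = 50, seed = 3)
  expect_identical(populationDraws(pop), populationDraws(pop2))
  pop3 <- samplePopulation(net, HX, n = 50, seed = 4)
  expect_false(identical(populationDraws(pop), populationDraws(pop3)))
})

test_that("population statistics summarize per-cell robustness correctly", {
  fx <- makeFixture("linear-decay")
  net <- fx$network
  line <- cellLine("decay", init = c(A = 100), cv = c(A = 0.3))
  pop <- samplePopulation(net, line, n = 60, seed = 5)
  # A(6) = A0 exp(-0.6); threshold 10 is satisfied by every draw
  f <- parseFormula("ev(B > 10)")
  st <- evaluatePopulation(net, pop, f, trailDose = NULL, horizon = 6,
                           gridStep = 1)
  expect_equal(st$pctSatisfied, 100)
  expect_equal(st$nConditioned, 60)
  expect_true(st$q1 <= st$median && st$median <= st$q3)
  expect_equal(st$median, median(st$robustness))

  # conditioning only filters cells, never changes retained values
  cond <- parseFormula("alw(A < 140)")
  stC <- evaluatePopulation(net, pop, f, condition = cond, trailDose = NULL,
                            horizon = 6, gridStep = 1)
  expect_lt(stC$nConditioned, 60)
  expect_true(all(stC$robustness %in% st$robustness))
  expect_error(
    evaluatePopulation(net, pop, f, condition = parseFormula("alw(A < 0)"),
                       trailDose = NULL, horizon = 6, gridStep = 1),
    "no cells retained")
})

test_that("percent-satisfaction sampling error scales as sqrt(p(1-p)/n)", {
  fx <- makeFixture("linear-decay")
  net <- fx$network
  line <- cellLine("decay", init = c(A = 100), cv = c(A = 0.3))
  # A0 > 100.2 <=> A(6) > 55: p is near 1/2 for lognormal(mean 100, cv 0.3)
  f <- parseFormula("ev(A < 55)")
  pct <- function(n, seed) {
    pop <- samplePopulation(net, line, n = n, seed = seed)
    evaluatePopulation(net, pop, f, trailDose = NULL, horizon = 6,
                       gridStep = 3)$pctSatisfied / 100
  }
  seeds <- 1:10
  for (n in c(100, 400)) {
    ps <- vapply(seeds, function(s) pct(n, s), 0)
    p <- mean(ps)
    expected <- sqrt(p * (1 - p) / n)
    expect_gt(sd(ps), expected / 3)
    expect_lt(sd(ps), expected * 3)
  }
})

test_that("the nominal cell's robustness lies within the sampled distribution", {
  net <- buildEarm()
  lines <- earmCellLines(net)
  f <- makeP1()
  for (nm in c("H", "HB")) {
    tr <- simulateNetwork(net, lines[[nm]], trailDose = 50, horizon = 6,
                          gridStep = 1 / 20)
    nominal <- robustnessAt(f, tr, 0)
    pop <- samplePopulation(net, lines[[nm]], n = 40, seed = 9)
    st <- evaluatePopulation(net, pop, f, trailDose = 50, horizon = 6,
                             gridStep = 1 / 20)
    expect_gte(nominal, min(st$robustness))
    expect_lte(nominal, max(st$robustness))
  }
})

test_that("the batch report covers every line-property pair with populated fields", {
  net <- buildEarm()
  lines <- earmCellLines(net)[c("H", "HB")]
  rep <- populationReport(net, lines, c("P1", "P3"), n = 12, seed = 2,
                          gridStep = 1 / 10)
  expect_equal(nrow(rep), 4)
  expect_true(all(c("line", "property", "n", "nConditioned", "mean", "q1",
                    "median", "q3", "pctSatisfied") %in% names(rep)))
  expect_true(all(is.finite(rep$mean)))
  expect_true(all(rep$nConditioned <= rep$n))
  # P3 conditioning (MOMP occurred and cell died) excludes HB survivors
  expect_lt(rep$nConditioned[rep$line == "HB" & rep$property == "P3"], 12)
})
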