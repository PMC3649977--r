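test_that("overlay crosses place lines at mean +/- standard deviation", {
  net <- buildEarm()
  lines <- earmCellLines(net)
  ov <- overlayPositions(lines[c("H", "S", "HX")], "XIAP", "pC3", net)
  expect_equal(ov$x[ov$line == "H"], 30000)
  expect_equal(ov$dx[ov$line == "H"], 30000 * 0.52)
  expect_equal(ov$y[ov$line == "S"], 886000)
  expect_equal(ov$dy[ov$line == "S"], 886000 * 0.31)
  expect_equal(ov$x[ov$line == "HX"], 0)      # XIAP deletion
  expect_equal(ov$dx[ov$line == "HX"], 0)
  expect_error(overlayPositions(lines["H"], "XIAP", "nosuch", net),
               "missing from the network")
})

test_that("slice specifications validate ranges and expose the printed defaults", {
  net <- buildEarm()
  H <- earmCellLines(net)$H
  s <- sliceSpec("XIAP", "pC3", refLine = H)
  expect_equal(s$xRange, c(0, 6e4))
  expect_equal(s$yRange, c(0, 1e6))
  expect_equal(sliceSpec("pC8", "flip", refLine = H)$xRange, c(1200, 4500))
  expect_equal(sliceSpec("pC8", "flip", refLine = H)$yRange, c(0, 800))
  expect_error(sliceSpec("Bid", "pC3", refLine = H), "no default range")
  expect_equal(sliceSpec("Bid", "pC3", refLine = H,
                         xRange = c(0, 1e5))$xRange, c(0, 1e5))
})

test_that("each diagram cell reproduces a pointwise simulate-and-monitor call", {
  fx <- makeFixture("two-state-switch")
  net <- fx$network
  line <- cellLine("toy")
  slice <- sliceSpec("A", "B", refLine = line, xRange = c(10, 90),
                     yRange = c(10, 90), n = 2)
  f <- parseFormula("ev[5,5](A > 50)")  # A near its high state after transient
  dg <- stlDiagram(net, slice, f, trailDose = NULL, horizon = 5,
                   gridStep = 0.5)
  vals <- diagramValues(dg)
  for (i in 1:2) for (j in 1:2) {
    tr <- simulateNetwork(net, line, horizon = 5, gridStep = 0.5,
                          init = c(A = dg@x[i], B = dg@y[j]))
    expect_identical(vals[i, j], robustnessAt(f, tr, 0))
  }
  # sign structure of the competition: the initially-dominant species wins
  expect_gt(vals[2, 1], 0)
  expect_lt(vals[1, 2], 0)
})

test_that("DLE matches linear closed forms to 1e-6 and vanishes for frozen dynamics", {
  lin <- reactionNetwork(
    data.frame(name = "X", role = "native", init = 1),
    list(rxn("forward", c(X = 1L), c(X = 2L), c(kf = "a"))),
    c(a = 0.5))
  expect_equal(dle(lin, t = 2, rtol = 1e-12, atol = 1e-12), 0.5,
               tolerance = 1e-6)
  expect_equal(dle(lin, t = 2, method = "sens", rtol = 1e-12, atol = 1e-12),
               0.5, tolerance = 1e-6)

  di <- reactionNetwork(
    data.frame(name = c("X", "Y"), role = "native", init = c(1, 1)),
    list(rxn("forward", c(X = 1L), c(X = 2L), c(kf = "a1")),
         rxn("forward", c(Y = 1L), c(Y = 2L), c(kf = "a2"))),
    c(a1 = 0.2, a2 = 0.7))
  expect_equal(dle(di, t = 3, rtol = 1e-12, atol = 1e-12), 0.7,
               tolerance = 1e-6)

  frozen <- lin
  parameters(frozen) <- c(a = 0)
  expect_equal(dle(frozen, t = 2, rtol = 1e-12, atol = 1e-12), 0,
               tolerance = 1e-6)

  # contraction gives a negative exponent (pure degradation X -> 0)
  dec <- reactionNetwork(
    data.frame(name = "X", role = "native", init = 1),
    list(rxn("forward", c(X = 1L),
             stats::setNames(integer(0), character(0)), c(kf = "d"))),
    c(d = 0.3))
  v <- dle(dec, t = 2, rtol = 1e-12, atol = 1e-12)
  expect_lt(v, 0)
  expect_true(is.finite(v))
})

test_that("the bistable fixture's DLE ridge separates the two basins", {
  fx <- makeFixture("two-state-switch")
  net <- fx$network
  line <- cellLine("toy")
  slice <- sliceSpec("A", "B", refLine = line, xRange = c(20, 60),
                     yRange = c(20, 60), n = 5)
  dg <- dleDiagram(net, slice, t = 8, trailDose = NULL, lines = list())
  vals <- diagramValues(dg)
  # on this symmetric slice the separatrix is the diagonal A0 = B0: the DLE
  # maximum of each row must sit where the basin flips
  for (i in 1:5) {
    basins <- vapply(1:5, function(j) fx$reference$basin(dg@x[i], dg@y[j]), "")
    flip <- which(basins[-1] != basins[-5])
    if (!length(flip)) next
    ridge <- which.max(vals[i, ])
    expect_lte(abs(ridge - (flip[1] + 0.5)), 1)
  }
})
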