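test_that("robustness matches hand-computed values on constant and ramp traces", {
  tr <- constTrace(5)
  expect_equal(robustnessAt(parseFormula("alw[0,6](x > 3)"), tr, 0), 2)
  expect_equal(robustnessAt(parseFormula("not (x > 3)"), tr, 0), -2)

  # x(t) = t sampled every 0.5 h on [0,6]: sup over samples of x - 3 is 3
  times <- seq(0, 6, by = 0.5)
  ramp <- timedTrace(times, cbind(x = times))
  expect_equal(robustnessAt(parseFormula("ev(x > 3)"), ramp, 0), 3)

  # release whose trigger never holds equals the global minimum of the
  # released operand: rho(MOMP) = -0.2 throughout, rho(alive) = +0.3
  tr2 <- timedTrace(times, cbind(momp = rep(0.2, 13), alive = rep(0.3, 13)))
  f <- parseFormula("momp > 0.4 release alive > 0")
  expect_equal(robustnessAt(f, tr2, 0), 0.3)
})

test_that("satisfies reports sign verdicts and flags exact-zero boundaries", {
  tr <- constTrace(5)
  expect_true(satisfies(parseFormula("x > 3"), tr))
  expect_false(satisfies(parseFormula("x > 7"), tr))
  b <- satisfies(parseFormula("x > 5"), tr)
  expect_false(as.logical(b))
  expect_true(isTRUE(attr(b, "boundary")))
})

test_that("windows beyond the horizon are empty and raise errors at evaluation", {
  tr <- constTrace(1, Tf = 2)
  expect_error(robustnessAt(parseFormula("ev[3,4](x > 0)"), tr, 0),
               "empty evaluation window")
  # in the signal, such instants are NA while valid instants are finite
  sig <- robustnessSignal(parseFormula("ev[1,1.5](x > 0)"), tr)
  v <- channelValues(sig, "rho")
  expect_true(all(is.finite(v[traceTimes(tr) <= 1 + 1e-9])))
  expect_true(all(is.na(v[traceTimes(tr) > 1 + 1e-9])))
  expect_error(robustnessAt(parseFormula("x > 0"), tr, 0.123),
               "not a sample instant")
  expect_error(robustnessAt(parseFormula("z > 0"), tr, 0), "absent")
})

test_that("the survival property's signal is the running minimum of the alive signal", {
  # cPARP fraction rising through 0.5: alive signal decreases and crosses zero
  times <- seq(0, 6, by = 0.1)
  frac <- 1 / (1 + exp(-(times - 3) * 3))
  tr <- timedTrace(times, cbind(cPARP_frac = frac))
  alive <- robustnessSignal(parseFormula("cPARP_frac < 0.5"), tr)
  av <- channelValues(alive, "rho")
  expect_true(av[1] > 0 && av[length(av)] < 0)
  expect_true(all(diff(av) < 0))
  crossing <- times[which(av < 0)[1]]
  expect_equal(crossing, times[which(frac > 0.5)[1]])

  p1sig <- channelValues(robustnessSignal(makeP1(propertySpec()), tr), "rho")
  manual <- vapply(seq_along(times), function(i) {
    js <- which(times >= times[i] & times <= pmin(times[i] + 6, 6) + 1e-9)
    min(av[js])
  }, 0)
  expect_equal(p1sig, manual)
})

test_that("quantitative semantics agree with the brute-force oracle on random cases", {
  set.seed(101)
  for (k in 1:120) {
    tr <- randomTrace(n = sample(c(15, 30, 60), 1))
    f <- randomFormula(maxDepth = 3)
    times <- traceTimes(tr); ch <- traceChannels(tr)
    sig <- channelValues(robustnessSignal(f, tr), "rho")
    for (i in sample(seq_along(times), 4)) {
      expect_equal(sig[i], bruteRho(f, times, ch, i), tolerance = 1e-12)
    }
  }
})

test_that("robustness sign always agrees with the independent Boolean semantics", {
  set.seed(202)
  boundary <- 0L
  for (k in 1:150) {
    tr <- randomTrace(n = 25)
    f <- randomFormula(maxDepth = 3)
    rho <- channelValues(robustnessSignal(f, tr), "rho")[1]
    if (is.na(rho)) next
    if (rho == 0) { boundary <- boundary + 1L; next }
    expect_identical(rho > 0,
                     as.logical(apopSTL:::satisfiesBoolean(f, tr)))
  }
  expect_lt(boundary, 5L)  # exact zeros are measure-zero on random traces
})

test_that("negation, always/eventually and release/until dualities hold numerically", {
  set.seed(303)
  for (k in 1:60) {
    tr <- randomTrace(n = 30)
    g <- randomFormula(maxDepth = 2)
    h <- randomFormula(maxDepth = 2)
    iv <- c(0, stats::runif(1, 1, 8))
    eqSig <- function(a, b)
      expect_equal(traceChannels(robustnessSignal(a, tr)),
                   traceChannels(robustnessSignal(b, tr)), tolerance = 1e-12)
    eqSig(stlNot(g), stlNot(g))
    # rho(not g) = -rho(g)
    expect_equal(channelValues(robustnessSignal(stlNot(g), tr), "rho"),
                 -channelValues(robustnessSignal(g, tr), "rho"))
    # alw_I g = not ev_I not g
    eqSig(stlAlw(g, iv), stlNot(stlEv(stlNot(g), iv)))
    # g R h = not (not g U not h)
    eqSig(stlRelease(g, h, iv),
          stlNot(stlUntil(stlNot(g), stlNot(h), iv)))
  }
})

test_that("shifting a predicate threshold shifts robustness by exactly the offset", {
  set.seed(404)
  for (k in 1:25) {
    tr <- randomTrace(n = 30)
    c0 <- stats::runif(1, -2, 2)
    delta <- stats::runif(1, 0.1, 1)
    for (wrap in list(identity,
                      function(p) stlAlw(p, c(0, 5)),
                      function(p) stlEv(p, c(1, 4)))) {
      r0 <- channelValues(robustnessSignal(wrap(stlPred("x", ">", c0)), tr), "rho")
      r1 <- channelValues(robustnessSignal(wrap(stlPred("x", ">", c0 + delta)), tr), "rho")
      expect_equal(r1, r0 - delta)
    }
  }
})

test_that("pointwise dominance on a positively-occurring channel never lowers robustness", {
  set.seed(505)
  for (k in 1:30) {
    trB <- randomTrace(n = 30)
    offset <- stats::runif(1, 0.1, 2)
    chA <- traceChannels(trB)
    chA[, "x"] <- chA[, "x"] + offset
    trA <- timedTrace(traceTimes(trB), chA)
    f <- randomFormula(maxDepth = 3, positiveOnly = TRUE)
    rA <- channelValues(robustnessSignal(f, trA), "rho")
    rB <- channelValues(robustnessSignal(f, trB), "rho")
    ok <- !is.na(rA) & !is.na(rB)
    expect_true(all(rA[ok] >= rB[ok] - 1e-12))
  }
})
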