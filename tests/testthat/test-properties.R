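test_that("the three property builders honor their thresholds, delay and horizon", {
  expect_equal(formatFormula(makeP1(propertySpec())),
               "alw[0,6](cPARP_frac < 0.5)")
  expect_equal(formatFormula(makeP1(propertySpec(alpha = 0.1))),
               "alw[0,6](cPARP_frac < 0.1)")
  expect_equal(makeP1(propertySpec(horizon = 4))@interval, c(0, 4))
  p2 <- makeP2(propertySpec())
  expect_equal(p2@kind, "ev")
  expect_equal(p2@subs[[1]]@subs[[2]]@interval, c(0, 1))
  expect_equal(makeP2(propertySpec(delay = 1.5))@subs[[1]]@subs[[2]]@interval,
               c(0, 1.5))
  expect_equal(p2@subs[[1]]@subs[[1]]@threshold, 0.01)
  p3 <- makeP3(propertySpec())
  expect_equal(p3@kind, "release")
  expect_equal(p3@subs[[1]]@threshold, 0.5)
  expect_error(propertySpec(alpha = 1.2), "alpha")
  expect_error(makeProperty("P9"), "unknown property")
})

test_that("property verdicts on hand-built traces follow the release/ev semantics", {
  times <- seq(0, 6, by = 0.1)
  spec <- propertySpec()
  # caspase-8 never activates: the sequence property fails
  quiet <- timedTrace(times, cbind(C8act_frac = rep(0.001, length(times)),
                                   C3act_frac = rep(0.0, length(times))))
  expect_lt(robustnessAt(makeP2(spec), quiet, 0), 0)

  # MOMP never occurs and the cell stays alive: MOMP-gating holds for any beta
  alive <- timedTrace(times, cbind(Apaf_free_frac = rep(1, length(times)),
                                   cPARP_frac = rep(0.05, length(times))))
  for (b in c(0.1, 0.5, 0.9))
    expect_gt(robustnessAt(makeP3(propertySpec(beta = b)), alive, 0), 0)

  # death strictly before MOMP violates the gating property
  early <- timedTrace(times, cbind(
    Apaf_free_frac = ifelse(times < 4, 1, 0.1),
    cPARP_frac = ifelse(times < 2, 0.1, 0.9)))
  f <- makeP3(spec)
  expect_lt(robustnessAt(f, early, 0), 0)
  expect_equal(robustnessAt(f, early, 0),
               bruteRho(f, times, traceChannels(early), 1))
})

test_that("the bundled observation table has exactly 16 scoreable entries", {
  obs <- observationTable()
  expect_equal(nrow(obs), 36)  # 12 lines x 3 properties
  sc <- scoreableEntries(obs)
  expect_equal(nrow(sc), 16)
  expect_true(all(substr(sc$line, 1, 1) %in% c("H", "S")))
  expect_true(all(obs$value[substr(obs$line, 1, 1) == "T"] == "mixed"))
  # text-derivable cross-checks on individual entries
  val <- function(l, p) obs$value[obs$line == l & obs$property == p]
  expect_equal(val("H", "P2"), "true")
  expect_equal(val("HX", "P3"), "true")
  expect_equal(val("HB", "P1"), "true")
  expect_equal(val("HBX", "P3"), "false")
  expect_equal(val("S", "P2"), "false")
  expect_equal(val("SB", "P2"), "false")
  expect_equal(val("SX", "P1"), "false")
})

test_that("countMatches scores perfect agreement and flags specific mismatches", {
  obs <- observationTable()
  sc <- scoreableEntries(obs)
  perfect <- data.frame(line = sc$line, property = sc$property,
                        robustness = ifelse(sc$observed, 1, -1),
                        satisfied = sc$observed)
  cm <- countMatches(perfect, obs)
  expect_equal(cm$nMatch, 16)
  expect_equal(nrow(cm$mismatches), 0)

  flipped <- perfect
  i <- which(flipped$line == "H" & flipped$property == "P2")
  flipped$satisfied[i] <- FALSE
  cm2 <- countMatches(flipped, obs)
  expect_equal(cm2$nMatch, 15)
  expect_equal(cm2$mismatches$line, "H")
  expect_equal(cm2$mismatches$property, "P2")

  expect_error(countMatches(perfect[-1, ], obs), "missing prediction")
})

test_that("a degenerate threshold sweep reduces to a single consistency count", {
  net <- buildEarm()
  lines <- earmCellLines(net)[c("H", "HX")]
  obs <- toyObservations(list(list("H", "P1", "false"),
                              list("H", "P2", "true"),
                              list("HX", "P3", "false")))
  sweep <- thresholdSweep(net, lines, obs, alpha = 0.5, beta = 0.5,
                          gamma = 0.01, gridStep = 1 / 20)
  expect_equal(nrow(sweep), 1)
  pred <- classifyLines(net, lines, gridStep = 1 / 20)
  expect_equal(sweep$nMatch, countMatches(pred, obs)$nMatch)
})
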