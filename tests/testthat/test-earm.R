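test_that("the transcription's censuses match the model's documented structure", {
  net <- buildEarm()
  cs <- parameterCensus(net)
  expect_equal(cs$nSpecies, 58)          # 17 native + 40 complexes + ligand
  expect_equal(cs$nNative, 17)
  expect_length(net@reactions, 28)
  expect_length(apopSTL:::elementaryReactions(net), 70)
  expect_equal(cs$nCatalytic, 14)
  expect_equal(cs$nSearchable, cs$nForward + cs$nCatalytic)
  expect_setequal(cs$searchable,
                  c(sprintf("k%d", 1:28),
                    sprintf("kc%d", c(1, 3, 5:10, 12, 19:21, 23, 25))))
  expect_equal(cs$nParams, cs$nForward + cs$nReverse + cs$nCatalytic)
})

test_that("measured initial concentrations and CVs are bundled exactly", {
  lines <- earmCellLines()
  H <- lines$H; S <- lines$S; T <- lines$T
  expect_equal(nominalConcentrations(H)[["XIAP"]], 30000)
  expect_equal(variationCoefficients(H)[["XIAP"]], 0.52)
  expect_equal(nominalConcentrations(H)[["pC3"]], 100000)
  expect_equal(variationCoefficients(H)[["pC3"]], 0.32)
  expect_equal(nominalConcentrations(S)[["pC3"]], 886000)
  expect_equal(variationCoefficients(S)[["pC3"]], 0.31)
  expect_equal(nominalConcentrations(S)[["XIAP"]], 11400)
  expect_equal(variationCoefficients(S)[["XIAP"]], 0.42)
  expect_equal(nominalConcentrations(T)[["Bcl2c"]], 4640)  # Mcl1 pool
  expect_equal(nominalConcentrations(H)[["Bcl2"]], 20000)
  expect_equal(H@defaultCV, 0.25)
  expect_named(lines, c("H", "HX", "HB", "HBX", "S", "SX", "SB", "SBX",
                        "T", "TX", "TB", "TBX"))
})

test_that("variants modify the documented quantities and compose in any order", {
  net <- buildEarm()
  H <- earmCellLines(net)$H
  expect_equal(nominalConcentrations(applyVariant(H, "dXIAP", net))[["XIAP"]], 0)
  expect_equal(nominalConcentrations(applyVariant(H, "oeBcl2", net))[["Bcl2"]],
               200000)   # 10 x 20000
  expect_equal(parameters(applyVariant(H, "dFB", net))[["k7"]], 0)
  ab <- applyVariant(applyVariant(H, "oeBcl2", net), "dXIAP", net)
  ba <- applyVariant(applyVariant(H, "dXIAP", net), "oeBcl2", net)
  expect_equal(sort(nominalConcentrations(ab)),
               sort(nominalConcentrations(ba)))
  expect_error(applyVariant(H, "bogus", net), "unknown variant")
})

test_that("the published revision scales the feedback and PARP-cleavage rates", {
  net <- buildEarm()
  rev <- revisedParameters(net)
  k <- parameters(net)
  expect_equal(rev[["k7"]] / k[["k7"]], 2.71)
  expect_equal(k[["kc9"]] / rev[["kc9"]], 55.6)
})

test_that("feedback deletion equalizes early caspase-8 activation across lines", {
  # with k7 = 0 the downstream difference between HCT116 and SKW6.4 no longer
  # feeds back on initiator-caspase activation
  net <- buildEarm()
  lines <- earmCellLines(net)
  tr <- lapply(list(H = lines$H, S = lines$S), function(ln)
    simulateNetwork(net, applyVariant(ln, "dFB", net), trailDose = 50,
                    horizon = 3, gridStep = 0.25))
  c8H <- channelValues(tr$H, "C8act_frac")
  c8S <- channelValues(tr$S, "C8act_frac")
  trH <- simulateNetwork(net, lines$H, trailDose = 50, horizon = 3,
                         gridStep = 0.25)
  trS <- simulateNetwork(net, lines$S, trailDose = 50, horizon = 3,
                         gridStep = 0.25)
  gapFB <- max(abs(c8H - c8S))
  gapWT <- max(abs(channelValues(trH, "C8act_frac") -
                   channelValues(trS, "C8act_frac")))
  expect_lt(gapFB, gapWT)
})
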