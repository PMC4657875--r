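pheno <- issPhenotypeMatrix()

test_that("growth prediction reads the susceptibility matrix correctly", {
  expect_identical(predictGrowth(pheno, "37C.Ct200"), "Bm")
  expect_setequal(predictGrowth(pheno, "37C.Tp100"), c("Ss", "Sp", "Bc"))
  expect_setequal(predictGrowth(pheno, "30C.Gm25"),
                  c("Cm", "Cg", "Bm", "Bc"))
  # slow growth promoted to growth widens the set
  expect_true(all(predictGrowth(pheno, "37C.Tp100") %in%
                  predictGrowth(pheno, "37C.Tp100", TRUE)))
  expect_true("Rp" %in% predictGrowth(pheno, "37C.Tp100", TRUE))
  # P. myrsianacearum is scored off the 37C no-selection plate
  expect_false("Pm" %in% predictGrowth(pheno, "37C.none"))
  expect_error(predictGrowth(pheno, "25C.none"), "unknown plating condition")
  # untested combinations raise rather than silently default
  expect_error(predictGrowth(pheno, "30C.PIA"), "unknown")
})

test_that("the default scheme identifies all nine species; colony class is load-bearing", {
  idc <- identifiabilityCheck(pheno, defaultPlatingScheme())
  expect_true(idc$identifiable)
  expect_length(idc$ambiguous, 0)
  # without colony appearance, C. gleum collides with C. metallidurans
  idc2 <- identifiabilityCheck(pheno, defaultPlatingScheme(),
                               useColonyClass = FALSE)
  expect_false(idc2$identifiable)
  collides <- vapply(idc2$ambiguous, function(g) "Cg" %in% g, TRUE)
  expect_setequal(idc2$ambiguous[collides][[1]], c("Cg", "Cm"))
})

test_that("a single undiscriminating condition leaves everyone ambiguous", {
  idc <- identifiabilityCheck(pheno, "30C.none", useColonyClass = FALSE)
  expect_false(idc$identifiable)
  expect_length(idc$ambiguous, 1)
  expect_length(idc$ambiguous[[1]], 9)
  expect_error(identifiabilityCheck(pheno, character(0)), "at least one")
})

test_that("toy three-species system resolves by back-substitution", {
  # truth p = (0.5, 0.3, 0.2); plates: total {Aa,Bb,Cc}, cond1 {Aa,Bb},
  # cond2 {Aa}; Cc has its own colony class.
  # Hand solve: Aa = cond2 white = 500; Bb = cond1 white - Aa = 300;
  # Cc = total blue = 200.
  truth <- c(Aa = 0.5, Bb = 0.3, Cc = 0.2)
  obs <- simulatePlateCounts(truth, toyPheno(), c("total", "cond1", "cond2"),
                             noiseModel(countTotal = 1000), exact = TRUE)
  est <- resolveComposition(obs, toyPheno())
  expect_equal(speciesProportions(est), truth, tolerance = 1e-12)
})

test_that("the full scheme recovers simulated compositions exactly at zero noise", {
  panel <- defaultSpeciesPanel()
  quiet <- noiseModel(compositionCV = 0)
  for (members in list(abbrev(panel), setdiff(abbrev(panel), "Cg"),
                       setdiff(abbrev(panel), "Bm"))) {
    comp <- simulateEndpointComposition(panel, members,
                                        defaultInteractionMatrix(), quiet)
    obs <- simulatePlateCounts(comp, pheno, defaultPlatingScheme(),
                               noiseModel(), exact = TRUE)
    est <- resolveComposition(obs, pheno)
    expect_equal(speciesProportions(est), speciesProportions(comp),
                 tolerance = 1e-9)
  }
})

test_that("resolved counts conserve the no-selection plate total at zero noise", {
  truth <- c(Aa = 0.5, Bb = 0.3, Cc = 0.2)
  obs <- simulatePlateCounts(truth, toyPheno(), c("total", "cond1", "cond2"),
                             noiseModel(countTotal = 1000), exact = TRUE)
  est <- resolveComposition(obs, toyPheno())
  totalPlate <- sum(obs$count[obs$condition == "total"])
  expect_equal(sum(speciesProportions(est)) * totalPlate, totalPlate)
})

test_that("multinomial resolution is unbiased within Monte-Carlo error", {
  ec <- endpointComposition()
  truth <- setNames(ec$pct_full / sum(ec$pct_full), ec$abbrev)
  nRep <- 400
  ests <- withr::with_seed(21, {
    replicate(nRep, {
      obs <- simulatePlateCounts(truth, pheno, defaultPlatingScheme(),
                                 noiseModel(countTotal = 500))
      speciesProportions(resolveComposition(obs, pheno))
    })
  })
  m <- rowMeans(ests)
  se <- apply(ests, 1, sd) / sqrt(nRep)
  # 3 SE per species to keep the joint false-alarm rate low
  expect_true(all(abs(m - truth[names(m)]) < 3 * pmax(se, 1e-4)))
})

test_that("standard errors shrink with count depth like multinomial theory", {
  truth <- c(Aa = 0.5, Bb = 0.3, Cc = 0.2)
  conds <- c("total", "cond1", "cond2")
  obsS <- simulatePlateCounts(truth, toyPheno(), conds,
                              noiseModel(countTotal = 100), exact = TRUE)
  obsL <- simulatePlateCounts(truth, toyPheno(), conds,
                              noiseModel(countTotal = 10000), exact = TRUE)
  seS <- proportionSE(resolveComposition(obsS, toyPheno(), conds))
  seL <- proportionSE(resolveComposition(obsL, toyPheno(), conds))
  expect_equal(unname(seS / seL), rep(10, 3), tolerance = 1e-9)
  expect_equal(seS[["Aa"]], sqrt(0.5 * 0.5 / 100))
})

test_that("an unidentifiable or rank-deficient scheme refuses to resolve", {
  truth <- c(Aa = 0.5, Bb = 0.3, Cc = 0.2)
  # total plate alone: Aa and Bb share growth pattern and colony class
  obsT <- simulatePlateCounts(truth, toyPheno(), "total",
                              noiseModel(countTotal = 1000), exact = TRUE)
  expect_error(resolveComposition(obsT, toyPheno(), "total"),
               "does not identify")
  # cond1+cond2: signatures distinct but Cc is never measured
  obsR <- simulatePlateCounts(truth, toyPheno(), c("cond1", "cond2"),
                              noiseModel(countTotal = 1000), exact = TRUE)
  expect_error(resolveComposition(obsR, toyPheno(), c("cond1", "cond2")),
               "rank deficient")
})

test_that("grossly inconsistent counts are rejected", {
  obs <- simulatePlateCounts(c(Aa = 0.5, Bb = 0.3, Cc = 0.2), toyPheno(),
                             c("total", "cond1", "cond2"),
                             noiseModel(countTotal = 1000), exact = TRUE)
  # claim far more colonies on the Aa-only plate than Aa can account for
  obs$count[obs$condition == "cond2" & obs$colony_class == "white"] <- 5000
  expect_error(resolveComposition(obs, toyPheno()), "inconsistent")
})
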