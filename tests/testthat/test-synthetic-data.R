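panel <- defaultSpeciesPanel()
im <- defaultInteractionMatrix()
quiet <- noiseModel(activityCV = 0, compositionCV = 0)

test_that("equal fitness, neutral interactions, zero noise give uniform proportions", {
  p <- defaultSpeciesPanel()
  p@fitness[] <- 1
  comp <- simulateEndpointComposition(p, abbrev(p), noise = quiet)
  expect_equal(unname(speciesProportions(comp)[abbrev(p)]), rep(1 / 9, 9))
})

test_that("zero-noise default community reproduces the measured endpoint compositions", {
  ec <- endpointComposition()
  full <- simulateEndpointComposition(panel, abbrev(panel), im, quiet)
  expect_equal(speciesProportions(full)[ec$abbrev],
               setNames(ec$pct_full / sum(ec$pct_full), ec$abbrev),
               tolerance = 1e-12)
  expect_equal(unname(speciesProportions(full)[["Cg"]]), 0.2776, tolerance = 0.005)

  noCg <- simulateEndpointComposition(panel, setdiff(abbrev(panel), "Cg"),
                                      im, quiet)
  expect_identical(unname(speciesProportions(noCg)[["Cg"]]), 0)
  # releasing Cg raises B. cepacia above its full-mix share
  expect_gt(speciesProportions(noCg)[["Bc"]],
            speciesProportions(full)[["Bc"]])
})

test_that("compositions sum to one, excluded species are exactly zero, and seeds reproduce", {
  for (members in list(c("Rp", "Cg"), c("Ss", "Bm", "Bc", "Sp"))) {
    c1 <- simulateEndpointComposition(panel, members, im,
                                      noiseModel(compositionCV = 0.3),
                                      seed = 11)
    c2 <- simulateEndpointComposition(panel, members, im,
                                      noiseModel(compositionCV = 0.3),
                                      seed = 11)
    expect_identical(c1, c2)
    p <- speciesProportions(c1)
    expect_equal(sum(p), 1, tolerance = 1e-9)
    expect_identical(unname(p[setdiff(abbrev(panel), members)]),
                     rep(0, 9 - length(members)))
  }
  expect_error(simulateEndpointComposition(panel, character(0)),
               "degenerate")
})

test_that("raising a species' fitness never lowers its endpoint share (neutral interactions)", {
  base <- defaultSpeciesPanel()
  for (f in c(0.5, 1, 2, 5)) {
    p2 <- base
    p2@fitness["Pm"] <- base@fitness[["Pm"]] * f
    lo <- speciesProportions(simulateEndpointComposition(base, abbrev(base),
                                                         noise = quiet))
    hi <- speciesProportions(simulateEndpointComposition(p2, abbrev(p2),
                                                         noise = quiet))
    if (f >= 1) expect_gte(hi[["Pm"]], lo[["Pm"]])
    else expect_lte(hi[["Pm"]], lo[["Pm"]])
  }
})

test_that("single-species forward signals invert to the intrinsic activity exactly", {
  for (sp in c("Cg", "Bc")) {
    comp <- setNames(as.numeric(abbrev(panel) == sp), abbrev(panel))
    sig <- simulateAssayReadouts(panel, paste0(sp, "-alone"), comp, quiet,
                                 nReplicates = 2, od600 = 0.3)
    act <- convertSignals(sig)
    for (e in enzymeClasses())
      expect_equal(act$activity[act$enzyme == e],
                   rep(intrinsicActivity(panel)[sp, e], 2),
                   tolerance = 1e-12)
  }
})

test_that("zero regulation silences every mixture signal down to blank", {
  reg <- setNames(rep(0, 4), enzymeClasses())
  sig <- simulateAssayReadouts(panel, "Mix",
                               setNames(rep(1 / 9, 9), abbrev(panel)),
                               quiet, nReplicates = 2, regulation = reg,
                               regulationModifiers = list())
  expect_equal(sig$signal_end, sig$signal_start, tolerance = 1e-15)
})

test_that("lognormal activity noise lands near its nominal CV", {
  comp <- setNames(as.numeric(abbrev(panel) == "Bc"), abbrev(panel))
  sig <- simulateAssayReadouts(panel, "Bc-alone", comp,
                               noiseModel(activityCV = 0.2),
                               nReplicates = 9, seed = 4)
  act <- convertSignals(sig)
  cvs <- vapply(split(act$activity, act$enzyme),
                function(x) sd(x) / mean(x), 0)
  # n = 9 per class: wide Monte-Carlo band around 0.2
  expect_true(all(cvs > 0.05 & cvs < 0.45))
  # pooled across the four classes the estimate tightens
  expect_gt(mean(cvs), 0.1)
  expect_lt(mean(cvs), 0.3)
  expect_error(noiseModel(activityCV = -1), "non-negative")
})

test_that("plate counts: monoculture plates carry a single colony class", {
  pheno <- issPhenotypeMatrix()
  comp <- setNames(as.numeric(abbrev(panel) == "Cg"), abbrev(panel))
  counts <- simulatePlateCounts(comp, pheno, "30C.none", noiseModel(),
                                seed = 2)
  expect_equal(sum(counts$count[counts$colony_class != "orange"]), 0)
  expect_equal(sum(counts$count), 900)
})

test_that("plate counts match multinomial expectations on the no-selection plate", {
  pheno <- issPhenotypeMatrix()
  unif <- setNames(rep(1 / 9, 9), abbrev(panel))
  draws <- withr::with_seed(9, {
    replicate(400, {
      ct <- simulatePlateCounts(unif, pheno, "30C.none", noiseModel())
      setNames(ct$count, ct$colony_class)
    })
  })
  m <- rowMeans(draws)
  # classes: orange = Cg, rough = Ri, white = remaining 7 of 9
  expect_equal(m[["orange"]], 100, tolerance = 0.05)
  expect_equal(m[["rough"]], 100, tolerance = 0.05)
  expect_equal(m[["white"]], 700, tolerance = 0.02)
})

test_that("cetrimide at 37C yields only B. multivorans colonies from the full mix", {
  pheno <- issPhenotypeMatrix()
  full <- speciesProportions(
    simulateEndpointComposition(panel, abbrev(panel), im, quiet))
  counts <- simulatePlateCounts(full, pheno, "37C.Ct200", noiseModel(),
                                seed = 5)
  expect_identical(predictGrowth(pheno, "37C.Ct200"), "Bm")
  expect_equal(sum(counts$count[counts$colony_class != "white"]), 0)
  # expected plate total scales with Bm's share of the community
  exact <- simulatePlateCounts(full, pheno, "37C.Ct200", noiseModel(),
                               exact = TRUE)
  expect_equal(sum(exact$count), 900 * full[["Bm"]], tolerance = 1e-12)
})

test_that("a condition nobody grows on is flagged as a zero-count observation", {
  g <- matrix(0L, 2, 1, dimnames = list(c("Aa", "Bb"), "hot"))
  pheno <- PhenotypeMatrix(g, data.frame(condition = "hot", temp = 50,
                                         supplement = "none"),
                           c(Aa = "white", Bb = "white"))
  ct <- simulatePlateCounts(c(Aa = 0.5, Bb = 0.5), pheno, "hot",
                            noiseModel(), seed = 1)
  expect_true(all(ct$no_growth))
  expect_equal(sum(ct$count), 0)
})

test_that("writeSyntheticData emits the three TSVs plus provenance, deterministically", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeSyntheticData(d1, noise = noiseModel(seed = 3L), nReplicates = 2)
  writeSyntheticData(d2, noise = noiseModel(seed = 3L), nReplicates = 2)
  files <- c("monoculture_activities.tsv", "community_signals.tsv",
             "plate_counts.tsv", "provenance.json")
  for (f in files) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})
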