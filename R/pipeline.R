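#' Study run configuration
#'
#' Collects every tunable of an end-to-end simulated study. Defaults
#' are the stated conditions of the nine-member community study: 0.05
#' OD600 per member, 9 replicates (three experiments of three), 20%
#' activity CV, 10% composition CV, 900 countable colonies per full
#' plate, family-wise alpha 0.05, and the literal-divide null-model
#' convention with input-proportion weighting.
#'
#' @param seed integer seed driving all randomness of the run.
#' @param nReplicates assay replicates per design and enzyme.
#' @param nCompositionReplicates replicate platings for the Mix vs -Cg
#'   composition comparison.
#' @param perMemberOD OD600 inoculum per member.
#' @param activityCV,compositionCV,countTotal noise settings
#'   (\linkS4class{NoiseModel}).
#' @param exactCounts use noiseless expected plate counts (the
#'   zero-noise limit for parameter-recovery checks).
#' @param mixingRule,regulation,regulationModifiers community activity
#'   generator settings (see \code{\link{communityActivity}}).
#' @param convention,weighting null-model settings.
#' @param alpha family-wise significance level.
#' @param constants \code{\link{assayConstants}}.
#' @param outDir optional directory to write the TSV report bundle.
#' @return list of class "study_config" with a \code{hash} field.
#' @export
studyConfig <- function(seed = 1L, nReplicates = 9,
                        nCompositionReplicates = 3, perMemberOD = 0.05,
                        activityCV = 0.2, compositionCV = 0.1,
                        countTotal = 900, exactCounts = FALSE,
                        mixingRule = "regulated_setpoint",
                        regulation = defaultRegulation(),
                        regulationModifiers = defaultRegulationModifiers(),
                        convention = "literal_divide",
                        weighting = "input_proportions", alpha = 0.05,
                        constants = assayConstants(), outDir = NULL) {
  cfg <- list(seed = as.integer(seed), nReplicates = nReplicates,
              nCompositionReplicates = nCompositionReplicates,
              perMemberOD = perMemberOD, activityCV = activityCV,
              compositionCV = compositionCV, countTotal = countTotal,
              exactCounts = exactCounts, mixingRule = mixingRule,
              regulation = regulation,
              regulationModifiers = regulationModifiers,
              convention = convention,
              weighting = weighting, alpha = alpha, constants = constants,
              outDir = outDir)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "outDir")])
  class(cfg) <- "study_config"
  cfg
}

#' Run the full simulated study
#'
#' Simulates the complete experiment from one seed and analyzes it with
#' the package's own pipeline: endpoint compositions for every design,
#' raw assay signals and their conversion to activities, selective
#' plating and composition deconvolution for all mixture designs,
#' diversity indices for the full mix and the -Cg community, the
#' null-model expected-versus-measured table (input-proportion and
#' endpoint-proportion weighted), many-to-one Dunnett comparisons of
#' every dropout against the full mix per enzyme, the per-enzyme
#' robustness verdicts, and the Sidak-adjusted Mix vs -Cg composition
#' contrasts. Deterministic given \code{config$seed}.
#'
#' @param config a \code{\link{studyConfig}}.
#' @return list with elements designs, activities, compositions
#'   (resolved \linkS4class{CompositionEstimate}s per mixture design),
#'   diversity, nullmodel, stats (per-enzyme Dunnett tables), verdicts,
#'   composition_test, characterization and config. If
#'   \code{config$outDir} is set, the tables are also written as TSVs
#'   with a provenance JSON.
#' @export
#' @examples
#' \donttest{
#' res <- runStudy(studyConfig(seed = 1))
#' res$verdicts
#' }
runStudy <- function(config = studyConfig()) {
  stopifnot(inherits(config, "study_config"))
  panel <- defaultSpeciesPanel()
  interactions <- defaultInteractionMatrix()
  noise <- noiseModel(config$activityCV, config$compositionCV,
                      config$countTotal, config$seed)
  designs <- buildDesigns(abbrev(panel), config$perMemberOD)
  ids <- designIds(designs)
  roles <- designRoles(designs)
  members <- designMembers(designs)
  mixIds <- ids[roles %in% c("mix", "dropout")]
  pheno <- issPhenotypeMatrix()
  scheme <- defaultPlatingScheme()

  withr::with_seed(config$seed, {
    # every replicate is its own well with its own endpoint composition,
    # so composition noise enters the within-group variance rather than
    # biasing a whole design
    signals <- do.call(rbind, lapply(ids, function(d)
      do.call(rbind, lapply(seq_len(config$nReplicates), function(r) {
        comp <- simulateEndpointComposition(panel, members[[d]],
                                            interactions, noise)
        s <- simulateAssayReadouts(panel, d, comp, noise, 1,
                                   constants = config$constants,
                                   mixingRule = config$mixingRule,
                                   regulation = config$regulation,
                                   regulationModifiers = config$regulationModifiers,
                                   interactions = interactions)
        s$replicate <- r
        s
      }))))
    activities <- convertSignals(signals, config$constants)

    resolved <- lapply(mixIds, function(d) {
      comp <- simulateEndpointComposition(panel, members[[d]],
                                          interactions, noise)
      counts <- simulatePlateCounts(comp, pheno, scheme, noise,
                                    exact = config$exactCounts)
      resolveComposition(counts, pheno, scheme)
    })
    names(resolved) <- mixIds

    compReps <- lapply(c("Mix", "-Cg"), function(d) {
      t(vapply(seq_len(config$nCompositionReplicates), function(r) {
        comp <- simulateEndpointComposition(panel, members[[d]],
                                            interactions, noise)
        counts <- simulatePlateCounts(comp, pheno, scheme, noise,
                                      exact = config$exactCounts)
        speciesProportions(resolveComposition(counts, pheno, scheme))
      }, setNames(numeric(length(panel)), abbrev(panel))))
    })
    names(compReps) <- c("Mix", "-Cg")
  })

  # zero-noise configurations have no within-group variance; the
  # variance-based comparisons are then undefined and reported empty
  degenerateNull <- function(e) {
    if (grepl("zero|degenerate", conditionMessage(e))) NULL else stop(e)
  }
  compositionTest <- tryCatch(
    sidakCompositionTest(compReps[["Mix"]], compReps[["-Cg"]]),
    error = degenerateNull)

  div <- do.call(rbind, lapply(c("Mix", "-Cg"), function(d)
    cbind(design_id = d,
          diversityReport(speciesProportions(resolved[[d]])))))

  nm <- rbind(
    nullModelTable(activities, designs, config$convention,
                   "input_proportions"),
    nullModelTable(activities, designs, config$convention,
                   "endpoint_proportions", resolved))

  dropIds <- ids[roles == "dropout"]
  statTabs <- lapply(enzymeClasses(), function(e) {
    ae <- activities[activities$enzyme == e &
                     activities$design_id %in% mixIds, ]
    groups <- split(ae$activity, ae$design_id)[c("Mix", dropIds)]
    tryCatch(dunnettVsReference(groups, "Mix", config$alpha),
             error = degenerateNull)
  })
  names(statTabs) <- enzymeClasses()
  statTabs <- Filter(Negate(is.null), statTabs)
  verdicts <- if (length(statTabs)) {
    classifyRobustness(statTabs, config$alpha, dropIds)
  } else {
    data.frame(enzyme = character(0), robust = logical(0),
               offending = character(0), stringsAsFactors = FALSE)
  }

  res <- list(designs = designs, activities = activities,
              compositions = resolved, diversity = div, nullmodel = nm,
              stats = statTabs, verdicts = verdicts,
              composition_test = compositionTest,
              characterization = communityCharacterization(),
              config = config)
  if (!is.null(config$outDir)) .writeStudyBundle(res, config)
  res
}

.writeStudyBundle <- function(res, config) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f)
    utils::write.table(x, file.path(config$outDir, f), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wt(as.data.frame(res$designs), "designs.tsv")
  wt(res$activities, "activities.tsv")
  comp <- do.call(rbind, lapply(names(res$compositions), function(d) {
    ce <- res$compositions[[d]]
    data.frame(design_id = d, species = names(speciesProportions(ce)),
               proportion = unname(speciesProportions(ce)),
               se = unname(proportionSE(ce)),
               pct = 100 * unname(speciesProportions(ce)))
  }))
  wt(comp, "composition.tsv")
  wt(res$diversity, "diversity.tsv")
  wt(res$nullmodel, "nullmodel.tsv")
  if (length(res$stats))
    wt(do.call(rbind, lapply(names(res$stats), function(e)
      cbind(enzyme = e, res$stats[[e]]))), "stats_fig_activity.tsv")
  if (!is.null(res$composition_test))
    wt(res$composition_test, "stats_composition.tsv")
  wt(res$verdicts, "robustness_verdicts.tsv")
  wt(res$characterization, "characterization.tsv")
  prov <- config[setdiff(names(config),
                         c("constants", "outDir", "regulationModifiers"))]
  prov$regulation <- as.list(prov$regulation)
  jsonlite::write_json(prov, file.path(config$outDir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(NULL)
}

#' Recompute the community's headline characterization numbers
#'
#' From the bundled endpoint composition table and the design
#' constants: Shannon index and Pielou equitability of the full-mix and
#' -Cg endpoint communities (renormalized percentages), Simpson
#' concentration for both, Reed's-law interaction capacity and the
#' pair-plus-triple interaction count for nine members, the full-mix
#' total inoculation OD600, and the per-species inoculum CFU/ml.
#'
#' @return data.frame(quantity, value).
#' @export
#' @examples
#' communityCharacterization()
communityCharacterization <- function() {
  full <- .referenceProportions("full")
  noCg <- .referenceProportions("noCg")
  Hf <- shannonIndex(full); Hn <- shannonIndex(noCg)
  data.frame(
    quantity = c("shannon_full", "equitability_full", "simpson_lambda_full",
                 "shannon_noCg", "equitability_noCg", "simpson_lambda_noCg",
                 "interaction_capacity_9", "k23_interactions_9",
                 "mix_total_od", "inoculum_cfu_per_ml"),
    value = c(Hf, equitability(Hf, sum(full > 0)), simpsonIndex(full),
              Hn, equitability(Hn, sum(noCg > 0)), simpsonIndex(noCg),
              interactionCapacity(9), kSubsetInteractions(9, 2, 3),
              sum(totalOD(buildDesigns(names(full)))[["Mix"]]),
              inoculumCFU(0.05, 2e9)),
    stringsAsFactors = FALSE
  )
}
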