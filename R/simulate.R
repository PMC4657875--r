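# lognormal multiplicative noise with mean 1 and the given CV;
# cv = 0 returns exactly 1 so the zero-noise limit is bit-exact
.lognoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sigma2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -sigma2 / 2, sqrt(sigma2)))
}

.withSeed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

#' Simulate the endpoint composition of a community design
#'
#' Endpoint proportions are proportional to each member's fitness times
#' the product of interaction modifiers exerted by the other members
#' present, perturbed by multiplicative lognormal noise
#' (\code{compositionCV}) and renormalized. Species not in the design
#' get exactly 0.
#'
#' @param panel a \linkS4class{SpeciesPanel}.
#' @param members character vector of member codes (subset of the panel).
#' @param interactions an \linkS4class{InteractionMatrix} (default
#'   neutral).
#' @param noise a \linkS4class{NoiseModel}.
#' @param seed optional integer seed for this draw (local RNG scope).
#' @return A \linkS4class{CompositionEstimate} over all panel species
#'   (excluded species have proportion exactly 0).
#' @export
#' @examples
#' panel <- defaultSpeciesPanel()
#' comp <- simulateEndpointComposition(panel, abbrev(panel),
#'   defaultInteractionMatrix(), noiseModel(compositionCV = 0))
#' round(speciesProportions(comp)["Cg"], 3)  # ~0.277
simulateEndpointComposition <- function(panel, members,
                                        interactions = neutralInteractions(abbrev(panel)),
                                        noise = noiseModel(),
                                        seed = NULL) {
  if (length(members) == 0) stop("degenerate community: empty design")
  if (!all(members %in% abbrev(panel)))
    stop("design members must be in the panel")
  e <- effects(interactions)
  w <- fitness(panel)[members]
  for (actor in members)
    w <- w * e[actor, members]
  .withSeed(seed, {
    w <- w * .lognoise(length(w), noise@compositionCV)
  })
  p <- setNames(numeric(length(panel)), abbrev(panel))
  p[members] <- w / sum(w)
  CompositionEstimate(p)
}

#' Community-level activity mixing rules
#'
#' The true per-OD activity of a mixed community is not specified by any
#' first-principles model; the generator exposes it as a pluggable rule
#' with three built-ins. \code{regulated_setpoint} (the default world)
#' encodes feedback-regulated production: every mixture settles at a
#' per-enzyme environment setpoint — the abundance-weighted mean
#' intrinsic activity of the zero-noise full community — times the
#' regulation factor, independent of which single member is absent;
#' actor-specific regulation modifiers (e.g. C. gleum halving the NPPC
#' factor while present) then carry the one non-robust interaction.
#' \code{regulated_mean} is the abundance-weighted mean of intrinsic
#' monoculture activities times the regulation factor, so output tracks
#' composition; \code{proportional_sum} is the regulation-free weighted
#' mean. Monocultures always return the intrinsic activity exactly.
#'
#' @param panel a \linkS4class{SpeciesPanel}.
#' @param proportions named proportions over design members (zeros allowed).
#' @param mixingRule "regulated_setpoint", "regulated_mean" or
#'   "proportional_sum".
#' @param regulation named per-enzyme factors in [0, 1]
#'   (\code{\link{defaultRegulation}}).
#' @param regulationModifiers list (enzyme -> named actor multipliers)
#'   applied to the regulation factor when the actor is present
#'   (\code{\link{defaultRegulationModifiers}}).
#' @param interactions \linkS4class{InteractionMatrix} used to compute
#'   the full-community setpoint composition (regulated_setpoint only).
#' @return Named vector of true activities per enzyme class.
#' @export
communityActivity <- function(panel, proportions,
                              mixingRule = c("regulated_setpoint",
                                             "regulated_mean",
                                             "proportional_sum"),
                              regulation = defaultRegulation(),
                              regulationModifiers = defaultRegulationModifiers(),
                              interactions = neutralInteractions(abbrev(panel))) {
  mixingRule <- match.arg(mixingRule)
  p <- proportions[proportions > 0]
  p <- p / sum(p)
  A <- intrinsicActivity(panel)[names(p), , drop = FALSE]
  wmean <- drop(crossprod(A, p))  # abundance-weighted mean per enzyme
  if (length(p) == 1 || mixingRule == "proportional_sum")
    return(wmean)
  if (any(regulation < 0) || any(regulation > 1))
    stop("regulation factors must lie in [0, 1]")
  reg <- regulation[names(wmean)]
  for (e in names(regulationModifiers)) {
    mod <- regulationModifiers[[e]]
    present <- intersect(names(mod), names(p))
    if (length(present))
      reg[e] <- reg[e] * prod(mod[present])
  }
  if (mixingRule == "regulated_mean") return(wmean * reg)
  # regulated_setpoint: environment-matched level of the full community
  full <- speciesProportions(simulateEndpointComposition(
    panel, abbrev(panel), interactions,
    noiseModel(activityCV = 0, compositionCV = 0)))
  setpoint <- drop(crossprod(intrinsicActivity(panel), full[abbrev(panel)]))
  setpoint[names(wmean)] * reg
}

#' Simulate raw plate-reader signals for one design
#'
#' The forward model of the assay module: the community's true per-OD
#' activity (from \code{\link{communityActivity}}) receives
#' multiplicative lognormal noise per replicate, then is converted to
#' the signal a plate reader would record — a Beer-Lambert A410 delta on
#' top of a substrate blank for the nitrophenyl substrates, and a
#' fluorescence gain over baseline autofluorescence for FITC-casein.
#'
#' @param panel a \linkS4class{SpeciesPanel}.
#' @param designId label recorded in the output.
#' @param composition a \linkS4class{CompositionEstimate} (or named
#'   proportion vector) consistent with the design.
#' @param noise a \linkS4class{NoiseModel}.
#' @param nReplicates replicates to draw (default 9 = 3 experiments x 3).
#' @param od600 measured culture OD used for normalization (default 0.45).
#' @param minutes colorimetric assay time (default 10).
#' @param proteaseHours FITC-casein incubation (default 4).
#' @param constants an \code{\link{assayConstants}} list.
#' @param mixingRule,regulation,regulationModifiers,interactions passed
#'   to \code{\link{communityActivity}}.
#' @param blankA410 substrate-only blank absorbance (default 0.05).
#' @param baselineRFU sample autofluorescence at t = 0 (default 400).
#' @param seed optional integer seed (local RNG scope).
#' @return data.frame(design_id, enzyme, replicate, signal_start,
#'   signal_end, minutes, od600); protease rows store minutes = hours x 60.
#' @export
simulateAssayReadouts <- function(panel, designId, composition,
                                  noise = noiseModel(), nReplicates = 9,
                                  od600 = 0.45, minutes = 10,
                                  proteaseHours = 4,
                                  constants = assayConstants(),
                                  mixingRule = "regulated_setpoint",
                                  regulation = defaultRegulation(),
                                  regulationModifiers = defaultRegulationModifiers(),
                                  interactions = neutralInteractions(abbrev(panel)),
                                  blankA410 = 0.05, baselineRFU = 400,
                                  seed = NULL) {
  p <- if (is(composition, "CompositionEstimate"))
    speciesProportions(composition) else composition
  truth <- communityActivity(panel, p, mixingRule, regulation,
                             regulationModifiers, interactions)
  enz <- enzymeClasses()
  out <- expand.grid(replicate = seq_len(nReplicates), enzyme = enz,
                     stringsAsFactors = FALSE)[, c(2, 1)]
  .withSeed(seed, {
    fac <- .lognoise(nrow(out), noise@activityCV)
  })
  a <- truth[out$enzyme] * fac
  isProt <- out$enzyme == "protease"
  start <- ifelse(isProt, baselineRFU, blankA410)
  delta <- numeric(nrow(out))
  delta[!isProt] <- activityToAbsorbance(a[!isProt], minutes, od600, constants)
  delta[isProt] <- a[isProt] * proteaseHours * od600
  data.frame(design_id = designId, enzyme = out$enzyme,
             replicate = out$replicate, signal_start = start,
             signal_end = start + delta,
             minutes = ifelse(isProt, proteaseHours * 60, minutes),
             od600 = od600, stringsAsFactors = FALSE)
}

#' Simulate selective-plate colony counts
#'
#' Emulates plating equal aliquots of the same community sample on each
#' condition: an aliquot that would yield \code{countTotal} colonies if
#' every species grew is plated, so a plate's colonies are a multinomial
#' draw of size \code{countTotal} over the species predicted to grow
#' there (\code{\link{predictGrowth}}) plus an unobserved
#' "does-not-grow" bin. Counts are binned by colony appearance class;
#' totals are therefore comparable across plates, which is what lets
#' \code{\link{resolveComposition}} couple them in one linear system.
#' Conditions on which no present species grows yield a zero-count
#' observation flagged \code{no_growth}.
#'
#' @param composition a \linkS4class{CompositionEstimate} or named
#'   proportion vector.
#' @param pheno a \linkS4class{PhenotypeMatrix}.
#' @param conditions character vector of condition ids to plate.
#' @param noise a \linkS4class{NoiseModel} (countTotal used).
#' @param slowCountsAsGrowth score "+" (slow) entries as growth.
#' @param exact if TRUE return the noiseless expected counts
#'   (real-valued) instead of a multinomial draw.
#' @param seed optional integer seed (local RNG scope).
#' @return data.frame(condition, colony_class, count, dilution_factor,
#'   no_growth).
#' @export
simulatePlateCounts <- function(composition, pheno, conditions,
                                noise = noiseModel(),
                                slowCountsAsGrowth = FALSE,
                                exact = FALSE, seed = NULL) {
  p <- if (is(composition, "CompositionEstimate"))
    speciesProportions(composition) else composition
  cls <- colonyClass(pheno)
  classes <- sort(unique(cls))
  res <- vector("list", length(conditions))
  .withSeed(seed, {
    for (i in seq_along(conditions)) {
      cond <- conditions[i]
      growers <- predictGrowth(pheno, cond, slowCountsAsGrowth)
      growers <- intersect(growers, names(p)[p > 0])
      tot <- sum(p[growers])
      counts <- setNames(numeric(length(classes)), classes)
      noGrowth <- length(growers) == 0 || tot <= 0
      if (!noGrowth) {
        draw <- if (exact) {
          noise@countTotal * p[growers]
        } else {
          probs <- c(p[growers], 1 - tot)
          stats::rmultinom(1, noise@countTotal, probs)[seq_along(growers), 1]
        }
        byClass <- tapply(draw, cls[growers], sum)
        counts[names(byClass)] <- byClass
      }
      res[[i]] <- data.frame(condition = cond, colony_class = classes,
                             count = unname(counts), dilution_factor = 1,
                             no_growth = noGrowth,
                             stringsAsFactors = FALSE, row.names = NULL)
    }
  })
  do.call(rbind, res)
}

#' Write a full synthetic dataset to disk
#'
#' Generates and writes the three TSVs a real study would produce —
#' \code{monoculture_activities.tsv} (raw monoculture signals),
#' \code{community_signals.tsv} (mix and dropout signals) and
#' \code{plate_counts.tsv} — plus \code{provenance.json} recording the
#' seed and generator parameters.
#'
#' @param dir output directory (created if needed).
#' @param panel,interactions,noise generator inputs (defaults as in the
#'   nine-member study).
#' @param nReplicates replicates per design and enzyme.
#' @param perMemberOD inoculation OD per member.
#' @param mixingRule,regulation,regulationModifiers community mixing
#'   rule settings.
#' @return Invisibly, the list of generated tables.
#' @export
writeSyntheticData <- function(dir, panel = defaultSpeciesPanel(),
                               interactions = defaultInteractionMatrix(),
                               noise = noiseModel(), nReplicates = 9,
                               perMemberOD = 0.05,
                               mixingRule = "regulated_setpoint",
                               regulation = defaultRegulation(),
                               regulationModifiers = defaultRegulationModifiers()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  designs <- buildDesigns(abbrev(panel), perMemberOD)
  pheno <- issPhenotypeMatrix()
  withr::with_seed(noise@seed, {
    sig <- lapply(seq_len(length(designs)), function(i) {
      m <- designMembers(designs)[[i]]
      comp <- simulateEndpointComposition(panel, m, interactions, noise)
      simulateAssayReadouts(panel, designIds(designs)[i], comp, noise,
                            nReplicates, mixingRule = mixingRule,
                            regulation = regulation,
                            regulationModifiers = regulationModifiers,
                            interactions = interactions)
    })
    signals <- do.call(rbind, sig)
    mono <- signals[grepl("-alone$", signals$design_id), ]
    comm <- signals[!grepl("-alone$", signals$design_id), ]
    fullComp <- simulateEndpointComposition(panel, abbrev(panel),
                                            interactions, noise)
    counts <- simulatePlateCounts(fullComp, pheno,
                                  defaultPlatingScheme(), noise)
  })
  utils::write.table(mono, file.path(dir, "monoculture_activities.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comm, file.path(dir, "community_signals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts, file.path(dir, "plate_counts.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- list(seed = noise@seed, activityCV = noise@activityCV,
               compositionCV = noise@compositionCV,
               countTotal = noise@countTotal, nReplicates = nReplicates,
               perMemberOD = perMemberOD, mixingRule = mixingRule,
               regulation = as.list(regulation))
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(monoculture = mono, community = comm, counts = counts))
}
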