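#' Bundled endpoint composition of the nine-member community
#'
#' Percent composition at 72 h (differential plating) of the full
#' community ("full") and of the community assembled without
#' C. gleum ("noCg"), with the published standard deviations.
#'
#' @return data.frame with columns species, abbrev, pct_full, sd_full,
#'   pct_noCg, sd_noCg. Columns sum to ~100 up to printed rounding.
#' @export
#' @examples
#' ec <- endpointComposition()
#' sum(ec$pct_full)
endpointComposition <- function() {
  utils::read.delim(system.file("extdata", "endpoint_composition.tsv",
                                package = "commrobust"),
                    stringsAsFactors = FALSE)
}

# renormalized proportion vectors from the bundled composition table
.referenceProportions <- function(which = c("full", "noCg")) {
  which <- match.arg(which)
  ec <- endpointComposition()
  p <- ec[[paste0("pct_", which)]]
  setNames(p / sum(p), ec$abbrev)
}

#' Default nine-species panel of drinking-water isolates
#'
#' Builds the default \linkS4class{SpeciesPanel} for the nine-member
#' model community (Rp, Cm, Cg, Ri, Ss, Bm, Pm, Sp, Bc). Intrinsic
#' monoculture activities are generator parameters chosen so that
#' S. sanguinis, B. multivorans and B. cepacia are the top three
#' producers of every enzyme class, as observed in monoculture assays.
#' Fitness weights equal the renormalized endpoint proportions of the
#' community grown without C. gleum (its presence effects live in
#' \code{\link{defaultInteractionMatrix}}), so that at zero noise the
#' simulated full-mix and -Cg endpoint compositions reproduce the
#' measured ones exactly. CFU/ml per OD600 is 2e9 for all species
#' (1e8 CFU/ml at the 0.05 inoculum) except C. gleum, 0.4 log10 units
#' lower.
#'
#' @return A \linkS4class{SpeciesPanel} of 9 species.
#' @export
#' @examples
#' panel <- defaultSpeciesPanel()
#' abbrev(panel)
defaultSpeciesPanel <- function() {
  ec <- endpointComposition()
  abb <- ec$abbrev
  act <- rbind(
    #       NPB  NPP NPPC protease
    Rp = c(  18,  12,   8,  900),
    Cm = c(  12,   8,   6,  600),
    Cg = c(  26,  24,  10, 1500),
    Ri = c(  22,  18,   9, 1000),
    Ss = c(  30,  28,  40, 1800),
    Bm = c(  32,  30,  38, 1900),
    Pm = c(  10,   6,   5,  500),
    Sp = c(  16,  14,  24,  900),
    Bc = c(  34,  32,  42, 2000)
  )
  colnames(act) <- enzymeClasses()
  act <- act[abb, , drop = FALSE]

  fit <- .referenceProportions("noCg")
  fit["Cg"] <- .referenceProportions("full")[["Cg"]]

  cfu <- setNames(rep(2e9, length(abb)), abb)
  cfu["Cg"] <- 2e9 * 10^(-0.4)

  cls <- setNames(rep("white", length(abb)), abb)
  cls["Cg"] <- "orange"
  cls["Ri"] <- "rough"

  SpeciesPanel(species = ec$species, abbrev = abb, intrinsicActivity = act,
               fitness = fit[abb], cfuPerOD = cfu[abb],
               colonyClass = cls[abb])
}

#' Default interaction matrix encoding the C. gleum presence effect
#'
#' All species pairs are neutral except the modifiers exerted by
#' C. gleum when present: its row equals the ratio of the renormalized
#' full-mix endpoint proportions to the -Cg endpoint proportions, so Cg
#' suppresses B. cepacia and both Sphingomonads (modifiers < 1) and its
#' removal releases them. Together with
#' \code{\link{defaultSpeciesPanel}} fitness weights, the zero-noise
#' endpoint simulator reproduces both measured compositions exactly.
#'
#' @return An \linkS4class{InteractionMatrix} over the nine species.
#' @export
defaultInteractionMatrix <- function() {
  full <- .referenceProportions("full")
  noCg <- .referenceProportions("noCg")
  abb <- names(full)
  im <- neutralInteractions(abb)
  e <- effects(im)
  others <- setdiff(abb, "Cg")
  e["Cg", others] <- full[others] / noCg[others]
  InteractionMatrix(e)
}

#' Default per-enzyme community regulation factors
#'
#' Multiplicative factors (<= 1) applied to the community activity
#' level when simulating mixed-community (not monoculture) assay
#' output. Values below 1 emulate community-level down-regulation of
#' secretion relative to monoculture capability; together with
#' \code{\link{defaultRegulationModifiers}} the effective NPPC factor
#' of Cg-containing mixtures is 0.35, reproducing the observation that
#' mixed communities hydrolyze NPPC far below the monoculture-based
#' expectation.
#'
#' @return Named numeric vector over \code{\link{enzymeClasses}}.
#' @export
defaultRegulation <- function() {
  c(NPB = 0.9, NPP = 0.85, NPPC = 0.7, protease = 0.6)
}

#' Default actor-specific regulation modifiers
#'
#' Presence effects on the regulation factor itself: while C. gleum is
#' in a mixture it halves the community's NPPC regulation factor
#' (0.7 -> 0.35), so its removal roughly doubles community NPPC
#' hydrolysis — a regulatory release that the accompanying rise of the
#' NPPC-producing species alone cannot account for.
#'
#' @return Named list (enzyme class -> named actor multipliers).
#' @export
defaultRegulationModifiers <- function() {
  list(NPPC = c(Cg = 0.5))
}
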