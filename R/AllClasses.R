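#' @import methods
NULL

#' Enzyme classes assayed by the pipeline
#'
#' The four secreted hydrolytic activities measured from community
#' supernatants: short-chain lipase (p-nitrophenyl butyrate, NPB),
#' long-chain lipase (p-nitrophenyl palmitate, NPP), choline-specific
#' phospholipase C (p-nitrophenyl phosphorylcholine, NPPC) and protease
#' (FITC-casein).
#'
#' @return Character vector of the four enzyme-class labels.
#' @export
#' @examples
#' enzymeClasses()
enzymeClasses <- function() c("NPB", "NPP", "NPPC", "protease")

#' SpeciesPanel: per-species traits of a model community
#'
#' Holds, for each community member, its full name, two-letter code,
#' intrinsic (monoculture) per-OD600 enzyme activities for the four
#' enzyme classes, a dimensionless competitive fitness weight, colony
#' forming units per ml at OD600 = 1, and a colony appearance class used
#' by differential plating.
#'
#' @slot species full species names.
#' @slot abbrev unique two-letter codes (e.g. "Cg").
#' @slot intrinsicActivity numeric matrix, species x enzyme class, of
#'   monoculture activities in nmol/ml/min/OD600 (protease in RFU/h/OD600).
#' @slot fitness non-negative competitive weights.
#' @slot cfuPerOD CFU/ml at OD600 = 1.0, strictly positive.
#' @slot colonyClass colony appearance labels ("orange", "rough", "white").
#'
#' @export
setClass("SpeciesPanel",
  representation(
    species = "character",
    abbrev = "character",
    intrinsicActivity = "matrix",
    fitness = "numeric",
    cfuPerOD = "numeric",
    colonyClass = "character"
  )
)

setValidity("SpeciesPanel", function(object) {
  n <- length(object@abbrev)
  msg <- character()
  if (length(object@species) != n || length(object@fitness) != n ||
      length(object@cfuPerOD) != n || length(object@colonyClass) != n)
    msg <- c(msg, "slot lengths differ")
  if (anyDuplicated(object@abbrev))
    msg <- c(msg, "abbrev codes must be unique")
  if (nrow(object@intrinsicActivity) != n)
    msg <- c(msg, "intrinsicActivity must have one row per species")
  if (!identical(rownames(object@intrinsicActivity), object@abbrev))
    msg <- c(msg, "intrinsicActivity rownames must equal abbrev")
  if (!all(enzymeClasses() %in% colnames(object@intrinsicActivity)))
    msg <- c(msg, "intrinsicActivity must cover all four enzyme classes")
  if (any(object@intrinsicActivity < 0))
    msg <- c(msg, "intrinsic activities must be >= 0")
  if (any(object@fitness < 0)) msg <- c(msg, "fitness must be >= 0")
  if (any(object@cfuPerOD <= 0)) msg <- c(msg, "cfuPerOD must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SpeciesPanel
#'
#' @param species full species names.
#' @param abbrev unique short codes.
#' @param intrinsicActivity species x enzyme matrix (rownames = abbrev).
#' @param fitness competitive weights (default 1 for all).
#' @param cfuPerOD CFU/ml at OD600 = 1 (default 2e9, i.e. 1e8 at OD 0.05).
#' @param colonyClass colony appearance labels (default "white").
#' @return A \linkS4class{SpeciesPanel}.
#' @export
SpeciesPanel <- function(species, abbrev, intrinsicActivity,
                         fitness = rep(1, length(abbrev)),
                         cfuPerOD = rep(2e9, length(abbrev)),
                         colonyClass = rep("white", length(abbrev))) {
  rownames(intrinsicActivity) <- abbrev
  names(fitness) <- names(cfuPerOD) <- names(colonyClass) <- abbrev
  new("SpeciesPanel", species = species, abbrev = abbrev,
      intrinsicActivity = intrinsicActivity, fitness = fitness,
      cfuPerOD = cfuPerOD, colonyClass = colonyClass)
}

#' InteractionMatrix: pairwise presence effects on endpoint abundance
#'
#' A square matrix of multiplicative modifiers: entry [actor, target] is
#' applied to the target's endpoint abundance whenever the actor is
#' present in the community. 1.0 is neutral; the diagonal is fixed at 1.
#' Removing an actor from a design removes its whole row of modifiers.
#'
#' @slot effects positive actor x target matrix with unit diagonal.
#' @export
setClass("InteractionMatrix", representation(effects = "matrix"))

setValidity("InteractionMatrix", function(object) {
  e <- object@effects
  msg <- character()
  if (nrow(e) != ncol(e)) msg <- c(msg, "effects must be square")
  if (!identical(rownames(e), colnames(e)))
    msg <- c(msg, "actor and target names must match")
  if (any(e <= 0)) msg <- c(msg, "all modifiers must be > 0")
  if (nrow(e) > 0 && any(abs(diag(e) - 1) > 1e-12))
    msg <- c(msg, "diagonal entries must be 1.0")
  if (length(msg)) msg else TRUE
})

#' @rdname InteractionMatrix-class
#' @param effects positive actor x target matrix, unit diagonal.
#' @return An \linkS4class{InteractionMatrix}.
#' @export
InteractionMatrix <- function(effects) new("InteractionMatrix", effects = effects)

#' Neutral interactions for a set of species
#' @param abbrev species codes.
#' @return An \linkS4class{InteractionMatrix} of all-ones.
#' @export
neutralInteractions <- function(abbrev) {
  e <- matrix(1, length(abbrev), length(abbrev),
              dimnames = list(abbrev, abbrev))
  InteractionMatrix(e)
}

#' NoiseModel: stochastic settings of the synthetic-data generator
#'
#' @slot activityCV coefficient of variation of multiplicative lognormal
#'   noise applied to assay activities (>= 0).
#' @slot compositionCV coefficient of variation of lognormal perturbation
#'   of endpoint abundances before renormalization (>= 0).
#' @slot countTotal total colonies counted per plating condition (>= 1).
#' @slot seed integer random seed.
#' @export
setClass("NoiseModel",
  representation(activityCV = "numeric", compositionCV = "numeric",
                 countTotal = "integer", seed = "integer")
)

setValidity("NoiseModel", function(object) {
  msg <- character()
  if (object@activityCV < 0) msg <- c(msg, "activityCV must be >= 0")
  if (object@compositionCV < 0) msg <- c(msg, "compositionCV must be >= 0")
  if (object@countTotal < 1L) msg <- c(msg, "countTotal must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname NoiseModel-class
#' @param activityCV,compositionCV,countTotal,seed see slots.
#' @return A \linkS4class{NoiseModel}.
#' @export
noiseModel <- function(activityCV = 0.2, compositionCV = 0.1,
                       countTotal = 900, seed = 1L) {
  if (activityCV < 0 || compositionCV < 0)
    stop("noise parameters must be non-negative")
  new("NoiseModel", activityCV = activityCV, compositionCV = compositionCV,
      countTotal = as.integer(countTotal), seed = as.integer(seed))
}

#' CommunityDesignSet: the study's inoculation designs
#'
#' An ordered collection of community designs: the full mix, the
#' single-species dropouts, and the monocultures. All members of a design
#' are inoculated at the same OD600.
#'
#' @slot designId design labels ("Mix", "-Cg", "Cg-alone", ...).
#' @slot role one of "mix", "dropout", "monoculture" per design.
#' @slot members list of character vectors of member codes.
#' @slot perMemberOD OD600 inoculum per member (scalar).
#' @export
setClass("CommunityDesignSet",
  representation(designId = "character", role = "character",
                 members = "list", perMemberOD = "numeric")
)

setValidity("CommunityDesignSet", function(object) {
  msg <- character()
  if (anyDuplicated(object@designId)) msg <- c(msg, "designId must be unique")
  if (length(object@role) != length(object@designId) ||
      length(object@members) != length(object@designId))
    msg <- c(msg, "slot lengths differ")
  if (!all(object@role %in% c("mix", "dropout", "monoculture")))
    msg <- c(msg, "unknown design role")
  if (any(vapply(object@members, length, 1L) == 0L))
    msg <- c(msg, "designs must have at least one member")
  if (any(vapply(object@members, anyDuplicated, 1L) > 0L))
    msg <- c(msg, "design members must be unique")
  if (length(object@perMemberOD) != 1L || object@perMemberOD <= 0)
    msg <- c(msg, "perMemberOD must be a positive scalar")
  if (length(msg)) msg else TRUE
})

#' PhenotypeMatrix: differential growth of species across plating conditions
#'
#' Growth levels are coded 0 (no apparent growth, "-"), 1 (slow growth,
#' "+") and 2 (normal growth, "++"), for each species under each plating
#' condition (a temperature x supplement pair).
#'
#' @slot growth integer matrix species x condition id, values in 0:2.
#' @slot conditions data.frame with columns condition, temp, supplement.
#' @slot colonyClass named colony appearance label per species.
#' @export
setClass("PhenotypeMatrix",
  representation(growth = "matrix", conditions = "data.frame",
                 colonyClass = "character")
)

setValidity("PhenotypeMatrix", function(object) {
  msg <- character()
  if (!identical(colnames(object@growth), object@conditions$condition))
    msg <- c(msg, "growth columns must match conditions table")
  if (!all(object@growth %in% c(0:2, NA)))
    msg <- c(msg, "growth levels must be 0, 1, 2 or NA (unknown)")
  if (!identical(sort(names(object@colonyClass)), sort(rownames(object@growth))))
    msg <- c(msg, "colonyClass must be named by species")
  if (length(msg)) msg else TRUE
})

#' @rdname PhenotypeMatrix-class
#' @param growth species x condition integer matrix (0/1/2).
#' @param conditions data.frame(condition, temp, supplement).
#' @param colonyClass named character of colony appearance per species.
#' @return A \linkS4class{PhenotypeMatrix}.
#' @export
PhenotypeMatrix <- function(growth, conditions, colonyClass) {
  new("PhenotypeMatrix", growth = growth, conditions = conditions,
      colonyClass = colonyClass)
}

#' CompositionEstimate: proportional abundances with standard errors
#'
#' @slot proportions named species proportions summing to 1.
#' @slot se named multinomial standard errors (NA when not derived from
#'   counts).
#' @export
setClass("CompositionEstimate",
  representation(proportions = "numeric", se = "numeric")
)

setValidity("CompositionEstimate", function(object) {
  msg <- character()
  if (is.null(names(object@proportions)))
    msg <- c(msg, "proportions must be named")
  if (any(object@proportions < 0)) msg <- c(msg, "proportions must be >= 0")
  if (abs(sum(object@proportions) - 1) > 1e-9)
    msg <- c(msg, "proportions must sum to 1 (+/- 1e-9)")
  if (!identical(names(object@proportions), names(object@se)))
    msg <- c(msg, "se must be named like proportions")
  if (length(msg)) msg else TRUE
})

#' @rdname CompositionEstimate-class
#' @param proportions named non-negative vector; renormalized to sum 1.
#' @param se named standard errors (defaults to NA).
#' @return A \linkS4class{CompositionEstimate}.
#' @export
CompositionEstimate <- function(proportions,
                                se = setNames(rep(NA_real_,
                                                  length(proportions)),
                                              names(proportions))) {
  s <- sum(proportions)
  if (s <= 0) stop("proportions must have positive sum")
  new("CompositionEstimate", proportions = proportions / s, se = se)
}
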