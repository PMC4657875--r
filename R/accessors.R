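#' @name accessors
#' @title Accessors for commrobust classes
#' @description Slot access for \linkS4class{SpeciesPanel},
#'   \linkS4class{InteractionMatrix}, \linkS4class{CommunityDesignSet},
#'   \linkS4class{PhenotypeMatrix} and \linkS4class{CompositionEstimate}.
#' @param x,object an object of the relevant class.
#' @param i index (abbrev codes or positions) for subsetting.
#' @param j,drop,... ignored.
NULL

setGeneric("abbrev", function(x) standardGeneric("abbrev"))
setGeneric("intrinsicActivity", function(x) standardGeneric("intrinsicActivity"))
setGeneric("fitness", function(x) standardGeneric("fitness"))
setGeneric("cfuPerOD", function(x) standardGeneric("cfuPerOD"))
setGeneric("colonyClass", function(x) standardGeneric("colonyClass"))
setGeneric("effects", function(x) standardGeneric("effects"))
setGeneric("designIds", function(x) standardGeneric("designIds"))
setGeneric("designRoles", function(x) standardGeneric("designRoles"))
setGeneric("designMembers", function(x) standardGeneric("designMembers"))
setGeneric("perMemberOD", function(x) standardGeneric("perMemberOD"))
setGeneric("totalOD", function(x) standardGeneric("totalOD"))
setGeneric("growthLevels", function(x) standardGeneric("growthLevels"))
setGeneric("platingConditions", function(x) standardGeneric("platingConditions"))
setGeneric("speciesProportions", function(x) standardGeneric("speciesProportions"))
setGeneric("proportionSE", function(x) standardGeneric("proportionSE"))

#' @rdname accessors
#' @export
setMethod("abbrev", "SpeciesPanel", function(x) x@abbrev)

#' @rdname accessors
#' @export
setMethod("intrinsicActivity", "SpeciesPanel", function(x) x@intrinsicActivity)

#' @rdname accessors
#' @export
setMethod("fitness", "SpeciesPanel", function(x) x@fitness)

#' @rdname accessors
#' @export
setMethod("cfuPerOD", "SpeciesPanel", function(x) x@cfuPerOD)

#' @rdname accessors
#' @export
setMethod("colonyClass", "SpeciesPanel", function(x) x@colonyClass)

#' @rdname accessors
#' @export
setMethod("colonyClass", "PhenotypeMatrix", function(x) x@colonyClass)

#' @rdname accessors
#' @export
setMethod("length", "SpeciesPanel", function(x) length(x@abbrev))

#' @rdname accessors
#' @export
setMethod("[", "SpeciesPanel", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@abbrev)
  SpeciesPanel(species = x@species[i], abbrev = x@abbrev[i],
               intrinsicActivity = x@intrinsicActivity[i, , drop = FALSE],
               fitness = x@fitness[i], cfuPerOD = x@cfuPerOD[i],
               colonyClass = x@colonyClass[i])
})

#' @rdname accessors
#' @export
setMethod("effects", "InteractionMatrix", function(x) x@effects)

#' @rdname accessors
#' @export
setMethod("designIds", "CommunityDesignSet", function(x) x@designId)

#' @rdname accessors
#' @export
setMethod("designRoles", "CommunityDesignSet", function(x) x@role)

#' @rdname accessors
#' @export
setMethod("designMembers", "CommunityDesignSet",
          function(x) setNames(x@members, x@designId))

#' @rdname accessors
#' @export
setMethod("perMemberOD", "CommunityDesignSet", function(x) x@perMemberOD)

#' @rdname accessors
#' @export
setMethod("totalOD", "CommunityDesignSet", function(x)
  setNames(x@perMemberOD * lengths(x@members), x@designId))

#' @rdname accessors
#' @export
setMethod("length", "CommunityDesignSet", function(x) length(x@designId))

#' @rdname accessors
#' @export
setMethod("[", "CommunityDesignSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@designId)
  new("CommunityDesignSet", designId = x@designId[i], role = x@role[i],
      members = x@members[i], perMemberOD = x@perMemberOD)
})

#' @rdname accessors
#' @export
setMethod("growthLevels", "PhenotypeMatrix", function(x) x@growth)

#' @rdname accessors
#' @export
setMethod("platingConditions", "PhenotypeMatrix", function(x) x@conditions)

#' @rdname accessors
#' @export
setMethod("speciesProportions", "CompositionEstimate", function(x) x@proportions)

#' @rdname accessors
#' @export
setMethod("proportionSE", "CompositionEstimate", function(x) x@se)

setMethod("show", "SpeciesPanel", function(object) {
  cat("SpeciesPanel with", length(object), "species:",
      paste(object@abbrev, collapse = " "), "\n")
  cat("  enzyme classes:", paste(colnames(object@intrinsicActivity),
                                 collapse = ", "), "\n")
})

setMethod("show", "InteractionMatrix", function(object) {
  e <- object@effects
  cat("InteractionMatrix over", nrow(e), "species;",
      sum(abs(e - 1) > 1e-12), "non-neutral modifiers\n")
})

setMethod("show", "CommunityDesignSet", function(object) {
  cat("CommunityDesignSet with", length(object), "designs (",
      sum(object@role == "mix"), "mix,",
      sum(object@role == "dropout"), "dropouts,",
      sum(object@role == "monoculture"), "monocultures ) at",
      object@perMemberOD, "OD600 per member\n")
})

setMethod("show", "PhenotypeMatrix", function(object) {
  cat("PhenotypeMatrix:", nrow(object@growth), "species x",
      ncol(object@growth), "plating conditions\n")
})

setMethod("show", "CompositionEstimate", function(object) {
  cat("CompositionEstimate over", length(object@proportions), "species\n")
  print(round(object@proportions, 4))
})

#' Designs as a data.frame
#'
#' Flatten a \linkS4class{CommunityDesignSet} into the `designs.tsv`
#' layout: one row per design with comma-separated members.
#'
#' @param x a CommunityDesignSet.
#' @param row.names,optional,... passed for generic compatibility, unused.
#' @return data.frame(design_id, role, members, per_member_od, total_od).
#' @export
as.data.frame.CommunityDesignSet <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  data.frame(
    design_id = x@designId,
    role = x@role,
    members = vapply(x@members, paste, "", collapse = ","),
    per_member_od = x@perMemberOD,
    total_od = x@perMemberOD * lengths(x@members),
    stringsAsFactors = FALSE
  )
}
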