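#' Enumerate study designs: full mix, dropouts, monocultures
#'
#' Builds the leave-one-out study layout for a community of N species:
#' one full mix, N single-species dropout communities, and N
#' monocultures (2N + 1 designs), in that fixed order. Every member of a
#' design is inoculated at the same OD600.
#'
#' @param species character vector (>= 2) of unique species codes.
#' @param perMemberOD OD600 inoculum per member (default 0.05).
#' @return A \linkS4class{CommunityDesignSet} of 2N + 1 designs with ids
#'   "Mix", "-<code>" and "<code>-alone".
#' @export
#' @examples
#' d <- buildDesigns(abbrev(defaultSpeciesPanel()))
#' length(d)          # 19
#' totalOD(d)["Mix"]  # 0.45
buildDesigns <- function(species, perMemberOD = 0.05) {
  if (length(species) < 2) stop("need at least 2 species")
  if (anyDuplicated(species)) stop("duplicate species codes")
  ids <- c("Mix", paste0("-", species), paste0(species, "-alone"))
  roles <- c("mix", rep("dropout", length(species)),
             rep("monoculture", length(species)))
  members <- c(list(species),
               lapply(species, function(s) setdiff(species, s)),
               lapply(species, function(s) s))
  new("CommunityDesignSet", designId = ids, role = roles,
      members = members, perMemberOD = perMemberOD)
}

#' Interaction capacity of a community (Reed's law)
#'
#' Number of distinct subgroups of size >= 2 that can form among n
#' members: 2^n - n - 1.
#'
#' @param n community size (>= 2).
#' @return Integer count of possible multi-member interaction sets.
#' @export
#' @examples
#' interactionCapacity(9) # 502
interactionCapacity <- function(n) {
  if (n < 2) stop("n must be >= 2")
  2^n - n - 1
}

#' Count k-membered interaction sets
#'
#' Number of subsets of size kMin..kMax of an n-member community,
#' sum of C(n, k). With the default bounds (pairs and triples) this is
#' the compromise between Reed's-law capacity and strictly pairwise
#' (Metcalfe) counting.
#'
#' @param n community size.
#' @param kMin,kMax subset-size bounds, 2 <= kMin <= kMax <= n.
#' @return Count of subsets.
#' @export
#' @examples
#' kSubsetInteractions(9) # 120
kSubsetInteractions <- function(n, kMin = 2, kMax = 3) {
  if (!(2 <= kMin && kMin <= kMax && kMax <= n))
    stop("require 2 <= kMin <= kMax <= n")
  sum(choose(n, kMin:kMax))
}

#' Inoculum density in CFU/ml
#'
#' @param perMemberOD inoculation OD600 (> 0).
#' @param cfuPerOD CFU/ml at OD600 = 1 (> 0).
#' @param log10 if TRUE report log10(CFU/ml).
#' @return CFU/ml (or its log10).
#' @export
#' @examples
#' inoculumCFU(0.05, 2e9) # 1e8
inoculumCFU <- function(perMemberOD, cfuPerOD, log10 = FALSE) {
  if (any(perMemberOD <= 0) || any(cfuPerOD <= 0))
    stop("perMemberOD and cfuPerOD must be > 0")
  x <- perMemberOD * cfuPerOD
  if (log10) base::log10(x) else x
}
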