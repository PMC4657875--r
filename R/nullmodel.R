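#' Expected mixture activity from monoculture activities
#'
#' Predicts the activity of a mixed community from the activities its
#' members produce in monoculture, weighted by their proportions, under
#' one of two conventions. \code{literal_divide} sums each monoculture
#' activity divided by the member's fractional proportion (1/9 for the
#' full mix, 1/8 for a dropout, or the measured endpoint proportion):
#' E = sum A_i / p_i. \code{proportional_sum} is the conservative
#' abundance-weighted alternative E = sum A_i x p_i, which always lies
#' between the smallest and largest monoculture activity.
#'
#' @param monoActivities named vector of monoculture activities A_i
#'   (>= 0) covering every design member.
#' @param proportions named member proportions p_i (> 0 for
#'   literal_divide; renormalized to sum 1).
#' @param convention "literal_divide" (default) or "proportional_sum".
#' @return Expected activity E with attribute \code{convention}.
#' @export
#' @examples
#' expectedActivity(c(X = 2, Y = 6), c(X = 0.25, Y = 0.75))  # 16
#' expectedActivity(c(X = 2, Y = 6), c(X = 0.25, Y = 0.75),
#'                  "proportional_sum")                      # 5
expectedActivity <- function(monoActivities, proportions,
                             convention = c("literal_divide",
                                            "proportional_sum")) {
  convention <- match.arg(convention)
  members <- names(proportions)
  if (is.null(members) || is.null(names(monoActivities)))
    stop("monoActivities and proportions must be named")
  missing <- setdiff(members, names(monoActivities))
  if (length(missing))
    stop("missing monoculture activity for: ",
         paste(missing, collapse = ", "))
  A <- monoActivities[members]
  if (any(A < 0)) stop("monoculture activities must be >= 0")
  if (convention == "literal_divide" && any(proportions <= 0))
    stop("literal_divide is undefined for members with proportion 0")
  p <- proportions / sum(proportions)
  E <- if (convention == "literal_divide") sum(A / p) else sum(A * p)
  structure(E, convention = convention)
}

#' Actual-minus-expected differences and their summary
#'
#' Sign convention: actual - expected, so negative values mean the
#' community produced less than the monoculture-based prediction.
#'
#' @param actualReplicates measured activities (>= 1 replicate).
#' @param expected expected activity (scalar).
#' @return list(differences, mean, sem); sem is NA for one replicate.
#' @export
#' @examples
#' actualMinusExpected(c(1, 2, 3), 4)$mean  # -2
actualMinusExpected <- function(actualReplicates, expected) {
  if (length(actualReplicates) < 1) stop("need at least one replicate")
  d <- actualReplicates - as.numeric(expected)
  list(differences = d, mean = mean(d),
       sem = if (length(d) > 1) stats::sd(d) / sqrt(length(d)) else NA_real_)
}

#' Null-model table over designs and enzyme classes
#'
#' Builds the expected-versus-measured comparison for every mixture
#' design: monoculture mean activities define A_i, weights are either
#' the exact input fractions (1/n members) or resolved endpoint
#' proportions (zeros dropped, remainder renormalized), and measured
#' replicates are compared as actual - expected.
#'
#' @param activities activity table from \code{\link{convertSignals}}
#'   covering monoculture designs ("<code>-alone") and mixtures.
#' @param designs a \linkS4class{CommunityDesignSet}.
#' @param convention passed to \code{\link{expectedActivity}}.
#' @param weighting "input_proportions" or "endpoint_proportions".
#' @param endpointCompositions named list (design_id ->
#'   \linkS4class{CompositionEstimate}) required for endpoint weighting.
#' @return data.frame(design_id, enzyme, convention, weighting,
#'   expected, mean_diff, sem_diff).
#' @export
nullModelTable <- function(activities, designs,
                           convention = c("literal_divide",
                                          "proportional_sum"),
                           weighting = c("input_proportions",
                                         "endpoint_proportions"),
                           endpointCompositions = NULL) {
  convention <- match.arg(convention)
  weighting <- match.arg(weighting)
  roles <- designRoles(designs)
  ids <- designIds(designs)
  members <- designMembers(designs)
  monoIds <- ids[roles == "monoculture"]
  monoSpecies <- vapply(members[monoIds], `[`, "", 1)
  enz <- intersect(enzymeClasses(), unique(activities$enzyme))
  mixIds <- ids[roles %in% c("mix", "dropout")]
  out <- list()
  for (e in enz) {
    ae <- activities[activities$enzyme == e, ]
    monoA <- vapply(monoIds, function(d)
      mean(ae$activity[ae$design_id == d]), 0)
    names(monoA) <- monoSpecies
    if (anyNA(monoA))
      stop("missing monoculture activities for enzyme ", e)
    for (d in mixIds) {
      m <- members[[d]]
      p <- if (weighting == "input_proportions") {
        setNames(rep(1 / length(m), length(m)), m)
      } else {
        if (is.null(endpointCompositions[[d]]))
          stop("no endpoint composition for design ", d)
        q <- speciesProportions(endpointCompositions[[d]])[m]
        q <- q[q > 0]
        q / sum(q)
      }
      E <- expectedActivity(monoA[names(p)], p, convention)
      act <- ae$activity[ae$design_id == d]
      if (length(act) == 0) stop("no measured activities for design ", d)
      s <- actualMinusExpected(act, E)
      out[[length(out) + 1L]] <- data.frame(
        design_id = d, enzyme = e, convention = convention,
        weighting = weighting, expected = as.numeric(E),
        mean_diff = s$mean, sem_diff = s$sem, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
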