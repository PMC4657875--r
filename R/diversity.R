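.cleanProportions <- function(proportions) {
  if (any(proportions < 0)) stop("proportions must be >= 0")
  p <- proportions[proportions > 0]
  if (length(p) == 0) stop("all proportions are zero")
  p / sum(p)
}

#' Shannon diversity index (natural log)
#'
#' H = -sum p_i ln p_i over detected (p > 0) species, after
#' renormalizing the input to sum 1. Zeros contribute nothing.
#'
#' @param proportions non-negative abundance vector (any scale).
#' @return H in nats.
#' @export
#' @examples
#' shannonIndex(rep(1, 9))  # ln 9
shannonIndex <- function(proportions) {
  p <- .cleanProportions(proportions)
  -sum(p * log(p))
}

#' Simpson concentration and its variants
#'
#' lambda = sum p_i^2 (probability two random draws are the same
#' species); "gini" returns 1 - lambda and "inverse" 1 / lambda.
#'
#' @param proportions non-negative abundance vector.
#' @param variant one of "lambda", "gini", "inverse".
#' @return The requested index.
#' @export
#' @examples
#' simpsonIndex(rep(1, 9))            # 1/9
#' simpsonIndex(rep(1, 9), "inverse") # 9
simpsonIndex <- function(proportions,
                         variant = c("lambda", "gini", "inverse")) {
  variant <- match.arg(variant)
  p <- .cleanProportions(proportions)
  lambda <- sum(p^2)
  switch(variant, lambda = lambda, gini = 1 - lambda, inverse = 1 / lambda)
}

#' Pielou equitability (evenness)
#'
#' J = H / ln S, the Shannon index relative to its maximum for S
#' detected species; 1 means a perfectly even community.
#'
#' @param H Shannon index in nats (>= 0).
#' @param S richness, number of detected species (>= 2).
#' @return J in [0, 1].
#' @export
#' @examples
#' equitability(1.92, 9)  # ~0.87
equitability <- function(H, S) {
  if (S < 2) stop("equitability needs S >= 2")
  if (H < 0) stop("H must be >= 0")
  H / log(S)
}

#' All diversity indices for one composition
#'
#' @param proportions non-negative abundance vector (renormalized).
#' @return data.frame with simpson_lambda, gini_simpson,
#'   inverse_simpson, shannon_H (nats), richness_S (species with p > 0)
#'   and equitability_J.
#' @export
#' @examples
#' ec <- endpointComposition()
#' diversityReport(ec$pct_full)
diversityReport <- function(proportions) {
  p <- .cleanProportions(proportions)
  H <- shannonIndex(p)
  S <- length(p)
  lambda <- sum(p^2)
  data.frame(simpson_lambda = lambda, gini_simpson = 1 - lambda,
             inverse_simpson = 1 / lambda, shannon_H = H, richness_S = S,
             equitability_J = if (S >= 2) H / log(S) else NA_real_)
}
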