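.tier <- function(p) {
  cut(p, c(-Inf, 0.001, 0.01, 0.05, Inf),
      labels = c("p<0.001", "p<0.01", "p<0.05", "ns"))
}

.tierSymbol <- c("p<0.001" = "#", "p<0.01" = "**", "p<0.05" = "*",
                 "ns" = "ns")

#' Distribution of the maximum absolute many-to-one t statistic
#'
#' P(max_i |T_i| <= q) where (T_1..T_k) are the comparisons of k
#' treatment groups against one shared reference, jointly multivariate t
#' with df error degrees of freedom and correlation
#' rho_ij = lambda_i lambda_j, lambda_i = sqrt(n_i / (n_i + n0)). The
#' shared-reference (one-factor) structure lets the k-variate
#' probability collapse to a double integral over the reference normal
#' deviate and the pooled-variance scale, evaluated by deterministic
#' adaptive quadrature — no Monte-Carlo.
#'
#' @param q non-negative quantile.
#' @param lambda vector of k correlation loadings in (0, 1); for a
#'   balanced design all equal sqrt(1/2).
#' @param df error degrees of freedom (Inf allowed).
#' @return P(max |T_i| <= q).
#' @export
pDunnettMax <- function(q, lambda, df) {
  if (q <= 0) return(0)
  s <- sqrt(1 - lambda^2)
  inner <- function(u) {
    f <- function(z) {
      pr <- rep(1, length(z))
      for (i in seq_along(lambda))
        pr <- pr * (stats::pnorm((q * u + lambda[i] * z) / s[i]) -
                    stats::pnorm((-q * u + lambda[i] * z) / s[i]))
      pr * stats::dnorm(z)
    }
    stats::integrate(f, -Inf, Inf, rel.tol = 1e-9)$value
  }
  if (is.infinite(df)) return(inner(1))
  g <- function(u) {
    vapply(u, function(ui)
      2 * df * ui * stats::dchisq(df * ui^2, df) * inner(ui), 0)
  }
  stats::integrate(g, 0, Inf, rel.tol = 1e-7)$value
}

#' Critical value of the many-to-one maximum-|t| statistic
#'
#' @param p coverage probability (e.g. 0.95 for alpha = 0.05 two-sided).
#' @inheritParams pDunnettMax
#' @return q such that \code{pDunnettMax(q, lambda, df) == p}.
#' @export
qDunnettMax <- function(p, lambda, df) {
  stats::uniroot(function(q) pDunnettMax(q, lambda, df) - p,
                 c(1e-6, 50), tol = 1e-7)$root
}

#' Many-to-one comparisons against a reference group (Dunnett)
#'
#' One-way ANOVA with every group compared to a single reference,
#' family-wise error controlled through the many-to-one multivariate-t
#' distribution (two-sided). With a single comparison the adjusted
#' p-value equals the pooled two-sample t-test p-value.
#'
#' @param groups named list of replicate vectors (>= 2 each).
#' @param referenceLabel name of the reference group (e.g. "Mix").
#' @param alpha family-wise level used for the significance tiers'
#'   starring only; tiers are fixed at 0.05/0.01/0.001.
#' @return data.frame(group, reference, estimate, t, p_adj,
#'   significance_tier, symbol) with attributes \code{omnibus_F},
#'   \code{omnibus_p}, \code{df} and \code{alpha}.
#' @export
#' @examples
#' g <- list(Mix = c(5, 6, 5.5), A = c(5.2, 5.9, 5.6), B = c(9, 10, 9.5))
#' dunnettVsReference(g, "Mix")
dunnettVsReference <- function(groups, referenceLabel, alpha = 0.05) {
  if (!referenceLabel %in% names(groups))
    stop("reference group '", referenceLabel, "' not found")
  if (length(groups) < 2) stop("need at least two groups")
  n <- vapply(groups, length, 1L)
  if (any(n < 2)) stop("every group needs >= 2 replicates")
  k <- length(groups)
  N <- sum(n)
  df <- N - k
  means <- vapply(groups, mean, 0)
  ss <- sum(vapply(groups, function(x) sum((x - mean(x))^2), 0))
  if (ss <= 0)
    stop("degenerate data: zero within-group variance everywhere")
  s2 <- ss / df
  grand <- sum(n * means) / N
  ssb <- sum(n * (means - grand)^2)
  Fstat <- (ssb / (k - 1)) / s2
  omnibusP <- stats::pf(Fstat, k - 1, df, lower.tail = FALSE)

  others <- setdiff(names(groups), referenceLabel)
  n0 <- n[[referenceLabel]]
  lambda <- sqrt(n[others] / (n[others] + n0))
  est <- means[others] - means[[referenceLabel]]
  tval <- est / sqrt(s2 * (1 / n[others] + 1 / n0))
  pAdj <- if (length(others) == 1) {
    2 * stats::pt(-abs(tval), df)
  } else {
    vapply(abs(tval), function(tt)
      1 - pDunnettMax(tt, unname(lambda), df), 0)
  }
  pAdj <- pmin(pmax(pAdj, 0), 1)
  res <- data.frame(group = others, reference = referenceLabel,
                    estimate = unname(est), t = unname(tval),
                    p_adj = unname(pAdj),
                    significance_tier = as.character(.tier(pAdj)),
                    stringsAsFactors = FALSE)
  res$symbol <- .tierSymbol[res$significance_tier]
  attr(res, "omnibus_F") <- Fstat
  attr(res, "omnibus_p") <- omnibusP
  attr(res, "df") <- df
  attr(res, "alpha") <- alpha
  res
}

#' Sidak family-wise adjustment
#'
#' p_adj = 1 - (1 - p)^m for m comparisons.
#'
#' @param p raw p-value(s).
#' @param m family size (>= 1).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' sidakAdjust(0.01, 5)  # ~0.049
sidakAdjust <- function(p, m) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, -expm1(m * log1p(-p)))
}

#' Per-species composition comparison between two conditions
#'
#' Two-way layout (species x condition) on replicate proportion
#' vectors: the pooled residual variance of the full interaction model
#' scales a per-species contrast between conditions, and p-values get a
#' Sidak adjustment over the m species compared.
#'
#' @param compA,compB numeric matrices, replicates x species, with
#'   identical species columns (rows sum to ~1).
#' @return data.frame(species, estimate, t, p, p_adj,
#'   significance_tier, symbol); estimate is mean(B) - mean(A).
#' @export
sidakCompositionTest <- function(compA, compB) {
  if (!identical(colnames(compA), colnames(compB)))
    stop("mismatched species sets between conditions")
  if (is.null(colnames(compA))) stop("composition matrices must have colnames")
  if (nrow(compA) < 2 || nrow(compB) < 2)
    stop("need >= 2 replicates per condition")
  sp <- colnames(compA)
  m <- length(sp)
  nA <- nrow(compA); nB <- nrow(compB)
  resid2 <- sum(sweep(compA, 2, colMeans(compA))^2) +
            sum(sweep(compB, 2, colMeans(compB))^2)
  dfRes <- m * (nA + nB) - 2 * m
  if (resid2 <= 0) stop("degenerate data: zero residual variance")
  mse <- resid2 / dfRes
  est <- colMeans(compB) - colMeans(compA)
  tval <- est / sqrt(mse * (1 / nA + 1 / nB))
  p <- 2 * stats::pt(-abs(tval), dfRes)
  pAdj <- sidakAdjust(p, m)
  res <- data.frame(species = sp, estimate = unname(est),
                    t = unname(tval), p = unname(p), p_adj = unname(pAdj),
                    significance_tier = as.character(.tier(pAdj)),
                    stringsAsFactors = FALSE)
  res$symbol <- .tierSymbol[res$significance_tier]
  res
}

#' Classify per-enzyme functional robustness
#'
#' An enzyme activity is functionally robust when no single-species
#' dropout community differs significantly from the full mix at the
#' family-wise level alpha — the operational definition used throughout
#' the dropout design.
#'
#' @param results named list (enzyme class -> data.frame from
#'   \code{\link{dunnettVsReference}} restricted to dropout designs).
#' @param alpha family-wise significance level (default 0.05).
#' @param dropoutIds optional character vector of dropout design ids
#'   each table must cover (error if any is missing).
#' @return data.frame(enzyme, robust, offending) where offending is a
#'   comma-separated list of significant dropout designs.
#' @export
classifyRobustness <- function(results, alpha = 0.05, dropoutIds = NULL) {
  out <- lapply(names(results), function(e) {
    r <- results[[e]]
    if (!is.null(dropoutIds)) {
      missing <- setdiff(dropoutIds, r$group)
      if (length(missing))
        stop("enzyme ", e, ": missing dropout designs: ",
             paste(missing, collapse = ", "))
    }
    sig <- r$group[r$p_adj < alpha]
    data.frame(enzyme = e, robust = length(sig) == 0,
               offending = paste(sig, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
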