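#' Differential-susceptibility matrix of the nine ISS isolates
#'
#' Loads the bundled growth phenotype table: growth of each species on
#' LB supplemented with carbenicillin 100 (Cb100), cetrimide 200
#' (Ct200), trimethoprim 100 (Tp100), gentamicin 25 (Gm25) or kanamycin
#' 100 ug/ml (Km100), on unsupplemented medium ("none", also standing in
#' for the no-salt/sucrose total-count plate), and on Pseudomonas
#' Isolation Agar (PIA, 37 C only), each at 30 and 37 C. Levels: "-"
#' no growth (0), "+" slow growth (1), "++" normal growth (2); NA marks
#' untested combinations and raises on use. P. myrsianacearum is scored
#' as no growth on unsupplemented medium at 37 C (it grows exceedingly
#' slowly there).
#'
#' @return A \linkS4class{PhenotypeMatrix} with condition ids like
#'   "30C.none", "37C.Gm25".
#' @export
#' @examples
#' pheno <- issPhenotypeMatrix()
#' predictGrowth(pheno, "37C.Ct200")  # "Bm"
issPhenotypeMatrix <- function() {
  tab <- utils::read.delim(system.file("extdata", "phenotype_matrix.tsv",
                                       package = "commrobust"),
                           stringsAsFactors = FALSE, na.strings = "NA")
  sups <- setdiff(names(tab), c("species", "abbrev", "temp"))
  abb <- unique(tab$abbrev)
  conds <- expand.grid(temp = sort(unique(tab$temp)), supplement = sups,
                       stringsAsFactors = FALSE)
  conds$condition <- paste0(conds$temp, "C.", conds$supplement)
  conds <- conds[, c("condition", "temp", "supplement")]
  code <- c("-" = 0L, "+" = 1L, "++" = 2L)
  g <- matrix(NA_integer_, length(abb), nrow(conds),
              dimnames = list(abb, conds$condition))
  for (i in seq_len(nrow(tab)))
    for (s in sups) {
      v <- tab[[s]][i]
      g[tab$abbrev[i], paste0(tab$temp[i], "C.", s)] <-
        if (is.na(v)) NA_integer_ else code[[v]]
    }
  cls <- setNames(rep("white", length(abb)), abb)
  cls["Cg"] <- "orange"  # distinctive orange colonies
  cls["Ri"] <- "rough"   # rough-edged colonies (vs C. metallidurans)
  PhenotypeMatrix(g, conds, cls)
}

#' Default plating scheme resolving all nine species
#'
#' Condition set used for composition deconvolution: total counts at 30
#' and 37 C, gentamicin at both temperatures, trimethoprim at both
#' temperatures, plus cetrimide and kanamycin at 37 C. Under strict
#' scoring (normal growth only) and colony classes, this scheme gives
#' every species a unique signature and a full-rank count system.
#'
#' @return Character vector of condition ids.
#' @export
defaultPlatingScheme <- function() {
  c("30C.none", "37C.none", "30C.Gm25", "37C.Gm25",
    "30C.Tp100", "37C.Tp100", "37C.Ct200", "37C.Km100")
}

#' Species predicted to grow under a plating condition
#'
#' @param pheno a \linkS4class{PhenotypeMatrix}.
#' @param condition a condition id (e.g. "37C.Ct200").
#' @param slowCountsAsGrowth if TRUE, slow growth ("+") counts as
#'   growth; by default only normal growth ("++") does, the conservative
#'   reading of colonies scored on selection plates.
#' @return Character vector of species codes.
#' @export
predictGrowth <- function(pheno, condition, slowCountsAsGrowth = FALSE) {
  g <- growthLevels(pheno)
  if (ncol(g) == 0) stop("empty phenotype matrix")
  if (!condition %in% colnames(g))
    stop("unknown plating condition: ", condition)
  lev <- g[, condition]
  if (anyNA(lev))
    stop("growth under ", condition, " is unknown for: ",
         paste(rownames(g)[is.na(lev)], collapse = ", "))
  thr <- if (slowCountsAsGrowth) 1L else 2L
  rownames(g)[lev >= thr]
}

# binary growth signature of every species over a condition set
.signatures <- function(pheno, conditions, useColonyClass,
                        slowCountsAsGrowth) {
  sp <- rownames(growthLevels(pheno))
  sig <- sapply(conditions, function(cond)
    sp %in% predictGrowth(pheno, cond, slowCountsAsGrowth))
  sig <- matrix(sig, nrow = length(sp),
                dimnames = list(sp, conditions))
  key <- apply(sig, 1, function(r) paste(as.integer(r), collapse = ""))
  if (useColonyClass) key <- paste(key, colonyClass(pheno)[sp], sep = "/")
  setNames(key, sp)
}

#' Check that a plating scheme identifies every species
#'
#' Builds each species' signature — its growth pattern across the
#' chosen conditions, optionally combined with its colony appearance
#' class — and reports whether all signatures are distinct.
#'
#' @inheritParams predictGrowth
#' @param conditions character vector of condition ids (>= 1).
#' @param useColonyClass include colony appearance in the signature.
#' @return list(identifiable = logical, ambiguous = list of colliding
#'   species sets, signatures = named character).
#' @export
#' @examples
#' identifiabilityCheck(issPhenotypeMatrix(), defaultPlatingScheme())$identifiable
identifiabilityCheck <- function(pheno, conditions, useColonyClass = TRUE,
                                 slowCountsAsGrowth = FALSE) {
  if (length(conditions) < 1) stop("need at least one condition")
  key <- .signatures(pheno, conditions, useColonyClass, slowCountsAsGrowth)
  groups <- split(names(key), key)
  amb <- unname(groups[lengths(groups) > 1])
  list(identifiable = length(amb) == 0, ambiguous = amb, signatures = key)
}

# Lawson-Hanson non-negative least squares: min ||Ax - b||, x >= 0
.nnls <- function(A, b, tol = 1e-10) {
  n <- ncol(A)
  x <- numeric(n)
  passive <- rep(FALSE, n)
  w <- drop(crossprod(A, b - A %*% x))
  iter <- 0L
  while (any(!passive) && any(w[!passive] > tol * max(1, max(abs(w))))) {
    iter <- iter + 1L
    if (iter > 30L * n) break
    j <- which(!passive)[which.max(w[!passive])]
    passive[j] <- TRUE
    repeat {
      z <- numeric(n)
      z[passive] <- qr.coef(qr(A[, passive, drop = FALSE]), b)
      z[passive][is.na(z[passive])] <- 0
      if (all(z[passive] > tol)) { x <- z; break }
      neg <- passive & z <= tol
      alpha <- min(x[neg] / (x[neg] - z[neg]))
      x <- x + alpha * (z - x)
      passive[passive & x <= tol] <- FALSE
      x[!passive] <- 0
    }
    w <- drop(crossprod(A, b - A %*% x))
  }
  x
}

#' Deconvolute plate counts into species proportions
#'
#' Each observed (condition, colony class) count is modeled as the sum
#' of the plated-volume-scaled abundances of the species that both grow
#' under that condition and share that colony class; the resulting
#' linear system is solved by non-negative least squares and normalized
#' to proportions. Counts must come from equal plated volumes (after
#' applying \code{dilution_factor}), so totals are comparable across
#' conditions. Multinomial standard errors are attached using the
#' largest observed plate total.
#'
#' @param observations data.frame(condition, colony_class, count) and
#'   optionally dilution_factor (counts are multiplied by it) and the
#'   no_growth flag written by \code{\link{simulatePlateCounts}}.
#' @inheritParams identifiabilityCheck
#' @return A \linkS4class{CompositionEstimate}.
#' @export
resolveComposition <- function(observations, pheno,
                               conditions = unique(observations$condition),
                               slowCountsAsGrowth = FALSE) {
  idc <- identifiabilityCheck(pheno, conditions, TRUE, slowCountsAsGrowth)
  if (!idc$identifiable)
    stop("plating scheme does not identify all species; ambiguous: ",
         paste(vapply(idc$ambiguous, paste, "", collapse = "+"),
               collapse = ", "))
  sp <- rownames(growthLevels(pheno))
  cls <- colonyClass(pheno)
  obs <- observations[observations$condition %in% conditions, ]
  if (nrow(obs) == 0) stop("no observations for the requested conditions")
  dil <- if ("dilution_factor" %in% names(obs)) obs$dilution_factor else 1
  y <- obs$count * dil

  rows <- vector("list", nrow(obs))
  for (i in seq_len(nrow(obs))) {
    growers <- predictGrowth(pheno, obs$condition[i], slowCountsAsGrowth)
    cell <- growers[cls[growers] == obs$colony_class[i]]
    rows[[i]] <- as.numeric(sp %in% cell)
  }
  A <- do.call(rbind, rows)
  colnames(A) <- sp
  keep <- rowSums(A) > 0 | y > 0
  A <- A[keep, , drop = FALSE]
  y <- y[keep]
  if (qr(A)$rank < length(sp))
    stop("count system is rank deficient for this condition set; ",
         "add conditions that split the unresolved species")

  totals <- tapply(y, obs$condition[keep], sum)
  n <- max(totals)
  # counting noise routinely drives rare species slightly negative in the
  # unconstrained solve; only a deficit far beyond multinomial error
  # signals genuinely inconsistent counts
  ols <- qr.coef(qr(A), y)
  if (any(ols < -5 * sqrt(n)))
    stop("inconsistent counts: least-squares species counts are ",
         "substantially negative")
  # plain least squares is unbiased; fall back to the non-negative
  # solver only when counting noise drives a species below zero
  x <- if (all(ols >= 0)) ols else .nnls(A, y)
  if (sum(x) <= 0) stop("all resolved counts are zero")
  p <- setNames(x / sum(x), sp)
  se <- sqrt(p * (1 - p) / n)
  CompositionEstimate(p, se)
}
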