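#' Select extreme-phenotype individuals
#'
#' Bulked-segregant style tail selection: the `floor(fraction * n)` highest
#' and lowest phenotyped individuals. Ties at a tail boundary are broken by
#' ascending individual id, so selection is deterministic and invariant to
#' input order.
#'
#' @param phenotypes named numeric vector (NAs dropped before selection).
#' @param fraction proportion per tail, in (0, 0.5].
#' @return list with character vectors `high` and `low`.
#' @examples
#' y <- setNames(rnorm(725), sprintf("i%03d", 1:725))
#' lengths(selectExtremes(y, 0.10))  # 72 per tail
#' @export
selectExtremes <- function(phenotypes, fraction = 0.10) {
  stopifnot(fraction > 0, fraction <= 0.5)
  y <- phenotypes[!is.na(phenotypes)]
  if (length(y) < 2) stop("need at least 2 phenotyped individuals")
  k <- floor(fraction * length(y))
  if (k < 1) stop("tail fraction too small: no individuals selected")
  if (2 * k > length(y))
    stop("tail fraction too large: tails of size ", k, " overlap at n = ",
         length(y))
  ids <- names(y)
  low <- ids[order(y, ids)][seq_len(k)]
  high <- ids[order(-y, ids)][seq_len(k)]
  list(high = high, low = low)
}

#' Pearson chi-square test of independence for one effect column
#'
#' L x 2 contingency test between the distinct observed values of an effect's
#' dummy column (rows) and extreme-group membership (columns), without
#' continuity correction; individuals with a missing column value are
#' excluded. Degrees of freedom are `(L - 1)` after dropping all-zero-margin
#' levels, so dominance-type columns (2 levels) give df = 1 and
#' additive/interaction product columns (3 levels) give df <= 2. An effect
#' with a single observed level (or an empty group) is untestable and
#' reported with `p = 1`.
#'
#' @param column numeric effect column restricted to the extreme individuals
#'   (may contain NA).
#' @param group logical or factor of the same length; `TRUE` (or the first
#'   level) = high group.
#' @return list with `chi2`, `df`, `p`, `untestable`.
#' @export
chi2Independence <- function(column, group) {
  if (is.factor(group)) group <- group == levels(group)[1]
  keep <- !is.na(column)
  column <- column[keep]; group <- group[keep]
  lev <- sort(unique(column))
  cH <- vapply(lev, function(v) sum(column == v & group), 0)
  cL <- vapply(lev, function(v) sum(column == v & !group), 0)
  rowtot <- cH + cL
  keepLev <- rowtot > 0
  cH <- cH[keepLev]; cL <- cL[keepLev]; rowtot <- rowtot[keepLev]
  L <- length(rowtot)
  nH <- sum(cH); nL <- sum(cL); N <- nH + nL
  if (L < 2 || nH == 0 || nL == 0)
    return(list(chi2 = 0, df = max(L - 1, 1), p = 1, untestable = TRUE))
  eH <- rowtot * nH / N
  eL <- rowtot * nL / N
  chi2 <- sum((cH - eH)^2 / eH) + sum((cL - eL)^2 / eL)
  df <- L - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), untestable = FALSE)
}

# Vectorized BSA screen of every candidate effect.
#
# x, z: encoded dummy matrices (with NA) restricted to the extreme
# individuals; highIdx: logical vector marking the high group. Individuals
# may appear in both tails in the degenerate all-tied case; they then count
# in both groups, as if listed twice.
#
# Returns a data.frame aligned with enumerateEffects(ncol(x)).
screenAllEffects <- function(x, z, high, low) {
  m <- ncol(x)
  obs <- (!is.na(x)) * 1
  P <- (x == 1) * 1;  P[is.na(P)] <- 0
  M <- (x == -1) * 1; M[is.na(M)] <- 0
  Z1 <- z;            Z1[is.na(Z1)] <- 0

  countsFor <- function(rows) {
    Pg <- P[rows, , drop = FALSE]; Mg <- M[rows, , drop = FALSE]
    Zg <- Z1[rows, , drop = FALSE]; Og <- obs[rows, , drop = FALSE]
    aP <- colSums(Pg); aM <- colSums(Mg); aO <- colSums(Og); dZ <- colSums(Zg)
    CPP <- crossprod(Pg); CMM <- crossprod(Mg); CPM <- crossprod(Pg, Mg)
    CPZ <- crossprod(Pg, Zg); CMZ <- crossprod(Mg, Zg)
    CZZ <- crossprod(Zg); COO <- crossprod(Og)
    list(aP = aP, aM = aM, aO = aO, dZ = dZ,
         CPP = CPP, CMM = CMM, CPM = CPM, CPZ = CPZ, CMZ = CMZ,
         CZZ = CZZ, COO = COO)
  }

  if (m >= 2) {
    j <- rep(seq_len(m - 1), times = (m - 1):1)
    k <- unlist(lapply(seq_len(m - 1), function(a) seq.int(a + 1, m)))
    jk <- cbind(j, k); kj <- cbind(k, j)
  }

  # Per-group count matrix: one row per effect (enumeration order), columns =
  # levels (-1, 0, +1). Levels absent from an effect kind carry zero counts
  # and drop out of the test.
  levelCounts <- function(cc) {
    mainCnt <- matrix(0, 2 * m, 3)
    ai <- seq(1, 2 * m, by = 2); di <- seq(2, 2 * m, by = 2)
    mainCnt[ai, 1] <- cc$aM
    mainCnt[ai, 3] <- cc$aP
    mainCnt[ai, 2] <- cc$aO - cc$aM - cc$aP
    mainCnt[di, 3] <- cc$dZ
    mainCnt[di, 2] <- cc$aO - cc$dZ
    if (m < 2) return(mainCnt)
    nPairs <- nrow(jk)
    pairObs <- cc$COO[jk]
    aa1 <- cc$CPP[jk] + cc$CMM[jk]
    aam <- cc$CPM[jk] + cc$CPM[kj]
    ad1 <- cc$CPZ[jk]; adm <- cc$CMZ[jk]
    da1 <- cc$CPZ[kj]; dam <- cc$CMZ[kj]
    dd1 <- cc$CZZ[jk]
    interCnt <- matrix(0, 4 * nPairs, 3)
    ia <- seq(1, 4 * nPairs, by = 4)
    interCnt[ia, ]     <- cbind(aam, pairObs - aa1 - aam, aa1)
    interCnt[ia + 1, ] <- cbind(adm, pairObs - ad1 - adm, ad1)
    interCnt[ia + 2, ] <- cbind(dam, pairObs - da1 - dam, da1)
    interCnt[ia + 3, ] <- cbind(0,   pairObs - dd1,       dd1)
    rbind(mainCnt, interCnt)
  }

  CH <- levelCounts(countsFor(high))
  CL <- levelCounts(countsFor(low))

  rowtot <- CH + CL
  nH <- rowSums(CH); nL <- rowSums(CL); N <- nH + nL
  nonzero <- rowtot > 0
  L <- rowSums(nonzero)
  eH <- rowtot * (nH / N); eL <- rowtot * (nL / N)
  termH <- (CH - eH)^2 / eH; termL <- (CL - eL)^2 / eL
  termH[!nonzero | !is.finite(termH)] <- 0
  termL[!nonzero | !is.finite(termL)] <- 0
  chi2 <- rowSums(termH) + rowSums(termL)
  df <- pmax(L - 1, 1)
  untestable <- L < 2 | nH == 0 | nL == 0
  chi2[untestable] <- 0
  p <- stats::pchisq(chi2, df, lower.tail = FALSE)
  p[untestable] <- 1

  out <- enumerateEffects(m)
  out$chi2 <- as.numeric(chi2)
  out$df <- as.integer(df)
  out$p <- as.numeric(p)
  out$untestable <- as.logical(untestable)
  out
}

#' Screen candidate effects on extreme-phenotype pools
#'
#' Runs the bulked-segregant chi-square screen of every candidate main and
#' interaction effect against high/low phenotype pools, and returns the top
#' candidates: among effects not already selected and not untestable, up to
#' `K` main effects and up to `K` interaction effects with the smallest
#' P-values satisfying `p <= alpha`, each category ranked by ascending
#' P-value with ties broken by canonical descriptor order.
#'
#' @param population an [NCIIPopulation-class].
#' @param phenotypes named numeric vector to screen on (e.g. the current
#'   corrected phenotype); defaults to the population's stored phenotypes.
#' @param alreadySelected effect descriptor data.frame to exclude from
#'   selection (accumulated effects are never re-screened).
#' @param K per-category cap (default 100).
#' @param alpha raw P-value entry threshold (default 0.05).
#' @param fraction proportion per tail (default 0.10).
#' @param mappingRoles roles eligible for mapping (default: parents and F1
#'   pooled).
#' @return data.frame of selected effects with columns `kind`, `locus1`,
#'   `locus2`, `chi2`, `df`, `p`, `category`, in ranked order; the full
#'   screen is attached as `attr(, "screen")`.
#' @export
screenTopEffects <- function(population, phenotypes = NULL,
                             alreadySelected = NULL, K = 100, alpha = 0.05,
                             fraction = 0.10,
                             mappingRoles = .VALID_ROLES) {
  stopifnot(K >= 1)
  if (is.null(phenotypes)) phenotypes <- population@phenotypes
  ids <- mappedIndividuals(population, mappingRoles)
  y <- phenotypes[ids]
  tails <- selectExtremes(y, fraction)
  g <- genotypes(population)
  enc <- encodeGenotypes(g[c(tails$high, tails$low), , drop = FALSE])
  nH <- length(tails$high)
  scr <- screenAllEffects(enc$x, enc$z,
                          high = seq_len(nH),
                          low = nH + seq_along(tails$low))
  scr$category <- ifelse(scr$kind %in% .MAIN_KINDS, "main", "interaction")

  excluded <- scr$untestable
  if (!is.null(alreadySelected) && nrow(alreadySelected) > 0)
    excluded <- excluded | effectKeys(scr) %in% effectKeys(alreadySelected)

  pick <- function(category) {
    idx <- which(!excluded & scr$category == category & scr$p <= alpha)
    idx <- idx[order(scr$p[idx], idx)]
    utils::head(idx, K)
  }
  sel <- scr[c(pick("main"), pick("interaction")), , drop = FALSE]
  sel$untestable <- NULL
  rownames(sel) <- NULL
  attr(sel, "screen") <- scr
  sel
}
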