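#' Predict the complete hybrid value table
#'
#' Evaluates every parentA x parentB combination: the F1 genotype at each QTL
#' marker is deduced from the (inbred) parents as the parental mean code, the
#' detected effects are evaluated on it, and the cell value is
#' `mu + sum_k w_k gamma_k`. Where a cross was realized and `useObserved` is
#' `TRUE`, the observed F1 phenotype replaces the prediction (the mean, if
#' several F1s share a cross). A parent missing a QTL marker code is imputed
#' from the parental reference-allele frequency, with a warning.
#'
#' @param population an [NCIIPopulation-class].
#' @param report a `qtlReport` from [runScan()] (needs attributes `mu` and
#'   columns `kind`, `locus1`, `locus2`, `effectSize`).
#' @param useObserved substitute observed F1 phenotypes where available
#'   (default TRUE).
#' @return A [HybridTable-class].
#' @export
predictHybridTable <- function(population, report, useObserved = TRUE) {
  r <- roles(population)
  idsA <- names(r)[r == "parentA"]
  idsB <- names(r)[r == "parentB"]
  if (!length(idsA) || !length(idsB))
    stop("population must contain both parentA and parentB lines")
  g <- genotypes(population)
  mu <- attr(report, "mu")
  if (is.null(mu)) stop("report carries no 'mu' attribute")

  loci <- sort(unique(stats::na.omit(c(report$locus1, report$locus2))))
  gA <- g[idsA, loci, drop = FALSE]
  gB <- g[idsB, loci, drop = FALSE]
  het <- c(gA, gB) == 1
  if (any(het, na.rm = TRUE))
    stop("hybrid prediction requires inbred parents at all QTL markers")
  if (anyNA(gA) || anyNA(gB)) {
    warning("missing parent genotype(s) at QTL marker(s); imputed from the ",
            "parental allele frequency")
    pf <- alleleFrequencies(population, over = c("parentA", "parentB"))[loci]
    for (jj in seq_along(loci)) {
      gA[is.na(gA[, jj]), jj] <- 2 * pf[jj]
      gB[is.na(gB[, jj]), jj] <- 2 * pf[jj]
    }
  }
  # per-locus reference-allele dose probability of each parent's gamete
  pA <- gA / 2
  pB <- gB / 2
  colIdx <- function(locus) match(locus, loci)

  v <- matrix(mu, length(idsA), length(idsB), dimnames = list(idsA, idsB))
  for (i in seq_len(nrow(report))) {
    kind <- report$kind[i]
    gammaK <- report$effectSize[i]
    l1 <- colIdx(report$locus1[i])
    l2 <- if (is.na(report$locus2[i])) NA else colIdx(report$locus2[i])
    xz <- function(locus) {
      a <- pA[, locus]; b <- pB[, locus]
      list(x = outer(a, b, function(u, w) u + w - 1),
           z = outer(a, b, function(u, w) u * (1 - w) + (1 - u) * w))
    }
    e1 <- xz(l1)
    w <- switch(kind,
      a  = e1$x,
      d  = e1$z,
      aa = e1$x * xz(l2)$x,
      ad = e1$x * xz(l2)$z,
      da = e1$z * xz(l2)$x,
      dd = e1$z * xz(l2)$z)
    v <- v + w * gammaK
  }

  prov <- matrix("predicted", length(idsA), length(idsB),
                 dimnames = list(idsA, idsB))
  if (isTRUE(useObserved)) {
    ped <- pedigree(population)
    ph <- population@phenotypes
    if (nrow(ped) > 0) {
      obs <- ph[ped$f1]
      ok <- !is.na(obs)
      if (any(ok)) {
        agg <- tapply(obs[ok], paste(ped$parentA[ok], ped$parentB[ok],
                                     sep = "\r"), mean)
        keyParts <- strsplit(names(agg), "\r", fixed = TRUE)
        for (i in seq_along(agg)) {
          v[keyParts[[i]][1], keyParts[[i]][2]] <- agg[[i]]
          prov[keyParts[[i]][1], keyParts[[i]][2]] <- "observed"
        }
      }
    }
  }
  new("HybridTable", values = v, provenance = prov)
}

#' General and specific combining abilities of a hybrid table
#'
#' Decomposes a complete hybrid value table as
#' `v_ij = grand mean + GCA_i + GCA_j + SCA_ij` with unweighted row/column
#' means. GCA vectors each sum to zero and every SCA row and column sums to
#' zero; the reconstruction identity is exact.
#'
#' @param table a [HybridTable-class] or a plain numeric matrix (rows =
#'   parentA, columns = parentB).
#' @return A [CombiningAbilities-class].
#' @examples
#' ca <- combiningAbilities(matrix(c(10, 14, 12, 20), 2,
#'                          dimnames = list(c("A1", "A2"), c("B1", "B2"))))
#' ca@grandMean  # 14
#' @export
combiningAbilities <- function(table) {
  v <- if (is(table, "HybridTable")) hybridValues(table) else as.matrix(table)
  grand <- mean(v)
  gcaA <- rowMeans(v) - grand
  gcaB <- colMeans(v) - grand
  sca <- sweep(sweep(v - grand, 1, gcaA), 2, gcaB)
  new("CombiningAbilities", grandMean = grand, gcaA = gcaA, gcaB = gcaB,
      sca = sca, bv = v)
}

#' Rank elite parents and crosses
#'
#' Parents are ranked by descending GCA within each group; crosses by
#' descending hybrid value (BV), with the cross's SCA reported alongside.
#' Ties are broken by ascending id.
#'
#' @param ca a [CombiningAbilities-class].
#' @param top number of rows per list (default 10).
#' @return list with data.frames `parentA` (`id`, `GCA`), `parentB`
#'   (`id`, `GCA`) and `crosses` (`parentA`, `parentB`, `BV`, `SCA`).
#' @export
rankElites <- function(ca, top = 10) {
  stopifnot(top >= 1)
  rankGCA <- function(gca) {
    ord <- order(-gca, names(gca))
    utils::head(data.frame(id = names(gca)[ord], GCA = unname(gca[ord]),
                           stringsAsFactors = FALSE), top)
  }
  bv <- ca@bv
  cells <- expand.grid(parentA = rownames(bv), parentB = colnames(bv),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  cells$BV <- as.vector(bv)
  cells$SCA <- as.vector(ca@sca)
  ord <- order(-cells$BV, cells$parentA, cells$parentB)
  list(parentA = rankGCA(ca@gcaA),
       parentB = rankGCA(ca@gcaB),
       crosses = utils::head(cells[ord, ], top))
}
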