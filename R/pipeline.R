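#' Scan configuration
#'
#' Tuning parameters of the iterative screen-shrink-test scan.
#'
#' @param fraction proportion of individuals per extreme tail (default 0.10).
#' @param K per-category screening cap: up to `K` main and `K` interaction
#'   effects enter each empirical Bayes fit (default 100).
#' @param alpha raw P-value entry threshold at screening (default 0.05).
#' @param lodThreshold LOD significance cutoff (default 2.0).
#' @param maxIterations cap on outer screen/correct iterations (default 20).
#' @param mappingRoles roles pooled into the mapping population (default:
#'   parents and F1 together).
#' @param ebayes an [ebayesConfig()].
#' @param verbose print one progress line per outer iteration.
#' @return list of class `scanConfig`.
#' @export
scanConfig <- function(fraction = 0.10, K = 100, alpha = 0.05,
                       lodThreshold = 2.0, maxIterations = 20L,
                       mappingRoles = c("parentA", "parentB", "F1"),
                       ebayes = ebayesConfig(), verbose = FALSE) {
  stopifnot(fraction > 0, fraction <= 0.5, K >= 1, alpha > 0, alpha <= 1,
            lodThreshold > 0, maxIterations >= 1)
  structure(list(fraction = fraction, K = K, alpha = alpha,
                 lodThreshold = lodThreshold,
                 maxIterations = as.integer(maxIterations),
                 mappingRoles = mappingRoles, ebayes = ebayes,
                 verbose = isTRUE(verbose)),
            class = "scanConfig")
}

#' Subtract fitted genetic effects from a phenotype
#'
#' Phenotype correction between scan iterations: `y' = y - W b`, where `W`
#' holds the columns of the newly significant effects and `b` their shrinkage
#' estimates.
#'
#' @param y phenotype vector.
#' @param W effect-column matrix (n x q).
#' @param b effect estimates (length q).
#' @return Corrected phenotype vector.
#' @export
correctPhenotype <- function(y, W, b) {
  if (length(b) == 0) return(y)
  W <- as.matrix(W)
  stopifnot(nrow(W) == length(y), ncol(W) == length(b))
  setNames(as.numeric(y - W %*% b), names(y))
}

#' Percent phenotypic variance explained by one effect
#'
#' `r2 = 100 * Var(w * gamma) / Var(y)` with the population variance
#' convention (divisor n).
#'
#' @param w effect column.
#' @param gamma effect estimate.
#' @param y phenotype vector.
#' @return r-squared in percent.
#' @export
varianceExplained <- function(w, gamma, y) {
  varPop <- function(v) mean((v - mean(v))^2)
  vy <- varPop(y)
  stopifnot(vy > 0)
  100 * varPop(w * gamma) / vy
}

#' Map main and interacted QTL in a partial NCII population
#'
#' Runs the full iterative scan on the phenotyped individuals: (1) select
#' extreme-phenotype pools and chi-square screen all candidate effects not yet
#' accumulated; (2) fit the selected effects by empirical Bayes shrinkage;
#' (3) LOD-test the non-zero effects and accumulate the significant ones;
#' (4) subtract the newly significant effects from the working phenotype;
#' repeat until an iteration adds nothing (or `maxIterations`); then (5) fit
#' all accumulated effects jointly on the original phenotype and keep those
#' passing the LOD threshold in that final joint model.
#'
#' @param population an [NCIIPopulation-class] with phenotypes.
#' @param config a [scanConfig()].
#' @return A `qtlReport` data.frame, main effects first then interactions,
#'   each ordered by ascending screening P-value, with columns `effect`
#'   (name), `kind`, `marker1`, `marker2`, `freq1`, `freq2`, `chi2`, `df`,
#'   `p`, `LOD`, `effectSize` and `r2` (percent variance explained).
#'   Attributes: `mu` (fitted population mean), `sigma2` (residual variance),
#'   `fit` (the final [EBayesFit-class]), `trait`, `n` (mapped individuals).
#' @export
runScan <- function(population, config = scanConfig()) {
  ids <- mappedIndividuals(population, config$mappingRoles)
  if (length(ids) < 4) stop("too few phenotyped individuals to map")
  y <- population@phenotypes[ids]
  if (max(y) == min(y)) stop("phenotype has zero variance")
  g <- genotypes(population)[ids, , drop = FALSE]
  enc <- imputeEncoding(encodeGenotypes(g))

  yCur <- y
  acc <- NULL  # accumulated significant effects with screening stats
  iterLog <- 0L

  repeat {
    iterLog <- iterLog + 1L
    if (iterLog > config$maxIterations) break
    sel <- screenTopEffects(population, yCur, alreadySelected = acc,
                            K = config$K, alpha = config$alpha,
                            fraction = config$fraction,
                            mappingRoles = config$mappingRoles)
    if (nrow(sel) == 0) break
    W <- effectColumns(sel, enc$x, enc$z)
    keepCol <- apply(W, 2, function(v) max(v) > min(v))
    if (any(!keepCol))
      message(sum(!keepCol), " zero-variance effect column(s) excluded")
    sel <- sel[keepCol, , drop = FALSE]
    W <- W[, keepCol, drop = FALSE]
    if (ncol(W) == 0) break
    fit <- fitEmpiricalBayes(yCur, W, config$ebayes, effects = sel)
    tests <- lodTest(fit, yCur, W, config$lodThreshold)
    sigIdx <- which(tests$significant & abs(tests$gamma) > 1e-6)
    if (config$verbose)
      message(sprintf("iteration %d: screened %d, selected %d, significant %d, cumulative %d",
                      iterLog, nrow(attr(sel, "screen")), nrow(sel),
                      length(sigIdx),
                      length(sigIdx) + if (is.null(acc)) 0 else nrow(acc)))
    if (length(sigIdx) == 0) break
    newSig <- sel[sigIdx, , drop = FALSE]
    newSig$iteration <- iterLog
    acc <- if (is.null(acc)) newSig else rbind(acc, newSig)
    yCur <- correctPhenotype(yCur, W[, sigIdx, drop = FALSE],
                             tests$gamma[sigIdx])
  }

  freq <- alleleFrequencies(population)
  markerNames <- colnames(g)
  emptyReport <- function(mu, sigma2, fit) {
    rep <- data.frame(effect = character(), kind = character(),
                      marker1 = character(), marker2 = character(),
                      freq1 = numeric(), freq2 = numeric(),
                      chi2 = numeric(), df = integer(), p = numeric(),
                      LOD = numeric(), effectSize = numeric(), r2 = numeric(),
                      stringsAsFactors = FALSE)
    structure(rep, mu = mu, sigma2 = sigma2, fit = fit,
              trait = traitName(population), n = length(ids),
              class = c("qtlReport", "data.frame"))
  }

  if (is.null(acc) || nrow(acc) == 0) {
    fit0 <- fitEmpiricalBayes(y, NULL, config$ebayes)
    return(emptyReport(fit0@beta, fit0@sigma2, fit0))
  }

  # final joint model of all accumulated effects on the ORIGINAL phenotype
  Wall <- effectColumns(acc, enc$x, enc$z)
  finalFit <- fitEmpiricalBayes(y, Wall, config$ebayes, effects = acc)
  finalTests <- lodTest(finalFit, y, Wall, config$lodThreshold)
  keep <- which(finalTests$significant & abs(finalTests$gamma) > 1e-6)
  if (length(keep) == 0)
    return(emptyReport(finalFit@beta, finalFit@sigma2, finalFit))

  rep <- acc[keep, , drop = FALSE]
  rep$LOD <- finalTests$LOD[keep]
  rep$effectSize <- finalTests$gamma[keep]
  rep$r2 <- vapply(keep, function(k)
    varianceExplained(Wall[, k], finalTests$gamma[k], y), 0)
  rep$effect <- effectNames(rep, markerNames)
  rep$marker1 <- markerNames[rep$locus1]
  rep$marker2 <- ifelse(is.na(rep$locus2), NA, markerNames[rep$locus2])
  rep$freq1 <- unname(freq[rep$locus1])
  rep$freq2 <- ifelse(is.na(rep$locus2), NA, unname(freq[rep$locus2]))
  isMain <- rep$kind %in% .MAIN_KINDS
  rep <- rbind(rep[isMain, ][order(rep$p[isMain]), ],
               rep[!isMain, ][order(rep$p[!isMain]), ])
  rownames(rep) <- NULL
  cols <- c("effect", "kind", "locus1", "locus2", "marker1", "marker2",
            "freq1", "freq2", "chi2", "df", "p", "LOD", "effectSize", "r2")
  rep <- rep[, cols]
  structure(rep, mu = finalFit@beta, sigma2 = finalFit@sigma2, fit = finalFit,
            trait = traitName(population), n = length(ids),
            class = c("qtlReport", "data.frame"))
}

#' Write a QTL report as TSV
#'
#' @param report a `qtlReport` from [runScan()].
#' @param file output path.
#' @return Invisibly, the file path.
#' @export
writeQTLReport <- function(report, file) {
  utils::write.table(as.data.frame(report), file, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(file)
}
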