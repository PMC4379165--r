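#' @import methods
NULL

.VALID_ROLES <- c("parentA", "parentB", "F1")
.MAIN_KINDS <- c("a", "d")
.INTERACTION_KINDS <- c("aa", "ad", "da", "dd")
.EFFECT_KINDS <- c(.MAIN_KINDS, .INTERACTION_KINDS)

#' Partial NCII mating-design population
#'
#' Container for a partial North Carolina design II population: a genotype
#' matrix over biallelic markers (codes count copies of the reference allele,
#' 0/1/2, `NA` = missing), a role per individual (`parentA`, e.g. sterile
#' lines; `parentB`, e.g. restorer lines; `F1` hybrids), the realized cross
#' pedigree, and one quantitative trait.
#'
#' @slot genotypes numeric matrix, individuals x markers, values in
#'   \{0, 1, 2, NA\}; rownames are individual ids, colnames marker names.
#' @slot roles named character vector over all individuals with values
#'   `parentA`, `parentB` or `F1`.
#' @slot pedigree data.frame with columns `f1`, `parentA`, `parentB`; one row
#'   per realized cross. A partial design realizes only a subset of the
#'   |parentA| x |parentB| factorial.
#' @slot phenotypes named numeric vector (may contain `NA` for individuals
#'   without a trait record); names are a subset of the individual ids.
#' @slot traitName single string naming the trait.
#'
#' @seealso [NCIIPopulation()] constructor, [loadPopulation()],
#'   [simulateNCIIPopulation()]
#' @export
setClass("NCIIPopulation",
  representation(
    genotypes = "matrix",
    roles = "character",
    pedigree = "data.frame",
    phenotypes = "numeric",
    traitName = "character"
  )
)

setValidity("NCIIPopulation", function(object) {
  g <- object@genotypes
  msgs <- character()
  ids <- rownames(g)
  if (is.null(ids) || anyDuplicated(ids))
    msgs <- c(msgs, "genotype rownames must be unique individual ids")
  if (is.null(colnames(g)) || anyDuplicated(colnames(g)))
    msgs <- c(msgs, "genotype colnames must be unique marker names")
  bad <- !(g %in% c(0, 1, 2) | is.na(g))
  if (any(bad))
    msgs <- c(msgs, "genotype codes must be 0, 1, 2 or NA")
  if (!setequal(names(object@roles), ids))
    msgs <- c(msgs, "roles must be named for exactly the genotyped individuals")
  if (!all(object@roles %in% .VALID_ROLES))
    msgs <- c(msgs, sprintf("roles must be one of %s",
                            paste(.VALID_ROLES, collapse = ", ")))
  ped <- object@pedigree
  if (!all(c("f1", "parentA", "parentB") %in% colnames(ped))) {
    msgs <- c(msgs, "pedigree must have columns f1, parentA, parentB")
  } else if (nrow(ped) > 0) {
    roles <- object@roles
    if (!all(ped$parentA %in% ids) || !all(ped$parentB %in% ids) ||
        !all(ped$f1 %in% ids))
      msgs <- c(msgs, "pedigree references individuals absent from genotypes")
    else {
      if (!all(roles[ped$parentA] == "parentA"))
        msgs <- c(msgs, "pedigree parentA column must reference parentA-role individuals")
      if (!all(roles[ped$parentB] == "parentB"))
        msgs <- c(msgs, "pedigree parentB column must reference parentB-role individuals")
      if (!all(roles[ped$f1] == "F1"))
        msgs <- c(msgs, "pedigree f1 column must reference F1-role individuals")
      nA <- sum(roles == "parentA"); nB <- sum(roles == "parentB")
      if (nrow(unique(ped[, c("parentA", "parentB")])) > nA * nB)
        msgs <- c(msgs, "pedigree has more distinct crosses than |parentA| x |parentB|")
    }
  }
  ph <- object@phenotypes
  if (length(ph) && (is.null(names(ph)) || !all(names(ph) %in% ids)))
    msgs <- c(msgs, "phenotype names must be a subset of the individual ids")
  if (length(ph) && any(is.infinite(ph)))
    msgs <- c(msgs, "phenotypes must be finite or NA")
  if (length(object@traitName) != 1)
    msgs <- c(msgs, "traitName must be a single string")
  if (length(msgs)) msgs else TRUE
})

#' Construct an NCIIPopulation
#'
#' @param genotypes individuals x markers numeric matrix of codes 0/1/2/NA
#'   with row and column names.
#' @param roles named character vector (`parentA`/`parentB`/`F1`), or a
#'   character vector in genotype row order.
#' @param pedigree data.frame with columns `f1`, `parentA`, `parentB`
#'   (default: no realized crosses).
#' @param phenotypes named numeric vector of trait values; individuals
#'   without an entry are treated as unphenotyped.
#' @param traitName trait label used in reports.
#' @return A validated [NCIIPopulation-class] object.
#' @examples
#' g <- rbind(P1 = c(M1 = 2, M2 = 0), R1 = c(2, 2), H1 = c(2, 1))
#' pop <- NCIIPopulation(g, c(P1 = "parentA", R1 = "parentB", H1 = "F1"),
#'                       data.frame(f1 = "H1", parentA = "P1", parentB = "R1"),
#'                       c(P1 = 10, R1 = 12, H1 = 13))
#' pop
#' @export
NCIIPopulation <- function(genotypes, roles, pedigree = NULL, phenotypes = numeric(),
                           traitName = "trait") {
  genotypes <- as.matrix(genotypes)
  storage.mode(genotypes) <- "double"
  if (is.null(names(roles))) names(roles) <- rownames(genotypes)
  if (is.null(pedigree))
    pedigree <- data.frame(f1 = character(), parentA = character(),
                           parentB = character(), stringsAsFactors = FALSE)
  ph <- as.numeric(phenotypes)
  names(ph) <- names(phenotypes)
  new("NCIIPopulation", genotypes = genotypes, roles = roles,
      pedigree = pedigree, phenotypes = ph, traitName = traitName)
}

#' Empirical Bayes shrinkage fit
#'
#' Result of fitting the selected-effect linear model Y = X beta + Z gamma + e
#' by the empirical Bayesian EM algorithm, where each effect gamma_k carries a
#' normal prior N(0, sigma2_k) and the variance components sigma2_k are
#' estimated by EM together with the intercept beta (the population mean mu)
#' and the residual variance sigma2.
#'
#' @slot beta intercept estimate (population mean).
#' @slot sigma2 residual variance estimate.
#' @slot gamma posterior means E(gamma_k), one per effect column.
#' @slot gammaVar posterior variances var(gamma_k).
#' @slot sigma2k per-effect prior variance components.
#' @slot logLik log marginal likelihood at the converged parameters.
#' @slot logLikTrace log marginal likelihood after each EM iteration.
#' @slot iterations number of EM iterations used.
#' @slot converged whether the parameter changes fell below tolerance.
#' @slot effects data.frame of effect descriptors (columns `kind`, `locus1`,
#'   `locus2`), one row per Z column; may be empty for anonymous columns.
#' @seealso [fitEmpiricalBayes()]
#' @export
setClass("EBayesFit",
  representation(
    beta = "numeric", sigma2 = "numeric",
    gamma = "numeric", gammaVar = "numeric", sigma2k = "numeric",
    logLik = "numeric", logLikTrace = "numeric",
    iterations = "integer", converged = "logical",
    effects = "data.frame"
  )
)

setValidity("EBayesFit", function(object) {
  msgs <- character()
  if (length(object@sigma2) != 1 || object@sigma2 <= 0)
    msgs <- c(msgs, "sigma2 must be a single positive value")
  q <- length(object@gamma)
  if (length(object@sigma2k) != q || length(object@gammaVar) != q)
    msgs <- c(msgs, "gamma, gammaVar and sigma2k must have one entry per effect")
  if (q > 0 && any(object@sigma2k < 0))
    msgs <- c(msgs, "sigma2k must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Predicted / observed hybrid value table
#'
#' Complete parentA x parentB table of hybrid values: observed F1 phenotypes
#' where a cross was realized (and observed values are requested), otherwise
#' genotypic values predicted from the detected QTL.
#'
#' @slot values numeric matrix, rows = parentA lines, columns = parentB lines.
#' @slot provenance character matrix of the same shape, `"observed"` or
#'   `"predicted"` per cell.
#' @seealso [predictHybridTable()], [combiningAbilities()]
#' @export
setClass("HybridTable",
  representation(values = "matrix", provenance = "matrix")
)

setValidity("HybridTable", function(object) {
  msgs <- character()
  if (!identical(dim(object@values), dim(object@provenance)))
    msgs <- c(msgs, "values and provenance must have identical dimensions")
  if (any(!is.finite(object@values)))
    msgs <- c(msgs, "hybrid table must be complete (finite values)")
  if (!all(object@provenance %in% c("observed", "predicted")))
    msgs <- c(msgs, "provenance must be 'observed' or 'predicted'")
  if (length(msgs)) msgs else TRUE
})

#' Combining-ability decomposition of a hybrid table
#'
#' Two-way main-effect decomposition of a complete hybrid value table:
#' v_ij = grand mean + GCA_i + GCA_j + SCA_ij, with GCA the unweighted
#' row/column mean deviations (general combining ability) and SCA the
#' cell residual (specific combining ability). `bv` holds the hybrid value
#' v_ij itself, the quantity crosses are ranked by.
#'
#' @slot grandMean grand mean of the table.
#' @slot gcaA named GCA per parentA line (row mean - grand mean).
#' @slot gcaB named GCA per parentB line (column mean - grand mean).
#' @slot sca SCA matrix (rows parentA, columns parentB).
#' @slot bv hybrid value matrix (same as the table values).
#' @seealso [combiningAbilities()], [rankElites()]
#' @export
setClass("CombiningAbilities",
  representation(grandMean = "numeric", gcaA = "numeric", gcaB = "numeric",
                 sca = "matrix", bv = "matrix")
)
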