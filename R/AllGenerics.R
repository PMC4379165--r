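#' @rdname NCIIPopulation-class
#' @param object,x an `NCIIPopulation`
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))

#' @rdname NCIIPopulation-class
#' @export
setGeneric("roles", function(x) standardGeneric("roles"))

#' @rdname NCIIPopulation-class
#' @export
setGeneric("pedigree", function(x) standardGeneric("pedigree"))

#' @rdname NCIIPopulation-class
#' @export
setGeneric("phenotypes", function(x) standardGeneric("phenotypes"))

#' @rdname NCIIPopulation-class
#' @export
setGeneric("traitName", function(x) standardGeneric("traitName"))

#' @rdname NCIIPopulation-class
#' @export
setMethod("genotypes", "NCIIPopulation", function(x) x@genotypes)

#' @rdname NCIIPopulation-class
#' @export
setMethod("roles", "NCIIPopulation", function(x) x@roles)

#' @rdname NCIIPopulation-class
#' @export
setMethod("pedigree", "NCIIPopulation", function(x) x@pedigree)

#' @rdname NCIIPopulation-class
#' @export
setMethod("phenotypes", "NCIIPopulation", function(x) {
  ids <- rownames(x@genotypes)
  full <- setNames(rep(NA_real_, length(ids)), ids)
  full[names(x@phenotypes)] <- x@phenotypes
  full
})

#' @rdname NCIIPopulation-class
#' @export
setMethod("traitName", "NCIIPopulation", function(x) x@traitName)

#' @rdname NCIIPopulation-class
#' @export
setMethod("show", "NCIIPopulation", function(object) {
  r <- object@roles
  cat(sprintf(
    "NCIIPopulation: %d individuals x %d markers (trait '%s')\n",
    nrow(object@genotypes), ncol(object@genotypes), object@traitName))
  cat(sprintf("  parentA: %d  parentB: %d  F1: %d\n",
              sum(r == "parentA"), sum(r == "parentB"), sum(r == "F1")))
  cat(sprintf("  realized crosses: %d of %d possible\n",
              nrow(object@pedigree),
              sum(r == "parentA") * sum(r == "parentB")))
  cat(sprintf("  phenotyped: %d\n", sum(!is.na(object@phenotypes))))
})

#' @rdname EBayesFit-class
#' @param object an `EBayesFit`
#' @export
setMethod("show", "EBayesFit", function(object) {
  cat(sprintf(
    "EBayesFit: %d effects, beta = %.4g, sigma2 = %.4g\n",
    length(object@gamma), object@beta, object@sigma2))
  cat(sprintf("  logLik = %.4f after %d iterations (%s)\n",
              object@logLik, object@iterations,
              if (object@converged) "converged" else "NOT converged"))
  cat(sprintf("  non-zero effects (|E(gamma)| > 1e-6): %d\n",
              sum(abs(object@gamma) > 1e-6)))
})

#' @rdname HybridTable-class
#' @param object a `HybridTable`
#' @export
setMethod("show", "HybridTable", function(object) {
  cat(sprintf("HybridTable: %d parentA x %d parentB (%d observed, %d predicted)\n",
              nrow(object@values), ncol(object@values),
              sum(object@provenance == "observed"),
              sum(object@provenance == "predicted")))
})

#' @rdname CombiningAbilities-class
#' @param object a `CombiningAbilities`
#' @export
setMethod("show", "CombiningAbilities", function(object) {
  cat(sprintf("CombiningAbilities: grand mean %.4g; %d parentA, %d parentB\n",
              object@grandMean, length(object@gcaA), length(object@gcaB)))
  cat(sprintf("  GCA(parentA) range: [%.3g, %.3g]; GCA(parentB) range: [%.3g, %.3g]\n",
              min(object@gcaA), max(object@gcaA),
              min(object@gcaB), max(object@gcaB)))
})

#' Values and provenance of a hybrid table
#' @param x a `HybridTable`
#' @return `hybridValues`: numeric matrix; `hybridProvenance`: character matrix.
#' @rdname HybridTable-class
#' @export
hybridValues <- function(x) x@values

#' @rdname HybridTable-class
#' @export
hybridProvenance <- function(x) x@provenance
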