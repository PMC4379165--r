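#' Load a partial NCII population from delimited text files
#'
#' Reads the three comma-delimited tables describing a partial NCII mating
#' design population and returns a validated [NCIIPopulation-class]. Genotype
#' codes count copies of the per-marker reference allele (0/1/2); an empty
#' field is a missing code. Individuals present in the genotype table but
#' absent from the phenotype table are retained with a missing phenotype (they
#' are excluded from mapping but still usable for pedigree and prediction).
#'
#' @param genotypeFile CSV with header `id,role,<marker1>,...`; roles are
#'   `parentA`, `parentB` or `F1`.
#' @param phenotypeFile CSV with header `id,<trait>`; the first trait column
#'   is used unless `trait` names one.
#' @param pedigreeFile CSV with header `f1_id,parentA_id,parentB_id`.
#' @param trait optional trait column name.
#' @param nonInbredParent what to do when a parent carries a heterozygous
#'   code: `"warning"` (default) or `"error"`.
#' @return An [NCIIPopulation-class].
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("id,role,M1,M2", "P1,parentA,2,0", "R1,parentB,0,0",
#'              "H1,F1,1,0"), file.path(dir, "g.csv"))
#' writeLines(c("id,oil", "P1,41.2", "R1,43.0", "H1,45.1"),
#'            file.path(dir, "p.csv"))
#' writeLines(c("f1_id,parentA_id,parentB_id", "H1,P1,R1"),
#'            file.path(dir, "d.csv"))
#' pop <- loadPopulation(file.path(dir, "g.csv"), file.path(dir, "p.csv"),
#'                       file.path(dir, "d.csv"))
#' @export
loadPopulation <- function(genotypeFile, phenotypeFile, pedigreeFile,
                           trait = NULL,
                           nonInbredParent = c("warning", "error")) {
  nonInbredParent <- match.arg(nonInbredParent)
  for (f in c(genotypeFile, phenotypeFile, pedigreeFile))
    if (!file.exists(f)) stop("file not found: ", f)

  gt <- utils::read.csv(genotypeFile, check.names = FALSE,
                        colClasses = "character", stringsAsFactors = FALSE)
  if (!all(c("id", "role") %in% colnames(gt)[1:2]))
    stop("genotype file must start with columns 'id,role'")
  if (anyDuplicated(gt$id))
    stop("duplicate individual id(s) in genotype file: ",
         paste(unique(gt$id[duplicated(gt$id)]), collapse = ", "))
  markers <- setdiff(colnames(gt), c("id", "role"))
  if (anyDuplicated(markers)) stop("duplicate marker name(s) in genotype file")
  g <- as.matrix(gt[, markers, drop = FALSE])
  suppressWarnings(storage.mode(g) <- "double")
  rownames(g) <- gt$id
  raw <- as.matrix(gt[, markers, drop = FALSE])
  unparsed <- !is.na(raw) & trimws(raw) != "" & is.na(g)
  if (any(unparsed))
    stop("non-numeric genotype code(s), e.g. '",
         raw[which(unparsed)[1]], "'")
  bad <- !is.na(g) & !(g %in% c(0, 1, 2))
  if (any(bad)) stop("genotype codes must be 0, 1, 2 or empty")

  roles <- setNames(gt$role, gt$id)

  ph <- utils::read.csv(phenotypeFile, stringsAsFactors = FALSE)
  if (colnames(ph)[1] != "id") stop("phenotype file must start with column 'id'")
  if (anyDuplicated(ph$id)) stop("duplicate id(s) in phenotype file")
  if (is.null(trait)) trait <- colnames(ph)[2]
  if (!trait %in% colnames(ph)) stop("trait column '", trait, "' not found")
  unknown <- setdiff(ph$id, gt$id)
  if (length(unknown))
    stop("phenotyped individual(s) absent from genotype file: ",
         paste(unknown, collapse = ", "))
  phenotypes <- setNames(as.numeric(ph[[trait]]), ph$id)

  ped <- utils::read.csv(pedigreeFile, stringsAsFactors = FALSE,
                         colClasses = "character")
  colnames(ped) <- c("f1", "parentA", "parentB")
  missingRef <- setdiff(c(ped$parentA, ped$parentB, ped$f1), gt$id)
  if (length(missingRef))
    stop("pedigree references unknown individual(s): ",
         paste(missingRef, collapse = ", "))

  parents <- names(roles)[roles %in% c("parentA", "parentB")]
  het <- g[parents, , drop = FALSE] == 1
  if (any(het, na.rm = TRUE)) {
    w <- which(het, arr.ind = TRUE)
    msg <- sprintf("non-inbred parent genotype(s): %s at %s",
                   rownames(het)[w[1, 1]], markers[w[1, 2]])
    if (nonInbredParent == "error") stop(msg) else warning(msg)
  }

  NCIIPopulation(g, roles, ped, phenotypes, traitName = trait)
}

#' Write a population back to delimited text files
#'
#' Inverse of [loadPopulation()]: writes `genotypes.csv`, `phenotypes.csv` and
#' `pedigree.csv` into `dir` so that a load/write/load cycle round-trips the
#' code domain bit-identically.
#'
#' @param population an [NCIIPopulation-class].
#' @param dir output directory (created if needed).
#' @return Invisibly, the three file paths.
#' @export
writePopulation <- function(population, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- genotypes(population)
  gdf <- data.frame(id = rownames(g), role = roles(population)[rownames(g)],
                    as.data.frame(g, check.names = FALSE),
                    check.names = FALSE, stringsAsFactors = FALSE)
  gFile <- file.path(dir, "genotypes.csv")
  utils::write.csv(gdf, gFile, row.names = FALSE, quote = FALSE, na = "")
  ph <- population@phenotypes
  pdf <- data.frame(id = names(ph), trait = unname(ph))
  colnames(pdf)[2] <- traitName(population)
  pFile <- file.path(dir, "phenotypes.csv")
  utils::write.csv(pdf, pFile, row.names = FALSE, quote = FALSE, na = "")
  ped <- pedigree(population)
  colnames(ped) <- c("f1_id", "parentA_id", "parentB_id")
  dFile <- file.path(dir, "pedigree.csv")
  utils::write.csv(ped, dFile, row.names = FALSE, quote = FALSE, na = "")
  invisible(c(genotypes = gFile, phenotypes = pFile, pedigree = dFile))
}

#' Deduce F1 genotypes from their inbred parents
#'
#' For every pedigree entry, the F1 code at each marker is the parental mean
#' code, `(codeA + codeB) / 2`; with inbred parents (codes 0 or 2) this lies in
#' \{0, 1, 2\}. A missing parent code propagates to a missing F1 code. F1 codes
#' already present are kept and checked for consistency with the deduction.
#' The operation is idempotent.
#'
#' @param population an [NCIIPopulation-class].
#' @return The population with F1 genotype codes filled in.
#' @export
deduceF1Genotypes <- function(population) {
  ped <- pedigree(population)
  if (nrow(ped) == 0) return(population)
  g <- genotypes(population)
  pA <- g[ped$parentA, , drop = FALSE]
  pB <- g[ped$parentB, , drop = FALSE]
  hetA <- which(pA == 1, arr.ind = TRUE)
  hetB <- which(pB == 1, arr.ind = TRUE)
  if (nrow(hetA) > 0)
    stop(sprintf("cannot deduce F1 genotype: parent %s heterozygous at marker %s",
                 ped$parentA[hetA[1, 1]], colnames(g)[hetA[1, 2]]))
  if (nrow(hetB) > 0)
    stop(sprintf("cannot deduce F1 genotype: parent %s heterozygous at marker %s",
                 ped$parentB[hetB[1, 1]], colnames(g)[hetB[1, 2]]))
  f1 <- (pA + pB) / 2
  rownames(f1) <- ped$f1
  existing <- g[ped$f1, , drop = FALSE]
  both <- !is.na(existing) & !is.na(f1)
  if (any(existing[both] != f1[both])) {
    w <- which(both & existing != f1, arr.ind = TRUE)
    stop(sprintf("provided F1 genotype inconsistent with parents: %s at marker %s",
                 ped$f1[w[1, 1]], colnames(g)[w[1, 2]]))
  }
  fill <- is.na(existing)
  existing[fill] <- f1[fill]
  g[ped$f1, ] <- existing
  population@genotypes <- g
  validObject(population)
  population
}

#' Reference-allele frequencies per marker
#'
#' Frequency of the reference allele per marker over a role subset of the
#' population: `sum(codes) / (2 * n_nonmissing)`.
#'
#' @param population an [NCIIPopulation-class].
#' @param over roles to include (default: all).
#' @return Named numeric vector over markers; `NA` (with a warning) for
#'   markers with no non-missing code in the subset.
#' @examples
#' g <- rbind(P1 = c(M = 2), P2 = c(M = 2), P3 = c(M = 0), H1 = c(M = 1))
#' pop <- NCIIPopulation(g, c(P1 = "parentA", P2 = "parentA",
#'                            P3 = "parentB", H1 = "F1"))
#' alleleFrequencies(pop)  # (2+2+0+1) / 8 = 0.625
#' @export
alleleFrequencies <- function(population, over = .VALID_ROLES) {
  g <- genotypes(population)
  keep <- roles(population)[rownames(g)] %in% over
  g <- g[keep, , drop = FALSE]
  nn <- colSums(!is.na(g))
  freq <- colSums(g, na.rm = TRUE) / (2 * nn)
  if (any(nn == 0)) {
    warning("allele frequency undefined (all codes missing) for marker(s): ",
            paste(colnames(g)[nn == 0], collapse = ", "))
    freq[nn == 0] <- NA_real_
  }
  freq
}

# Individuals used for mapping: non-missing phenotype and an allowed role.
mappedIndividuals <- function(population, mappingRoles = .VALID_ROLES) {
  ph <- population@phenotypes
  ids <- names(ph)[!is.na(ph)]
  ids[roles(population)[ids] %in% mappingRoles]
}
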