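#' Default eight-QTL simulation architecture
#'
#' Two additive, two dominance, and one each of aa, ad, da, dd interaction
#' QTL, all located on markers, spread across the marker panel, each with the
#' same heritability.
#'
#' @param m marker count (>= 10 so that the eight QTL sit on distinct loci).
#' @param h2 per-QTL heritability (default 0.05).
#' @return data.frame with columns `kind`, `locus1`, `locus2`, `h2`.
#' @export
defaultQTLArchitecture <- function(m, h2 = 0.05) {
  stopifnot(m >= 10)
  at <- function(f) pmax(1L, pmin(m, as.integer(round(f * m))))
  qtl <- data.frame(
    kind = c("a", "a", "d", "d", "aa", "ad", "da", "dd"),
    locus1 = c(at(0.05), at(0.30), at(0.50), at(0.70),
               at(0.10), at(0.25), at(0.40), at(0.60)),
    locus2 = c(NA, NA, NA, NA,
               at(0.55), at(0.65), at(0.80), at(0.95)),
    h2 = h2,
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(effectKeys(qtl)))
  qtl
}

#' Specify a partial NCII simulation
#'
#' Parameterization of one Monte Carlo setting: the marker panel, the
#' population structure (parentA lines, parentB lines, F1 count realized by a
#' partial cross scheme), the QTL architecture with per-QTL heritabilities,
#' and the phenotype model `y = mu + sum_i e_i w_i + N(0, sigma2)`.
#'
#' The default emulates the rapeseed study conditions: 205 markers at
#' reference-allele frequency 0.5, 298 parentA (sterile) lines, 143 parentB
#' (restorer) lines, 284 F1 hybrids (each parentB crossed to two sterile
#' lines), eight QTL, residual variance 1.
#'
#' @param markers marker count.
#' @param frequencies per-marker reference allele frequency in (0,1),
#'   recycled (default 0.5).
#' @param nParentA,nParentB,nF1 structure counts; `nF1 = 0` gives a
#'   parents-only design.
#' @param qtl QTL data.frame (`kind`, `locus1`, `locus2`, `h2`); default
#'   [defaultQTLArchitecture()].
#' @param sigma2 residual variance (default 1).
#' @param mu population mean (default 0).
#' @param crossesPerParentB distinct parentA mates drawn per parentB per
#'   cycle (default 2, mirroring restorer lines each crossed to a pair of
#'   sterile lines).
#' @return list of class `simulationSpec`.
#' @export
simulationSpec <- function(markers = 205, frequencies = 0.5,
                           nParentA = 298, nParentB = 143, nF1 = 284,
                           qtl = defaultQTLArchitecture(markers),
                           sigma2 = 1, mu = 0, crossesPerParentB = 2) {
  frequencies <- rep_len(frequencies, markers)
  stopifnot(all(frequencies > 0 & frequencies < 1),
            nParentA >= 0, nParentB >= 0, nF1 >= 0, sigma2 >= 0,
            sum(qtl$h2) < 1, all(qtl$h2 >= 0),
            all(qtl$kind %in% .EFFECT_KINDS),
            all(qtl$locus1 <= markers),
            all(is.na(qtl$locus2) | qtl$locus2 <= markers))
  if (nF1 > 0 && (nParentA < 2 || nParentB < 1))
    stop("F1 hybrids require at least 2 parentA and 1 parentB lines")
  structure(list(markers = markers, frequencies = frequencies,
                 nParentA = nParentA, nParentB = nParentB, nF1 = nF1,
                 qtl = canonicalizeEffects(qtl), sigma2 = sigma2, mu = mu,
                 crossesPerParentB = crossesPerParentB),
            class = "simulationSpec")
}

#' Simulate a partial NCII population
#'
#' Inbred parent genotypes are drawn per marker as code 2 with probability
#' equal to the reference-allele frequency, else 0, independently over
#' markers and individuals (no linkage: QTL sit on markers). The partial
#' pedigree cycles over parentB lines, each drawing `crossesPerParentB`
#' distinct random parentA mates, until the requested F1 count is reached;
#' F1 genotypes are deduced from the parents. Individuals are drawn in a
#' fixed order so that smaller structures are nested within larger ones at
#' the same seed.
#'
#' @param spec a [simulationSpec()].
#' @param seed integer seed (genotypes and pedigree only; phenotype noise is
#'   seeded separately in [simulatePhenotypes()]).
#' @return An [NCIIPopulation-class] without phenotypes.
#' @export
simulateNCIIPopulation <- function(spec, seed = 1L) {
  set.seed(seed)
  m <- spec$markers
  drawParents <- function(nInd, prefix) {
    codes <- 2 * (stats::runif(nInd * m) < rep(spec$frequencies, nInd))
    g <- matrix(codes, nrow = nInd, ncol = m, byrow = TRUE)
    rownames(g) <- sprintf("%s%04d", prefix, seq_len(nInd))
    g
  }
  gA <- drawParents(spec$nParentA, "A")
  gB <- drawParents(spec$nParentB, "B")
  colnames(gA) <- colnames(gB) <- sprintf("M%03d", seq_len(m))

  ped <- data.frame(f1 = character(), parentA = character(),
                    parentB = character(), stringsAsFactors = FALSE)
  gF <- matrix(numeric(0), 0, m, dimnames = list(NULL, colnames(gA)))
  if (spec$nF1 > 0) {
    crosses <- character(0)
    pedA <- character(0); pedB <- character(0)
    bIdx <- 0L
    while (length(pedA) < spec$nF1) {
      bIdx <- bIdx %% spec$nParentB + 1L
      b <- rownames(gB)[bIdx]
      mates <- sample(rownames(gA),
                      min(spec$crossesPerParentB, spec$nParentA))
      for (a in mates) {
        key <- paste(a, b)
        if (key %in% crosses) next
        crosses <- c(crosses, key)
        pedA <- c(pedA, a); pedB <- c(pedB, b)
        if (length(pedA) >= spec$nF1) break
      }
    }
    f1Ids <- sprintf("H%04d", seq_along(pedA))
    ped <- data.frame(f1 = f1Ids, parentA = pedA, parentB = pedB,
                      stringsAsFactors = FALSE)
    gF <- (gA[pedA, , drop = FALSE] + gB[pedB, , drop = FALSE]) / 2
    rownames(gF) <- f1Ids
  }

  g <- rbind(gA, gB, gF)
  rolesVec <- setNames(rep(c("parentA", "parentB", "F1"),
                           c(nrow(gA), nrow(gB), nrow(gF))), rownames(g))
  NCIIPopulation(g, rolesVec, ped, traitName = "simTrait")
}

#' Calibrate QTL effect magnitudes to target heritabilities
#'
#' Converts each QTL's heritability into a genetic variance
#' `sigma2_G = h2 * sigma2 / (1 - sum(h2))` (residual variance `sigma2`), and
#' sets the effect magnitude to `e = sqrt(sigma2_G / Var(w))`, where `Var(w)`
#' is the realized population variance (divisor n) of the QTL's dummy column
#' over the given individuals. By construction `Var(e w) = sigma2_G` exactly
#' in the simulated population.
#'
#' @param population an [NCIIPopulation-class].
#' @param spec a [simulationSpec()].
#' @param individuals ids over which variances are computed (default all).
#' @return `spec$qtl` with columns `sigma2G` and `effect` added.
#' @export
calibrateQTLEffects <- function(population, spec,
                                individuals = rownames(genotypes(population))) {
  qtl <- spec$qtl
  g <- genotypes(population)[individuals, , drop = FALSE]
  enc <- imputeEncoding(encodeGenotypes(g))
  W <- effectColumns(qtl, enc$x, enc$z)
  varPop <- function(v) mean((v - mean(v))^2)
  vw <- apply(W, 2, varPop)
  qtl$sigma2G <- qtl$h2 * spec$sigma2 / (1 - sum(qtl$h2))
  if (any(vw == 0 & qtl$sigma2G > 0))
    stop("zero-variance QTL column(s) in this population structure (",
         paste(effectNames(qtl[vw == 0, ], colnames(g)), collapse = ", "),
         "); e.g. dominance columns vanish in a parents-only design - ",
         "choose a structure containing F1 hybrids")
  qtl$effect <- ifelse(qtl$sigma2G == 0, 0, sqrt(qtl$sigma2G / vw))
  qtl
}

#' Simulate phenotypes from calibrated QTL
#'
#' `y = mu + sum_i e_i w_i + epsilon`, `epsilon ~ N(0, sigma2)` i.i.d. The
#' per-individual genotypic value (without noise) is kept as attribute
#' `genotypicValue` of the returned population's report; it is also returned
#' as an attribute of the phenotype vector.
#'
#' @param population an [NCIIPopulation-class].
#' @param qtlEffects output of [calibrateQTLEffects()].
#' @param spec a [simulationSpec()].
#' @param seed integer seed for the residual draw.
#' @param individuals ids to phenotype (default all).
#' @return The population with phenotypes set; the truth record (genotypic
#'   values, calibrated effects) is attached as attribute `truth` of the
#'   phenotype vector in `attr(, "truth")` of the returned object.
#' @export
simulatePhenotypes <- function(population, qtlEffects, spec, seed = 1L,
                               individuals = rownames(genotypes(population))) {
  set.seed(seed)
  g <- genotypes(population)[individuals, , drop = FALSE]
  enc <- imputeEncoding(encodeGenotypes(g))
  W <- effectColumns(qtlEffects, enc$x, enc$z)
  gv <- spec$mu + as.numeric(W %*% qtlEffects$effect)
  y <- gv + stats::rnorm(length(gv), 0, sqrt(spec$sigma2))
  names(y) <- individuals
  population@phenotypes <- y
  attr(population, "truth") <- list(
    mu = spec$mu, sigma2 = spec$sigma2, qtl = qtlEffects,
    genotypicValue = setNames(gv, individuals))
  population
}

#' Simulate one complete replicate
#'
#' Convenience wrapper: population, calibration and phenotypes, with the
#' genotype/pedigree and residual randomness seeded separately so that
#' conditions sharing a replicate index share genotypes and residual noise
#' (common random numbers across heritability / structure settings).
#'
#' @param spec a [simulationSpec()].
#' @param seed base integer seed.
#' @param mappingRoles roles whose individuals receive phenotypes and enter
#'   variance calibration (default all).
#' @return An [NCIIPopulation-class] with phenotypes and a `truth` attribute.
#' @export
simulateNCII <- function(spec, seed = 1L,
                         mappingRoles = c("parentA", "parentB", "F1")) {
  pop <- simulateNCIIPopulation(spec, seed = seed)
  ids <- rownames(genotypes(pop))[roles(pop) %in% mappingRoles]
  eff <- calibrateQTLEffects(pop, spec, individuals = ids)
  simulatePhenotypes(pop, eff, spec, seed = seed + 104729L,
                     individuals = ids)
}

#' Run a Monte Carlo mapping experiment
#'
#' Simulates `replicates` populations under `spec`, scans each with
#' [runScan()], and matches reported effects to the simulated truth by exact
#' descriptor equality. Per true QTL, power is the fraction of replicates
#' whose LOD exceeds the threshold; bias is the absolute difference between
#' the estimated and true effect in replicates where the QTL was detected.
#' The false positive rate is the count of reported effects not among the
#' true QTL divided by the number of zero effects in the full model
#' (`2m + 2m(m-1) - nQTL`) summed over replicates.
#'
#' @param spec a [simulationSpec()].
#' @param config a [scanConfig()].
#' @param replicates number of Monte Carlo replicates.
#' @param baseSeed base seed; replicate `i` uses `baseSeed + 7919 * i`.
#' @param mappingRoles roles phenotyped and mapped (default all).
#' @return list of class `metricsResult`: `perQTL` data.frame (descriptor,
#'   `h2`, `power`, `biasMean`, `biasSD`), `fpr`, `falsePositives`,
#'   `zeroEffects`, `replicates`.
#' @export
runExperiment <- function(spec, config = scanConfig(), replicates = 20,
                          baseSeed = 1L,
                          mappingRoles = c("parentA", "parentB", "F1")) {
  stopifnot(replicates >= 1)
  qtlKeys <- effectKeys(spec$qtl)
  nQTL <- length(qtlKeys)
  totalEffects <- 2 * spec$markers + 2 * spec$markers * (spec$markers - 1)
  detected <- matrix(FALSE, replicates, nQTL)
  bias <- matrix(NA_real_, replicates, nQTL)
  fp <- 0L
  config$mappingRoles <- mappingRoles

  for (i in seq_len(replicates)) {
    pop <- simulateNCII(spec, seed = baseSeed + 7919L * i,
                        mappingRoles = mappingRoles)
    truth <- attr(pop, "truth")
    report <- runScan(pop, config)
    if (nrow(report) == 0) next
    repKeys <- effectKeys(report[, c("kind", "locus1", "locus2")])
    hit <- match(repKeys, qtlKeys)
    fp <- fp + sum(is.na(hit))
    found <- which(!is.na(hit))
    detected[i, hit[found]] <- TRUE
    bias[i, hit[found]] <- abs(report$effectSize[found] -
                                 truth$qtl$effect[hit[found]])
  }

  perQTL <- spec$qtl
  perQTL$power <- colMeans(detected)
  perQTL$biasMean <- suppressWarnings(apply(bias, 2, mean, na.rm = TRUE))
  perQTL$biasSD <- suppressWarnings(apply(bias, 2, stats::sd, na.rm = TRUE))
  zeroEffects <- (totalEffects - nQTL) * replicates
  structure(list(perQTL = perQTL, fpr = fp / zeroEffects,
                 falsePositives = fp, zeroEffects = zeroEffects,
                 replicates = replicates, totalEffects = totalEffects),
            class = "metricsResult")
}
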