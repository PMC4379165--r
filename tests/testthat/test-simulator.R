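test_that("simulated structures honor the requested counts and pedigree scheme", {
  qtl <- data.frame(kind = "a", locus1 = 3, locus2 = NA, h2 = 0.05)
  # parents-only: 300 + 300, no crosses
  po <- simulateNCIIPopulation(
    simulationSpec(markers = 12, nParentA = 300, nParentB = 300, nF1 = 0,
                   qtl = qtl), seed = 1)
  expect_equal(nrow(genotypes(po)), 600)
  expect_equal(nrow(pedigree(po)), 0)
  expect_equal(sum(roles(po) == "parentA"), 300)
  expect_equal(sum(roles(po) == "parentB"), 300)

  # 1:1:2-style n = 500: 200 parentA + 100 parentB + 200 F1
  s500 <- simulateNCIIPopulation(
    simulationSpec(markers = 12, nParentA = 200, nParentB = 100, nF1 = 200,
                   qtl = qtl), seed = 1)
  r <- roles(s500)
  expect_equal(unname(c(sum(r == "parentA"), sum(r == "parentB"),
                        sum(r == "F1"))), c(200L, 100L, 200L))
  ped <- pedigree(s500)
  expect_equal(nrow(ped), 200)
  expect_false(anyDuplicated(ped[, c("parentA", "parentB")]) > 0)
  # each parentB line used for (about) crossesPerParentB crosses
  expect_true(all(table(ped$parentB) == 2))

  # parents are inbred; F1 codes are parental means in {0, 1, 2}
  g <- genotypes(s500)
  expect_true(all(g[r != "F1", ] %in% c(0, 2)))
  f1codes <- g[ped$f1, ]
  expect_true(all(f1codes %in% c(0, 1, 2)))
  expect_equal(f1codes,
               (g[ped$parentA, ] + g[ped$parentB, ]) / 2,
               ignore_attr = TRUE)
})

test_that("realized allele frequencies concentrate near their targets", {
  spec <- simulationSpec(markers = 10, frequencies = 0.5, nParentA = 300,
                         nParentB = 300, nF1 = 0,
                         qtl = data.frame(kind = "a", locus1 = 1,
                                          locus2 = NA, h2 = 0.05))
  pop <- simulateNCIIPopulation(spec, seed = 42)
  f <- alleleFrequencies(pop)
  expect_true(all(f > 0.4 & f < 0.6))
})

test_that("effect calibration hits the closed-form genetic variances exactly", {
  spec5 <- simulationSpec(markers = 20, nParentA = 100, nParentB = 50,
                          nF1 = 150, qtl = defaultQTLArchitecture(20, 0.05))
  pop <- simulateNCIIPopulation(spec5, seed = 6)
  eff <- calibrateQTLEffects(pop, spec5)
  expect_equal(eff$sigma2G, rep(0.05 / 0.60, 8), tolerance = 1e-12)

  spec2 <- simulationSpec(markers = 20, nParentA = 100, nParentB = 50,
                          nF1 = 150, qtl = defaultQTLArchitecture(20, 0.02))
  eff2 <- calibrateQTLEffects(pop, spec2)
  expect_equal(eff2$sigma2G, rep(0.02 / 0.84, 8), tolerance = 1e-12)

  # identity: realized Var(e * w) = sigma2G by construction
  enc <- NCIIqtl:::imputeEncoding(NCIIqtl:::encodeGenotypes(genotypes(pop)))
  W <- NCIIqtl:::effectColumns(eff, enc$x, enc$z)
  varPop <- function(v) mean((v - mean(v))^2)
  for (i in 1:8)
    expect_equal(varPop(W[, i] * eff$effect[i]), eff$sigma2G[i],
                 tolerance = 1e-12)

  # dominance columns are inestimable in parents-only structures
  specPO <- simulationSpec(markers = 20, nParentA = 60, nParentB = 60,
                           nF1 = 0, qtl = defaultQTLArchitecture(20, 0.05))
  popPO <- simulateNCIIPopulation(specPO, seed = 6)
  expect_error(calibrateQTLEffects(popPO, specPO), "zero-variance")
})

test_that("phenotypes decompose into genotypic value plus normal noise", {
  spec0 <- simulationSpec(markers = 15, nParentA = 100, nParentB = 50,
                          nF1 = 150, sigma2 = 0,
                          qtl = defaultQTLArchitecture(15, 0.05))
  pop0 <- simulateNCII(spec0, seed = 9)
  truth0 <- attr(pop0, "truth")
  expect_equal(unname(pop0@phenotypes),
               unname(truth0$genotypicValue[names(pop0@phenotypes)]))

  # the clean decomposition Var(y) = sigma2 / (1 - sum h2) presumes mutually
  # independent QTL columns; that holds in an all-F1 population (dominance
  # dummies at distinct markers are independent there), whereas mixing
  # parents and F1 correlates dominance-type columns through the shared
  # parent/F1 partition and inflates the total variance
  spec <- simulationSpec(markers = 20, nParentA = 150, nParentB = 150,
                         nF1 = 725, qtl = defaultQTLArchitecture(20, 0.05))
  pop <- simulateNCII(spec, seed = 9, mappingRoles = "F1")
  vy <- stats::var(pop@phenotypes)
  expect_equal(length(pop@phenotypes), 725)
  expect_lt(abs(vy - 1 / 0.60) / (1 / 0.60), 0.10)   # sigma2 / (1 - sum h2)

  # pure noise is N(mu, sigma2)
  specN <- simulationSpec(markers = 15, nParentA = 240, nParentB = 120,
                          nF1 = 240, mu = 3,
                          qtl = defaultQTLArchitecture(15, 0))
  popN <- simulateNCII(specN, seed = 10)
  expect_lt(abs(mean(popN@phenotypes) - 3), 0.15)
  expect_lt(abs(stats::var(popN@phenotypes) - 1), 0.15)
})

test_that("replicates are bit-identical under the same seed", {
  spec <- simulationSpec(markers = 12, nParentA = 40, nParentB = 20,
                         nF1 = 60, qtl = defaultQTLArchitecture(12, 0.05))
  p1 <- simulateNCII(spec, seed = 77)
  p2 <- simulateNCII(spec, seed = 77)
  expect_identical(genotypes(p1), genotypes(p2))
  expect_identical(pedigree(p1), pedigree(p2))
  expect_identical(p1@phenotypes, p2@phenotypes)
  p3 <- simulateNCII(spec, seed = 78)
  expect_false(identical(p1@phenotypes, p3@phenotypes))
})

test_that("the experiment harness books power, bias and the FPR denominator", {
  spec <- simulationSpec(markers = 12, nParentA = 80, nParentB = 40,
                         nF1 = 120, qtl = defaultQTLArchitecture(12, 0.10))
  res <- runExperiment(spec, scanConfig(), replicates = 2, baseSeed = 3)
  m <- 12
  expect_equal(res$totalEffects, 2 * m + 2 * m * (m - 1))
  expect_equal(res$zeroEffects, (res$totalEffects - 8) * 2)
  expect_true(all(res$perQTL$power >= 0 & res$perQTL$power <= 1))
  expect_gte(res$fpr, 0)
  expect_lte(res$fpr, 1)
  expect_true(all(is.na(res$perQTL$biasMean) | res$perQTL$biasMean >= 0))
  # strong main QTL should be found in both replicates
  expect_true(all(res$perQTL$power[res$perQTL$kind == "a"] == 1))
})
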