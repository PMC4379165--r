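test_that("the 2x2 combining-ability decomposition matches hand arithmetic", {
  v <- matrix(c(10, 14, 12, 20), 2, 2,
              dimnames = list(c("A1", "A2"), c("B1", "B2")))
  ca <- combiningAbilities(v)
  expect_equal(ca@grandMean, 14)
  expect_equal(unname(ca@gcaA), c(-3, 3))
  expect_equal(unname(ca@gcaB), c(-2, 2))
  expect_equal(unname(ca@sca), matrix(c(1, -1, -1, 1), 2, 2))
  elites <- rankElites(ca, top = 1)
  expect_identical(elites$crosses$parentA, "A2")
  expect_identical(elites$crosses$parentB, "B2")
  expect_equal(elites$crosses$BV, 20)
  expect_equal(elites$crosses$SCA, 1)
})

test_that("reconstruction and zero-sum identities hold on random tables", {
  set.seed(4)
  v <- matrix(rnorm(7 * 5, 40, 3), 7, 5,
              dimnames = list(paste0("A", 1:7), paste0("B", 1:5)))
  ca <- combiningAbilities(v)
  recon <- ca@grandMean + outer(ca@gcaA, ca@gcaB, `+`) + ca@sca
  expect_equal(unname(recon), unname(v), tolerance = 1e-12)
  expect_lt(abs(sum(ca@gcaA)), 1e-9)
  expect_lt(abs(sum(ca@gcaB)), 1e-9)
  expect_true(all(abs(rowSums(ca@sca)) < 1e-9))
  expect_true(all(abs(colSums(ca@sca)) < 1e-9))
})

test_that("purely additive and constant tables have zero SCA / GCA", {
  g <- rnorm(6); h <- rnorm(4)
  v <- outer(g, h, `+`)
  dimnames(v) <- list(paste0("A", 1:6), paste0("B", 1:4))
  ca <- combiningAbilities(v)
  expect_true(all(abs(ca@sca) < 1e-9))
  cc <- combiningAbilities(matrix(7, 3, 3,
                                  dimnames = list(paste0("A", 1:3),
                                                  paste0("B", 1:3))))
  expect_true(all(abs(cc@gcaA) < 1e-12) && all(abs(cc@sca) < 1e-12))
  # all-equal table: ranking falls back to id order with zero GCA
  el <- rankElites(cc, top = 2)
  expect_identical(el$parentA$id, c("A1", "A2"))
  expect_equal(el$parentA$GCA, c(0, 0))
})

test_that("single-QTL hybrid predictions follow the cross genetics", {
  g <- rbind(A1 = c(M1 = 2), B1 = c(M1 = 0), B2 = c(M1 = 2))
  pop <- NCIIPopulation(g, c(A1 = "parentA", B1 = "parentB", B2 = "parentB"))
  mkReport <- function(kind, effect) {
    structure(data.frame(kind = kind, locus1 = 1L, locus2 = NA_integer_,
                         effectSize = effect), mu = 10)
  }
  # additive QTL a=2: AA x aa -> Aa, x = 0 -> v = mu; AA x AA -> x = 1
  va <- hybridValues(predictHybridTable(pop, mkReport("a", 2),
                                        useObserved = FALSE))
  expect_equal(unname(va["A1", ]), c(10, 12))
  # dominance QTL d=1: AA x aa -> het -> v = mu + 1; AA x AA -> v = mu
  vd <- hybridValues(predictHybridTable(pop, mkReport("d", 1),
                                        useObserved = FALSE))
  expect_equal(unname(vd["A1", ]), c(11, 10))
})

test_that("with the true effects supplied, predictions equal true genotypic values", {
  pop <- simPop(m = 12, nA = 20, nB = 10, nF1 = 35, h2 = 0.08, seed = 13)
  truth <- attr(pop, "truth")
  report <- structure(
    data.frame(kind = truth$qtl$kind, locus1 = truth$qtl$locus1,
               locus2 = truth$qtl$locus2, effectSize = truth$qtl$effect),
    mu = truth$mu)
  ht <- predictHybridTable(pop, report, useObserved = FALSE)
  ped <- pedigree(pop)
  pred <- hybridValues(ht)[cbind(ped$parentA, ped$parentB)]
  expect_equal(unname(pred), unname(truth$genotypicValue[ped$f1]),
               tolerance = 1e-10)
  expect_gte(stats::cor(pred, truth$genotypicValue[ped$f1]), 1 - 1e-12)

  # observed substitution marks provenance and reuses measured phenotypes
  ht2 <- predictHybridTable(pop, report, useObserved = TRUE)
  prov <- hybridProvenance(ht2)
  expect_equal(sum(prov == "observed"), nrow(unique(ped[, 2:3])))
  expect_equal(hybridValues(ht2)[ped$parentA[1], ped$parentB[1]],
               unname(pop@phenotypes[ped$f1[1]]))
})

test_that("hybrid prediction is invariant to parent ordering", {
  pop <- simPop(m = 10, nA = 8, nB = 6, nF1 = 12, h2 = 0.08, seed = 17)
  truth <- attr(pop, "truth")
  report <- structure(
    data.frame(kind = truth$qtl$kind, locus1 = truth$qtl$locus1,
               locus2 = truth$qtl$locus2, effectSize = truth$qtl$effect),
    mu = truth$mu)
  v1 <- hybridValues(predictHybridTable(pop, report, useObserved = FALSE))
  perm <- sample(nrow(genotypes(pop)))
  pop2 <- NCIIPopulation(genotypes(pop)[perm, ], roles(pop)[perm],
                         pedigree(pop), pop@phenotypes, traitName(pop))
  v2 <- hybridValues(predictHybridTable(pop2, report, useObserved = FALSE))
  expect_equal(v1, v2[rownames(v1), colnames(v1)])
})

test_that("missing parent codes at QTL markers are imputed with a warning", {
  g <- rbind(A1 = c(M1 = 2, M2 = 2), A2 = c(M1 = NA, M2 = 0),
             B1 = c(M1 = 0, M2 = 2))
  pop <- NCIIPopulation(g, c(A1 = "parentA", A2 = "parentA", B1 = "parentB"))
  report <- structure(data.frame(kind = "a", locus1 = 1L,
                                 locus2 = NA_integer_, effectSize = 1),
                      mu = 0)
  expect_warning(ht <- predictHybridTable(pop, report, useObserved = FALSE),
                 "imputed")
  expect_true(all(is.finite(hybridValues(ht))))
})
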