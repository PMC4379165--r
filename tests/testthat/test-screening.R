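test_that("extreme-group selection takes floor(fraction * n) per tail with id tie-breaks", {
  set.seed(1)
  y <- setNames(rnorm(725), sprintf("i%03d", 1:725))
  tails <- selectExtremes(y, 0.10)
  expect_length(tails$high, 72)
  expect_length(tails$low, 72)
  expect_length(intersect(tails$high, tails$low), 0)
  expect_equal(min(y[tails$high]), unname(sort(y, decreasing = TRUE)[72]))

  y10 <- setNames(rnorm(10), letters[1:10])
  expect_equal(lengths(selectExtremes(y10, 0.10)), c(high = 1, low = 1))

  # all-tied phenotypes: tails filled in ascending id order
  yt <- setNames(rep(1, 10), letters[10:1])
  tt <- selectExtremes(yt, 0.2)
  expect_identical(tt$low, c("a", "b"))
  expect_identical(tt$high, c("a", "b"))

  expect_error(selectExtremes(y10, 0.6), "fraction")
  expect_error(selectExtremes(setNames(rnorm(9), letters[1:9]), 0.05),
               "no individuals")
})

test_that("chi-square independence matches stats::chisq.test without correction", {
  # hand-checked 2x2: [[30,10],[10,30]] -> chi2 = 20, df = 1 (all E = 20)
  column <- rep(c(0, 1), c(40, 40))
  group <- c(rep(TRUE, 30), rep(FALSE, 10), rep(TRUE, 10), rep(FALSE, 30))
  res <- chi2Independence(column, group)
  expect_equal(res$chi2, 20)
  expect_equal(res$df, 1)
  expect_equal(res$p, stats::pchisq(20, 1, lower.tail = FALSE))

  set.seed(42)
  for (i in 1:10) {
    col <- sample(c(-1, 0, 1), 60, replace = TRUE)
    grp <- rep(c(TRUE, FALSE), each = 30)
    col[sample(60, 4)] <- NA
    ours <- chi2Independence(col, grp)
    ref <- suppressWarnings(
      stats::chisq.test(table(col, grp), correct = FALSE))
    expect_equal(ours$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(ours$df, unname(ref$parameter))
    expect_equal(ours$p, unname(ref$p.value), tolerance = 1e-12)
  }

  # identical distributions -> chi2 0, p 1; single level -> untestable
  same <- chi2Independence(rep(c(0, 1), each = 20), rep(c(TRUE, FALSE), 20))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  flat <- chi2Independence(rep(1, 20), rep(c(TRUE, FALSE), 10))
  expect_true(flat$untestable)
  expect_equal(flat$p, 1)
})

test_that("vectorized screen agrees with per-effect chi-square tests", {
  pop <- simPop(m = 8, nA = 25, nB = 12, nF1 = 40, seed = 9,
                qtl = data.frame(kind = "a", locus1 = 3, locus2 = NA,
                                 h2 = 0.2))
  g <- genotypes(pop)
  g[sample(length(g), 15)] <- NA   # exercise missing-genotype exclusion
  pop@genotypes <- g
  y <- pop@phenotypes
  set.seed(2)
  tails <- selectExtremes(y, 0.25)
  ids <- c(tails$high, tails$low)
  grp <- rep(c(TRUE, FALSE), c(length(tails$high), length(tails$low)))
  enc <- NCIIqtl:::encodeGenotypes(g[ids, , drop = FALSE])
  scr <- NCIIqtl:::screenAllEffects(enc$x, enc$z,
                                    high = which(grp), low = which(!grp))
  eff <- enumerateEffects(8)
  for (i in seq_len(nrow(eff))) {
    w <- effectColumn(eff$kind[i], enc$x, enc$z, eff$locus1[i], eff$locus2[i])
    ref <- chi2Independence(w, grp)
    expect_equal(scr$chi2[i], ref$chi2, tolerance = 1e-10)
    expect_equal(scr$p[i], ref$p, tolerance = 1e-10)
    expect_equal(scr$untestable[i], ref$untestable)
    if (!ref$untestable) expect_equal(scr$df[i], ref$df)
  }
})

test_that("degrees of freedom follow the dummy coding per effect kind", {
  pop <- simPop(m = 10, nA = 40, nB = 20, nF1 = 60, seed = 5)
  sel <- screenTopEffects(pop, K = 10000, alpha = 1)
  scr <- attr(sel, "screen")
  ok <- !scr$untestable
  expect_true(all(scr$df[ok & scr$kind %in% c("d", "dd")] == 1))
  expect_true(all(scr$df[ok & scr$kind %in% c("a", "aa", "ad", "da")] <= 2))
  expect_true(all(scr$df[ok] >= 1))
  expect_true(all(scr$chi2[ok] >= 0))
  expect_true(all(scr$p > 0 & scr$p <= 1))
})

test_that("screening is calibrated under a permuted-phenotype null", {
  spec <- simulationSpec(markers = 16, nParentA = 120, nParentB = 60,
                         nF1 = 120,
                         qtl = data.frame(kind = "a", locus1 = 5,
                                          locus2 = NA, h2 = 0))
  pop <- simulateNCII(spec, seed = 3)
  props <- vapply(1:20, function(p) {
    set.seed(p)
    yp <- setNames(sample(pop@phenotypes), names(pop@phenotypes))
    scr <- attr(screenTopEffects(pop, yp, K = 10000, alpha = 1), "screen")
    mean(scr$p[!scr$untestable] < 0.05)
  }, 0)
  se <- sqrt(0.05 * 0.95 / 500)
  expect_gt(mean(props), 0.05 - 3 * se)
  expect_lt(mean(props), 0.05 + 3 * se)
})

test_that("top-K caps apply per category and honor exclusions and row order", {
  pop <- simPop(m = 12, nA = 40, nB = 20, nF1 = 60, seed = 7)
  sel <- screenTopEffects(pop, K = 5, alpha = 1)
  expect_equal(sum(sel$category == "main"), 5)
  expect_equal(sum(sel$category == "interaction"), 5)
  expect_false(is.unsorted(sel$p[sel$category == "main"]))
  expect_false(is.unsorted(sel$p[sel$category == "interaction"]))

  # excluded effects never reappear
  sel2 <- screenTopEffects(pop, K = 5, alpha = 1, alreadySelected = sel)
  expect_length(intersect(NCIIqtl:::effectKeys(sel),
                          NCIIqtl:::effectKeys(sel2)), 0)

  # invariance to individual row order
  perm <- sample(nrow(genotypes(pop)))
  pop2 <- NCIIPopulation(genotypes(pop)[perm, ], roles(pop)[perm],
                         pedigree(pop), pop@phenotypes, traitName(pop))
  sel3 <- screenTopEffects(pop2, K = 5, alpha = 1)
  expect_identical(NCIIqtl:::effectKeys(sel), NCIIqtl:::effectKeys(sel3))
  expect_equal(sel$chi2, sel3$chi2)
})
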