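#' Likelihood-ratio (LOD) test of each retained effect
#'
#' Two-stage significance testing: after the empirical Bayes fit, each effect
#' with a non-zero shrinkage estimate is tested by a likelihood ratio that
#' compares the converged model with the same model with that effect removed
#' (`gamma_k = 0`, i.e. its variance component set to zero), all other
#' parameters held at their converged values (profile-style, no refit).
#' `LOD = LR / (2 ln 10)`; negative LR values are clipped to zero. Effects
#' already shrunk to zero (`|E(gamma_k)| <= 1e-6`) get LR = 0.
#'
#' @param fit an [EBayesFit-class].
#' @param y phenotype vector used for the fit.
#' @param Z effect-column matrix used for the fit.
#' @param threshold LOD significance threshold (default 2.0, the conventional
#'   0.05-level cutoff used here).
#' @return data.frame with one row per effect: descriptor columns, `gamma`,
#'   `LR`, `LOD`, `significant` (`LOD >= threshold`, boundary inclusive).
#' @export
lodTest <- function(fit, y, Z, threshold = 2.0) {
  Z <- as.matrix(Z)
  q <- ncol(Z)
  stopifnot(length(fit@gamma) == q)
  out <- fit@effects
  out$gamma <- fit@gamma
  out$LR <- 0
  if (q > 0) {
    G <- crossprod(Z)
    full <- ebLogLikInternal(y, Z, G, fit@beta, fit@sigma2, fit@sigma2k)
    for (k in which(abs(fit@gamma) > 1e-6)) {
      dRed <- fit@sigma2k
      dRed[k] <- 0
      red <- ebLogLikInternal(y, Z[, -k, drop = FALSE],
                              G[-k, -k, drop = FALSE],
                              fit@beta, fit@sigma2, dRed[-k])
      out$LR[k] <- max(2 * (full - red), 0)
    }
  }
  out$LOD <- out$LR / (2 * log(10))
  out$significant <- out$LOD >= threshold
  out
}

#' Retain significant effects
#'
#' @param tests data.frame from [lodTest()].
#' @param threshold LOD threshold (default 2.0); ties at the boundary are
#'   retained.
#' @return The significant rows, sorted by descending LOD.
#' @examples
#' tests <- data.frame(kind = "a", locus1 = 1:3, locus2 = NA,
#'                     LOD = c(3.1, 1.9, 2.0))
#' nrow(significantEffects(tests))  # 2
#' @export
significantEffects <- function(tests, threshold = 2.0) {
  stopifnot(threshold > 0)
  keep <- tests[tests$LOD >= threshold, , drop = FALSE]
  keep[order(-keep$LOD), , drop = FALSE]
}
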