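#' Enumerate all candidate genetic effects
#'
#' The full genetic model for `m` markers contains, per marker, an additive
#' (`a`) and a dominance (`d`) main effect, and per unordered marker pair
#' `j < k` the four interaction effects `aa`, `ad`, `da`, `dd` (`ad` =
#' additive at locus1 x dominance at locus2; `da` the reverse — they are
#' distinct effects). Total: `2m + 2m(m-1)`. For the 205 markers of a typical
#' rapeseed panel this is 410 main + 83,640 interaction = 84,050 effects.
#'
#' @param m number of markers (>= 1).
#' @return data.frame with columns `kind` (one of a, d, aa, ad, da, dd),
#'   `locus1`, `locus2` (`NA` for main effects), in canonical order: main
#'   effects a, d per marker, then aa, ad, da, dd per pair `j < k` (j-major).
#' @examples
#' nrow(enumerateEffects(2))    # 8
#' nrow(enumerateEffects(205))  # 84050
#' @export
enumerateEffects <- function(m) {
  stopifnot(m >= 1)
  main <- data.frame(
    kind = rep(c("a", "d"), m),
    locus1 = rep(seq_len(m), each = 2),
    locus2 = NA_integer_,
    stringsAsFactors = FALSE
  )
  if (m < 2) return(main)
  j <- rep(seq_len(m - 1), times = (m - 1):1)
  k <- unlist(lapply(seq_len(m - 1), function(a) seq.int(a + 1, m)))
  inter <- data.frame(
    kind = rep(.INTERACTION_KINDS, length(j)),
    locus1 = rep(j, each = 4),
    locus2 = rep(k, each = 4),
    stringsAsFactors = FALSE
  )
  rbind(main, inter)
}

#' Encode genotype codes as additive and dominance dummies
#'
#' F-infinity-style coding: additive dummy `x = code - 1` (so -1/0/1 for
#' 0/1/2 copies of the reference allele) and dominance dummy `z = 1` for
#' heterozygotes, else 0. Missing codes give missing dummies; model-matrix
#' construction imputes them with the column mean (equivalently `2p - 1` on
#' the additive scale and the observed heterozygote frequency on the
#' dominance scale).
#'
#' @param codes numeric vector of genotype codes in \{0, 1, 2, NA\}.
#' @return list with numeric vectors `x` and `z`.
#' @examples
#' encodeMarker(c(2, 1, 0))  # x = 1, 0, -1; z = 0, 1, 0
#' @export
encodeMarker <- function(codes) {
  stopifnot(all(codes %in% c(0, 1, 2) | is.na(codes)))
  list(x = codes - 1, z = as.numeric(codes == 1))
}

# Encode a genotype matrix into x (additive) and z (dominance) matrices,
# keeping NAs. Rows = individuals, columns = markers.
encodeGenotypes <- function(g) {
  x <- g - 1
  z <- (g == 1) * 1
  list(x = x, z = z)
}

# Column-mean imputation of missing dummies (all-missing columns become 0).
imputeEncoding <- function(enc) {
  fill <- function(mat) {
    mu <- colMeans(mat, na.rm = TRUE)
    mu[is.nan(mu)] <- 0
    idx <- which(is.na(mat), arr.ind = TRUE)
    if (nrow(idx)) mat[idx] <- mu[idx[, 2]]
    mat
  }
  list(x = fill(enc$x), z = fill(enc$z))
}

#' Build the model-matrix column of one effect
#'
#' Main effects use the additive (`a` -> x) or dominance (`d` -> z) dummy of
#' their locus; interactions are elementwise products: `aa` = x1 * x2,
#' `ad` = x1 * z2, `da` = z1 * x2, `dd` = z1 * z2.
#'
#' @param kind effect kind, one of `a, d, aa, ad, da, dd`.
#' @param x,z encoded dummy matrices (individuals x markers).
#' @param locus1,locus2 marker indices (`locus2` ignored for main effects).
#' @return Numeric vector of length `nrow(x)`.
#' @export
effectColumn <- function(kind, x, z, locus1, locus2 = NA_integer_) {
  switch(kind,
    a  = x[, locus1],
    d  = z[, locus1],
    aa = x[, locus1] * x[, locus2],
    ad = x[, locus1] * z[, locus2],
    da = z[, locus1] * x[, locus2],
    dd = z[, locus1] * z[, locus2],
    stop("unknown effect kind: ", kind)
  )
}

# Materialize columns for a set of effect descriptors. Returns an
# n x nrow(effects) matrix.
effectColumns <- function(effects, x, z) {
  n <- nrow(x)
  out <- matrix(0, n, nrow(effects))
  for (i in seq_len(nrow(effects)))
    out[, i] <- effectColumn(effects$kind[i], x, z,
                             effects$locus1[i], effects$locus2[i])
  colnames(out) <- effectNames(effects, colnames(x))
  out
}

#' Human-readable effect names
#'
#' Report naming convention: `a:marker` for main effects and, e.g.,
#' `aa:marker1 x marker2` for interactions (locus1 x locus2 order, which for
#' `ad`/`da` identifies which locus carries the additive part).
#'
#' @param effects effect descriptor data.frame (see [enumerateEffects()]).
#' @param markerNames marker name vector indexed by locus.
#' @return Character vector of names.
#' @export
effectNames <- function(effects, markerNames = NULL) {
  nm1 <- if (is.null(markerNames)) as.character(effects$locus1) else
    markerNames[effects$locus1]
  nm2 <- if (is.null(markerNames)) as.character(effects$locus2) else
    ifelse(is.na(effects$locus2), NA, markerNames[effects$locus2])
  ifelse(effects$kind %in% .MAIN_KINDS,
         paste0(effects$kind, ":", nm1),
         paste0(effects$kind, ":", nm1, "\u00d7", nm2))
}

# Canonicalize descriptors: interactions get locus1 < locus2, swapping
# ad <-> da when loci swap. Main effects get locus2 = NA.
canonicalizeEffects <- function(effects) {
  effects$locus2[effects$kind %in% .MAIN_KINDS] <- NA_integer_
  swap <- !is.na(effects$locus2) & effects$locus1 > effects$locus2
  if (any(swap)) {
    tmp <- effects$locus1[swap]
    effects$locus1[swap] <- effects$locus2[swap]
    effects$locus2[swap] <- tmp
    k <- effects$kind[swap]
    effects$kind[swap] <- ifelse(k == "ad", "da", ifelse(k == "da", "ad", k))
  }
  effects
}

# Stable key for descriptor identity.
effectKeys <- function(effects) {
  effects <- canonicalizeEffects(effects)
  paste(effects$kind, effects$locus1, effects$locus2, sep = ":")
}
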