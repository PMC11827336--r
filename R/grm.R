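## Genomic relationship matrices: additive (centered-dosage) and dominance
## (genotypic / dominance-deviation coding), plus numerator blending.

## per-marker frequency of the counted allele, estimated on non-missing calls
.markerFreq <- function(M) colMeans(M, na.rm = TRUE) / 2

## anchor coding so the counted allele is the second most frequent one
## (dosage 2 = minor homozygote); returns the possibly re-coded matrix
.anchorMinor <- function(M, p) {
  flip <- !is.na(p) & p > 0.5
  if (any(flip)) {
    M[, flip] <- 2 - M[, flip]
    p[flip] <- 1 - p[flip]
  }
  list(M = M, p = p)
}

## per-marker mean imputation of missing calls
.meanImpute <- function(M) {
  nas <- which(is.na(M), arr.ind = TRUE)
  if (nrow(nas)) {
    mu <- colMeans(M, na.rm = TRUE)
    M[nas] <- mu[nas[, 2]]
  }
  M
}

.asDosageMatrix <- function(g) {
  if (is(g, "GenotypeDosage")) dosages(g) else as.matrix(g)
}

#' Additive genomic relationship matrix (centered dosages)
#'
#' Builds the realized additive relationship matrix
#' \deqn{G_a = \frac{Z Z'}{2 \sum_j p_j (1 - p_j)}}
#' where Z holds centered dosages, \eqn{Z_{ij} \in \{2 - 2p_j,\; 1 - 2p_j,\;
#' -2p_j\}} for dosages 2, 1, 0, and \eqn{p_j} is the frequency of the
#' counted (second most frequent) allele at marker j. Missing calls are
#' mean-imputed per marker before centering; monomorphic markers contribute
#' nothing (zero column, zero denominator term).
#'
#' @param g a \linkS4class{GenotypeDosage} or dosage matrix (individuals x
#'   markers). One row per genotype: ramets of an ortet must not be
#'   duplicated, or they would inflate the allele frequencies.
#' @param freqs optional per-marker allele frequencies; when supplied the
#'   dosage coding is taken as-is, otherwise frequencies are estimated from
#'   the data and the coding is anchored to the minor allele.
#' @return A \linkS4class{RelationshipMatrix} of kind \code{"Ga"}.
#' @examples
#' m <- matrix(c(0, 2), 2, 1, dimnames = list(c("i1", "i2"), "m1"))
#' relValues(grmAdditive(m))   # [[2, -2], [-2, 2]]
#' @export
grmAdditive <- function(g, freqs = NULL) {
  M <- .asDosageMatrix(g)
  if (is.null(freqs)) {
    p <- .markerFreq(M)
    an <- .anchorMinor(M, p)
    M <- an$M; p <- an$p
  } else {
    stopifnot(length(freqs) == ncol(M))
    p <- freqs
  }
  M <- .meanImpute(M)
  denom <- 2 * sum(p * (1 - p))
  if (denom <= 0) stop("all markers monomorphic: zero denominator")
  Z <- sweep(M, 2, 2 * p, "-")
  G <- tcrossprod(Z) / denom
  relationshipMatrix(G, kind = "Ga", alleleFreqs = p)
}

#' Dominance genomic relationship matrix (dominance deviations)
#'
#' Builds the dominance relationship matrix
#' \deqn{G_d = \frac{S S'}{4 \sum_j (p_j (1 - p_j))^2}}
#' where the dominance-deviation coding is \eqn{S_{ij} \in \{-2(1-p_j)^2,\;
#' 2 p_j (1-p_j),\; -2 p_j^2\}} for dosages 2, 1, 0 (the same dosage order
#' as the additive coding, making S mean-zero under Hardy-Weinberg
#' proportions). Missing calls are
#' mean-imputed on the dosage scale first (fractional dosages interpolate
#' the codes linearly in the heterozygosity indicator).
#'
#' @inheritParams grmAdditive
#' @return A \linkS4class{RelationshipMatrix} of kind \code{"Gd"}.
#' @export
grmDominance <- function(g, freqs = NULL) {
  M <- .asDosageMatrix(g)
  if (is.null(freqs)) {
    p <- .markerFreq(M)
    an <- .anchorMinor(M, p)
    M <- an$M; p <- an$p
  } else {
    stopifnot(length(freqs) == ncol(M))
    p <- freqs
  }
  M <- .meanImpute(M)
  denom <- 4 * sum((p * (1 - p))^2)
  if (denom <= 0) stop("all markers monomorphic: zero denominator")
  ## piecewise-linear interpolation between the exact codes at dosage 0/1/2
  ## (fractional values only arise from mean imputation); the codes follow
  ## the dosage order of the centered additive coding, so the coding is
  ## mean-zero under Hardy-Weinberg proportions
  lo <- pmin(M, 1)
  hi <- pmax(M - 1, 0)
  c0 <- matrix(-2 * p^2, nrow(M), ncol(M), byrow = TRUE)
  c1 <- matrix(2 * p * (1 - p), nrow(M), ncol(M), byrow = TRUE)
  c2 <- matrix(-2 * (1 - p)^2, nrow(M), ncol(M), byrow = TRUE)
  S <- c0 * (1 - lo) + c1 * (lo - hi) + c2 * hi
  dimnames(S) <- dimnames(M)
  G <- tcrossprod(S) / denom
  relationshipMatrix(G, kind = "Gd", alleleFreqs = p)
}

#' Blend a genomic matrix with the pedigree submatrix
#'
#' Convex combination \eqn{G^* = \alpha G_a + (1 - \alpha) A_{22}} used to
#' restore invertibility when the genomic matrix is singular (clones, more
#' markers than individuals). The default weight is \eqn{\alpha = 0.98}.
#'
#' @param Ga a \linkS4class{RelationshipMatrix} (kind \code{"Ga"} or
#'   \code{"Gd"}).
#' @param A22 a \linkS4class{RelationshipMatrix} of kind \code{"A22"} over
#'   the same individuals in the same order.
#' @param alpha blending weight in [0, 1].
#' @return A \linkS4class{RelationshipMatrix} of kind \code{"Gstar"}.
#' @export
blendGrm <- function(Ga, A22, alpha = 0.98) {
  stopifnot(alpha >= 0, alpha <= 1)
  va <- relValues(Ga); vb <- relValues(A22)
  if (!identical(rownames(va), rownames(vb)))
    stop("individual order mismatch between genomic and pedigree matrices")
  relationshipMatrix(alpha * va + (1 - alpha) * vb, kind = "Gstar",
                     alleleFreqs = alleleFreqs(Ga))
}

#' Write / read a relationship matrix as plain-text triplets
#'
#' Persists the lower triangle (including diagonal) as \code{i j value}
#' triplets with a header line listing the individual order.
#'
#' @param x a \linkS4class{RelationshipMatrix}.
#' @param path output file.
#' @export
writeGrm <- function(x, path) {
  v <- relValues(x)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#kind ", relKind(x)), con)
  writeLines(paste0("#ids ", paste(rownames(v), collapse = "\t")), con)
  idx <- which(lower.tri(v, diag = TRUE), arr.ind = TRUE)
  writeLines(sprintf("%d\t%d\t%.10g", idx[, 1], idx[, 2], v[idx]), con)
}

#' @rdname writeGrm
#' @param path input file written by \code{writeGrm}.
#' @export
readGrm <- function(path) {
  lines <- readLines(path, n = 2)
  kind <- sub("^#kind ", "", lines[1])
  ids <- strsplit(sub("^#ids ", "", lines[2]), "\t")[[1]]
  tr <- read.delim(path, skip = 2, header = FALSE,
                   col.names = c("i", "j", "value"))
  n <- length(ids)
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  v[cbind(tr$i, tr$j)] <- tr$value
  v[cbind(tr$j, tr$i)] <- tr$value
  relationshipMatrix(v, kind = kind)
}
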