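#' @import methods
NULL

#' Genotype dosage matrix
#'
#' Stores biallelic SNP genotypes as allele dosages (0, 1, 2 copies of the
#' counted allele; \code{NA} for a missing call) for a set of individuals.
#' Rows are individuals (one row per genotype -- ramets of an ortet share a
#' single row), columns are markers. The optional \code{panel} slot records,
#' per marker, which genotyping panel(s) carry it (\code{"both"}, \code{"A"}
#' or \code{"B"}), used when two marker panels must be merged by
#' intersection.
#'
#' @slot dosage numeric matrix, individuals x markers, entries in
#'   \{0, 1, 2, NA\}, with row and column names.
#' @slot panel character vector of length \code{ncol(dosage)} (or length 0
#'   when panel membership is not tracked).
#' @export
setClass("GenotypeDosage",
  representation(dosage = "matrix", panel = "character"),
  prototype(dosage = matrix(numeric(0), 0, 0), panel = character(0))
)

setValidity("GenotypeDosage", function(object) {
  d <- object@dosage
  if (!is.numeric(d)) return("dosage must be a numeric matrix")
  v <- d[!is.na(d)]
  if (length(v) && (any(v < 0) || any(v > 2)))
    return("dosages must lie in [0, 2]")
  if (nrow(d) > 0 && is.null(rownames(d)))
    return("dosage matrix must have individual identifiers as rownames")
  if (ncol(d) > 0 && is.null(colnames(d)))
    return("dosage matrix must have marker identifiers as colnames")
  if (length(object@panel) && length(object@panel) != ncol(d))
    return("panel must have one entry per marker (or length 0)")
  TRUE
})

#' Construct a GenotypeDosage object
#'
#' @param dosage numeric matrix of allele dosages, individuals x markers,
#'   with row (individual) and column (marker) names.
#' @param panel optional character vector of per-marker panel membership.
#' @return A \linkS4class{GenotypeDosage} object.
#' @examples
#' m <- matrix(c(0, 1, 2, 1), 2, 2,
#'             dimnames = list(c("i1", "i2"), c("m1", "m2")))
#' genotypeDosage(m)
#' @export
genotypeDosage <- function(dosage, panel = character(0)) {
  storage.mode(dosage) <- "double"
  new("GenotypeDosage", dosage = dosage, panel = panel)
}

#' @describeIn genotypeDosage Extract the dosage matrix.
#' @param x a \code{GenotypeDosage} object.
#' @export
dosages <- function(x) x@dosage

#' @describeIn genotypeDosage Marker identifiers.
#' @export
markerIds <- function(x) colnames(x@dosage)

#' @describeIn genotypeDosage Individual identifiers.
#' @export
sampleIds <- function(x) rownames(x@dosage)

#' @describeIn genotypeDosage Per-marker panel membership (may be empty).
#' @export
markerPanel <- function(x) x@panel

setMethod("show", "GenotypeDosage", function(object) {
  d <- object@dosage
  miss <- if (length(d)) mean(is.na(d)) else 0
  cat("GenotypeDosage:", nrow(d), "individuals x", ncol(d), "markers;",
      sprintf("%.2f%% missing", 100 * miss), "\n")
  if (length(object@panel))
    cat("  panels:", paste(sprintf("%s=%d", names(table(object@panel)),
                                   as.integer(table(object@panel))),
                           collapse = ", "), "\n")
  invisible(object)
})

#' Subset a GenotypeDosage by individuals and/or markers
#'
#' @param x a \code{GenotypeDosage}.
#' @param i,j individual / marker indices or names.
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{GenotypeDosage}.
#' @export
setMethod("[", "GenotypeDosage", function(x, i, j, ..., drop = FALSE) {
  d <- x@dosage
  if (missing(i)) i <- seq_len(nrow(d))
  if (missing(j)) j <- seq_len(ncol(d))
  p <- x@panel
  dd <- d[i, j, drop = FALSE]
  if (length(p)) {
    jj <- seq_len(ncol(d))
    names(jj) <- colnames(d)
    p <- p[jj[colnames(dd)]]
  }
  genotypeDosage(dd, panel = p)
})

#' Relationship matrix over an ordered set of individuals
#'
#' A symmetric relationship matrix together with its kind -- pedigree
#' numerator (\code{"A"}), genotyped submatrix (\code{"A22"}), genomic
#' additive (\code{"Ga"}), genomic dominance (\code{"Gd"}) or blended
#' (\code{"Gstar"}) -- and, for the genomic kinds, the per-marker allele
#' frequencies used in its construction.
#'
#' @slot values symmetric numeric matrix with matching dimnames.
#' @slot kind one of \code{"A"}, \code{"A22"}, \code{"Ga"}, \code{"Gd"},
#'   \code{"Gstar"}.
#' @slot alleleFreqs per-marker frequency of the counted (second most
#'   frequent) allele; empty for pedigree kinds.
#' @export
setClass("RelationshipMatrix",
  representation(values = "matrix", kind = "character",
                 alleleFreqs = "numeric"),
  prototype(values = matrix(numeric(0), 0, 0), kind = "A",
            alleleFreqs = numeric(0))
)

setValidity("RelationshipMatrix", function(object) {
  v <- object@values
  if (!identical(rownames(v), colnames(v)))
    return("row and column names must match")
  if (nrow(v) != ncol(v)) return("matrix must be square")
  if (nrow(v) > 1 && max(abs(v - t(v))) > 1e-8 * (1 + max(abs(v))))
    return("matrix must be symmetric")
  if (!object@kind %in% c("A", "A22", "Ga", "Gd", "Gstar"))
    return("unknown relationship kind")
  TRUE
})

#' Construct a RelationshipMatrix
#'
#' @param values symmetric numeric matrix with individual ids as dimnames.
#' @param kind matrix kind, see \linkS4class{RelationshipMatrix}.
#' @param alleleFreqs optional per-marker allele frequencies used to build a
#'   genomic matrix.
#' @return A \linkS4class{RelationshipMatrix}.
#' @export
relationshipMatrix <- function(values, kind, alleleFreqs = numeric(0)) {
  new("RelationshipMatrix", values = values, kind = kind,
      alleleFreqs = alleleFreqs)
}

#' @describeIn relationshipMatrix The matrix of relationship values.
#' @param x a \code{RelationshipMatrix}.
#' @export
relValues <- function(x) x@values

#' @describeIn relationshipMatrix The matrix kind.
#' @export
relKind <- function(x) x@kind

#' @describeIn relationshipMatrix Allele frequencies used in construction.
#' @export
alleleFreqs <- function(x) x@alleleFreqs

setMethod("show", "RelationshipMatrix", function(object) {
  v <- object@values
  cat("RelationshipMatrix (", object@kind, "): ", nrow(v), " x ", ncol(v),
      " individuals; mean diagonal ",
      if (nrow(v)) sprintf("%.3f", mean(diag(v))) else "NA", "\n", sep = "")
  invisible(object)
})

#' REML mixed-model fit
#'
#' Result of \code{\link{remlFit}}: variance components with asymptotic
#' standard errors, fixed-effect estimates (BLUE), random-effect predictions
#' (BLUP) with per-level prediction error variances, the restricted
#' log-likelihood and convergence information.
#'
#' @slot theta named variance-component estimates (one per random term and
#'   residual group; the AR1 spatial variance where applicable).
#' @slot se asymptotic standard errors of \code{theta} (from the inverse
#'   average-information matrix; NA where a component sat on the boundary).
#' @slot beta named fixed-effect estimates.
#' @slot blup list of named BLUP vectors, one per random term.
#' @slot pev list of per-level prediction error variances matching
#'   \code{blup}.
#' @slot loglik restricted log-likelihood at the final estimates.
#' @slot converged logical convergence flag.
#' @slot niter number of iterations performed.
#' @slot details list of auxiliary results (estimated AR1 correlations,
#'   iteration trace, dropped fixed-effect columns, ...).
#' @export
setClass("CptFit",
  representation(theta = "numeric", se = "numeric", beta = "numeric",
                 blup = "list", pev = "list", loglik = "numeric",
                 converged = "logical", niter = "integer",
                 details = "list"))

#' @describeIn remlFit Named variance-component estimates.
#' @param fit a \code{CptFit} object.
#' @export
varComp <- function(fit) fit@theta

#' @describeIn remlFit Asymptotic standard errors of the components.
#' @export
varCompSE <- function(fit) fit@se

#' @describeIn remlFit Fixed-effect estimates (BLUE).
#' @export
fixedEffects <- function(fit) fit@beta

#' @describeIn remlFit List of BLUP vectors per random term.
#' @export
blups <- function(fit) fit@blup

#' @describeIn remlFit List of per-level prediction error variances.
#' @export
pevs <- function(fit) fit@pev

#' @describeIn remlFit Restricted log-likelihood.
#' @export
logLikReml <- function(fit) fit@loglik

setMethod("show", "CptFit", function(object) {
  cat("CptFit:", if (object@converged) "converged" else "NOT converged",
      "in", object@niter, "iterations; restricted logLik",
      sprintf("%.4f", object@loglik), "\n")
  est <- cbind(estimate = object@theta, se = object@se)
  print(round(est, 5))
  invisible(object)
})
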