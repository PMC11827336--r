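#' Validate a pedigree table
#'
#' A pedigree is a data.frame with character columns \code{id}, \code{sire},
#' \code{dam}; \code{"0"} marks an unknown parent. Parents that appear only
#' in the sire/dam columns are added as founder rows. Cycles (an individual
#' among its own ancestors) are rejected.
#'
#' @param ped data.frame with columns id, sire, dam.
#' @return the completed pedigree, topologically sorted (parents before
#'   offspring), with an attribute \code{"order"} giving the original ids.
#' @export
asPedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  ped <- data.frame(id = as.character(ped$id), sire = as.character(ped$sire),
                    dam = as.character(ped$dam), stringsAsFactors = FALSE)
  if (anyDuplicated(ped$id)) stop("duplicated ids in pedigree")
  if (any(ped$id == "0")) stop('"0" is reserved for unknown parents')
  parents <- setdiff(unique(c(ped$sire, ped$dam)), c("0", ped$id))
  if (length(parents))
    ped <- rbind(data.frame(id = parents, sire = "0", dam = "0",
                            stringsAsFactors = FALSE), ped)
  if (any(ped$sire == ped$id | ped$dam == ped$id))
    stop("individual listed as its own parent")
  ## Kahn topological sort; detects cycles
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(ped$sire == "0", NA_integer_, idx[ped$sire])
  di <- ifelse(ped$dam == "0", NA_integer_, idx[ped$dam])
  placed <- logical(n)
  order <- integer(0)
  while (!all(placed)) {
    ready <- which(!placed &
                   (is.na(si) | placed[ifelse(is.na(si), 1L, si)]) &
                   (is.na(di) | placed[ifelse(is.na(di), 1L, di)]))
    if (!length(ready)) stop("pedigree contains a cycle")
    placed[ready] <- TRUE
    order <- c(order, ready)
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "order") <- ped$id
  out
}

#' Pedigree numerator relationship matrix (tabular method)
#'
#' Builds the additive numerator relationship matrix A over all pedigree
#' members with Henderson's tabular method:
#' \eqn{A_{ii} = 1 + 0.5 A_{sd}} and
#' \eqn{A_{ij} = 0.5 (A_{j,s} + A_{j,d})}, unknown parents contributing 0.
#'
#' @param ped pedigree data.frame (id, sire, dam; "0" = unknown); it is run
#'   through \code{\link{asPedigree}} first.
#' @return A \linkS4class{RelationshipMatrix} of kind \code{"A"}, ordered as
#'   the (completed) input pedigree.
#' @examples
#' ped <- data.frame(id = c("f1", "f2", "p1", "p2"),
#'                   sire = c("0", "0", "f1", "f1"),
#'                   dam  = c("0", "0", "f2", "f2"))
#' relValues(numeratorA(ped))["p1", "p2"]   # full sibs: 0.5
#' @export
numeratorA <- function(ped) {
  ped <- asPedigree(ped)
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  si <- ifelse(ped$sire == "0", 0L, idx[ped$sire])
  di <- ifelse(ped$dam == "0", 0L, idx[ped$dam])
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) {
    s <- si[i]; d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- 0.5 * ((if (s > 0L) A[j, s] else 0) +
                    (if (d > 0L) A[j, d] else 0))
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (s > 0L && d > 0L) 0.5 * A[s, d] else 0
  }
  ## return in the original id order
  ord <- attr(ped, "order")
  relationshipMatrix(A[ord, ord, drop = FALSE], kind = "A")
}

#' Genotyped submatrix A22 of the numerator matrix
#'
#' Restricts a pedigree numerator matrix to the genotyped individuals
#' (row/column selection only).
#'
#' @param A a \linkS4class{RelationshipMatrix} of kind \code{"A"}.
#' @param ids character vector of genotyped individual ids.
#' @return A \linkS4class{RelationshipMatrix} of kind \code{"A22"}.
#' @export
a22Matrix <- function(A, ids) {
  stopifnot(relKind(A) == "A")
  missing <- setdiff(ids, rownames(relValues(A)))
  if (length(missing))
    stop("ids not in pedigree: ", paste(utils::head(missing, 5),
                                        collapse = ", "))
  relationshipMatrix(relValues(A)[ids, ids, drop = FALSE], kind = "A22")
}
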