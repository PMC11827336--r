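## Single-stage genomic model and the replicate-reduction (ramets per
## ortet) study: subset enumeration, per-subset refits, rank-sum
## aggregation and ranking-coincidence statistics.

#' Enumerate replicate subsets
#'
#' All \eqn{C(total, k)} subsets of \code{1:total} in lexicographic order.
#'
#' @param total number of replicates available (e.g. 5).
#' @param k subset size, 1 <= k <= total.
#' @return list of integer vectors.
#' @examples
#' length(enumerateSubsets(5, 2))   # 10
#' @export
enumerateSubsets <- function(total, k) {
  if (k < 1 || k > total) stop("k must lie in [1, total]")
  cols <- combn(total, k)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

#' Single-stage multi-site genomic model
#'
#' Fits the tree-level model across sites with fixed site, sub-trial-within-
#' site and replication-within-sub-trial effects, random incomplete block
#' (iid), additive (G*) and dominance (Gd) genetic effects, and a residual
#' variance per site (block-diagonal heterogeneous structure). Genetic
#' parameters use \eqn{\sigma_{p_s}^2 = \sigma_{a_s}^2 + \sigma_{d_s}^2 +
#' \sigma_{b_s}^2 + \overline{\sigma_{e_s}^2}} (mean of the site residual
#' variances).
#'
#' @param pheno tree-level phenotype table (columns site, sub_trial,
#'   replicate, block, genotype_id and the trait).
#' @param Gstar,Gd relationship kernels over the genotypes.
#' @param trait trait column name (default \code{"vol_dm3"}).
#' @param ... passed to \code{\link{remlFit}}.
#' @return list: \code{varComp} (additive, dominance, block, per-site
#'   residuals), \code{parameters} (sigmaPs2, h2a, delta2, H2, accuracies),
#'   \code{gv} (a + d BLUPs), \code{ranking} (positions), \code{fit}.
#' @export
fitSingleStage <- function(pheno, Gstar, Gd, trait = "vol_dm3", ...) {
  GA <- if (is(Gstar, "RelationshipMatrix")) relValues(Gstar) else Gstar
  GD <- if (is(Gd, "RelationshipMatrix")) relValues(Gd) else Gd
  stopifnot(identical(rownames(GA), rownames(GD)))
  pheno <- pheno[!is.na(pheno[[trait]]), , drop = FALSE]
  keep <- pheno$genotype_id %in% rownames(GA)
  if (any(!keep))
    message(sum(!keep), " trees dropped (genotype not in kernels)")
  pheno <- pheno[keep, , drop = FALSE]
  sites <- sort(unique(pheno$site))
  if (length(sites) < 1) stop("no site left in the subset data")
  gUsed <- sort(unique(pheno$genotype_id))
  GA <- GA[gUsed, gUsed]
  GD <- GD[gUsed, gUsed]
  ## fixed: replication within sub-trial within site (spans site and
  ## sub-trial margins)
  X <- .indicator(interaction(pheno$sub_trial, pheno$replicate, drop = TRUE))
  Zg <- .indicator(factor(pheno$genotype_id, levels = gUsed))
  random <- list(
    block = randomTerm(interaction(pheno$sub_trial, pheno$replicate,
                                   pheno$block, drop = TRUE)),
    additive = randomTerm(Zg, GA),
    dominance = randomTerm(Zg, GD))
  fit <- remlFit(pheno[[trait]], X, random = random,
                 residual = residualByGroup(pheno$site), ...)
  vc <- varComp(fit)
  resid <- vc[grep("^residual\\.", names(vc))]
  sigmaPs2 <- unname(vc["additive"] + vc["dominance"] + vc["block"] +
                     mean(resid))
  params <- list(
    sigmaPs2 = sigmaPs2,
    h2a = unname(vc["additive"] / sigmaPs2),
    delta2 = unname(vc["dominance"] / sigmaPs2),
    H2 = unname((vc["additive"] + vc["dominance"]) / sigmaPs2))
  if (length(pevs(fit))) {
    if (vc["additive"] > 0)
      params$accuracyAdditive <- pevToAccuracy(pevs(fit)$additive,
                                               vc[["additive"]])
    if (vc["dominance"] > 0)
      params$accuracyDominance <- pevToAccuracy(pevs(fit)$dominance,
                                                vc[["dominance"]])
  }
  gv <- if (length(blups(fit)))
    blups(fit)$additive + blups(fit)$dominance else NULL
  list(varComp = vc, parameters = params, gv = gv,
       ranking = if (is.null(gv)) NULL else rankPositions(gv), fit = fit)
}

#' Aggregate rankings by rank sum
#'
#' Combines several rankings of the same clones by the sum of per-ranking
#' positions (Mulamba-Mock): clones are ordered by ascending rank sum, ties
#' broken by the clone identifier.
#'
#' @param rankings list of named position vectors over the same clone set.
#' @return named integer vector of aggregated positions.
#' @export
rankSumAggregate <- function(rankings) {
  stopifnot(length(rankings) >= 1)
  ids <- sort(names(rankings[[1]]))
  for (r in rankings)
    if (!identical(sort(names(r)), ids)) stop("mismatched clone sets")
  sums <- Reduce(`+`, lapply(rankings, function(r) r[ids]))
  ord <- order(sums, ids)
  pos <- integer(length(ids))
  pos[ord] <- seq_along(ids)
  names(pos) <- ids
  pos
}

#' Ranking coincidence percentage
#'
#' \eqn{R = 100 C / S} where C is the number of clones shared by the
#' reference and candidate selections and S the reference selection size.
#'
#' @param referenceTop,candidateTop character vectors of selected clones.
#' @return percentage in [0, 100].
#' @export
rankingCoincidence <- function(referenceTop, candidateTop) {
  if (!length(referenceTop)) stop("empty reference selection")
  100 * length(intersect(referenceTop, candidateTop)) / length(referenceTop)
}

#' Minimum selection size to recover a reference selection
#'
#' The lowest (worst) position that any reference clone occupies in a
#' candidate ranking: selecting that many clones from the candidate ranking
#' guarantees the whole reference selection is included.
#'
#' @param referenceTop character vector of reference clones.
#' @param candidateRanking named position vector covering them.
#' @return integer count.
#' @export
minSelectionSize <- function(referenceTop, candidateRanking) {
  pos <- candidateRanking[referenceTop]
  if (any(is.na(pos))) stop("reference clone missing from candidate ranking")
  max(pos)
}

#' Replicate-reduction study
#'
#' Re-fits the single-stage genomic model for every subset of the available
#' replicates of each size in \code{kSet}, averages the genetic parameters
#' per size, aggregates the per-subset rankings by rank sum, and compares
#' each aggregated ranking to the full-replication reference: ranking
#' coincidence for each selection size in \code{topN} and the minimum
#' selection size needed to recover the reference top-\code{topN[1]}.
#'
#' @param pheno tree-level phenotype table across sites.
#' @param Gstar,Gd relationship kernels.
#' @param kSet replicate counts to evaluate (default all, descending).
#' @param topN selection sizes (default 10, 20, 30).
#' @param trait trait column name.
#' @param ... passed to \code{\link{remlFit}} via
#'   \code{\link{fitSingleStage}}.
#' @return list: \code{summary} (per k: combinations, mean parameters,
#'   coincidences, minimum selection size), \code{rankings} (aggregated
#'   positions per k), \code{reference} (full-replication fit).
#' @export
replicationStudy <- function(pheno, Gstar, Gd, kSet = NULL,
                             topN = c(10, 20, 30), trait = "vol_dm3", ...) {
  total <- max(pheno$replicate)
  if (is.null(kSet)) kSet <- rev(seq_len(total))
  reference <- fitSingleStage(pheno, Gstar, Gd, trait = trait, ...)
  refRank <- reference$ranking
  topN <- pmin(topN, length(refRank))
  refTops <- lapply(topN, function(nn) names(sort(refRank))[seq_len(nn)])
  rows <- list(); aggs <- list()
  for (k in kSet) {
    combos <- enumerateSubsets(total, k)
    pars <- matrix(NA_real_, length(combos), 6,
                   dimnames = list(NULL, c("h2a", "delta2", "H2",
                                           "accuracyAdditive",
                                           "accuracyDominance",
                                           "sigmaPs2")))
    ranks <- vector("list", length(combos))
    for (ci in seq_along(combos)) {
      sub <- pheno[pheno$replicate %in% combos[[ci]], , drop = FALSE]
      f <- fitSingleStage(sub, Gstar, Gd, trait = trait, ...)
      p <- f$parameters
      pars[ci, ] <- c(p$h2a, p$delta2, p$H2,
                      if (is.null(p$accuracyAdditive)) NA else
                        p$accuracyAdditive,
                      if (is.null(p$accuracyDominance)) NA else
                        p$accuracyDominance,
                      p$sigmaPs2)
      ranks[[ci]] <- f$ranking
    }
    agg <- rankSumAggregate(ranks)
    aggs[[as.character(k)]] <- agg
    coin <- vapply(seq_along(topN), function(ti) {
      candTop <- names(sort(agg))[seq_len(topN[ti])]
      rankingCoincidence(refTops[[ti]], candTop)
    }, 0)
    rows[[as.character(k)]] <- data.frame(
      k = k, nCombinations = length(combos),
      t(colMeans(pars, na.rm = TRUE)),
      t(setNames(coin, paste0("R", topN))),
      minSelectionSize = minSelectionSize(refTops[[1]], agg))
  }
  list(summary = do.call(rbind, rows), rankings = aggs,
       reference = reference)
}

#' Bundled clone-ranking example
#'
#' Ranking positions of the ten best clones of a two-site eucalypt cloned
#' progeny trial under five down to one ramets per progeny (columns
#' \code{r5} ... \code{r1}; rank-sum aggregated over replicate subsets).
#' Used to illustrate \code{\link{minSelectionSize}} and
#' \code{\link{rankingCoincidence}}.
#'
#' @return matrix of positions, rownames = clone labels.
#' @export
cloneRankingExample <- function() {
  path <- system.file("extdata", "clone_rankings.csv", package = "cptEval")
  df <- read.csv(path, check.names = FALSE, colClasses = c(clone = "character"))
  m <- as.matrix(df[, -1])
  rownames(m) <- df$clone
  m
}
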