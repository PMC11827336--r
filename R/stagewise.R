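## Stage-wise genomic evaluation: per-sub-trial spatial adjustment, then a
## multi-environment additive + dominance genomic model on adjusted means.

.indicator <- function(f) {
  if (!is.factor(f)) f <- factor(f)
  Z <- matrix(0, length(f), nlevels(f), dimnames = list(NULL, levels(f)))
  Z[cbind(seq_along(f), as.integer(f))] <- 1
  Z
}

#' First-stage spatial analysis of one sub-trial
#'
#' Fits, within a single sub-trial, the model with genotype as a fixed
#' effect, replication and incomplete block (nested in replication) as iid
#' random effects, and spatially correlated residuals over the plot grid
#' with a separable AR1(column) x AR1(row) structure. The genotype BLUEs are
#' the spatially adjusted genotype means passed to the second stage. Trees
#' with a missing trait value (mortality) are excluded.
#'
#' @param data phenotype rows of one sub-trial: columns \code{genotype_id},
#'   \code{replicate}, \code{block}, \code{row}, \code{col} and the trait.
#' @param trait trait column name (default \code{"vol_dm3"}).
#' @param rhoRow,rhoCol fixed residual autocorrelations; NULL (default)
#'   profiles them by REML.
#' @param ... passed to \code{\link{remlFit}} (tolerances, iterations).
#' @return list: \code{adjustedMeans} (named genotype BLUEs),
#'   \code{varComp} (replicate, block, spatial residual), \code{rhoRow},
#'   \code{rhoCol}, \code{fit}.
#' @export
fitStage1 <- function(data, trait = "vol_dm3", rhoRow = NULL, rhoCol = NULL,
                      ...) {
  stopifnot(length(unique(data$sub_trial)) <= 1)
  data <- data[!is.na(data[[trait]]), , drop = FALSE]
  if (!nrow(data)) stop("no non-missing observations in sub-trial")
  X <- .indicator(data$genotype_id)
  if (any(colSums(X) == 0)) X <- X[, colSums(X) > 0, drop = FALSE]
  random <- list(
    replicate = randomTerm(factor(data$replicate)),
    block = randomTerm(interaction(data$replicate, data$block, drop = TRUE)))
  fit <- remlFit(data[[trait]], X, random = random,
                 residual = residualAr1(data$row, data$col,
                                        rhoRow = rhoRow, rhoCol = rhoCol),
                 computeBlup = FALSE, ...)
  vc <- varComp(fit)
  rho <- fit@details$rho
  list(adjustedMeans = fixedEffects(fit),
       varComp = c(replicate = unname(vc["replicate"]),
                   block = unname(vc["block"]),
                   spatial = unname(vc["residual"])),
       rhoRow = unname(rho["rhoRow"]), rhoCol = unname(rho["rhoCol"]),
       fit = fit)
}

#' First-stage analysis over all sub-trials
#'
#' Applies \code{\link{fitStage1}} to every (site, sub-trial) combination
#' and stacks the adjusted genotype means.
#'
#' @param pheno phenotype table covering several sub-trials.
#' @inheritParams fitStage1
#' @return list: \code{means} (data.frame genotype_id, site, sub_trial,
#'   mean), \code{components} (per-sub-trial variance components and
#'   estimated correlations).
#' @export
fitStage1All <- function(pheno, trait = "vol_dm3", rhoRow = NULL,
                         rhoCol = NULL, ...) {
  subs <- unique(pheno[, c("site", "sub_trial")])
  means <- list(); comps <- list()
  for (i in seq_len(nrow(subs))) {
    st <- subs$sub_trial[i]
    res <- fitStage1(pheno[pheno$sub_trial == st, , drop = FALSE],
                     trait = trait, rhoRow = rhoRow, rhoCol = rhoCol, ...)
    means[[i]] <- data.frame(genotype_id = names(res$adjustedMeans),
                             site = subs$site[i], sub_trial = st,
                             mean = unname(res$adjustedMeans),
                             stringsAsFactors = FALSE)
    comps[[i]] <- data.frame(site = subs$site[i], sub_trial = st,
                             t(res$varComp), rhoRow = res$rhoRow,
                             rhoCol = res$rhoCol)
  }
  list(means = do.call(rbind, means), components = do.call(rbind, comps))
}

#' Second-stage multi-environment genomic model
#'
#' Fits, on the stage-one adjusted means, the across-environment model with
#' site as a fixed effect and random sub-trial-within-site (iid), additive
#' (blended genomic kernel G*), dominance (Gd), additive x site
#' (G* Kronecker identity over sites), dominance x site and an iid residual.
#' Genotypes absent from the kernels are dropped with a message.
#'
#' @param means data.frame from \code{\link{fitStage1All}} (columns
#'   genotype_id, site, sub_trial, mean).
#' @param Gstar blended additive \linkS4class{RelationshipMatrix}.
#' @param Gd dominance \linkS4class{RelationshipMatrix}.
#' @param ... passed to \code{\link{remlFit}}.
#' @return list: \code{varComp} (named: additive, dominance, trial, axE,
#'   dxE, residual), \code{fit} (a \linkS4class{CptFit}),
#'   \code{gv} (genotypic values a + d per genotype), \code{nDropped}.
#' @export
fitStage2 <- function(means, Gstar, Gd, ...) {
  GA <- if (is(Gstar, "RelationshipMatrix")) relValues(Gstar) else Gstar
  GD <- if (is(Gd, "RelationshipMatrix")) relValues(Gd) else Gd
  gids <- rownames(GA)
  stopifnot(identical(gids, rownames(GD)))
  keep <- means$genotype_id %in% gids
  nDropped <- sum(!keep)
  if (nDropped)
    message(nDropped, " adjusted means dropped (genotype not in kernels)")
  means <- means[keep, , drop = FALSE]
  gUsed <- sort(unique(means$genotype_id))
  GA <- GA[gUsed, gUsed]
  GD <- GD[gUsed, gUsed]
  sites <- sort(unique(means$site))
  X <- .indicator(means$site)
  Zg <- .indicator(factor(means$genotype_id, levels = gUsed))
  gsLevels <- as.vector(outer(gUsed, sites, function(g, s) paste(s, g)))
  Zgs <- .indicator(factor(paste(means$site, means$genotype_id),
                           levels = gsLevels))
  KA <- kronecker(diag(length(sites)), GA)
  KD <- kronecker(diag(length(sites)), GD)
  dimnames(KA) <- dimnames(KD) <- list(gsLevels, gsLevels)
  random <- list(
    trial = randomTerm(factor(means$sub_trial)),
    additive = randomTerm(Zg, GA),
    dominance = randomTerm(Zg, GD),
    axE = randomTerm(Zgs, KA),
    dxE = randomTerm(Zgs, KD))
  fit <- remlFit(means$mean, X, random = random, residual = residualIid(),
                 ...)
  vc <- varComp(fit)
  out <- c(additive = unname(vc["additive"]),
           dominance = unname(vc["dominance"]),
           trial = unname(vc["trial"]), axE = unname(vc["axE"]),
           dxE = unname(vc["dxE"]), residual = unname(vc["residual"]))
  gv <- if (length(blups(fit)))
    blups(fit)$additive + blups(fit)$dominance else NULL
  list(varComp = out, fit = fit, gv = gv, nDropped = nDropped)
}

#' Genetic parameters from variance components
#'
#' Heritabilities and variance shares from the six second-stage components:
#' \eqn{\sigma_p^2 = \sigma_a^2 + \sigma_d^2 + \sigma_t^2 + \sigma_j^2 +
#' \sigma_k^2 + \sigma_e^2}, narrow-sense \eqn{h_a^2 = \sigma_a^2 /
#' \sigma_p^2}, dominance determination \eqn{\delta^2 = \sigma_d^2 /
#' \sigma_p^2} and broad-sense \eqn{H^2 = (\sigma_a^2 + \sigma_d^2) /
#' \sigma_p^2}. When a fitted model is supplied, accuracies use the mean
#' prediction error variance (\eqn{r = \sqrt{1 - \overline{PEV}/\sigma^2}})
#' and per-clone reliabilities the per-level PEV.
#'
#' @param vc named variance components: additive, dominance, trial, axE,
#'   dxE, residual.
#' @param fit optional \linkS4class{CptFit} with \code{additive} and
#'   \code{dominance} terms for PEV-based accuracy.
#' @return list: \code{sigmaP2}, \code{h2a}, \code{delta2}, \code{H2},
#'   \code{shares} (per-component fraction of \code{sigmaP2}), and when
#'   \code{fit} is given \code{accuracyAdditive}, \code{accuracyDominance},
#'   \code{reliabilityAdditive}, \code{reliabilityDominance}.
#' @examples
#' vc <- c(additive = 250.76, dominance = 365.14, trial = 796.16,
#'         axE = 37.47, dxE = 6.28, residual = 200.39)
#' summarizeParameters(vc)$H2   # 0.37
#' @export
summarizeParameters <- function(vc, fit = NULL) {
  need <- c("additive", "dominance", "trial", "axE", "dxE", "residual")
  stopifnot(all(need %in% names(vc)))
  if (any(vc[need] < 0)) stop("components must be non-negative")
  sigmaP2 <- sum(vc[need])
  if (sigmaP2 == 0) stop("zero phenotypic variance")
  out <- list(sigmaP2 = unname(sigmaP2),
              h2a = unname(vc["additive"] / sigmaP2),
              delta2 = unname(vc["dominance"] / sigmaP2),
              H2 = unname((vc["additive"] + vc["dominance"]) / sigmaP2),
              shares = vc[need] / sigmaP2)
  if (!is.null(fit) && all(c("additive", "dominance") %in%
                           names(pevs(fit)))) {
    if (vc["additive"] > 0) {
      out$accuracyAdditive <- pevToAccuracy(pevs(fit)$additive,
                                            vc[["additive"]])
      out$reliabilityAdditive <- reliability(pevs(fit)$additive,
                                             vc[["additive"]])
    }
    if (vc["dominance"] > 0) {
      out$accuracyDominance <- pevToAccuracy(pevs(fit)$dominance,
                                             vc[["dominance"]])
      out$reliabilityDominance <- reliability(pevs(fit)$dominance,
                                              vc[["dominance"]])
    }
  }
  out
}

#' Rank positions from genotypic values
#'
#' Positions 1..n (1 = best) by descending value; ties broken by the
#' genotype identifier.
#'
#' @param gv named numeric vector of genotypic values.
#' @return named integer vector of positions (a permutation of 1..n).
#' @export
rankPositions <- function(gv) {
  stopifnot(!is.null(names(gv)))
  ord <- order(-gv, names(gv))
  pos <- integer(length(gv))
  pos[ord] <- seq_along(gv)
  names(pos) <- names(gv)
  pos
}

#' Selection differential and response to selection
#'
#' Ranks genotypes by genotypic value (a + d), selects the best
#' \code{nSelect}, and computes the selection differential
#' \eqn{S = \bar x_s - \bar x_0 = i \sigma_p} and the response
#' \eqn{\Delta_R = S H^2}, where \eqn{\bar x_s} is the phenotypic mean of
#' the selected group, \eqn{\bar x_0} the base mean, and \eqn{i} the
#' standardized selection differential. Both the raw-scale response and the
#' standardized-scale response (\eqn{\sigma_p = 1}) are reported, along with
#' the response as a percentage of the base mean.
#'
#' @param gv named genotypic values (a + d) per genotype.
#' @param pheno named phenotypic values per genotype (same ids; e.g. mean
#'   adjusted means).
#' @param H2 broad-sense heritability used for the response.
#' @param nSelect number of genotypes to select.
#' @return list: \code{selected}, \code{x0}, \code{xs}, \code{sigmaP},
#'   \code{S}, \code{intensity}, \code{deltaR}, \code{responsePct},
#'   \code{deltaRStandardized}, \code{ranking}.
#' @export
selectAndRespond <- function(gv, pheno, H2, nSelect) {
  if (nSelect <= 0) stop("nSelect must be positive")
  if (nSelect > length(gv)) stop("nSelect exceeds number of genotypes")
  common <- intersect(names(gv), names(pheno))
  gv <- gv[common]; pheno <- pheno[common]
  pos <- rankPositions(gv)
  selected <- names(sort(pos))[seq_len(nSelect)]
  x0 <- mean(pheno)
  xs <- mean(pheno[selected])
  sigmaP <- sd(pheno)
  S <- xs - x0
  i <- S / sigmaP
  list(selected = selected, x0 = x0, xs = xs, sigmaP = sigmaP, S = S,
       intensity = i, deltaR = S * H2, responsePct = 100 * S * H2 / x0,
       deltaRStandardized = i * H2, ranking = pos)
}
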