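#' Configuration for a synthetic cloned progeny trial
#'
#' Defines the breeding population, field design and variance structure of a
#' simulated cloned progeny trial. The defaults reproduce the study
#' conditions of a two-site subtropical eucalypt CPT: 48 genitors, 47
#' open-pollinated (half-sib) plus 11 controlled-cross (full-sib) families
#' of 60 progeny each, nursery survival of 3142/3480, five ramets per ortet,
#' an alpha-lattice 16 x 16 layout (256 treatments = 250 progeny + 6 control
#' clones per sub-trial), 11 and 12 sub-trials at the two sites, a 15,490
#' SNP panel with MAF in [0.02, 0.5], and trait variances (dm^3 scale)
#' additive 250.76, dominance 365.14, sub-trial 796.16, additive x
#' environment 37.47, dominance x environment 6.28 and spatial residual
#' 200.39 per site, with near-zero residual autocorrelations.
#'
#' @param nFounders number of founder genitors.
#' @param nSnps number of biallelic markers.
#' @param mafRange allele-frequency range (0, 0.5] markers are drawn from.
#' @param nHsFamilies,nFsFamilies numbers of half-sib (open-pollinated,
#'   pollen parent hidden) and full-sib (controlled cross) families.
#' @param progenyPerFamily progeny (ortets) per family.
#' @param rametsPerOrtet ramets per ortet = replicates per sub-trial (1-5).
#' @param sites named integer vector: sub-trials per site.
#' @param blockSize incomplete-block size; each sub-trial holds
#'   \code{blockSize^2} treatments in \code{blockSize} blocks per replicate.
#' @param nControls control clones shared by every sub-trial.
#' @param survivalRate nursery survival of progeny before field planting.
#' @param trueVariances named vector: \code{additive}, \code{dominance},
#'   \code{trial}, \code{axE}, \code{dxE}, \code{nugget} (trait-variance
#'   units).
#' @param residualPerSite spatial residual variance per site (recycled).
#' @param rhoCol,rhoRow residual autocorrelations along columns and rows.
#' @param traitMean overall trait mean (volume, dm^3).
#' @param siteEffects fixed site deviations (recycled over sites).
#' @param missingRate,errorRate genotyping artifact rates in [0, 1].
#' @param panelOverlapFraction fraction of markers shared by the two
#'   synthetic genotyping panels (the rest split evenly between A-only and
#'   B-only).
#' @param seed integer seed; every draw flows from it.
#' @return a validated configuration (class \code{"cptConfig"}).
#' @export
cptConfig <- function(nFounders = 48L, nSnps = 15490L,
                      mafRange = c(0.02, 0.5),
                      nHsFamilies = 47L, nFsFamilies = 11L,
                      progenyPerFamily = 60L, rametsPerOrtet = 5L,
                      sites = c(MAT = 11L, PAL = 12L), blockSize = 16L,
                      nControls = 6L, survivalRate = 3142 / 3480,
                      trueVariances = c(additive = 250.76,
                                        dominance = 365.14, trial = 796.16,
                                        axE = 37.47, dxE = 6.28,
                                        nugget = 0),
                      residualPerSite = c(200.39, 200.39),
                      rhoCol = -0.01, rhoRow = -0.09,
                      traitMean = 52.36, siteEffects = 0,
                      missingRate = 0, errorRate = 0,
                      panelOverlapFraction = 1, seed = 1L) {
  cfg <- list(nFounders = as.integer(nFounders), nSnps = as.integer(nSnps),
              mafRange = mafRange, nHsFamilies = as.integer(nHsFamilies),
              nFsFamilies = as.integer(nFsFamilies),
              progenyPerFamily = as.integer(progenyPerFamily),
              rametsPerOrtet = as.integer(rametsPerOrtet),
              sites = sites, blockSize = as.integer(blockSize),
              treatmentsPerSubtrial = as.integer(blockSize)^2,
              nControls = as.integer(nControls),
              survivalRate = survivalRate,
              trueVariances = trueVariances,
              residualPerSite = rep(residualPerSite,
                                    length.out = length(sites)),
              rhoCol = rhoCol, rhoRow = rhoRow, traitMean = traitMean,
              siteEffects = rep(siteEffects, length.out = length(sites)),
              missingRate = missingRate, errorRate = errorRate,
              panelOverlapFraction = panelOverlapFraction,
              seed = as.integer(seed))
  stopifnot(cfg$nFounders >= 2, cfg$nSnps >= 1,
            cfg$rametsPerOrtet >= 1L, cfg$rametsPerOrtet <= 5L,
            cfg$blockSize >= 2L,
            cfg$nControls >= 0L,
            cfg$nControls < cfg$treatmentsPerSubtrial,
            length(cfg$sites) >= 1, all(cfg$sites >= 1))
  if (length(cfg$mafRange) != 2 || cfg$mafRange[1] <= 0 ||
      cfg$mafRange[2] > 0.5 || cfg$mafRange[1] > cfg$mafRange[2])
    stop("mafRange must lie within (0, 0.5]")
  need <- c("additive", "dominance", "trial", "axE", "dxE", "nugget")
  stopifnot(all(need %in% names(cfg$trueVariances)))
  if (any(cfg$trueVariances < 0) || any(cfg$residualPerSite < 0))
    stop("variances must be non-negative")
  if (abs(cfg$rhoCol) >= 1 || abs(cfg$rhoRow) >= 1)
    stop("|rho| must be < 1")
  if (cfg$survivalRate < 0 || cfg$survivalRate > 1 ||
      cfg$missingRate < 0 || cfg$missingRate > 1 ||
      cfg$errorRate < 0 || cfg$errorRate > 1 ||
      cfg$panelOverlapFraction < 0 || cfg$panelOverlapFraction > 1)
    stop("rates must lie in [0, 1]")
  if (is.null(names(cfg$sites)))
    names(cfg$sites) <- paste0("S", seq_along(cfg$sites))
  class(cfg) <- "cptConfig"
  cfg
}

#' Design arithmetic for a CPT configuration
#'
#' Counts implied by the design: total progeny, nursery survivors, survival
#' percentage, genotypes and trees per site.
#'
#' @param config a \code{\link{cptConfig}}.
#' @return list of counts.
#' @export
designCounts <- function(config) {
  nProgeny <- (config$nHsFamilies + config$nFsFamilies) *
    config$progenyPerFamily
  nSurvivors <- round(nProgeny * config$survivalRate)
  progPerSub <- config$treatmentsPerSubtrial - config$nControls
  list(nFamilies = config$nHsFamilies + config$nFsFamilies,
       nProgeny = nProgeny,
       nSurvivors = nSurvivors,
       survivalPct = 100 * nSurvivors / nProgeny,
       progenyPerSubtrial = progPerSub,
       genotypesPerSite = as.integer(config$sites) * progPerSub,
       treesPerSite = as.integer(config$sites) *
         config$treatmentsPerSubtrial * config$rametsPerOrtet,
       blocksPerReplicate = config$blockSize)
}

#' Simulate founder genotypes
#'
#' Draws founder dosages per marker from Hardy-Weinberg proportions at an
#' allele frequency sampled uniformly from \code{mafRange}. No missing
#' calls: this is the truth matrix.
#'
#' @param config a \code{\link{cptConfig}}.
#' @return a \linkS4class{GenotypeDosage} of founders F001, F002, ...
#' @export
simulateFounders <- function(config) {
  p <- runif(config$nSnps, config$mafRange[1], config$mafRange[2])
  M <- matrix(rbinom(config$nFounders * config$nSnps, 2,
                     rep(p, each = config$nFounders)),
              nrow = config$nFounders,
              dimnames = list(sprintf("F%03d", seq_len(config$nFounders)),
                              sprintf("snp%05d", seq_len(config$nSnps))))
  genotypeDosage(M)
}

## Mendelian gene dropping: one gamete (0/1 allele count) per parent row
.gamete <- function(d) (d == 2) + (d == 1) * rbinom(length(d), 1, 0.5)

#' Create families by Mendelian gene dropping
#'
#' Full-sib families come from fixed founder parent pairs; half-sib families
#' have a known mother while the pollen father is drawn per seed among the
#' other founders. The hidden fathers are recorded in the truth pedigree but
#' masked ("0") in the declared pedigree, emulating open pollination and
#' enabling pedigree-correction tests.
#'
#' @param founders founder \linkS4class{GenotypeDosage}.
#' @param config a \code{\link{cptConfig}}.
#' @return list: \code{genotypes} (progeny \code{GenotypeDosage}),
#'   \code{declared} and \code{truth} pedigrees (id, sire, dam),
#'   \code{family} (data.frame id, family_id, type).
#' @export
makeFamilies <- function(founders, config) {
  Fm <- dosages(founders)
  fids <- rownames(Fm)
  nfam <- config$nHsFamilies + config$nFsFamilies
  if (config$nHsFamilies > length(fids))
    stop("more half-sib families than available mothers")
  if (config$nFsFamilies > choose(length(fids), 2))
    stop("more full-sib families than distinct parent pairs")
  hsMothers <- sample(fids, config$nHsFamilies)
  pairs <- t(combn(fids, 2))
  fsPairs <- pairs[sample(nrow(pairs), config$nFsFamilies), , drop = FALSE]
  npro <- nfam * config$progenyPerFamily
  M <- matrix(0, npro, config$nSnps,
              dimnames = list(sprintf("P%04d", seq_len(npro)),
                              colnames(Fm)))
  dec <- truth <- data.frame(id = rownames(M), sire = "0", dam = "0",
                             stringsAsFactors = FALSE)
  fam <- data.frame(id = rownames(M), family_id = "", type = "",
                    stringsAsFactors = FALSE)
  k <- 0L
  for (f in seq_len(nfam)) {
    fs <- f > config$nHsFamilies
    famId <- sprintf("FAM%02d", f)
    for (j in seq_len(config$progenyPerFamily)) {
      k <- k + 1L
      if (fs) {
        sire <- fsPairs[f - config$nHsFamilies, 1]
        dam <- fsPairs[f - config$nHsFamilies, 2]
        dec$sire[k] <- sire
      } else {
        dam <- hsMothers[f]
        sire <- sample(setdiff(fids, dam), 1)
      }
      dec$dam[k] <- dam
      truth$sire[k] <- sire
      truth$dam[k] <- dam
      M[k, ] <- .gamete(Fm[sire, ]) + .gamete(Fm[dam, ])
      fam$family_id[k] <- famId
      fam$type[k] <- if (fs) "FS" else "HS"
    }
  }
  list(genotypes = genotypeDosage(M), declared = dec, truth = truth,
       family = fam)
}

#' Simulate control-clone genotypes
#'
#' Controls are unrelated, founder-equivalent genotypes drawn from
#' Hardy-Weinberg proportions at the founders' empirical allele frequencies.
#'
#' @param founders founder \linkS4class{GenotypeDosage}.
#' @param config a \code{\link{cptConfig}}.
#' @return a \linkS4class{GenotypeDosage} of controls C01, C02, ...
#' @export
simulateControls <- function(founders, config) {
  if (config$nControls == 0L)
    return(genotypeDosage(matrix(numeric(0), 0, ncol(dosages(founders)),
                                 dimnames = list(NULL,
                                                 markerIds(founders)))))
  p <- colMeans(dosages(founders)) / 2
  M <- matrix(rbinom(config$nControls * length(p), 2,
                     rep(p, each = config$nControls)),
              nrow = config$nControls,
              dimnames = list(sprintf("C%02d", seq_len(config$nControls)),
                              names(p)))
  genotypeDosage(M)
}

#' Assign genotypes to the alpha-lattice field layout
#'
#' Each sub-trial receives a disjoint set of progeny plus the shared
#' controls. Within every replicate the treatments are randomly partitioned
#' into \code{blockSize} incomplete blocks of \code{blockSize} trees; each
#' replicate is laid out as a \code{blockSize} x \code{blockSize} grid
#' (block = grid row, random order within) and the replicates are tiled
#' side-by-side along the column axis. Plot spacing is 2.5 m within rows and
#' 3.6 m between rows.
#'
#' @param progenyIds character vector of available (surviving) progeny ids.
#' @param controlIds character vector of control ids (length
#'   \code{nControls}).
#' @param config a \code{\link{cptConfig}}.
#' @return data.frame: tree_id, genotype_id, site, sub_trial, replicate,
#'   block, row, col (coordinates local to the sub-trial).
#' @export
assignLayout <- function(progenyIds, controlIds, config) {
  bs <- config$blockSize
  tr <- config$treatmentsPerSubtrial
  progPerSub <- tr - config$nControls
  if (length(controlIds) != config$nControls)
    stop("need exactly nControls control ids")
  out <- vector("list", sum(config$sites) * config$rametsPerOrtet)
  li <- 0L
  for (s in seq_along(config$sites)) {
    siteName <- names(config$sites)[s]
    nSub <- config$sites[s]
    need <- nSub * progPerSub
    if (length(progenyIds) < need)
      stop("not enough progeny for site ", siteName, ": need ", need)
    sitePool <- sample(progenyIds, need)
    for (st in seq_len(nSub)) {
      treats <- c(sitePool[((st - 1) * progPerSub + 1):(st * progPerSub)],
                  controlIds)
      for (rp in seq_len(config$rametsPerOrtet)) {
        ord <- sample(treats)                  # random partition into blocks
        blocks <- rep(seq_len(bs), each = bs)
        rowIdx <- blocks                        # block = grid row
        colIdx <- unlist(lapply(seq_len(bs), function(b) sample(seq_len(bs))))
        li <- li + 1L
        out[[li]] <- data.frame(
          genotype_id = ord, site = siteName,
          sub_trial = sprintf("%s_T%02d", siteName, st),
          replicate = rp,
          block = sprintf("B%02d", blocks),
          row = rowIdx, col = colIdx + (rp - 1L) * bs,
          stringsAsFactors = FALSE)
      }
    }
  }
  layout <- do.call(rbind, out)
  layout$tree_id <- sprintf("tree%06d", seq_len(nrow(layout)))
  layout[, c("tree_id", "genotype_id", "site", "sub_trial", "replicate",
             "block", "row", "col")]
}

## sample a mean-zero AR1(rhoRow) x AR1(rhoCol) field on an nr x nc grid
.ar1Field <- function(nr, nc, rhoRow, rhoCol, sigma2) {
  Lr <- t(chol(ar1Matrix(nr, rhoRow)))
  Lc <- t(chol(ar1Matrix(nc, rhoCol)))
  sqrt(sigma2) * (Lr %*% matrix(rnorm(nr * nc), nr, nc) %*% t(Lc))
}

#' Simulate phenotypes on a field layout
#'
#' Generates the trait as trait mean + site effect + sub-trial effect +
#' breeding value + dominance deviation + additive x site + dominance x
#' site + spatially autocorrelated residual + nugget. Breeding values are
#' centered-dosage marker scores with iid normal effects rescaled so their
#' realized variance matches the configured additive variance; dominance
#' deviations use the dominance-deviation coding the same way. The spatial
#' field is AR1(rhoRow) x AR1(rhoCol) over each sub-trial grid with the
#' site's residual variance.
#'
#' @param layout layout data.frame from \code{\link{assignLayout}}.
#' @param genotypes \linkS4class{GenotypeDosage} covering every genotype in
#'   the layout (one row per ortet).
#' @param config a \code{\link{cptConfig}}.
#' @return list: \code{pheno} (layout + \code{vol_dm3}), \code{truth}
#'   (breeding values \code{a}, dominance deviations \code{d}, genotypic
#'   values \code{g}, per-(genotype, site) interactions, sub-trial effects,
#'   per-tree spatial residuals).
#' @export
simulatePhenotypes <- function(layout, genotypes, config) {
  M <- dosages(genotypes)
  ids <- rownames(M)
  stopifnot(all(layout$genotype_id %in% ids))
  tv <- config$trueVariances
  p <- colMeans(M, na.rm = TRUE) / 2
  poly <- p > 0 & p < 1
  Z <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly], "-")
  scaleTo <- function(x, v) {
    if (v == 0) return(setNames(rep(0, length(x)), names(x)))
    x <- x - mean(x)
    x * sqrt(v / var(x))
  }
  a <- scaleTo(drop(Z %*% rnorm(ncol(Z))), tv["additive"])
  pj <- p[poly]
  lo <- pmin(M[, poly, drop = FALSE], 1)
  hi <- pmax(M[, poly, drop = FALSE] - 1, 0)
  S <- sweep(1 - lo, 2, -2 * pj^2, "*") +
    sweep(lo - hi, 2, 2 * pj * (1 - pj), "*") +
    sweep(hi, 2, -2 * (1 - pj)^2, "*")
  d <- scaleTo(drop(S %*% rnorm(ncol(S))), tv["dominance"])
  names(a) <- names(d) <- ids

  sites <- names(config$sites)
  subTrials <- unique(layout[, c("site", "sub_trial")])
  trialEff <- setNames(rnorm(nrow(subTrials), 0, sqrt(tv["trial"])),
                       subTrials$sub_trial)
  axe <- matrix(rnorm(length(ids) * length(sites), 0, sqrt(tv["axE"])),
                length(ids), dimnames = list(ids, sites))
  dxe <- matrix(rnorm(length(ids) * length(sites), 0, sqrt(tv["dxE"])),
                length(ids), dimnames = list(ids, sites))

  y <- numeric(nrow(layout))
  spatial <- numeric(nrow(layout))
  siteEff <- setNames(config$siteEffects, sites)
  for (stName in subTrials$sub_trial) {
    idx <- which(layout$sub_trial == stName)
    siteName <- layout$site[idx[1]]
    nr <- max(layout$row[idx]); nc <- max(layout$col[idx])
    fld <- .ar1Field(nr, nc, config$rhoRow, config$rhoCol,
                     config$residualPerSite[match(siteName, sites)])
    spatial[idx] <- fld[cbind(layout$row[idx], layout$col[idx])]
    gid <- layout$genotype_id[idx]
    y[idx] <- config$traitMean + siteEff[siteName] + trialEff[stName] +
      a[gid] + d[gid] + axe[cbind(gid, siteName)] +
      dxe[cbind(gid, siteName)] + spatial[idx]
  }
  if (tv["nugget"] > 0)
    y <- y + rnorm(length(y), 0, sqrt(tv["nugget"]))
  pheno <- layout
  pheno$vol_dm3 <- y
  list(pheno = pheno,
       truth = list(a = a, d = d, g = a + d, axe = axe, dxe = dxe,
                    trialEffects = trialEff, spatial = spatial))
}

#' Inject genotyping artifacts
#'
#' Sets calls missing at \code{missingRate}, perturbs non-missing calls to a
#' different dosage at \code{errorRate} (uniformly between the two other
#' values), and assigns markers to two synthetic panels: a fraction
#' \code{panelOverlapFraction} is shared ("both"), the rest split evenly
#' between "A"-only and "B"-only.
#'
#' @param genotypes a \linkS4class{GenotypeDosage}.
#' @param config a \code{\link{cptConfig}}.
#' @return a \linkS4class{GenotypeDosage} with artifacts and a panel slot.
#' @export
injectGenotypingArtifacts <- function(genotypes, config) {
  M <- dosages(genotypes)
  nm <- length(M)
  if (config$errorRate > 0) {
    err <- which(!is.na(M) & runif(nm) < config$errorRate)
    if (length(err)) {
      cur <- M[err]
      shift <- 1 + rbinom(length(err), 1, 0.5)   # +1 or +2 mod 3
      M[err] <- (cur + shift) %% 3
    }
  }
  if (config$missingRate > 0)
    M[runif(nm) < config$missingRate] <- NA
  nmark <- ncol(M)
  nShared <- round(config$panelOverlapFraction * nmark)
  panel <- rep("both", nmark)
  if (nShared < nmark) {
    solo <- sample(nmark, nmark - nShared)
    panel[solo] <- rep(c("A", "B"), length.out = length(solo))
  }
  genotypeDosage(M, panel = panel)
}

#' Simulate a complete cloned progeny trial
#'
#' Orchestrates founder simulation, family creation, nursery survival, field
#' layout, phenotype simulation and genotyping artifacts from one seeded
#' configuration. Every output is reproducible from (config, seed).
#'
#' @param config a \code{\link{cptConfig}}.
#' @return list: \code{config}, \code{founders}, \code{progeny} (truth
#'   genotypes), \code{controls}, \code{genotypes} (founders + surviving
#'   progeny + controls, truth), \code{observed} (same with artifacts),
#'   \code{declared}/\code{truthPedigree}, \code{family}, \code{survivors},
#'   \code{layout}, \code{pheno}, \code{truth}.
#' @export
simulateCpt <- function(config = cptConfig()) {
  set.seed(config$seed)
  founders <- simulateFounders(config)
  famOut <- makeFamilies(founders, config)
  controls <- simulateControls(founders, config)
  nPro <- nrow(dosages(famOut$genotypes))
  survivors <- sort(sample(sampleIds(famOut$genotypes),
                           round(nPro * config$survivalRate)))
  layout <- assignLayout(survivors, sampleIds(controls), config)
  used <- unique(layout$genotype_id)
  allGeno <- genotypeDosage(rbind(dosages(founders),
                                  dosages(famOut$genotypes),
                                  dosages(controls)))
  phen <- simulatePhenotypes(layout, allGeno, config)
  observed <- injectGenotypingArtifacts(allGeno, config)
  fam <- famOut$family
  list(config = config, founders = founders, progeny = famOut$genotypes,
       controls = controls, genotypes = allGeno, observed = observed,
       declared = famOut$declared, truthPedigree = famOut$truth,
       family = fam, survivors = survivors, usedGenotypes = used,
       layout = layout, pheno = phen$pheno, truth = phen$truth)
}
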