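test_that("configuration invariants are enforced", {
  cfg <- cptConfig()
  expect_equal(cfg$treatmentsPerSubtrial, 256)
  expect_equal(cfg$nHsFamilies + cfg$nFsFamilies, 58)
  expect_error(cptConfig(mafRange = c(0, 0.5)), "mafRange")
  expect_error(cptConfig(mafRange = c(0.1, 0.6)), "mafRange")
  expect_error(cptConfig(rhoCol = 1), "rho")
  expect_error(cptConfig(missingRate = 1.2), "rates")
  expect_error(cptConfig(trueVariances = c(additive = -1, dominance = 1,
                                           trial = 1, axE = 1, dxE = 1,
                                           nugget = 0)),
               "non-negative")
})

test_that("founder genotypes follow Hardy-Weinberg at the drawn frequencies", {
  set.seed(1)
  cfg <- cptConfig(nFounders = 48, nSnps = 2000, seed = 1)
  f <- simulateFounders(cfg)
  M <- dosages(f)
  expect_equal(dim(M), c(48, 2000))
  expect_true(all(M %in% 0:2))
  # forced frequency 0.5
  cfg2 <- cptConfig(nFounders = 400, nSnps = 50, mafRange = c(0.5, 0.5),
                    seed = 2)
  set.seed(2)
  M2 <- dosages(simulateFounders(cfg2))
  expect_equal(mean(colMeans(M2) / 2), 0.5, tolerance = 0.02)
  # observed heterozygosity matches 2p(1-p) averaged over markers
  p <- colMeans(M) / 2
  hetObs <- colMeans(M == 1)
  expect_equal(mean(hetObs), mean(2 * p * (1 - p)), tolerance = 0.02)
})

test_that("families count and segregate as declared", {
  set.seed(6)
  cfg <- cptConfig(nSnps = 50, seed = 6)   # full 58 x 60 family structure
  fam <- makeFamilies(simulateFounders(cfg), cfg)
  expect_equal(nrow(dosages(fam$genotypes)), 3480)
  expect_equal(length(unique(fam$family$family_id)), 58)
  expect_equal(sum(fam$declared$sire == "0"), 47 * 60)
  # Mendelian segregation: parents 0 x 2 -> offspring always dosage 1
  cfgFS <- cptConfig(nFounders = 2, nSnps = 10, nHsFamilies = 0,
                     nFsFamilies = 1, progenyPerFamily = 25,
                     rametsPerOrtet = 1, sites = c(S = 1), blockSize = 4,
                     nControls = 0, seed = 6)
  f2 <- genotypeDosage(matrix(c(rep(0, 10), rep(2, 10)), 2, 10,
                              byrow = TRUE,
                              dimnames = list(c("F001", "F002"),
                                              paste0("m", 1:10))))
  fam2 <- makeFamilies(f2, cfgFS)
  expect_true(all(dosages(fam2$genotypes) == 1))
  expect_error(makeFamilies(f2, cptConfig(nFounders = 2, nSnps = 10,
                                          nHsFamilies = 0, nFsFamilies = 2,
                                          progenyPerFamily = 5,
                                          seed = 1)),
               "parent pairs")
})

test_that("the field layout satisfies the design counting rules", {
  set.seed(10)
  cfg <- smallCptConfig(10)
  sim <- simulateCpt(cfg)
  lay <- sim$layout
  counts <- designCounts(cfg)
  # trees per sub-trial = treatments x replicates
  perSub <- table(lay$sub_trial)
  expect_true(all(perSub == cfg$treatmentsPerSubtrial * cfg$rametsPerOrtet))
  # each genotype exactly once per replicate within its sub-trial
  once <- aggregate(tree_id ~ genotype_id + sub_trial + replicate,
                    lay, length)
  expect_true(all(once$tree_id == 1))
  # blocks partition each replicate into blockSize blocks of blockSize
  for (st in unique(lay$sub_trial)[1:2]) {
    one <- lay[lay$sub_trial == st & lay$replicate == 1, ]
    expect_equal(length(unique(one$block)), cfg$blockSize)
    expect_true(all(table(one$block) == cfg$blockSize))
    expect_equal(sort(unique(one$genotype_id)),
                 sort(one$genotype_id))       # no duplicates
  }
  # controls appear in every sub-trial; progeny sets are disjoint per site
  ctrl <- sampleIds(sim$controls)
  for (st in unique(lay$sub_trial))
    expect_true(all(ctrl %in% lay$genotype_id[lay$sub_trial == st]))
  for (s in names(cfg$sites)) {
    sl <- lay[lay$site == s & !lay$genotype_id %in% ctrl, ]
    tab <- table(unique(sl[, c("genotype_id", "sub_trial")])$genotype_id)
    expect_true(all(tab == 1))
  }
  expect_equal(nrow(lay),
               sum(counts$treesPerSite))
  expect_error(assignLayout(paste0("P", 1:10), paste0("C", 1:6), cfg),
               "not enough progeny")
})

test_that("phenotype variance components are calibrated", {
  set.seed(14)
  # degenerate: only residual variance -> phenotypic variance matches it
  cfgR <- smallCptConfig(14,
    trueVariances = c(additive = 0, dominance = 0, trial = 0, axE = 0,
                      dxE = 0, nugget = 0),
    residualPerSite = c(100, 100), rhoCol = 0, rhoRow = 0)
  simR <- simulateCpt(cfgR)
  expect_equal(var(simR$pheno$vol_dm3), 100, tolerance = 0.1 * 100)
  # iid limit: no lag-1 autocorrelation along rows/columns
  one <- simR$pheno[simR$pheno$sub_trial == simR$pheno$sub_trial[1], ]
  g <- matrix(NA_real_, max(one$row), max(one$col))
  g[cbind(one$row, one$col)] <- one$vol_dm3
  lag1 <- cor(as.vector(g[, -1]), as.vector(g[, -ncol(g)]))
  expect_lt(abs(lag1), 0.15)
  # clone consistency: ramets of an ortet share the true genotypic value
  sim <- simulateCpt(smallCptConfig(15))
  expect_equal(var(sim$truth$a), 250.76, tolerance = 1e-6)
  expect_equal(var(sim$truth$d), 365.14, tolerance = 1e-6)
})

test_that("realized variances match the configuration across seeds", {
  # mean realized variance of the drawn components over 30 seeds within 10%
  nSeeds <- 30
  comp <- matrix(NA_real_, nSeeds, 3,
                 dimnames = list(NULL, c("trial", "axE", "spatial")))
  for (s in seq_len(nSeeds)) {
    cfg <- cptConfig(nFounders = 20, nSnps = 60, nHsFamilies = 10,
                     nFsFamilies = 4, progenyPerFamily = 10,
                     rametsPerOrtet = 2, sites = c(A = 5, B = 5),
                     blockSize = 4, nControls = 2, survivalRate = 1,
                     rhoCol = 0, rhoRow = 0, seed = 300 + s)
    sim <- simulateCpt(cfg)
    comp[s, "trial"] <- var(sim$truth$trialEffects)
    comp[s, "axE"] <- var(as.vector(sim$truth$axe))
    comp[s, "spatial"] <- var(sim$truth$spatial)
  }
  cfg0 <- cptConfig()
  expect_equal(mean(comp[, "trial"]), 796.16, tolerance = 0.10 * 796.16)
  expect_equal(mean(comp[, "axE"]), 37.47, tolerance = 0.10 * 37.47)
  expect_equal(mean(comp[, "spatial"]), 200.39, tolerance = 0.10 * 200.39)
})

test_that("the spatial field has the configured autocorrelation decay", {
  set.seed(33)
  cfg <- cptConfig(nFounders = 8, nSnps = 30, nHsFamilies = 4,
                   nFsFamilies = 2, progenyPerFamily = 20,
                   rametsPerOrtet = 5, sites = c(A = 1), blockSize = 10,
                   nControls = 4, survivalRate = 1,
                   trueVariances = c(additive = 0, dominance = 0,
                                     trial = 0, axE = 0, dxE = 0,
                                     nugget = 0),
                   residualPerSite = 150, rhoCol = 0.6, rhoRow = 0.4,
                   seed = 33)
  sim <- simulateCpt(cfg)
  lay <- sim$pheno
  corLag <- function(colwise) {
    num <- 0; acc <- c()
    for (st in unique(lay$sub_trial)) {
      one <- lay[lay$sub_trial == st, ]
      gmat <- matrix(NA_real_, max(one$row), max(one$col))
      gmat[cbind(one$row, one$col)] <- one$vol_dm3
      if (colwise)
        acc <- c(acc, cor(as.vector(gmat[, -1]),
                          as.vector(gmat[, -ncol(gmat)])))
      else
        acc <- c(acc, cor(as.vector(gmat[-1, ]),
                          as.vector(gmat[-nrow(gmat), ])))
    }
    mean(acc)
  }
  expect_equal(corLag(TRUE), 0.6, tolerance = 0.12)
  expect_equal(corLag(FALSE), 0.4, tolerance = 0.15)
})

test_that("genotyping artifacts behave as configured", {
  set.seed(40)
  M <- matrix(rbinom(50 * 200, 2, 0.3), 50, 200,
              dimnames = list(paste0("i", 1:50), paste0("m", 1:200)))
  g <- genotypeDosage(M)
  cfg0 <- smallCptConfig(40, missingRate = 0, errorRate = 0)
  expect_equal(dosages(injectGenotypingArtifacts(g, cfg0)), M)
  cfgM <- smallCptConfig(40, missingRate = 0.5, errorRate = 0)
  noisy <- injectGenotypingArtifacts(g, cfgM)
  fracNA <- mean(is.na(dosages(noisy)))
  se <- sqrt(0.5 * 0.5 / length(M))
  expect_lt(abs(fracNA - 0.5), 3 * se)
  cfgE <- smallCptConfig(40, missingRate = 0, errorRate = 0.1)
  err <- injectGenotypingArtifacts(g, cfgE)
  expect_lt(abs(mean(dosages(err) != M) - 0.1), 0.01)
  expect_true(all(dosages(err) %in% 0:2))
  cfgP <- smallCptConfig(40, panelOverlapFraction = 0.6)
  pan <- markerPanel(injectGenotypingArtifacts(g, cfgP))
  expect_equal(mean(pan == "both"), 0.6, tolerance = 0.01)
  expect_equal(sum(pan == "A"), sum(pan == "B"))
})

test_that("simulation is reproducible from (config, seed)", {
  s1 <- simulateCpt(smallCptConfig(99))
  s2 <- simulateCpt(smallCptConfig(99))
  expect_identical(s1$pheno, s2$pheno)
  expect_identical(dosages(s1$observed), dosages(s2$observed))
  s3 <- simulateCpt(smallCptConfig(100))
  expect_false(identical(s1$pheno$vol_dm3, s3$pheno$vol_dm3))
})

test_that("design arithmetic reproduces the reference configuration", {
  counts <- designCounts(cptConfig())
  expect_equal(counts$nProgeny, 3480)
  expect_equal(counts$nSurvivors, 3142)
  expect_equal(round(counts$survivalPct, 1), 90.3)
  expect_equal(counts$treesPerSite, c(14080, 15360))
  expect_equal(counts$genotypesPerSite, c(2750, 3000))
})
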