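# Shared simulation helpers for the test suite. All fixtures are built in
# code from seeded configurations.

# a small two-site CPT: 20 families x 10 progeny x 3 ramets, 6x6 lattice
smallCptConfig <- function(seed = 7, ...) {
  cptConfig(nFounders = 20, nSnps = 400, nHsFamilies = 14, nFsFamilies = 6,
            progenyPerFamily = 10, rametsPerOrtet = 3,
            sites = c(MAT = 2, PAL = 2), blockSize = 6, nControls = 6,
            survivalRate = 1, seed = seed, ...)
}

# kernels for the genotypes actually planted in a simulated CPT
cptKernels <- function(sim, alpha = 0.98) {
  gids <- sim$usedGenotypes
  g <- sim$genotypes[gids, ]
  Ga <- grmAdditive(g)
  Gd <- grmDominance(g)
  ped <- rbind(sim$declared,
               data.frame(id = sampleIds(sim$controls), sire = "0",
                          dam = "0"))
  A22 <- a22Matrix(numeratorA(ped), gids)
  list(Gstar = blendGrm(Ga, A22, alpha), Gd = Gd)
}

# simulate adjusted-mean scale data directly from the second-stage model:
# two sites, nSub sub-trials per site, genotypes from a gene-dropped
# pedigree, genetic effects drawn with covariance sigma^2 * kernel
stage2Sim <- function(seed, nGenotypes = 1000, nSnps = 1000, nSub = 10,
                      tv = c(additive = 250.76, dominance = 365.14,
                             trial = 796.16, axE = 37.47, dxE = 6.28,
                             residual = 200.39)) {
  set.seed(seed)
  perFam <- 20
  nFam <- nGenotypes / perFam
  cfg <- cptConfig(nFounders = 48, nSnps = nSnps,
                   nHsFamilies = round(0.8 * nFam),
                   nFsFamilies = nFam - round(0.8 * nFam),
                   progenyPerFamily = perFam, rametsPerOrtet = 1,
                   sites = c(MAT = 1, PAL = 1), blockSize = 4,
                   nControls = 0, survivalRate = 1, seed = seed)
  founders <- simulateFounders(cfg)
  fam <- makeFamilies(founders, cfg)
  g <- fam$genotypes
  Ga <- grmAdditive(g)
  Gd <- grmDominance(g)
  A22 <- a22Matrix(numeratorA(fam$declared), sampleIds(g))
  Gstar <- blendGrm(Ga, A22, 0.98)
  n <- nrow(dosages(g))
  ids <- sampleIds(g)
  cG <- chol(relValues(Gstar) + diag(1e-8, n))
  cD <- chol(relValues(Gd) + diag(1e-6, n))
  drawG <- function(v, ch) sqrt(v) * drop(t(ch) %*% rnorm(n))
  a <- drawG(tv["additive"], cG)
  d <- drawG(tv["dominance"], cD)
  sites <- c("MAT", "PAL")
  sub <- lapply(sites, function(s) sample(rep(seq_len(nSub),
                                              length.out = n)))
  tEff <- rnorm(2 * nSub, 0, sqrt(tv["trial"]))
  aE <- vapply(sites, function(s) drawG(tv["axE"], cG), numeric(n))
  dE <- vapply(sites, function(s) drawG(tv["dxE"], cD), numeric(n))
  means <- do.call(rbind, lapply(1:2, function(si) {
    data.frame(genotype_id = ids, site = sites[si],
               sub_trial = sprintf("%s_T%02d", sites[si], sub[[si]]),
               mean = 52.36 + tEff[(si - 1) * nSub + sub[[si]]] + a + d +
                 aE[, si] + dE[, si] + rnorm(n, 0, sqrt(tv["residual"])),
               stringsAsFactors = FALSE)
  }))
  list(means = means, Gstar = Gstar, Gd = Gd, truth = tv,
       a = setNames(a, ids), d = setNames(d, ids))
}
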