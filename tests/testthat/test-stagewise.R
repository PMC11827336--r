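# one sub-trial worth of data with configurable effects
oneSubTrial <- function(seed, nGeno = 30, reps = 3, sdNoise = 1,
                        genoMeans = NULL) {
  set.seed(seed)
  ids <- sprintf("G%02d", seq_len(nGeno))
  if (is.null(genoMeans)) genoMeans <- setNames(rnorm(nGeno, 50, 5), ids)
  bs <- ceiling(sqrt(nGeno))
  rows <- vector("list", reps)
  for (r in seq_len(reps)) {
    ord <- sample(ids)
    rows[[r]] <- data.frame(
      genotype_id = ord, sub_trial = "T1", site = "S1", replicate = r,
      block = sprintf("B%02d", rep(seq_len(bs),
                                   length.out = nGeno)),
      row = rep(seq_len(bs), length.out = nGeno),
      col = (seq_len(nGeno) - 1) %/% bs + 1 + (r - 1) * bs)
  }
  d <- do.call(rbind, rows)
  d$vol_dm3 <- genoMeans[d$genotype_id] + rnorm(nrow(d), 0, sdNoise)
  d
}

test_that("with no design effects the adjusted means are the ramet means", {
  d <- oneSubTrial(1, nGeno = 24, reps = 3, sdNoise = 0.5)
  res <- fitStage1(d, rhoRow = 0, rhoCol = 0)
  raw <- tapply(d$vol_dm3, d$genotype_id, mean)
  expect_equal(unname(res$adjustedMeans[names(raw)]), as.vector(raw),
               tolerance = 1e-3)
  # replicate and block variances collapse towards the boundary
  expect_lt(res$varComp["replicate"], 0.1 * res$varComp["spatial"])
  expect_lt(res$varComp["block"], 0.1 * res$varComp["spatial"])
})

test_that("adjusted means are location equivariant", {
  d <- oneSubTrial(2, nGeno = 20, reps = 3, sdNoise = 1)
  res1 <- fitStage1(d, rhoRow = 0, rhoCol = 0)
  d2 <- d
  d2$vol_dm3 <- d2$vol_dm3 + 7.5
  res2 <- fitStage1(d2, rhoRow = 0, rhoCol = 0)
  expect_equal(res2$adjustedMeans, res1$adjustedMeans + 7.5,
               tolerance = 1e-6)
})

test_that("missing trees are excluded rather than imputed", {
  d <- oneSubTrial(3, nGeno = 16, reps = 3, sdNoise = 0.5)
  dead <- d$genotype_id == "G01" & d$replicate < 3
  d$vol_dm3[dead] <- NA
  res <- fitStage1(d, rhoRow = 0, rhoCol = 0)
  alive <- d$genotype_id == "G01" & !is.na(d$vol_dm3)
  expect_equal(unname(res$adjustedMeans["G01"]),
               mean(d$vol_dm3[alive]), tolerance = 0.15)
})

test_that("spatial autocorrelation parameters are recovered on average", {
  errs <- matrix(NA_real_, 12, 2)
  for (s in seq_len(nrow(errs))) {
    set.seed(500 + s)
    cfg <- cptConfig(nFounders = 10, nSnps = 40, nHsFamilies = 4,
                     nFsFamilies = 2, progenyPerFamily = 6,
                     rametsPerOrtet = 3, sites = c(A = 1), blockSize = 6,
                     nControls = 4,
                     trueVariances = c(additive = 30, dominance = 20,
                                       trial = 0, axE = 0, dxE = 0,
                                       nugget = 0),
                     residualPerSite = 150, rhoCol = 0.4, rhoRow = 0.3,
                     survivalRate = 1, seed = 500 + s)
    sim <- simulateCpt(cfg)
    res <- fitStage1(sim$pheno)
    errs[s, ] <- c(res$rhoRow - 0.3, res$rhoCol - 0.4)
  }
  expect_lt(abs(mean(errs[, 1])), 0.15)
  expect_lt(abs(mean(errs[, 2])), 0.15)
})

test_that("the second-stage likelihood matches a dense oracle", {
  s <- stage2Sim(4, nGenotypes = 60, nSnps = 300, nSub = 3)
  theta <- c(trial = 700, additive = 250, dominance = 350, axE = 40,
             dxE = 10, residual = 200)
  fit <- fitStage2(s$means, s$Gstar, s$Gd, fixTheta = theta,
                   computeBlup = FALSE)
  # dense oracle
  m <- s$means
  gids <- sort(unique(m$genotype_id))
  GA <- relValues(s$Gstar)[gids, gids]
  GD <- relValues(s$Gd)[gids, gids]
  n <- nrow(m)
  ind <- function(f) {
    f <- factor(f)
    Z <- matrix(0, length(f), nlevels(f))
    Z[cbind(seq_along(f), as.integer(f))] <- 1
    Z
  }
  Zt <- ind(m$sub_trial)
  Zg <- ind(factor(m$genotype_id, levels = gids))
  sites <- sort(unique(m$site))
  Zgs <- ind(factor(paste(m$site, m$genotype_id),
                    levels = as.vector(outer(gids, sites,
                                             function(g, s)
                                               paste(s, g)))))
  V <- theta["trial"] * tcrossprod(Zt) +
    theta["additive"] * Zg %*% GA %*% t(Zg) +
    theta["dominance"] * Zg %*% GD %*% t(Zg) +
    theta["axE"] * Zgs %*% kronecker(diag(2), GA) %*% t(Zgs) +
    theta["dxE"] * Zgs %*% kronecker(diag(2), GD) %*% t(Zgs) +
    theta["residual"] * diag(n)
  X <- ind(m$site)
  Vi <- solve(V)
  P <- Vi - Vi %*% X %*% solve(t(X) %*% Vi %*% X) %*% t(X) %*% Vi
  ll <- -0.5 * (determinant(V)$modulus +
                determinant(t(X) %*% Vi %*% X)$modulus +
                drop(t(m$mean) %*% P %*% m$mean))
  expect_equal(logLikReml(fit$fit), drop(ll), tolerance = 1e-8,
               ignore_attr = TRUE)
})

test_that("a zero-dominance truth drives the dominance share to the boundary", {
  d2 <- numeric(4)
  for (s in 1:4) {
    sim <- stage2Sim(600 + s, nGenotypes = 400, nSnps = 500, nSub = 4,
                     tv = c(additive = 250.76, dominance = 0,
                            trial = 100, axE = 0, dxE = 0,
                            residual = 200.39))
    f <- fitStage2(sim$means, sim$Gstar, sim$Gd, tol = 1e-6,
                   tolTheta = 1e-3, computeBlup = FALSE)
    p <- summarizeParameters(f$varComp)
    d2[s] <- p$delta2
  }
  expect_lt(mean(d2), 0.02)
})

test_that("the parameter summary reproduces the worked reference table", {
  vc <- c(additive = 250.76, dominance = 365.14, trial = 796.16,
          axE = 37.47, dxE = 6.28, residual = 200.39)
  p <- summarizeParameters(vc)
  expect_equal(p$sigmaP2, 1656.20, tolerance = 0.02 / 1656.2)
  expect_equal(round(p$h2a, 2), 0.15)
  expect_equal(round(p$delta2, 2), 0.22)
  expect_equal(round(p$H2, 2), 0.37)
  expect_equal(round(100 * p$shares[["trial"]]), 48)
  expect_equal(round(100 * p$shares[["residual"]]), 12)
  expect_equal(p$h2a + p$delta2, p$H2)
  # degenerate cases
  vc0 <- c(additive = 0, dominance = 0, trial = 1, axE = 0, dxE = 0,
           residual = 1)
  p0 <- summarizeParameters(vc0)
  expect_equal(p0$h2a, 0)
  expect_equal(p0$H2, 0)
  vcA <- c(additive = 2, dominance = 0, trial = 1, axE = 0, dxE = 0,
           residual = 1)
  pA <- summarizeParameters(vcA)
  expect_equal(pA$H2, pA$h2a)
  expect_error(summarizeParameters(vc0 * 0), "zero phenotypic")
})

test_that("selection differential and response follow their definitions", {
  # select everything: no differential, no response
  gv <- setNames(1:10, paste0("g", 1:10))
  ph <- setNames(rnorm(10, 50, 5), paste0("g", 1:10))
  all <- selectAndRespond(gv, ph, H2 = 0.4, nSelect = 10)
  expect_equal(all$S, 0)
  expect_equal(all$deltaR, 0)
  # hand-built case mirroring the reference table
  n <- 100; nSel <- 30
  gv <- setNames(seq(n, 1), sprintf("g%03d", 1:n))
  ph <- numeric(n)
  names(ph) <- names(gv)
  ph[1:nSel] <- 113.56
  ph[(nSel + 1):n] <- (52.36 * n - 113.56 * nSel) / (n - nSel)
  sel <- selectAndRespond(gv, ph, H2 = 0.37, nSelect = nSel)
  expect_equal(sel$x0, 52.36, tolerance = 1e-10)
  expect_equal(sel$xs, 113.56)
  expect_equal(sel$S, 61.20, tolerance = 1e-10)
  expect_equal(sel$deltaR, 61.20 * 0.37, tolerance = 1e-10)
  expect_equal(sel$deltaRStandardized, sel$intensity * 0.37)
  expect_equal(sel$S, sel$intensity * sel$sigmaP)
  # ranking invariant to a constant shift of the values
  expect_equal(rankPositions(gv), rankPositions(gv + 123))
  expect_error(selectAndRespond(gv, ph, 0.4, 0), "positive")
  expect_error(selectAndRespond(gv, ph, 0.4, 1000), "exceeds")
})

test_that("stage-wise and single-stage estimates agree on balanced data", {
  cfg <- smallCptConfig(7, rhoCol = 0, rhoRow = 0)
  sim <- simulateCpt(cfg)
  ker <- cptKernels(sim)
  ctrl <- sampleIds(sim$controls)
  s1 <- fitStage1All(sim$pheno, rhoRow = 0, rhoCol = 0)
  m <- s1$means[!s1$means$genotype_id %in% ctrl, ]
  s2 <- fitStage2(m, ker$Gstar, ker$Gd, computeBlup = FALSE)
  ss <- fitSingleStage(sim$pheno[!sim$pheno$genotype_id %in% ctrl, ],
                       ker$Gstar, ker$Gd, computeBlup = FALSE)
  relDiff <- function(a, b) abs(a - b) / pmax(abs(b), 1e-8)
  expect_lt(relDiff(s2$varComp["additive"], ss$varComp["additive"]), 0.10)
  expect_lt(relDiff(s2$varComp["dominance"], ss$varComp["dominance"]), 0.10)
})
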