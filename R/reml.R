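## Dense average-information REML with an EM-style fallback, supplied
## covariance kernels, separable AR1 x AR1 spatial residuals (correlation
## parameters profiled by bounded outer optimisation) and heterogeneous
## residual groups. Sized for desk-scale problems (n up to a few thousand):
## everything is dense and goes through one Cholesky of V per iteration.

#' First-order autoregressive correlation matrix
#'
#' Entry (i, j) equals \eqn{\rho^{|i-j|}}. The inverse is tridiagonal and
#' the log-determinant has the closed form \eqn{(n-1) \log(1-\rho^2)}.
#'
#' @param n dimension (>= 1).
#' @param rho autocorrelation, |rho| < 1.
#' @return n x n correlation matrix.
#' @examples
#' ar1Matrix(3, 0.5)
#' @export
ar1Matrix <- function(n, rho) {
  stopifnot(n >= 1)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  idx <- seq_len(n)
  rho^abs(outer(idx, idx, "-"))
}

#' @rdname ar1Matrix
#' @return \code{ar1LogDet}: the log-determinant \eqn{(n-1)\log(1-\rho^2)}.
#' @export
ar1LogDet <- function(n, rho) (n - 1) * log(1 - rho^2)

#' Separable AR1 x AR1 correlation between plot coordinates
#'
#' Correlation between observations at grid coordinates (row, col):
#' \eqn{\rho_c^{|c_i - c_j|} \rho_r^{|r_i - r_j|}}, i.e. the selection of an
#' AR1(col) Kronecker AR1(row) field at the observed plots (grids with
#' missing plots are handled naturally).
#'
#' @param row,col integer plot coordinates, one per observation.
#' @param rhoRow,rhoCol autocorrelations along rows and columns, |rho| < 1.
#' @return dense correlation matrix over observations.
#' @export
spatialAr1 <- function(row, col, rhoRow, rhoCol) {
  if (abs(rhoRow) >= 1 || abs(rhoCol) >= 1) stop("|rho| must be < 1")
  Dr <- abs(outer(row, row, "-"))
  Dc <- abs(outer(col, col, "-"))
  (rhoRow^Dr) * (rhoCol^Dc)
}

#' Random term specification for remlFit
#'
#' @param Z incidence matrix (n observations x q levels) with level names as
#'   colnames; a factor is expanded to its indicator matrix.
#' @param K optional q x q covariance kernel over the levels (symmetric PSD,
#'   e.g. a relationship matrix); identity when NULL.
#' @return term specification for \code{\link{remlFit}}.
#' @export
randomTerm <- function(Z, K = NULL) {
  if (is.factor(Z) || is.character(Z)) {
    f <- if (is.factor(Z)) Z else factor(Z)
    Zm <- matrix(0, length(f), nlevels(f),
                 dimnames = list(NULL, levels(f)))
    Zm[cbind(seq_along(f), as.integer(f))] <- 1
    Z <- Zm
  }
  if (is(K, "RelationshipMatrix")) K <- relValues(K)
  if (!is.null(K)) {
    stopifnot(ncol(Z) == nrow(K))
    if (!is.null(colnames(Z)) && !is.null(rownames(K)) &&
        !identical(colnames(Z), rownames(K)))
      K <- K[colnames(Z), colnames(Z)]
  }
  list(Z = Z, K = K)
}

#' Residual structures for remlFit
#'
#' \code{residualIid}: one iid residual variance. \code{residualByGroup}:
#' one residual variance per group level (block-diagonal heterogeneous
#' structure, e.g. per site). \code{residualAr1}: spatially correlated
#' residuals over plot coordinates with a separable AR1 x AR1 correlation;
#' when \code{rhoRow}/\code{rhoCol} are NULL they are profiled by an outer
#' bounded optimisation of the restricted likelihood.
#'
#' @return residual specification for \code{\link{remlFit}}.
#' @export
residualIid <- function() list(kind = "iid")

#' @rdname residualIid
#' @param groups factor (or coercible) of residual groups, one per
#'   observation.
#' @export
residualByGroup <- function(groups) list(kind = "group",
                                         groups = factor(groups))

#' @rdname residualIid
#' @param row,col plot coordinates per observation.
#' @param rhoRow,rhoCol fixed autocorrelations, or NULL to estimate.
#' @export
residualAr1 <- function(row, col, rhoRow = NULL, rhoCol = NULL)
  list(kind = "ar1", row = row, col = col, rhoRow = rhoRow, rhoCol = rhoCol)

## One restricted-likelihood state evaluation at variance vector theta.
.remlState <- function(theta, y, X, Mlist) {
  n <- length(y)
  V <- matrix(0, n, n)
  for (t in seq_along(Mlist)) V <- V + theta[t] * Mlist[[t]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    V <- V + diag(1e-8 * mean(diag(V)), n)
    ch <- chol(V)
  }
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e)
    stop("singular fixed-effect equations; confounded fixed term"))
  logdetX <- 2 * sum(log(diag(chx)))
  beta <- drop(chol2inv(chx) %*% crossprod(ViX, y))
  P <- Vi - ViX %*% chol2inv(chx) %*% t(ViX)
  Py <- drop(P %*% y)
  ll <- -0.5 * (logdetV + logdetX + sum(y * Py))
  list(ll = ll, P = P, Py = Py, beta = beta, Vi = Vi)
}

## AI-REML iteration loop over a linear covariance structure
## V = sum_t theta_t M_t. Guarantees a non-decreasing restricted
## log-likelihood via the EM-style fallback with step halving.
.remlCore <- function(y, X, Mlist, init = NULL, fixed = NULL,
                      tol = 1e-8, tolTheta = 1e-6, maxIter = 200L) {
  n <- length(y)
  nt <- length(Mlist)
  vy <- var(y)
  lower <- 1e-8 * vy
  theta <- if (is.null(init)) rep(vy / nt, nt) else pmax(init, lower)
  names(theta) <- names(Mlist)
  free <- if (is.null(fixed)) rep(TRUE, nt) else !fixed
  st <- .remlState(theta, y, X, Mlist)
  trace <- st$ll
  converged <- FALSE
  iter <- 0L
  AIfree <- NULL
  while (iter < maxIter && any(free)) {
    iter <- iter + 1L
    ## score and average information on the free components
    w <- lapply(Mlist, function(M) drop(M %*% st$Py))
    yPMPy <- vapply(w, function(wi) sum(wi * st$Py), 0)
    trPM <- vapply(Mlist, function(M) sum(st$P * M), 0)
    score <- -0.5 * (trPM - yPMPy)
    W <- do.call(cbind, w)
    AI <- 0.5 * crossprod(W, st$P %*% W)
    AIfree <- AI[free, free, drop = FALSE]
    delta <- tryCatch(
      solve(AIfree + diag(1e-10 * max(diag(AIfree)), sum(free)),
            score[free]),
      error = function(e) score[free] / (diag(AIfree) + 1e-12))
    cand <- theta
    cand[free] <- pmax(theta[free] + delta, lower)
    stCand <- .remlState(cand, y, X, Mlist)
    if (stCand$ll < st$ll - 1e-10) {
      ## EM-style multiplicative fallback with step halving; keeps the
      ## restricted log-likelihood non-decreasing
      em <- theta
      ratio <- ifelse(trPM > 0, yPMPy / trPM, 1)
      em[free] <- pmax(theta[free] * ratio[free], lower)
      s <- 1
      repeat {
        cand <- theta
        cand[free] <- pmax(theta[free] + s * (em[free] - theta[free]), lower)
        stCand <- .remlState(cand, y, X, Mlist)
        if (stCand$ll >= st$ll - 1e-10 || s < 1e-4) break
        s <- s / 2
      }
      if (stCand$ll < st$ll - 1e-10) { # stalled: keep current state
        converged <- TRUE
        break
      }
    }
    relTheta <- max(abs(cand - theta) / pmax(abs(theta), lower))
    relLl <- abs(stCand$ll - st$ll) / (1 + abs(st$ll))
    theta <- cand
    st <- stCand
    trace <- c(trace, st$ll)
    if (relLl < tol && relTheta < tolTheta) {
      converged <- TRUE
      break
    }
  }
  if (!any(free)) converged <- TRUE
  se <- rep(NA_real_, nt)
  if (!is.null(AIfree) && all(is.finite(AIfree))) {
    vc <- tryCatch(solve(AIfree), error = function(e) NULL)
    if (!is.null(vc)) se[free] <- sqrt(pmax(diag(vc), 0))
  }
  names(se) <- names(theta)
  list(theta = theta, se = se, state = st, loglik = st$ll,
       converged = converged, niter = iter, trace = trace, lower = lower)
}

#' Fit a linear mixed model by restricted maximum likelihood
#'
#' Average-information REML with an EM-style fallback for the variance
#' components of \eqn{y = X\beta + \sum_t Z_t u_t + e}, where each
#' \eqn{u_t \sim N(0, \sigma_t^2 K_t)} for a supplied (or identity) kernel
#' and the residual is iid, heterogeneous by group, or spatially correlated
#' with a separable AR1 x AR1 structure whose correlations are profiled.
#' Components are bounded below at \code{1e-8 * var(y)}; aliased columns of
#' X are dropped automatically. BLUEs/BLUPs solve the mixed-model equations
#' at the final components; per-level prediction error variances come from
#' \eqn{\mathrm{Var}(u - \hat u) = \sigma^2 K - \sigma^4 K Z' P Z K}.
#'
#' @param y numeric response vector.
#' @param X fixed-effect design matrix (an intercept-only matrix when NULL).
#' @param random named list of \code{\link{randomTerm}} specifications.
#' @param residual a \code{\link{residualIid}}, \code{\link{residualByGroup}}
#'   or \code{\link{residualAr1}} specification.
#' @param init optional named starting values for the variance components;
#'   default splits \code{var(y)} equally.
#' @param fixTheta optional named numeric vector of components to hold fixed
#'   at the given values (e.g. to evaluate BLUP/PEV at known variances).
#' @param tol relative restricted log-likelihood convergence tolerance
#'   (default 1e-8; combined with a relative component change below
#'   \code{tolTheta}).
#' @param tolTheta relative component-change tolerance (default 1e-6).
#' @param maxIter maximum iterations (default 200; non-convergence is
#'   flagged, last iterate returned).
#' @param computeBlup compute BLUPs and PEVs for every random term (default
#'   TRUE; skip for speed in large batch fits).
#' @return a \linkS4class{CptFit}.
#' @examples
#' set.seed(1)
#' g <- gl(5, 4)
#' y <- rnorm(5, sd = 2)[g] + rnorm(20)
#' fit <- remlFit(y, random = list(group = randomTerm(g)))
#' varComp(fit)
#' @export
remlFit <- function(y, X = NULL, random = list(), residual = residualIid(),
                    init = NULL, fixTheta = NULL, tol = 1e-8,
                    tolTheta = 1e-6, maxIter = 200L, computeBlup = TRUE) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  ## drop aliased fixed-effect columns
  qrX <- qr(X)
  dropped <- character(0)
  if (qrX$rank < ncol(X)) {
    keep <- qrX$pivot[seq_len(qrX$rank)]
    dropped <- colnames(X)[-keep]
    X <- X[, keep, drop = FALSE]
  }
  if (n <= ncol(X)) stop("need more observations than fixed-effect rank")
  if (length(random) && is.null(names(random)))
    names(random) <- paste0("term", seq_along(random))

  Mrand <- lapply(random, function(tm) {
    Z <- tm$Z
    stopifnot(nrow(Z) == n)
    if (is.null(tm$K)) tcrossprod(Z) else Z %*% tm$K %*% t(Z)
  })

  buildResid <- function(rhoRow = NULL, rhoCol = NULL) {
    switch(residual$kind,
      iid = list(residual = diag(n)),
      group = {
        f <- residual$groups
        ms <- lapply(levels(f), function(l) diag(as.numeric(f == l), n))
        names(ms) <- paste0("residual.", levels(f))
        ms
      },
      ar1 = list(residual = spatialAr1(residual$row, residual$col,
                                       rhoRow, rhoCol)),
      stop("unknown residual kind"))
  }

  initVec <- function(Mlist) {
    v <- rep(var(y) / length(Mlist), length(Mlist))
    names(v) <- names(Mlist)
    if (!is.null(init)) v[names(init)] <- init
    fixed <- rep(FALSE, length(Mlist))
    names(fixed) <- names(Mlist)
    if (!is.null(fixTheta)) {
      v[names(fixTheta)] <- fixTheta
      fixed[names(fixTheta)] <- TRUE
    }
    list(init = v, fixed = fixed)
  }

  profiled <- residual$kind == "ar1" &&
    (is.null(residual$rhoRow) || is.null(residual$rhoCol))
  rhoHat <- c(rhoRow = NA_real_, rhoCol = NA_real_)
  if (!profiled) {
    Mlist <- c(Mrand, buildResid(residual$rhoRow, residual$rhoCol))
    iv <- initVec(Mlist)
    core <- .remlCore(y, X, Mlist, init = iv$init, fixed = iv$fixed,
                      tol = tol, tolTheta = tolTheta, maxIter = maxIter)
    if (residual$kind == "ar1")
      rhoHat <- c(rhoRow = residual$rhoRow, rhoCol = residual$rhoCol)
  } else {
    ## profile the AR1 correlations: outer bounded search, inner variance
    ## updates warm-started between evaluations
    warm <- NULL
    bestCore <- NULL; bestRho <- c(0, 0); bestLl <- -Inf
    objective <- function(z) {
      rho <- 0.99 * tanh(z)
      Mlist <- c(Mrand, buildResid(rho[1], rho[2]))
      iv <- initVec(Mlist)
      if (!is.null(warm)) iv$init[] <- pmax(warm, 1e-10)
      core <- .remlCore(y, X, Mlist, init = iv$init, fixed = iv$fixed,
                        tol = max(tol, 1e-8), tolTheta = tolTheta,
                        maxIter = maxIter)
      warm <<- core$theta
      if (core$loglik > bestLl) {
        bestLl <<- core$loglik; bestCore <<- core; bestRho <<- rho
      }
      -core$loglik
    }
    opt <- optim(c(0, 0), objective, method = "Nelder-Mead",
                 control = list(reltol = 1e-7, maxit = 80))
    core <- bestCore
    rhoHat <- c(rhoRow = bestRho[1], rhoCol = bestRho[2])
  }

  beta <- core$state$beta
  names(beta) <- colnames(X)
  blup <- list(); pev <- list()
  if (computeBlup && length(random)) {
    P <- core$state$P
    Py <- core$state$Py
    for (tn in names(random)) {
      th <- core$theta[tn]
      Z <- random[[tn]]$Z
      K <- random[[tn]]$K
      if (is.null(K)) {
        ZtPy <- drop(crossprod(Z, Py))
        u <- th * ZtPy
        PZ <- P %*% Z
        pv <- th - th^2 * colSums(Z * PZ)
      } else {
        A <- K %*% t(Z)              # q x n
        u <- th * drop(A %*% Py)
        AP <- A %*% P
        pv <- th * diag(K) - th^2 * rowSums(AP * A)
      }
      names(u) <- colnames(Z)
      names(pv) <- colnames(Z)
      blup[[tn]] <- u
      pev[[tn]] <- pv
    }
  }
  new("CptFit", theta = core$theta, se = core$se, beta = beta,
      blup = blup, pev = pev, loglik = core$loglik,
      converged = core$converged, niter = as.integer(core$niter),
      details = list(rho = rhoHat, trace = core$trace,
                     droppedFixed = dropped, lowerBound = core$lower))
}

#' Accuracy and reliability from prediction error variance
#'
#' Accuracy of predicted genetic effects from the mean prediction error
#' variance: \eqn{r = \sqrt{1 - \overline{PEV}/\sigma^2}}. Per-level
#' reliability omits the square root: \eqn{r^2_l = 1 - PEV_l/\sigma^2}.
#' PEV values outside [0, sigma2] are clamped with a warning.
#'
#' @param pev prediction error variance(s); the mean is used for accuracy.
#' @param sigma2 the variance component of the term (> 0).
#' @return \code{pevToAccuracy}: scalar accuracy in [0, 1];
#'   \code{reliability}: per-level reliabilities in [0, 1].
#' @examples
#' pevToAccuracy(0.25, 1)   # 0.866
#' @export
pevToAccuracy <- function(pev, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  m <- mean(pev)
  if (m < 0 || m > sigma2) {
    warning("PEV outside [0, sigma2]; clamped")
    m <- min(max(m, 0), sigma2)
  }
  sqrt(1 - m / sigma2)
}

#' @rdname pevToAccuracy
#' @export
reliability <- function(pev, sigma2) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  pmin(pmax(1 - pev / sigma2, 0), 1)
}
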