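#' Individual tree volume from circumference and height
#'
#' Computes total stem volume with bark from circumference at breast height
#' (CBH, cm) and total height (TH, m), using a fixed stem-taper multiplier:
#' \deqn{VOL = \frac{CBH^2 \pi}{40000} \, TH \, ST}
#' The constant 40000 folds the cm-to-m unit conversion of the circumference
#' into the sectional-area term, and ST is a fixed form factor accounting for
#' stem taper.
#'
#' @param cbh circumference at breast height in cm (vectorised; NA allowed,
#'   e.g. dead trees).
#' @param th total height in m.
#' @param st stem taper, dimensionless in (0, 1]; default 0.45.
#' @param unit \code{"m3"} (default) or \code{"dm3"} (1 m3 = 1000 dm3).
#' @return numeric vector of volumes; NA where cbh or th is missing.
#' @examples
#' computeVolume(100, 30)            # 10.6029 m3
#' computeVolume(100, 30, unit = "dm3")
#' @export
computeVolume <- function(cbh, th, st = 0.45, unit = c("m3", "dm3")) {
  unit <- match.arg(unit)
  if (any(cbh < 0, na.rm = TRUE)) stop("cbh must be non-negative")
  if (any(th < 0, na.rm = TRUE)) stop("th must be non-negative")
  if (any(st <= 0) || any(st > 1)) stop("st must lie in (0, 1]")
  vol <- (cbh^2 * pi / 40000) * th * st
  if (unit == "dm3") vol <- vol * 1000
  vol
}

#' Standardize a trait to z-scores
#'
#' Centers and scales trait values: \eqn{z_i = (x_i - \mu_x) / \sigma_x},
#' where \eqn{\mu_x} and \eqn{\sigma_x} are the mean and standard deviation
#' of the raw values. The scale uses the sample (n-1) denominator. Missing
#' values are ignored for the center/scale and propagated in the output.
#'
#' @param x numeric vector, at least two non-missing values with non-zero
#'   dispersion.
#' @return list with \code{values} (z-scores), \code{center} and
#'   \code{scale}.
#' @examples
#' standardizeTrait(c(1, 2, 3))$values   # -1 0 1
#' @export
standardizeTrait <- function(x) {
  xx <- x[!is.na(x)]
  if (length(xx) < 2) stop("need at least two non-missing values")
  mu <- mean(xx)
  sdev <- sd(xx)
  if (sdev == 0) stop("trait has zero dispersion; cannot standardize")
  list(values = (x - mu) / sdev, center = mu, scale = sdev)
}

#' Derive volume columns for a phenotype table
#'
#' Augments a phenotype data frame holding \code{cbh_cm} and \code{th_m}
#' columns with \code{vol_m3}, \code{vol_dm3} and globally standardized
#' \code{vol_z} columns. Trees with a missing measurement (mortality) get
#' missing volumes and are excluded from the standardization statistics.
#'
#' @param pheno data.frame with columns \code{cbh_cm} and \code{th_m}.
#' @param st stem taper, default 0.45.
#' @param perSite if TRUE standardize within each level of a \code{site}
#'   column instead of globally (default FALSE: one global mean/sd).
#' @return the input data.frame with the three volume columns appended.
#' @export
addVolume <- function(pheno, st = 0.45, perSite = FALSE) {
  stopifnot(all(c("cbh_cm", "th_m") %in% names(pheno)))
  pheno$vol_m3 <- computeVolume(pheno$cbh_cm, pheno$th_m, st = st)
  pheno$vol_dm3 <- pheno$vol_m3 * 1000
  if (perSite) {
    stopifnot("site" %in% names(pheno))
    pheno$vol_z <- NA_real_
    for (s in unique(pheno$site)) {
      idx <- pheno$site == s
      pheno$vol_z[idx] <- standardizeTrait(pheno$vol_dm3[idx])$values
    }
  } else {
    pheno$vol_z <- standardizeTrait(pheno$vol_dm3)$values
  }
  pheno
}
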