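#' Quality-control thresholds
#'
#' Container for the marker/sample filtering thresholds and the accepted
#' Mendelian-error rate used in pedigree verification. Defaults: markers are
#' removed below a 95\% call rate or below 2\% minor allele frequency
#' (strict \code{<}: a MAF of exactly 0.02 is retained), samples below an
#' 80\% call rate, and a declared parent-offspring pair is flagged above a
#' 1\% opposing-homozygote rate.
#'
#' @param markerCallRateMin minimum marker call rate, default 0.95.
#' @param mafMin minimum minor allele frequency, default 0.02.
#' @param sampleCallRateMin minimum sample call rate, default 0.80.
#' @param mendelErrorMax maximum accepted per-pair Mendelian-error rate,
#'   default 0.01.
#' @return named list of thresholds (class \code{"qcThresholds"}).
#' @export
qcThresholds <- function(markerCallRateMin = 0.95, mafMin = 0.02,
                         sampleCallRateMin = 0.80, mendelErrorMax = 0.01) {
  t <- list(markerCallRateMin = markerCallRateMin, mafMin = mafMin,
            sampleCallRateMin = sampleCallRateMin,
            mendelErrorMax = mendelErrorMax)
  stopifnot(all(unlist(t) >= 0), all(unlist(t) <= 1))
  class(t) <- "qcThresholds"
  t
}

#' Intersect two genotyping panels
#'
#' Keeps the markers shared by two panels and harmonizes allele orientation:
#' if a shared marker is coded on opposite reference alleles (dosage d in one
#' panel, 2 - d in the other), panel B is re-coded to match panel A. The
#' orientation check compares allele frequencies in the two panels and flips
#' a marker when the swapped coding agrees better; markers whose frequencies
#' are uninformative (both near 0.5) are left as coded.
#'
#' @param panelA,panelB \linkS4class{GenotypeDosage} objects with comparable
#'   marker identifiers; samples are assumed disjoint (two platforms typing
#'   different trees).
#' @return a \linkS4class{GenotypeDosage} with all samples from both panels
#'   over the shared markers.
#' @export
intersectPanels <- function(panelA, panelB) {
  shared <- intersect(markerIds(panelA), markerIds(panelB))
  if (!length(shared)) stop("no shared markers between panels")
  A <- dosages(panelA)[, shared, drop = FALSE]
  B <- dosages(panelB)[, shared, drop = FALSE]
  pa <- colMeans(A, na.rm = TRUE) / 2
  pb <- colMeans(B, na.rm = TRUE) / 2
  flip <- !is.na(pa) & !is.na(pb) &
    (abs(pb - pa) > abs((1 - pb) - pa)) & (abs(pa - 0.5) > 0.01)
  if (any(flip)) B[, flip] <- 2 - B[, flip]
  genotypeDosage(rbind(A, B))
}

#' Filter markers and samples
#'
#' Applies the marker-level rules first -- optional exclusion list (e.g.
#' platform clustering quality), non-autosomal and duplicate-position rules
#' when marker metadata are available, call rate, then MAF -- and the sample
#' call-rate rule last, in that documented order. MAF is computed on
#' non-missing calls and folded to the minor allele.
#'
#' @param g a \linkS4class{GenotypeDosage}.
#' @param thresholds a \code{\link{qcThresholds}} object.
#' @param markerMeta optional data.frame with rownames = marker ids and
#'   optional columns \code{chrom} (autosome numbers; anything else is
#'   removed as non-autosomal) and \code{pos} (duplicate chrom+pos removed,
#'   keeping the first). Markers absent from the metadata pass these rules.
#' @param exclude optional character vector of marker ids to drop up front.
#' @return list with \code{genotypes} (filtered \code{GenotypeDosage}) and
#'   \code{report} (counts per rule).
#' @export
filterGenotypes <- function(g, thresholds = qcThresholds(),
                            markerMeta = NULL, exclude = NULL) {
  M <- dosages(g)
  report <- list(markersIn = ncol(M), samplesIn = nrow(M),
                 removedByRule = c(excluded = 0L, nonAutosomal = 0L,
                                   duplicatePosition = 0L, callRate = 0L,
                                   maf = 0L),
                 samplesRemoved = 0L)
  keep <- colnames(M)
  drop1 <- intersect(keep, exclude)
  report$removedByRule["excluded"] <- length(drop1)
  keep <- setdiff(keep, drop1)
  if (!is.null(markerMeta)) {
    mm <- markerMeta[intersect(keep, rownames(markerMeta)), , drop = FALSE]
    if ("chrom" %in% names(mm)) {
      bad <- rownames(mm)[is.na(suppressWarnings(as.integer(mm$chrom)))]
      report$removedByRule["nonAutosomal"] <- length(bad)
      keep <- setdiff(keep, bad)
      mm <- mm[setdiff(rownames(mm), bad), , drop = FALSE]
    }
    if (all(c("chrom", "pos") %in% names(mm))) {
      key <- paste(mm$chrom, mm$pos)
      bad <- rownames(mm)[duplicated(key)]
      report$removedByRule["duplicatePosition"] <- length(bad)
      keep <- setdiff(keep, bad)
    }
  }
  Mk <- M[, keep, drop = FALSE]
  cr <- colMeans(!is.na(Mk))
  bad <- keep[cr < thresholds$markerCallRateMin]
  report$removedByRule["callRate"] <- length(bad)
  keep <- setdiff(keep, bad)
  Mk <- M[, keep, drop = FALSE]
  p <- colMeans(Mk, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  bad <- keep[is.na(maf) | maf < thresholds$mafMin]
  report$removedByRule["maf"] <- length(bad)
  keep <- setdiff(keep, bad)
  if (!length(keep)) stop("all markers removed by quality control")
  Mk <- M[, keep, drop = FALSE]
  scr <- rowMeans(!is.na(Mk))
  sampleKeep <- scr >= thresholds$sampleCallRateMin
  report$samplesRemoved <- sum(!sampleKeep)
  Mk <- Mk[sampleKeep, , drop = FALSE]
  report$markersOut <- ncol(Mk)
  report$samplesOut <- nrow(Mk)
  pan <- markerPanel(g)
  if (length(pan)) {
    names(pan) <- markerIds(g)
    pan <- unname(pan[keep])
  }
  list(genotypes = genotypeDosage(Mk, panel = pan), report = report)
}

#' Mendelian-error (opposing-homozygote) rate of a pair
#'
#' Fraction of jointly non-missing markers at which two individuals are
#' opposing homozygotes (dosages 0 and 2). For a true parent-offspring pair
#' this is zero absent genotyping error, so an elevated rate flags either a
#' wrong pedigree link or poor genotyping.
#'
#' @param offspring,parent numeric dosage vectors over the same markers.
#' @return rate in [0, 1].
#' @export
mendelErrorRate <- function(offspring, parent) {
  if (length(offspring) != length(parent))
    stop("dosage vectors must cover the same markers")
  ok <- !is.na(offspring) & !is.na(parent)
  if (!any(ok)) stop("no jointly non-missing markers")
  opposing <- (offspring == 0 & parent == 2) | (offspring == 2 & parent == 0)
  sum(opposing[ok]) / sum(ok)
}

## ME rates of one offspring against a matrix of candidate parents (rows)
.mendelRates <- function(off, Cand) {
  offM <- matrix(off, nrow(Cand), length(off), byrow = TRUE)
  ok <- !is.na(offM) & !is.na(Cand)
  opp <- (offM == 0 & Cand == 2) | (offM == 2 & Cand == 0)
  opp[!ok] <- FALSE
  n <- rowSums(ok)
  ifelse(n > 0, rowSums(opp) / n, NA_real_)
}

#' Verify and correct a pedigree with genomic data
#'
#' Checks every declared parent-offspring pair by its opposing-homozygote
#' (Mendelian error) rate. Pairs above the accepted rate are flagged; for a
#' flagged or undeclared parent slot, the genotyped candidate parent with the
#' lowest ME rate is substituted if it passes the threshold, otherwise the
#' slot is set unknown. The search is an exhaustive scan over the supplied
#' candidates; ties are broken by the lowest candidate identifier. The
#' threshold is applied per pair.
#'
#' @param declared pedigree data.frame (id, sire, dam; "0" unknown).
#' @param g \linkS4class{GenotypeDosage} covering the individuals to test.
#' @param thresholds \code{\link{qcThresholds}} (uses
#'   \code{mendelErrorMax}).
#' @param candidates character vector of candidate parent ids (must be
#'   genotyped); default: all genotyped individuals declared as a parent of
#'   someone.
#' @param recoverUnknown also search parents for unknown ("0") slots of
#'   genotyped offspring (default TRUE).
#' @return list with \code{pedigree} (corrected) and \code{conflicts}
#'   (data.frame: offspring, slot, declared_parent, me_rate, action,
#'   new_parent, new_me_rate).
#' @export
verifyPedigree <- function(declared, g, thresholds = qcThresholds(),
                           candidates = NULL, recoverUnknown = TRUE) {
  ped <- data.frame(id = as.character(declared$id),
                    sire = as.character(declared$sire),
                    dam = as.character(declared$dam),
                    stringsAsFactors = FALSE)
  M <- dosages(g)
  gids <- rownames(M)
  if (is.null(candidates))
    candidates <- intersect(gids, setdiff(unique(c(ped$sire, ped$dam)), "0"))
  candidates <- sort(intersect(candidates, gids))
  Cand <- M[candidates, , drop = FALSE]
  conf <- list()
  thr <- thresholds$mendelErrorMax
  for (r in seq_len(nrow(ped))) {
    id <- ped$id[r]
    if (!id %in% gids) next
    off <- M[id, ]
    for (slot in c("sire", "dam")) {
      par <- ped[[slot]][r]
      other <- ped[[if (slot == "sire") "dam" else "sire"]][r]
      if (par != "0") {
        if (!par %in% gids) {
          warning("declared ", slot, " ", par, " of ", id,
                  " is not genotyped; pair skipped")
          conf[[length(conf) + 1L]] <- data.frame(
            offspring = id, slot = slot, declared_parent = par,
            me_rate = NA_real_, action = "skipped_ungenotyped",
            new_parent = par, new_me_rate = NA_real_)
          next
        }
        rate <- mendelErrorRate(off, M[par, ])
        if (rate <= thr) next
        ## flagged: search replacement
        cand <- setdiff(candidates, c(id, par, other))
        action <- "set_unknown"; newPar <- "0"; newRate <- NA_real_
        if (length(cand)) {
          rates <- .mendelRates(off, M[cand, , drop = FALSE])
          best <- which.min(rates)  # candidates sorted: lowest id wins ties
          if (!is.na(rates[best]) && rates[best] <= thr) {
            action <- "replaced"; newPar <- cand[best]
            newRate <- rates[best]
          }
        }
        ped[[slot]][r] <- newPar
        conf[[length(conf) + 1L]] <- data.frame(
          offspring = id, slot = slot, declared_parent = par,
          me_rate = rate, action = action, new_parent = newPar,
          new_me_rate = newRate)
      } else if (recoverUnknown) {
        cand <- setdiff(candidates, c(id, other))
        if (!length(cand)) next
        rates <- .mendelRates(off, M[cand, , drop = FALSE])
        best <- which.min(rates)
        if (!is.na(rates[best]) && rates[best] <= thr) {
          ped[[slot]][r] <- cand[best]
          conf[[length(conf) + 1L]] <- data.frame(
            offspring = id, slot = slot, declared_parent = "0",
            me_rate = NA_real_, action = "recovered",
            new_parent = cand[best], new_me_rate = rates[best])
        }
      }
    }
  }
  conflicts <- if (length(conf)) do.call(rbind, conf) else
    data.frame(offspring = character(0), slot = character(0),
               declared_parent = character(0), me_rate = numeric(0),
               action = character(0), new_parent = character(0),
               new_me_rate = numeric(0))
  list(pedigree = ped, conflicts = conflicts)
}
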