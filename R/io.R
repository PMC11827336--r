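## Readers/writers for the plain-text exchange formats and the end-to-end
## pipeline driver.

#' Write / read a dosage matrix
#'
#' Tab-delimited text, individuals in rows, markers in columns, \code{NA}
#' for missing calls; first column holds the individual identifier.
#'
#' @param g a \linkS4class{GenotypeDosage}.
#' @param path file path.
#' @export
writeDosage <- function(g, path) {
  M <- dosages(g)
  df <- data.frame(id = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname writeDosage
#' @return \code{readDosage}: a \linkS4class{GenotypeDosage}.
#' @export
readDosage <- function(path) {
  df <- read.delim(path, check.names = FALSE,
                   colClasses = list(id = "character"))
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) stop("malformed dosage matrix: non-numeric entries")
  rownames(M) <- df$id
  genotypeDosage(M)
}

#' Read genotypes from a VCF file
#'
#' Converts GT fields to alternate-allele dosages (0/1, 1|1, ./. -> 1, 2,
#' NA). Non-biallelic records are skipped with a message.
#'
#' @param path path to an (uncompressed or gzipped) VCF.
#' @return a \linkS4class{GenotypeDosage} (individuals x markers).
#' @export
readVcfDosage <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  biallelic <- !grepl(",", alt) & !is.na(alt) & alt != "."
  if (any(!biallelic))
    message(sum(!biallelic), " non-biallelic records skipped")
  v <- v[biallelic, ]
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- vcfR::getID(v)
  ids[is.na(ids)] <- paste0("var", which(is.na(ids)))
  count <- function(s) {
    a <- strsplit(s, "[/|]")
    vapply(a, function(x) {
      if (any(x == "." | is.na(x))) NA_real_ else sum(x != "0")
    }, 0)
  }
  M <- apply(gt, 2, count)
  if (is.null(dim(M))) M <- matrix(M, nrow = 1)
  M <- t(M)                     # individuals x markers
  colnames(M) <- ids
  genotypeDosage(M)
}

#' Write / read a phenotype table
#'
#' @param pheno phenotype data.frame.
#' @param path file path.
#' @export
writePhenotypes <- function(pheno, path)
  write.csv(pheno, path, row.names = FALSE, quote = FALSE)

#' @rdname writePhenotypes
#' @export
readPhenotypes <- function(path)
  read.csv(path, stringsAsFactors = FALSE)

#' Write / read a pedigree (id, sire, dam; "0" = unknown)
#'
#' @param ped pedigree data.frame.
#' @param path file path.
#' @export
writePedigree <- function(ped, path)
  write.csv(ped[, c("id", "sire", "dam")], path, row.names = FALSE,
            quote = FALSE)

#' @rdname writePedigree
#' @export
readPedigree <- function(path)
  read.csv(path, colClasses = "character")

#' Run the cloned-progeny-trial evaluation pipeline
#'
#' Executes simulate -> qc -> grm -> stage1 -> stage2 -> parameters ->
#' replication (any prefix selectable) on a simulated population and writes
#' the module outputs plus a run manifest (config hash, seed, package
#' version, per-stage wall time and record counts) to \code{outDir}.
#'
#' @param config a \code{\link{cptConfig}}.
#' @param outDir output directory (created if needed); NULL to skip writing.
#' @param stages stages to run (a prefix of the full list).
#' @param alpha blending weight for the additive kernel (default 0.98).
#' @param nSelect selection size for the response to selection (default 30).
#' @param topN selection sizes for the replication study.
#' @param qcEnabled apply marker/sample filters (default TRUE).
#' @param estimateRho profile the stage-one spatial correlations (default
#'   TRUE; FALSE fixes them at zero).
#' @param ... passed to the model-fitting functions.
#' @return (invisibly) a list with the outputs of every executed stage.
#' @export
runCptPipeline <- function(config = cptConfig(), outDir = NULL,
                           stages = c("simulate", "qc", "grm", "stage1",
                                      "stage2", "parameters",
                                      "replication"),
                           alpha = 0.98, nSelect = 30,
                           topN = c(10, 20, 30), qcEnabled = TRUE,
                           estimateRho = TRUE, ...) {
  allStages <- c("simulate", "qc", "grm", "stage1", "stage2", "parameters",
                 "replication")
  stages <- match.arg(stages, allStages, several.ok = TRUE)
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  res <- list(config = config)
  manifest <- list(seed = config$seed,
                   package = as.character(utils::packageVersion("cptEval")),
                   stages = list())
  tmp <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), tmp, auto_unbox = TRUE, digits = NA)
  manifest$configHash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  tick <- function(stage, expr) {
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[stage]] <<- list(
      seconds = as.numeric(difftime(Sys.time(), t0, units = "secs")))
    out
  }

  if ("simulate" %in% stages) {
    res$sim <- tick("simulate", simulateCpt(config))
    manifest$stages$simulate$nTrees <- nrow(res$sim$pheno)
    if (!is.null(outDir)) {
      writePhenotypes(res$sim$pheno, file.path(outDir, "phenotypes.csv"))
      writePedigree(res$sim$declared, file.path(outDir, "pedigree.csv"))
      writeDosage(res$sim$observed, file.path(outDir, "dosages.tsv"))
      jsonlite::write_json(
        list(trueVariances = as.list(config$trueVariances)),
        file.path(outDir, "truth.json"), auto_unbox = TRUE, digits = NA)
    }
  }
  if ("qc" %in% stages) {
    res$qc <- tick("qc", {
      g <- res$sim$observed
      out <- if (qcEnabled) filterGenotypes(g) else
        list(genotypes = g, report = list(skipped = TRUE))
      ver <- verifyPedigree(res$sim$declared, out$genotypes,
                            candidates = sampleIds(res$sim$founders))
      list(genotypes = out$genotypes, report = out$report,
           pedigree = ver$pedigree, conflicts = ver$conflicts)
    })
    if (!is.null(outDir)) {
      jsonlite::write_json(res$qc$report, file.path(outDir,
                                                    "qc_report.json"),
                           auto_unbox = TRUE, digits = NA)
      write.csv(res$qc$conflicts, file.path(outDir, "conflicts.csv"),
                row.names = FALSE)
    }
  }
  if ("grm" %in% stages) {
    res$grm <- tick("grm", {
      gids <- intersect(res$sim$usedGenotypes,
                        sampleIds(res$qc$genotypes))
      gsub <- res$qc$genotypes[gids, ]
      ped <- rbind(res$qc$pedigree,
                   data.frame(id = sampleIds(res$sim$controls), sire = "0",
                              dam = "0"))
      A <- numeratorA(ped)
      A22 <- a22Matrix(A, gids)
      Ga <- grmAdditive(gsub)
      Gd <- grmDominance(gsub)
      list(Gstar = blendGrm(Ga, A22, alpha = alpha), Gd = Gd, A = A)
    })
  }
  if ("stage1" %in% stages) {
    res$stage1 <- tick("stage1", fitStage1All(
      res$sim$pheno,
      rhoRow = if (estimateRho) NULL else 0,
      rhoCol = if (estimateRho) NULL else 0, ...))
    if (!is.null(outDir))
      write.csv(res$stage1$means, file.path(outDir, "adjusted_means.csv"),
                row.names = FALSE)
  }
  if ("stage2" %in% stages) {
    res$stage2 <- tick("stage2", {
      m <- res$stage1$means
      m <- m[!m$genotype_id %in% sampleIds(res$sim$controls), ,
             drop = FALSE]
      fitStage2(m, res$grm$Gstar, res$grm$Gd, ...)
    })
  }
  if ("parameters" %in% stages) {
    res$parameters <- tick("parameters", {
      pars <- summarizeParameters(res$stage2$varComp, res$stage2$fit)
      m <- res$stage1$means
      phenoMean <- tapply(m$mean, m$genotype_id, mean)
      gv <- res$stage2$gv
      sel <- selectAndRespond(gv, phenoMean[names(gv)], pars$H2,
                              min(nSelect, length(gv)))
      list(parameters = pars, selection = sel)
    })
    if (!is.null(outDir)) {
      p <- res$parameters$parameters
      s <- res$parameters$selection
      jsonlite::write_json(
        list(varComp = as.list(res$stage2$varComp), sigmaP2 = p$sigmaP2,
             h2a = p$h2a, delta2 = p$delta2, H2 = p$H2,
             shares = as.list(p$shares),
             accuracyAdditive = p$accuracyAdditive,
             accuracyDominance = p$accuracyDominance,
             x0 = s$x0, xs = s$xs, S = s$S, deltaR = s$deltaR,
             responsePct = s$responsePct),
        file.path(outDir, "parameters.json"), auto_unbox = TRUE,
        digits = NA)
      rk <- res$parameters$selection$ranking
      write.csv(data.frame(genotype_id = names(sort(rk)),
                           position = sort(rk),
                           gv = res$stage2$gv[names(sort(rk))]),
                file.path(outDir, "ranking.csv"), row.names = FALSE)
    }
  }
  if ("replication" %in% stages) {
    res$replication <- tick("replication", replicationStudy(
      res$sim$pheno[!res$sim$pheno$genotype_id %in%
                    sampleIds(res$sim$controls), ],
      res$grm$Gstar, res$grm$Gd, topN = topN, ...))
    if (!is.null(outDir))
      write.csv(res$replication$summary,
                file.path(outDir, "replication_summary.csv"),
                row.names = FALSE)
  }
  if (!is.null(outDir))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  res$manifest <- manifest
  invisible(res)
}
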