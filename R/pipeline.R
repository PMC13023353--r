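## End-to-end orchestration: filter -> PCA -> association -> inflation ->
## thresholding -> LD decay & sufficiency -> windows -> segregation ->
## system call -> gene assignment -> DEG overlap -> InDel screen ->
## validation.

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

.banner <- function(...) message("[SexLinkScan] ", ...)

#' Run the full sex-linked marker discovery pipeline
#'
#' Executes, in order: hard filter, site filter, genotype PCA and
#' eigenvalue > 1 covariate selection, per-variant GLM association with
#' genomic inflation, significance thresholding, LD decay and marker
#' sufficiency, lead-SNP candidate windows, pooled zygosity segregation and
#' the sex-system call, interval-based gene assignment, the
#' differential-expression stage with GWAS overlap, the sex-linked InDel
#' marker screen, and (when validation cohorts are supplied) marker
#' validation. Every intermediate table is written to `outDir` as TSV along
#' with a run log and a human-readable report; an empty significant set
#' short-circuits the downstream stages with an explicit no-signal report.
#'
#' @param vcf Path to a VCF file, or a [GenotypeData-class] object.
#' @param phenotypes Path to a phenotype TSV or a
#'   `data.frame(sample_id, sex)`.
#' @param geneTable Optional gene-interval table (path or `data.frame`
#'   with `chrom`, `start`, `end`, `gene_id`).
#' @param exprCounts,exprGroup Optional expression count matrix and its
#'   testis/ovary group factor; alternatively supply `degTable`.
#' @param degTable Optional precomputed DEG table (`gene_id`, `log2fc`,
#'   `p`).
#' @param outDir Output directory (created if absent).
#' @param thresholdMode,alpha,fixedP Passed to [applyThreshold()].
#' @param ldBinSize,ldMaxDist Passed to [ldDecayCurve()].
#' @param flank Window flank in bp; `NULL` uses the computed LD half-decay
#'   distance (falling back to 5844 bp when the curve never halves).
#' @param tHet,tHom Passed to [callSexSystem()].
#' @param minLengthDiff,minConcordance Passed to [screenSexIndels()].
#' @param validationPopulations Optional named list of
#'   [GenotypeData-class] cohorts for [validateMarker()].
#' @param genomeSize Genome size in bp for [markerSufficiency()]; defaults
#'   to the sum of known chromosome lengths.
#' @param seed Seed recorded in the run log (the scan itself is
#'   deterministic).
#' @return A list with every stage result (`filtered`, `pca`, `assoc`,
#'   `lambda`, `ld`, `sufficiency`, `windows`, `segregation`, `system_call`,
#'   `candidate_genes`, `degs`, `overlap`, `indel_candidates`,
#'   `validation`).
#' @export
runSexPipeline <- function(vcf, phenotypes, geneTable = NULL,
                           exprCounts = NULL, exprGroup = NULL,
                           degTable = NULL, outDir = tempfile("sexscan"),
                           thresholdMode = "suggestive", alpha = 0.05,
                           fixedP = NULL, ldBinSize = 100,
                           ldMaxDist = 3e5, flank = NULL, tHet = 0.7,
                           tHom = 0.7, minLengthDiff = 8L,
                           minConcordance = 0.9,
                           validationPopulations = NULL,
                           genomeSize = NULL, seed = 1L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, f) write.table(x, file.path(outDir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  log <- c(sprintf("SexLinkScan %s",
                   as.character(utils::packageVersion("SexLinkScan"))),
           sprintf("seed: %d", seed),
           sprintf("threshold: %s (alpha=%g)", thresholdMode, alpha))

  gd <- .stage("input", {
    g <- if (is.character(vcf)) readVCF(vcf) else vcf
    if (nrow(g) == 0) stop("VCF contains zero variants")
    ph <- if (is.character(phenotypes)) readPhenotypeTable(phenotypes)
          else phenotypes
    sampleSex(g) <- ph$sex[match(colnames(g), ph$sample_id)]
    g
  })
  .banner("input: ", nrow(gd), " variants, ", ncol(gd), " samples")

  gd <- .stage("hard_filter", {
    keep <- hardFilter(gd)
    gd[which(keep), ]
  })
  .banner("hard filter: ", nrow(gd), " variants pass")
  gd <- .stage("site_filter", siteFilter(gd))
  .banner("site filter: ", nrow(gd), " variants retained")
  if (nrow(gd) == 0)
    .stage("site_filter", stop("no variants survive filtering"))
  log <- c(log, sprintf("variants after filtering: %d", nrow(gd)))

  pca <- .stage("pca", genotypePCA(gd))
  covs <- .stage("pca", suppressWarnings(selectCovariates(pca)))
  .banner("PCA: ", ncol(covs), " covariates (eigenvalue > 1)")
  writeCovariates(covs, file.path(outDir, "covariates.tsv"))

  res <- .stage("association", glmAssociation(gd, covariates = covs))
  lambda <- .stage("association", genomicInflation(res$p))
  .banner(sprintf("association: %d tested, lambda = %.3f",
                  sum(res$tested), lambda))
  res <- .stage("threshold",
                applyThreshold(res, mode = thresholdMode, alpha = alpha,
                               fixedP = fixedP))
  tsv(res, "association.tsv")
  exportScan(res, file.path(outDir, "manhattan.tsv"),
             file.path(outDir, "qq.tsv"))
  nSig <- sum(res$significant)
  log <- c(log, sprintf("lambda: %.4f", lambda),
           sprintf("significant variants: %d (threshold %.3g)", nSig,
                   attr(res, "threshold")))

  ld <- .stage("ld_decay", ldDecayCurve(gd, maxDist = ldMaxDist,
                                        binSize = ldBinSize))
  tsv(ld@curve, "ld_decay.tsv")
  sl <- GenomeInfoDb::seqlengths(rowRanges(gd))
  if (is.null(genomeSize)) genomeSize <- sum(as.numeric(sl), na.rm = TRUE)
  suff <- if (!is.na(ld@halfDecayDist) && genomeSize >= ld@halfDecayDist)
    .stage("ld_decay", markerSufficiency(genomeSize, ld@halfDecayDist))
  else NULL
  .banner("LD: half-decay ", ld@halfDecayDist, " bp",
          if (!is.null(suff)) paste0("; ", suff$n_required,
                                     " markers needed") else "")

  if (nSig == 0) {
    .banner("no significant variants: downstream stages skipped")
    writeLines(c(log, "NO SIGNAL: no variant reached the threshold; ",
                 "windows, segregation, system call, gene assignment and ",
                 "marker screen were skipped."),
               file.path(outDir, "report.txt"))
    return(list(filtered = gd, pca = pca, assoc = res, lambda = lambda,
                ld = ld, sufficiency = suff, windows = NULL,
                segregation = NULL, system_call = NULL,
                candidate_genes = NULL, degs = NULL, overlap = NULL,
                indel_candidates = NULL, validation = NULL))
  }

  if (is.null(flank))
    flank <- if (is.na(ld@halfDecayDist)) 5844 else ld@halfDecayDist
  windows <- .stage("windows",
                    extractLeadWindows(res, flank = flank,
                                       chromLengths = sl))
  tsv(windows, "windows.tsv")
  .banner("windows: ", nrow(windows), " clusters, flank ", flank, " bp")

  seg <- .stage("segregation", zygositySummary(gd[res$significant, ]))
  sysCall <- .stage("segregation", callSexSystem(seg, tHet, tHom))
  writeSegregationReport(seg, sysCall,
                         file.path(outDir, "segregation.tsv"),
                         file.path(outDir, "sex_system.txt"))
  .banner("sex system: ", sysCall@system)
  log <- c(log,
           sprintf("p_het_male: %.4f  p_hom_female: %.4f",
                   seg@pHetMale, seg@pHomFemale),
           sprintf("sex system: %s", sysCall@system))

  candGenes <- NULL
  if (!is.null(geneTable)) {
    gt <- if (is.character(geneTable)) readGeneTable(geneTable)
          else geneTable
    candGenes <- .stage("gene_assignment", genesInWindows(windows, gt))
    tsv(candGenes, "candidate_genes.tsv")
    .banner("candidate genes: ", nrow(candGenes))
  }

  degs <- NULL
  if (!is.null(exprCounts)) {
    de <- .stage("expression", deTest(exprCounts, exprGroup))
    degs <- .stage("expression", filterDEGs(de))
    tsv(degs$records, "deg.tsv")
    .banner("DEGs: ", degs$n_deg, " (", degs$n_testis, " testis / ",
            degs$n_ovary, " ovary)")
  } else if (!is.null(degTable)) {
    de <- if (is.character(degTable))
      read.table(degTable, header = TRUE, sep = "\t",
                 stringsAsFactors = FALSE) else degTable
    degs <- .stage("expression", filterDEGs(de))
    tsv(degs$records, "deg.tsv")
  }

  overlap <- NULL
  if (!is.null(candGenes) && !is.null(degs)) {
    overlap <- .stage("overlap", overlapCandidates(candGenes,
                                                   degs$records))
    tsv(overlap, "overlap.tsv")
    .banner("GWAS x DEG overlap: ", nrow(overlap), " genes")
  }

  indels <- .stage("marker_screen",
                   screenSexIndels(gd, minLengthDiff = minLengthDiff,
                                   minConcordance = minConcordance))
  tsv(indels, "indel_candidates.tsv")
  .banner("InDel marker candidates: ", nrow(indels))

  validation <- NULL
  if (!is.null(validationPopulations) && nrow(indels) > 0) {
    validation <- .stage("validation",
                         validateMarker(indels[1, ],
                                        validationPopulations))
    tsv(validation, "validation.tsv")
  }

  writeLines(log, file.path(outDir, "run_log.txt"))
  report <- c(log, "",
              sprintf("LD half-decay: %s bp (max mean r2 %.3f)",
                      format(ld@halfDecayDist), ld@maxR2),
              if (!is.null(suff))
                sprintf("Markers needed at half-decay spacing: %d",
                        suff$n_required),
              sprintf("Lead windows: %d", nrow(windows)),
              if (!is.null(candGenes))
                sprintf("Candidate genes in windows: %d", nrow(candGenes)),
              if (!is.null(overlap))
                sprintf("GWAS x DEG overlapping genes: %d", nrow(overlap)),
              sprintf("InDel marker candidates: %d", nrow(indels)))
  writeLines(report, file.path(outDir, "report.txt"))

  list(filtered = gd, pca = pca, assoc = res, lambda = lambda, ld = ld,
       sufficiency = suff, windows = windows, segregation = seg,
       system_call = sysCall, candidate_genes = candGenes, degs = degs,
       overlap = overlap, indel_candidates = indels,
       validation = validation)
}
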