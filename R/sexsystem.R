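## Pooled zygosity classification at significant loci and the
## sex-determination system call.

#' Pooled zygosity summary at a set of loci
#'
#' Every non-missing genotype call at the given loci is classified
#' heterozygous (dosage 1) or homozygous (dosage 0 or 2) and pooled over
#' all locus x individual calls by sex; missing calls are excluded from all
#' denominators. Pooling at the call level (rather than per-locus
#' majorities) is what makes `nCalls = n_loci x n_individuals` on a
#' zero-missingness matrix.
#'
#' @param gd A [GenotypeData-class] object with sample sexes, subset to the
#'   loci of interest (e.g. `gd[res$significant, ]`).
#' @return A [SegregationSummary-class] object.
#' @export
zygositySummary <- function(gd) {
  if (nrow(gd) < 1) stop("need at least one locus")
  sx <- sampleSex(gd)
  if (!all(c("F", "M") %in% sx)) stop("both sexes must be present")
  d <- dosage(gd)
  if (all(is.na(d))) stop("no non-missing genotype calls")
  isM <- which(sx == "M"); isF <- which(sx == "F")
  het <- d == 1L
  hom <- d == 0L | d == 2L
  cnt <- function(m, cols) as.integer(sum(m[, cols, drop = FALSE],
                                          na.rm = TRUE))
  hetM <- cnt(het, isM); homM <- cnt(hom, isM)
  hetF <- cnt(het, isF); homF <- cnt(hom, isF)
  perLocus <- data.frame(
    variant_id = variantInfo(gd)$variant_id,
    het_male = rowSums(het[, isM, drop = FALSE], na.rm = TRUE),
    hom_male = rowSums(hom[, isM, drop = FALSE], na.rm = TRUE),
    het_female = rowSums(het[, isF, drop = FALSE], na.rm = TRUE),
    hom_female = rowSums(hom[, isF, drop = FALSE], na.rm = TRUE),
    stringsAsFactors = FALSE)
  new("SegregationSummary",
      nLoci = nrow(gd), nCalls = hetM + homM + hetF + homF,
      hetMale = hetM, homMale = homM, hetFemale = hetF, homFemale = homF,
      pHetMale = hetM / (hetM + homM), pHomMale = homM / (hetM + homM),
      pHetFemale = hetF / (hetF + homF),
      pHomFemale = homF / (hetF + homF),
      perLocus = perLocus)
}

#' Call the sex-determination system from a segregation summary
#'
#' XY (male-heterogametic) requires the pooled male heterozygote proportion
#' to reach `tHet` and the pooled female homozygote proportion to reach
#' `tHom`; ZW is the mirror image; anything else is undetermined. With
#' thresholds above 0.5 the two rules cannot both fire. The defaults (0.7)
#' sit comfortably above the autosomal expectation (about 0.5) while
#' tolerating realistic genotyping error.
#'
#' @param summary A [SegregationSummary-class] object.
#' @param tHet,tHom Decision thresholds in (0.5, 1].
#' @return A [SexSystemCall-class] object.
#' @export
callSexSystem <- function(summary, tHet = 0.7, tHom = 0.7) {
  stopifnot(tHet > 0.5, tHet <= 1, tHom > 0.5, tHom <= 1)
  xy <- summary@pHetMale >= tHet && summary@pHomFemale >= tHom
  zw <- summary@pHetFemale >= tHet && summary@pHomMale >= tHom
  if (xy && !zw) {
    system <- "XY"
    support <- c(p_het_male = summary@pHetMale,
                 p_hom_female = summary@pHomFemale)
  } else if (zw && !xy) {
    system <- "ZW"
    support <- c(p_het_female = summary@pHetFemale,
                 p_hom_male = summary@pHomMale)
  } else {
    system <- "undetermined"
    support <- c(p_het_male = summary@pHetMale,
                 p_hom_female = summary@pHomFemale,
                 p_het_female = summary@pHetFemale,
                 p_hom_male = summary@pHomMale)
  }
  new("SexSystemCall", system = system, support = support,
      thresholds = c(t_het = tHet, t_hom = tHom))
}

#' Write the segregation summary and system call as a report
#'
#' @param summary A [SegregationSummary-class] object.
#' @param call A [SexSystemCall-class] object.
#' @param tsvPath,txtPath Output paths for the per-locus TSV and the
#'   human-readable text block.
#' @export
writeSegregationReport <- function(summary, call, tsvPath, txtPath) {
  write.table(summary@perLocus, tsvPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  txt <- c(
    sprintf("Loci: %d   Non-missing calls: %d", summary@nLoci,
            summary@nCalls),
    sprintf("Male heterozygous:  %.2f%%", 100 * summary@pHetMale),
    sprintf("Female homozygous:  %.2f%%", 100 * summary@pHomFemale),
    sprintf("Female heterozygous: %.2f%%", 100 * summary@pHetFemale),
    sprintf("Male homozygous:    %.2f%%", 100 * summary@pHomMale),
    sprintf("Thresholds: t_het = %.2f, t_hom = %.2f",
            call@thresholds[["t_het"]], call@thresholds[["t_hom"]]),
    sprintf("Sex-determination system: %s", call@system))
  writeLines(txt, txtPath)
  invisible(txtPath)
}
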