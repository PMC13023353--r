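#' @importClassesFrom SummarizedExperiment RangedSummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   rowRanges colData
#' @importFrom SummarizedExperiment "rowRanges<-" "colData<-"
#' @importFrom S4Vectors DataFrame mcols metadata
#' @importFrom S4Vectors "mcols<-" "metadata<-"
#' @importFrom GenomicRanges GRanges seqnames start end findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlengths
NULL

## ---------------------------------------------------------------------------
## GenotypeData: the central container
## ---------------------------------------------------------------------------

#' GenotypeData: a population genotype matrix with variant and sample metadata
#'
#' `GenotypeData` extends `RangedSummarizedExperiment`. Rows are variants
#' (a `GRanges` whose metadata columns carry `variant_id`, `ref`, `alt`,
#' `vtype` and, when present, the site-quality annotations `QD`, `FS`, `MQ`,
#' `SOR`, `ReadPosRankSum`, `MQRankSum`), columns are samples. The `"dosage"`
#' assay holds alternate-allele dosages 0/1/2 with `NA` for missing calls; an
#' optional `"depth"` assay holds per-call read depth. Sample sex (`"F"`/`"M"`)
#' lives in `colData(x)$sex`.
#'
#' @aliases GenotypeData-class
#' @export
setClass("GenotypeData", contains = "RangedSummarizedExperiment")

setValidity("GenotypeData", function(object) {
  msg <- NULL
  if (!("dosage" %in% assayNames(object)))
    msg <- c(msg, "assay 'dosage' is required")
  else {
    d <- assay(object, "dosage")
    bad <- d[!is.na(d)]
    if (length(bad) && !all(bad %in% 0:2))
      msg <- c(msg, "dosages must be 0, 1, 2 or NA")
  }
  mc <- mcols(rowRanges(object))
  need <- c("variant_id", "ref", "alt", "vtype")
  miss <- setdiff(need, colnames(mc))
  if (length(miss))
    msg <- c(msg, paste0("rowRanges metadata must contain: ",
                         paste(miss, collapse = ", ")))
  else {
    if (anyDuplicated(mc$variant_id))
      msg <- c(msg, "variant ids must be unique")
    if (!all(mc$vtype %in% c("SNP", "InDel")))
      msg <- c(msg, "vtype must be 'SNP' or 'InDel'")
  }
  if (anyDuplicated(colnames(object)))
    msg <- c(msg, "sample ids must be unique")
  if ("sex" %in% colnames(colData(object))) {
    sx <- colData(object)$sex
    if (!all(is.na(sx) | sx %in% c("F", "M")))
      msg <- c(msg, "sex must be 'F', 'M' or NA")
  }
  if (is.null(msg)) TRUE else msg
})

#' Construct a GenotypeData object
#'
#' @param dosage Integer matrix, variants x samples, values 0/1/2/`NA`.
#' @param variants `GRanges` (one range per variant, 1-based start = POS,
#'   width = `nchar(ref)`) with metadata columns `variant_id`, `ref`, `alt`,
#'   `vtype`; quality annotations `QD`, `FS`, `MQ`, `SOR`, `ReadPosRankSum`,
#'   `MQRankSum` are optional.
#' @param sex Optional character/factor of `"F"`/`"M"` per sample.
#' @param depth Optional numeric matrix of per-call read depths, same shape
#'   as `dosage`.
#' @return A [GenotypeData-class] object.
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(10, 20), width = 1),
#'   variant_id = c("v1", "v2"), ref = c("A", "C"), alt = c("G", "T"),
#'   vtype = c("SNP", "SNP"))
#' gd <- GenotypeData(matrix(c(0L, 1L, 2L, 1L), 2,
#'   dimnames = list(c("v1", "v2"), c("s1", "s2"))), gr, sex = c("F", "M"))
#' dosage(gd)
#' @export
GenotypeData <- function(dosage, variants, sex = NULL, depth = NULL) {
  if (!is.matrix(dosage))
    stop("'dosage' must be a matrix")
  storage.mode(dosage) <- "integer"
  rownames(dosage) <- mcols(variants)$variant_id
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("S", seq_len(ncol(dosage)))
  assays <- list(dosage = dosage)
  if (!is.null(depth)) {
    dimnames(depth) <- dimnames(dosage)
    assays$depth <- depth
  }
  cd <- DataFrame(row.names = colnames(dosage))
  if (!is.null(sex))
    cd$sex <- factor(as.character(sex), levels = c("F", "M"))
  names(variants) <- mcols(variants)$variant_id
  se <- SummarizedExperiment(assays = assays, rowRanges = variants,
                             colData = cd)
  new("GenotypeData", se)
}

#' @rdname dosage
#' @export
setMethod("dosage", "GenotypeData", function(x) assay(x, "dosage"))

#' @rdname depthMatrix
#' @export
setMethod("depthMatrix", "GenotypeData", function(x) {
  if ("depth" %in% assayNames(x)) assay(x, "depth") else NULL
})

#' @rdname sampleSex
#' @export
setMethod("sampleSex", "GenotypeData", function(x) {
  if ("sex" %in% colnames(colData(x))) colData(x)$sex
  else factor(rep(NA_character_, ncol(x)), levels = c("F", "M"))
})

#' @rdname sampleSex-set
#' @name sampleSex<-
#' @aliases sampleSex<-,GenotypeData-method
#' @export
setReplaceMethod("sampleSex", "GenotypeData", function(x, value) {
  colData(x)$sex <- factor(as.character(value), levels = c("F", "M"))
  validObject(x)
  x
})

#' @rdname variantInfo
#' @export
setMethod("variantInfo", "GenotypeData", function(x) {
  gr <- rowRanges(x)
  df <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                   as.data.frame(mcols(gr)), stringsAsFactors = FALSE,
                   row.names = NULL)
  df
})

#' @rdname variantType
#' @export
setMethod("variantType", "GenotypeData", function(x)
  mcols(rowRanges(x))$vtype)

setMethod("show", "GenotypeData", function(object) {
  sx <- table(sampleSex(object))
  cat("GenotypeData:", nrow(object), "variants x", ncol(object), "samples\n")
  cat("  types:", sum(variantType(object) == "SNP"), "SNP,",
      sum(variantType(object) == "InDel"), "InDel\n")
  cat("  sex: ", sx[["F"]], " F / ", sx[["M"]], " M\n", sep = "")
  cat("  missing calls:",
      sprintf("%.2f%%", 100 * mean(is.na(dosage(object)))), "\n")
})

## ---------------------------------------------------------------------------
## Simulation parameters
## ---------------------------------------------------------------------------

#' Simulation parameters for a sex-linked population
#'
#' Holds every knob of the forward simulator: population composition,
#' chromosome layout, the sex-determining region (SDR), variant counts,
#' the recombination model that makes sex linkage decay with distance from
#' the SDR midpoint, genotyping noise, site-annotation failures, and the
#' negative-binomial gonadal expression model. See [simulatePopulation()].
#'
#' @slot nMales,nFemales Individuals per sex.
#' @slot nChromosomes Number of chromosomes.
#' @slot chromLength Chromosome length in bp (common to all chromosomes).
#' @slot sdSystem `"XY"` (male-heterogametic) or `"ZW"` (female-heterogametic).
#' @slot sdrChrom Index of the chromosome carrying the SDR.
#' @slot sdrInterval 1-based inclusive bp interval of the SDR.
#' @slot nSnps,nIndels Variant counts across the genome.
#' @slot indelLengthRange Min/max allele length difference (bp) for InDels.
#' @slot mafBetaParams Beta shape parameters for autosomal alt-allele
#'   frequencies.
#' @slot recombRatePerBp Per-bp recombination probability; the sex-linked
#'   allele is retained at distance D from the SDR midpoint with probability
#'   (1 - r)^D.
#' @slot genotypingErrorRate Per-call probability of a one-step dosage error.
#' @slot missingRate Per-call probability of a missing genotype.
#' @slot annotationFailFraction Fraction of sites given hard-filter-failing
#'   quality annotations.
#' @slot exprNGenes,exprNSexBiased Gene counts for the expression simulator.
#' @slot exprLog2fc Absolute log2 fold change planted in sex-biased genes.
#' @slot exprDispersion Negative-binomial dispersion (size = 1/dispersion).
#' @slot exprLibsize Expected sequencing depth (total counts) per sample.
#' @slot meanDepth Mean per-call read depth for the genotype simulator.
#' @slot seed Master seed; per-stage child seeds are derived at fixed offsets.
#' @aliases SimParams-class
#' @export
setClass("SimParams",
  representation(
    nMales = "integer", nFemales = "integer",
    nChromosomes = "integer", chromLength = "numeric",
    sdSystem = "character", sdrChrom = "integer", sdrInterval = "numeric",
    nSnps = "integer", nIndels = "integer", indelLengthRange = "integer",
    mafBetaParams = "numeric", recombRatePerBp = "numeric",
    genotypingErrorRate = "numeric", missingRate = "numeric",
    annotationFailFraction = "numeric",
    exprNGenes = "integer", exprNSexBiased = "integer",
    exprLog2fc = "numeric", exprDispersion = "numeric",
    exprLibsize = "numeric", meanDepth = "numeric", seed = "integer"),
  prototype(
    nMales = 72L, nFemales = 215L,
    nChromosomes = 4L, chromLength = 2e6,
    sdSystem = "XY", sdrChrom = 1L, sdrInterval = c(9.5e5, 1.05e6),
    nSnps = 4000L, nIndels = 800L, indelLengthRange = c(1L, 30L),
    mafBetaParams = c(0.8, 0.8), recombRatePerBp = 1e-5,
    genotypingErrorRate = 0.01, missingRate = 0.02,
    annotationFailFraction = 0, exprNGenes = 2000L, exprNSexBiased = 100L,
    exprLog2fc = 2, exprDispersion = 0.1, exprLibsize = 5e6,
    meanDepth = 12, seed = 1L))

setValidity("SimParams", function(object) {
  msg <- NULL
  cnt <- c(object@nMales, object@nFemales, object@nChromosomes,
           object@nSnps, object@nIndels, object@exprNGenes,
           object@exprNSexBiased)
  if (any(cnt < 0)) msg <- c(msg, "counts must be >= 0")
  if (!object@sdSystem %in% c("XY", "ZW"))
    msg <- c(msg, "sdSystem must be 'XY' or 'ZW'")
  if (object@sdrChrom < 1L || object@sdrChrom > object@nChromosomes)
    msg <- c(msg, "sdrChrom out of range")
  if (length(object@sdrInterval) != 2 ||
      object@sdrInterval[1] > object@sdrInterval[2] ||
      object@sdrInterval[1] < 1 ||
      object@sdrInterval[2] > object@chromLength)
    msg <- c(msg, "sdrInterval must lie within the SDR chromosome")
  rates <- c(object@recombRatePerBp, object@genotypingErrorRate,
             object@missingRate, object@annotationFailFraction)
  if (any(rates < 0 | rates > 1))
    msg <- c(msg, "rates/fractions must be in [0, 1]")
  if (object@indelLengthRange[1] < 1L)
    msg <- c(msg, "indelLengthRange minimum must be >= 1")
  if (object@exprNSexBiased > object@exprNGenes)
    msg <- c(msg, "exprNSexBiased must be <= exprNGenes")
  if (object@exprDispersion <= 0)
    msg <- c(msg, "exprDispersion must be > 0")
  if (is.null(msg)) TRUE else msg
})

#' Create simulation parameters
#'
#' Defaults mirror the study conditions this package targets: 215 females and
#' 72 males, one sex-determining region on chromosome 1, male-heterogametic
#' (XY) segregation, 1% genotyping error and 2% missingness, and a 3-vs-3
#' gonadal expression design with 5% sex-biased genes at |log2 FC| = 2.
#'
#' @param ... Named parameters overriding slots documented in
#'   [SimParams-class] (e.g. `nMales = 100`, `sdSystem = "ZW"`,
#'   `seed = 42`). Integer-valued slots accept plain numbers.
#' @return A validated `SimParams` object.
#' @examples
#' sp <- simParams(nMales = 20, nFemales = 20, nSnps = 200, seed = 7)
#' @export
simParams <- function(...) {
  args <- list(...)
  obj <- new("SimParams")
  intSlots <- c("nMales", "nFemales", "nChromosomes", "sdrChrom", "nSnps",
                "nIndels", "indelLengthRange", "exprNGenes",
                "exprNSexBiased", "seed")
  for (nm in names(args)) {
    if (!nm %in% slotNames(obj))
      stop("unknown simulation parameter: ", nm)
    val <- args[[nm]]
    if (nm %in% intSlots) val <- as.integer(val)
    slot(obj, nm) <- val
  }
  validObject(obj)
  obj
}

setMethod("show", "SimParams", function(object) {
  cat("SimParams:", object@nFemales, "F /", object@nMales, "M;",
      object@nChromosomes, "chromosomes of", object@chromLength, "bp\n")
  cat("  system ", object@sdSystem, "; SDR chr", object@sdrChrom, ":",
      object@sdrInterval[1], "-", object@sdrInterval[2], "\n", sep = "")
  cat("  ", object@nSnps, " SNPs, ", object@nIndels, " InDels; r/bp = ",
      object@recombRatePerBp, "; error = ", object@genotypingErrorRate,
      "; missing = ", object@missingRate, "\n", sep = "")
})

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' Pooled zygosity segregation summary at significant loci
#'
#' Counts of heterozygous and homozygous genotype calls by sex, pooled over
#' all locus x individual calls at the loci under study (missing calls are
#' excluded from every denominator), plus a per-locus breakdown.
#'
#' @slot nLoci Number of loci summarised.
#' @slot nCalls Total non-missing genotype calls.
#' @slot hetMale,homMale,hetFemale,homFemale Pooled call counts.
#' @slot pHetMale,pHomMale,pHetFemale,pHomFemale Pooled call proportions.
#' @slot perLocus `data.frame` with per-locus het/hom counts by sex.
#' @aliases SegregationSummary-class
#' @export
setClass("SegregationSummary",
  representation(nLoci = "integer", nCalls = "integer",
    hetMale = "integer", homMale = "integer",
    hetFemale = "integer", homFemale = "integer",
    pHetMale = "numeric", pHomMale = "numeric",
    pHetFemale = "numeric", pHomFemale = "numeric",
    perLocus = "data.frame"))

setValidity("SegregationSummary", function(object) {
  msg <- NULL
  if (object@hetMale + object@homMale + object@hetFemale + object@homFemale
      != object@nCalls)
    msg <- c(msg, "het/hom counts must sum to nCalls")
  pr <- c(object@pHetMale, object@pHomMale, object@pHetFemale,
          object@pHomFemale)
  if (any(is.finite(pr) & (pr < 0 | pr > 1)))
    msg <- c(msg, "proportions must be in [0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SegregationSummary", function(object) {
  cat("SegregationSummary:", object@nLoci, "loci,", object@nCalls,
      "non-missing calls\n")
  cat(sprintf("  males:   %.2f%% heterozygous (%d het / %d hom)\n",
              100 * object@pHetMale, object@hetMale, object@homMale))
  cat(sprintf("  females: %.2f%% homozygous   (%d hom / %d het)\n",
              100 * object@pHomFemale, object@homFemale, object@hetFemale))
})

#' A sex-determination system call
#'
#' @slot system `"XY"`, `"ZW"` or `"undetermined"`.
#' @slot support Named numeric: the two proportions driving the call.
#' @slot thresholds Named numeric: `t_het` and `t_hom` used.
#' @aliases SexSystemCall-class
#' @export
setClass("SexSystemCall",
  representation(system = "character", support = "numeric",
                 thresholds = "numeric"))

setMethod("show", "SexSystemCall", function(object) {
  cat("Sex-determination system call:", object@system, "\n")
  for (nm in names(object@support))
    cat(sprintf("  %s = %.4f\n", nm, object@support[[nm]]))
  cat(sprintf("  thresholds: t_het = %.2f, t_hom = %.2f\n",
              object@thresholds[["t_het"]], object@thresholds[["t_hom"]]))
})

#' A binned linkage-disequilibrium decay curve
#'
#' @slot curve `data.frame` with `bin_start`, `bin_end`, `bin_mid`,
#'   `n_pairs`, `mean_r2`.
#' @slot maxR2 Maximum binned mean r-squared.
#' @slot halfDecayDist Midpoint (bp) of the first bin whose mean r-squared is
#'   at or below half the maximum; `NA` when not reached within `max_dist`.
#' @slot r2AtHalf Mean r-squared in that bin.
#' @aliases LDDecayCurve-class
#' @export
setClass("LDDecayCurve",
  representation(curve = "data.frame", maxR2 = "numeric",
                 halfDecayDist = "numeric", r2AtHalf = "numeric"))

setMethod("show", "LDDecayCurve", function(object) {
  cat("LDDecayCurve:", nrow(object@curve), "bins; max mean r2 =",
      sprintf("%.3f", object@maxR2), "\n")
  if (is.na(object@halfDecayDist))
    cat("  half-decay distance not reached within evaluated range\n")
  else
    cat(sprintf("  half-decay: r2 = %.3f at %.0f bp\n",
                object@r2AtHalf, object@halfDecayDist))
})
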