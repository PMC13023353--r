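#' @import methods
#' @importFrom stats cor lm.fit median pt qchisq rbeta rbinom rgeom rnbinom
#'   rnorm rpois runif rt setNames t.test complete.cases sd var p.adjust
#' @importFrom utils read.table write.table head
NULL

#' Extract the genotype dosage matrix
#'
#' @param x A [GenotypeData-class] object.
#' @return Integer matrix, variants x samples; values 0/1/2 count copies of
#'   the alternate allele, `NA` marks missing calls.
#' @export
setGeneric("dosage", function(x) standardGeneric("dosage"))

#' Extract the per-call sequencing depth matrix
#'
#' @param x A [GenotypeData-class] object.
#' @return Numeric matrix, variants x samples, or `NULL` when depth was not
#'   recorded.
#' @export
setGeneric("depthMatrix", function(x) standardGeneric("depthMatrix"))

#' Extract sample sexes
#'
#' @param x A [GenotypeData-class] object.
#' @return Factor with levels `F`, `M`, one entry per sample ( `NA` when
#'   unphenotyped). Numeric coding used throughout the package is female = 0,
#'   male = 1.
#' @export
setGeneric("sampleSex", function(x) standardGeneric("sampleSex"))

#' Assign sample sexes
#' @param x A [GenotypeData-class] object.
#' @param value Character or factor of `"F"`/`"M"` per sample.
#' @export
setGeneric("sampleSex<-", function(x, value) standardGeneric("sampleSex<-"))

#' Per-variant metadata table
#'
#' @param x A [GenotypeData-class] object.
#' @return `data.frame` with variant id, chromosome, position, alleles, type
#'   and any site-quality annotations.
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))

#' Variant type labels
#'
#' @param x A [GenotypeData-class] object.
#' @return Character vector, `"SNP"` or `"InDel"` per variant.
#' @export
setGeneric("variantType", function(x) standardGeneric("variantType"))
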