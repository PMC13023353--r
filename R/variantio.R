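## VCF v4.2 and table I/O, GATK-style hard filters, VCFtools-style site
## filters. Parsing is delegated to vcfR; writing is plain text generation.

.annKeys <- c("QD", "FS", "MQ", "SOR", "ReadPosRankSum", "MQRankSum")

#' Classify a variant as SNP or InDel
#'
#' A variant is a SNP iff the reference allele and every alternate allele
#' have length 1; anything else is an InDel. Multi-allelic alternates may be
#' given comma-separated.
#'
#' @param ref Reference allele string(s).
#' @param alt Alternate allele string(s), possibly comma-separated.
#' @return Character vector of `"SNP"` / `"InDel"`.
#' @examples
#' classifyVariantType("A", "G")           # SNP
#' classifyVariantType("ATTTCTTTGAG", "A") # InDel (9 bp difference: no --
#'                                         # a 10 bp ref vs 1 bp alt)
#' @export
classifyVariantType <- function(ref, alt) {
  if (any(!nzchar(ref)) || any(!nzchar(alt)))
    stop("empty allele string")
  altMax <- vapply(strsplit(alt, ",", fixed = TRUE),
                   function(a) {
                     if (any(!nzchar(a))) stop("empty allele string")
                     max(nchar(a))
                   }, 0L)
  ifelse(nchar(ref) == 1L & altMax == 1L, "SNP", "InDel")
}

#' Write a GenotypeData object as VCF v4.2
#'
#' Emits 1-based positions, `GT` (and `DP` when depth is present) per-sample
#' fields, and the site-quality annotations as INFO keys.
#'
#' @param gd A [GenotypeData-class] object.
#' @param path Output file path (plain text).
#' @return `path`, invisibly.
#' @export
writeVCF <- function(gd, path) {
  gr <- rowRanges(gd)
  mc <- mcols(gr)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=SexLinkScan")
  sl <- GenomeInfoDb::seqlengths(gr)
  for (i in seq_along(sl))
    if (!is.na(sl[i]))
      hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                            names(sl)[i], sl[i]))
  for (k in .annKeys)
    hdr <- c(hdr, sprintf(
      "##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">", k, k))
  hdr <- c(hdr,
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  hasDepth <- !is.null(depthMatrix(gd))
  if (hasDepth)
    hdr <- c(hdr,
      "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", colnames(gd)),
                      collapse = "\t"))
  d <- dosage(gd)
  gt <- matrix(c("0/0", "0/1", "1/1")[d + 1L], nrow = nrow(d))
  gt[is.na(d)] <- "./."
  if (hasDepth) {
    dp <- depthMatrix(gd)
    gt <- matrix(paste(gt, dp, sep = ":"), nrow = nrow(d))
  }
  info <- rep(".", nrow(gd))
  annPresent <- intersect(.annKeys, colnames(mc))
  if (length(annPresent)) {
    parts <- lapply(annPresent, function(k) {
      v <- mc[[k]]
      ifelse(is.na(v), NA_character_, sprintf("%s=%.4g", k, v))
    })
    info <- apply(do.call(cbind, parts), 1, function(row)
      if (all(is.na(row))) "." else paste(row[!is.na(row)], collapse = ";"))
  }
  body <- paste(as.character(seqnames(gr)), start(gr), mc$variant_id,
                mc$ref, mc$alt, ".", ".", info,
                if (hasDepth) "GT:DP" else "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  if (nrow(gd) == 0) body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF into a GenotypeData object
#'
#' Per-sample genotypes become alternate-allele dosages (0/1/2); missing and
#' half-missing calls (`./.`, `./1`) become `NA`. `DP` depths and the INFO
#' annotations `QD`, `FS`, `MQ`, `SOR`, `ReadPosRankSum`, `MQRankSum` are
#' carried into the object when present. Malformed rows raise an error
#' naming the offending line number.
#'
#' @param path Path to a VCF v4.2 file (plain or gzipped).
#' @return A [GenotypeData-class] object (without sample sexes; attach them
#'   with [sampleSex<-] from a phenotype table).
#' @export
readVCF <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdrIdx <- which(startsWith(lines, "#CHROM"))
  if (length(hdrIdx) != 1)
    stop("malformed VCF: expected exactly one #CHROM header line")
  hdrFields <- strsplit(lines[hdrIdx], "\t", fixed = TRUE)[[1]]
  if (length(hdrFields) < 10)
    stop("malformed VCF header at line ", hdrIdx,
         ": need FORMAT plus at least one sample column")
  sampleIds <- hdrFields[-(1:9)]
  dataIdx <- setdiff(seq_along(lines), seq_len(hdrIdx))
  dataIdx <- dataIdx[nzchar(lines[dataIdx])]
  for (i in dataIdx) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) != length(hdrFields))
      stop("malformed VCF record at line ", i, ": ", length(f),
           " fields, expected ", length(hdrFields))
    if (is.na(suppressWarnings(as.integer(f[2]))))
      stop("malformed VCF record at line ", i, ": non-numeric POS")
  }
  sl <- .parseContigLengths(lines[seq_len(hdrIdx - 1)])

  if (length(dataIdx) == 0) {
    gr <- GRanges()
    mcols(gr) <- DataFrame(variant_id = character(0), ref = character(0),
                           alt = character(0), vtype = character(0))
    d <- matrix(integer(0), nrow = 0, ncol = length(sampleIds),
                dimnames = list(NULL, sampleIds))
    return(GenotypeData(d, gr))
  }

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fx <- vcfR::getFIX(v)
  fx <- matrix(fx, ncol = ncol(fx), dimnames = dimnames(fx))
  chrom <- fx[, "CHROM"]; posn <- as.integer(fx[, "POS"])
  ref <- fx[, "REF"]; alt <- fx[, "ALT"]
  vid <- fx[, "ID"]
  noId <- is.na(vid) | vid == "."
  vid[noId] <- paste0(chrom[noId], "_", posn[noId])
  gtRaw <- vcfR::extract.gt(v, element = "GT")
  alleles <- function(g) {
    a <- strsplit(g, "[/|]")
    vapply(a, function(x) {
      x <- suppressWarnings(as.integer(x))
      if (length(x) != 2 || anyNA(x)) NA_integer_ else sum(x > 0L)
    }, 0L)
  }
  d <- apply(gtRaw, 2, alleles)
  d <- matrix(as.integer(d), nrow = nrow(gtRaw),
              dimnames = list(vid, colnames(gtRaw)))
  depth <- NULL
  if ("DP" %in% vcfR::vcf_field_names(v, tag = "FORMAT")$ID) {
    dp <- suppressWarnings(
      vcfR::extract.gt(v, element = "DP", as.numeric = TRUE))
    if (!all(is.na(dp))) depth <- dp
  }
  keep <- names(sl)[names(sl) %in% unique(chrom)]
  grArgs <- list(chrom, IRanges(start = posn, width = nchar(ref)),
                 variant_id = vid, ref = ref, alt = alt,
                 vtype = classifyVariantType(ref, alt))
  if (length(keep)) grArgs$seqlengths <- sl[keep]
  gr <- do.call(GRanges, grArgs)
  for (k in .annKeys) {
    val <- suppressWarnings(
      vcfR::extract.info(v, element = k, as.numeric = TRUE))
    if (!all(is.na(val))) mcols(gr)[[k]] <- val
  }
  GenotypeData(d, gr, depth = depth)
}

.parseContigLengths <- function(metaLines) {
  ct <- grep("^##contig=", metaLines, value = TRUE)
  if (!length(ct)) return(setNames(integer(0), character(0)))
  ids <- sub(".*ID=([^,>]+).*", "\\1", ct)
  lens <- suppressWarnings(as.integer(sub(".*length=([0-9]+).*", "\\1", ct)))
  setNames(lens, ids)
}

#' GATK-style hard filter on site-quality annotations
#'
#' A SNP fails when any of `QD < 2.0`, `FS > 60.0`, `MQ < 40.0`,
#' `SOR > 3.0`, `ReadPosRankSum < -8.0`, `MQRankSum < -12.5` holds; an InDel
#' fails on `QD < 2.0`, `FS > 200.0`, `SOR > 10.0`,
#' `ReadPosRankSum < -20.0`, `MQRankSum < -12.5`. All comparisons are
#' strict, and an absent annotation never triggers failure (matching the
#' upstream caller's behaviour when an annotation is undefined).
#'
#' @param gd A [GenotypeData-class] object with `vtype` set per variant.
#' @return Logical vector: `TRUE` where the site passes.
#' @export
hardFilter <- function(gd) {
  mc <- mcols(rowRanges(gd))
  vt <- mc$vtype
  g <- function(k) if (k %in% colnames(mc)) mc[[k]]
       else rep(NA_real_, nrow(gd))
  lt <- function(x, thr) !is.na(x) & x < thr
  gt <- function(x, thr) !is.na(x) & x > thr
  failSNP <- lt(g("QD"), 2.0) | gt(g("FS"), 60.0) | lt(g("MQ"), 40.0) |
    gt(g("SOR"), 3.0) | lt(g("ReadPosRankSum"), -8.0) |
    lt(g("MQRankSum"), -12.5)
  failInDel <- lt(g("QD"), 2.0) | gt(g("FS"), 200.0) |
    gt(g("SOR"), 10.0) | lt(g("ReadPosRankSum"), -20.0) |
    lt(g("MQRankSum"), -12.5)
  !ifelse(vt == "SNP", failSNP, failInDel)
}

#' VCFtools-style site filter
#'
#' Retains biallelic sites whose minor allele frequency (computed over
#' non-missing calls), mean per-sample depth and missing fraction satisfy
#' the configured bounds. Defaults reproduce `min-alleles 2`,
#' `max-alleles 2`, `maf 0.05`, `min-meanDP 3` and `max-missing 0.75`
#' (the VCFtools convention: at least 75% of samples called, i.e. at most
#' 25% missing). The depth criterion is skipped when the object carries no
#' depth assay. Retained variants keep their input order; the filter is
#' idempotent.
#'
#' @param gd A [GenotypeData-class] object.
#' @param minAlleles,maxAlleles Allowed total allele count (REF + ALTs).
#' @param minMaf Minimum minor allele frequency.
#' @param minMeanDepth Minimum mean per-sample read depth.
#' @param maxMissing Maximum fraction of missing calls per site.
#' @return The filtered [GenotypeData-class] object.
#' @export
siteFilter <- function(gd, minAlleles = 2L, maxAlleles = 2L,
                       minMaf = 0.05, minMeanDepth = 3,
                       maxMissing = 0.25) {
  if (ncol(gd) == 0) stop("site filter undefined on a zero-sample matrix")
  stopifnot(minMaf >= 0, minMaf <= 1, maxMissing >= 0, maxMissing <= 1)
  mc <- mcols(rowRanges(gd))
  nAlleles <- 1L + lengths(strsplit(mc$alt, ",", fixed = TRUE))
  d <- dosage(gd)
  nOk <- rowSums(!is.na(d))
  f <- rowSums(d, na.rm = TRUE) / (2 * nOk)
  maf <- pmin(f, 1 - f)
  missFrac <- 1 - nOk / ncol(gd)
  keep <- nAlleles >= minAlleles & nAlleles <= maxAlleles &
    nOk > 0 & maf >= minMaf & missFrac <= maxMissing
  dp <- depthMatrix(gd)
  if (!is.null(dp)) keep <- keep & rowMeans(dp, na.rm = TRUE) >= minMeanDepth
  gd[which(keep), ]
}

#' Read / write a two-column sex-phenotype table
#'
#' Tab-separated with header `sample_id<TAB>sex`; sex is `M` or `F`.
#' Numeric coding used by the association scan is female = 0, male = 1.
#'
#' @param path File path.
#' @return `data.frame(sample_id, sex)`.
#' @export
readPhenotypeTable <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("sample_id", "sex") %in% colnames(ph)))
    stop("phenotype table needs columns 'sample_id' and 'sex'")
  if (anyDuplicated(ph$sample_id)) stop("duplicate sample ids")
  if (!all(ph$sex %in% c("M", "F")))
    stop("sex must be 'M' or 'F'")
  ph
}

#' @rdname readPhenotypeTable
#' @param ph `data.frame(sample_id, sex)`.
#' @export
writePhenotypeTable <- function(ph, path) {
  write.table(ph, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene-interval annotation table
#'
#' Tab-separated with header columns `chrom`, `start`, `end`, `gene_id`;
#' coordinates are 1-based inclusive.
#'
#' @param path File path.
#' @return `data.frame(chrom, start, end, gene_id)`.
#' @export
readGeneTable <- function(path) {
  gt <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "gene_id")
  if (!all(need %in% colnames(gt)))
    stop("gene table needs columns: ", paste(need, collapse = ", "))
  gt
}
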