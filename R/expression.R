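## Simplified gonadal differential-expression stage, DEG filtering,
## 2^-ddCt quantification, and the GWAS x RNA-Seq candidate overlap.

#' RPKM normalisation
#'
#' RPKM = count / (gene length in kb x library size in millions).
#'
#' @param counts Genes x samples count matrix.
#' @param geneLengths Gene lengths in bp (recycled per sample).
#' @param librarySizes Mapped reads per sample; defaults to column sums.
#' @return Numeric matrix of RPKM values, same shape as `counts`.
#' @examples
#' rpkm(matrix(10), geneLengths = 1000, librarySizes = 1e6)  # 10
#' @export
rpkm <- function(counts, geneLengths, librarySizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (any(geneLengths <= 0)) stop("gene lengths must be > 0")
  if (any(librarySizes <= 0)) stop("library sizes must be > 0")
  t(t(counts / (geneLengths / 1e3)) / (librarySizes / 1e6))
}

#' Two-group differential-expression test (testis vs ovary)
#'
#' A deliberately simple DE stage: counts are library-normalised by total
#' counts (scaled to the mean library size), the fold change is
#' `log2((mean testis + 1) / (mean ovary + 1))` on normalised counts
#' (pseudocount 1 handles zeros), and the p-value comes from a two-sided
#' Welch t test on `log2(normalised + 1)`. Genes with zero variance in both
#' groups (including all-zero genes) are returned untested. P-values are
#' raw by default, matching a raw-p DEG threshold; set `fdr = TRUE` to add
#' a Benjamini-Hochberg column.
#'
#' @param counts Genes x samples count matrix.
#' @param group Factor with levels `testis`, `ovary` per sample; at least
#'   two samples per group.
#' @param fdr Add a BH-adjusted `padj` column.
#' @return `data.frame(gene_id, log2fc, p, tested)` (plus `padj` when
#'   requested); `log2fc` is oriented male/female (testis over ovary).
#' @export
deTest <- function(counts, group, fdr = FALSE) {
  counts <- as.matrix(counts)
  group <- factor(as.character(group), levels = c("testis", "ovary"))
  if (anyNA(group)) stop("group must be 'testis' or 'ovary'")
  n1 <- sum(group == "testis"); n2 <- sum(group == "ovary")
  if (n1 < 2 || n2 < 2) stop("need at least 2 samples per group")
  libs <- colSums(counts)
  if (any(libs == 0)) stop("zero library size")
  norm <- t(t(counts) / libs) * mean(libs)
  lg <- log2(norm + 1)
  i1 <- group == "testis"; i2 <- group == "ovary"
  m1 <- rowMeans(lg[, i1, drop = FALSE])
  m2 <- rowMeans(lg[, i2, drop = FALSE])
  v1 <- apply(lg[, i1, drop = FALSE], 1, var)
  v2 <- apply(lg[, i2, drop = FALSE], 1, var)
  tested <- (v1 + v2) > 0
  sed <- sqrt(v1 / n1 + v2 / n2)
  tstat <- (m1 - m2) / sed
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(tstat), df)
  lfc <- log2((rowMeans(norm[, i1, drop = FALSE]) + 1) /
              (rowMeans(norm[, i2, drop = FALSE]) + 1))
  out <- data.frame(
    gene_id = if (is.null(rownames(counts)))
      sprintf("gene%05d", seq_len(nrow(counts))) else rownames(counts),
    log2fc = lfc, p = ifelse(tested, p, NA_real_), tested = tested,
    row.names = NULL, stringsAsFactors = FALSE)
  if (fdr) out$padj <- p.adjust(out$p, method = "BH")
  out
}

#' Filter differentially expressed genes at fold-change and p thresholds
#'
#' Strict inequalities on both criteria: testis-biased iff
#' `log2fc > lfcThreshold` and `p < pThreshold`; ovary-biased iff
#' `log2fc < -lfcThreshold` and `p < pThreshold`. Defaults are the
#' conventional |log2 FC| > 1, p < 0.05.
#'
#' @param records `data.frame` with `gene_id`, `log2fc`, `p` (e.g. from
#'   [deTest()]).
#' @param lfcThreshold,pThreshold Thresholds.
#' @param useAdjusted Filter on `padj` instead of `p` when present.
#' @return List with `records` (input plus a `bias` column in
#'   `{testis, ovary, none}`), `testis`, `ovary` (gene id vectors),
#'   `n_testis`, `n_ovary`, `n_deg`.
#' @export
filterDEGs <- function(records, lfcThreshold = 1, pThreshold = 0.05,
                       useAdjusted = FALSE) {
  p <- if (useAdjusted && "padj" %in% colnames(records)) records$padj
       else records$p
  sig <- !is.na(p) & p < pThreshold
  bias <- rep("none", nrow(records))
  bias[sig & records$log2fc > lfcThreshold] <- "testis"
  bias[sig & records$log2fc < -lfcThreshold] <- "ovary"
  records$bias <- bias
  list(records = records,
       testis = records$gene_id[bias == "testis"],
       ovary = records$gene_id[bias == "ovary"],
       n_testis = sum(bias == "testis"), n_ovary = sum(bias == "ovary"),
       n_deg = sum(bias != "none"))
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target - Ct_reference)_test -
#' (Ct_target - Ct_reference)_calibrator`; the relative expression is
#' `2^-ddCt`. Adding a constant to all four Ct values leaves the result
#' unchanged.
#'
#' @param ctTargetTest,ctRefTest Target and reference-gene Ct in the test
#'   condition.
#' @param ctTargetCal,ctRefCal The same in the calibrator condition.
#' @return Relative expression (positive scalar, 1 = no change).
#' @examples
#' ddct(18.2, 16.0, 20.5, 16.1)
#' @export
ddct <- function(ctTargetTest, ctRefTest, ctTargetCal, ctRefCal) {
  ct <- c(ctTargetTest, ctRefTest, ctTargetCal, ctRefCal)
  if (length(ct) != 4 || anyNA(ct) || any(!is.finite(ct)))
    stop("all four Ct values must be finite")
  2^-((ctTargetTest - ctRefTest) - (ctTargetCal - ctRefCal))
}

#' Intersect GWAS window genes with sex-biased DEGs
#'
#' Exact set intersection on gene ids; each overlapping gene keeps its GWAS
#' window support (lead variants) and its expression statistics.
#'
#' @param gwasGenes `data.frame` from [genesInWindows()].
#' @param degRecords `data.frame` with `gene_id`, `log2fc`, `p`, `bias`
#'   (e.g. `filterDEGs(...)$records`), restricted or not: only genes with
#'   `bias != "none"` count as DEGs.
#' @return `data.frame(gene_id, chrom, start, end, lead_ids, log2fc, p,
#'   bias)`, one row per overlapping gene.
#' @export
overlapCandidates <- function(gwasGenes, degRecords) {
  degs <- degRecords[degRecords$bias %in% c("testis", "ovary"), ,
                     drop = FALSE]
  hit <- gwasGenes[gwasGenes$gene_id %in% degs$gene_id, , drop = FALSE]
  if (nrow(hit) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_ids = character(0), log2fc = numeric(0),
                      p = numeric(0), bias = character(0),
                      stringsAsFactors = FALSE))
  j <- match(hit$gene_id, degs$gene_id)
  hit$log2fc <- degs$log2fc[j]
  hit$p <- degs$p[j]
  hit$bias <- degs$bias[j]
  rownames(hit) <- NULL
  hit
}
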