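## Forward simulator of sex-linked populations and gonadal expression.
##
## Generative model (documented in the methods vignette): the heterogametic
## sex carries one sex-linked haplotype per individual. Along each arm of the
## SDR chromosome the distance from the SDR midpoint to the first crossover
## is geometric(r), so the sex-linked (alternate) allele is retained at
## distance D with probability (1 - r)^D, and retention is nested along an
## arm -- which is what makes inter-locus r-squared decay with distance.
## SDR-internal loci are fully linked. Loci on other chromosomes are
## autosomal Hardy-Weinberg draws with Beta-distributed allele frequency.

childSeed <- function(seed, stage) {
  as.integer((as.numeric(seed) + stage * 7919) %% 2147483646) + 1L
}

#' Simulate a diploid population with one sex-determining region
#'
#' Generates genotype dosages for `nFemales + nMales` individuals at
#' `nSnps + nIndels` loci. Under an XY system every male carries a sex-linked
#' haplotype whose alternate allele is retained at distance D from the SDR
#' midpoint with probability `(1 - recombRatePerBp)^D` (probability 1 inside
#' the SDR); females are homozygous reference there. Under ZW the roles are
#' mirrored. Autosomal loci follow Hardy-Weinberg with Beta-distributed
#' alternate-allele frequencies. Genotyping error (symmetric one-step dosage
#' perturbation) and missingness are applied last.
#'
#' @param params A [SimParams-class] object; see [simParams()].
#' @return A list with elements:
#'   \describe{
#'     \item{genotypes}{[GenotypeData-class] with `dosage` and `depth` assays
#'       and sample sex in `colData`.}
#'     \item{phenotypes}{`data.frame(sample_id, sex)`.}
#'     \item{truth}{`data.frame(variant_id, chrom, pos, sex_linked,
#'       distance_to_sdr)`; `sex_linked` marks SDR-internal loci,
#'       `distance_to_sdr` is bp from the SDR midpoint (0 inside the SDR,
#'       `NA` off the SDR chromosome).}
#'   }
#' @examples
#' sim <- simulatePopulation(simParams(nMales = 10, nFemales = 10,
#'   nSnps = 100, nIndels = 20, seed = 1))
#' sim$genotypes
#' @export
simulatePopulation <- function(params) {
  validObject(params)
  if (params@nMales == 0L || params@nFemales == 0L)
    stop("both sexes must be represented: sex-linked segregation is ",
         "undefined with zero males or zero females")
  set.seed(childSeed(params@seed, 1L))

  nF <- params@nFemales; nM <- params@nMales; n <- nF + nM
  sex <- c(rep("F", nF), rep("M", nM))
  sampleIds <- sprintf("S%04d", seq_len(n))
  hetero <- if (params@sdSystem == "XY") sex == "M" else sex == "F"

  nChr <- params@nChromosomes
  L <- params@chromLength
  nVar <- params@nSnps + params@nIndels
  perChr <- diff(round(seq(0, nVar, length.out = nChr + 1)))
  chrom <- rep(seq_len(nChr), perChr)
  pos <- unlist(lapply(perChr, function(k) sort(sample.int(L, k))))
  isIndel <- rep(FALSE, nVar)
  isIndel[sample.int(nVar, params@nIndels)] <- TRUE

  sdrLo <- params@sdrInterval[1]; sdrHi <- params@sdrInterval[2]
  mid <- floor((sdrLo + sdrHi) / 2)
  onSdrChrom <- chrom == params@sdrChrom
  inSdr <- onSdrChrom & pos >= sdrLo & pos <= sdrHi
  D <- ifelse(onSdrChrom, ifelse(inSdr, 0, abs(pos - mid)), NA_real_)

  dose <- matrix(0L, nrow = nVar, ncol = n)

  ## sex-linked block: one truncation distance per heterogametic individual
  ## per arm; allele retained iff the locus lies before the first crossover
  r <- params@recombRatePerBp
  sdrIdx <- which(onSdrChrom)
  if (length(sdrIdx)) {
    arm <- sign(pos[sdrIdx] - mid)
    for (i in which(hetero)) {
      if (r > 0) {
        tl <- rgeom(1, r); tr <- rgeom(1, r)
      } else tl <- tr <- Inf
      Tarm <- ifelse(arm < 0, tl, tr)
      carried <- inSdr[sdrIdx] | (D[sdrIdx] <= Tarm)
      dose[sdrIdx[carried], i] <- 1L
    }
  }

  ## autosomal block: HWE with Beta-distributed alt-allele frequency
  autoIdx <- which(!onSdrChrom)
  if (length(autoIdx)) {
    f <- rbeta(length(autoIdx), params@mafBetaParams[1],
               params@mafBetaParams[2])
    dose[autoIdx, ] <- matrix(
      rbinom(length(autoIdx) * n, 2L, rep(f, n)),
      nrow = length(autoIdx))
  }

  ## alleles
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nVar, replace = TRUE)
  alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
  if (any(isIndel)) {
    idx <- which(isIndel)
    dlen <- sample(seq(params@indelLengthRange[1],
                       params@indelLengthRange[2]),
                   length(idx), replace = TRUE)
    isDel <- runif(length(idx)) < 0.5
    extra <- vapply(dlen, function(k)
      paste(sample(bases, k, replace = TRUE), collapse = ""), "")
    ref[idx] <- ifelse(isDel, paste0(ref[idx], extra), ref[idx])
    alt[idx] <- ifelse(isDel, substr(ref[idx], 1, 1),
                       paste0(alt[idx], extra))
    alt[idx][!isDel] <- paste0(substr(ref[idx][!isDel], 1, 1),
                               extra[!isDel])
    ref[idx][!isDel] <- substr(ref[idx][!isDel], 1, 1)
  }

  ## genotyping error: symmetric one-step dosage perturbation, then missing
  e <- params@genotypingErrorRate
  if (e > 0) {
    hit <- which(runif(length(dose)) < e)
    if (length(hit)) {
      old <- dose[hit]
      dose[hit] <- ifelse(old == 0L, 1L,
                   ifelse(old == 2L, 1L,
                          sample(c(0L, 2L), length(hit), replace = TRUE)))
    }
  }
  m <- params@missingRate
  if (m > 0)
    dose[runif(length(dose)) < m] <- NA_integer_

  depth <- matrix(rpois(nVar * n, params@meanDepth), nrow = nVar)

  vid <- sprintf("chr%d_%d", chrom, pos)
  gr <- GRanges(paste0("chr", chrom),
                IRanges(start = pos, width = nchar(ref)),
                variant_id = vid, ref = ref, alt = alt,
                vtype = ifelse(isIndel, "InDel", "SNP"),
                seqlengths = setNames(rep(L, nChr),
                                      paste0("chr", seq_len(nChr))))
  dimnames(dose) <- list(vid, sampleIds)
  gd <- GenotypeData(dose, gr, sex = sex, depth = depth)
  metadata(gd)$sim_params <- params

  list(genotypes = gd,
       phenotypes = data.frame(sample_id = sampleIds, sex = sex,
                               stringsAsFactors = FALSE),
       truth = data.frame(variant_id = vid, chrom = paste0("chr", chrom),
                          pos = pos, sex_linked = inSdr,
                          distance_to_sdr = D, stringsAsFactors = FALSE))
}

## annotation value ranges: passing values sit well inside the passing
## region; failing values violate exactly one threshold for the site's type
.passRanges <- list(QD = c(10, 30), FS = c(1, 30), MQ = c(50, 60),
                    SOR = c(0.5, 2), ReadPosRankSum = c(-2, 2),
                    MQRankSum = c(-2, 2))
.failRanges <- list(
  SNP = list(QD = c(0, 1.9), FS = c(61, 100), MQ = c(20, 39),
             SOR = c(3.1, 6), ReadPosRankSum = c(-20, -8.1),
             MQRankSum = c(-25, -12.6)),
  InDel = list(QD = c(0, 1.9), FS = c(201, 300), SOR = c(10.1, 15),
               ReadPosRankSum = c(-40, -20.1), MQRankSum = c(-25, -12.6)))

#' Attach simulated site-quality annotations
#'
#' Gives every variant the GATK-style INFO annotations (`QD`, `FS`, `MQ`,
#' `SOR`, `ReadPosRankSum`, `MQRankSum`). Exactly
#' `round(failFraction * n_sites)` sites, chosen at random, receive one
#' annotation violating the hard-filter threshold for their variant type;
#' all other sites receive values well inside the passing region.
#'
#' @param gd A [GenotypeData-class] object.
#' @param failFraction Fraction of sites to fail, in \[0, 1\].
#' @param seed Integer seed.
#' @return `gd` with annotation columns added to its variant metadata.
#' @export
simulateSiteAnnotations <- function(gd, failFraction, seed = 1L) {
  stopifnot(failFraction >= 0, failFraction <= 1)
  set.seed(childSeed(seed, 2L))
  nVar <- nrow(gd)
  ann <- sapply(names(.passRanges), function(k)
    runif(nVar, .passRanges[[k]][1], .passRanges[[k]][2]))
  ann <- matrix(ann, nrow = nVar,
                dimnames = list(NULL, names(.passRanges)))
  nFail <- round(failFraction * nVar)
  vt <- variantType(gd)
  if (nFail > 0) {
    failIdx <- sample.int(nVar, nFail)
    for (i in failIdx) {
      opts <- .failRanges[[vt[i]]]
      key <- sample(names(opts), 1)
      ann[i, key] <- runif(1, opts[[key]][1], opts[[key]][2])
    }
  }
  gr <- rowRanges(gd)
  for (k in colnames(ann)) mcols(gr)[[k]] <- ann[, k]
  rowRanges(gd) <- gr
  gd
}

#' Simulate gonadal expression counts with planted sex-biased genes
#'
#' Draws negative-binomial counts for a testis-vs-ovary design. A random set
#' of `exprNSexBiased` genes gets its testis-group mean multiplied by
#' `2^(true_log2fc)` with `true_log2fc = +/- exprLog2fc` (half testis-,
#' half ovary-biased); when `exprLog2fc` is 0 no gene is sex-biased.
#'
#' @param params A [SimParams-class] object.
#' @param nTestis,nOvary Samples per group (the targeted design pooled three
#'   RNA libraries per gonad).
#' @return A list with `counts` (genes x samples integer matrix, columns
#'   named `testis*`/`ovary*`), `group` (factor per sample),
#'   `gene_lengths` (bp), and `truth`
#'   (`data.frame(gene_id, sex_biased, true_log2fc)`).
#' @export
simulateExpression <- function(params, nTestis = 3L, nOvary = 3L) {
  validObject(params)
  if (params@exprDispersion <= 0) stop("dispersion must be > 0")
  set.seed(childSeed(params@seed, 3L))
  G <- params@exprNGenes
  geneIds <- sprintf("gene%05d", seq_len(G))
  lfc <- rep(0, G)
  biased <- integer(0)
  if (params@exprLog2fc != 0 && params@exprNSexBiased > 0) {
    biased <- sample.int(G, params@exprNSexBiased)
    sgn <- rep_len(c(1, -1), length(biased))
    lfc[biased] <- sgn * params@exprLog2fc
  }
  base <- exp(rnorm(G, 1, 1))
  mu <- base / sum(base) * params@exprLibsize
  muT <- mu * 2^lfc
  sz <- 1 / params@exprDispersion
  cntT <- matrix(rnbinom(G * nTestis, mu = rep(muT, nTestis), size = sz),
                 nrow = G)
  cntO <- matrix(rnbinom(G * nOvary, mu = rep(mu, nOvary), size = sz),
                 nrow = G)
  counts <- cbind(cntT, cntO)
  dimnames(counts) <- list(geneIds,
    c(sprintf("testis%d", seq_len(nTestis)),
      sprintf("ovary%d", seq_len(nOvary))))
  group <- factor(rep(c("testis", "ovary"), c(nTestis, nOvary)),
                  levels = c("testis", "ovary"))
  lens <- round(runif(G, 500, 5000))
  list(counts = counts, group = group,
       gene_lengths = setNames(lens, geneIds),
       truth = data.frame(gene_id = geneIds, sex_biased = lfc != 0,
                          true_log2fc = lfc, stringsAsFactors = FALSE))
}

#' Simulate a gene-interval annotation table
#'
#' Places `exprNGenes` genes of fixed width evenly across the simulated
#' chromosomes (1-based inclusive coordinates), so that gene ids are shared
#' with [simulateExpression()] and some genes overlap the SDR.
#'
#' @param params A [SimParams-class] object.
#' @param geneWidth Gene width in bp.
#' @return `data.frame(chrom, start, end, gene_id)`.
#' @export
simulateGeneTable <- function(params, geneWidth = 2000) {
  validObject(params)
  G <- params@exprNGenes
  nChr <- params@nChromosomes
  perChr <- diff(round(seq(0, G, length.out = nChr + 1)))
  rows <- lapply(seq_len(nChr), function(ch) {
    k <- perChr[ch]
    if (k == 0) return(NULL)
    starts <- round(seq(1, params@chromLength - geneWidth, length.out = k))
    data.frame(chrom = paste0("chr", ch), start = starts,
               end = starts + geneWidth - 1, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$gene_id <- sprintf("gene%05d", seq_len(nrow(out)))
  out
}
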