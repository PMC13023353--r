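## Fixture builders shared across test files. Everything is generated in
## code; no binary fixtures.

## A GenotypeData from explicit pieces, with sensible defaults.
toyGenotypeData <- function(dosage, chrom = "chr1", pos = NULL,
                            ref = NULL, alt = NULL, sex = NULL,
                            depth = NULL, chromLength = NA) {
  nV <- nrow(dosage)
  if (is.null(pos)) pos <- seq_len(nV) * 100L
  if (is.null(ref)) ref <- rep("A", nV)
  if (is.null(alt)) alt <- rep("G", nV)
  chrom <- rep_len(chrom, nV)
  vt <- SexLinkScan::classifyVariantType(ref, alt)
  sl <- NULL
  if (!is.na(chromLength))
    sl <- stats::setNames(rep(chromLength, length(unique(chrom))),
                          unique(chrom))
  args <- list(chrom, IRanges::IRanges(start = pos, width = nchar(ref)),
               variant_id = paste0(chrom, "_", pos), ref = ref, alt = alt,
               vtype = vt)
  if (!is.null(sl)) args$seqlengths <- sl
  gr <- do.call(GenomicRanges::GRanges, args)
  GenotypeData(dosage, gr, sex = sex, depth = depth)
}

## Perfect XY fixture: males all heterozygous, females all homozygous ref.
perfectXY <- function(nLoci, nMales, nFemales) {
  d <- cbind(matrix(0L, nLoci, nFemales), matrix(1L, nLoci, nMales))
  toyGenotypeData(d, sex = c(rep("F", nFemales), rep("M", nMales)))
}

## Null (autosomal-only) population: simulate then drop the SDR chromosome.
nullPopulation <- function(nMales, nFemales, nSites, seed,
                           errorRate = 0.01, missingRate = 0) {
  nChr <- 5L
  perChr <- ceiling(nSites / (nChr - 1))
  sim <- simulatePopulation(simParams(
    nMales = nMales, nFemales = nFemales, nChromosomes = nChr,
    nSnps = perChr * nChr, nIndels = 0,
    genotypingErrorRate = errorRate, missingRate = missingRate,
    seed = seed))
  keep <- which(is.na(sim$truth$distance_to_sdr))
  sim$genotypes[keep[seq_len(min(nSites, length(keep)))], ]
}
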