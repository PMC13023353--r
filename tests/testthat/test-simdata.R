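test_that("error-free full linkage: SDR-internal loci segregate perfectly", {
  sim <- simulatePopulation(simParams(
    nMales = 30, nFemales = 40, nChromosomes = 2, nSnps = 300,
    nIndels = 50, genotypingErrorRate = 0, missingRate = 0, seed = 11))
  gd <- sim$genotypes
  sdr <- which(sim$truth$sex_linked)
  expect_gt(length(sdr), 0)
  d <- dosage(gd[sdr, ])
  males <- sampleSex(gd) == "M"
  expect_true(all(d[, males] == 1L))
  expect_true(all(d[, !males] == 0L))
  ## mirrored under ZW
  simZ <- simulatePopulation(simParams(
    nMales = 30, nFemales = 40, nChromosomes = 2, nSnps = 300,
    nIndels = 50, sdSystem = "ZW", genotypingErrorRate = 0,
    missingRate = 0, seed = 11))
  dz <- dosage(simZ$genotypes[which(simZ$truth$sex_linked), ])
  femalesZ <- sampleSex(simZ$genotypes) == "F"
  expect_true(all(dz[, femalesZ] == 1L))
  expect_true(all(dz[, !femalesZ] == 0L))
})

test_that("identical seed gives bit-identical output; sexes are required", {
  p <- simParams(nMales = 15, nFemales = 15, nSnps = 120, nIndels = 30,
                 seed = 99)
  a <- simulatePopulation(p)
  b <- simulatePopulation(p)
  expect_identical(dosage(a$genotypes), dosage(b$genotypes))
  expect_identical(a$truth, b$truth)
  expect_error(simulatePopulation(simParams(nMales = 0, nFemales = 10)),
               "both sexes")
})

test_that("male heterozygote proportion at distance D matches (1-r)^D and a gamete-level oracle", {
  r <- 1e-4
  sim <- simulatePopulation(simParams(
    nMales = 10000, nFemales = 10, nChromosomes = 1, chromLength = 4e4,
    sdrChrom = 1, sdrInterval = c(1, 100), nSnps = 60, nIndels = 0,
    recombRatePerBp = r, genotypingErrorRate = 0, missingRate = 0,
    seed = 5))
  tr <- sim$truth
  males <- sampleSex(sim$genotypes) == "M"
  loci <- which(!tr$sex_linked & tr$distance_to_sdr > 500 &
                  tr$distance_to_sdr < 20000)
  expect_gt(length(loci), 5)
  for (j in loci[1:5]) {
    D <- tr$distance_to_sdr[j]
    pHet <- mean(dosage(sim$genotypes)[j, males] == 1L)
    expected <- (1 - r)^D
    se <- sqrt(expected * (1 - expected) / sum(males))
    expect_lt(abs(pHet - expected), 3 * se + 1e-12)
    ## brute-force gamete oracle: allele retained iff zero crossovers
    ## hit any of the D base pairs between locus and SDR midpoint
    set.seed(1000 + j)
    oracle <- mean(rbinom(20000, round(D), r) == 0)
    seO <- sqrt(expected * (1 - expected) / 20000)
    expect_lt(abs(oracle - expected), 4 * seO + 1e-12)
  }
})

test_that("site annotations fail exactly the requested fraction, per an exhaustive threshold oracle", {
  sim <- simulatePopulation(simParams(
    nMales = 5, nFemales = 5, nSnps = 800, nIndels = 200, seed = 3))
  for (ff in c(0, 0.3, 1)) {
    gd <- simulateSiteAnnotations(sim$genotypes, ff, seed = 7)
    pass <- hardFilter(gd)
    expect_equal(sum(pass), 1000 - round(ff * 1000))
    ## exhaustive re-check of every threshold, independent of hardFilter()
    vi <- variantInfo(gd)
    failOracle <- ifelse(vi$vtype == "SNP",
      vi$QD < 2 | vi$FS > 60 | vi$MQ < 40 | vi$SOR > 3 |
        vi$ReadPosRankSum < -8 | vi$MQRankSum < -12.5,
      vi$QD < 2 | vi$FS > 200 | vi$SOR > 10 |
        vi$ReadPosRankSum < -20 | vi$MQRankSum < -12.5)
    expect_identical(unname(pass), unname(!failOracle))
  }
})

test_that("expression simulator: zero effect size plants nothing; seeds reproduce", {
  p0 <- simParams(exprNGenes = 150, exprNSexBiased = 20, exprLog2fc = 0,
                  seed = 4)
  e0 <- simulateExpression(p0)
  expect_false(any(e0$truth$sex_biased))
  p1 <- simParams(exprNGenes = 150, exprNSexBiased = 20, seed = 4)
  expect_identical(simulateExpression(p1)$counts,
                   simulateExpression(p1)$counts)
  expect_error(simParams(exprDispersion = 0), "exprDispersion")
})

test_that("de_test power on simulated effects matches an independent Welch-t reimplementation", {
  ## same simulated matrices scored by deTest and by a per-gene
  ## stats::t.test loop: p-values and hence detection power must agree
  nRep <- 30
  hits <- hitsOracle <- 0; planted <- 0
  for (i in seq_len(nRep)) {
    sim <- simulateExpression(simParams(
      exprNGenes = 80, exprNSexBiased = 10, exprLog2fc = 2,
      exprDispersion = 0.1, seed = 6000 + i))
    de <- deTest(sim$counts, sim$group)
    libs <- colSums(sim$counts)
    lg <- log2(t(t(sim$counts) / libs) * mean(libs) + 1)
    pOracle <- vapply(seq_len(nrow(lg)), function(g) {
      x <- lg[g, sim$group == "testis"]; y <- lg[g, sim$group == "ovary"]
      if (var(x) + var(y) == 0) return(NA_real_)
      t.test(x, y)$p.value
    }, 0)
    expect_equal(de$p, pOracle, tolerance = 1e-10)
    deg <- filterDEGs(de)
    isBiased <- sim$truth$sex_biased
    planted <- planted + sum(isBiased)
    hits <- hits + sum(de$gene_id[isBiased] %in%
                         c(deg$testis, deg$ovary))
    sigO <- !is.na(pOracle) & pOracle < 0.05 & abs(de$log2fc) > 1
    hitsOracle <- hitsOracle + sum(sigO[isBiased])
  }
  expect_equal(hits, hitsOracle)
  expect_gt(hits / planted, 0.5)
})

test_that("SDR-to-autosome r2 converges to the unlinked expectation at large n", {
  sim <- simulatePopulation(simParams(
    nMales = 1000, nFemales = 1000, nChromosomes = 2, chromLength = 1e5,
    sdrInterval = c(4e4, 6e4), nSnps = 60, nIndels = 0,
    genotypingErrorRate = 0, missingRate = 0, seed = 21))
  gd <- sim$genotypes
  tr <- sim$truth
  sdrIdx <- head(which(tr$sex_linked), 10)
  autoIdx <- head(which(tr$chrom == "chr2"), 10)
  expect_gte(length(sdrIdx), 2)
  d <- dosage(gd)
  r2 <- outer(sdrIdx, autoIdx, Vectorize(function(i, j)
    pairwiseR2(d[i, ], d[j, ])))
  ## unlinked loci: E[r2] ~ 1/n for the squared sample correlation
  expect_lt(mean(r2, na.rm = TRUE), 5 / 2000)
})

test_that("VCF round trip preserves the dosage matrix", {
  sim <- simulatePopulation(simParams(
    nMales = 8, nFemales = 8, nSnps = 60, nIndels = 20,
    missingRate = 0.05, seed = 31))
  gd <- simulateSiteAnnotations(sim$genotypes, 0.2, seed = 8)
  f <- tempfile(fileext = ".vcf")
  writeVCF(gd, f)
  back <- readVCF(f)
  expect_identical(unname(dosage(back)), unname(dosage(gd)))
  expect_identical(variantInfo(back)$pos, variantInfo(gd)$pos)
  expect_identical(variantInfo(back)$ref, variantInfo(gd)$ref)
  expect_equal(variantInfo(back)$QD, variantInfo(gd)$QD,
               tolerance = 1e-3)
})
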