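test_that("variant type classification follows allele lengths", {
  expect_equal(classifyVariantType("A", "G"), "SNP")
  expect_equal(classifyVariantType("ATTTCTTTGA", "A"), "InDel")
  expect_error(classifyVariantType("A", ""), "empty allele")
  ## 20-variant fixture against a character-length oracle
  set.seed(42)
  bases <- c("A", "C", "G", "T")
  ref <- replicate(20, paste(sample(bases, sample(1:6, 1),
                                    replace = TRUE), collapse = ""))
  alt <- replicate(20, paste(sample(bases, sample(1:6, 1),
                                    replace = TRUE), collapse = ""))
  oracle <- ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNP", "InDel")
  expect_identical(classifyVariantType(ref, alt), oracle)
})

test_that("hard filter: strict inequalities, absent annotations pass", {
  mkSnp <- function(...) {
    gd <- toyGenotypeData(matrix(c(0L, 1L, 2L, 1L), 1, 4),
                          sex = c("F", "F", "M", "M"))
    gr <- SummarizedExperiment::rowRanges(gd)
    ann <- list(...)
    for (k in names(ann)) S4Vectors::mcols(gr)[[k]] <- ann[[k]]
    SummarizedExperiment::rowRanges(gd) <- gr
    gd
  }
  ## QD below 2 fails even with every other annotation passing
  expect_false(hardFilter(mkSnp(QD = 1.5, FS = 10, MQ = 55, SOR = 1,
                                ReadPosRankSum = 0, MQRankSum = 0)))
  ## exact boundary values all pass (comparisons are strict)
  expect_true(hardFilter(mkSnp(QD = 2.0, FS = 60.0, MQ = 40.0, SOR = 3.0,
                               ReadPosRankSum = -8.0,
                               MQRankSum = -12.5)))
  ## absent annotations never trigger failure
  expect_true(hardFilter(mkSnp(QD = 10)))
  expect_true(hardFilter(toyGenotypeData(matrix(0:1, 1, 2))))
})

test_that("site filter retains by MAF, depth and missingness; defaults match the standard thresholds", {
  ## (0,0,0,1) over 4 samples: alt frequency 1/8 = 0.125 >= 0.05 -> kept;
  ## monomorphic site removed; verified by direct allele counting
  d <- rbind(c(0L, 0L, 0L, 1L), c(0L, 0L, 0L, 0L))
  gd <- toyGenotypeData(d)
  kept <- siteFilter(gd)
  expect_equal(nrow(kept), 1)
  expect_equal(variantInfo(kept)$pos, variantInfo(gd)$pos[1])
  expect_equal(sum(d[1, ]) / 8, 0.125)
  expect_identical(formals(siteFilter)$minMaf, 0.05)
  expect_identical(formals(siteFilter)$minMeanDepth, 3)
  expect_identical(formals(siteFilter)$maxMissing, 0.25)
  ## depth criterion: mean depth below 3 drops the site
  gdDeep <- toyGenotypeData(rbind(c(0L, 1L, 1L, 1L)),
                            depth = matrix(c(1, 2, 1, 2), 1))
  expect_equal(nrow(siteFilter(gdDeep)), 0)
  ## missingness: 2/4 missing > 0.25 drops the site
  gdMiss <- toyGenotypeData(rbind(c(0L, 1L, NA, NA)))
  expect_equal(nrow(siteFilter(gdMiss)), 0)
  expect_error(siteFilter(gd[, 0]), "zero-sample")
})

test_that("site filter is idempotent, order-preserving, and bounds retained MAF", {
  sim <- simulatePopulation(simParams(
    nMales = 20, nFemales = 20, nSnps = 400, nIndels = 100,
    missingRate = 0.05, seed = 13))
  f1 <- siteFilter(sim$genotypes)
  f2 <- siteFilter(f1)
  expect_identical(dosage(f1), dosage(f2))
  ids <- variantInfo(sim$genotypes)$variant_id
  expect_identical(variantInfo(f1)$variant_id,
                   ids[ids %in% variantInfo(f1)$variant_id])
  d <- dosage(f1)
  f <- rowSums(d, na.rm = TRUE) / (2 * rowSums(!is.na(d)))
  maf <- pmin(f, 1 - f)
  expect_true(all(maf >= 0.05 & maf <= 0.5))
})

test_that("a hand-written VCF fixture is transcribed exactly", {
  vcf <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1,length=100000>",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2\ts3",
    "chr1\t100\tv1\tA\tG\t.\t.\tQD=25\tGT\t0/0\t0/1\t1/1",
    "chr1\t250\tv2\tATT\tA\t.\t.\tQD=12\tGT\t0/1\t./.\t0/0",
    "chr1\t300\tv3\tC\tCGGG\t.\t.\t.\tGT\t1/1\t1/1\t0/1",
    "chr1\t450\tv4\tT\tA\t.\t.\tQD=3\tGT\t0|1\t0/0\t./1",
    "chr1\t500\tv5\tG\tC\t.\t.\t.\tGT\t0/0\t0/0\t0/0")
  f <- tempfile(fileext = ".vcf")
  writeLines(vcf, f)
  gd <- readVCF(f)
  expect_equal(nrow(gd), 5)
  ## hand transcription of every genotype; half-missing ./1 is missing
  expect_identical(unname(dosage(gd)),
                   matrix(c(0L, 1L, 2L,
                            1L, NA, 0L,
                            2L, 2L, 1L,
                            1L, 0L, NA,
                            0L, 0L, 0L), 5, 3, byrow = TRUE))
  expect_identical(variantType(gd), c("SNP", "InDel", "InDel", "SNP",
                                      "SNP"))
  expect_equal(variantInfo(gd)$QD, c(25, 12, NA, 3, NA))
})

test_that("VCF reading validates structure and reports line numbers", {
  f <- tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\t100\tv1\tA\tG\t.\t.\t.\tGT"), f)
  expect_error(readVCF(f), "line 3")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1",
               "chr1\tXX\tv1\tA\tG\t.\t.\t.\tGT\t0/0"), f)
  expect_error(readVCF(f), "POS")
  ## a header-only VCF yields a zero-variant object
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1"),
             f)
  expect_equal(nrow(readVCF(f)), 0)
})

test_that("phenotype table round-trips and is validated", {
  ph <- data.frame(sample_id = c("a", "b"), sex = c("F", "M"))
  f <- tempfile(fileext = ".tsv")
  writePhenotypeTable(ph, f)
  expect_identical(readPhenotypeTable(f), ph)
  writeLines("sample_id\tsex\na\tX", f)
  expect_error(readPhenotypeTable(f), "sex")
})
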