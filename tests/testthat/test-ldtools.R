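test_that("pairwise r2: identity, monomorphic flag, and hand-computed value", {
  expect_equal(pairwiseR2(c(0, 1, 2, 0, 2), c(0, 1, 2, 0, 2)), 1)
  flagged <- pairwiseR2(c(1, 1, 1, 1), c(0, 1, 2, 0))
  expect_true(is.na(flagged))
  expect_match(attr(flagged, "reason"), "monomorphic")
  expect_error(pairwiseR2(c(0, 1), c(0, 1, 2)), "length")
  ## hand-computed Pearson correlation squared
  d1 <- c(0, 1, 2, 0, 2); d2 <- c(0, 1, 1, 0, 2)
  x <- d1 - mean(d1); y <- d2 - mean(d2)
  oracle <- (sum(x * y) / sqrt(sum(x^2) * sum(y^2)))^2
  expect_equal(pairwiseR2(d1, d2), oracle, tolerance = 1e-10)
  ## symmetry
  expect_equal(pairwiseR2(d1, d2), pairwiseR2(d2, d1))
})

test_that("decay curve: single-pair bin, half-decay at <= boundary, sample-order invariance", {
  ## bin1 holds an r2=1 pair, bin2 an exact r2=0.5 pair: the half-decay
  ## bin is the one whose mean EQUALS max/2 (<=, not <)
  d <- rbind(a1 = c(0L, 1L, 1L, 2L),
             a2 = c(0L, 1L, 1L, 2L),
             b1 = c(0L, 1L, 1L, 2L),
             b2 = c(0L, 1L, 0L, 1L))
  gd <- toyGenotypeData(d, pos = c(100L, 110L, 1000L, 1150L))
  ld <- ldDecayCurve(gd, maxDist = 200, binSize = 100)
  expect_equal(nrow(ld@curve), 2)
  expect_equal(ld@curve$mean_r2, c(1, 0.5))
  expect_equal(ld@maxR2, 1)
  expect_equal(ld@halfDecayDist, 150.5)
  expect_equal(ld@r2AtHalf, 0.5)
  ## two linked loci at distance 3000: one occupied bin, mean = pairwise r2
  gd2 <- toyGenotypeData(d[c(1, 4), ], pos = c(1000L, 4000L))
  ld2 <- ldDecayCurve(gd2, maxDist = 5000, binSize = 500)
  expect_equal(nrow(ld2@curve), 1)
  expect_equal(ld2@curve$mean_r2, pairwiseR2(d[1, ], d[4, ]))
  ## invariant to sample order
  perm <- c(3, 1, 4, 2)
  ld3 <- ldDecayCurve(toyGenotypeData(d[, perm],
                                      pos = c(100L, 110L, 1000L, 1150L)),
                      maxDist = 200, binSize = 100)
  expect_equal(ld3@curve, ld@curve)
  expect_error(ldDecayCurve(gd, maxDist = 5), "no eligible")
})

test_that("marker sufficiency bound is round(G/d) and non-increasing in d", {
  expect_equal(markerSufficiency(939190000, 5844)$n_required, 160710)
  expect_equal(markerSufficiency(5844, 5844)$n_required, 1)
  expect_equal(markerSufficiency(1e6, 1e4)$n_required, 100)
  expect_error(markerSufficiency(100, 0), "> 0")
  ds <- c(1000, 2000, 5000, 10000)
  ns <- vapply(ds, function(d) markerSufficiency(1e8, d)$n_required, 0)
  expect_true(all(diff(ns) <= 0))
})

test_that("lead windows: clamping, tie-break, and a brute-force clustering oracle", {
  mk <- function(pos, p, chrom = "chr1")
    data.frame(variant_id = paste0(chrom, "_", pos), chrom = chrom,
               pos = pos, p = p, tested = TRUE, significant = TRUE)
  ## clamping at chromosome start
  w <- extractLeadWindows(mk(1000, 1e-8), flank = 5844,
                          chromLengths = c(chr1 = 1e6))
  expect_equal(c(w$window_start, w$window_end), c(1, 6844))
  ## equal p 100 bp apart: one cluster, leftmost is lead
  w2 <- extractLeadWindows(mk(c(5000, 5100), c(1e-6, 1e-6)),
                           flank = 1000)
  expect_equal(nrow(w2), 1)
  expect_equal(w2$lead_pos, 5000)
  ## 30-variant fixture vs a brute-force oracle
  set.seed(77)
  pos <- sort(sample.int(1e5, 30))
  res <- mk(pos, runif(30, 1e-10, 1e-4))
  minGap <- 2000
  w3 <- extractLeadWindows(res, flank = 2000, minGap = minGap)
  ## oracle: walk positions, break clusters at gaps >= minGap, lead =
  ## min p then leftmost
  grp <- cumsum(c(1, diff(pos) >= minGap))
  oracleLeads <- vapply(split(seq_along(pos), grp), function(ii) {
    ii[order(res$p[ii], pos[ii])][1]
  }, 0L)
  expect_equal(w3$lead_pos, pos[oracleLeads])
  expect_equal(w3$lead_p, res$p[oracleLeads])
  expect_equal(sum(w3$n_variants), 30)
  expect_error(extractLeadWindows(mk(1, 0.5)[0, ]), "empty")
})

test_that("gene assignment: inclusive 1 bp overlap and an exhaustive interval oracle", {
  win <- data.frame(cluster = 1:2, chrom = c("chr1", "chr2"),
                    lead_id = c("L1", "L2"), lead_pos = c(5000, 8000),
                    lead_p = c(1e-9, 1e-8), n_variants = c(3, 1),
                    window_start = c(4000, 7000),
                    window_end = c(6000, 9000))
  genes <- data.frame(
    chrom = c("chr1", "chr1", "chr1", "chr2"),
    start = c(6000, 6001, 100, 8999),
    end   = c(6500, 6500, 300, 9500),
    gene_id = c("edge_in", "edge_out", "far", "tail_in"))
  got <- genesInWindows(win, genes)
  expect_setequal(got$gene_id, c("edge_in", "tail_in"))
  expect_equal(got$lead_ids[got$gene_id == "edge_in"], "L1")
  ## 50-gene random fixture vs exhaustive overlap oracle
  set.seed(5)
  g50 <- data.frame(chrom = sample(c("chr1", "chr2"), 50, TRUE),
                    start = sample.int(2e4, 50))
  g50$end <- g50$start + sample.int(3000, 50)
  g50$gene_id <- paste0("g", 1:50)
  win2 <- data.frame(cluster = 1:3, chrom = c("chr1", "chr1", "chr2"),
                     lead_id = paste0("L", 1:3),
                     lead_pos = c(2000, 9000, 15000),
                     lead_p = rep(1e-8, 3), n_variants = 1,
                     window_start = c(1500, 8500, 14000),
                     window_end = c(2500, 9500, 16000))
  oracle <- vapply(seq_len(50), function(i) any(
    win2$chrom == g50$chrom[i] & g50$start[i] <= win2$window_end &
      g50$end[i] >= win2$window_start), TRUE)
  expect_setequal(genesInWindows(win2, g50)$gene_id, g50$gene_id[oracle])
  ## empty interface
  expect_equal(nrow(genesInWindows(win[0, ], genes)), 0)
})

test_that("within-SDR pairs show stronger LD than SDR-autosome pairs", {
  sim <- simulatePopulation(simParams(
    nMales = 250, nFemales = 250, nChromosomes = 2, chromLength = 1e5,
    sdrInterval = c(4e4, 6e4), nSnps = 80, nIndels = 0,
    genotypingErrorRate = 0.05, missingRate = 0, seed = 55))
  d <- dosage(sim$genotypes)
  tr <- sim$truth
  sdr <- head(which(tr$sex_linked), 8)
  auto <- head(which(tr$chrom == "chr2"), 8)
  expect_gte(length(sdr), 2)
  within <- outer(sdr, sdr, Vectorize(function(i, j)
    if (i < j) pairwiseR2(d[i, ], d[j, ]) else NA))
  across <- outer(sdr, auto, Vectorize(function(i, j)
    pairwiseR2(d[i, ], d[j, ])))
  expect_gt(mean(within, na.rm = TRUE), mean(across, na.rm = TRUE))
})

test_that("windows convert to BED 0-based half-open coordinates", {
  win <- data.frame(chrom = "chr1", window_start = 101, window_end = 200,
                    lead_id = "L1")
  bed <- windowsToBed(win)
  expect_equal(bed$start, 100)
  expect_equal(bed$end, 200)
})
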