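## Pairwise composite r2, LD decay, marker sufficiency, lead-SNP windows,
## and interval-based gene assignment.

#' Composite linkage disequilibrium r-squared between two sites
#'
#' Squared Pearson correlation of genotype dosages over the samples
#' non-missing at both sites (composite LD: no phasing required).
#'
#' @param d1,d2 Aligned dosage vectors (0/1/2/`NA`).
#' @return r-squared, or `NA` (with the reason as an attribute) when fewer
#'   than two complete pairs exist or either site is monomorphic among
#'   complete pairs.
#' @examples
#' pairwiseR2(c(0, 1, 2, 0, 2), c(0, 1, 1, 0, 2))
#' @export
pairwiseR2 <- function(d1, d2) {
  if (length(d1) != length(d2)) stop("dosage vectors differ in length")
  cc <- !is.na(d1) & !is.na(d2)
  if (sum(cc) < 2)
    return(structure(NA_real_, reason = "fewer than 2 complete pairs"))
  x <- d1[cc]; y <- d2[cc]
  if (var(x) == 0 || var(y) == 0)
    return(structure(NA_real_, reason = "monomorphic among complete pairs"))
  cor(x, y)^2
}

#' Binned LD decay curve and half-decay distance
#'
#' Computes r-squared for every intra-chromosomal site pair separated by at
#' most `maxDist` bp, bins pairs by distance, and takes the mean r-squared
#' per bin. The half-decay distance is the midpoint of the first (smallest
#' distance) bin whose mean r-squared is at or below half the maximum
#' binned mean. Pairs across chromosomes are excluded; undefined pairwise
#' values (monomorphic sites) are dropped.
#'
#' @param gd A [GenotypeData-class] object (positions sorted within
#'   chromosome).
#' @param maxDist Maximum pair distance in bp.
#' @param binSize Bin width in bp.
#' @return An [LDDecayCurve-class] object.
#' @export
ldDecayCurve <- function(gd, maxDist = 3e5, binSize = 100) {
  vi <- variantInfo(gd)
  d <- dosage(gd)
  dist <- list(); r2 <- list()
  for (ch in unique(vi$chrom)) {
    idx <- which(vi$chrom == ch)
    if (length(idx) < 2) next
    idx <- idx[order(vi$pos[idx])]
    ps <- vi$pos[idx]
    ## dosage correlation matrix per chromosome (pairwise complete obs);
    ## NA where a site is monomorphic among complete pairs
    C <- suppressWarnings(
      cor(t(d[idx, , drop = FALSE]), use = "pairwise.complete.obs"))^2
    pr <- which(upper.tri(C), arr.ind = TRUE)
    pd <- abs(ps[pr[, 2]] - ps[pr[, 1]])
    keep <- pd <= maxDist & pd > 0 & is.finite(C[pr])
    dist[[ch]] <- pd[keep]
    r2[[ch]] <- C[pr][keep]
  }
  dist <- unlist(dist, use.names = FALSE)
  r2 <- unlist(r2, use.names = FALSE)
  if (!length(r2)) stop("no eligible intra-chromosomal pairs within maxDist")
  bin <- floor((dist - 1) / binSize)
  agg <- tapply(r2, bin, mean)
  cnt <- tapply(r2, bin, length)
  bi <- as.integer(names(agg))
  curve <- data.frame(bin_start = bi * binSize + 1,
                      bin_end = (bi + 1) * binSize,
                      bin_mid = bi * binSize + (binSize + 1) / 2,
                      n_pairs = as.integer(cnt),
                      mean_r2 = as.numeric(agg))
  curve <- curve[order(curve$bin_start), , drop = FALSE]
  rownames(curve) <- NULL
  maxR2 <- max(curve$mean_r2)
  hit <- which(curve$mean_r2 <= maxR2 / 2 + 1e-12)
  if (length(hit)) {
    hd <- curve$bin_mid[hit[1]]
    rh <- curve$mean_r2[hit[1]]
  } else {
    hd <- NA_real_; rh <- NA_real_
  }
  new("LDDecayCurve", curve = curve, maxR2 = maxR2,
      halfDecayDist = hd, r2AtHalf = rh)
}

#' Marker count needed to tag a genome at the LD half-decay scale
#'
#' With LD informative out to the half-decay distance `d`, a genome of `G`
#' bp needs about `round(G / d)` evenly spaced markers for association
#' signals to be capturable anywhere.
#'
#' @param G Genome size in bp.
#' @param d Half-decay distance in bp.
#' @return List with `genome_size`, `half_decay`, `n_required`.
#' @examples
#' markerSufficiency(939190000, 5844)$n_required  # 160710
#' @export
markerSufficiency <- function(G, d) {
  if (d <= 0) stop("half-decay distance must be > 0")
  if (G < d) stop("genome size must be >= half-decay distance")
  list(genome_size = G, half_decay = d, n_required = round(G / d))
}

#' Cluster significant variants and extract lead-SNP windows
#'
#' Significant variants are clustered greedily along each chromosome:
#' consecutive significant variants closer than `minGap` bp join one
#' cluster. Each cluster's lead is its lowest-p variant (ties broken by
#' leftmost position), and the window is the lead position plus/minus
#' `flank` bp, clamped to `[1, chromosome length]`.
#'
#' @param res Thresholded result table from [applyThreshold()].
#' @param flank Flank size in bp on each side of the lead (the targeted
#'   study used the LD half-decay distance, 5844 bp).
#' @param minGap Clustering gap in bp; defaults to `flank` so clusters merge
#'   when their windows would overlap.
#' @param chromLengths Optional named vector of chromosome lengths for
#'   right-side clamping.
#' @return `data.frame` with `cluster`, `chrom`, `lead_id`, `lead_pos`,
#'   `lead_p`, `n_variants`, `window_start`, `window_end` (1-based
#'   inclusive).
#' @export
extractLeadWindows <- function(res, flank = 5844, minGap = flank,
                               chromLengths = NULL) {
  sig <- res[!is.na(res$significant) & res$significant, , drop = FALSE]
  if (nrow(sig) == 0) stop("significant set is empty")
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  out <- list()
  cl <- 0L
  for (ch in unique(sig$chrom)) {
    s <- sig[sig$chrom == ch, , drop = FALSE]
    grp <- cumsum(c(1, diff(s$pos) >= minGap))
    for (g in unique(grp)) {
      cl <- cl + 1L
      sg <- s[grp == g, , drop = FALSE]
      lead <- sg[order(sg$p, sg$pos), , drop = FALSE][1, ]
      lo <- max(1, lead$pos - flank)
      hi <- lead$pos + flank
      if (!is.null(chromLengths) && ch %in% names(chromLengths))
        hi <- min(hi, chromLengths[[ch]])
      out[[cl]] <- data.frame(cluster = cl, chrom = ch,
                              lead_id = lead$variant_id,
                              lead_pos = lead$pos, lead_p = lead$p,
                              n_variants = nrow(sg),
                              window_start = lo, window_end = hi,
                              stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Genes overlapping candidate windows
#'
#' A gene is a candidate iff its interval (1-based inclusive) overlaps any
#' lead window by at least one bp. Each reported gene is annotated with its
#' supporting lead variant(s); genes hit by several windows appear once.
#'
#' @param windows Window table from [extractLeadWindows()].
#' @param geneTable `data.frame(chrom, start, end, gene_id)`.
#' @return `data.frame(gene_id, chrom, start, end, lead_ids)` with
#'   `lead_ids` a comma-joined list of supporting leads.
#' @export
genesInWindows <- function(windows, geneTable) {
  if (nrow(windows) == 0 || nrow(geneTable) == 0)
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_ids = character(0), stringsAsFactors = FALSE))
  w <- GRanges(windows$chrom,
               IRanges(windows$window_start, windows$window_end))
  g <- GRanges(geneTable$chrom, IRanges(geneTable$start, geneTable$end))
  ov <- findOverlaps(g, w)
  if (!length(ov))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      lead_ids = character(0), stringsAsFactors = FALSE))
  hits <- split(windows$lead_id[S4Vectors::subjectHits(ov)],
                S4Vectors::queryHits(ov))
  gi <- as.integer(names(hits))
  data.frame(gene_id = geneTable$gene_id[gi],
             chrom = geneTable$chrom[gi],
             start = geneTable$start[gi], end = geneTable$end[gi],
             lead_ids = vapply(hits, function(x)
               paste(unique(x), collapse = ","), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Convert 1-based inclusive windows to BED (0-based half-open)
#'
#' @param windows Window table from [extractLeadWindows()].
#' @param path Optional output path.
#' @return `data.frame(chrom, start, end, name)` in BED coordinates.
#' @export
windowsToBed <- function(windows, path = NULL) {
  bed <- data.frame(chrom = windows$chrom,
                    start = windows$window_start - 1L,
                    end = windows$window_end,
                    name = windows$lead_id, stringsAsFactors = FALSE)
  if (!is.null(path))
    write.table(bed, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  bed
}
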