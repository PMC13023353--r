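## InDel marker screening, gel band-pattern prediction, and validation on
## independent populations.

.indelConcordance <- function(g, hetero) {
  ## g: dosage vector; hetero: logical per sample (heterogametic sex)
  gH <- g[hetero]; gO <- g[!hetero]
  gH <- gH[!is.na(gH)]; gO <- gO[!is.na(gO)]
  if (!length(gH) || !length(gO))
    return(list(concordance = NA_real_, hom_dosage = NA_integer_))
  homTab <- table(factor(gO[gO != 1L], levels = c(0, 2)))
  homDosage <- if (sum(homTab) == 0) 0L
               else as.integer(names(homTab)[which.max(homTab)])
  matches <- sum(gH == 1L) + sum(gO == homDosage)
  list(concordance = matches / (length(gH) + length(gO)),
       hom_dosage = homDosage)
}

#' Screen InDels for sex-linked PCR marker candidates
#'
#' A candidate InDel has an allele length difference strictly greater than
#' `minLengthDiff` bp and a segregation pattern in which the heterogametic
#' sex is heterozygous while the homogametic sex is homozygous for its
#' modal allele, in at least `minConcordance` of non-missing calls.
#' Candidates are ranked by concordance (descending), then length
#' difference (descending), then chromosome and position, so the output is
#' stable under input reordering.
#'
#' @param gd A [GenotypeData-class] object with sample sexes.
#' @param minLengthDiff Minimum allele length difference, exclusive
#'   (default 8: "longer than 8 bp" read strictly, so 9 bp and up).
#' @param minConcordance Minimum fraction of sex-concordant calls.
#' @param sexSystem `"XY"`, `"ZW"`, or `"auto"` (score both orientations
#'   and keep the better one per variant).
#' @return `data.frame` with `variant_id`, `chrom`, `pos`, `ref_len`,
#'   `alt_len`, `length_diff`, `allele` (whether the alternate, sex-linked
#'   allele is a deletion or insertion relative to the reference),
#'   `orientation`, `hom_dosage`, `concordance`; zero rows when nothing
#'   qualifies.
#' @export
screenSexIndels <- function(gd, minLengthDiff = 8L, minConcordance = 0.9,
                            sexSystem = c("auto", "XY", "ZW")) {
  sexSystem <- match.arg(sexSystem)
  sx <- sampleSex(gd)
  if (!all(c("F", "M") %in% sx)) stop("both sexes must be present")
  idx <- which(variantType(gd) == "InDel")
  empty <- data.frame(variant_id = character(0), chrom = character(0),
                      pos = integer(0), ref_len = integer(0),
                      alt_len = integer(0), length_diff = integer(0),
                      allele = character(0), orientation = character(0),
                      hom_dosage = integer(0), concordance = numeric(0),
                      stringsAsFactors = FALSE)
  if (!length(idx)) return(empty)
  vi <- variantInfo(gd)[idx, , drop = FALSE]
  d <- dosage(gd)[idx, , drop = FALSE]
  refLen <- nchar(vi$ref)
  altLen <- nchar(vapply(strsplit(vi$alt, ",", fixed = TRUE),
                         `[`, "", 1L))
  lenDiff <- abs(refLen - altLen)
  rows <- lapply(seq_along(idx), function(i) {
    if (lenDiff[i] <= minLengthDiff) return(NULL)
    cands <- list()
    if (sexSystem %in% c("auto", "XY"))
      cands$XY <- .indelConcordance(d[i, ], sx == "M")
    if (sexSystem %in% c("auto", "ZW"))
      cands$ZW <- .indelConcordance(d[i, ], sx == "F")
    conc <- vapply(cands, function(x) x$concordance, 0)
    if (all(is.na(conc))) return(NULL)
    best <- names(cands)[which.max(conc)]
    if (conc[[best]] < minConcordance) return(NULL)
    data.frame(variant_id = vi$variant_id[i], chrom = vi$chrom[i],
               pos = vi$pos[i], ref_len = refLen[i], alt_len = altLen[i],
               length_diff = lenDiff[i],
               allele = if (altLen[i] < refLen[i]) "deletion"
                        else "insertion",
               orientation = best,
               hom_dosage = cands[[best]]$hom_dosage,
               concordance = conc[[best]], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(-out$concordance, -out$length_diff, out$chrom,
                   out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict per-sex gel band patterns for a sex-linked InDel marker
#'
#' The homogametic sex (females under XY, males under ZW), homozygous for
#' the non-linked allele, shows a single band at the reference amplicon
#' length. The heterogametic sex, heterozygous for the sex-linked allele,
#' shows two bands: the reference amplicon plus the amplicon shortened (for
#' a deletion allele) or lengthened (insertion) by the InDel length.
#'
#' @param ampliconRefLen Reference-allele amplicon length in bp; must
#'   exceed `lengthDiff`.
#' @param lengthDiff InDel allele length difference in bp.
#' @param allele `"deletion"` or `"insertion"` (the sex-linked allele
#'   relative to the reference).
#' @param sexSystem `"XY"` or `"ZW"`.
#' @param minBandDiff Smallest band difference the gel protocol resolves
#'   (default 8 bp on a 3% agarose-style setup).
#' @param maxAmplicon Largest amplicon scored as gel-friendly.
#' @return List with `bands_female`, `bands_male` (sorted bp vectors) and
#'   `resolvable`.
#' @examples
#' predictBandPattern(82, 9, "deletion", "XY")  # female 82; male 73, 82
#' @export
predictBandPattern <- function(ampliconRefLen, lengthDiff,
                               allele = c("deletion", "insertion"),
                               sexSystem = c("XY", "ZW"),
                               minBandDiff = 8L, maxAmplicon = 500L) {
  allele <- match.arg(allele)
  sexSystem <- match.arg(sexSystem)
  if (ampliconRefLen <= lengthDiff)
    stop("amplicon must be longer than the InDel length difference")
  linkedBand <- if (allele == "deletion") ampliconRefLen - lengthDiff
                else ampliconRefLen + lengthDiff
  hetBands <- sort(unique(c(ampliconRefLen, linkedBand)))
  homBands <- ampliconRefLen
  res <- lengthDiff >= minBandDiff && ampliconRefLen <= maxAmplicon
  if (sexSystem == "XY")
    list(bands_female = homBands, bands_male = hetBands,
         resolvable = res)
  else
    list(bands_female = hetBands, bands_male = homBands,
         resolvable = res)
}

#' Validate a marker candidate on independent populations
#'
#' For each validation cohort, every individual's predicted band pattern
#' (heterozygous = two bands, homozygous for the discovery-population modal
#' allele = one band) is compared with the pattern expected for its sex
#' under the candidate's orientation. Individuals with missing genotypes
#' are excluded from the denominator and counted.
#'
#' @param candidate One row of the [screenSexIndels()] table.
#' @param populations Named list of [GenotypeData-class] cohorts carrying
#'   sample sexes.
#' @return `data.frame` with one row per population: `population`, `n`,
#'   `n_missing`, `concordance`, `concordance_male`, `concordance_female`.
#' @export
validateMarker <- function(candidate, populations) {
  stopifnot(is.data.frame(candidate), nrow(candidate) == 1)
  hetSex <- if (candidate$orientation == "XY") "M" else "F"
  rows <- lapply(names(populations), function(nm) {
    gd <- populations[[nm]]
    vi <- variantInfo(gd)
    j <- match(candidate$variant_id, vi$variant_id)
    if (is.na(j))
      stop("marker ", candidate$variant_id,
           " absent from validation population '", nm, "'")
    g <- dosage(gd)[j, ]
    sx <- as.character(sampleSex(gd))
    ok <- !is.na(g) & !is.na(sx)
    match_i <- ifelse(sx == hetSex, g == 1L,
                      g == candidate$hom_dosage)
    conc <- function(sel) {
      sel <- sel & ok
      if (!any(sel)) NA_real_ else mean(match_i[sel])
    }
    data.frame(population = nm, n = sum(ok), n_missing = sum(!ok),
               concordance = conc(rep(TRUE, length(g))),
               concordance_male = conc(sx == "M"),
               concordance_female = conc(sx == "F"),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
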