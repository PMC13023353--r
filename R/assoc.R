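## Per-variant GLM association scan of sex on genotype dosage with
## principal-component covariates, genomic inflation, thresholds.

.P_MIN <- 1e-300   # minimum representable p; avoids -log10 infinities

#' Per-variant association scan (general linear model)
#'
#' For every variant, ordinary least squares of the 0/1 sex phenotype
#' (female = 0, male = 1) on an intercept, the supplied covariates and the
#' allele dosage, with a two-sided t test on the dosage coefficient -- the
#' model family of classical GWAS GLM implementations. Samples missing a
#' dosage are dropped for that site only (complete-case per site).
#' Monomorphic sites, sites collinear with the covariates, and sites with
#' too few complete cases are returned untested. When the matrix has no
#' missing dosages at all, the scan runs through a single residualisation
#' against the covariate block (Frisch-Waugh), which is algebraically
#' identical to the per-site fit. Underflowing p-values are clipped at
#' 1e-300.
#'
#' @param gd A [GenotypeData-class] object whose `colData` carries sex, or
#'   `phenotype` given explicitly.
#' @param covariates Optional numeric matrix (samples x covariates), e.g.
#'   from [selectCovariates()]; row order must match the samples.
#' @param phenotype Optional numeric 0/1 vector overriding `colData` sex.
#' @return `data.frame` with `variant_id`, `chrom`, `pos`, `effect`, `se`,
#'   `t`, `p`, `n_used`, `tested`.
#' @export
glmAssociation <- function(gd, covariates = NULL, phenotype = NULL) {
  d <- dosage(gd)
  if (is.null(phenotype)) {
    sx <- sampleSex(gd)
    if (all(is.na(sx))) stop("no sex phenotype available")
    y <- as.numeric(sx == "M")
  } else y <- as.numeric(phenotype)
  if (anyNA(y)) stop("phenotype contains missing values")
  n <- ncol(d)
  if (length(y) != n) stop("phenotype length does not match samples")
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != n)
      stop("covariate rows do not match samples")
  }
  Z <- cbind(Intercept = rep(1, n), covariates)

  vi <- variantInfo(gd)
  out <- data.frame(variant_id = vi$variant_id, chrom = vi$chrom,
                    pos = vi$pos, effect = NA_real_, se = NA_real_,
                    t = NA_real_, p = NA_real_, n_used = 0L,
                    tested = FALSE, stringsAsFactors = FALSE)
  if (nrow(d) == 0) return(out)

  if (!anyNA(d)) {
    qz <- qr(Z)
    kz <- qz$rank
    ey <- qr.resid(qz, y)
    E <- t(qr.resid(qz, t(d)))          # variants x samples, residualised
    ete <- rowSums(E^2)
    df <- n - kz - 1L
    testable <- ete > 1e-8 & df > 0
    beta <- rowSums(E * rep(ey, each = nrow(E))) / ete
    rss <- pmax(sum(ey^2) - beta^2 * ete, 0)
    se <- sqrt(rss / df / ete)
    tstat <- beta / se
    p <- pmax(2 * pt(-abs(tstat), df), .P_MIN)
    out$effect[testable] <- beta[testable]
    out$se[testable] <- pmax(se[testable], .P_MIN)
    out$t[testable] <- tstat[testable]
    out$p[testable] <- p[testable]
    out$n_used <- n
    out$tested <- testable
    return(out)
  }

  for (j in seq_len(nrow(d))) {
    cc <- !is.na(d[j, ])
    nj <- sum(cc)
    out$n_used[j] <- nj
    if (nj < 3) next
    g <- d[j, cc]
    if (var(g) == 0) next
    X <- cbind(Z[cc, , drop = FALSE], dosage = g)
    fit <- lm.fit(X, y[cc])
    co <- fit$coefficients
    if (is.na(co[["dosage"]])) next        # collinear with covariates
    df <- nj - fit$rank
    if (df <= 0) next
    rss <- sum(fit$residuals^2)
    rk <- fit$rank
    R <- qr.R(fit$qr)[seq_len(rk), seq_len(rk), drop = FALSE]
    xtxi <- chol2inv(R)
    piv <- fit$qr$pivot[seq_len(rk)]
    vc <- rep(NA_real_, ncol(X)); vc[piv] <- diag(xtxi)
    se <- sqrt(max(rss / df * vc[ncol(X)], 0))
    se <- max(se, .P_MIN)
    tstat <- co[["dosage"]] / se
    out$effect[j] <- co[["dosage"]]
    out$se[j] <- se
    out$t[j] <- tstat
    out$p[j] <- max(2 * pt(-abs(tstat), df), .P_MIN)
    out$tested[j] <- TRUE
  }
  out
}

#' Genomic inflation factor
#'
#' `lambda` = median of the 1-df chi-square statistics implied by the
#' p-values, divided by the 1-df chi-square median (0.4549364). Values near
#' 1 indicate controlled confounding; the conventional acceptable band is
#' 0.95 to 1.05.
#'
#' @param p Numeric vector of p-values (NAs ignored).
#' @return The inflation factor, a positive scalar.
#' @examples
#' genomicInflation(rep(0.5, 10))  # exactly 1
#' @export
genomicInflation <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) stop("no finite p-values")
  chisq <- qchisq(p, df = 1, lower.tail = FALSE)
  median(chisq) / qchisq(0.5, df = 1)
}

#' Flag significant variants
#'
#' `bonferroni`: p < alpha / N; `suggestive`: p < 1 / N; `fixed`:
#' p < `fixedP`. N counts tested variants only, and every comparison is
#' strict.
#'
#' @param res Result table from [glmAssociation()].
#' @param mode One of `"bonferroni"`, `"suggestive"`, `"fixed"`.
#' @param alpha Family-wise alpha for Bonferroni.
#' @param fixedP Cutoff when `mode = "fixed"`.
#' @return `res` with a logical `significant` column; the cutoff used is
#'   attached as `attr(, "threshold")`.
#' @export
applyThreshold <- function(res, mode = c("bonferroni", "suggestive",
                                         "fixed"),
                           alpha = 0.05, fixedP = NULL) {
  mode <- match.arg(mode)
  if (nrow(res) == 0) stop("empty result table")
  N <- sum(res$tested)
  thr <- switch(mode,
    bonferroni = alpha / N,
    suggestive = 1 / N,
    fixed = {
      if (is.null(fixedP)) stop("fixedP required when mode = 'fixed'")
      fixedP
    })
  res$significant <- res$tested & !is.na(res$p) & res$p < thr
  attr(res, "threshold") <- thr
  res
}

#' Export Manhattan and QQ plot tables
#'
#' @param res Result table from [glmAssociation()].
#' @param manhattanPath,qqPath Optional TSV output paths.
#' @return List with `manhattan` (`chrom`, `pos`, `neglog10p`) and `qq`
#'   (`expected`, `observed` p-value quantiles, expected quantile for rank
#'   i of N being i / (N + 1)).
#' @export
exportScan <- function(res, manhattanPath = NULL, qqPath = NULL) {
  tested <- res[res$tested & !is.na(res$p), , drop = FALSE]
  man <- data.frame(chrom = tested$chrom, pos = tested$pos,
                    neglog10p = -log10(tested$p))
  pSort <- sort(tested$p)
  N <- length(pSort)
  qq <- data.frame(expected = if (N) seq_len(N) / (N + 1) else numeric(0),
                   observed = pSort)
  if (!is.null(manhattanPath))
    write.table(man, manhattanPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(qqPath))
    write.table(qq, qqPath, sep = "\t", quote = FALSE, row.names = FALSE)
  list(manhattan = man, qq = qq)
}
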