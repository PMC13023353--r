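## Principal components of the genotype matrix and covariate selection.

#' Principal component analysis of genotype dosages
#'
#' Sites are mean-imputed (missing dosages replaced by the site mean over
#' non-missing calls), centred and standardised to unit variance, so the
#' decomposition is on the correlation scale and the Kaiser-style
#' "eigenvalue > 1" covariate rule is well defined. Eigenvalues are those of
#' the sample-by-sample matrix (1/p) X X-transpose of the standardised
#' dosage matrix X (n samples x p sites); they sum to n - 1 and average 1
#' over the non-null spectrum, so an eigenvalue above 1 marks a component
#' explaining more than the average standardised variance. Each score column
#' is oriented so that its largest-magnitude site loading is positive, which
#' makes signs deterministic.
#'
#' @param gd A [GenotypeData-class] object with at least 2 samples and one
#'   polymorphic site.
#' @param k Number of components to return; default `min(20, n - 1)`.
#' @return A list of class `PCAResult` with `eigenvalues` (descending),
#'   `scores` (samples x components, rownames = sample ids), `loadings_sign`
#'   fixed as documented, and `n_sites` used.
#' @export
genotypePCA <- function(gd, k = NULL) {
  d <- dosage(gd)
  n <- ncol(d)
  if (n < 2) stop("PCA needs at least 2 samples")
  X <- t(d)                                   # samples x sites
  mu <- colMeans(X, na.rm = TRUE)
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  sdv <- apply(X, 2, sd)
  poly <- sdv > 0
  if (!any(poly)) stop("all sites monomorphic: PCA undefined")
  X <- scale(X[, poly, drop = FALSE])
  p <- ncol(X)
  if (is.null(k)) k <- min(20L, n - 1L)
  k <- min(k, n - 1L, p)
  sv <- svd(X, nu = k, nv = k)
  ev <- sv$d^2 / p                            # all eigenvalues, sum = n - 1
  scores <- sv$u %*% diag(sv$d[seq_len(k)], k, k)
  ## deterministic sign: largest-|loading| positive per component
  for (j in seq_len(k)) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- colnames(gd)
  colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(eigenvalues = ev, scores = scores, n_sites = p),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("PCAResult:", nrow(x$scores), "samples,", x$n_sites, "sites,",
      ncol(x$scores), "components\n")
  cat("  top eigenvalues:",
      paste(sprintf("%.3f", head(x$eigenvalues, 5)), collapse = ", "), "\n")
  cat("  eigenvalues > 1:", sum(x$eigenvalues > 1), "\n")
  invisible(x)
}

#' Select principal-component covariates by the eigenvalue > 1 rule
#'
#' Returns, in order, the score columns whose eigenvalue exceeds 1 on the
#' correlation-type scale of [genotypePCA()]. An empty selection is allowed
#' (with a warning): the association scan then runs without population
#' structure covariates.
#'
#' @param pca A `PCAResult` from [genotypePCA()].
#' @return Numeric matrix (samples x selected components), possibly with
#'   zero columns.
#' @export
selectCovariates <- function(pca) {
  nSel <- sum(pca$eigenvalues > 1)
  nSel <- min(nSel, ncol(pca$scores))
  if (nSel == 0) {
    warning("no eigenvalue exceeds 1; returning zero covariates")
    return(pca$scores[, 0, drop = FALSE])
  }
  pca$scores[, seq_len(nSel), drop = FALSE]
}

#' Write PC covariates as a TSV (sample_id, PC1..PCk)
#'
#' @param covariates Matrix from [selectCovariates()].
#' @param path Output path.
#' @export
writeCovariates <- function(covariates, path) {
  df <- data.frame(sample_id = rownames(covariates), covariates,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
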