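## pca_outliers: PCA-based SNP outlier detection on allele frequencies.
##
## Each SNP's per-pool frequency profile is regressed on the first K
## principal-component score vectors of the pools x SNPs matrix; the
## standardized regression coefficients are the z-scores. Outliers are
## called by Mahalanobis distance of the z-vector against the covariance
## estimated from all SNPs, with chi-squared(K) p-values and
## Benjamini-Hochberg q-values.

#' Build a per-SNP minor-allele frequency matrix from pooled counts
#'
#' Sites are reduced to the two globally most frequent alleles; the
#' reported frequency is the globally minor allele's read fraction per
#' population (renormalized over the top two alleles). Sites monomorphic
#' across all pools, or with a population lacking top-two reads, are
#' excluded.
#'
#' @param x a `pooled_counts` object.
#' @param params a [subsample_params] object (subsampling + min_count
#'   filtering as elsewhere).
#' @return list with `freq` (SNPs x populations matrix), `chrom`, `pos`,
#'   `major`, `minor` allele vectors.
#' @export
build_freq_matrix <- function(x, params = subsample_params()) {
  sub <- subsample_sync(x, params)
  np <- n_pops(x)
  all_ok <- Reduce(`&`, lapply(sub, function(s) s$status == "ok"))
  mats <- lapply(sub, function(s) {
    apply_min_count(s$counts[all_ok, , drop = FALSE], params$min_count)
  })
  total <- Reduce(`+`, mats)
  ## top two alleles globally, per site
  ord <- t(apply(total, 1L, order, decreasing = TRUE))
  n_sites <- nrow(total)
  take <- function(m, j) m[cbind(seq_len(n_sites), j)]
  major_n <- take(total, ord[, 1L]); minor_n <- take(total, ord[, 2L])
  seg <- minor_n > 0L
  freq <- matrix(NA_real_, n_sites, np)
  for (p in seq_len(np)) {
    a <- take(mats[[p]], ord[, 1L]); b <- take(mats[[p]], ord[, 2L])
    freq[, p] <- ifelse(a + b > 0, b / (a + b), NA_real_)
  }
  keep <- seg & rowSums(is.na(freq)) == 0L
  bases <- colnames(mats[[1]])
  list(freq = freq[keep, , drop = FALSE],
       chrom = x$chrom[all_ok][keep], pos = x$pos[all_ok][keep],
       major = bases[ord[keep, 1L]], minor = bases[ord[keep, 2L]])
}

#' Per-SNP z-scores from a K-component PCA
#'
#' Columns of the pools x SNPs matrix are centered (and optionally scaled);
#' principal-component scores are taken from the SVD; each SNP's z-vector
#' is its standardized regression coefficients on the K score vectors,
#' using residual variance with df = n_pools - K.
#'
#' @param freq SNPs x populations frequency matrix (as from
#'   [build_freq_matrix]).
#' @param K number of components (default 2).
#' @param scale "none" (default) or "sd" to scale each SNP column to unit
#'   variance before the PCA.
#' @return SNPs x K matrix of z-scores.
#' @export
pca_zscores <- function(freq, K = 2L, scale = c("none", "sd")) {
  scale <- match.arg(scale)
  X <- t(freq)                      # pools x SNPs
  n <- nrow(X)
  if (n <= K + 1L) {
    warning(sprintf("pca_zscores: only %d pools for K = %d; the scan is weakly powered",
                    n, K))
  }
  if (n <= K) stop("pca_zscores: need more pools than components")
  X <- sweep(X, 2L, colMeans(X))
  if (scale == "sd") {
    s <- apply(X, 2L, stats::sd)
    s[s == 0] <- 1
    X <- sweep(X, 2L, s, "/")
  }
  if (all(X == 0)) stop("pca_zscores: zero-variance matrix")
  sv <- svd(X, nu = K, nv = 0L)
  if (sum(sv$d > 1e-12) < K) stop("pca_zscores: matrix rank below K")
  U <- sv$u[, seq_len(K), drop = FALSE]     # orthonormal score vectors
  B <- crossprod(U, X)                       # K x SNPs coefficients
  df <- n - 1L - K                           # centering consumes 1 df
  if (df >= 1L) {
    rss <- colSums(X^2) - colSums(B^2)
    rss[rss < 0] <- 0
    sigma <- sqrt(rss / df)
    Z <- t(B) / sigma
    Z[!is.finite(Z)] <- 0
  } else {
    ## n = K + 1 pools: the fit is exact and no residual variance exists;
    ## fall back to raw coefficients (the downstream Mahalanobis
    ## covariance absorbs their scale)
    Z <- t(B)
  }
  colnames(Z) <- paste0("z", seq_len(K))
  Z
}

#' Mahalanobis distances and chi-squared p-values for z-score vectors
#'
#' `d2 = z' Sigma^-1 z` with Sigma estimated from all SNPs; p-values are
#' the upper tail of the chi-squared distribution with K degrees of
#' freedom. An optional genomic inflation factor rescaling (`gif`) and a
#' robust (median-based) covariance are available but off by default.
#'
#' @param zscores SNPs x K matrix from [pca_zscores].
#' @param robust use median-based scaling of the covariance diagonal.
#' @param gif divide d2 by the genomic inflation factor
#'   (median(d2)/qchisq(0.5, K)) before the chi-squared transform.
#' @return data.table with d2, p_value, q_value (BH).
#' @export
mahalanobis_pvalues <- function(zscores, robust = FALSE, gif = FALSE) {
  Z <- as.matrix(zscores)
  K <- ncol(Z)
  Sigma <- crossprod(Z) / (nrow(Z) - 1L)   # covariance about the origin
  if (robust) {
    sc <- apply(Z, 2L, function(z) stats::mad(z, center = 0))
    R <- stats::cov2cor(Sigma)
    Sigma <- R * tcrossprod(sc)
  }
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-12 * max(ev)) {
    stop("mahalanobis_pvalues: singular z-score covariance (rank ",
         sum(ev > 1e-12 * max(ev)), " < ", K, ")")
  }
  d2 <- stats::mahalanobis(Z, center = rep(0, K), cov = Sigma)
  if (gif) d2 <- d2 / (stats::median(d2) / stats::qchisq(0.5, df = K))
  p <- stats::pchisq(d2, df = K, lower.tail = FALSE)
  p[p == 0] <- .Machine$double.xmin
  data.table::data.table(d2 = d2, p_value = p, q_value = fdr_correct(p))
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return q-values in the original order.
#' @export
fdr_correct <- function(pvalues) {
  p <- as.numeric(pvalues)
  m <- length(p)
  if (!m) return(numeric())
  if (any(!is.na(p) & (p <= 0 | p > 1))) stop("fdr_correct: p-values must be in (0, 1]")
  ord <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[ord] * m / seq(m, 1)))
  q[order(ord)]
}

#' Full PCA outlier scan
#'
#' @param x a `pooled_counts` object.
#' @param params a [subsample_params] object.
#' @param K number of principal components (default 2).
#' @param scale,robust,gif see [pca_zscores] and [mahalanobis_pvalues].
#' @return data.table: chrom, pos, d2, p_value, q_value (Manhattan-ready).
#' @export
pca_outlier_scan <- function(x, params = subsample_params(), K = 2L,
                             scale = "none", robust = FALSE, gif = FALSE) {
  fm <- build_freq_matrix(x, params)
  Z <- pca_zscores(fm$freq, K = K, scale = scale)
  res <- mahalanobis_pvalues(Z, robust = robust, gif = gif)
  data.table::data.table(chrom = fm$chrom, pos = fm$pos, res)
}
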