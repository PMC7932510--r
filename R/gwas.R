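# Mixed-model genome-wide association scan for inbred line panels:
# covariate adjustment, genomic relationship matrix, EMMA-style REML null
# fit, P3D/exact single-marker generalized least squares, MAF and
# significance filters, variant site classification and gene nomination.

#' Construct a line panel
#'
#' Genotypes of fully inbred (homozygous) lines are coded as the
#' minor-allele indicator: 0 = homozygous major, 1 = homozygous minor,
#' `NA` = missing. MAF is the folded mean of the non-missing indicator.
#'
#' @param geno Numeric matrix, lines x variants, entries in \{0, 1, NA\}.
#' @param variants Data frame with one row per variant; columns `id`,
#'   `chrom`, `pos` (1-based), `ref`, `minor`, `major`, `type` (`SNP`,
#'   `INS` or `DEL`). Minimal default metadata is synthesized when omitted.
#' @return A `line_panel` object.
#' @export
line_panel <- function(geno, variants = NULL) {
  geno <- as.matrix(geno)
  if (!all(geno %in% c(0, 1, NA))) {
    stop("genotypes must be 0/1 minor-allele indicators (inbred lines)")
  }
  if (is.null(rownames(geno))) rownames(geno) <- paste0("line_", seq_len(nrow(geno)))
  if (is.null(colnames(geno))) colnames(geno) <- paste0("v", seq_len(ncol(geno)))
  if (is.null(variants)) {
    variants <- data.frame(id = colnames(geno), chrom = "chr1",
                           pos = seq_len(ncol(geno)), ref = "A", minor = "T",
                           major = "A", type = "SNP",
                           stringsAsFactors = FALSE)
  }
  stopifnot(nrow(variants) == ncol(geno))
  m <- colMeans(geno, na.rm = TRUE)
  structure(list(geno = geno, variants = variants,
                 lines = rownames(geno), maf = pmin(m, 1 - m)),
            class = "line_panel")
}

#' @export
print.line_panel <- function(x, ...) {
  cat(sprintf("line_panel: %d lines x %d variants (MAF %.3f .. %.3f)\n",
              nrow(x$geno), ncol(x$geno), min(x$maf), max(x$maf)))
  invisible(x)
}

#' Adjust line phenotypes for Wolbachia and inversion covariates
#'
#' Ordinary least squares of the line phenotype on an intercept plus the
#' covariate columns (Wolbachia infection status and inversion genotypes);
#' the residuals are the adjusted phenotype used by the association scan.
#' Collinear covariate columns are dropped with a warning; lines with
#' missing covariates are dropped with a warning.
#'
#' @param y Named numeric vector of line phenotypes.
#' @param covariates Data frame of numeric covariates, one row per line
#'   (rownames or a `line_id` column matching `names(y)`).
#' @return Named numeric vector of residuals.
#' @export
adjust_covariates <- function(y, covariates) {
  if ("line_id" %in% names(covariates)) {
    rownames(covariates) <- covariates$line_id
    covariates$line_id <- NULL
  }
  if (is.null(names(y))) names(y) <- rownames(covariates)[seq_along(y)]
  cv <- covariates[match(names(y), rownames(covariates)), , drop = FALSE]
  ok <- stats::complete.cases(cv) & !is.na(y)
  if (any(!ok)) {
    warning(sprintf("%d lines dropped (missing phenotype or covariates)",
                    sum(!ok)))
  }
  dat <- data.frame(.y = y[ok], cv[ok, , drop = FALSE])
  fit <- stats::lm(.y ~ ., data = dat)
  if (anyNA(stats::coef(fit))) {
    warning("collinear covariate column(s) dropped: ",
            paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                  collapse = ", "))
  }
  r <- stats::residuals(fit)
  names(r) <- names(y)[ok]
  r
}

#' Filter variants by minor allele frequency
#'
#' Keeps variants with MAF strictly greater than the threshold.
#'
#' @param panel A `line_panel`.
#' @param threshold MAF threshold (default 0.05, strict inequality).
#' @return The filtered `line_panel`.
#' @export
maf_filter <- function(panel, threshold = 0.05) {
  keep <- which(panel$maf > threshold)
  line_panel(panel$geno[, keep, drop = FALSE],
             panel$variants[keep, , drop = FALSE])
}

#' Genomic relationship matrix
#'
#' `K = Z Z' / m` over the m polymorphic variants, where Z holds the
#' per-variant standardized genotypes `(g - p) / sqrt(p (1 - p))` with
#' `p` the variant's minor-allele indicator mean. Missing genotypes are
#' mean-imputed per variant; monomorphic variants are skipped.
#'
#' @param panel A `line_panel`.
#' @return Symmetric lines x lines matrix.
#' @export
compute_grm <- function(panel) {
  g <- panel$geno
  if (ncol(g) < 2L) stop("need at least 2 variants for a GRM")
  p <- colMeans(g, na.rm = TRUE)
  if (anyNA(g)) {
    idx <- which(is.na(g), arr.ind = TRUE)
    g[idx] <- p[idx[, 2]]
  }
  poly <- p > 0 & p < 1
  g <- g[, poly, drop = FALSE]
  p <- p[poly]
  if (ncol(g) < 2L) stop("fewer than 2 polymorphic variants")
  z <- sweep(sweep(g, 2, p, "-"), 2, sqrt(p * (1 - p)), "/")
  k <- tcrossprod(z) / ncol(z)
  dimnames(k) <- list(panel$lines, panel$lines)
  (k + t(k)) / 2
}

reml_loglik_parts <- function(delta, s, xt, yt) {
  w <- s + delta
  p <- ncol(xt)
  xw <- xt / w
  xwx <- crossprod(xw, xt)
  beta <- solve(xwx, crossprod(xw, yt))
  r <- yt - xt %*% beta
  q <- sum(r^2 / w)
  df <- length(yt) - p
  sg <- q / df
  ll <- -0.5 * (df * log(2 * pi * sg) + df + sum(log(w)) +
                  determinant(xwx, logarithm = TRUE)$modulus[1])
  list(ll = ll, sigma2_g = sg, beta = beta, xwx = xwx, w = w)
}

#' REML fit of the polygenic null model
#'
#' Fits `Var(y) = sigma2_g K + sigma2_e I` with intercept-only fixed
#' effects by restricted maximum likelihood, using a single
#' eigendecomposition of K and one-dimensional optimization of the REML
#' log-likelihood in `delta = sigma2_e / sigma2_g` (coarse log-grid followed
#' by local refinement).
#'
#' @param y Numeric line phenotype (typically covariate-adjusted residuals).
#' @param K Genomic relationship matrix, same order as `y`.
#' @param X Fixed-effects design matrix (default intercept only).
#' @return List with `sigma2_g`, `sigma2_e`, `delta`, `loglik`, the
#'   eigendecomposition (`eigen`), and a `degenerate` flag (set when K is
#'   numerically the identity and the split is unidentifiable).
#' @export
fit_null_reml <- function(y, K, X = NULL) {
  n <- length(y)
  if (n < 10L) stop("need at least 10 lines for the REML fit")
  if (is.null(X)) X <- matrix(1, n, 1)
  eig <- eigen(K, symmetric = TRUE)
  s <- pmax(eig$values, 0)
  if (min(eig$values) < -1e-6) {
    warning("K has negative eigenvalues; clipped at 0")
  }
  degenerate <- stats::sd(s) < 1e-10
  if (degenerate) {
    return(list(sigma2_g = 0, sigma2_e = stats::var(y), delta = Inf,
                loglik = NA_real_, eigen = eig, degenerate = TRUE))
  }
  yt <- crossprod(eig$vectors, y)
  xt <- crossprod(eig$vectors, X)
  f <- function(ld) reml_loglik_parts(10^ld, s, xt, yt)$ll
  grid <- seq(-6, 6, by = 0.2)
  ll <- vapply(grid, f, 0)
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]
  hi <- grid[min(length(grid), i + 1L)]
  opt <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-6)
  delta <- 10^opt$maximum
  parts <- reml_loglik_parts(delta, s, xt, yt)
  list(sigma2_g = parts$sigma2_g, sigma2_e = delta * parts$sigma2_g,
       delta = delta, loglik = parts$ll, eigen = eig,
       degenerate = FALSE)
}

#' Single-marker mixed-model association scan
#'
#' Generalized least squares of the adjusted phenotype on an intercept plus
#' each variant's minor-allele indicator, with marker covariance
#' `V = sigma2_g K + sigma2_e I`. In the default P3D mode the variance
#' components are fixed at the null REML estimates; in `exact` mode they
#' are re-estimated by REML for every marker. The residual scale is
#' re-estimated per marker, and the Wald test uses the t reference with
#' n - 2 degrees of freedom, so the scan reduces exactly to ordinary
#' single-marker regression when `sigma2_g = 0`. Lines with a missing
#' genotype are dropped for that marker; markers monomorphic after the drop
#' are skipped.
#'
#' @param y Adjusted line phenotype, ordered as `panel$lines`.
#' @param panel A `line_panel` (typically MAF-filtered).
#' @param K Genomic relationship matrix; computed from `panel` when `NULL`.
#' @param mode `"p3d"` (default) or `"exact"`.
#' @param null_fit Optional result of [fit_null_reml()] to reuse.
#' @return Data frame with `variant_id`, `chrom`, `pos`, `maf`,
#'   `beta_minor`, `se`, `p_value`, sorted as the panel.
#' @export
association_scan <- function(y, panel, K = NULL, mode = c("p3d", "exact"),
                             null_fit = NULL) {
  mode <- match.arg(mode)
  if (is.null(K)) K <- compute_grm(panel)
  if (is.null(null_fit)) null_fit <- fit_null_reml(y, K)
  n <- length(y)
  G <- panel$geno
  res <- data.frame(variant_id = panel$variants$id,
                    chrom = panel$variants$chrom,
                    pos = panel$variants$pos,
                    maf = panel$maf,
                    beta_minor = NA_real_, se = NA_real_,
                    p_value = NA_real_, stringsAsFactors = FALSE)
  if (mode == "p3d") {
    eig <- null_fit$eigen
    s <- pmax(eig$values, 0)
    delta <- if (is.finite(null_fit$delta)) null_fit$delta else NULL
    if (is.null(delta) || null_fit$degenerate) {
      w <- rep(1, n)  # V proportional to I
    } else {
      w <- s + delta
    }
    U <- eig$vectors
    sw <- sqrt(w)
    yt <- crossprod(U, y)[, 1] / sw
    onet <- crossprod(U, rep(1, n))[, 1] / sw
    complete <- !apply(is.na(G), 2, any)
    if (any(complete)) {
      Gt <- crossprod(U, G[, complete, drop = FALSE]) / sw
      a11 <- sum(onet^2)
      b1 <- sum(onet * yt)
      yy <- sum(yt^2)
      a12 <- colSums(Gt * onet)
      a22 <- colSums(Gt^2)
      b2 <- colSums(Gt * yt)
      det <- a11 * a22 - a12^2
      mono <- apply(G[, complete, drop = FALSE], 2,
                    function(g) length(unique(g)) < 2L)
      det[mono] <- NA
      bg <- (a11 * b2 - a12 * b1) / det
      b0 <- (a22 * b1 - a12 * b2) / det
      rss <- pmax(yy - b0 * b1 - bg * b2, 0)
      df <- n - 2
      se <- sqrt(rss / df * a11 / det)
      tval <- bg / se
      res$beta_minor[complete] <- bg
      res$se[complete] <- se
      res$p_value[complete] <- 2 * stats::pt(-abs(tval), df)
    }
    # markers with missing genotypes: per-marker line drop
    for (j in which(!complete)) {
      keep <- !is.na(G[, j])
      g <- G[keep, j]
      if (length(unique(g)) < 2L) next
      Vk <- null_fit$sigma2_g * K[keep, keep] +
        null_fit$sigma2_e * diag(sum(keep))
      fit <- gls_marker(y[keep], g, Vk)
      res$beta_minor[j] <- fit$beta
      res$se[j] <- fit$se
      res$p_value[j] <- fit$p
    }
  } else {
    for (j in seq_len(ncol(G))) {
      keep <- !is.na(G[, j])
      g <- G[keep, j]
      if (length(unique(g)) < 2L) next
      X <- cbind(1, g)
      nf <- fit_null_reml(y[keep], K[keep, keep], X = X)
      V <- nf$sigma2_g * K[keep, keep] + nf$sigma2_e * diag(sum(keep))
      fit <- gls_marker(y[keep], g, V)
      res$beta_minor[j] <- fit$beta
      res$se[j] <- fit$se
      res$p_value[j] <- fit$p
    }
  }
  res
}

gls_marker <- function(y, g, V) {
  n <- length(y)
  X <- cbind(1, g)
  Vi <- solve(V)
  xvx <- crossprod(X, Vi %*% X)
  xvy <- crossprod(X, Vi %*% y)
  beta <- solve(xvx, xvy)
  r <- y - X %*% beta
  s2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - 2)
  covb <- s2 * solve(xvx)
  se <- sqrt(covb[2, 2])
  tval <- beta[2] / se
  list(beta = beta[2], se = se, p = 2 * stats::pt(-abs(tval), n - 2))
}

#' Filter association records at a nominal significance threshold
#'
#' @param records Scan results from [association_scan()] (or any data frame
#'   with a `p_value` column).
#' @param alpha Threshold (default 1e-5, strict inequality).
#' @return The significant subset, sorted by increasing p-value.
#' @export
significant_hits <- function(records, alpha = 1e-5) {
  hits <- records[!is.na(records$p_value) & records$p_value < alpha, ,
                  drop = FALSE]
  hits[order(hits$p_value), , drop = FALSE]
}

#' Genomic-control inflation factor
#'
#' Median association chi-square divided by its null median.
#'
#' @param p Vector of scan p-values.
#' @return Scalar lambda_GC.
#' @export
lambda_gc <- function(p) {
  p <- p[!is.na(p)]
  stats::median(stats::qchisq(p, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
}
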