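# Quantitative genetics: one-way ANOVA variance components and broad-sense
# heritability, Pearson correlation tests, chi-squared goodness of fit.

#' Broad-sense heritability from per-fly line data
#'
#' Method-of-moments (one-way random effects ANOVA) estimators: the error
#' variance is the within-line mean square, the among-line variance is
#' `(MS_between - MS_within) / n0` with `n0` the unbalanced-design effective
#' replicate count `(N - sum(n_i^2)/N) / (k - 1)`. A negative among-line
#' component is truncated to zero (flagged). Broad-sense heritability is
#' `H2 = sigma2_g / (sigma2_g + sigma2_e)`.
#'
#' @param line_id Line identifiers (one per observation).
#' @param value Phenotype values (one per fly).
#' @return A `variance_components` object: list with `sigma2_g`, `sigma2_e`,
#'   `H2`, `n_lines`, `n0`, `truncated`, and the ANOVA table (`anova`
#'   with df, SS, MS rows for among/within).
#' @export
variance_components <- function(line_id, value) {
  ok <- !is.na(value) & !is.na(line_id)
  line_id <- as.character(line_id)[ok]
  value <- value[ok]
  n_i <- table(line_id)
  if (length(n_i) < 2L) stop("need at least 2 lines")
  if (max(n_i) < 2L) stop("need replicates within at least one line")
  N <- length(value)
  k <- length(n_i)
  grand <- mean(value)
  means <- tapply(value, line_id, mean)
  n_i <- as.numeric(n_i[names(means)])
  ss_between <- sum(n_i * (means - grand)^2)
  ss_within <- sum((value - means[line_id])^2)
  df_between <- k - 1
  df_within <- N - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  n0 <- (N - sum(n_i^2) / N) / (k - 1)
  sigma2_g <- (ms_between - ms_within) / n0
  truncated <- sigma2_g < 0
  if (truncated) sigma2_g <- 0
  sigma2_e <- ms_within
  structure(list(
    sigma2_g = sigma2_g, sigma2_e = sigma2_e,
    H2 = sigma2_g / (sigma2_g + sigma2_e),
    n_lines = k, n0 = n0, truncated = truncated,
    anova = data.frame(
      source = c("among_lines", "within_lines"),
      df = c(df_between, df_within),
      SS = c(ss_between, ss_within),
      MS = c(ms_between, ms_within))),
    class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Broad-sense heritability H2 = %.4f (sigma2_G = %.4g, sigma2_E = %.4g%s)\n",
              x$H2, x$sigma2_g, x$sigma2_e,
              if (x$truncated) "; among-line component truncated at 0" else ""))
  print(x$anova, row.names = FALSE)
  invisible(x)
}

#' Heritability from per-line summary statistics
#'
#' Recomputes the one-way variance components from line means, SEMs and
#' replicate counts (as published in strain summary tables): the within-line
#' sum of squares for a line is `(n - 1) * n * sem^2`. Balanced or
#' unbalanced summaries give exactly the same estimate as
#' [variance_components()] on matching per-fly data.
#'
#' @param mean Per-line means.
#' @param sem Per-line standard errors of the mean.
#' @param n Per-line replicate counts.
#' @param line_id Optional identifiers (used only for drop warnings).
#' @return A `variance_components` object.
#' @export
heritability_from_summaries <- function(mean, sem, n, line_id = NULL) {
  if (is.null(line_id)) line_id <- as.character(seq_along(mean))
  ok <- !is.na(mean) & !is.na(sem) & !is.na(n) & n >= 2
  if (any(!ok)) warning(sprintf("%d lines dropped (missing mean/sem or n < 2)",
                                sum(!ok)))
  mean <- mean[ok]; sem <- sem[ok]; n <- n[ok]
  k <- length(mean)
  if (k < 2L) stop("need at least 2 usable lines")
  N <- sum(n)
  grand <- sum(n * mean) / N
  ss_between <- sum(n * (mean - grand)^2)
  ss_within <- sum((n - 1) * n * sem^2)
  df_between <- k - 1
  df_within <- N - k
  ms_between <- ss_between / df_between
  ms_within <- ss_within / df_within
  n0 <- (N - sum(n^2) / N) / (k - 1)
  sigma2_g <- (ms_between - ms_within) / n0
  truncated <- sigma2_g < 0
  if (truncated) sigma2_g <- 0
  structure(list(
    sigma2_g = sigma2_g, sigma2_e = ms_within,
    H2 = if (sigma2_g + ms_within > 0) sigma2_g / (sigma2_g + ms_within) else 0,
    n_lines = k, n0 = n0, truncated = truncated,
    anova = data.frame(
      source = c("among_lines", "within_lines"),
      df = c(df_between, df_within),
      SS = c(ss_between, ss_within),
      MS = c(ms_between, ms_within))),
    class = "variance_components")
}

#' Pearson correlation test
#'
#' Sample Pearson correlation with the two-sided t-test on n - 2 degrees of
#' freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3, finite).
#' @return List with `rho`, `p_value`, `n`.
#' @export
pearson_test <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance in x or y: correlation undefined")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Chi-squared goodness-of-fit test for given probabilities
#'
#' @param observed Non-negative counts.
#' @param expected_probs Probabilities summing to 1, one per cell.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
chisq_gof <- function(observed, expected_probs) {
  if (abs(sum(expected_probs) - 1) > 1e-8) {
    stop("expected probabilities must sum to 1")
  }
  if (any(observed < 0)) stop("counts must be non-negative")
  if (any(expected_probs == 0 & observed > 0)) {
    stop("expected cell probability 0 with observed > 0")
  }
  ht <- suppressWarnings(stats::chisq.test(observed, p = expected_probs,
                                           correct = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       df = unname(ht$parameter))
}
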