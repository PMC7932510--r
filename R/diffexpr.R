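# Negative-binomial differential expression on gene x sample counts with
# median-of-ratios normalization, moment dispersion shrunk toward the
# mean-dispersion trend, Wald tests, BH FDR, and the fold-change/FDR call.

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median across reference genes of its counts
#' divided by the gene's geometric mean over samples; genes with any zero
#' count are excluded from the reference. If no usable reference gene
#' exists the factors fall back to total-count scaling (with a warning).
#'
#' @param counts Non-negative integer matrix, genes x samples.
#' @return Numeric vector of size factors (one per sample), geometric mean
#'   scaled to 1.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  ref_ok <- rowSums(counts == 0) == 0
  if (!any(ref_ok)) {
    warning("no gene without zeros; falling back to total-count scaling")
    sf <- colSums(counts)
    return(sf / exp(mean(log(sf))))
  }
  lgm <- rowMeans(log(counts[ref_ok, , drop = FALSE]))
  sf <- apply(counts[ref_ok, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - lgm)))
  sf / exp(mean(log(sf)))
}

moment_dispersions <- function(counts, sf, condition) {
  q <- sweep(counts, 2, sf, "/")
  disp <- rep(NA_real_, nrow(counts))
  mu <- rowMeans(q)
  for (lev in unique(condition)) {
    sel <- condition == lev
    m <- rowMeans(q[, sel, drop = FALSE])
    v <- apply(q[, sel, drop = FALSE], 1, stats::var)
    d <- (v - m) / m^2
    disp <- ifelse(is.na(disp), 0, disp) + pmax(d, 0) / length(unique(condition))
  }
  list(mu = mu, disp = disp)
}

shrink_dispersions <- function(mu, disp, weight = 0.5) {
  ok <- mu > 0
  x <- log(mu[ok])
  y <- log(disp[ok] + 1e-8)
  trend <- rep(mean(y), length(mu))
  if (length(unique(round(x, 6))) >= 5) {
    lo <- stats::lowess(x, y, f = 0.5)
    trend[ok] <- stats::approx(lo$x, lo$y, xout = x, rule = 2)$y
  }
  exp((1 - weight) * log(disp + 1e-8) + weight * trend)
}

#' Negative-binomial Wald test of the starvation condition effect
#'
#' Per gene: a moment estimate of the NB dispersion on normalized counts
#' (averaged within conditions), shrunk halfway (log scale) toward the
#' lowess mean-dispersion trend; then a Wald test of the condition
#' coefficient in an NB log-link GLM with size-factor offsets. The reported
#' `log2fc` (starvation vs food) uses normalized condition means with a
#' prior count of 0.5. Genes with all-zero counts are skipped (`NA`).
#'
#' @param counts Genes x samples count matrix.
#' @param condition Sample condition labels (`"food"` / `"starvation"`),
#'   >= 2 samples per condition.
#' @param sf Size factors; computed with [size_factors()] when `NULL`.
#' @return Data frame with `gene_id`, `base_mean`, `log2fc`, `dispersion`,
#'   `p_value`.
#' @export
nb_test <- function(counts, condition, sf = NULL) {
  counts <- as.matrix(counts)
  condition <- as.character(condition)
  if (sum(condition == "food") < 2L || sum(condition == "starvation") < 2L) {
    stop("need >= 2 samples per condition")
  }
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  md <- moment_dispersions(counts, sf, condition)
  disp <- shrink_dispersions(md$mu, md$disp)
  q <- sweep(counts, 2, sf, "/")
  mf <- rowMeans(q[, condition == "food", drop = FALSE])
  ms <- rowMeans(q[, condition == "starvation", drop = FALSE])
  log2fc <- log2((ms + 0.5) / (mf + 0.5))
  cond <- factor(condition, levels = c("food", "starvation"))
  off <- log(sf)
  p <- rep(NA_real_, nrow(counts))
  for (i in seq_len(nrow(counts))) {
    yy <- counts[i, ]
    if (all(yy == 0)) next
    fit <- tryCatch({
      if (disp[i] < 1e-4) {
        stats::glm(yy ~ cond + offset(off), family = stats::poisson())
      } else {
        stats::glm(yy ~ cond + offset(off),
                   family = MASS::negative.binomial(theta = 1 / disp[i]))
      }
    }, error = function(e) NULL, warning = function(w) {
      suppressWarnings(
        if (disp[i] < 1e-4) {
          stats::glm(yy ~ cond + offset(off), family = stats::poisson())
        } else {
          stats::glm(yy ~ cond + offset(off),
                     family = MASS::negative.binomial(theta = 1 / disp[i]))
        })
    })
    if (is.null(fit)) next
    sm <- summary(fit)$coefficients
    if (nrow(sm) >= 2) p[i] <- sm[2, 4]
  }
  data.frame(gene_id = rownames(counts), base_mean = md$mu,
             log2fc = log2fc, dispersion = disp, p_value = p,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up BH false-discovery-rate adjustment with monotonicity.
#'
#' @param p Vector of p-values in [0, 1].
#' @return Vector of FDR values.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression call
#'
#' A gene is called `up` when `fdr < fdr_alpha` and `log2fc >= log2(fc_gate)`,
#' `down` when `fdr < fdr_alpha` and `log2fc <= -log2(fc_gate)`, otherwise
#' `ns`. Defaults implement "FDR < 0.05 and fold change >= 2 or <= -2".
#'
#' @param results Data frame from [nb_test()]; an `fdr` column is added
#'   with [bh_adjust()] when absent.
#' @param fdr_alpha FDR significance level (default 0.05).
#' @param fc_gate Linear fold-change gate (default 2).
#' @return `results` with `fdr` and `call` columns; attributes `n_up` and
#'   `n_down` carry the summary counts.
#' @export
de_filter <- function(results, fdr_alpha = 0.05, fc_gate = 2) {
  if (!"fdr" %in% names(results)) results$fdr <- bh_adjust(results$p_value)
  lfc_gate <- log2(fc_gate)
  results$call <- ifelse(is.na(results$fdr) | results$fdr >= fdr_alpha, "ns",
                  ifelse(results$log2fc >= lfc_gate, "up",
                  ifelse(results$log2fc <= -lfc_gate, "down", "ns")))
  attr(results, "n_up") <- sum(results$call == "up")
  attr(results, "n_down") <- sum(results$call == "down")
  results
}
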