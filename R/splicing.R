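# Intron-excision clustering, percent-spliced-in (PSI) and delta-PSI,
# Dirichlet-multinomial differential-splicing test, FDR and magnitude
# classification.

#' Cluster intron junctions by shared splice sites
#'
#' Junctions on the same chromosome and strand that share a start or end
#' coordinate are connected; clusters are the connected components.
#' After clustering, introns carrying less than `min_intron_fraction` of
#' their cluster's total reads are pruned and clusters with fewer than
#' `min_cluster_reads` total reads (or a single intron) are dropped;
#' pruning and re-clustering repeat until stable.
#'
#' @param junctions Data frame with `id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open intron intervals, BED convention).
#' @param counts Numeric matrix, junctions x samples, rownames matching
#'   `junctions$id`.
#' @param min_cluster_reads Minimum total reads per retained cluster.
#' @param min_intron_fraction Minimum fraction of cluster reads per intron.
#' @return List of `intron_cluster` objects, each with `cluster_id`,
#'   `junctions` (data frame) and `counts` (matrix).
#' @export
cluster_introns <- function(junctions, counts, min_cluster_reads = 30,
                            min_intron_fraction = 0.001) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts))) rownames(counts) <- junctions$id
  ord <- order(junctions$chrom, junctions$strand, junctions$start,
               junctions$end)
  junctions <- junctions[ord, , drop = FALSE]
  counts <- counts[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(junctions))
  repeat {
    jj <- junctions[keep, , drop = FALSE]
    cc <- counts[keep, , drop = FALSE]
    if (nrow(jj) == 0L) return(list())
    comp <- connected_components(jj)
    tot <- rowSums(cc)
    cl_tot <- tapply(tot, comp, sum)[as.character(comp)]
    drop_intron <- tot < min_intron_fraction * cl_tot
    cl_ok <- stats::ave(rep(1, nrow(jj)), comp, FUN = sum) >= 2 &
      cl_tot >= min_cluster_reads
    new_keep <- keep
    new_keep[keep] <- !drop_intron & cl_ok
    if (identical(new_keep, keep)) break
    keep <- new_keep
  }
  jj <- junctions[keep, , drop = FALSE]
  cc <- counts[keep, , drop = FALSE]
  comp <- connected_components(jj)
  ids <- sort(unique(comp))
  lapply(seq_along(ids), function(i) {
    sel <- comp == ids[i]
    structure(list(cluster_id = sprintf("clu_%d", i),
                   junctions = jj[sel, , drop = FALSE],
                   counts = cc[sel, , drop = FALSE]),
              class = "intron_cluster")
  })
}

connected_components <- function(junctions) {
  n <- nrow(junctions)
  skey <- paste(junctions$chrom, junctions$strand, junctions$start, "s")
  ekey <- paste(junctions$chrom, junctions$strand, junctions$end, "e")
  keys <- unique(c(skey, ekey))
  g <- igraph::make_empty_graph(n = n + length(keys), directed = FALSE)
  edges <- rbind(cbind(seq_len(n), n + match(skey, keys)),
                 cbind(seq_len(n), n + match(ekey, keys)))
  g <- igraph::add_edges(g, t(edges))
  igraph::components(g)$membership[seq_len(n)]
}

#' Per-intron PSI by condition
#'
#' PSI of an intron in a condition is its summed count across that
#' condition's samples divided by the cluster total in the condition; PSIs
#' within a cluster sum to 1 per condition. A condition with zero cluster
#' total yields `NA` PSIs and a `flagged` attribute.
#'
#' @param cluster An `intron_cluster`.
#' @param condition Character/factor vector of sample conditions (`"food"`
#'   or `"starvation"`), one per counts column.
#' @return Data frame with `intron_id`, `psi_food`, `psi_starved`, `dpsi`
#'   (`psi_starved - psi_food`).
#' @export
compute_psi <- function(cluster, condition) {
  condition <- as.character(condition)
  f <- rowSums(cluster$counts[, condition == "food", drop = FALSE])
  s <- rowSums(cluster$counts[, condition == "starvation", drop = FALSE])
  flagged <- FALSE
  psi_f <- if (sum(f) > 0) f / sum(f) else {flagged <- TRUE; rep(NA_real_, length(f))}
  psi_s <- if (sum(s) > 0) s / sum(s) else {flagged <- TRUE; rep(NA_real_, length(s))}
  out <- data.frame(intron_id = cluster$junctions$id,
                    psi_food = psi_f, psi_starved = psi_s,
                    dpsi = psi_s - psi_f, stringsAsFactors = FALSE,
                    row.names = NULL)
  attr(out, "flagged") <- flagged
  out
}

dm_loglik <- function(x_mat, pi, conc) {
  # x_mat: samples x introns; multinomial coefficient omitted (cancels in LRT)
  ll <- 0
  a <- conc * pi
  for (i in seq_len(nrow(x_mat))) {
    x <- x_mat[i, ]
    n <- sum(x)
    ll <- ll + lgamma(conc) - lgamma(n + conc) +
      sum(lgamma(x + a) - lgamma(a))
  }
  ll
}

softmax0 <- function(eta) {
  e <- exp(c(0, eta) - max(0, eta))
  e / sum(e)
}

fit_dm_null <- function(x_mat, logc_max) {
  k <- ncol(x_mat)
  pooled <- colSums(x_mat) + 0.5
  pi0 <- pooled / sum(pooled)
  par0 <- c(log(pi0[-1] / pi0[1]), log(50))
  nll <- function(par) {
    pi <- softmax0(par[seq_len(k - 1)])
    -dm_loglik(x_mat, pi, exp(par[k]))
  }
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = c(rep(-20, k - 1), -5),
                      upper = c(rep(20, k - 1), logc_max),
                      control = list(maxit = 500))
  list(ll = -opt$value, logc = opt$par[k],
       pi = softmax0(opt$par[seq_len(k - 1)]))
}

# profile log-likelihood over proportions with the concentration held
# fixed (at the null estimate); holding the nuisance concentration fixed
# keeps the LRT calibrated at small sample sizes
fit_dm_profile <- function(x_mat, conc) {
  k <- ncol(x_mat)
  p0 <- colSums(x_mat) + 0.5
  p0 <- p0 / sum(p0)
  par0 <- log(p0[-1] / p0[1])
  nll <- function(par) -dm_loglik(x_mat, softmax0(par), conc)
  if (k == 2) {
    opt <- stats::optimize(function(e) nll(e), c(-20, 20))
    return(-opt$objective)
  }
  opt <- stats::optim(par0, nll, method = "L-BFGS-B",
                      lower = rep(-20, k - 1), upper = rep(20, k - 1),
                      control = list(maxit = 500))
  -opt$value
}

multinomial_gtest <- function(xf, xs) {
  of <- colSums(xf); os <- colSums(xs)
  pooled <- of + os
  p0 <- pooled / sum(pooled)
  ef <- sum(of) * p0; es <- sum(os) * p0
  terms <- function(o, e) {
    sel <- o > 0
    2 * sum(o[sel] * log(o[sel] / e[sel]))
  }
  g <- terms(of, ef) + terms(os, es)
  df <- length(of) - 1
  list(statistic = g, df = df,
       p = stats::pchisq(g, df, lower.tail = FALSE))
}

#' Differential intron-usage test for one cluster
#'
#' Likelihood-ratio test of condition-specific versus shared intron-usage
#' proportions under a per-sample Dirichlet-multinomial model with a single
#' cluster-level concentration shared across conditions
#' (df = number of introns - 1). The concentration is estimated by maximum
#' likelihood under the null and held fixed in the condition-specific fit,
#' which keeps the test calibrated at small sample sizes. When the fitted
#' concentration diverges (no detectable overdispersion) the test falls
#' back to a multinomial G-test on the pooled condition totals.
#'
#' @param logc_max Upper bound on the log concentration; hitting it
#'   triggers the multinomial fallback.
#' @param method `"auto"` (Dirichlet-multinomial with multinomial fallback,
#'   the default), `"dm"` (always Dirichlet-multinomial) or `"g"` (always
#'   the multinomial G-test on pooled condition totals).
#'
#' @param cluster An `intron_cluster` with at least 2 introns.
#' @param condition Sample condition labels (>= 2 samples per condition).
#' @return List with `p_value`, `statistic`, `df`, `method`
#'   (`"dirichlet-multinomial"` or `"multinomial-g"`).
#' @export
test_cluster <- function(cluster, condition, logc_max = 16,
                         method = c("auto", "dm", "g")) {
  method <- match.arg(method)
  condition <- as.character(condition)
  x <- t(cluster$counts)
  k <- ncol(x)
  if (k < 2L) stop("cluster with a single intron is not testable")
  if (sum(condition == "food") < 2L || sum(condition == "starvation") < 2L) {
    stop("need >= 2 samples per condition")
  }
  xf <- x[condition == "food", , drop = FALSE]
  xs <- x[condition == "starvation", , drop = FALSE]
  if (method == "g") {
    gt <- multinomial_gtest(xf, xs)
    return(list(p_value = gt$p, statistic = gt$statistic, df = gt$df,
                method = "multinomial-g"))
  }
  null_fit <- fit_dm_null(x, logc_max)
  if (method == "auto" && null_fit$logc >= logc_max - 1e-6) {
    gt <- multinomial_gtest(xf, xs)
    return(list(p_value = gt$p, statistic = gt$statistic, df = gt$df,
                method = "multinomial-g"))
  }
  conc <- exp(null_fit$logc)
  ll_alt <- fit_dm_profile(xf, conc) + fit_dm_profile(xs, conc)
  stat <- max(0, 2 * (ll_alt - null_fit$ll))
  df <- k - 1
  list(p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       statistic = stat, df = df, method = "dirichlet-multinomial")
}

#' Benjamini-Hochberg FDR and delta-PSI magnitude classes
#'
#' Adjusts cluster p-values by the Benjamini-Hochberg step-up rule and
#' classifies each significant cluster by its maximum absolute delta-PSI:
#' `below-threshold` when |dPSI| <= `dpsi_floor` (default 0.10), `small`
#' when 0.10 < |dPSI| < 0.25, `intermediate` when 0.25 <= |dPSI| <= 0.50,
#' `large` when |dPSI| > 0.50.
#'
#' @param results Data frame with `cluster_id`, `p_value`, `max_abs_dpsi`.
#' @param fdr_alpha Significance level on the FDR (default 0.05).
#' @param dpsi_floor Magnitude floor (default 0.10).
#' @return `results` with added `fdr`, `significant`, `magnitude_class`.
#' @export
fdr_and_classify <- function(results, fdr_alpha = 0.05, dpsi_floor = 0.10) {
  results$fdr <- stats::p.adjust(results$p_value, method = "BH")
  results$significant <- results$fdr < fdr_alpha
  d <- abs(results$max_abs_dpsi)
  results$magnitude_class <- ifelse(d <= dpsi_floor, "below-threshold",
                             ifelse(d < 0.25, "small",
                             ifelse(d <= 0.50, "intermediate", "large")))
  results
}

#' Full differential-splicing analysis
#'
#' Clusters junctions, computes per-intron PSI and delta-PSI, tests every
#' cluster, and applies FDR and magnitude classification.
#'
#' @inheritParams cluster_introns
#' @param condition Sample condition labels, one per counts column.
#' @param fdr_alpha,dpsi_floor See [fdr_and_classify()].
#' @return List with `clusters` (per-cluster results incl. `fdr` and
#'   `magnitude_class`) and `introns` (per-intron PSI table).
#' @export
differential_splicing <- function(junctions, counts, condition,
                                  min_cluster_reads = 30,
                                  min_intron_fraction = 0.001,
                                  fdr_alpha = 0.05, dpsi_floor = 0.10) {
  clusters <- cluster_introns(junctions, counts, min_cluster_reads,
                              min_intron_fraction)
  if (length(clusters) == 0L) {
    return(list(clusters = data.frame(), introns = data.frame()))
  }
  intron_tabs <- list()
  rows <- list()
  for (cl in clusters) {
    psi <- compute_psi(cl, condition)
    tst <- test_cluster(cl, condition)
    psi$cluster_id <- cl$cluster_id
    intron_tabs[[cl$cluster_id]] <- psi
    rows[[cl$cluster_id]] <- data.frame(
      cluster_id = cl$cluster_id, n_introns = nrow(cl$junctions),
      p_value = tst$p_value, method = tst$method,
      max_abs_dpsi = max(abs(psi$dpsi)), stringsAsFactors = FALSE)
  }
  res <- fdr_and_classify(do.call(rbind, rows), fdr_alpha, dpsi_floor)
  rownames(res) <- NULL
  introns <- do.call(rbind, intron_tabs)
  rownames(introns) <- NULL
  introns$fdr <- res$fdr[match(introns$cluster_id, res$cluster_id)]
  list(clusters = res, introns = introns)
}

#' Write / read a junction count table (TSV)
#'
#' Long-lived exchange format: `chrom`, `start`, `end`, `strand`, `id`
#' followed by one column per sample.
#'
#' @param junctions,counts As in [cluster_introns()].
#' @param path File path.
#' @return `path` invisibly (write) or a list with `junctions` and `counts`
#'   (read).
#' @export
write_junction_table <- function(junctions, counts, path) {
  utils::write.table(cbind(junctions[, c("chrom", "start", "end", "strand",
                                         "id")], as.data.frame(counts)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_junction_table
#' @export
read_junction_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  meta <- d[, c("chrom", "start", "end", "strand", "id")]
  counts <- as.matrix(d[, setdiff(names(d), names(meta)), drop = FALSE])
  rownames(counts) <- meta$id
  list(junctions = meta, counts = counts)
}
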