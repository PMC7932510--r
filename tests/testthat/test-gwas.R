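test_that("covariate adjustment is OLS residualization", {
  y <- c(8, 12, 10, 18, 22, 20)
  cov <- data.frame(w = c(0, 0, 0, 1, 1, 1))
  rownames(cov) <- names(y) <- sprintf("l%d", 1:6)
  r <- adjust_covariates(y, cov)
  expect_equal(unname(r), c(-2, 2, 0, -2, 2, 0))
  # residuals orthogonal to every covariate column
  expect_lt(abs(sum(r * cov$w)), 1e-10)
  # all-constant covariate: residuals are y - mean(y) (collinear col dropped)
  cov2 <- data.frame(k = rep(1, 6)); rownames(cov2) <- names(y)
  expect_warning(r2 <- adjust_covariates(y, cov2), "collinear")
  expect_equal(unname(r2), unname(y - mean(y)))
})

test_that("MAF filter is strict and matches brute force", {
  set.seed(15)
  g <- sapply(c(0.03, 0.05, 0.051, 0.2, 0.5), function(p)
    c(rep(1, round(p * 100)), rep(0, 100 - round(p * 100))))
  panel <- line_panel(g)
  kept <- maf_filter(panel, 0.05)
  expect_equal(ncol(kept$geno), sum(panel$maf > 0.05))
  expect_false("v2" %in% kept$variants$id)  # MAF exactly 0.05 excluded
  g10 <- matrix(rbinom(50 * 10, 1, 0.3), 50, 10)
  p10 <- line_panel(g10)
  expect_equal(maf_filter(p10, 0.2)$variants$id,
               p10$variants$id[p10$maf > 0.2])
})

test_that("GRM: identical lines coincide, null panels decorrelate, PSD", {
  set.seed(16)
  g <- matrix(rbinom(10 * 100, 1, 0.3), 10, 100)
  g[2, ] <- g[1, ]
  K <- compute_grm(line_panel(g))
  expect_equal(K[1, 2], K[1, 1], tolerance = 1e-12)
  expect_true(isSymmetric(K))
  expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  g2 <- matrix(rbinom(40 * 5000, 1, 0.25), 40, 5000)
  K2 <- compute_grm(line_panel(g2))
  off <- K2[upper.tri(K2)]
  expect_lt(abs(mean(off)), 0.05)
  expect_gte(min(eigen(K2, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("REML recovers variance components and beats a grid search", {
  set.seed(17)
  n <- 120
  K <- compute_grm(line_panel(matrix(rbinom(n * 500, 1, 0.3), n, 500)))
  L <- t(chol(K + diag(1e-8, n)))
  ests <- replicate(30, {
    y <- as.vector(L %*% rnorm(n)) + rnorm(n)
    f <- fit_null_reml(y, K)
    c(f$sigma2_g, f$sigma2_e)
  })
  expect_equal(mean(ests[1, ]), 1, tolerance = 0.2)
  expect_equal(mean(ests[2, ]), 1, tolerance = 0.2)

  # grid-search oracle on the REML log-likelihood
  y <- as.vector(L %*% rnorm(n)) + rnorm(n)
  fit <- fit_null_reml(y, K)
  eig <- eigen(K, symmetric = TRUE)
  s <- pmax(eig$values, 0)
  yt <- crossprod(eig$vectors, y)
  xt <- crossprod(eig$vectors, rep(1, n))
  ll <- function(delta) {
    w <- s + delta
    xwx <- sum(xt^2 / w)
    beta <- sum(xt * yt / w) / xwx
    q <- sum((yt - xt * beta)^2 / w)
    sg <- q / (n - 1)
    -0.5 * ((n - 1) * log(2 * pi * sg) + (n - 1) + sum(log(w)) + log(xwx))
  }
  grid_best <- max(vapply(10^seq(-4, 4, length.out = 2000), ll, 0))
  expect_lt(abs(fit$loglik - grid_best), 1e-3)
  expect_gte(fit$loglik, grid_best - 1e-6)

  # unidentifiable split for K = I: total variance with a degeneracy flag
  y_id <- rnorm(20)
  f_id <- fit_null_reml(y_id, diag(20))
  expect_true(f_id$degenerate)
  expect_equal(f_id$sigma2_e, var(y_id))
})

test_that("near-noiseless y along K pushes delta to the boundary", {
  set.seed(18)
  n <- 50
  K <- compute_grm(line_panel(matrix(rbinom(n * 300, 1, 0.3), n, 300)))
  L <- t(chol(K + diag(1e-8, n)))
  y <- as.vector(L %*% rnorm(n))
  fit <- fit_null_reml(y, K)
  expect_lt(fit$delta, 1e-2)
  expect_lt(fit$sigma2_e / fit$sigma2_g, 1e-2)
})

test_that("GLS scan equals brute-force matrix formulas and OLS reduction", {
  set.seed(19)
  n <- 20
  K <- compute_grm(line_panel(matrix(rbinom(n * 200, 1, 0.3), n, 200)))
  y <- rnorm(n)
  g <- rbinom(n, 1, 0.4)
  panel <- line_panel(cbind(v1 = g, v2 = rbinom(n, 1, 0.3)))
  nf <- list(sigma2_g = 0.7, sigma2_e = 0.4, delta = 0.4 / 0.7,
             eigen = eigen(K, symmetric = TRUE), degenerate = FALSE)
  scan <- association_scan(y, panel, K, null_fit = nf)
  V <- 0.7 * K + 0.4 * diag(n)
  Vi <- solve(V)
  X <- cbind(1, g)
  b <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% b
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - 2)
  se <- sqrt((s2 * solve(t(X) %*% Vi %*% X))[2, 2])
  tv <- b[2] / se
  expect_equal(scan$beta_minor[1], b[2], tolerance = 1e-10)
  expect_equal(scan$se[1], se, tolerance = 1e-10)
  expect_equal(scan$p_value[1], 2 * pt(-abs(tv), n - 2), tolerance = 1e-10)

  # sigma2_g = 0 reduces to ordinary regression
  nf0 <- list(sigma2_g = 0, sigma2_e = 1, delta = Inf,
              eigen = eigen(diag(n), symmetric = TRUE), degenerate = TRUE)
  scan0 <- association_scan(y, panel, diag(n), null_fit = nf0)
  expect_equal(scan0$p_value[1], summary(lm(y ~ g))$coefficients[2, 4],
               tolerance = 1e-10)

  # allele relabeling flips beta, keeps p
  panel_flip <- line_panel(cbind(v1 = 1 - g, v2 = panel$geno[, 2]))
  scan_f <- association_scan(y, panel_flip, K, null_fit = nf)
  expect_equal(scan_f$beta_minor[1], -scan$beta_minor[1], tolerance = 1e-10)
  expect_equal(scan_f$p_value[1], scan$p_value[1], tolerance = 1e-10)
})

test_that("P3D and exact modes agree within a factor of 2", {
  set.seed(20)
  sim <- simulate_panel(panel_sim_config(n_lines = 198, n_variants = 40,
                                         n_causal = 2, seed = 20))
  lm_ <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
  y <- adjust_covariates(lm_[sim$panel$lines], sim$covariates)
  K <- compute_grm(sim$panel)
  p3d <- association_scan(y, sim$panel, K, mode = "p3d")
  ex <- association_scan(y, sim$panel, K, mode = "exact")
  ratio <- p3d$p_value / ex$p_value
  expect_true(all(ratio > 0.5 & ratio < 2))
})

test_that("a strong single causal variant ranks first", {
  hits <- 0L
  for (i in 1:100) {
    sim <- simulate_panel(panel_sim_config(
      n_lines = 198, n_variants = 200, causal_idx = 7, causal_beta = 1.2,
      sigma2_poly = 0, sigma2_line = 0.05, h2_target = 0.6,
      seed = 3000 + i))
    lm_ <- tapply(sim$phenotypes$value, sim$phenotypes$line_id, mean)
    y <- adjust_covariates(lm_[sim$panel$lines], sim$covariates)
    scan <- association_scan(y, sim$panel)
    if (which.min(scan$p_value) == 7L) hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("significant_hits filters strictly and sorts by p", {
  rec <- data.frame(variant_id = c("a", "b", "c"),
                    p_value = c(1e-5, 9e-6, 2e-7))
  out <- significant_hits(rec, 1e-5)
  expect_equal(out$variant_id, c("c", "b"))  # exactly 1e-5 excluded
})
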