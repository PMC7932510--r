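# Seed-deterministic generators for every pipeline input: DAM activity
# series with circadian structure, starvation-induced hyperactivity and
# activity-inferred death; inbred-line genotype panels with planted
# heritability and variant effects; Dirichlet-multinomial junction counts
# with planted delta-PSI; negative-binomial gene counts with planted fold
# changes.

#' Bimodal circadian activity profile
#'
#' Expected beam-break counts per 30-min bin: a low trough plus Gaussian
#' bumps centred at the lights-off (bin 0 mod 48) and lights-on (bin 24
#' mod 48) transitions.
#'
#' @param bins Number of bins.
#' @param trough Trough rate (counts/bin).
#' @param peak_height Extra rate at each peak centre.
#' @param peak_width Gaussian SD of each peak, in bins.
#' @return Numeric vector of per-bin rates.
#' @export
circadian_profile <- function(bins = 120, trough = 5, peak_height = 25,
                              peak_width = 2) {
  b <- seq_len(bins) - 1L
  m <- b %% 48
  bump <- function(centre) {
    d <- pmin(abs(m - centre), 48 - abs(m - centre))
    exp(-0.5 * (d / peak_width)^2)
  }
  trough + peak_height * (bump(0) + bump(24))
}

#' Configuration for the activity simulator
#'
#' Defaults encode the screening design of a DGRP-style panel: 198 strains,
#' 8 flies per condition per strain, 120 bins (60 h), a strain Delta
#' Activity spectrum spanning 93.61..2101.91 with broad-sense heritability
#' 0.38, strain starvation-resistance indices latently correlated with DA
#' at -0.231, and a baseline-activity scale latently correlated with DA at
#' 0.046. The latent Gaussian-copula correlations are corrected for the
#' attenuation induced by the non-Gaussian marginals so the planted
#' strain-level Pearson correlations match the targets.
#'
#' @param n_strains Number of strains.
#' @param flies_per_condition Flies per strain per condition.
#' @param bins Number of 30-min bins.
#' @param trough,peak_height,peak_width Circadian profile (see
#'   [circadian_profile()]).
#' @param dispersion NB dispersion of per-bin counts.
#' @param h2_target Broad-sense heritability of the per-fly DA.
#' @param da_range Anchors (min, max) of the lognormal-quantile spectrum of
#'   observed strain DA means (extreme order-statistic positions); the
#'   planted true spectrum is the deconvolved (noise-shrunk) version.
#' @param rho_da_sr Target strain-level Pearson correlation of DA and SR.
#' @param rho_da_baseline Target correlation of DA and baseline activity.
#' @param sr_mean,sr_sd Normal marginal of the SR index (rounded, clamped
#'   to [24, 121]; values above 120 are survivors).
#' @param scale_sdlog Lognormal sdlog of the per-strain activity scale.
#' @param uplift_shape `"step"` (persistent uplift from assay start) or
#'   `"ramp"` (linear ramp over the first 12 h, then persistent).
#' @param strain_truth Optional explicit per-strain truth table
#'   (`strain_id`, `delta`, `sr`, `scale`); generated when `NULL`. An `NA`
#'   `sr` plants no deaths in that strain; an optional `death_time` column
#'   (last active bin) forces that death time on every starved fly of the
#'   strain.
#' @param seed RNG seed; every draw flows from it.
#' @return An `activity_sim_config` list.
#' @export
activity_sim_config <- function(n_strains = 198, flies_per_condition = 8,
                                bins = 120, trough = 5, peak_height = 25,
                                peak_width = 2, dispersion = 0.05,
                                h2_target = 0.38,
                                da_range = c(93.61, 2101.91),
                                rho_da_sr = -0.231,
                                rho_da_baseline = 0.046,
                                sr_mean = 85, sr_sd = 18,
                                scale_sdlog = 0.25,
                                uplift_shape = c("step", "ramp"),
                                strain_truth = NULL, seed = 1) {
  stopifnot(h2_target >= 0, h2_target < 1, bins >= 1)
  structure(list(n_strains = n_strains,
                 flies_per_condition = flies_per_condition, bins = bins,
                 trough = trough, peak_height = peak_height,
                 peak_width = peak_width, dispersion = dispersion,
                 h2_target = h2_target, da_range = da_range,
                 rho_da_sr = rho_da_sr, rho_da_baseline = rho_da_baseline,
                 sr_mean = sr_mean, sr_sd = sr_sd,
                 scale_sdlog = scale_sdlog,
                 uplift_shape = match.arg(uplift_shape),
                 strain_truth = strain_truth, seed = seed),
            class = "activity_sim_config")
}

# correlation between a fixed sorted marginal and normal scores; used to
# pre-correct Gaussian-copula latent correlations for marginal attenuation
marginal_factor <- function(sorted_values) {
  n <- length(sorted_values)
  if (n < 3 || stats::sd(sorted_values) == 0) return(1)
  stats::cor(sorted_values, stats::qnorm(stats::ppoints(n)))
}

# exactly-correlated standard-normal latents (sample correlation == rho);
# e is a raw normal draw, orthogonalized against z1
correlated_latent <- function(z1, rho, e) {
  z1s <- as.vector(scale(z1))
  e <- stats::residuals(stats::lm(e ~ z1s))
  e <- as.vector(scale(e))
  rho * z1s + sqrt(1 - rho^2) * e
}

# per-strain gamma variance of the per-fly uplift realizing the target
# heritability: the target within-line variance minus the window-count
# noise, capped at delta^2/2 (gamma shape >= 2) and rescaled to preserve
# the mean
uplift_noise_variances <- function(delta, cfg) {
  lambda <- circadian_profile(cfg$bins, cfg$trough, cfg$peak_height,
                              cfg$peak_width)
  mean_uplift <- mean(pmax(delta, 0)) / 24
  v_bin <- (lambda + mean_uplift) + (lambda + mean_uplift)^2 * cfg$dispersion
  n_win <- max(1L, cfg$bins %/% 24L)
  v_window <- sum(v_bin[seq_len(n_win * 24L)]) / n_win
  v_noise <- 0.45 * v_window * (1 + 1 / cfg$flies_per_condition)
  sigma2_g <- stats::var(delta)
  sigma2_fly <- if (cfg$h2_target > 0 && is.finite(sigma2_g) && sigma2_g > 0)
    max(sigma2_g * (1 - cfg$h2_target) / cfg$h2_target - v_noise, 0) else 0
  sigma2_i <- rep(0, length(delta))
  if (sigma2_fly > 0) {
    cap <- pmax(delta, 0)^2 / 2
    if (mean(cap) <= sigma2_fly) {
      sigma2_i <- cap
    } else {
      cstar <- stats::uniroot(function(cc) mean(pmin(cc, cap)) - sigma2_fly,
                              c(0, max(cap)))$root
      sigma2_i <- pmin(cstar, cap)
    }
  }
  list(sigma2_i = sigma2_i, v_window = v_window)
}

# analytic prediction of the Pearson correlation between the pipeline's
# observed strain DA means and SR: the max-of-k-windows estimator bias
# grows with the number of windows a strain's flies survive, which couples
# the DA estimate to SR; expectations of extreme order statistics of k
# standard normals give the bias and variance factors
predict_observed_cor_sr <- function(delta, sr, scale, cfg, sigma2_i) {
  if (length(delta) < 3 || stats::sd(sr) == 0 || stats::sd(delta) == 0) {
    return(NA_real_)
  }
  lam_mean <- mean(circadian_profile(cfg$bins, cfg$trough, cfg$peak_height,
                                     cfg$peak_width))
  k <- pmax(1, pmin(5, round(sr / 24)))
  cmax <- c(0, 0.564, 0.846, 1.029, 1.163)  # E[max of k std normals]
  vmax <- c(1, 0.682, 0.560, 0.492, 0.448)  # Var[max of k std normals]
  mu_s <- lam_mean * scale + pmax(delta, 0) / 24
  mu_f <- lam_mean * scale
  s2w <- 24 * (mu_s + mu_s^2 * cfg$dispersion) +
    24 * (mu_f + mu_f^2 * cfg$dispersion) / cfg$flies_per_condition
  bias <- cmax[k] * sqrt(s2w)
  varm <- (sigma2_i + vmax[k] * s2w) / cfg$flies_per_condition
  m <- delta + bias
  stats::cov(m, sr) / sqrt((stats::var(m) + mean(varm)) * stats::var(sr))
}

default_strain_truth <- function(cfg) {
  n <- cfg$n_strains
  p <- stats::ppoints(n)
  # lognormal quantile spectrum anchored so its extreme order-statistic
  # positions hit the configured DA range
  meanlog <- mean(log(cfg$da_range))
  sdlog <- diff(log(cfg$da_range)) / 2 / stats::qnorm(p[n])
  spectrum <- stats::qlnorm(p, meanlog, sdlog)
  # the anchors describe observed strain means (true value + mean of
  # flies_per_condition noisy flies at heritability h2); plant the
  # deconvolved spectrum so the pipeline's observed spectrum reproduces
  # the anchors in expectation
  f_att <- if (cfg$h2_target > 0)
    sqrt(1 / (1 + (1 - cfg$h2_target) /
                (cfg$h2_target * cfg$flies_per_condition))) else 1
  spectrum <- mean(spectrum) + f_att * (spectrum - mean(spectrum))
  sr_marg <- pmin(pmax(round(stats::qnorm(p, cfg$sr_mean, cfg$sr_sd)), 24),
                  121)
  # attenuation corrections for the latent copula correlations:
  # marginal shape (non-Gaussian marginals) and DA estimation noise
  f_da <- marginal_factor(sort(spectrum))
  f_sr <- marginal_factor(sort(sr_marg))
  clamp <- function(r) max(-0.95, min(0.95, r))
  rho1 <- clamp(cfg$rho_da_sr / (f_da * f_sr * f_att))
  rho2 <- clamp(cfg$rho_da_baseline / (f_da * f_att))
  z1 <- stats::rnorm(n)
  e2 <- stats::rnorm(n)
  e3 <- stats::rnorm(n)
  z3 <- correlated_latent(z1, rho2, e3)
  delta <- sort(spectrum)[rank(z1, ties.method = "first")]
  scale <- exp(cfg$scale_sdlog * z3 - cfg$scale_sdlog^2 / 2)
  sr_sorted <- sort(sr_marg)
  make_sr <- function(rho) {
    z2 <- correlated_latent(z1, rho, e2)
    sr_sorted[rank(z2, ties.method = "first")]
  }
  sr <- make_sr(rho1)
  # fixed-point refinement of the latent DA-SR correlation against the
  # analytic prediction of what the pipeline will observe
  if (n >= 10 && cfg$rho_da_sr != 0) {
    noise <- uplift_noise_variances(delta, cfg)
    for (it in 1:4) {
      pred <- predict_observed_cor_sr(delta, sr, scale, cfg, noise$sigma2_i)
      if (!is.finite(pred) || abs(pred) < 1e-4) break
      rho1 <- clamp(rho1 * cfg$rho_da_sr / pred)
      sr <- make_sr(rho1)
    }
  }
  data.frame(strain_id = sprintf("line_%03d", seq_len(n)),
             delta = delta, sr = as.integer(sr), scale = scale,
             stringsAsFactors = FALSE)
}

#' Simulate a DAM activity experiment
#'
#' Food-condition flies draw overdispersed (negative-binomial) counts
#' around the strain-scaled bimodal circadian profile. Starved flies add a
#' persistent per-fly uplift whose expected 12-h window total equals the
#' fly's planted Delta Activity; per-fly DAs are gamma-distributed around
#' the strain DA with the variance chosen so the expected
#' broad-sense heritability of the per-fly DA equals `h2_target`. Starved
#' flies die at planted times (all bins after the death bin are zero; a
#' beam cross is guaranteed in the final active bin so the planted death
#' time is identifiable); the latest death bin per strain realizes the
#' planted SR index, with 121 denoting a survivor.
#'
#' @param cfg An [activity_sim_config()].
#' @return List with `monitors` (list of `monitor_file`), `layout` (channel
#'   map data frame), `origin` (lights-off POSIXct), `strain_truth` and
#'   `fly_truth` data frames.
#' @export
simulate_activity <- function(cfg) {
  set.seed(cfg$seed)
  truth <- cfg$strain_truth
  if (is.null(truth)) truth <- default_strain_truth(cfg)
  n <- nrow(truth)
  fpc <- cfg$flies_per_condition
  lambda <- circadian_profile(cfg$bins, cfg$trough, cfg$peak_height,
                              cfg$peak_width)
  # per-fly DA noise needed on top of the activity-count noise to realize
  # the target heritability of the per-fly DA
  sigma2_i <- uplift_noise_variances(truth$delta, cfg)$sigma2_i
  shape <- if (cfg$uplift_shape == "ramp")
    pmin(seq_len(cfg$bins) / 24, 1) else rep(1, cfg$bins)

  flies <- list()
  fly_truth <- list()
  counts_all <- list()
  for (i in seq_len(n)) {
    sid <- truth$strain_id[i]
    lam_s <- lambda * truth$scale[i]
    for (cond in c("food", "starvation")) {
      for (j in seq_len(fpc)) {
        fly_id <- sprintf("%s_%s_%d", sid, ifelse(cond == "food", "F", "S"), j)
        if (cond == "food") {
          mu <- lam_s
          death <- NA_integer_
          d_fly <- NA_real_
        } else {
          d_fly <- if (sigma2_i[i] > 0 && truth$delta[i] > 0) {
            stats::rgamma(1, shape = truth$delta[i]^2 / sigma2_i[i],
                          rate = truth$delta[i] / sigma2_i[i])
          } else max(truth$delta[i], 0)
          mu <- lam_s + shape * d_fly / 24
          if (!is.null(truth$death_time) && !is.na(truth$death_time[i])) {
            # explicit last-active bin for every starved fly of the strain
            death <- truth$death_time[i] + 1L
          } else if (is.na(truth$sr[i])) {
            death <- NA_integer_  # no deaths in this strain
          } else if (j == 1L) {
            death <- truth$sr[i]
          } else {
            hi <- if (truth$sr[i] >= 121L) 121L else truth$sr[i]
            lo <- min(max(36L, hi - 30L), hi)
            death <- lo + sample.int(hi - lo + 1L, 1L) - 1L
          }
        }
        cnt <- stats::rnbinom(cfg$bins, mu = mu, size = 1 / cfg$dispersion)
        if (!is.na(death)) {
          if (death <= cfg$bins) {
            last_active <- death - 1L
            if (last_active >= 0L) {
              cnt[last_active + 1L] <- max(cnt[last_active + 1L], 1L)
              if (last_active + 2L <= cfg$bins)
                cnt[(last_active + 2L):cfg$bins] <- 0L
            } else {
              cnt[] <- 0L
            }
          } else {
            cnt[cfg$bins] <- max(cnt[cfg$bins], 1L)  # survivor
          }
        }
        flies[[length(flies) + 1L]] <- list(fly_id = fly_id, strain_id = sid,
                                            condition = cond)
        counts_all[[length(counts_all) + 1L]] <- cnt
        fly_truth[[length(fly_truth) + 1L]] <- data.frame(
          fly_id = fly_id, strain_id = sid, condition = cond,
          delta_fly = d_fly, death_bin = death, stringsAsFactors = FALSE)
      }
    }
  }
  n_flies <- length(flies)
  origin <- as.POSIXct("2020-01-01 18:00:00", tz = "UTC")
  times <- origin + (seq_len(cfg$bins) - 1L) * 1800
  monitors <- list()
  layout <- list()
  n_mon <- ceiling(n_flies / 32)
  for (m in seq_len(n_mon)) {
    idx <- ((m - 1L) * 32L + 1L):min(m * 32L, n_flies)
    cmat <- matrix(0L, nrow = cfg$bins, ncol = 32)
    for (k in seq_along(idx)) cmat[, k] <- counts_all[[idx[k]]]
    mid <- sprintf("Monitor%02d", m)
    monitors[[m]] <- monitor_file(mid, seq_len(cfg$bins), times,
                                  rep(1L, cfg$bins), cmat)
    layout[[m]] <- data.frame(
      monitor_id = mid, channel = seq_along(idx),
      fly_id = vapply(flies[idx], `[[`, "", "fly_id"),
      strain_id = vapply(flies[idx], `[[`, "", "strain_id"),
      condition = vapply(flies[idx], `[[`, "", "condition"),
      stringsAsFactors = FALSE)
  }
  list(monitors = monitors, layout = do.call(rbind, layout),
       origin = origin, strain_truth = truth,
       fly_truth = do.call(rbind, fly_truth))
}

#' Configuration for the inbred-line panel simulator
#'
#' @param n_lines Number of fully inbred lines.
#' @param n_variants Number of simulated variants.
#' @param maf_range Uniform range of minor-allele frequencies.
#' @param n_causal Number of causal variants (ignored when `causal_idx`
#'   given).
#' @param causal_idx,causal_beta Explicit causal variant indices and
#'   effects; sampled when `NULL` (`beta ~ N(0, beta_sd)`).
#' @param beta_sd SD of sampled causal effects.
#' @param sigma2_poly Variance of the polygenic term (covariance
#'   proportional to the realized GRM).
#' @param sigma2_line Variance of the iid line-specific deviation.
#' @param h2_target Target broad-sense heritability of the per-fly value.
#' @param flies_per_line Replicate flies per line.
#' @param wolbachia_freq Infection frequency.
#' @param inversion_freqs Frequencies of the five inversion polymorphisms.
#' @param covariate_effects Effects of (wolbachia, 5 inversions) on the
#'   line value.
#' @param seed RNG seed.
#' @return A `panel_sim_config` list.
#' @export
panel_sim_config <- function(n_lines = 198, n_variants = 1000,
                             maf_range = c(0.05, 0.5), n_causal = 10,
                             causal_idx = NULL, causal_beta = NULL,
                             beta_sd = 0.3, sigma2_poly = 0.3,
                             sigma2_line = 0.1, h2_target = 0.38,
                             flies_per_line = 8, wolbachia_freq = 0.5,
                             inversion_freqs = rep(0.2, 5),
                             covariate_effects = c(0.3, rep(0.15, 5)),
                             seed = 1) {
  stopifnot(h2_target >= 0, h2_target < 1)
  if (!is.null(causal_idx) && any(causal_idx > n_variants)) {
    stop("causal variant index outside panel")
  }
  structure(as.list(environment()), class = "panel_sim_config")
}

#' Simulate an inbred-line genotype-phenotype panel
#'
#' Line values are the sum of covariate effects (Wolbachia + five
#' inversions), planted per-variant effects, a polygenic draw with
#' covariance proportional to the realized GRM, and an iid line deviation.
#' Per-fly values add Gaussian error scaled so the expected broad-sense
#' heritability equals `h2_target` (for `h2_target = 0` all line-level
#' components are zeroed and unit error is used).
#'
#' @param cfg A [panel_sim_config()].
#' @return List with `panel` (a `line_panel`), `covariates` (data frame),
#'   `phenotypes` (per-fly `line_id`, `value`), `line_values`, and `truth`
#'   (causal indices/effects, components, error SD).
#' @export
simulate_panel <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_lines
  m <- cfg$n_variants
  maf <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
  geno <- matrix(stats::rbinom(n * m, 1, rep(maf, each = n)), nrow = n)
  rownames(geno) <- sprintf("line_%03d", seq_len(n))
  colnames(geno) <- sprintf("v%04d", seq_len(m))
  panel <- line_panel(geno)
  wol <- stats::rbinom(n, 1, cfg$wolbachia_freq)
  inv <- vapply(cfg$inversion_freqs, function(f) stats::rbinom(n, 2, f),
                integer(n))
  covs <- data.frame(wolbachia = wol, inv)
  names(covs) <- c("wolbachia", sprintf("In%d", seq_along(cfg$inversion_freqs)))
  rownames(covs) <- rownames(geno)
  causal_idx <- cfg$causal_idx
  causal_beta <- cfg$causal_beta
  if (is.null(causal_idx)) {
    causal_idx <- if (cfg$n_causal > 0) sort(sample.int(m, cfg$n_causal))
                  else integer(0)
  }
  if (is.null(causal_beta)) {
    causal_beta <- stats::rnorm(length(causal_idx), 0, cfg$beta_sd)
  }
  if (cfg$h2_target == 0) {
    line_values <- rep(0, n)
    poly <- rep(0, n)
    sigma_e <- 1
  } else {
    cov_part <- as.matrix(covs) %*% cfg$covariate_effects
    var_part <- if (length(causal_idx))
      geno[, causal_idx, drop = FALSE] %*% causal_beta else rep(0, n)
    poly <- if (cfg$sigma2_poly > 0) {
      K <- compute_grm(panel)
      ek <- eigen(K, symmetric = TRUE)
      as.vector(ek$vectors %*% (sqrt(pmax(ek$values, 0)) * stats::rnorm(n))) *
        sqrt(cfg$sigma2_poly)
    } else rep(0, n)
    dev <- stats::rnorm(n, 0, sqrt(cfg$sigma2_line))
    line_values <- as.vector(cov_part + var_part) + poly + dev
    vl <- stats::var(line_values)
    sigma_e <- sqrt(vl * (1 - cfg$h2_target) / cfg$h2_target)
    if (!is.finite(sigma_e) || sigma_e == 0) sigma_e <- 1
  }
  phen <- data.frame(
    line_id = rep(rownames(geno), each = cfg$flies_per_line),
    value = rep(line_values, each = cfg$flies_per_line) +
      stats::rnorm(n * cfg$flies_per_line, 0, sigma_e),
    stringsAsFactors = FALSE)
  list(panel = panel, covariates = covs, phenotypes = phen,
       line_values = stats::setNames(line_values, rownames(geno)),
       truth = list(causal_idx = causal_idx, causal_beta = causal_beta,
                    maf = maf, sigma_e = sigma_e, polygenic = poly))
}

#' Configuration for the junction-count simulator
#'
#' With `clusters = NULL` the default emulates a starvation-response
#' splicing screen: 359 shifted intron clusters whose planted maximum
#' |delta-PSI| magnitudes fall 290 / 67 / 2 into the small (0.10-0.25),
#' intermediate (0.25-0.50) and large (> 0.50) bins, plus 100 null
#' clusters, plus one 10-intron cluster whose planted delta-PSIs are topped
#' by -0.12 and +0.06 (a syncrip-like alternative 3'-terminus cluster).
#'
#' @param clusters Optional list of cluster specs, each a list with
#'   `pi_food`, `pi_starved` (proportions summing to 1) and optional
#'   `depth`.
#' @param samples_per_condition Samples per condition.
#' @param depth Reads per cluster per sample.
#' @param rho_dm Dirichlet-multinomial overdispersion in [0, 1); 0 gives
#'   multinomial sampling.
#' @param n_small,n_intermediate,n_large,n_null Cluster counts for the
#'   default set.
#' @param seed RNG seed.
#' @return A `splicing_sim_config` list.
#' @export
splicing_sim_config <- function(clusters = NULL, samples_per_condition = 4,
                                depth = 2000, rho_dm = 0.005,
                                n_small = 290, n_intermediate = 67,
                                n_large = 2, n_null = 100, seed = 1) {
  stopifnot(rho_dm >= 0, rho_dm < 1)
  structure(as.list(environment()), class = "splicing_sim_config")
}

two_intron_cluster <- function(dpsi, base) {
  lo <- 0.02
  p_f <- min(max(base - dpsi / 2, lo + max(0, -dpsi)),
             1 - lo - max(0, dpsi))
  p_s <- p_f + dpsi
  list(pi_food = c(p_f, 1 - p_f), pi_starved = c(p_s, 1 - p_s),
       dpsi_planted = c(dpsi, -dpsi))
}

syp_like_cluster <- function() {
  pi_f <- c(0.30, 0.14, 0.10, 0.08, 0.08, 0.07, 0.06, 0.06, 0.06, 0.05)
  dpsi <- c(-0.12, 0.06, rep(0.0075, 8))
  list(pi_food = pi_f, pi_starved = pi_f + dpsi, dpsi_planted = dpsi)
}

default_cluster_set <- function(cfg) {
  mag <- c(stats::runif(cfg$n_small, 0.105, 0.245),
           stats::runif(cfg$n_intermediate, 0.255, 0.495),
           stats::runif(cfg$n_large, 0.52, 0.65),
           rep(0, cfg$n_null))
  sgn <- sample(c(-1, 1), length(mag), replace = TRUE)
  base <- stats::runif(length(mag), 0.35, 0.65)
  cl <- lapply(seq_along(mag), function(i)
    two_intron_cluster(sgn[i] * mag[i], base[i]))
  c(cl, list(syp_like_cluster()))
}

rdirichlet_multinom <- function(n_samples, size, pi, rho) {
  k <- length(pi)
  out <- matrix(0L, nrow = k, ncol = n_samples)
  for (s in seq_len(n_samples)) {
    p <- if (rho > 0) {
      a <- pi * (1 - rho) / rho
      g <- stats::rgamma(k, shape = a)
      if (sum(g) == 0) pi else g / sum(g)
    } else pi
    out[, s] <- stats::rmultinom(1, size, p)[, 1]
  }
  out
}

#' Simulate intron-junction counts with planted usage shifts
#'
#' Per sample, each cluster's counts are Dirichlet-multinomial draws around
#' the condition's planted usage proportions. Junction coordinates share a
#' cluster-specific start (alternative 3' splice sites) so the planted
#' clusters are exactly recoverable by [cluster_introns()].
#'
#' @param cfg A [splicing_sim_config()].
#' @return List with `junctions`, `counts`, `condition` and `truth`
#'   (per-intron planted delta-PSI with cluster ids).
#' @export
simulate_junctions <- function(cfg) {
  set.seed(cfg$seed)
  clusters <- cfg$clusters
  if (is.null(clusters)) clusters <- default_cluster_set(cfg)
  spc <- cfg$samples_per_condition
  condition <- rep(c("food", "starvation"), each = spc)
  jrows <- list()
  crows <- list()
  trows <- list()
  for (ci in seq_along(clusters)) {
    cl <- clusters[[ci]]
    k <- length(cl$pi_food)
    depth <- if (!is.null(cl$depth)) cl$depth else cfg$depth
    xf <- rdirichlet_multinom(spc, depth, cl$pi_food, cfg$rho_dm)
    xs <- rdirichlet_multinom(spc, depth, cl$pi_starved, cfg$rho_dm)
    base_pos <- ci * 100000L
    ids <- sprintf("clu%04d_j%d", ci, seq_len(k))
    jrows[[ci]] <- data.frame(id = ids, chrom = "3R",
                              start = base_pos,
                              end = base_pos + 500L * seq_len(k),
                              strand = "+", stringsAsFactors = FALSE)
    cmat <- cbind(xf, xs)
    rownames(cmat) <- ids
    crows[[ci]] <- cmat
    trows[[ci]] <- data.frame(
      intron_id = ids, planted_cluster = sprintf("planted_%04d", ci),
      dpsi_planted = if (!is.null(cl$dpsi_planted)) cl$dpsi_planted else
        cl$pi_starved - cl$pi_food,
      stringsAsFactors = FALSE)
  }
  junctions <- do.call(rbind, jrows)
  counts <- do.call(rbind, crows)
  colnames(counts) <- sprintf("%s_%d", substr(condition, 1, 1),
                              c(seq_len(spc), seq_len(spc)))
  list(junctions = junctions, counts = counts, condition = condition,
       truth = do.call(rbind, trows))
}

#' Configuration for the gene-count simulator
#'
#' @param n_genes Number of genes.
#' @param samples_per_condition Samples per condition.
#' @param mean_log_mu,sd_log_mu Lognormal baseline-mean parameters.
#' @param dispersion NB dispersion (shared).
#' @param n_de Number of differentially expressed genes (half up, half
#'   down).
#' @param lfc Absolute log2 fold change planted in DE genes.
#' @param depth_range Uniform range of per-sample depth factors.
#' @param seed RNG seed.
#' @return An `expr_sim_config` list.
#' @export
expr_sim_config <- function(n_genes = 2000, samples_per_condition = 4,
                            mean_log_mu = log(200), sd_log_mu = 1,
                            dispersion = 0.05, n_de = 100, lfc = 2,
                            depth_range = c(0.7, 1.4), seed = 1) {
  structure(as.list(environment()), class = "expr_sim_config")
}

#' Simulate a gene x sample count matrix with planted fold changes
#'
#' Counts are negative binomial around `mu * depth_s * 2^(+/- lfc / 2)`
#' (the planted fold change split symmetrically across conditions).
#'
#' @param cfg An [expr_sim_config()].
#' @return List with `counts`, `condition`, `truth` (per-gene `de`
#'   in \{-1, 0, 1\} and `lfc_planted`).
#' @export
simulate_expression <- function(cfg) {
  set.seed(cfg$seed)
  g <- cfg$n_genes
  spc <- cfg$samples_per_condition
  condition <- rep(c("food", "starvation"), each = spc)
  mu <- stats::rlnorm(g, cfg$mean_log_mu, cfg$sd_log_mu)
  de <- rep(0L, g)
  n_de <- min(cfg$n_de, g)
  if (n_de > 0) {
    idx <- sample.int(g, n_de)
    de[idx] <- rep(c(1L, -1L), length.out = n_de)
  }
  lfc_planted <- de * cfg$lfc
  depth <- stats::runif(2 * spc, cfg$depth_range[1], cfg$depth_range[2])
  counts <- matrix(0L, nrow = g, ncol = 2 * spc,
                   dimnames = list(sprintf("gene_%04d", seq_len(g)),
                                   sprintf("%s_%d", substr(condition, 1, 1),
                                           c(seq_len(spc), seq_len(spc)))))
  for (s in seq_len(2 * spc)) {
    shift <- ifelse(condition[s] == "starvation", 1, -1) * lfc_planted / 2
    mu_s <- mu * depth[s] * 2^shift
    counts[, s] <- stats::rnbinom(g, mu = mu_s, size = 1 / cfg$dispersion)
  }
  list(counts = counts, condition = condition,
       truth = data.frame(gene_id = rownames(counts), de = de,
                          lfc_planted = lfc_planted,
                          stringsAsFactors = FALSE))
}
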