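test_that("generators are seed-deterministic", {
  a1 <- simulate_activity(activity_sim_config(n_strains = 3, seed = 40))
  a2 <- simulate_activity(activity_sim_config(n_strains = 3, seed = 40))
  expect_identical(lapply(a1$monitors, `[[`, "counts"),
                   lapply(a2$monitors, `[[`, "counts"))
  p1 <- simulate_panel(panel_sim_config(n_lines = 30, n_variants = 50,
                                        seed = 41))
  p2 <- simulate_panel(panel_sim_config(n_lines = 30, n_variants = 50,
                                        seed = 41))
  expect_identical(p1$panel$geno, p2$panel$geno)
  expect_identical(p1$phenotypes, p2$phenotypes)
  j1 <- simulate_junctions(splicing_sim_config(n_small = 5,
                                               n_intermediate = 2,
                                               n_large = 0, n_null = 2,
                                               seed = 42))
  j2 <- simulate_junctions(splicing_sim_config(n_small = 5,
                                               n_intermediate = 2,
                                               n_large = 0, n_null = 2,
                                               seed = 42))
  expect_identical(j1$counts, j2$counts)
  e1 <- simulate_expression(expr_sim_config(n_genes = 50, seed = 43))
  e2 <- simulate_expression(expr_sim_config(n_genes = 50, seed = 43))
  expect_identical(e1$counts, e2$counts)
})

test_that("activity design is balanced and deaths silence later bins", {
  tr <- data.frame(strain_id = c("sA", "sB"), delta = c(200, 400),
                   sr = c(55L, NA), scale = 1,
                   death_time = c(40L, NA))
  sim <- simulate_activity(activity_sim_config(n_strains = 2,
                                               strain_truth = tr,
                                               seed = 44))
  at <- to_activity_table(sim$monitors, sim$layout, sim$origin)
  tab <- table(unique(at[, c("fly_id", "strain_id", "condition")])[, -1])
  expect_true(all(tab == 8))
  # death_time = 40: all starved sA bins 41..119 are zero
  sa <- at[at$strain_id == "sA" & at$condition == "starvation", ]
  expect_true(all(sa$count[sa$bin_index > 40] == 0))
  expect_true(any(sa$count[sa$bin_index == 40] > 0))
  # food flies unaffected by death
  fa <- at[at$strain_id == "sA" & at$condition == "food", ]
  expect_gt(sum(fa$count[fa$bin_index > 40]), 0)
  expect_equal(starvation_resistance(at)$sr[1], 41L)
})

test_that("null strains show window DAs near zero; planted delta recovers", {
  tr0 <- data.frame(strain_id = sprintf("s%02d", 1:30), delta = 0,
                    sr = NA_integer_, scale = 1)
  sim0 <- simulate_activity(activity_sim_config(n_strains = 30,
                                                strain_truth = tr0,
                                                seed = 45))
  at0 <- to_activity_table(sim0$monitors, sim0$layout, sim0$origin)
  das0 <- delta_activity(window_sums(at0))
  wmat <- as.matrix(das0[, paste0("da_", c("N1", "D1", "N2", "D2", "N3"))])
  sem <- sd(wmat) / sqrt(length(wmat))
  expect_lt(abs(mean(wmat)), 3 * sem)
})

test_that("the simulated circadian profile is bimodal", {
  lam <- circadian_profile()
  expect_equal(which.max(lam[1:24]), 1L)         # lights-off peak
  expect_gt(lam[25], lam[12])                    # lights-on peak vs trough
  expect_true(all(lam >= 0))
})

test_that("panel simulator: null heritability estimates are near zero", {
  set.seed(50)
  est <- replicate(60, {
    s <- simulate_panel(panel_sim_config(n_lines = 80, n_variants = 20,
                                         h2_target = 0,
                                         seed = sample.int(1e6, 1)))
    variance_components(s$phenotypes$line_id, s$phenotypes$value)$H2
  })
  expect_lt(abs(mean(est)), 0.02)
})

test_that("panel simulator validates causal indices and genotypes", {
  expect_error(panel_sim_config(n_variants = 10, causal_idx = 11),
               "outside panel")
  s <- simulate_panel(panel_sim_config(n_lines = 40, n_variants = 30,
                                       seed = 46))
  expect_true(all(s$panel$geno %in% c(0, 1)))
  expect_true(all(s$panel$maf <= 0.5))
  expect_equal(nrow(s$phenotypes), 40 * 8)
})

test_that("junction simulator plants recoverable usage shifts", {
  cfg <- splicing_sim_config(
    clusters = list(list(pi_food = c(0.7, 0.3), pi_starved = c(0.3, 0.7))),
    depth = 1000, rho_dm = 0, samples_per_condition = 4, seed = 47)
  sim <- simulate_junctions(cfg)
  cl <- cluster_introns(sim$junctions, sim$counts)
  psi <- compute_psi(cl[[1]], sim$condition)
  expect_equal(psi$dpsi[1], -0.40, tolerance = 0.03)
  # rho 0 and equal proportions -> dpsi ~ 0
  cfg0 <- splicing_sim_config(
    clusters = list(list(pi_food = c(0.5, 0.5), pi_starved = c(0.5, 0.5))),
    depth = 1000, rho_dm = 0, seed = 48)
  sim0 <- simulate_junctions(cfg0)
  psi0 <- compute_psi(cluster_introns(sim0$junctions, sim0$counts)[[1]],
                      sim0$condition)
  expect_lt(abs(psi0$dpsi[1]), 0.05)
})

test_that("expression simulator records truth and plants fold changes", {
  sim <- simulate_expression(expr_sim_config(n_genes = 400, n_de = 40,
                                             lfc = 2, seed = 49))
  expect_equal(sum(sim$truth$de != 0), 40L)
  q <- sweep(sim$counts, 2, size_factors(sim$counts), "/")
  up <- sim$truth$de == 1
  lfc_obs <- log2(rowMeans(q[, sim$condition == "starvation"]) + 0.5) -
    log2(rowMeans(q[, sim$condition == "food"]) + 0.5)
  expect_gt(mean(lfc_obs[up]), 1.5)
  expect_lt(abs(mean(lfc_obs[sim$truth$de == 0])), 0.1)
})
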