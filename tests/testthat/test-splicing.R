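test_that("junctions sharing splice sites form one cluster", {
  j <- data.frame(id = c("ad", "ab", "cd"), chrom = "2L",
                  start = c(100, 100, 300), end = c(400, 200, 400),
                  strand = "+")
  cnt <- matrix(20, 3, 4, dimnames = list(j$id, NULL))
  cl <- cluster_introns(j, cnt, min_cluster_reads = 30)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$junctions$id, c("ad", "ab", "cd"))
})

test_that("unconnected junction sets split into separate clusters", {
  j <- data.frame(id = c("a1", "a2", "b1", "b2"), chrom = "2L",
                  start = c(100, 100, 9000, 9000),
                  end = c(200, 300, 9100, 9200), strand = "+")
  cnt <- matrix(25, 4, 4, dimnames = list(j$id, NULL))
  cl <- cluster_introns(j, cnt)
  expect_length(cl, 2L)
})

test_that("clustering matches a union-find oracle and ignores input order", {
  set.seed(23)
  n <- 40
  j <- data.frame(id = sprintf("j%02d", 1:n),
                  chrom = sample(c("2L", "3R"), n, TRUE),
                  start = sample(seq(100, 1000, by = 100), n, TRUE),
                  end = sample(seq(2000, 3000, by = 100), n, TRUE),
                  strand = sample(c("+", "-"), n, TRUE))
  cnt <- matrix(50, n, 4, dimnames = list(j$id, NULL))
  cl <- cluster_introns(j, cnt, min_cluster_reads = 0,
                        min_intron_fraction = 0)
  got <- lapply(cl, function(c) sort(c$junctions$id))
  ref_comp <- uf_components(j)
  want <- unname(lapply(split(j$id, ref_comp), sort))
  want <- want[lengths(want) >= 2]  # single-intron clusters are dropped
  expect_setequal(lapply(got, paste, collapse = ","),
                  lapply(want, paste, collapse = ","))
  perm <- sample(n)
  cl2 <- cluster_introns(j[perm, ], cnt[perm, ], min_cluster_reads = 0,
                         min_intron_fraction = 0)
  got2 <- lapply(cl2, function(c) sort(c$junctions$id))
  expect_setequal(lapply(got2, paste, collapse = ","),
                  lapply(got, paste, collapse = ","))
})

test_that("low-coverage introns and small clusters are pruned", {
  j <- data.frame(id = c("a", "b", "tiny"), chrom = "2L",
                  start = c(100, 100, 100), end = c(200, 300, 400),
                  strand = "+")
  cnt <- rbind(a = rep(500, 4), b = rep(500, 4), tiny = rep(0.4, 4))
  cl <- cluster_introns(j, cnt, min_cluster_reads = 30,
                        min_intron_fraction = 0.001)
  expect_setequal(cl[[1]]$junctions$id, c("a", "b"))
  cl2 <- cluster_introns(j, cnt * 0.001, min_cluster_reads = 30)
  expect_length(cl2, 0L)
})

test_that("PSI is the within-cluster count share per condition", {
  cond <- rep(c("food", "starvation"), each = 2)
  cl <- make_cluster(cbind(c(30, 15, 5), c(30, 15, 5),
                           c(10, 10, 30), c(10, 10, 30)))
  psi <- compute_psi(cl, cond)
  expect_equal(psi$psi_food, c(0.6, 0.3, 0.1))
  expect_equal(psi$psi_starved, c(0.2, 0.2, 0.6))
  expect_equal(psi$dpsi, psi$psi_starved - psi$psi_food)
  expect_equal(sum(psi$psi_food), 1)
  # single-intron cluster: PSI 1 in both conditions
  psi1 <- compute_psi(make_cluster(matrix(c(5, 5, 5, 5), 1)), cond)
  expect_equal(psi1$psi_food, 1)
  expect_equal(psi1$psi_starved, 1)
  # dPSI is antisymmetric under swapping condition labels
  psi_sw <- compute_psi(cl, rev(cond))
  expect_equal(psi_sw$dpsi, -psi$dpsi)
})

test_that("test_cluster: null gives p ~ 1, strong shifts give tiny p", {
  cond <- rep(c("food", "starvation"), each = 4)
  same <- make_cluster(matrix(rep(c(70, 30), 8), nrow = 2))
  r0 <- test_cluster(same, cond)
  expect_gt(r0$p_value, 0.99)
  shift <- make_cluster(cbind(matrix(rep(c(175, 75), 4), 2),
                              matrix(rep(c(75, 175), 4), 2)))
  # the Dirichlet-multinomial path still flags the shift
  expect_lt(test_cluster(shift, cond)$p_value, 0.05)
  # pooled-count multinomial G-test path
  r1 <- test_cluster(shift, cond, method = "g")
  expect_lt(r1$p_value, 1e-10)
  # multinomial G statistic closed form (pooled 700/300 vs 300/700)
  of <- c(700, 300); os <- c(300, 700)
  p0 <- (of + os) / sum(of + os)
  g_manual <- 2 * sum(of * log(of / (1000 * p0))) +
    2 * sum(os * log(os / (1000 * p0)))
  expect_equal(r1$statistic, g_manual, tolerance = 1e-8)
  expect_equal(r1$df, 1)
  expect_error(test_cluster(make_cluster(matrix(5, 1, 8)), cond),
               "single intron")
})

test_that("multinomial G-test p-values are uniform under the null", {
  set.seed(24)
  cond <- rep(c("food", "starvation"), each = 4)
  ps <- replicate(800, {
    cnt <- rmultinom(8, 1000, c(0.5, 0.5))
    rownames(cnt) <- c("a", "b")
    test_cluster(make_cluster(cnt), cond)$p_value
  })
  expect_lt(suppressWarnings(ks.test(ps, "punif"))$statistic, 0.05)
})

test_that("FDR and magnitude classes apply the reported boundaries", {
  res <- data.frame(cluster_id = sprintf("c%d", 1:5),
                    p_value = c(1e-6, 1e-6, 1e-6, 1e-6, 0.9),
                    max_abs_dpsi = c(0.25, 0.51, 0.10, 0.12, 0.4))
  out <- fdr_and_classify(res)
  expect_equal(out$magnitude_class,
               c("intermediate", "large", "below-threshold", "small",
                 "intermediate"))
  expect_equal(out$fdr, p.adjust(res$p_value, "BH"))
  expect_true(all(out$significant[1:4]), !out$significant[5])
})

test_that("junction tables round-trip through TSV", {
  sim <- simulate_junctions(splicing_sim_config(
    clusters = list(two_intron <- list(pi_food = c(0.5, 0.5),
                                       pi_starved = c(0.3, 0.7))),
    seed = 25))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_junction_table(sim$junctions, sim$counts, path)
  back <- read_junction_table(path)
  expect_equal(unname(back$counts), unname(sim$counts))
  expect_equal(back$junctions$start, sim$junctions$start)
})
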