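test_that("window sums match their definitions and a loop oracle", {
  m <- make_monitor(matrix(1L, 120, 32))
  at <- to_activity_table(m, simple_layout(2), "2020-01-01 18:00:00")
  ws <- window_sums(at)
  expect_true(all(as.matrix(ws[, c("N1", "D1", "N2", "D2", "N3")]) == 24))

  # bins 0-23 = 2, rest 0
  cnt <- matrix(0L, 120, 32); cnt[1:24, ] <- 2L
  at2 <- to_activity_table(make_monitor(cnt), simple_layout(1),
                           "2020-01-01 18:00:00")
  ws2 <- window_sums(at2)
  expect_equal(unname(unlist(ws2[1, c("N1", "D1", "N2", "D2", "N3")])),
               c(48, 0, 0, 0, 0))

  # random fixture vs independent loop summation
  set.seed(4)
  cnt3 <- matrix(rpois(120 * 32, 6), 120, 32)
  at3 <- to_activity_table(make_monitor(cnt3), simple_layout(4),
                           "2020-01-01 18:00:00")
  ws3 <- window_sums(at3)
  for (f in seq_len(4)) {
    v <- at3$count[at3$fly_id == sprintf("f%02d", f)]
    v <- v[order(at3$bin_index[at3$fly_id == sprintf("f%02d", f)])]
    manual <- numeric(5)
    for (w in 1:5) for (b in ((w - 1) * 24 + 1):(w * 24)) {
      manual[w] <- manual[w] + v[b]
    }
    expect_equal(unname(unlist(
      ws3[ws3$fly_id == sprintf("f%02d", f),
          c("N1", "D1", "N2", "D2", "N3")])), manual)
  }
})

test_that("incomplete windows are NA and flagged", {
  m <- make_monitor(matrix(1L, 100, 32))  # bins 0-99: N3 incomplete
  at <- to_activity_table(m, simple_layout(1), "2020-01-01 18:00:00")
  expect_warning(ws <- window_sums(at), "incomplete")
  expect_true(is.na(ws$N3))
  expect_equal(ws$N1, 24)
})

test_that("delta activity is starved total minus strain food mean, max over windows", {
  baseline <- data.frame(strain_id = "s1", N1 = 100, D1 = 80, N2 = 100,
                         D2 = 80, N3 = 100)
  ws <- make_ws("fly1", "s1", "starvation", c(150, 200, 120, 90, 100))
  das <- delta_activity(ws, baseline)
  expect_equal(unname(unlist(das[1, paste0("da_", c("N1", "D1", "N2", "D2",
                                                    "N3"))])),
               c(50, 120, 20, 10, 0))
  expect_equal(das$da, 120)

  # starved equals baseline -> all zero
  ws0 <- make_ws("fly2", "s1", "starvation", c(100, 80, 100, 80, 100))
  das0 <- delta_activity(ws0, baseline)
  expect_equal(das0$da, 0)
})

test_that("DA is the signed maximum, and translation-equivariant", {
  baseline <- data.frame(strain_id = "s1", N1 = 0, D1 = 0, N2 = 0, D2 = 0,
                         N3 = 0)
  ws <- make_ws("f1", "s1", "starvation", c(-5, -40, -10, -20, -30) + 50)
  baseline[, 2:6] <- 50
  das <- delta_activity(ws, baseline)
  expect_equal(das$da, -5)  # signed maximum, not max |.|
  c_shift <- 7 * 24
  ws_shift <- ws
  ws_shift[, 4:8] <- ws_shift[, 4:8] + c_shift
  das2 <- delta_activity(ws_shift, baseline)
  expect_equal(das2$da, das$da + c_shift)
})

test_that("strain summary: mean, SEM, baseline, permutation invariance", {
  das <- data.frame(fly_id = c("a", "b", "c"), strain_id = "s1",
                    da = c(10, 20, 30))
  cnt <- matrix(2L, 120, 32)
  at <- to_activity_table(make_monitor(cnt),
                          simple_layout(2, condition = "food"),
                          "2020-01-01 18:00:00")
  s <- strain_summary(das, at)
  expect_equal(s$da_mean, 20)
  expect_equal(s$da_sem, 10 / sqrt(3))
  expect_equal(s$baseline, 240)
  s_perm <- strain_summary(das[c(3, 1, 2), ], at)
  expect_equal(s_perm, s)
  # identical flies -> SEM 0; single fly -> SEM missing
  expect_equal(strain_summary(transform(das, da = 5), at)$da_sem, 0)
  expect_true(is.na(strain_summary(das[1, ], at)$da_sem))
})

test_that("starvation resistance follows the death-bin rule", {
  mk_at <- function(last_active) {
    rows <- lapply(seq_along(last_active), function(i) {
      cnt <- integer(120)
      if (last_active[i] >= 0) cnt[seq_len(last_active[i] + 1)] <- 1L
      data.frame(fly_id = sprintf("f%d", i), strain_id = "s1",
                 condition = "starvation", monitor_id = "M1", channel = i,
                 bin_index = 0:119, count = cnt)
    })
    do.call(rbind, rows)
  }
  expect_equal(starvation_resistance(mk_at(c(9, 19, 54)))$sr, 55L)
  expect_equal(starvation_resistance(mk_at(119))$sr, 121L)  # survivor
  expect_equal(starvation_resistance(mk_at(-1))$sr, 0L)     # all-zero
  # monotone: extending a fly's activity never decreases SR
  base <- starvation_resistance(mk_at(c(9, 19, 54)))$sr
  expect_gte(starvation_resistance(mk_at(c(9, 19, 80)))$sr, base)
})

test_that("strain_phenotypes assembles the full S1-style table", {
  cfg <- activity_sim_config(n_strains = 4, seed = 6)
  sim <- simulate_activity(cfg)
  at <- to_activity_table(sim$monitors, sim$layout, sim$origin)
  phen <- strain_phenotypes(at)
  expect_setequal(names(phen), c("strain_id", "da_mean", "da_sem", "sr",
                                 "baseline", "n_flies"))
  expect_equal(nrow(phen), 4L)
  expect_true(all(phen$n_flies == 8L))
  expect_true(all(phen$sr >= 0 & phen$sr <= 121))
})
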