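test_that("normalization coefficient is the ratio of input means", {
  expect_equal(normalization_coefficient(c(2, 2, 2), c(1, 1, 1)), 2)
  expect_equal(normalization_coefficient(c(1, 2, 3), c(3, 2, 1)), 1)
  expect_warning(normalization_coefficient(c(10, 10, 10), c(1, 1, 1)),
                 "plausible")
  expect_error(normalization_coefficient(c(0, 0, 0), c(1, 1, 1)),
               "positive")
  expect_equal(fold_deviation(c(0.5, 1, 2)), c(2, 1, 2))
})

test_that("equal-chromatin extract pairs give k inside the observed envelope", {
  # triplicate inputs with 20% CV from identical chromatin amounts
  set.seed(20)
  k <- replicate(400, normalization_coefficient(
    noisy_signals(3, 1e6, 0.2), noisy_signals(3, 1e6, 0.2)))
  expect_gt(mean(k >= 0.6 & k <= 1.55), 0.95)
})

test_that("specific signal subtracts the mutant background with quadrature errors", {
  s <- specific_signal(c(12, 12, 12), c(4, 4, 4), k = 1.2)
  expect_equal(s$value, 6)
  expect_equal(specific_signal(c(5, 5, 5), c(5, 5, 5), k = 1)$value, 0)

  wt <- summarize_triplicate(c(20, 20, 20))
  wt$sd_signal <- 3; wt$mean_signal <- 10
  mut <- wt; mut$sd_signal <- 4; mut$mean_signal <- 2
  expect_equal(specific_signal(wt, mut, k = 1)$sd, 5)   # 3-4-5 quadrature

  nd <- specific_signal(summarize_triplicate(c(20, NA, NA)),
                        summarize_triplicate(c(20, 20, 20)), k = 1)
  expect_true(nd$nd)
})

test_that("percent occupancy divides by the pooled normalized input", {
  spec <- list(value = 5, sd = 1, nd = FALSE)
  p <- percent_occupancy(spec, wt_input = c(100, 100, 100),
                         mut_input = c(100, 100, 100), k = 1)
  expect_equal(p$percent, 5)
  expect_equal(p$sd, 1)

  # wild-type inputs are divided by k before pooling (fixed point of k)
  wt_in <- c(180, 210, 190); mut_in <- c(95, 105, 100)
  k <- normalization_coefficient(wt_in, mut_in)
  expect_equal(mean(wt_in / k), mean(mut_in))

  p2 <- percent_occupancy(spec, wt_in, mut_in, k,
                          propagate_input_error = TRUE)
  expect_gt(p2$sd, 100 * spec$sd / p2$input_avg)  # extra variance term
  expect_error(percent_occupancy(spec, -wt_in, -mut_in, k), "positive")
})

test_that("occupancy t-test matches the hand-computed statistic and codes", {
  r <- occupancy_significance(c(10, 11, 12), c(4, 5, 6))
  expect_equal(r$t, 7.34846922834953, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p_value, 0.00182626066825998, tolerance = 1e-12)
  expect_equal(r$code, "***")

  same <- occupancy_significance(c(3, 3, 3), c(3, 3, 3))
  expect_equal(same$p_value, 1)
  expect_equal(same$code, "ne")
  degen <- occupancy_significance(c(4, 4, 4), c(3, 3, 3))
  expect_equal(degen$p_value, 0)
  expect_equal(degen$code, "****")
  expect_equal(occupancy_significance(c(1, NA, NA), c(1, 2, 3))$code, "nd")
})

test_that("significance codes follow the fixed confidence table", {
  expect_equal(significance_code(c(5e-5, 0.005, 0.04, 0.07, 0.2, 0.5)),
               c("****", "***", "**", "*", "±", "ne"))
  expect_equal(significance_code(NA_real_), "nd")
})

test_that("co-factor differential test detects a planted occupancy drop", {
  expect_equal(hdac_differential(c(5, 5, 5), c(5, 5, 5), k = 1)$code, "ne")
  expect_equal(hdac_differential(c(5, NA, NA), c(5, 5, 5), k = 1)$code, "nd")

  # planted 2-fold HDAC loss at 10% CV: detected at ** or better in the
  # majority of seeded runs
  set.seed(30)
  codes <- replicate(200, {
    hdac_differential(noisy_signals(3, 10, 0.1),
                      noisy_signals(3, 5, 0.1), k = 1)$p_value
  })
  expect_gt(mean(codes < 0.05), 0.5)
})

test_that("plate-level analysis satisfies the arithmetic and scale invariants", {
  cfg <- chip_sim_config(seed = 77)
  plate <- simulate_chip_pair(cfg, c("a1", "a2", "a3"))
  occ <- analyze_occupancy(plate)
  # conservation identity: normalized WT precipitate = specific + background
  expect_equal(occ$specific_signal + occ$mutppt, occ$wtppt_norm)
  expect_true(all(occ$primary))

  # shifting every Ct by a constant rescales all signals by a common
  # factor and must change nothing downstream
  plate2 <- plate
  plate2$ct <- plate2$ct - 2          # 4x more material everywhere
  occ2 <- analyze_occupancy(plate2)
  expect_equal(occ2$percent_occupancy, occ$percent_occupancy)
  expect_equal(occ2$p_value, occ$p_value)
  expect_equal(occ2$code, occ$code)
  expect_equal(occ2$k, occ$k)
})

test_that("amplicons measured in several extract pairs flag the most significant", {
  p1 <- simulate_chip_pair(chip_sim_config(seed = 5, ct_noise_sd = 0.05),
                           "amp1", pair_id = "pairA")
  p2 <- simulate_chip_pair(chip_sim_config(seed = 6, ct_noise_sd = 0.6),
                           "amp1", pair_id = "pairB")
  occ <- analyze_occupancy(rbind(p1, p2))
  expect_equal(nrow(occ), 2L)
  expect_equal(sum(occ$primary), 1L)
  expect_equal(occ$pair_id[occ$primary], occ$pair_id[which.min(occ$p_value)])
})
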