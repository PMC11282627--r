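test_that("invalid configurations are rejected with the offending field named", {
  expect_error(generator_config(p_facility = 1.2), "p_facility")
  expect_error(generator_config(missingness_rate = 1), "missingness_rate")
  expect_error(generator_config(n_psu_per_stratum = 1), "n_psu_per_stratum")
  expect_error(generator_config(p_sba_given_home = -0.1), "p_sba_given_home")
  expect_error(generator_config(mmr_noise_sd = -5), "mmr_noise_sd")
})

test_that("identical seed and config give identical output; seeds differ otherwise", {
  cfg <- generator_config(n_countries = 3, women_per_country = 200, seed = 11)
  a <- generate_population(cfg)
  b <- generate_population(cfg)
  expect_identical(a, b)
  expect_identical(generate_mmr(a$truth, cfg), generate_mmr(b$truth, cfg))
  cfg2 <- generator_config(n_countries = 3, women_per_country = 200, seed = 12)
  expect_false(identical(generate_population(cfg2)$women, a$women))
})

test_that("degenerate probabilities pin every downstream score", {
  top <- generator_config(n_countries = 2, women_per_country = 50,
                          p_facility = 1, p_hospital_given_facility = 1,
                          p_sba_given_facility = 1, p_stay24_given_facility = 1,
                          p_pnc48_given_facility = 1, missingness_rate = 0,
                          wealth_gradient = 0, seed = 3)
  sc <- score_women(generate_population(top)$women)
  expect_true(all(sc$score_total == 5L))

  bottom <- generator_config(n_countries = 2, women_per_country = 50,
                             p_facility = 0, p_sba_given_home = 0,
                             p_pnc48_given_home = 0, missingness_rate = 0,
                             wealth_gradient = 0, seed = 3)
  sc0 <- score_women(generate_population(bottom)$women)
  expect_true(all(sc0$score_total == 0L))
})

test_that("home births never report a 24+ hour facility stay", {
  cfg <- generator_config(n_countries = 3, women_per_country = 500,
                          p_facility = 0.3, missingness_rate = 0.05, seed = 5)
  women <- generate_population(cfg)$women
  expect_true(all(women$stay24[women$place == "home"] %in% c("no", "missing")))
})

test_that("empirical component proportions converge to configured probabilities", {
  n <- 20000
  cfg <- generator_config(n_countries = 1, women_per_country = n,
                          p_facility = 0.76, p_hospital_given_facility = 0.5,
                          p_sba_given_facility = 0.97, p_sba_given_home = 0.18,
                          p_stay24_given_facility = 0.89,
                          wealth_gradient = 0, missingness_rate = 0, seed = 21)
  women <- generate_population(cfg)$women
  mc_se <- function(p) sqrt(p * (1 - p) / n)

  p_fac <- mean(women$place %in% c("lower", "hospital"))
  expect_lt(abs(p_fac - 0.76), 3 * mc_se(0.76))

  p_sba_true <- 0.76 * 0.97 + 0.24 * 0.18
  expect_lt(abs(mean(women$sba == "yes") - p_sba_true), 3 * mc_se(p_sba_true))

  p_stay_true <- 0.76 * 0.89
  expect_lt(abs(mean(women$stay24 == "yes") - p_stay_true),
            3 * mc_se(p_stay_true))
})

test_that("a positive wealth gradient makes facility delivery non-decreasing in quintile", {
  cfg <- generator_config(n_countries = 1, women_per_country = 50000,
                          p_facility = 0.6, wealth_gradient = 0.5,
                          missingness_rate = 0, seed = 8)
  women <- generate_population(cfg)$women
  by_q <- tapply(women$place %in% c("lower", "hospital"),
                 women$wealth_quintile, mean)
  expect_true(all(diff(by_q) >= 0))
})

test_that("weights are positive and sum to the country sample size", {
  cfg <- generator_config(n_countries = 3, women_per_country = c(100, 250, 400),
                          seed = 2)
  women <- generate_population(cfg)$women
  expect_true(all(women$weight > 0))
  sums <- tapply(women$weight, women$country_id, sum)
  expect_equal(as.numeric(sums), c(100, 250, 400), tolerance = 1e-9)
})

test_that("generate_mmr follows the linear truth model", {
  cfg <- generator_config(n_countries = 3, women_per_country = 50,
                          mmr_intercept = 900, mmr_slope = -8,
                          mmr_noise_sd = 0, seed = 4)
  truth <- true_values(cfg)
  mmr <- generate_mmr(truth, cfg)
  expect_equal(mmr$mmr, pmax(0, 900 - 8 * truth$true_score), tolerance = 1e-9)

  # closed-form corners of the linear model
  truth100 <- truth
  truth100$true_score <- c(100, 0, 50)
  mmr2 <- generate_mmr(truth100, cfg)
  expect_equal(mmr2$mmr, c(100, 900, 500))
})

test_that("truth table satisfies the scoring linearity identity", {
  cfg <- generator_config(n_countries = 4, women_per_country = 50,
                          missingness_rate = 0.1, seed = 6)
  truth <- true_values(cfg)
  lhs <- truth$true_score
  rhs <- (2 * truth$p_hospital + truth$p_lower + truth$p_sba +
            truth$p_stay24 + truth$p_pnc48) / 5 * 100
  expect_equal(lhs, rhs, tolerance = 1e-12)
})
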