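test_that("weighted coverage reproduces hand-computed estimates", {
  w <- score_women(make_women(place = c("hospital", "home"),
                              sba = c("yes", "no"), stay24 = c("yes", "no"),
                              pnc48 = c("yes", "no"), weight = c(1, 1)))
  expect_equal(weighted_coverage(w, "delivery_care")$point, 50)

  w2 <- score_women(make_women(place = c("hospital", "home"),
                               weight = c(3, 1)))
  expect_equal(weighted_coverage(w2, "facility")$point, 75)
  expect_equal(weighted_coverage(w2, "hospital")$point, 75)

  all1 <- score_women(make_women(place = rep("lower", 4),
                                 weight = c(0.2, 5, 1, 9)))
  expect_equal(weighted_coverage(all1, "facility")$point, 100)

  expect_error(weighted_coverage(w[0, ], "facility"), "empty")
  expect_error(weighted_coverage(w, "facility", weights = c(0, 0)), "positive")
  expect_error(indicator_values(w, "nonsense"), "unknown indicator")
})

test_that("pooled estimate equals the unweighted mean of country estimates and is size-invariant", {
  a <- make_women(place = "hospital", sba = "no", stay24 = "no", pnc48 = "no",
                  country_id = "A")[rep(1, 10), ]      # care coverage 40
  b <- make_women(place = "hospital", sba = "yes", stay24 = "yes",
                  pnc48 = "yes", country_id = "B")[rep(1, 400), ]  # 100
  b$psu <- rep(c("1", "2"), 200)
  pooled <- pooled_estimate(score_women(dplyr::bind_rows(a, b)), "delivery_care")
  expect_equal(pooled$point, 70, tolerance = 1e-12)

  # replicating one country k-fold must not move the pooled estimate
  b_rep <- b[rep(seq_len(nrow(b)), 5), ]
  pooled_rep <- pooled_estimate(score_women(dplyr::bind_rows(a, b_rep)),
                                "delivery_care")
  expect_equal(pooled_rep$point, pooled$point, tolerance = 1e-12)

  # arbitrary within-country weights: identity still holds after the
  # internal normalization
  gen <- generate_population(generator_config(n_countries = 4,
                                              women_per_country = c(100, 900, 50, 300),
                                              seed = 13))
  sc <- score_women(gen$women)
  per_country <- vapply(split(sc, sc$country_id),
                        function(s) weighted_coverage(s, "delivery_care")$point,
                        numeric(1))
  expect_equal(pooled_estimate(sc, "delivery_care")$point,
               mean(per_country), tolerance = 1e-9)
})

test_that("country summary uses linear-interpolation quartiles", {
  s <- country_summary(c(10, 20, 30))
  expect_equal(s$median, 20)
  expect_equal(s$q1, 15)
  expect_equal(s$q3, 25)

  one <- country_summary(42)
  expect_equal(unlist(one[c("median", "q1", "q3")]),
               c(median = 42, q1 = 42, q3 = 42))
  expect_equal(country_summary(rep(7, 5))$q3 - country_summary(rep(7, 5))$q1, 0)
  expect_error(country_summary(numeric(0)), "no country")
})

test_that("score distribution is a weighted probability over 0-5", {
  top <- score_women(make_women(place = rep("hospital", 4)))
  expect_equal(score_distribution(top)$proportion, c(0, 0, 0, 0, 0, 1))

  mix <- score_women(make_women(place = c("hospital", "home"),
                                sba = c("yes", "no"), stay24 = c("yes", "no"),
                                pnc48 = c("yes", "no")))
  expect_equal(score_distribution(mix)$proportion, c(0.5, 0, 0, 0, 0, 0.5))

  gen <- score_women(generate_population(
    generator_config(n_countries = 3, women_per_country = 300,
                     missingness_rate = 0.1, seed = 17))$women)
  for (pooled in c(FALSE, TRUE)) {
    d <- score_distribution(gen, pooled = pooled)
    expect_equal(sum(d$proportion), 1, tolerance = 1e-9)
  }
})

test_that("score distribution matches the analytic enumeration of the hierarchical model", {
  n <- 20000
  pf <- 0.7; ph <- 0.6; psf <- 0.9; psh <- 0.2; pst <- 0.8; ppf <- 0.9; pph <- 0.5
  cfg <- generator_config(n_countries = 1, women_per_country = n,
                          p_facility = pf, p_hospital_given_facility = ph,
                          p_sba_given_facility = psf, p_sba_given_home = psh,
                          p_stay24_given_facility = pst,
                          p_pnc48_given_facility = ppf, p_pnc48_given_home = pph,
                          wealth_gradient = 0, missingness_rate = 0, seed = 19)
  # enumerate P(score = s) exactly from the generative branches
  probs <- numeric(6)
  for (hosp in 0:1) for (fac in 0:1) for (sba in 0:1) for (stay in 0:1)
    for (pnc in 0:1) {
      if (!fac && (hosp || stay)) next
      p <- (if (fac) pf * (if (hosp) ph else 1 - ph) else 1 - pf) *
        (if (fac) (if (sba) psf else 1 - psf) else (if (sba) psh else 1 - psh)) *
        (if (fac) (if (stay) pst else 1 - pst) else 1) *
        (if (fac) (if (pnc) ppf else 1 - ppf) else (if (pnc) pph else 1 - pph))
      s <- (if (fac) (if (hosp) 2 else 1) else 0) + sba + stay + pnc
      probs[s + 1] <- probs[s + 1] + p
    }
  expect_equal(sum(probs), 1, tolerance = 1e-12)

  sc <- score_women(generate_population(cfg)$women)
  emp <- score_distribution(sc)$proportion
  mc_se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(emp - probs) <= 3 * mc_se + 1e-12))
})

test_that("cluster bootstrap is deterministic, collapses on degenerate data, and validates input", {
  sc <- score_women(generate_population(
    generator_config(n_countries = 1, women_per_country = 400,
                     n_strata_per_country = 5, seed = 23))$women)
  ci1 <- bootstrap_ci(sc, "facility", B = 100, seed = 99)
  ci2 <- bootstrap_ci(sc, "facility", B = 100, seed = 99)
  expect_identical(ci1, ci2)
  expect_true(ci1[["ci_low"]] <= ci1[["ci_high"]])

  flat <- score_women(make_women(place = rep("hospital", 8)))
  ci0 <- bootstrap_ci(flat, "facility", B = 50, seed = 1)
  expect_equal(unname(ci0), c(100, 100))

  expect_error(bootstrap_ci(sc, "facility", B = 1), "at least 2")
  lone <- score_women(make_women(place = rep("home", 3), psu = "1"))
  expect_error(bootstrap_ci(lone, "facility", B = 10), "single PSU")
})
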