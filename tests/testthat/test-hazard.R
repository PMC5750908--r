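test_that("fit_lognormal matches closed forms", {
  f <- fit_lognormal(c(2, 2, 2, 2))
  expect_equal(f$gm, 2)
  expect_equal(f$sigma_log, 0)
  expect_equal(f$n, 4L)
  f2 <- fit_lognormal(c(1, exp(2), exp(4)))
  expect_equal(f2$gm, exp(2))
  expect_equal(f2$sigma_log, 2)
  expect_error(fit_lognormal(5), "at least 2")
  expect_error(fit_lognormal(c(1, -1)), "positive")
})

test_that("published stratum models reproduce their tabulated percentages", {
  # stratum 04: the highest-hazard geology
  p04 <- category_probabilities(lognormal_model(1.213, 2.542))
  expect_lt(max(abs(100 * as.numeric(p04) - c(47.0, 24.2, 8.54, 20.3))),
            0.05)
  # stratum 01: the mineralised zone
  p01 <- category_probabilities(lognormal_model(0.885, 1.805))
  expect_lt(max(abs(100 * as.numeric(p01) - c(52.7, 30.4, 7.91, 8.95))),
            0.05)
  # stratum 07 has a 0.01% exceedance
  e07 <- exceedance_probability(lognormal_model(0.175, 1.109), 10)
  expect_lt(abs(100 * e07 - 0.01), 0.05)
})

test_that("category probabilities always sum to one", {
  set.seed(97)
  for (i in 1:20) {
    m <- lognormal_model(exp(runif(1, -3, 3)), runif(1, 0.01, 3))
    expect_lt(abs(sum(category_probabilities(m)) - 1), 1e-12)
  }
})

test_that("a degenerate model is a point mass in the band containing gm", {
  expect_equal(as.numeric(category_probabilities(lognormal_model(0.5, 0))),
               c(1, 0, 0, 0))
  expect_equal(as.numeric(category_probabilities(lognormal_model(3, 0))),
               c(0, 1, 0, 0))
  expect_equal(as.numeric(category_probabilities(lognormal_model(10, 0))),
               c(0, 0, 0, 1))
  expect_equal(exceedance_probability(lognormal_model(10, 0), 10), 1)
})

test_that("exceedance probability has its closed form and monotonicity", {
  expect_equal(exceedance_probability(lognormal_model(7, 1.3), 7), 0.5)
  expect_equal(exceedance_probability(lognormal_model(0.5, 1), 10),
               1 - pnorm(log(20)), tolerance = 1e-12)
  # increasing in gm at fixed sigma; increasing in sigma when gm < threshold
  gms <- seq(0.1, 5, length.out = 20)
  e1 <- sapply(gms, function(g)
    exceedance_probability(lognormal_model(g, 1.5), 10))
  expect_true(all(diff(e1) > 0))
  sig <- seq(0.2, 3, length.out = 20)
  e2 <- sapply(sig, function(s)
    exceedance_probability(lognormal_model(0.8, s), 10))
  expect_true(all(diff(e2) > 0))
})

test_that("probabilities are invariant to the log base used consistently", {
  # z = (log10(c) - log10(gm)) / (sigma_log / ln 10) equals the ln form
  m <- lognormal_model(1.213, 2.542)
  z_ln <- (log(10) - log(m$gm)) / m$sigma_log
  z_10 <- (log10(10) - log10(m$gm)) / (m$sigma_log / log(10))
  expect_equal(z_ln, z_10, tolerance = 1e-14)
})

test_that("hazard ranks follow the four-band rule with closed edges", {
  expect_equal(hazard_rank(0.203), 1L)
  expect_equal(hazard_rank(0.0238), 3L)
  expect_equal(hazard_rank(0.0093), 4L)
  expect_equal(hazard_rank(0), 4L)
  expect_equal(hazard_rank(1), 1L)
  # edge conventions: 10% and 5% belong to rank 2, 1% to rank 3
  expect_equal(hazard_rank(c(0.10, 0.05, 0.01)), c(2L, 2L, 3L))
  # non-increasing step function of p
  p <- seq(0, 1, by = 0.001)
  expect_true(all(diff(hazard_rank(p)) <= 0))
  expect_error(hazard_rank(1.2), "\\[0, 1\\]")
})

test_that("all ten published stratum ranks are reproduced", {
  models <- Map(lognormal_model, table_params$gm, table_params$sigma_log)
  ranks <- sapply(models, function(m)
    hazard_rank(exceedance_probability(m, 10)))
  expect_equal(unname(ranks), c(2L, 4L, 4L, 1L, 2L, 3L, 4L, 4L, 2L, 4L))
})

test_that("dwelling counts scale probabilities with half-up rounding", {
  p04 <- category_probabilities(lognormal_model(1.213, 2.542))
  pred <- predict_dwellings(p04, 200)
  expect_equal(sum(pred$expected), 200, tolerance = 1e-9)
  expect_equal(pred$expected[["p_exceed"]], 40.66, tolerance = 0.01)
  expect_equal(pred$rounded[["p_exceed"]], 41L)

  zero <- predict_dwellings(p04, 0)
  expect_equal(unname(zero$expected), rep(0, 4))

  # 1000 x 0.93% rounds to 9
  p02 <- category_probabilities(lognormal_model(0.575, 1.214))
  expect_equal(predict_dwellings(p02, 1000)$rounded[["p_exceed"]], 9L)
  expect_error(predict_dwellings(p04, -1), "non-negative")
})

test_that("regional totals aggregate unrounded expectations", {
  models <- setNames(Map(lognormal_model, table_params$gm,
                         table_params$sigma_log), table_params$sbgc)
  region <- predict_region(models, n_dwellings = 200)
  expect_equal(region$total_rounded, 96L)
  # per-stratum rounding first would give 97; the unrounded path gives 95.98
  expect_equal(region$total_expected_exceedances, 95.98, tolerance = 0.005)
  expect_equal(unname(region$per_stratum_share[["04"]]), 0.424,
               tolerance = 0.001)
  expect_lt(abs(sum(region$per_stratum_share) - 1), 1e-12)

  single <- predict_region(models["04"], 200)
  expect_equal(single$total_expected_exceedances,
               region$rows$exp_ge10[region$rows$sbgc == "04"])
  doubled <- predict_region(models, 400)
  expect_equal(doubled$total_expected_exceedances,
               2 * region$total_expected_exceedances)
})

test_that("capture fraction is the expected-exceedance share of a rank set", {
  models <- setNames(Map(lognormal_model, table_params$gm,
                         table_params$sigma_log), table_params$sbgc)
  region <- predict_region(models, 200)
  expect_equal(capture_fraction(region, 1:4), 1)
  expect_equal(capture_fraction(region, integer(0)), 0)
  # ranks 1 and 2 hold strata 01, 04, 05, 09: 89.24 of 95.98 exceedances
  expect_equal(capture_fraction(region, c(1, 2)), 0.930, tolerance = 0.001)
  expect_equal(capture_fraction(region, c(1, 2)),
               sum(region$rows$exp_ge10[region$rows$rank <= 2]) /
                 region$total_expected_exceedances)
})

test_that("fitting a simulation recovers the generator's band probabilities", {
  p <- stratum_sim_params("01", gm = 0.885, sigma_log = 1.805,
                          n_dwellings = 1e5)
  x <- generate_stratum(p, lod = 1e-12, seed = 101)$arsenic_ugL
  refit <- category_probabilities(fit_lognormal(x))
  truth <- category_probabilities(lognormal_model(0.885, 1.805))
  se <- sqrt(as.numeric(truth) * (1 - as.numeric(truth)) / 1e5)
  expect_true(all(abs(as.numeric(refit) - as.numeric(truth)) < 3 * se))
})

test_that("the packaged parameter fixture matches the published table", {
  models <- cornwall_sbgc_params()
  expect_equal(names(models), table_params$sbgc)
  expect_equal(sapply(models, `[[`, "gm"), setNames(table_params$gm,
                                                    table_params$sbgc))
  expect_equal(unname(sapply(models, `[[`, "sigma_log")),
               table_params$sigma_log)
  expect_equal(unname(sapply(models, `[[`, "n")), table_params$n)
})
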