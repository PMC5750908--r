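# brute-force Levene W, written straight from the definition
brute_levene <- function(groups, centre_fun) {
  z <- lapply(groups, function(x) abs(x - centre_fun(x)))
  k <- length(z); ni <- lengths(z); n <- sum(ni)
  zi <- sapply(z, mean); zz <- mean(unlist(z))
  w <- (n - k) / (k - 1) * sum(ni * (zi - zz)^2) /
    sum(unlist(lapply(z, function(g) (g - mean(g))^2)))
  list(W = w, p = pf(w, k - 1, n - k, lower.tail = FALSE))
}

# brute-force Kruskal-Wallis with mid-ranks and tie correction
brute_kw <- function(groups) {
  x <- unlist(groups); n <- length(x)
  r <- rank(x)
  g <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) length(ri) * mean(ri)^2)) - 3 * (n + 1)
  ties <- table(x)
  h <- h / (1 - sum(ties^3 - ties) / (n^3 - n))
  list(H = h, p = pchisq(h, length(groups) - 1, lower.tail = FALSE))
}

test_that("identical groups give Levene W = 0, p = 1", {
  g <- list(c(1, 2, 3), c(1, 2, 3))
  for (ctr in c("median", "trimmed_mean_10")) {
    lev <- levene_robust(g, ctr)
    expect_equal(lev$W, 0)
    expect_equal(lev$p_value, 1)
  }
})

test_that("Levene W is invariant to within-group location shifts", {
  set.seed(61)
  g <- list(rnorm(15), rnorm(20, 0, 2), rnorm(12, 0, 0.5))
  base <- levene_robust(g, "median")
  shifted <- g
  shifted[[2]] <- shifted[[2]] + 5
  expect_equal(levene_robust(shifted, "median")$W, base$W,
               tolerance = 1e-12)
})

test_that("Levene W matches brute force and car::leveneTest", {
  set.seed(67)
  g <- list(rnorm(18, 0, 1), rnorm(25, 1, 3), rnorm(14, -2, 0.4))
  lev <- levene_robust(g, "median")
  ref <- brute_levene(g, median)
  expect_equal(lev$W, ref$W, tolerance = 1e-10)
  expect_equal(lev$p_value, ref$p, tolerance = 1e-10)

  levt <- levene_robust(g, "trimmed_mean_10")
  reft <- brute_levene(g, function(x) mean(x, trim = 0.1))
  expect_equal(levt$W, reft$W, tolerance = 1e-10)
  expect_equal(levt$p_value, reft$p, tolerance = 1e-10)

  y <- unlist(g)
  grp <- factor(rep(seq_along(g), lengths(g)))
  car_med <- car::leveneTest(y, grp, center = median)
  expect_equal(lev$W, car_med[1, "F value"], tolerance = 1e-10)
  car_trim <- car::leveneTest(y, grp, center = mean, trim = 0.1)
  expect_equal(levt$W, car_trim[1, "F value"], tolerance = 1e-10)
})

test_that("identical groups give Kruskal-Wallis H = 0, p = 1", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(1, 2, 3)))
  expect_equal(kw$H, 0)
  expect_equal(kw$p_value, 1)
})

test_that("Kruskal-Wallis H is exactly rank-invariant under log", {
  set.seed(71)
  g <- lapply(c(10, 14, 12), function(n) exp(rnorm(n, 0, 1.5)))
  expect_identical(kruskal_wallis(g)$H, kruskal_wallis(lapply(g, log))$H)
})

test_that("Kruskal-Wallis matches brute-force mid-rank computation", {
  set.seed(73)
  g <- list(sample(1:6, 15, TRUE), sample(1:6, 20, TRUE),
            sample(2:8, 10, TRUE), sample(1:4, 12, TRUE))  # heavy ties
  kw <- kruskal_wallis(g)
  ref <- brute_kw(g)
  expect_equal(kw$H, ref$H, tolerance = 1e-10)
  expect_equal(kw$p_value, ref$p, tolerance = 1e-10)
  expect_equal(kw$df, 3)
})

test_that("degenerate and undersized inputs are rejected", {
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_error(levene_robust(list(1, c(1, 2))), "at least 2 observations")
  expect_error(levene_robust(list(c(1, 2))), "at least 2 groups")
})

test_that("the default synthetic study triggers the heteroscedastic branch", {
  study <- generate_study(default_sim_config(seed = 10))
  rep <- compare_strata(study)
  expect_false(rep$homoscedastic)
  expect_equal(rep$final_test, "kruskal_wallis")
  expect_lt(rep$final_p, 0.001)
})

test_that("two equal-variance strata route to the pooled t-test", {
  set.seed(79)
  df <- rbind(make_samples(exp(rnorm(100, 0, 1)), sbgc = "a"),
              make_samples(exp(rnorm(100, 0, 1)), sbgc = "b",
                           dwelling_id = sprintf("e%03d", 1:100),
                           supply_id = sprintf("t%03d", 1:100)))
  rep <- compare_strata(df)
  expect_true(rep$homoscedastic)
  expect_equal(rep$final_test, "t_test")
})

test_that("several equal-variance strata route to one-way ANOVA", {
  set.seed(83)
  parts <- lapply(1:4, function(i) {
    make_samples(exp(rnorm(80, i * 0.1, 1)), sbgc = paste0("g", i),
                 dwelling_id = sprintf("g%d-%03d", i, 1:80),
                 supply_id = sprintf("g%d-s%03d", i, 1:80))
  })
  rep <- compare_strata(do.call(rbind, parts))
  if (rep$homoscedastic) {
    expect_equal(rep$final_test, "anova")
  } else {
    expect_equal(rep$final_test, "kruskal_wallis")
  }
})

test_that("decision-flow type-I error is near nominal under the null", {
  set.seed(89)
  n_rep <- 200
  rejections <- 0
  for (i in 1:n_rep) {
    df <- rbind(
      make_samples(exp(rnorm(200, 0, 1)), sbgc = "a",
                   dwelling_id = sprintf("a%03d", 1:200),
                   supply_id = sprintf("as%03d", 1:200)),
      make_samples(exp(rnorm(200, 0, 1)), sbgc = "b",
                   dwelling_id = sprintf("b%03d", 1:200),
                   supply_id = sprintf("bs%03d", 1:200)))
    rejections <- rejections + (compare_strata(df)$final_p < 0.05)
  }
  se <- sqrt(0.05 * 0.95 / n_rep)
  expect_lt(abs(rejections / n_rep - 0.05), 3 * se)
})

test_that("a single stratum cannot be compared", {
  expect_error(compare_strata(make_samples(c(1, 2, 3))), "at least 2 strata")
})
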