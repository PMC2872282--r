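test_that("age-standardised prevalence follows the exponentiate-and-
           normalise form", {
  counties <- tiny_counties(10, 2, seed = 6)
  p0 <- param_set(n_counties = 10, n_states = 2)
  prev <- standardized_prevalence(p0, counties, model_spec(1))
  expect_equal(prev$p, matrix(1 / 6, 10, 6))
  expect_true(all(prev$w[, 6] == 1))

  p1 <- p0
  p1$alpha <- c(log(5), 0, 0, 0, 0)
  prev1 <- standardized_prevalence(p1, counties, model_spec(1))
  expect_equal(prev1$p[, 1], rep(0.5, 10))
  expect_equal(prev1$p[, 2], rep(0.1, 10))

  # independent oracle per county, with all terms active
  p <- rand_params(10, 2, seed = 44)
  spec <- model_spec(2)
  prev2 <- standardized_prevalence(p, counties, spec)
  X <- as.matrix(counties[, c("poverty", "log_density", "top_black",
                              "top_hisp", "top_other")])
  for (cc in c(1, 4, 10)) {
    w <- c(vapply(1:5, function(j) {
      exp(p$alpha[j] + sum(p$delta[j, ] * X[cc, ]) +
            p$lambda[j] * p$v[cc] +
            p$kappa[j] * p$u[counties$state[cc]])
    }, numeric(1)), 1)
    expect_equal(prev2$p[cc, ], w / sum(w), tolerance = 1e-12)
    expect_equal(prev2$w[cc, ], w, tolerance = 1e-12)
  }
  expect_true(all(abs(rowSums(prev2$p) - 1) < 1e-12))

  # re-applying the constraints must not change any prevalence
  prev3 <- standardized_prevalence(apply_constraints(p), counties, spec)
  expect_equal(prev3$p, prev2$p)
})

test_that("composite latent effects combine loadings and both levels", {
  counties <- tiny_counties(4, 2)
  p <- param_set(n_counties = 4, n_states = 2)
  p$v <- rep(0.2, 4)
  p$u <- rep(0.1, 2)
  t_mat <- composite_effects(p, counties)
  expect_equal(t_mat[, 1], rep(0.3, 4))   # lambda_1 = kappa_1 = 1

  # loadings at the magnitudes reported for the baseline US fit
  p$lambda[2] <- 0.72
  p$kappa[2] <- 0.88
  p$v <- rep(1, 4)
  p$u <- rep(1, 2)
  expect_equal(composite_effects(p, counties)[, 2], rep(1.60, 4))

  p$v[] <- 0
  p$u[] <- 0
  expect_equal(composite_effects(p, counties), matrix(0, 4, 5),
               ignore_attr = TRUE)
})

test_that("marginal latent variance is zero without area variation and
           translation-stable", {
  counties <- tiny_counties(4, 2)
  resp <- tiny_respondents(100)
  p <- param_set(n_counties = 4, n_states = 2)
  expect_equal(marginal_latent_variance(p, resp, counties), 0)

  one_cty <- tiny_counties(1, 1)
  resp1 <- tiny_respondents(40, nc = 1)
  p1 <- rand_params(1, 1)
  expect_equal(marginal_latent_variance(p1, resp1, one_cty), 0)
  expect_error(marginal_latent_variance(p, resp[0, ], counties), "empty")

  p2 <- rand_params(4, 2, seed = 8)
  m0 <- marginal_latent_variance(p2, resp, counties)
  expect_gt(m0, 0)
  p3 <- p2
  p3$v <- p3$v + 5          # centering restores the same variance
  p3 <- apply_constraints(p3)
  expect_equal(marginal_latent_variance(p3, resp, counties), m0,
               tolerance = 1e-10)
  # dropping reference-category respondents is the documented alternative
  m_drop <- marginal_latent_variance(p2, resp, counties,
                                     reference = "drop")
  expect_gt(m_drop, 0)
})

test_that("poverty decile profile ranks counties into near-equal groups", {
  set.seed(10)
  pov <- runif(10)
  t1 <- rnorm(10)
  prof <- poverty_decile_profile(t1, pov)
  expect_equal(prof$n, rep(1L, 10))
  expect_equal(prof$mean_effect, t1[order(pov)])

  expect_equal(poverty_decile_profile(rep(0, 37), runif(37))$mean_effect,
               rep(0, 10))
  pov2 <- runif(45)
  prof2 <- poverty_decile_profile(rank(pov2), pov2)
  expect_true(all(diff(prof2$mean_effect) > 0))
  expect_equal(sum(prof2$n), 45)
  expect_error(poverty_decile_profile(1:5, runif(5)), "10 counties")
})

test_that("cross-tabulations reproduce the worked survey percentages", {
  # education group sizes and obese-diabetic counts as printed for the
  # lowest and highest education strata
  n1 <- 14158
  k1 <- 794
  n4 <- 48186
  k4 <- 1562
  resp <- data.frame(
    id = seq_len(n1 + n4),
    age_group = rep(1L, n1 + n4),
    race = 1L,
    education = rep(c(1L, 4L), c(n1, n4)),
    county = 1L,
    weight = 1,
    category = c(rep(c(1L, 6L), c(k1, n1 - k1)),
                 rep(c(1L, 6L), c(k4, n4 - k4))))
  expect_warning(ct <- crosstab_prevalence(resp, "education"),
                 "omitted")   # middle education groups are empty here
  expect_equal(round(ct$cat1[ct$group == 1], 1), 5.6)
  expect_equal(round(ct$cat1[ct$group == 4], 1), 3.2)
  expect_true(all(abs(rowSums(ct[, paste0("cat", 1:6)]) - 100) < 1e-9))
})

test_that("cross-tabulations handle degenerate groups, weights and age
           standardisation", {
  resp <- tiny_respondents(400, seed = 33)
  resp$category <- 2L
  resp$race[resp$race == 4L] <- 3L   # leave race group 4 empty
  expect_warning(ct <- crosstab_prevalence(resp, "race"), "omitted")
  present <- ct[ct$n > 0, ]
  expect_true(all(present$cat2 == 100))
  expect_true(all(present[, paste0("cat", c(1, 3:6))] == 0))

  resp2 <- tiny_respondents(2000, seed = 34)
  ct_u <- suppressWarnings(crosstab_prevalence(resp2, "education"))
  expect_true(all(abs(rowSums(ct_u[, paste0("cat", 1:6)]) - 100) < 1e-9))

  # with equal weights, the weighted table equals the unweighted one
  resp2$weight <- 2
  ct_w <- suppressWarnings(crosstab_prevalence(resp2, "education",
                                               weighted = TRUE))
  expect_equal(ct_w, ct_u)

  # age standardisation to the overall age mix, by state grouping
  counties <- tiny_counties(4, 2)
  ct_s <- suppressWarnings(
    crosstab_prevalence(resp2, "state", age_standardize = TRUE,
                        counties = counties))
  expect_true(all(abs(rowSums(ct_s[, paste0("cat", 1:6)]) - 100) < 1e-6))
})
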