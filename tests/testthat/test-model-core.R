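test_that("linear predictor is zero in the null configuration and masks
           inactive blocks", {
  counties <- tiny_counties()
  resp <- tiny_respondents(10)
  null_p <- param_set(n_counties = 4, n_states = 2)
  phi <- linear_predictor(resp, counties, null_p, model_spec(3))
  expect_equal(phi, matrix(0, 10, 5))

  # under model 1 the race/education and county-covariate blocks are
  # switched off, so nonzero values there must not change the output
  p <- rand_params()
  p_masked <- p
  p_masked$beta[] <- 0
  p_masked$gamma[] <- 0
  p_masked$delta[] <- 0
  expect_equal(linear_predictor(resp, counties, p, model_spec(1)),
               linear_predictor(resp, counties, p_masked, model_spec(1)))
})

test_that("linear predictor matches a term-by-term hand summation", {
  counties <- tiny_counties(6, 3, seed = 4)
  resp <- tiny_respondents(25, nc = 6, seed = 5)
  for (m in 1:3) {
    spec <- model_spec(m)
    p <- rand_params(6, 3, seed = m + 10)
    phi <- linear_predictor(resp, counties, p, spec)
    for (i in c(1, 7, 25)) {
      for (j in 1:5) {
        expect_term <- p$alpha[j] + p$eta[j, resp$age_group[i]] +
          p$lambda[j] * p$v[resp$county[i]] +
          p$kappa[j] * p$u[counties$state[resp$county[i]]]
        if (spec$include_race_education) {
          expect_term <- expect_term + p$beta[j, resp$race[i]] +
            p$gamma[j, resp$education[i]]
        }
        if (spec$include_county_covariates) {
          xs <- unlist(counties[resp$county[i],
                                c("poverty", "log_density", "top_black",
                                  "top_hisp", "top_other")])
          expect_term <- expect_term + sum(p$delta[j, ] * xs)
        }
        expect_equal(phi[i, j], unname(expect_term), tolerance = 1e-12)
      }
    }
  }
})

test_that("category probabilities follow the multinomial logit closed form",
          {
  expect_equal(drop(category_probs(rep(0, 5))), rep(1 / 6, 6))
  expect_equal(drop(category_probs(c(log(2), 0, 0, 0, 0))),
               c(2, 1, 1, 1, 1, 1) / 7)
  # saturated predictor: overflow-safe and still a probability vector
  pi_sat <- drop(category_probs(c(50, 0, 0, 0, 0)))
  expect_gt(pi_sat[1], 1 - 1e-15)
  expect_true(all(pi_sat[-1] < 1e-15))
  expect_equal(sum(pi_sat), 1)
})

test_that("category probabilities always sum to one", {
  set.seed(42)
  for (k in 1:50) {
    phi <- matrix(rnorm(20 * 5, 0, sample(c(0.5, 3, 20), 1)), 20, 5)
    expect_true(all(abs(rowSums(category_probs(phi)) - 1) < 1e-12))
  }
})

test_that("weighted log-likelihood has the survey-weighted form", {
  counties <- tiny_counties()
  r1 <- tiny_respondents(1)
  r1$weight <- 1
  p0 <- param_set(n_counties = 4, n_states = 2)
  spec <- model_spec(3)
  expect_equal(weighted_loglik(r1, counties, p0, spec), log(1 / 6),
               tolerance = 1e-12)
  r2 <- r1
  r2$weight <- 2.5
  expect_equal(weighted_loglik(r2, counties, p0, spec), 2.5 * log(1 / 6),
               tolerance = 1e-12)
})

test_that("weighted log-likelihood matches the brute-force product form", {
  for (seed in 1:4) {
    counties <- tiny_counties(5, 2, seed = seed)
    resp <- tiny_respondents(20, nc = 5, seed = seed + 50)
    p <- rand_params(5, 2, seed = seed + 100)
    for (m in c(1, 3)) {
      spec <- model_spec(m)
      expect_equal(weighted_loglik(resp, counties, p, spec),
                   oracle_loglik(resp, counties, p, spec),
                   tolerance = 1e-10)
    }
  }
})

test_that("weighted log-likelihood is permutation invariant and with unit
           weights equals the unweighted form", {
  counties <- tiny_counties()
  resp <- tiny_respondents(30)
  p <- rand_params()
  spec <- model_spec(3)
  perm <- sample(30)
  expect_equal(weighted_loglik(resp[perm, ], counties, p, spec),
               weighted_loglik(resp, counties, p, spec), tolerance = 1e-12)
  resp$weight <- 1
  manual <- {
    phi <- linear_predictor(resp, counties, p, spec)
    pi_all <- category_probs(phi)
    sum(log(pi_all[cbind(seq_len(30), resp$category)]))
  }
  expect_equal(weighted_loglik(resp, counties, p, spec), manual,
               tolerance = 1e-12)
})

test_that("model nesting: model 1 equals model 3 with the extra blocks
           zeroed", {
  counties <- tiny_counties()
  resp <- tiny_respondents(40)
  p <- rand_params()
  p$beta[] <- 0
  p$gamma[] <- 0
  p$delta[] <- 0
  expect_identical(weighted_loglik(resp, counties, p, model_spec(1)),
                   weighted_loglik(resp, counties, p, model_spec(3)))
})

test_that("constraint application is idempotent and preserves structure", {
  p <- rand_params()
  p1 <- apply_constraints(p)
  expect_equal(apply_constraints(p1), p1)

  p$eta[1, ] <- 1
  p2 <- apply_constraints(p)
  expect_equal(p2$eta[1, ], rep(0, 12))

  p$v <- p$v + 0.7
  p3 <- apply_constraints(p)
  expect_equal(mean(p3$v), 0, tolerance = 1e-12)
  expect_equal(diff(p3$v), diff(p$v), tolerance = 1e-12)
  expect_identical(p3$beta[, 1], rep(0, 5))
  expect_identical(p3$lambda[1], 1)
})

test_that("top-decile indicator codes exactly the top tenth", {
  set.seed(9)
  vals <- sample(seq_len(3110) / 3110)
  expect_equal(sum(top_decile_indicator(vals)), 311)
  expect_equal(sum(top_decile_indicator(runif(10))), 1)
  expect_equal(top_decile_indicator(rep(0.2, 25)), rep(0L, 25))
  expect_error(top_decile_indicator(numeric(0)), "empty")
})
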