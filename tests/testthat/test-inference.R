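make_fake_fit <- function(draw_list, deviances, params, resp, counties,
                          spec = model_spec(1),
                          mcmc = mcmc_config(n_chains = length(draw_list),
                                             n_iter = 100)) {
  structure(list(draws = draw_list, deviance = deviances,
                 spec = spec, mcmc = mcmc,
                 layout = colnames(draw_list[[1]]),
                 n_counties = nrow(counties),
                 n_states = max(counties$state),
                 weights = resp$weight, posterior_mean = params),
            class = "jp_fit")
}

test_that("PSRF sits at the correction floor for identical chains and
           detects separation", {
  set.seed(1)
  x <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "a"))
  psrf_same <- gelman_rubin(list(x, x))
  floor_val <- sqrt((5000 - 1) / 5000)
  expect_equal(unname(psrf_same), floor_val, tolerance = 1e-6)

  y1 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "a"))
  y2 <- matrix(rnorm(5000), ncol = 1, dimnames = list(NULL, "a"))
  expect_lt(gelman_rubin(list(y1, y2)), 1.05)

  z2 <- y2 + 10
  expect_gt(gelman_rubin(list(y1, z2)), 5)
  expect_error(gelman_rubin(list(y1)), "two chains")
})

test_that("PSRF agrees with an independent implementation", {
  set.seed(7)
  ch <- lapply(1:3, function(i) {
    matrix(rnorm(2000 * 2, mean = c(0, 0.05 * i)), ncol = 2,
           dimnames = list(NULL, c("a", "b")))
  })
  ours <- gelman_rubin(ch)
  ref <- coda::gelman.diag(coda::mcmc.list(lapply(ch, coda::mcmc)),
                           autoburnin = FALSE, multivariate = FALSE)
  expect_equal(unname(ours), unname(ref$psrf[, 1]), tolerance = 0.02)
})

test_that("DIC follows Dbar + pD with pD from the posterior mean", {
  counties <- tiny_counties()
  resp <- tiny_respondents(50)
  spec <- model_spec(1)
  p <- rand_params()
  vec <- jointprev:::.pack_params(p, spec, latent = TRUE)
  layout <- jointprev:::.pack_layout(spec, 4, 2, latent = TRUE)
  d0 <- -2 * weighted_loglik(resp, counties, p, spec)

  # a point-mass "posterior": no complexity penalty
  draws <- matrix(rep(vec, 10), nrow = 10, byrow = TRUE,
                  dimnames = list(NULL, layout))
  fit <- make_fake_fit(list(draws), list(rep(d0, 10)), p, resp, counties)
  dic <- compute_dic(fit, resp, counties)
  expect_equal(dic$pD, 0, tolerance = 1e-8)
  expect_equal(dic$DIC, d0, tolerance = 1e-8)
  expect_equal(dic$DIC, dic$Dbar + dic$pD)

  # two-draw trace: hand arithmetic
  d1 <- d0 + 3
  d2 <- d0 + 7
  fit2 <- make_fake_fit(list(draws[1:2, ]), list(c(d1, d2)), p, resp,
                        counties)
  dic2 <- compute_dic(fit2, resp, counties)
  expect_equal(dic2$Dbar, (d1 + d2) / 2)
  expect_equal(dic2$pD, (d1 + d2) / 2 - d0)
  expect_equal(dic2$DIC, (d1 + d2) - d0)
})

test_that("posterior summaries have the reference layout and sane
           distributional behaviour", {
  counties <- tiny_counties()
  resp <- tiny_respondents(10)
  spec <- model_spec(1)
  p <- rand_params()
  layout <- jointprev:::.pack_layout(spec, 4, 2, latent = TRUE)

  const <- matrix(rep(jointprev:::.pack_params(p, spec), 40), nrow = 40,
                  byrow = TRUE, dimnames = list(NULL, layout))
  fit <- make_fake_fit(list(const), list(rep(1, 40)), p, resp, counties)
  sm <- fit_summary(fit)
  expect_true(all(sm$sd == 0))
  expect_true(all(sm$mc_error == 0))
  expect_equal(sm$q2.5, sm$mean)
  expect_equal(sm$q97.5, sm$mean)

  set.seed(5)
  z <- matrix(rnorm(50000), ncol = 1, dimnames = list(NULL, "z"))
  fitz <- make_fake_fit(list(z), list(rep(1, 50000)), p, resp, counties)
  smz <- fit_summary(fitz, params = "z")
  expect_lt(abs(smz$mean), 0.03)
  expect_lt(abs(smz$q2.5 - (-1.96)), 0.05)
  expect_lt(abs(smz$q97.5 - 1.96), 0.05)
  expect_true(all(sm$q2.5 <= sm$median & sm$median <= sm$q97.5))
})

test_that("the sampler is deterministic given a seed", {
  sim <- generate_dataset(sim_config(n_counties = 12, n_states = 2,
                                     n_respondents = 600, seed = 9))
  cfgm <- mcmc_config(n_chains = 1, n_iter = 120, seed = 13)
  f1 <- run_mcmc(sim$respondents, sim$counties, sim$geography,
                 model_spec(1), cfgm)
  f2 <- run_mcmc(sim$respondents, sim$counties, sim$geography,
                 model_spec(1), cfgm)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$deviance, f2$deviance)
})

test_that("intercept-only posterior concentrates at the empirical category
           log-odds", {
  # data from a flat-age model; latent effects pinned at zero in the fit
  p <- param_set(n_counties = 12, n_states = 2)
  p$alpha <- c(log(2), -0.5, 0, 0.4, 0)
  p$sigma2_v <- 0
  p$sigma2_u <- 0
  cfg <- sim_config(n_counties = 12, n_states = 2, n_respondents = 8000,
                    true_params = p, weight_jitter_sdlog = 0, seed = 51)
  sim <- generate_dataset(cfg)
  fit <- run_mcmc(sim$respondents, sim$counties, sim$geography,
                  model_spec(1),
                  mcmc_config(n_chains = 1, n_iter = 800, seed = 3,
                              fix_latent_at_zero = TRUE))
  sm <- fit_summary(fit)
  w <- fit$weights
  y <- sim$respondents$category
  shares <- vapply(1:6, function(j) sum(w[y == j]), numeric(1))
  target <- log(shares[1:5] / shares[6])
  al <- sm[match(paste0("alpha[", 1:5, "]"), sm$parameter), ]
  expect_true(all(abs(al$mean - target) < 3 * pmax(al$sd, 0.02)))
})
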