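test_that("joint log-prior equals the sum of its component densities", {
  cg <- path_graph(4)
  sg <- path_graph(2)
  p <- param_set(n_counties = 4, n_states = 2, sigma2_v = 1, sigma2_u = 1,
                 lambda = c(1, rep(0, 4)), kappa = c(1, rep(0, 4)))
  spec <- model_spec(3)
  got <- log_prior(p, cg, sg, spec)
  J <- 5
  A <- 12
  # each block evaluated independently at the null configuration
  comp <- J * dnorm(0, 0, 10, log = TRUE) +                    # alpha
    2 * 3 * J * dnorm(0, 0, 10, log = TRUE) +                  # beta, gamma
    5 * J * dnorm(0, 0, 10, log = TRUE) +                      # delta
    2 * (J - 1) * dnorm(0, 0, 10, log = TRUE) +                # loadings
    icar_logpdf_kernel(numeric(4), cg, 1) +
    icar_logpdf_kernel(numeric(2), sg, 1) +
    2 * (log(2) + dnorm(1, 0, 1, log = TRUE)) +                # half-normal
    (-(A - 1) / 2 * J * log(2 * pi))                           # age RW at 0
  # inverse-Wishart(J + 2, I) at the identity, from its closed form
  nu <- J + 2
  lmvgamma <- (J * (J - 1) / 4) * log(pi) +
    sum(lgamma(nu / 2 + (1 - seq_len(J)) / 2))
  comp <- comp - (nu * J / 2) * log(2) - lmvgamma - J / 2
  expect_equal(got, comp, tolerance = 1e-8)
})

test_that("log-prior support violations return -Inf, not errors", {
  cg <- path_graph(4)
  sg <- path_graph(2)
  spec <- model_spec(3)
  p <- param_set(n_counties = 4, n_states = 2)
  p$sigma2_v <- -1
  expect_identical(log_prior(p, cg, sg, spec), -Inf)
  p$sigma2_v <- 0
  expect_identical(log_prior(p, cg, sg, spec), -Inf)
})

test_that("log-prior masks inactive blocks under reduced models", {
  cg <- path_graph(4)
  sg <- path_graph(2)
  p <- rand_params(4, 2, seed = 3)
  p1 <- p
  p1$beta[] <- 0
  p1$gamma[] <- 0
  p1$delta[] <- 0
  # the model-1 prior must not see beta/gamma/delta at all
  expect_equal(log_prior(p, cg, sg, model_spec(1)),
               log_prior(p1, cg, sg, model_spec(1)))
})

test_that("age random-walk prior is smoothing: rougher profiles are less
           likely", {
  cg <- path_graph(4)
  sg <- path_graph(2)
  spec <- model_spec(1)
  t <- (1:12 - 6.5) / 6
  smooth <- param_set(n_counties = 4, n_states = 2,
                      eta = outer(rep(1, 5), t))
  rough <- param_set(n_counties = 4, n_states = 2,
                     eta = outer(rep(1, 5), t * rep(c(1, -1), 6)))
  expect_gt(log_prior(smooth, cg, sg, spec),
            log_prior(rough, cg, sg, spec))
})
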