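test_that("lattice geography builds nested rook grids", {
  geo <- make_lattice_geography(4, 2)
  expect_equal(geo$nrow * geo$ncol, 4)
  expect_equal(sum(geo$county_graph$degree) / 2, 4)   # 2x2 grid: 4 edges
  expect_equal(as.vector(table(geo$county_state)), c(2, 2))

  solo <- make_lattice_geography(1, 1)
  expect_equal(solo$county_graph$degree, 0L)
  expect_true(solo$county_graph$island)

  geo100 <- make_lattice_geography(100, 5)
  expect_true(all(geo100$county_graph$degree >= 2 &
                    geo100$county_graph$degree <= 4))
  expect_equal(geo100$state_graph$n_components, 1L)
  # state graph must be derivable from county adjacency + membership
  ed <- graph_edges(geo100$county_graph)
  cross <- geo100$county_state[ed[, 1]] != geo100$county_state[ed[, 2]]
  for (k in which(cross)) {
    s1 <- geo100$county_state[ed[k, 1]]
    s2 <- geo100$county_state[ed[k, 2]]
    expect_true(s2 %in% geo100$state_graph$nbr[[s1]])
  }
  expect_error(make_lattice_geography(3, 5), "exceed")
})

test_that("forward simulation reproduces the generating category
           probabilities", {
  # null configuration: all six categories equally likely
  null_p <- param_set(n_counties = 12, n_states = 2,
                      sigma2_v = 1e-12, sigma2_u = 1e-12)
  null_p$sigma2_v <- 0
  null_p$sigma2_u <- 0
  cfg <- sim_config(n_counties = 12, n_states = 2, n_respondents = 60000,
                    true_params = null_p, weight_jitter_sdlog = 0,
                    seed = 31)
  sim <- generate_dataset(cfg)
  shares <- as.vector(table(factor(sim$respondents$category, 1:6))) / 60000
  se3 <- 3 * sqrt((1 / 6) * (5 / 6) / 60000)
  expect_true(all(abs(shares - 1 / 6) < se3))

  # alpha_1 = log 2 shifts category 1 to 2/7 and the rest to 1/7
  p2 <- null_p
  p2$alpha[1] <- log(2)
  cfg2 <- sim_config(n_counties = 12, n_states = 2, n_respondents = 60000,
                     true_params = p2, weight_jitter_sdlog = 0, seed = 32)
  sim2 <- generate_dataset(cfg2)
  sh2 <- as.vector(table(factor(sim2$respondents$category, 1:6))) / 60000
  expect_lt(abs(sh2[1] - 2 / 7), 3 * sqrt((2 / 7) * (5 / 7) / 60000))
  expect_true(all(abs(sh2[-1] - 1 / 7) <
                    3 * sqrt((1 / 7) * (6 / 7) / 60000)))
})

test_that("simulation is bit-reproducible given the seed", {
  cfg <- sim_config(n_counties = 20, n_states = 2, n_respondents = 2000,
                    seed = 77)
  s1 <- generate_dataset(cfg)
  s2 <- generate_dataset(cfg)
  expect_identical(s1$respondents, s2$respondents)
  expect_identical(s1$counties, s2$counties)
  expect_identical(s1$true_params, s2$true_params)
})

test_that("dataset construction wires counties, indicators and latent
           fields together", {
  sim <- generate_dataset(sim_config(n_counties = 50, n_states = 5,
                                     n_respondents = 3000, seed = 5))
  validate_counties(sim$counties)
  validate_respondents(sim$respondents, sim$counties)
  expect_equal(sum(sim$counties$top_black), 5)   # floor(50/10) flagged
  expect_equal(sum(sim$true_params$v), 0, tolerance = 1e-9)
  expect_equal(sum(sim$true_params$u), 0, tolerance = 1e-9)
})

test_that("survey weights are inverse stratum sampling probabilities", {
  resp <- tiny_respondents(200, seed = 12)
  uniform <- list(age = rep(0.5, 12), race = rep(1, 4))
  w_u <- assign_survey_weights(resp, uniform)$weight
  expect_true(all(w_u == w_u[1]))

  scheme <- list(age = rep(1, 12), race = c(0.8, 0.2, 0.8, 0.8))
  w <- assign_survey_weights(resp, scheme)$weight
  ratio <- w[resp$race == 2][1] / w[resp$race == 1][1]
  expect_equal(ratio, 4)
  expect_error(assign_survey_weights(resp, list(age = rep(0, 12),
                                                race = rep(1, 4))),
               "positive")
})

test_that("weighted shares correct informative sampling, unweighted do
           not", {
  # population simulated from a known model, then thinned with
  # age-dependent response so the sample over-represents the old
  p <- param_set(n_counties = 12, n_states = 2)
  p$alpha[1] <- log(2)
  p$eta[1, ] <- seq(-1, 1, length.out = 12)   # category 1 rises with age
  p <- apply_constraints(p)
  p$sigma2_v <- 0
  p$sigma2_u <- 0
  cfg <- sim_config(n_counties = 12, n_states = 2, n_respondents = 40000,
                    true_params = p, weight_jitter_sdlog = 0, seed = 41)
  pop <- generate_dataset(cfg)$respondents
  scheme <- list(age = seq(0.1, 1, length.out = 12), race = rep(1, 4))
  set.seed(42)
  keep <- runif(nrow(pop)) < scheme$age[pop$age_group]
  sample_df <- assign_survey_weights(pop[keep, ], scheme)
  pop_share <- mean(pop$category == 1)
  unw <- mean(sample_df$category == 1)
  wtd <- sum(sample_df$weight * (sample_df$category == 1)) /
    sum(sample_df$weight)
  expect_gt(abs(unw - pop_share), 0.01)     # informative sampling biases
  expect_lt(abs(wtd - pop_share), 0.01)     # weighting removes the bias
  expect_lt(abs(wtd - pop_share), abs(unw - pop_share) / 2)
})
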