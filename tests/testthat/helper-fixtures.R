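# shared in-code fixtures: tiny geographies, county/respondent tables and
# randomly filled (but constraint-satisfying) parameter sets

path_graph <- function(n) {
  nbr <- lapply(seq_len(n), function(i) {
    c(if (i > 1) i - 1L, if (i < n) i + 1L)
  })
  adjacency_graph(nbr)
}

tiny_counties <- function(nc = 4L, ns = 2L, seed = 1L) {
  set.seed(seed)
  data.frame(county = seq_len(nc),
             state = rep(seq_len(ns), length.out = nc)[order(
               rep(seq_len(ns), length.out = nc))],
             poverty = round(runif(nc, 0.05, 0.4), 3),
             log_density = round(rnorm(nc, 4, 1), 3),
             top_black = as.integer(seq_len(nc) %% 3 == 0),
             top_hisp = as.integer(seq_len(nc) %% 4 == 0),
             top_other = 0L)
}

tiny_respondents <- function(n = 20L, nc = 4L, seed = 1L, weights = NULL) {
  set.seed(seed)
  data.frame(id = seq_len(n),
             age_group = sample.int(12L, n, replace = TRUE),
             race = sample.int(4L, n, replace = TRUE),
             education = sample.int(4L, n, replace = TRUE),
             county = sample.int(nc, n, replace = TRUE),
             weight = if (is.null(weights)) round(runif(n, 0.5, 3), 3)
             else weights,
             category = sample.int(6L, n, replace = TRUE))
}

rand_params <- function(nc = 4L, ns = 2L, seed = 1L, latent = TRUE) {
  set.seed(seed)
  param_set(J = 5L, A = 12L, n_counties = nc, n_states = ns,
            alpha = rnorm(5, 0, 0.5),
            beta = cbind(0, matrix(rnorm(15, 0, 0.3), 5, 3)),
            gamma = cbind(0, matrix(rnorm(15, 0, 0.3), 5, 3)),
            eta = matrix(rnorm(60, 0, 0.2), 5, 12),
            delta = matrix(rnorm(25, 0, 0.2), 5, 5),
            v = if (latent) rnorm(nc, 0, 0.4) else numeric(nc),
            u = if (latent) rnorm(ns, 0, 0.2) else numeric(ns),
            lambda = c(1, runif(4, 0.5, 1.5)),
            kappa = c(1, runif(4, 0.2, 1.2)),
            sigma2_v = 0.3, sigma2_u = 0.1)
}

# record-level likelihood oracle: exponentiate-then-log product form,
# written independently of the package's vectorised implementation
oracle_loglik <- function(respondents, counties, params, spec) {
  total <- 0
  for (i in seq_len(nrow(respondents))) {
    r <- respondents[i, ]
    cty <- counties[r$county, ]
    phi <- numeric(spec$J)
    for (j in seq_len(spec$J)) {
      phi[j] <- params$alpha[j] + params$eta[j, r$age_group] +
        params$lambda[j] * params$v[r$county] +
        params$kappa[j] * params$u[cty$state]
      if (spec$include_race_education) {
        phi[j] <- phi[j] + params$beta[j, r$race] +
          params$gamma[j, r$education]
      }
      if (spec$include_county_covariates) {
        x <- c(cty$poverty, cty$log_density, cty$top_black, cty$top_hisp,
               cty$top_other)
        phi[j] <- phi[j] + sum(params$delta[j, ] * x)
      }
    }
    pi_all <- c(exp(phi), 1) / (1 + sum(exp(phi)))
    total <- total + r$weight * log(pi_all[r$category])
  }
  total
}
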