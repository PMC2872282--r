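#' Two-level lattice geography
#'
#' Builds the simplest geography with genuine two-level spatial nesting: a
#' near-square rook-adjacency grid of counties, partitioned into contiguous
#' column-strip states. States are adjacent when any of their member
#' counties are. A single-county layout yields an empty adjacency with the
#' county flagged as an island.
#'
#' @param n_counties number of counties (factorised into the most
#'   square grid; a prime count gives a path)
#' @param n_states number of states (must not exceed the number of grid
#'   columns so every state is a non-empty contiguous block)
#' @param seed unused placeholder for interface uniformity; the layout is
#'   fully deterministic in (n_counties, n_states)
#' @return an object of class \code{jp_geography}: grid dimensions, the
#'   county-to-state assignment, and \code{jp_graph}s for both levels
#' @export
make_lattice_geography <- function(n_counties, n_states, seed = NULL) {
  n_counties <- as.integer(n_counties)
  n_states <- as.integer(n_states)
  if (n_states > n_counties) stop("n_states must not exceed n_counties")
  if (n_states < 1L) stop("n_states must be >= 1")
  # most-square factorisation
  d <- floor(sqrt(n_counties))
  while (d > 1L && n_counties %% d != 0L) d <- d - 1L
  nr <- max(d, 1L)
  ncol_ <- n_counties %/% nr
  if (n_states > ncol_) {
    stop("n_states (", n_states, ") exceeds grid columns (", ncol_, ")")
  }
  # county k sits at (row, col) in column-major order
  row_of <- (seq_len(n_counties) - 1L) %% nr + 1L
  col_of <- (seq_len(n_counties) - 1L) %/% nr + 1L
  # contiguous column strips define states
  cuts <- round(seq(0, ncol_, length.out = n_states + 1L))
  col_state <- rep(seq_len(n_states), times = diff(cuts))
  county_state <- col_state[col_of]
  nbr <- vector("list", n_counties)
  for (k in seq_len(n_counties)) {
    r <- row_of[[k]]
    cc <- col_of[[k]]
    v <- integer(0)
    if (r > 1L) v <- c(v, k - 1L)
    if (r < nr) v <- c(v, k + 1L)
    if (cc > 1L) v <- c(v, k - nr)
    if (cc < ncol_) v <- c(v, k + nr)
    nbr[[k]] <- v
  }
  county_graph <- adjacency_graph(nbr)
  # state adjacency induced by county adjacency
  snbr <- lapply(seq_len(n_states), function(s) integer(0))
  ed <- graph_edges(county_graph)
  if (nrow(ed)) {
    s1 <- county_state[ed[, 1]]
    s2 <- county_state[ed[, 2]]
    cross <- s1 != s2
    for (k in which(cross)) {
      snbr[[s1[[k]]]] <- union(snbr[[s1[[k]]]], s2[[k]])
      snbr[[s2[[k]]]] <- union(snbr[[s2[[k]]]], s1[[k]])
    }
  }
  structure(list(n_counties = n_counties, n_states = n_states,
                 nrow = nr, ncol = ncol_, row = row_of, col = col_of,
                 county_state = county_state,
                 county_graph = county_graph,
                 state_graph = adjacency_graph(snbr)),
            class = "jp_geography")
}

#' @export
print.jp_geography <- function(x, ...) {
  cat("jp_geography:", x$nrow, "x", x$ncol, "grid,", x$n_counties,
      "counties in", x$n_states, "states\n")
  invisible(x)
}

#' Sample an intrinsic CAR field
#'
#' Draws from the ICAR distribution by spectral construction: within each
#' connected component the graph Laplacian is eigendecomposed and
#' independent Normal(0, sigma2 / ev_k) coordinates are drawn along the
#' non-null eigenvectors, so every component sums to zero exactly and the
#' covariance of the draws is sigma2 times the Laplacian pseudo-inverse.
#' Islands, being single-node components, are identically zero under the
#' per-component centering.
#'
#' @param graph a \code{jp_graph}
#' @param sigma2 conditional variance (>= 0; 0 gives the zero field)
#' @param n number of draws
#' @return numeric vector (n = 1) or n x nodes matrix of draws
#' @export
sample_icar <- function(graph, sigma2, n = 1L) {
  stopifnot(inherits(graph, "jp_graph"), sigma2 >= 0)
  out <- matrix(0, n, graph$n)
  if (sigma2 > 0) {
    for (k in seq_len(graph$n_components)) {
      idx <- which(graph$component == k)
      m <- length(idx)
      if (m < 2L) next
      eg <- eigen(graph$laplacian[idx, idx, drop = FALSE], symmetric = TRUE)
      pos <- eg$values > 1e-9
      Z <- matrix(stats::rnorm(n * sum(pos)), n, sum(pos))
      Z <- sweep(Z, 2L, sqrt(sigma2 / eg$values[pos]), `*`)
      out[, idx] <- Z %*% t(eg$vectors[, pos, drop = FALSE])
    }
  }
  if (n == 1L) drop(out) else out
}

#' True parameter values used by the default synthetic scenario
#'
#' A full (model 3) parameter configuration anchored to values of the
#' magnitude reported for the US obesity-diabetes application: intercepts
#' at the logits of the overall category shares (4.2, 3.1, 1.4, 22.4, 40.2
#' vs 28.8 percent in the reference class), race and education contrasts,
#' county covariate effects, county loadings (1, 1.25, 1.27, 2.44, 1.65),
#' state loadings (1, 1.09, 0.45, 0.48, 0.30), conditional variances
#' sigma2_v = 0.3 and sigma2_u = 0.1, and smooth age profiles rising with
#' age for the diabetic categories only. Latent fields are zero here and
#' are drawn by \code{\link{generate_dataset}}.
#'
#' @param n_counties,n_states geography sizes for the latent-field slots
#' @return a \code{jp_params}
#' @export
default_true_params <- function(n_counties = 100L, n_states = 5L) {
  shares <- c(4.2, 3.1, 1.4, 22.4, 40.2, 28.8) / 100
  alpha <- log(shares[1:5] / shares[[6]])
  beta <- cbind(0,
                c(0.60, 0.81, 0.56, 0.39, 0.08),
                c(0.74, 0.87, 0.67, 0.48, 0.41),
                c(-0.12, -0.01, 0.34, -0.63, -0.31))
  gamma <- cbind(0,
                 c(-0.09, 0.13, -0.12, 0.26, 0.15),
                 c(0.02, 0.02, -0.34, 0.37, 0.29),
                 c(-0.66, -0.25, -0.50, -0.16, 0.15))
  delta <- cbind(c(2.07, 0.58, 0.07, 1.06, 0.15),
                 c(-0.11, -0.07, 0.01, -0.08, -0.04),
                 c(0.07, -0.28, -0.04, -0.09, -0.08),
                 c(-0.13, 0.03, 0.12, -0.25, -0.20),
                 c(-0.08, -0.12, -0.15, -0.17, -0.09))
  t <- ((1:12) - 6.5) / 3.3
  eta <- rbind(1.4 * t, 1.3 * t, 1.2 * t, 0.3 - 0.25 * t^2, 0.35 * t)
  param_set(J = 5L, A = 12L, n_counties = n_counties, n_states = n_states,
            alpha = alpha, beta = beta, gamma = gamma, eta = eta,
            delta = delta,
            lambda = c(1, 1.25, 1.27, 2.44, 1.65),
            kappa = c(1, 1.09, 0.45, 0.48, 0.30),
            sigma2_v = 0.3, sigma2_u = 0.1,
            Sigma_eta = 0.05 * (0.5 * diag(5) + 0.5))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic BRFSS-like generator. Defaults
#' describe the desk-scale scenario: 100 counties in 5 states, 20,000 male
#' respondents, county poverty ~ Beta(2, 10), log population density ~
#' Normal(4, 1.5), county race composition ~ Dirichlet(8, 1.2, 0.8, 0.6),
#' log-normal county population sizes, and an informative telephone-survey
#' style weighting scheme in which response propensity rises with age and
#' is lower for minority strata.
#'
#' @param n_counties,n_states,n_respondents scenario size
#' @param true_params optional \code{jp_params}; defaults to
#'   \code{\link{default_true_params}} with latent fields drawn from the
#'   ICAR model
#' @param poverty_shape Beta shape pair for county poverty
#' @param logdens_mean,logdens_sd Normal parameters for log density
#' @param race_dirichlet Dirichlet concentration for county (white, black,
#'   Hispanic, other) composition
#' @param age_probs,race_probs,edu_probs respondent covariate distributions
#' @param county_size_sdlog log-normal spread of county population sizes
#' @param weight_scheme per-stratum (age x race) sampling probabilities:
#'   list with \code{age} (length A) and \code{race} (length 4) factors
#' @param weight_jitter_sdlog log-normal jitter on weights (0 = none)
#' @param seed master seed; all stages derive their streams from it
#' @return a list of class \code{jp_sim_config}
#' @export
sim_config <- function(n_counties = 100L, n_states = 5L,
                       n_respondents = 20000L, true_params = NULL,
                       poverty_shape = c(2, 10),
                       logdens_mean = 4, logdens_sd = 1.5,
                       race_dirichlet = c(8, 1.2, 0.8, 0.6),
                       age_probs = NULL,
                       race_probs = c(0.70, 0.10, 0.12, 0.08),
                       edu_probs = c(0.11, 0.30, 0.21, 0.38),
                       county_size_sdlog = 1,
                       weight_scheme = list(
                         age = seq(0.3, 1, length.out = 12),
                         race = c(1, 0.6, 0.6, 0.7)),
                       weight_jitter_sdlog = 0.2,
                       seed = 1L) {
  if (is.null(age_probs)) {
    # adult male age-group pyramid, thinning at the oldest groups
    age_probs <- c(10, 9, 9, 9, 10, 10, 10, 9, 8, 6, 5, 5)
    age_probs <- age_probs / sum(age_probs)
  }
  cfg <- list(n_counties = as.integer(n_counties),
              n_states = as.integer(n_states),
              n_respondents = as.integer(n_respondents),
              true_params = true_params,
              poverty_shape = poverty_shape,
              logdens_mean = logdens_mean, logdens_sd = logdens_sd,
              race_dirichlet = race_dirichlet,
              age_probs = age_probs / sum(age_probs),
              race_probs = race_probs / sum(race_probs),
              edu_probs = edu_probs / sum(edu_probs),
              county_size_sdlog = county_size_sdlog,
              weight_scheme = weight_scheme,
              weight_jitter_sdlog = weight_jitter_sdlog,
              seed = as.integer(seed))
  stopifnot(all(cfg$age_probs > 0), all(cfg$race_probs > 0),
            all(cfg$edu_probs > 0), all(poverty_shape > 0),
            all(race_dirichlet > 0), county_size_sdlog >= 0,
            weight_jitter_sdlog >= 0)
  class(cfg) <- "jp_sim_config"
  cfg
}

.rdirichlet1 <- function(n, alpha) {
  g <- matrix(stats::rgamma(n * length(alpha), shape = alpha),
              n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate a synthetic hierarchical survey dataset
#'
#' Forward-simulates the full model on a lattice geography: county
#' covariates are drawn from the configured distributions with the three
#' top-decile race-composition indicators computed by
#' \code{\link{top_decile_indicator}}; latent county and state fields are
#' drawn from the ICAR model at the true conditional variances; each
#' respondent is assigned a county (probability proportional to a simulated
#' log-normal county population), demographic covariates, a survey weight
#' from the informative response scheme, and an outcome category drawn from
#' the multinomial probabilities of the true linear predictor. Fully
#' reproducible given the config seed.
#'
#' @param config a \code{jp_sim_config}
#' @return list of class \code{jp_simdata} with elements
#'   \code{respondents}, \code{counties}, \code{geography},
#'   \code{true_params} and \code{config}
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "jp_sim_config"))
  geo <- make_lattice_geography(config$n_counties, config$n_states)
  nc <- geo$n_counties

  set.seed(config$seed %% 2147480000L + 11L)
  poverty <- stats::rbeta(nc, config$poverty_shape[[1]],
                          config$poverty_shape[[2]])
  log_density <- stats::rnorm(nc, config$logdens_mean, config$logdens_sd)
  comp <- .rdirichlet1(nc, config$race_dirichlet)
  counties <- data.frame(
    county = seq_len(nc), state = geo$county_state,
    poverty = poverty, log_density = log_density,
    top_black = top_decile_indicator(comp[, 2]),
    top_hisp = top_decile_indicator(comp[, 3]),
    top_other = top_decile_indicator(comp[, 4]))

  truth <- config$true_params
  if (is.null(truth)) truth <- default_true_params(nc, geo$n_states)
  stopifnot(inherits(truth, "jp_params"),
            truth$n_counties == nc, truth$n_states == geo$n_states)
  set.seed(config$seed %% 2147480000L + 22L)
  if (all(truth$v == 0) && truth$sigma2_v > 0) {
    truth$v <- sample_icar(geo$county_graph, truth$sigma2_v)
  }
  if (all(truth$u == 0) && truth$sigma2_u > 0) {
    truth$u <- sample_icar(geo$state_graph, truth$sigma2_u)
  }
  truth <- apply_constraints(truth, geo$county_graph, geo$state_graph)

  set.seed(config$seed %% 2147480000L + 33L)
  n <- config$n_respondents
  size <- stats::rlnorm(nc, 0, config$county_size_sdlog)
  resp <- data.frame(
    id = seq_len(n),
    age_group = sample.int(12L, n, replace = TRUE, prob = config$age_probs),
    race = sample.int(4L, n, replace = TRUE, prob = config$race_probs),
    education = sample.int(4L, n, replace = TRUE, prob = config$edu_probs),
    county = sample.int(nc, n, replace = TRUE, prob = size / sum(size)),
    weight = 1, category = 1L)
  resp <- assign_survey_weights(resp, config$weight_scheme,
                                jitter_sdlog = config$weight_jitter_sdlog,
                                seed = config$seed %% 2147480000L + 44L)

  set.seed(config$seed %% 2147480000L + 55L)
  pi_mat <- category_probs(
    linear_predictor(resp, counties, truth, model_spec(3L)))
  un <- stats::runif(n)
  cum <- pi_mat[, 1]
  y <- rep.int(6L, n)
  assigned <- un < cum
  y[assigned] <- 1L
  for (j in 2:5) {
    cum <- cum + pi_mat[, j]
    newly <- !assigned & un < cum
    y[newly] <- j
    assigned <- assigned | newly
  }
  resp$category <- y

  structure(list(respondents = resp, counties = counties, geography = geo,
                 true_params = truth, config = config),
            class = "jp_simdata")
}

#' Assign survey weights by inverse stratum sampling probability
#'
#' Emulates differential survey response over age x race strata: each
#' stratum's sampling probability is the product of an age factor and a
#' race factor, and the design weight is its inverse, optionally jittered
#' log-normally (mean-one jitter) to mimic post-stratification noise.
#'
#' @param respondents respondent table
#' @param scheme list with positive \code{age} (length A) and \code{race}
#'   (length 4) probability factors
#' @param jitter_sdlog log-normal jitter sd on the log scale (0 = exact
#'   inverse-probability weights)
#' @param seed RNG seed for the jitter
#' @return the respondent table with its \code{weight} column replaced
#' @export
assign_survey_weights <- function(respondents, scheme,
                                  jitter_sdlog = 0, seed = NULL) {
  p <- scheme$age[respondents$age_group] * scheme$race[respondents$race]
  if (any(!is.finite(p) | p <= 0)) {
    stop("sampling probabilities must be positive for every stratum")
  }
  w <- 1 / p
  if (jitter_sdlog > 0) {
    if (!is.null(seed)) set.seed(seed)
    w <- w * stats::rlnorm(length(w), -jitter_sdlog^2 / 2, jitter_sdlog)
  }
  respondents$weight <- w
  respondents
}
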