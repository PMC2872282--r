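#' Intrinsic CAR log-density
#'
#' Log-density of the intrinsic conditional autoregressive (ICAR) prior with
#' binary adjacency: a pairwise-difference Gaussian kernel
#' \deqn{-\frac{1}{2\sigma^2}\sum_{i \sim j} (x_i - x_j)^2}
#' (each edge counted once) which, restricted to the sum-to-zero subspace of
#' each connected component, is the density of a degenerate Gaussian with
#' precision \eqn{L/\sigma^2} (L the graph Laplacian). The full normalising
#' constant is included: each component of size m contributes
#' \eqn{-\tfrac{m-1}{2}\log(2\pi\sigma^2)} plus half the log pseudo-
#' determinant of its Laplacian. Isolated nodes (islands) contribute
#' independent Normal(0, sigma^2) log-densities instead.
#'
#' The kernel depends on x only through pairwise differences, so it is
#' invariant to adding a constant within a component; callers are expected
#' to keep x centered (see \code{\link{apply_constraints}}).
#'
#' @param x numeric vector of area effects, centered to sum zero per
#'   component
#' @param graph a \code{jp_graph}
#' @param sigma2 conditional variance (> 0)
#' @return scalar log-density; \code{-Inf} when \code{sigma2 <= 0}
#' @export
icar_logpdf_kernel <- function(x, graph, sigma2) {
  if (!inherits(graph, "jp_graph")) {
    stop("'graph' must be a validated jp_graph (symmetric adjacency)")
  }
  stopifnot(length(x) == graph$n)
  if (!is.finite(sigma2) || sigma2 <= 0) return(-Inf)
  ed <- graph_edges(graph)
  q <- if (nrow(ed)) sum((x[ed[, 1]] - x[ed[, 2]])^2) else 0
  n_eff <- graph$n - graph$n_components  # rank of the Laplacian
  ll <- -q / (2 * sigma2) + 0.5 * graph$slogdet -
    (n_eff / 2) * log(2 * pi * sigma2)
  if (any(graph$island)) {
    ll <- ll + sum(stats::dnorm(x[graph$island], 0, sqrt(sigma2),
                                log = TRUE))
  }
  ll
}

# log inverse-Wishart(nu, S) density at Sigma (p x p)
.ldiwish <- function(Sigma, nu, S) {
  p <- nrow(Sigma)
  cS <- chol(Sigma)
  ldetSig <- 2 * sum(log(diag(cS)))
  ldetS <- determinant(S, logarithm = TRUE)$modulus[[1]]
  lmvgamma <- (p * (p - 1) / 4) * log(pi) +
    sum(lgamma(nu / 2 + (1 - seq_len(p)) / 2))
  Sinv_tr <- sum(diag(solve(Sigma, S)))
  (nu / 2) * ldetS - (nu * p / 2) * log(2) - lmvgamma -
    ((nu + p + 1) / 2) * ldetSig - 0.5 * Sinv_tr
}

# log-density of the correlated age-effect prior: first-order random walk
# across age groups with innovations jointly MVN(0, Sigma_eta) across the J
# categories (level handled by the sum-to-zero constraint, so only the A-1
# innovations carry density)
.age_rw_logpdf <- function(eta, Sigma_eta) {
  J <- nrow(eta)
  A <- ncol(eta)
  D <- eta[, -1, drop = FALSE] - eta[, -A, drop = FALSE]  # J x (A-1)
  cS <- tryCatch(chol(Sigma_eta), error = function(e) NULL)
  if (is.null(cS)) return(-Inf)
  ldet <- 2 * sum(log(diag(cS)))
  z <- backsolve(cS, D, transpose = TRUE)
  -0.5 * (A - 1) * (J * log(2 * pi) + ldet) - 0.5 * sum(z^2)
}

#' Joint log-prior of the model parameters
#'
#' Sums the log prior densities of every block active under the model
#' specification: Normal(0, 10^2) on each free fixed effect (intercepts,
#' race, education, county covariates) and on the free loadings
#' \code{lambda[2..J]}, \code{kappa[2..J]}; the ICAR kernel on the county
#' and state latent fields with their conditional variances; half-Normal(0,1)
#' on \code{sigma_v} and \code{sigma_u} (densities in sigma, not sigma^2);
#' the correlated age-effect prior (per-category first-order random walk
#' with MVN(0, Sigma_eta) cross-category innovations); and
#' inverse-Wishart(J + 2, I) on \code{Sigma_eta}. Support violations return
#' \code{-Inf} rather than raising, so an MCMC proposal is simply rejected.
#'
#' @param params a \code{jp_params} satisfying the constraints
#' @param county_graph,state_graph \code{jp_graph}s for the two latent fields
#' @param spec a \code{jp_spec}
#' @param prior_sd standard deviation of the Normal prior on fixed effects
#'   and free loadings (default 10)
#' @return scalar log prior density
#' @export
log_prior <- function(params, county_graph, state_graph, spec,
                      prior_sd = 10) {
  p <- params
  if (!is.finite(p$sigma2_v) || p$sigma2_v <= 0 ||
      !is.finite(p$sigma2_u) || p$sigma2_u <= 0) {
    return(-Inf)
  }
  J <- spec$J
  lp <- sum(stats::dnorm(p$alpha, 0, prior_sd, log = TRUE))
  if (spec$include_race_education) {
    lp <- lp + sum(stats::dnorm(p$beta[, -1], 0, prior_sd, log = TRUE)) +
      sum(stats::dnorm(p$gamma[, -1], 0, prior_sd, log = TRUE))
  }
  if (spec$include_county_covariates) {
    lp <- lp + sum(stats::dnorm(p$delta, 0, prior_sd, log = TRUE))
  }
  lp <- lp +
    sum(stats::dnorm(p$lambda[-1], 0, prior_sd, log = TRUE)) +
    sum(stats::dnorm(p$kappa[-1], 0, prior_sd, log = TRUE))
  lp <- lp + icar_logpdf_kernel(p$v, county_graph, p$sigma2_v) +
    icar_logpdf_kernel(p$u, state_graph, p$sigma2_u)
  # half-Normal(0, 1) on the conditional standard deviations
  lp <- lp + log(2) + stats::dnorm(sqrt(p$sigma2_v), 0, 1, log = TRUE) +
    log(2) + stats::dnorm(sqrt(p$sigma2_u), 0, 1, log = TRUE)
  lp <- lp + .age_rw_logpdf(p$eta, p$Sigma_eta)
  lp + .ldiwish(p$Sigma_eta, J + 2, diag(J))
}
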