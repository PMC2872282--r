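#' Parameter set for the multilevel multinomial model
#'
#' Bundles every model unknown: per-category intercepts \code{alpha};
#' race and education fixed effects \code{beta}, \code{gamma} (J x 4, first
#' column the reference, fixed at 0); correlated age random effects
#' \code{eta} (J x A, each row sum-to-zero); county covariate effects
#' \code{delta} (J x 5); latent spatially structured county and state
#' factors \code{v}, \code{u} (each centered to sum zero); their
#' category-specific loadings \code{lambda}, \code{kappa} (first loading
#' fixed at 1 for identifiability); conditional ICAR variances
#' \code{sigma2_v}, \code{sigma2_u}; and the cross-category covariance
#' \code{Sigma_eta} of the age-effect random-walk innovations.
#'
#' All arguments default to the zero/identity null configuration; supplied
#' values are passed through \code{\link{apply_constraints}} so a
#' \code{jp_params} object always satisfies the identifiability constraints.
#'
#' @param J,A numbers of non-reference categories and age groups
#' @param n_counties,n_states geography sizes
#' @param alpha,beta,gamma,eta,delta,v,u,lambda,kappa,sigma2_v,sigma2_u,Sigma_eta
#'   optional initial values (recycled/validated)
#' @return an object of class \code{jp_params}
#' @export
param_set <- function(J = 5L, A = 12L, n_counties = 1L, n_states = 1L,
                      alpha = numeric(J), beta = matrix(0, J, 4),
                      gamma = matrix(0, J, 4), eta = matrix(0, J, A),
                      delta = matrix(0, J, 5), v = numeric(n_counties),
                      u = numeric(n_states), lambda = rep(1, J),
                      kappa = rep(1, J), sigma2_v = 1, sigma2_u = 1,
                      Sigma_eta = diag(J)) {
  p <- structure(list(J = as.integer(J), A = as.integer(A),
                      n_counties = as.integer(n_counties),
                      n_states = as.integer(n_states),
                      alpha = as.numeric(alpha),
                      beta = as.matrix(beta), gamma = as.matrix(gamma),
                      eta = as.matrix(eta), delta = as.matrix(delta),
                      v = as.numeric(v), u = as.numeric(u),
                      lambda = as.numeric(lambda),
                      kappa = as.numeric(kappa),
                      sigma2_v = as.numeric(sigma2_v),
                      sigma2_u = as.numeric(sigma2_u),
                      Sigma_eta = as.matrix(Sigma_eta)),
                 class = "jp_params")
  stopifnot(length(p$alpha) == J, nrow(p$beta) == J, ncol(p$beta) == 4,
            nrow(p$gamma) == J, ncol(p$gamma) == 4,
            nrow(p$eta) == J, ncol(p$eta) == A,
            nrow(p$delta) == J, ncol(p$delta) == 5,
            length(p$v) == n_counties, length(p$u) == n_states,
            length(p$lambda) == J, length(p$kappa) == J,
            nrow(p$Sigma_eta) == J, ncol(p$Sigma_eta) == J)
  apply_constraints(p)
}

#' Enforce the model's identifiability constraints
#'
#' Applies, in place: corner constraints \code{beta[, 1] = gamma[, 1] = 0};
#' per-category sum-to-zero centering of the age effects \code{eta};
#' reference loadings \code{lambda[1] = kappa[1] = 1}; and sum-to-zero
#' centering of the latent fields \code{v} and \code{u} (per connected
#' component when the corresponding graph is supplied, overall otherwise).
#' Centering a latent field preserves all pairwise differences, so the ICAR
#' kernel value is unchanged; the removed level is absorbed by the free
#' intercepts. The operation is idempotent.
#'
#' @param params a \code{jp_params}
#' @param county_graph,state_graph optional \code{jp_graph}s for
#'   per-component centering
#' @return the constrained \code{jp_params}
#' @export
apply_constraints <- function(params, county_graph = NULL,
                              state_graph = NULL) {
  p <- params
  p$beta[, 1] <- 0
  p$gamma[, 1] <- 0
  p$eta <- p$eta - rowMeans(p$eta)
  p$lambda[1] <- 1
  p$kappa[1] <- 1
  p$v <- .center_field(p$v, county_graph)
  p$u <- .center_field(p$u, state_graph)
  p
}

.center_field <- function(x, graph) {
  if (is.null(graph)) return(x - mean(x))
  for (k in seq_len(graph$n_components)) {
    idx <- graph$component == k
    x[idx] <- x[idx] - mean(x[idx])
  }
  x
}

#' @export
print.jp_params <- function(x, ...) {
  cat("jp_params: J =", x$J, "A =", x$A, "|", x$n_counties, "counties,",
      x$n_states, "states\n")
  cat("  alpha:", signif(x$alpha, 3), "\n")
  cat("  lambda:", signif(x$lambda, 3), " kappa:", signif(x$kappa, 3), "\n")
  cat("  sigma2_v:", signif(x$sigma2_v, 3),
      " sigma2_u:", signif(x$sigma2_u, 3), "\n")
  invisible(x)
}
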