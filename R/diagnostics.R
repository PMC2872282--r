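#' Brooks-Gelman-Rubin potential scale reduction factor
#'
#' Computes the corrected PSRF per scalar parameter from two or more chains
#' of equal post-burn-in length: with within-chain variance W, between-chain
#' variance B and the pooled estimate
#' \eqn{\hat V = \frac{n-1}{n} W + \frac{B}{n} + \frac{B}{mn}}, the
#' statistic is \eqn{\sqrt{\frac{m+1}{m}\hat V / W - \frac{n-1}{mn}}}.
#' Identical chains give the correction's floor \eqn{\sqrt{(n-1)/n}}
#' (marginally below 1); values at or below 1.1 are conventionally reported
#' as converged. Parameters with zero variance in every chain return 1.
#'
#' @param chains either a \code{jp_fit} or a list of draw matrices
#'   (iterations x parameters), one per chain, with equal dimensions
#' @return named numeric vector of PSRF values
#' @export
gelman_rubin <- function(chains) {
  if (inherits(chains, "jp_fit")) chains <- chains$draws
  if (!is.list(chains) || length(chains) < 2L) {
    stop("gelman_rubin needs at least two chains")
  }
  n <- unique(vapply(chains, nrow, integer(1)))
  if (length(n) != 1L) stop("chains must have equal lengths")
  m <- length(chains)
  means <- vapply(chains, colMeans, numeric(ncol(chains[[1]])))
  vars <- vapply(chains, function(x) apply(x, 2L, stats::var),
                 numeric(ncol(chains[[1]])))
  if (is.null(dim(means))) {
    means <- matrix(means, nrow = 1L)
    vars <- matrix(vars, nrow = 1L)
  }
  W <- rowMeans(vars)
  B_n <- apply(means, 1L, stats::var)          # = B / n
  Vhat <- (n - 1) / n * W + B_n + B_n / m
  psrf <- sqrt(pmax(0, (m + 1) / m * Vhat / W - (n - 1) / (m * n)))
  psrf[W < 1e-300 & B_n < 1e-300] <- 1
  psrf[W < 1e-300 & B_n >= 1e-300] <- Inf
  names(psrf) <- colnames(chains[[1]])
  psrf
}

#' Deviance Information Criterion
#'
#' DIC = Dbar + pD, with Dbar the average of the sampled deviances
#' (-2 times the weighted log-likelihood) and the effective number of
#' parameters pD = Dbar - D(posterior mean). Lower values indicate better
#' fit after the complexity penalty. A negative pD (possible in pathological
#' fits) is reported verbatim with a warning.
#'
#' @param fit a \code{jp_fit}
#' @param respondents,counties the data the model was fitted to
#' @return list of class \code{jp_dic} with \code{Dbar}, \code{pD},
#'   \code{DIC} and \code{D_at_mean}
#' @export
compute_dic <- function(fit, respondents, counties) {
  stopifnot(inherits(fit, "jp_fit"))
  devs <- unlist(fit$deviance)
  if (!length(devs)) stop("empty deviance trace")
  Dbar <- mean(devs)
  resp <- respondents
  resp$weight <- fit$weights
  D_hat <- -2 * weighted_loglik(resp, counties, fit$posterior_mean,
                                fit$spec)
  pD <- Dbar - D_hat
  if (pD < 0) warning("negative effective parameter count pD = ",
                      round(pD, 2))
  structure(list(Dbar = Dbar, pD = pD, DIC = Dbar + pD,
                 D_at_mean = D_hat),
            class = "jp_dic")
}

#' @export
print.jp_dic <- function(x, ...) {
  cat(sprintf("DIC = %.1f (Dbar = %.1f, pD = %.1f)\n",
              x$DIC, x$Dbar, x$pD))
  invisible(x)
}

# batch-means Monte Carlo standard error (50 batches over pooled draws)
.mc_error <- function(x, n_batches = 50L) {
  n <- length(x)
  if (n < 2L * n_batches) n_batches <- max(2L, n %/% 2L)
  bs <- n %/% n_batches
  bm <- colMeans(matrix(x[seq_len(bs * n_batches)], nrow = bs))
  stats::sd(bm) / sqrt(n_batches)
}

#' Posterior summary table
#'
#' One row per stored parameter in the reference reporting layout:
#' posterior mean, standard deviation, batch-means MC error, and the 2.5,
#' 50 and 97.5 percent quantiles of the pooled post-burn-in draws, plus the
#' between-chain PSRF when at least two chains were run.
#'
#' @param fit a \code{jp_fit}
#' @param params optional character vector restricting the rows
#' @return a data.frame with one row per parameter
#' @export
fit_summary <- function(fit, params = NULL) {
  stopifnot(inherits(fit, "jp_fit"))
  pooled <- do.call(rbind, fit$draws)
  keep <- if (is.null(params)) colnames(pooled) else params
  pooled <- pooled[, keep, drop = FALSE]
  qs <- t(apply(pooled, 2L, stats::quantile,
                probs = c(0.025, 0.5, 0.975), names = FALSE))
  out <- data.frame(
    parameter = keep,
    mean = colMeans(pooled),
    sd = apply(pooled, 2L, stats::sd),
    mc_error = apply(pooled, 2L, .mc_error),
    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3],
    row.names = NULL)
  if (length(fit$draws) >= 2L) {
    out$psrf <- unname(gelman_rubin(fit$draws)[keep])
  }
  out
}

#' @export
summary.jp_fit <- function(object, ...) fit_summary(object, ...)

#' Names of the reported (table-style) parameters of a fit
#'
#' The model parameters a report tabulates: intercepts, race and education
#' contrasts, county covariate effects, free loadings and the conditional
#' variances. Random effects that are displayed only as posterior-mean
#' summaries -- the per-area latent values \code{v[c]}, \code{u[s]}, the
#' age profiles \code{eta[j,a]} and the innovation covariance entries --
#' are excluded (their PSRF values are still available through
#' \code{\link{fit_summary}}).
#'
#' @param fit a \code{jp_fit}
#' @return character vector of parameter names
#' @export
reported_parameters <- function(fit) {
  nm <- fit$layout
  nm[!grepl("^(v\\[|u\\[|eta\\[|Sigma_eta\\[)", nm)]
}
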