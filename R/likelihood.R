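#' Multinomial linear predictor
#'
#' Evaluates, for every respondent, the J regression terms of the
#' multinomial logit model (the reference category's term is implicitly 0):
#' \deqn{\phi_{ij} = \alpha_j + \beta_{j,r_i} + \gamma_{j,e_i} +
#'   \eta_{j,a_i} + \sum_k \delta_{jk} x_{k,C_i} +
#'   \lambda_j v_{C_i} + \kappa_j u_{S_{C_i}}}
#' with the race/education and county-covariate blocks switched off when the
#' model specification excludes them (models 1 and 2 of the incremental
#' strategy).
#'
#' @param respondents respondent table (see \code{\link{read_respondents}})
#' @param counties county table carrying state membership and covariates
#' @param params a \code{jp_params}
#' @param spec a \code{jp_spec}
#' @return numeric matrix, \code{nrow(respondents)} x J
#' @export
linear_predictor <- function(respondents, counties, params, spec) {
  J <- spec$J
  cty <- respondents$county
  if (any(cty < 1L | cty > nrow(counties))) {
    stop("respondent county index does not resolve to a county record")
  }
  X <- .county_design(counties)
  if (any(!is.finite(X))) stop("non-finite county covariate")
  st <- as.integer(counties$state)
  if (any(st < 1L | st > length(params$u))) {
    stop("county state index does not resolve to a state effect")
  }
  a <- respondents$age_group
  r <- respondents$race
  e <- respondents$education
  phi <- matrix(0, nrow(respondents), J)
  Xd <- if (spec$include_county_covariates) X %*% t(params$delta) else NULL
  for (j in seq_len(J)) {
    ph <- params$alpha[[j]] + params$eta[j, a] +
      params$lambda[[j]] * params$v[cty] +
      params$kappa[[j]] * params$u[st[cty]]
    if (spec$include_race_education) {
      ph <- ph + params$beta[j, r] + params$gamma[j, e]
    }
    if (spec$include_county_covariates) ph <- ph + Xd[cty, j]
    phi[, j] <- ph
  }
  phi
}

.county_design <- function(counties) {
  as.matrix(counties[, c("poverty", "log_density", "top_black",
                         "top_hisp", "top_other")])
}

#' Category probabilities from linear predictors
#'
#' Maps the J-vector of regression terms for each respondent to the J + 1
#' category probabilities of the multinomial logit, with the final
#' (non-morbid) category as reference:
#' \eqn{\pi_j = e^{\phi_j} / (1 + \sum_{j'} e^{\phi_{j'}})} and
#' \eqn{\pi_{J+1} = 1 / (1 + \sum_{j'} e^{\phi_{j'}})}. Computed through an
#' overflow-safe log-sum-exp so saturated predictors do not produce NaN.
#'
#' @param phi numeric matrix n x J (or a J-vector for one respondent)
#' @return numeric matrix n x (J + 1); rows sum to 1
#' @export
category_probs <- function(phi) {
  if (is.null(dim(phi))) phi <- matrix(phi, nrow = 1L)
  lse <- .row_logsumexp0(phi)
  cbind(exp(phi - lse), exp(-lse))
}

# log(1 + sum_j exp(phi_j)) per row, overflow-safe
.row_logsumexp0 <- function(phi) {
  m <- rep(0, nrow(phi))
  for (j in seq_len(ncol(phi))) m <- pmax(m, phi[, j])
  s <- exp(-m)
  for (j in seq_len(ncol(phi))) s <- s + exp(phi[, j] - m)
  m + log(s)
}

#' Survey-weighted multinomial log-likelihood
#'
#' The weighted pseudo-log-likelihood
#' \eqn{\sum_i w_i \sum_j d_{ij} \log \pi_{ij}} with \eqn{d_{ij} = 1} when
#' respondent i is observed in category j. With all weights equal to 1 this
#' is the ordinary multinomial log-likelihood. If an observed category has
#' probability exactly zero the function returns \code{-Inf} (not an error),
#' so MCMC proposals into degenerate regions are rejected rather than
#' aborting the chain.
#'
#' @inheritParams linear_predictor
#' @return scalar log-likelihood
#' @export
weighted_loglik <- function(respondents, counties, params, spec) {
  phi <- linear_predictor(respondents, counties, params, spec)
  lse <- .row_logsumexp0(phi)
  y <- respondents$category
  lp <- -lse
  obs <- y <= spec$J
  lp[obs] <- phi[cbind(which(obs), y[obs])] - lse[obs]
  sum(respondents$weight * lp)
}

# Aggregate respondents into unique covariate cells with per-category summed
# weights: the weighted log-likelihood depends on the data only through
# these sufficient statistics, which is what makes the pure-R sampler fast.
.build_cells <- function(respondents, counties, spec) {
  n <- nrow(respondents)
  a <- as.integer(respondents$age_group)
  cty <- as.integer(respondents$county)
  if (spec$include_race_education) {
    r <- as.integer(respondents$race)
    e <- as.integer(respondents$education)
    code <- (((cty - 1L) * spec$A + (a - 1L)) * 4L + (r - 1L)) * 4L +
      (e - 1L)
  } else {
    r <- rep(1L, n)
    e <- rep(1L, n)
    code <- (cty - 1L) * spec$A + (a - 1L)
  }
  uniq <- sort(unique(code))
  idx <- match(code, uniq)
  Wfull <- matrix(0, n, spec$J + 1L)
  Wfull[cbind(seq_len(n), as.integer(respondents$category))] <-
    respondents$weight
  W <- rowsum(Wfull, idx, reorder = TRUE)
  ncell <- length(uniq)
  if (spec$include_race_education) {
    e_c <- uniq %% 4L + 1L
    rest <- uniq %/% 4L
    r_c <- rest %% 4L + 1L
    rest <- rest %/% 4L
    a_c <- rest %% spec$A + 1L
    cty_c <- rest %/% spec$A + 1L
  } else {
    a_c <- uniq %% spec$A + 1L
    cty_c <- uniq %/% spec$A + 1L
    r_c <- rep(1L, ncell)
    e_c <- rep(1L, ncell)
  }
  nc <- nrow(counties)
  ns <- max(as.integer(counties$state))
  st_c <- as.integer(counties$state)[as.integer(cty_c)]
  list(n_cells = ncell, a = as.integer(a_c), r = as.integer(r_c),
       e = as.integer(e_c), county = as.integer(cty_c),
       W = unname(W), wobs = unname(W[, seq_len(spec$J), drop = FALSE]),
       wtot = unname(rowSums(W)),
       state = st_c,
       by_county = split(seq_len(ncell),
                         factor(as.integer(cty_c), levels = seq_len(nc))),
       by_state = split(seq_len(ncell), factor(st_c, levels = seq_len(ns))))
}

# weighted log-likelihood from cell sufficient statistics; `rows` restricts
# to a subset of cells (used by latent-effect block updates)
.cells_phi <- function(cells, params, spec, Xd, rows = NULL) {
  sub <- !is.null(rows)
  a <- if (sub) cells$a[rows] else cells$a
  cty <- if (sub) cells$county[rows] else cells$county
  st <- if (sub) cells$state[rows] else cells$state
  # the intercept is folded into the age-effect lookup (both per category)
  tEA <- t(params$eta) + rep(params$alpha, each = spec$A)
  phi <- tEA[a, , drop = FALSE] +
    params$v[cty] %o% params$lambda + params$u[st] %o% params$kappa
  if (spec$include_race_education) {
    phi <- phi +
      t(params$beta)[if (sub) cells$r[rows] else cells$r, ,
                     drop = FALSE] +
      t(params$gamma)[if (sub) cells$e[rows] else cells$e, ,
                      drop = FALSE]
  }
  if (spec$include_county_covariates) {
    phi <- phi + Xd[cty, , drop = FALSE]
  }
  phi
}

# per-cell contributions sum_j W_ij phi_ij - (sum_j W_ij) lse_i
.cells_ll_vec <- function(cells, params, spec, Xd, rows = NULL) {
  phi <- .cells_phi(cells, params, spec, Xd, rows)
  # fast path: the unstabilised form is exact to double precision whenever
  # the predictors are moderate, which non-degenerate MCMC states are
  if (max(phi) < 30) {
    lse <- log1p(rowSums(exp(phi)))
  } else {
    lse <- .row_logsumexp0(phi)
  }
  wobs <- if (is.null(rows)) cells$wobs else
    cells$wobs[rows, , drop = FALSE]
  wtot <- if (is.null(rows)) cells$wtot else cells$wtot[rows]
  rowSums(wobs * phi) - wtot * lse
}

.cells_loglik <- function(cells, params, spec, Xd, rows = NULL) {
  sum(.cells_ll_vec(cells, params, spec, Xd, rows))
}
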