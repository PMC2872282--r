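#' Age-standardised county prevalence estimates
#'
#' County-by-category prevalence on a common age basis: the category scores
#' are \eqn{w_{cj} = \exp(\alpha_j + \sum_k \delta_{jk} x_{kc} +
#' \lambda_j v_c + \kappa_j u_{S_c})} (the covariate term entering only
#' when the model specification includes it), with \eqn{w_{c,J+1} = 1} for
#' the reference category, normalised to
#' \eqn{p_{cj} = w_{cj} / \sum_{j'} w_{cj'}}. Subject-level race, education
#' and age terms are standardised out by construction.
#'
#' For a fitted model the default is the posterior mean of the per-draw
#' \eqn{p_{cj}} (correct under the nonlinear transform); the prevalence at
#' the posterior-mean parameters is available via \code{method = "at_mean"}.
#'
#' @param x a \code{jp_params} or a \code{jp_fit}
#' @param counties county table
#' @param spec a \code{jp_spec} (taken from the fit when \code{x} is one)
#' @param method for fits: \code{"draws"} (posterior mean of per-draw
#'   prevalences, default) or \code{"at_mean"}
#' @return list of class \code{jp_prevalence} with \code{p} and \code{w},
#'   both \code{n_counties} x (J + 1) matrices
#' @export
standardized_prevalence <- function(x, counties, spec = NULL,
                                    method = c("draws", "at_mean")) {
  method <- match.arg(method)
  if (inherits(x, "jp_fit")) {
    spec <- x$spec
    if (method == "at_mean") {
      return(standardized_prevalence(x$posterior_mean, counties, spec))
    }
    pooled <- do.call(rbind, x$draws)
    acc_p <- 0
    acc_w <- 0
    for (k in seq_len(nrow(pooled))) {
      pk <- .unpack_params(pooled[k, ], spec, x$n_counties, x$n_states,
                           latent = !x$mcmc$fix_latent_at_zero)
      pr <- .prevalence_once(pk, counties, spec)
      acc_p <- acc_p + pr$p
      acc_w <- acc_w + pr$w
    }
    out <- list(p = acc_p / nrow(pooled), w = acc_w / nrow(pooled))
    class(out) <- "jp_prevalence"
    return(out)
  }
  stopifnot(inherits(x, "jp_params"))
  if (is.null(spec)) spec <- model_spec(3L)
  out <- .prevalence_once(x, counties, spec)
  class(out) <- "jp_prevalence"
  out
}

.prevalence_once <- function(params, counties, spec) {
  J <- spec$J
  nc <- nrow(counties)
  st <- as.integer(counties$state)
  lw <- matrix(0, nc, J + 1L)  # log scores; reference column stays 0
  Xd <- if (spec$include_county_covariates) {
    .county_design(counties) %*% t(params$delta)
  } else NULL
  for (j in seq_len(J)) {
    lw[, j] <- params$alpha[[j]] + params$lambda[[j]] * params$v +
      params$kappa[[j]] * params$u[st]
    if (!is.null(Xd)) lw[, j] <- lw[, j] + Xd[, j]
  }
  m <- apply(lw, 1L, max)
  w <- exp(lw)
  p <- exp(lw - m) / rowSums(exp(lw - m))
  list(p = p, w = w)
}

#' Composite latent area effects
#'
#' The total unmeasured-area contribution for category j in county c,
#' \eqn{t_{jc} = \lambda_j v_c + \kappa_j u_{S_c}}; under the
#' identifiability constraint \eqn{\lambda_1 = \kappa_1 = 1} the first
#' category reduces to the plain sum \eqn{v_c + u_{S_c}}.
#'
#' @param params a \code{jp_params} (e.g. the posterior mean of a fit)
#' @param counties county table (for state membership)
#' @return matrix n_counties x J of composite effects
#' @export
composite_effects <- function(params, counties) {
  stopifnot(inherits(params, "jp_params"))
  st <- as.integer(counties$state)
  J <- length(params$lambda)
  t_mat <- matrix(0, nrow(counties), J)
  for (j in seq_len(J)) {
    t_mat[, j] <- params$lambda[[j]] * params$v +
      params$kappa[[j]] * params$u[st]
  }
  colnames(t_mat) <- paste0("t", seq_len(J))
  t_mat
}

#' Marginal variance of the latent spatial effects
#'
#' The variance, over the respondent distribution, of the latent area
#' contribution \eqn{s_i = \lambda_{j(i)} v_{C_i} + \kappa_{j(i)} u_{S_i}}
#' evaluated at each respondent's observed category j(i). Respondents in
#' the reference (non-morbid) category have no own category loading; by
#' default they contribute the category-share-weighted average of the J
#' per-category composite effects (an approximation to an under-specified
#' marginal quantity; see the methods vignette), or they can be excluded
#' with \code{reference = "drop"}.
#'
#' For a fitted model the posterior mean of the per-draw variance is
#' returned.
#'
#' @param x a \code{jp_params} or \code{jp_fit}
#' @param respondents respondent table
#' @param counties county table
#' @param reference \code{"share_weighted"} (default) or \code{"drop"}
#' @return scalar marginal variance
#' @export
marginal_latent_variance <- function(x, respondents, counties,
                                     reference = c("share_weighted",
                                                   "drop")) {
  reference <- match.arg(reference)
  if (nrow(respondents) == 0L) stop("empty respondent set")
  if (inherits(x, "jp_fit")) {
    pooled <- do.call(rbind, x$draws)
    idx <- round(seq(1L, nrow(pooled),
                     length.out = min(400L, nrow(pooled))))
    vals <- vapply(idx, function(k) {
      pk <- .unpack_params(pooled[k, ], x$spec, x$n_counties, x$n_states,
                           latent = !x$mcmc$fix_latent_at_zero)
      .marginal_var_once(pk, respondents, counties, reference)
    }, numeric(1))
    return(mean(vals))
  }
  stopifnot(inherits(x, "jp_params"))
  .marginal_var_once(x, respondents, counties, reference)
}

.marginal_var_once <- function(params, respondents, counties, reference) {
  J <- length(params$lambda)
  st <- as.integer(counties$state)
  cty <- respondents$county
  y <- respondents$category
  vv <- params$v[cty]
  uu <- params$u[st[cty]]
  obs <- y <= J
  s <- numeric(length(y))
  s[obs] <- params$lambda[y[obs]] * vv[obs] + params$kappa[y[obs]] * uu[obs]
  if (reference == "drop") {
    s <- s[obs]
  } else {
    shares <- vapply(seq_len(J), function(j) {
      sum(respondents$weight[y == j])
    }, numeric(1))
    shares <- shares / sum(shares)
    lam_bar <- sum(shares * params$lambda)
    kap_bar <- sum(shares * params$kappa)
    s[!obs] <- lam_bar * vv[!obs] + kap_bar * uu[!obs]
  }
  if (length(s) < 2L) return(0)
  stats::var(s)
}

#' Mean composite effect by county poverty decile
#'
#' Ranks counties by poverty rate, splits the ranking into ten near-equal
#' groups (any remainder spread over the lowest deciles), and returns the
#' mean of the supplied composite latent effect in each decile, ordered
#' from least to most poor.
#'
#' @param t1 numeric vector of composite effects, one per county
#' @param poverty numeric vector of county poverty rates, same length
#' @return data.frame with columns \code{decile}, \code{n},
#'   \code{mean_effect}
#' @export
poverty_decile_profile <- function(t1, poverty) {
  stopifnot(length(t1) == length(poverty))
  n <- length(t1)
  if (n < 10L) stop("at least 10 counties are required for deciles")
  base <- n %/% 10L
  rem <- n %% 10L
  sizes <- rep(base, 10L) + c(rep(1L, rem), rep(0L, 10L - rem))
  grp <- rep(seq_len(10L), times = sizes)
  ord <- order(poverty, seq_len(n))  # stable tie-break by county index
  dec <- integer(n)
  dec[ord] <- grp
  data.frame(decile = seq_len(10L), n = sizes,
             mean_effect = vapply(seq_len(10L),
                                  function(d) mean(t1[dec == d]),
                                  numeric(1)))
}

#' Cross-tabulated category prevalence by demographic group
#'
#' Percentage of subjects in each of the J + 1 outcome categories within
#' each level of a grouping variable (education, race, or state of
#' residence), optionally survey-weighted and optionally directly
#' age-standardised to the overall sample's (weighted) age distribution.
#' Each row sums to 100 up to rounding. Empty groups are dropped with a
#' warning; under age standardisation a group's missing age strata are
#' renormalised away.
#'
#' @param respondents respondent table
#' @param group_by one of \code{"education"}, \code{"race"}, \code{"state"}
#' @param weighted use survey weights
#' @param age_standardize directly standardise to the overall age
#'   distribution
#' @param counties county table; required when grouping by state
#' @param spec a \code{jp_spec} for the category/age ranges
#' @return data.frame of class \code{jp_crosstab}: one row per group,
#'   columns \code{group}, \code{n}, and \code{cat1..cat6} percentages
#' @export
crosstab_prevalence <- function(respondents,
                                group_by = c("education", "race", "state"),
                                weighted = FALSE, age_standardize = FALSE,
                                counties = NULL, spec = model_spec(3L)) {
  group_by <- match.arg(group_by)
  g <- switch(group_by,
              education = respondents$education,
              race = respondents$race,
              state = {
                if (is.null(counties)) {
                  stop("grouping by state requires the county table")
                }
                as.integer(counties$state)[respondents$county]
              })
  w <- if (weighted) respondents$weight else rep(1, nrow(respondents))
  y <- respondents$category
  a <- respondents$age_group
  K <- spec$J + 1L
  levels_g <- switch(group_by,
                     education = seq_len(spec$n_edu),
                     race = seq_len(spec$n_race),
                     state = seq_len(max(as.integer(counties$state))))
  # overall (weighted) age distribution as the standard population
  p_age <- vapply(seq_len(spec$A), function(aa) sum(w[a == aa]),
                  numeric(1))
  p_age <- p_age / sum(p_age)
  rows <- lapply(levels_g, function(gg) {
    in_g <- g == gg
    if (!any(in_g)) return(NULL)
    if (!age_standardize) {
      tot <- sum(w[in_g])
      pct <- vapply(seq_len(K), function(j) {
        100 * sum(w[in_g & y == j]) / tot
      }, numeric(1))
    } else {
      num <- matrix(0, spec$A, K)
      present <- logical(spec$A)
      for (aa in seq_len(spec$A)) {
        sel <- in_g & a == aa
        tot_a <- sum(w[sel])
        if (tot_a > 0) {
          present[[aa]] <- TRUE
          num[aa, ] <- vapply(seq_len(K), function(j) {
            sum(w[sel & y == j]) / tot_a
          }, numeric(1))
        }
      }
      wt <- p_age * present
      wt <- wt / sum(wt)
      pct <- 100 * colSums(num * wt)
    }
    c(group = gg, n = sum(in_g), stats::setNames(pct, paste0("cat",
                                                             seq_len(K))))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!all(keep)) warning("empty group(s) omitted from cross-tabulation")
  out <- as.data.frame(do.call(rbind, rows[keep]))
  class(out) <- c("jp_crosstab", "data.frame")
  out
}
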