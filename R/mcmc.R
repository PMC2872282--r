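#' MCMC configuration
#'
#' Settings for the adaptive Metropolis-within-Gibbs sampler. Defaults
#' follow the reference workflow: two chains of 10,000 iterations with the
#' first half discarded as burn-in, dispersed starting values, and
#' random-walk proposals adapted during burn-in (then frozen, preserving
#' detailed balance for the retained draws).
#'
#' @param n_chains number of chains (>= 2 for between-chain diagnostics)
#' @param n_iter iterations per chain
#' @param burn_frac fraction discarded as burn-in, in (0, 1)
#' @param seed master seed; chain c uses a stream derived from it
#' @param adapt_window iterations between proposal-scale refreshes
#' @param normalize_weights rescale survey weights to mean 1 before the
#'   pseudo-likelihood (keeps prior/likelihood balance sample-size honest);
#'   set \code{FALSE} to use raw weights
#' @param fix_latent_at_zero pin the latent fields (and loadings) at zero:
#'   used for intercept-only checks against the closed-form multinomial MLE
#' @param prior_sd Normal prior sd for fixed effects and free loadings
#' @return a list of class \code{jp_mcmc_config}
#' @export
mcmc_config <- function(n_chains = 2L, n_iter = 10000L, burn_frac = 0.5,
                        seed = 1L, adapt_window = 50L,
                        normalize_weights = TRUE,
                        fix_latent_at_zero = FALSE, prior_sd = 10) {
  stopifnot(n_chains >= 1L, n_iter >= 20L,
            burn_frac > 0, burn_frac < 1, adapt_window >= 10L)
  structure(list(n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter), burn_frac = burn_frac,
                 seed = as.integer(seed),
                 adapt_window = as.integer(adapt_window),
                 normalize_weights = isTRUE(normalize_weights),
                 fix_latent_at_zero = isTRUE(fix_latent_at_zero),
                 prior_sd = prior_sd),
            class = "jp_mcmc_config")
}

# ---- parameter vector packing -------------------------------------------

# names and extractors for the free parameters stored per draw
.pack_layout <- function(spec, n_counties, n_states, latent = TRUE) {
  J <- spec$J
  A <- spec$A
  nm <- paste0("alpha[", 1:J, "]")
  if (spec$include_race_education) {
    nm <- c(nm,
            paste0("beta[", rep(1:J, 3), ",", rep(2:4, each = J), "]"),
            paste0("gamma[", rep(1:J, 3), ",", rep(2:4, each = J), "]"))
  }
  nm <- c(nm, paste0("eta[", rep(1:J, A), ",", rep(1:A, each = J), "]"))
  if (spec$include_county_covariates) {
    nm <- c(nm, paste0("delta[", rep(1:J, 5), ",", rep(1:5, each = J), "]"))
  }
  if (latent) {
    nm <- c(nm, paste0("v[", seq_len(n_counties), "]"),
            paste0("u[", seq_len(n_states), "]"),
            paste0("lambda[", 2:J, "]"), paste0("kappa[", 2:J, "]"),
            "sigma2_v", "sigma2_u")
  }
  ut <- which(upper.tri(diag(J), diag = TRUE), arr.ind = TRUE)
  nm <- c(nm, paste0("Sigma_eta[", ut[, 1], ",", ut[, 2], "]"))
  nm
}

.pack_params <- function(p, spec, latent = TRUE) {
  out <- p$alpha
  if (spec$include_race_education) {
    out <- c(out, as.vector(p$beta[, 2:4]), as.vector(p$gamma[, 2:4]))
  }
  out <- c(out, as.vector(p$eta))
  if (spec$include_county_covariates) out <- c(out, as.vector(p$delta))
  if (latent) {
    out <- c(out, p$v, p$u, p$lambda[-1], p$kappa[-1],
             p$sigma2_v, p$sigma2_u)
  }
  c(out, p$Sigma_eta[upper.tri(p$Sigma_eta, diag = TRUE)])
}

.unpack_params <- function(vec, spec, n_counties, n_states,
                           latent = TRUE) {
  J <- spec$J
  A <- spec$A
  p <- param_set(J, A, n_counties, n_states)
  pos <- 0L
  take <- function(k) {
    out <- vec[pos + seq_len(k)]
    pos <<- pos + k
    out
  }
  p$alpha <- take(J)
  if (spec$include_race_education) {
    p$beta[, 2:4] <- take(3L * J)
    p$gamma[, 2:4] <- take(3L * J)
  }
  p$eta <- matrix(take(J * A), J, A)
  if (spec$include_county_covariates) {
    p$delta <- matrix(take(5L * J), J, 5L)
  }
  if (latent) {
    p$v <- take(n_counties)
    p$u <- take(n_states)
    p$lambda <- c(1, take(J - 1L))
    p$kappa <- c(1, take(J - 1L))
    p$sigma2_v <- take(1L)
    p$sigma2_u <- take(1L)
  }
  S <- matrix(0, J, J)
  S[upper.tri(S, diag = TRUE)] <- take(J * (J + 1L) / 2L)
  p$Sigma_eta <- S + t(S) - diag(diag(S))
  p
}

# ---- sampler ------------------------------------------------------------

#' Fit the multilevel multinomial model by MCMC
#'
#' Adaptive Metropolis-within-Gibbs on the survey-weighted
#' pseudo-posterior, evaluated through per-cell sufficient statistics.
#' Update blocks per sweep: two fixed-effect sub-blocks per outcome
#' category (intercept with county covariate effects; intercept with
#' race/education contrasts) using multivariate normal proposals seeded
#' from the weighted multinomial MLE covariance and refined by
#' empirical-covariance adaptation; the age-effect row of each category
#' (sum-to-zero-projected proposals shaped by MLE information blended with
#' the random-walk prior precision, plus a linear-trend tilt move); a
#' conjugate inverse-Wishart Gibbs draw for the cross-category innovation
#' covariance; the latent county and state fields by element-wise
#' Metropolis over graph-colouring classes under their ICAR conditionals;
#' loadings as per-level vector blocks with an additional prior
#' independence refresh of the weakly identified state loadings; and
#' interweaving moves (field/variance rescale, loading/field rescale,
#' state-county exchange, exact likelihood-invariant covariate/field
#' shear) that traverse the posterior's soft ridges. The county variance
#' is updated on the log scale against the ICAR kernel; the state
#' variance moves only jointly with its field. After every sweep the
#' latent fields and age effects are re-centered with the compensating
#' intercept shift, which leaves the likelihood exactly invariant.
#'
#' Proposal scales adapt towards 20--50\% acceptance during burn-in and are
#' frozen afterwards. Chains start from MLE-centred dispersed values
#' (later chains overdispersed threefold). Runs are reproducible given the
#' config seed. A non-finite posterior at initialization is retried with
#' fresh draws up to 20 times.
#'
#' @param respondents respondent table
#' @param counties county table
#' @param geography a \code{jp_geography}, or a list with
#'   \code{county_graph} and \code{state_graph}
#' @param spec a \code{jp_spec}
#' @param mcmc a \code{jp_mcmc_config}
#' @return an object of class \code{jp_fit}: per-chain draw matrices of all
#'   free parameters, deviance traces (-2 x weighted log-likelihood),
#'   acceptance rates per block, the posterior-mean parameter set, and the
#'   data/weights actually used
#' @export
run_mcmc <- function(respondents, counties, geography, spec = model_spec(3L),
                     mcmc = mcmc_config()) {
  respondents <- validate_respondents(respondents, counties, spec)
  counties <- validate_counties(counties)
  cg <- geography$county_graph
  sg <- geography$state_graph
  stopifnot(inherits(cg, "jp_graph"), inherits(sg, "jp_graph"))
  nc <- nrow(counties)
  ns <- max(as.integer(counties$state))
  stopifnot(cg$n == nc, sg$n >= ns)

  w <- respondents$weight
  if (mcmc$normalize_weights) w <- w * length(w) / sum(w)
  resp <- respondents
  resp$weight <- w
  cells <- .build_cells(resp, counties, spec)
  Xd_fun <- function(p) {
    if (spec$include_county_covariates) {
      .county_design(counties) %*% t(p$delta)
    } else NULL
  }

  latent <- !mcmc$fix_latent_at_zero
  layout <- .pack_layout(spec, nc, ns, latent)
  n_keep <- mcmc$n_iter - floor(mcmc$n_iter * mcmc$burn_frac)
  chains <- vector("list", mcmc$n_chains)
  dev <- vector("list", mcmc$n_chains)
  acc_all <- vector("list", mcmc$n_chains)
  mle <- tryCatch(.fixed_mle(cells, spec), error = function(e) NULL)
  for (ch in seq_len(mcmc$n_chains)) {
    res <- .run_one_chain(cells, counties, cg, sg, spec, mcmc, ch,
                          Xd_fun, latent, layout, n_keep, mle)
    chains[[ch]] <- res$draws
    dev[[ch]] <- res$deviance
    acc_all[[ch]] <- res$accept
  }
  pm <- .unpack_params(colMeans(do.call(rbind, chains)), spec, nc, ns,
                       latent)
  structure(list(draws = chains, deviance = dev, accept = acc_all,
                 spec = spec, mcmc = mcmc, layout = layout,
                 n_counties = nc, n_states = ns,
                 weights = w, posterior_mean = pm,
                 county_graph = cg, state_graph = sg),
            class = "jp_fit")
}

#' @export
print.jp_fit <- function(x, ...) {
  cat("jp_fit: model", x$spec$model, "|", length(x$draws), "chain(s) x",
      nrow(x$draws[[1]]), "kept draws |", length(x$layout),
      "parameters\n")
  cat("  mean deviance:",
      round(mean(unlist(x$deviance)), 1), "\n")
  invisible(x)
}

# weighted multinomial MLE of the subject-level fixed effects (no latent
# terms), used as the centre of the dispersed starting values: random-walk
# burn-in from arbitrary starts would need many thousands of sweeps to
# reach the well-identified fixed-effect mode
.fixed_mle <- function(cells, spec) {
  J <- spec$J
  df <- data.frame(a = factor(cells$a, levels = seq_len(spec$A)))
  form <- "a"
  if (spec$include_race_education) {
    df$r <- factor(cells$r, levels = 1:4)
    df$e <- factor(cells$e, levels = 1:4)
    form <- "a + r + e"
  }
  # reference category first: nnet uses the first response column as base
  Y <- cbind(cells$W[, J + 1L], cells$W[, seq_len(J)])
  fit <- nnet::multinom(stats::as.formula(paste("Y ~", form)), data = df,
                        trace = FALSE, maxit = 300, Hess = TRUE)
  cf <- stats::coef(fit)  # J x (1 + dummies)
  ca <- cbind(0, cf[, grep("^a", colnames(cf)), drop = FALSE])
  out <- list(alpha = unname(cf[, 1] + rowMeans(ca)),
              eta = unname(ca - rowMeans(ca)),
              beta = matrix(0, J, 4), gamma = matrix(0, J, 4))
  if (spec$include_race_education) {
    out$beta[, 2:4] <- cf[, grep("^r", colnames(cf)), drop = FALSE]
    out$gamma[, 2:4] <- cf[, grep("^e", colnames(cf)), drop = FALSE]
  }
  # the asymptotic covariance seeds the fixed-effect proposal shapes so
  # burn-in moves are well-sized and oriented from the start (the
  # intercept/contrast directions are strongly correlated a posteriori)
  V <- tryCatch(stats::vcov(fit), error = function(e) NULL)
  if (!is.null(V)) {
    out$se_alpha <- sqrt(diag(V))[paste0(2:(J + 1), ":(Intercept)")]
    out$vcovA_age <- lapply(seq_len(J), function(j) {
      nm <- paste0(j + 1, ":a", 2:spec$A)
      V[nm, nm]
    })
    if (spec$include_race_education) {
      out$vcovB <- lapply(seq_len(J), function(j) {
        nm <- paste0(j + 1, ":", c("(Intercept)", "r2", "r3", "r4",
                                   "e2", "e3", "e4"))
        V[nm, nm]
      })
    }
  }
  out
}

.init_params <- function(spec, nc, ns, cg, sg, mcmc, chain, cells, mle) {
  # dispersed starting values: chain 1 starts near the subject-level MLE
  # with modest noise, later chains are overdispersed threefold
  disp <- if (chain == 1L) 1 else 3
  scale <- 0.1 * disp
  J <- spec$J
  A <- spec$A
  p <- param_set(J, A, nc, ns)
  if (is.null(mle)) {
    shares <- colSums(cells$W) / sum(cells$wtot)
    mle <- list(alpha = log(shares[seq_len(J)] / shares[[J + 1L]]),
                eta = matrix(0, J, A),
                beta = matrix(0, J, 4), gamma = matrix(0, J, 4))
  }
  p$alpha <- mle$alpha + stats::rnorm(J, 0, scale)
  if (spec$include_race_education) {
    p$beta[, 2:4] <- mle$beta[, 2:4] + stats::rnorm(3 * J, 0, scale)
    p$gamma[, 2:4] <- mle$gamma[, 2:4] + stats::rnorm(3 * J, 0, scale)
  }
  p$eta <- mle$eta + matrix(stats::rnorm(J * A, 0, scale), J, A)
  if (spec$include_county_covariates) {
    p$delta <- matrix(stats::rnorm(5 * J, 0, scale), J, 5)
  }
  if (!mcmc$fix_latent_at_zero) {
    p$sigma2_v <- exp(stats::rnorm(1, log(0.2), 0.5))
    p$sigma2_u <- exp(stats::rnorm(1, log(0.1), 0.5))
    p$v <- sample_icar(cg, p$sigma2_v)
    p$u <- sample_icar(sg, p$sigma2_u)
    p$lambda <- c(1, pmax(0.1, 1 + stats::rnorm(J - 1, 0, 0.3)))
    p$kappa <- c(1, pmax(0.1, 1 + stats::rnorm(J - 1, 0, 0.3)))
  } else {
    p$sigma2_v <- p$sigma2_u <- 1e-6
    p$v <- numeric(nc)
    p$u <- numeric(ns)
    p$lambda <- p$kappa <- c(1, numeric(J - 1))
  }
  p$Sigma_eta <- diag(J) * stats::runif(1, 0.02, 0.2)
  apply_constraints(p)
}

# greedy proper colouring: areas of one colour form an independent set
.graph_coloring <- function(graph) {
  n <- graph$n
  col <- integer(n)
  for (i in order(-graph$degree)) {
    used <- col[graph$nbr[[i]]]
    k <- 1L
    while (k %in% used) k <- k + 1L
    col[[i]] <- k
  }
  col
}

.color_classes <- function(graph, by_area) {
  col <- .graph_coloring(graph)
  lapply(sort(unique(col)), function(k) {
    members <- which(col == k)
    sub <- by_area[members]
    list(members = members,
         rows = unlist(sub, use.names = FALSE),
         grp = rep(seq_along(members), lengths(sub)))
  })
}

# element-wise Metropolis update of a latent ICAR field over colouring
# classes; returns the updated field, the total accepted log-likelihood
# change, and the number of acceptances
.field_update <- function(field, sigma2, scale, classes, deg, L,
                          make_params, cells, spec, Xd) {
  n_acc <- 0L
  dll <- 0
  for (cl in classes) {
    m <- cl$members
    eps <- stats::rnorm(length(m), 0, scale)
    f2 <- field
    f2[m] <- f2[m] + eps
    llo <- numeric(length(m))
    lln <- numeric(length(m))
    if (length(cl$rows)) {
      rs_o <- rowsum(.cells_ll_vec(cells, make_params(field), spec, Xd,
                                   cl$rows), cl$grp)
      rs_n <- rowsum(.cells_ll_vec(cells, make_params(f2), spec, Xd,
                                   cl$rows), cl$grp)
      llo[as.integer(rownames(rs_o))] <- rs_o
      lln[as.integer(rownames(rs_n))] <- rs_n
    }
    # ICAR conditional: quadratic deg*x^2 - 2*x*sum(neighbours); islands
    # get the free Normal(0, sigma2) term instead
    sum_nb <- (deg * field - drop(L %*% field))[m]
    a_coef <- pmax(deg[m], 1L)
    old <- field[m]
    new <- f2[m]
    dpr <- -(a_coef * (new^2 - old^2) - 2 * sum_nb * (new - old)) /
      (2 * sigma2)
    loga <- lln - llo + dpr
    ok <- is.finite(loga) & log(stats::runif(length(m))) < loga
    field[m[ok]] <- new[ok]
    dll <- dll + sum((lln - llo)[ok])
    n_acc <- n_acc + sum(ok)
  }
  list(field = field, dll = dll, n_acc = n_acc)
}

.run_one_chain <- function(cells, counties, cg, sg, spec, mcmc, chain,
                           Xd_fun, latent, layout, n_keep, mle = NULL) {
  set.seed((mcmc$seed %% 20000000L) * 100L + chain * 7L)
  J <- spec$J
  A <- spec$A
  nc <- cg$n
  ns <- sg$n
  n_burn <- mcmc$n_iter - n_keep
  prior_sd <- mcmc$prior_sd

  # initialization with a finite-posterior retry guard
  for (try in 1:20) {
    p <- .init_params(spec, nc, ns, cg, sg, mcmc, chain, cells, mle)
    Xd <- Xd_fun(p)
    ll <- .cells_loglik(cells, p, spec, Xd)
    if (is.finite(ll)) break
    if (try == 20) stop("non-finite posterior at initialization")
  }

  # --- adaptive proposal scales: windowed acceptance tracking, adapted
  # --- during burn-in with a constant gain, frozen afterwards
  # fixed-effect sub-blocks per category: A = intercept + county covariate
  # effects, B = race/education contrasts (two moderate blocks mix better
  # than one large one)
  dimA <- 1L + (if (spec$include_county_covariates) 5L else 0L)
  dimB <- if (spec$include_race_education) 7L else 0L
  blocks <- list()
  for (j in seq_len(J)) {
    blocks[[paste0("thA", j)]] <- list(j = j, type = "A", dim = dimA)
    if (dimB > 0L) {
      blocks[[paste0("thB", j)]] <- list(j = j, type = "B", dim = dimB)
    }
  }
  ls <- c(vapply(blocks, function(b) log(0.1 / sqrt(b$dim)), numeric(1)),
          stats::setNames(rep(log(0.05), J), paste0("eta", 1:J)),
          # (eta scales are re-seeded below when the MLE covariance exists)
          stats::setNames(rep(log(0.1), J), paste0("tilt", 1:J)),
          v = log(0.3), u = log(0.3),
          lambda = log(0.1 / sqrt(J - 1)), kappa = log(0.1 / sqrt(J - 1)),
          sv = log(0.3), swap = log(0.2),
          scv = log(0.3), scu = log(0.3),
          rlv = log(0.2), rku = log(0.2),
          stats::setNames(rep(log(0.1), 5L), paste0("shear", 1:5)))
  targets <- c(thA = 0.25, thB = 0.25, eta = 0.25, tilt = 0.44,
               v = 0.44, u = 0.44,
               lambda = 0.25, kappa = 0.25, sv = 0.44,
               swap = 0.44, scv = 0.44, scu = 0.44,
               rlv = 0.44, rku = 0.44, shear = 0.44)
  scale_group <- sub("[0-9]+$", "", names(ls))
  wacc <- numeric(length(ls))
  wtry <- numeric(length(ls))
  names(wacc) <- names(wtry) <- names(ls)
  bump <- function(key, ok, ntry = 1) {
    wacc[[key]] <<- wacc[[key]] + ok
    wtry[[key]] <<- wtry[[key]] + ntry
  }
  # age-row proposal shape: MLE information blended with the random-walk
  # prior precision, so data-poor tail ages move in smooth correlated
  # patterns instead of being proposed (and rejected) independently
  eta_chol <- rep(list(NULL), J)
  if (!is.null(mle$vcovA_age)) {
    Dm <- diag(A - 1L)
    if (A > 2L) for (i in 2:(A - 1L)) Dm[i, i - 1L] <- -1
    Qrw <- crossprod(Dm)
    for (j in seq_len(J)) {
      V <- mle$vcovA_age[[j]]
      info <- tryCatch(solve(V), error = function(e) NULL)
      if (is.null(info)) next
      qj <- 1 / p$Sigma_eta[j, j]
      eta_chol[[j]] <- tryCatch(chol(solve(info + qj * Qrw)),
                                error = function(e) NULL)
    }
  }
  blk_mean <- lapply(blocks, function(b) numeric(b$dim))
  blk_ss <- lapply(blocks, function(b) matrix(0, b$dim, b$dim))
  blk_chol <- lapply(blocks, function(b) diag(b$dim))
  blk_fixed <- lapply(blocks, function(b) FALSE)
  if (!is.null(mle$se_alpha)) {
    for (bk in names(blocks)) {
      b <- blocks[[bk]]
      if (b$type == "B" && !is.null(mle$vcovB)) {
        ch_try <- tryCatch(chol(mle$vcovB[[b$j]]),
                           error = function(e) NULL)
        if (!is.null(ch_try)) {
          blk_chol[[bk]] <- ch_try
          ls[[bk]] <- log(2.38 / sqrt(b$dim))
          # the MLE shape approximates the conditional well; freeze it and
          # adapt only the scalar scale (the early empirical covariance of
          # a slowly moving chain would be badly underdispersed)
          blk_fixed[[bk]] <- TRUE
        }
      } else if (b$type == "A") {
        if (!is.null(eta_chol[[b$j]])) {
          ls[[paste0("eta", b$j)]] <- log(2.38 / sqrt(spec$A - 1))
        }
        # county covariate effect scales: broad guesses, refined by the
        # empirical covariance once the chain is moving
        sc <- if (b$dim == 6L) {
          c(mle$se_alpha[[b$j]], 0.3, 0.05, 0.1, 0.1, 0.1)
        } else {
          mle$se_alpha[[b$j]]
        }
        blk_chol[[bk]] <- diag(sc, b$dim)
        ls[[bk]] <- log(2.38 / sqrt(b$dim))
      }
    }
  }
  blk_n <- 0L
  lam_mean <- kap_mean <- numeric(J - 1L)
  lam_ss <- kap_ss <- matrix(0, J - 1L, J - 1L)
  lam_chol <- kap_chol <- diag(J - 1L)
  acc <- c(theta = 0, eta = 0, v = 0, u = 0, lambda = 0, kappa = 0,
           sigma = 0, swap = 0)
  try_n <- acc

  # the intercept sits in both sub-blocks so that its strong posterior
  # correlations with either covariate group are captured by the
  # empirical-covariance proposals
  get_blk <- function(p, j, type) {
    if (type == "A") {
      c(p$alpha[[j]],
        if (spec$include_county_covariates) p$delta[j, ])
    } else {
      c(p$alpha[[j]], p$beta[j, 2:4], p$gamma[j, 2:4])
    }
  }
  set_blk <- function(p, j, type, th) {
    p$alpha[[j]] <- th[[1L]]
    if (type == "A") {
      if (spec$include_county_covariates) p$delta[j, ] <- th[-1L]
    } else {
      p$beta[j, 2:4] <- th[2:4]
      p$gamma[j, 2:4] <- th[5:7]
    }
    p
  }

  draws <- matrix(NA_real_, n_keep, length(layout),
                  dimnames = list(NULL, layout))
  deviance <- numeric(n_keep)
  if (latent) {
    classes_v <- .color_classes(cg, cells$by_county)
    classes_u <- .color_classes(sg, cells$by_state)
    # per-state structures for the v/u exchange move
    state_members <- split(seq_len(nc),
                           factor(as.integer(counties$state),
                                  levels = seq_len(ns)))
    ed <- graph_edges(cg)
    st_of <- as.integer(counties$state)
    state_cross <- lapply(seq_len(ns), function(s) {
      ins <- st_of[ed[, 1]] == s
      jns <- st_of[ed[, 2]] == s
      rbind(ed[ins & !jns, c(1, 2), drop = FALSE],
            ed[!ins & jns, c(2, 1), drop = FALSE])  # (inside, outside)
    })
  }

  for (it in seq_len(mcmc$n_iter)) {
    adapting <- it <= n_burn

    # -- fixed-effect sub-blocks per category --
    for (bk in names(blocks)) {
      b <- blocks[[bk]]
      th <- get_blk(p, b$j, b$type)
      eps <- exp(ls[[bk]]) * drop(stats::rnorm(b$dim) %*% blk_chol[[bk]])
      p2 <- set_blk(p, b$j, b$type, th + eps)
      needs_xd <- b$type == "A" && spec$include_county_covariates
      Xd2 <- if (needs_xd) Xd_fun(p2) else Xd
      ll2 <- .cells_loglik(cells, p2, spec, Xd2)
      lpr <- sum(stats::dnorm(th + eps, 0, prior_sd, log = TRUE)) -
        sum(stats::dnorm(th, 0, prior_sd, log = TRUE))
      a <- ll2 - ll + lpr
      ok <- is.finite(a) && log(stats::runif(1)) < a
      if (ok) {
        p <- p2
        Xd <- Xd2
        ll <- ll2
      }
      try_n[["theta"]] <- try_n[["theta"]] + 1
      acc[["theta"]] <- acc[["theta"]] + ok
      bump(bk, ok)
    }
    # empirical-covariance (Haario) bookkeeping for the sub-blocks
    if (adapting) {
      blk_n <- blk_n + 1L
      for (bk in names(blocks)) {
        b <- blocks[[bk]]
        th <- get_blk(p, b$j, b$type)
        d0 <- th - blk_mean[[bk]]
        blk_mean[[bk]] <- blk_mean[[bk]] + d0 / blk_n
        blk_ss[[bk]] <- blk_ss[[bk]] + tcrossprod(d0, th - blk_mean[[bk]])
      }
      if (blk_n >= 100L && it %% mcmc$adapt_window == 0L) {
        for (bk in names(blocks)) {
          if (isTRUE(blk_fixed[[bk]])) next
          b <- blocks[[bk]]
          S <- blk_ss[[bk]] / (blk_n - 1L)
          S <- 2.38^2 / b$dim * S + 1e-8 * diag(b$dim)
          ch_try <- tryCatch(chol(S), error = function(e) NULL)
          if (!is.null(ch_try)) blk_chol[[bk]] <- ch_try
        }
      }
    }

    # -- age-effect rows per category (two passes: these rows mix most
    # -- slowly under the smoothing prior) --
    for (pass_ in 1:2) for (j in seq_len(J)) {
      key <- paste0("eta", j)
      if (!is.null(eta_chol[[j]])) {
        eps <- exp(ls[[key]]) *
          c(0, drop(stats::rnorm(A - 1L) %*% eta_chol[[j]]))
      } else {
        eps <- stats::rnorm(A, 0, exp(ls[[key]]))
      }
      eps <- eps - mean(eps)
      p2 <- p
      p2$eta[j, ] <- p$eta[j, ] + eps
      ll2 <- .cells_loglik(cells, p2, spec, Xd)
      lpr <- .age_rw_logpdf(p2$eta, p$Sigma_eta) -
        .age_rw_logpdf(p$eta, p$Sigma_eta)
      a <- ll2 - ll + lpr
      ok <- is.finite(a) && log(stats::runif(1)) < a
      if (ok) {
        p <- p2
        ll <- ll2
      }
      try_n[["eta"]] <- try_n[["eta"]] + 1
      acc[["eta"]] <- acc[["eta"]] + ok
      bump(key, ok)
    }

    # -- age-profile tilt: a scalar move along the linear-trend direction,
    # -- the smooth principal axis of the random-walk prior along which
    # -- plain row proposals move slowly --
    ramp <- ((seq_len(A)) - (A + 1) / 2) / A
    for (j in seq_len(J)) {
      key <- paste0("tilt", j)
      e <- stats::rnorm(1, 0, exp(ls[[key]]))
      p2 <- p
      p2$eta[j, ] <- p$eta[j, ] + e * ramp
      ll2 <- .cells_loglik(cells, p2, spec, Xd)
      lpr <- .age_rw_logpdf(p2$eta, p$Sigma_eta) -
        .age_rw_logpdf(p$eta, p$Sigma_eta)
      a <- ll2 - ll + lpr
      ok <- is.finite(a) && log(stats::runif(1)) < a
      if (ok) {
        p <- p2
        ll <- ll2
      }
      try_n[["eta"]] <- try_n[["eta"]] + 1
      acc[["eta"]] <- acc[["eta"]] + ok
      bump(key, ok)
    }

    # -- Sigma_eta: conjugate inverse-Wishart Gibbs draw --
    D <- p$eta[, -1, drop = FALSE] - p$eta[, -A, drop = FALSE]
    Spost <- diag(J) + tcrossprod(D)
    W <- stats::rWishart(1L, df = (J + 2) + (A - 1), Sigma = solve(Spost))
    p$Sigma_eta <- solve(W[, , 1L])

    if (latent) {
      # -- county field: Metropolis over graph-colouring classes --
      # areas in one colour class are conditionally independent (the
      # likelihood factorises by area; the ICAR prior couples neighbours
      # only), so a whole class is proposed and accepted element-wise
      res_v <- .field_update(p$v, p$sigma2_v, exp(ls[["v"]]), classes_v,
                             cg$degree, cg$laplacian,
                             function(field) {
                               p2 <- p
                               p2$v <- field
                               p2
                             }, cells, spec, Xd)
      p$v <- res_v$field
      ll <- ll + res_v$dll
      try_n[["v"]] <- try_n[["v"]] + nc
      acc[["v"]] <- acc[["v"]] + res_v$n_acc
      bump("v", res_v$n_acc, nc)

      # -- state field --
      res_u <- .field_update(p$u, p$sigma2_u, exp(ls[["u"]]), classes_u,
                             sg$degree, sg$laplacian,
                             function(field) {
                               p2 <- p
                               p2$u <- field
                               p2
                             }, cells, spec, Xd)
      p$u <- res_u$field
      ll <- ll + res_u$dll
      try_n[["u"]] <- try_n[["u"]] + ns
      acc[["u"]] <- acc[["u"]] + res_u$n_acc
      bump("u", res_u$n_acc, ns)

      # -- v/u exchange: shift a state's county effects against its state
      # -- effect, mixing the soft county/state attribution direction
      if (ns >= 2L) {
        for (s in seq_len(ns)) {
          d <- stats::rnorm(1, 0, exp(ls[["swap"]]))
          mem <- state_members[[s]]
          rows <- cells$by_state[[s]]
          p2 <- p
          p2$v[mem] <- p$v[mem] - d
          p2$u[[s]] <- p$u[[s]] + d
          ll_old <- if (length(rows)) {
            .cells_loglik(cells, p, spec, Xd, rows)
          } else 0
          ll_new <- if (length(rows)) {
            .cells_loglik(cells, p2, spec, Xd, rows)
          } else 0
          # v prior: only edges crossing the state boundary change
          cr <- state_cross[[s]]
          dq_v <- if (nrow(cr)) {
            dv <- p$v[cr[, 1]] - p$v[cr[, 2]]
            sum((dv - d)^2 - dv^2)
          } else 0
          isl <- mem[cg$degree[mem] == 0L]
          dq_v <- dq_v + sum((p$v[isl] - d)^2 - p$v[isl]^2)
          # u prior: single-site change
          nbr_s <- sg$nbr[[s]]
          dq_u <- if (length(nbr_s)) {
            sum((p$u[[s]] + d - p$u[nbr_s])^2 -
                  (p$u[[s]] - p$u[nbr_s])^2)
          } else {
            (p$u[[s]] + d)^2 - p$u[[s]]^2
          }
          a <- ll_new - ll_old - dq_v / (2 * p$sigma2_v) -
            dq_u / (2 * p$sigma2_u)
          ok <- is.finite(a) && log(stats::runif(1)) < a
          if (ok) {
            p <- p2
            ll <- ll + ll_new - ll_old
          }
          try_n[["swap"]] <- try_n[["swap"]] + 1
          acc[["swap"]] <- acc[["swap"]] + ok
          bump("swap", ok)
        }
      }

      # -- loadings: one empirical-covariance block per level --
      for (lv in c("lambda", "kappa")) {
        cur <- if (lv == "lambda") p$lambda[-1] else p$kappa[-1]
        chl <- if (lv == "lambda") lam_chol else kap_chol
        eps <- exp(ls[[lv]]) * drop(stats::rnorm(J - 1L) %*% chl)
        p2 <- p
        if (lv == "lambda") {
          p2$lambda <- c(1, cur + eps)
        } else {
          p2$kappa <- c(1, cur + eps)
        }
        ll2 <- .cells_loglik(cells, p2, spec, Xd)
        lpr <- sum(stats::dnorm(cur + eps, 0, prior_sd, log = TRUE)) -
          sum(stats::dnorm(cur, 0, prior_sd, log = TRUE))
        a <- ll2 - ll + lpr
        ok <- is.finite(a) && log(stats::runif(1)) < a
        if (ok) {
          p <- p2
          ll <- ll2
        }
        try_n[[lv]] <- try_n[[lv]] + 1
        acc[[lv]] <- acc[[lv]] + ok
        bump(lv, ok)
      }
      # loading-block covariance bookkeeping
      if (adapting && blk_n >= 1L) {
        d0 <- p$lambda[-1] - lam_mean
        lam_mean <- lam_mean + d0 / blk_n
        lam_ss <- lam_ss + tcrossprod(d0, p$lambda[-1] - lam_mean)
        d0 <- p$kappa[-1] - kap_mean
        kap_mean <- kap_mean + d0 / blk_n
        kap_ss <- kap_ss + tcrossprod(d0, p$kappa[-1] - kap_mean)
        if (blk_n >= 100L && it %% mcmc$adapt_window == 0L) {
          for (lv in c("lambda", "kappa")) {
            S <- (if (lv == "lambda") lam_ss else kap_ss) / (blk_n - 1L)
            S <- 2.38^2 / (J - 1) * S + 1e-8 * diag(J - 1L)
            ch_try <- tryCatch(chol(S), error = function(e) NULL)
            if (!is.null(ch_try)) {
              if (lv == "lambda") lam_chol <- ch_try else kap_chol <- ch_try
            }
          }
        }
      }

      # -- independence refresh of the state loadings from their prior:
      # -- when the state field is near zero the likelihood barely
      # -- constrains kappa, and a prior draw then mixes the whole block in
      # -- one step (the prior cancels against the proposal density)
      p2 <- p
      p2$kappa <- c(1, stats::rnorm(J - 1L, 0, prior_sd))
      ll2 <- .cells_loglik(cells, p2, spec, Xd)
      a <- ll2 - ll
      ok <- is.finite(a) && log(stats::runif(1)) < a
      if (ok) {
        p <- p2
        ll <- ll2
      }
      try_n[["kappa"]] <- try_n[["kappa"]] + 1
      acc[["kappa"]] <- acc[["kappa"]] + ok

      # -- interweaving rescale of (field, variance): (x, s2) -> (cx, c2 s2)
      # -- traverses the funnel between a latent field and its variance;
      # -- the ICAR kernel is scale-invariant under the joint map and the
      # -- transformation Jacobian cancels its normalisation change, so the
      # -- acceptance reduces to the likelihood and sigma-prior ratios + eps
      for (which_f in c("v", "u")) {
        key <- if (which_f == "v") "scv" else "scu"
        eps <- stats::rnorm(1, 0, exp(ls[[key]]))
        cfac <- exp(eps)
        p2 <- p
        if (which_f == "v") {
          p2$v <- cfac * p$v
          p2$sigma2_v <- cfac^2 * p$sigma2_v
          sg_old <- sqrt(p$sigma2_v)
        } else {
          p2$u <- cfac * p$u
          p2$sigma2_u <- cfac^2 * p$sigma2_u
          sg_old <- sqrt(p$sigma2_u)
        }
        ll2 <- .cells_loglik(cells, p2, spec, Xd)
        a <- ll2 - ll +
          stats::dnorm(cfac * sg_old, 0, 1, log = TRUE) -
          stats::dnorm(sg_old, 0, 1, log = TRUE) + eps
        ok <- is.finite(a) && log(stats::runif(1)) < a
        if (ok) {
          p <- p2
          ll <- ll2
        }
        try_n[["sigma"]] <- try_n[["sigma"]] + 1
        acc[["sigma"]] <- acc[["sigma"]] + ok
        bump(key, ok)
      }

      # -- loading/field interweaving: (x, loadings, s2) ->
      # -- (cx, loadings / c, c2 s2) keeps every product for categories
      # -- 2..J fixed, so the likelihood moves only through the reference
      # -- loading (fixed at 1); this traverses the factor scale ridge.
      # -- Jacobian and kernel terms reduce to (2 - J) eps
      for (which_f in c("v", "u")) {
        key <- if (which_f == "v") "rlv" else "rku"
        eps <- stats::rnorm(1, 0, exp(ls[[key]]))
        cfac <- exp(eps)
        p2 <- p
        if (which_f == "v") {
          p2$v <- cfac * p$v
          p2$lambda <- c(1, p$lambda[-1] / cfac)
          p2$sigma2_v <- cfac^2 * p$sigma2_v
          sg_old <- sqrt(p$sigma2_v)
          dload <- sum(stats::dnorm(p2$lambda[-1], 0, prior_sd,
                                    log = TRUE)) -
            sum(stats::dnorm(p$lambda[-1], 0, prior_sd, log = TRUE))
        } else {
          p2$u <- cfac * p$u
          p2$kappa <- c(1, p$kappa[-1] / cfac)
          p2$sigma2_u <- cfac^2 * p$sigma2_u
          sg_old <- sqrt(p$sigma2_u)
          dload <- sum(stats::dnorm(p2$kappa[-1], 0, prior_sd,
                                    log = TRUE)) -
            sum(stats::dnorm(p$kappa[-1], 0, prior_sd, log = TRUE))
        }
        ll2 <- .cells_loglik(cells, p2, spec, Xd)
        a <- ll2 - ll + dload +
          stats::dnorm(cfac * sg_old, 0, 1, log = TRUE) -
          stats::dnorm(sg_old, 0, 1, log = TRUE) + (2 - J) * eps
        ok <- is.finite(a) && log(stats::runif(1)) < a
        if (ok) {
          p <- p2
          ll <- ll2
        }
        try_n[["sigma"]] <- try_n[["sigma"]] + 1
        acc[["sigma"]] <- acc[["sigma"]] + ok
        bump(key, ok)
      }

      # -- shear along the exact likelihood-invariant direction between a
      # -- county covariate effect and the spatial field:
      # -- v_c -> v_c - e x_kc, delta_jk -> delta_jk + lambda_j e keeps
      # -- every linear predictor fixed, so only the priors decide
      if (spec$include_county_covariates) {
        Xmat <- .county_design(counties)
        edv <- graph_edges(cg)
        for (k in 1:5) {
          key <- paste0("shear", k)
          e <- stats::rnorm(1, 0, exp(ls[[key]]))
          xk <- Xmat[, k]
          dxe <- xk[edv[, 1]] - xk[edv[, 2]]
          dve <- p$v[edv[, 1]] - p$v[edv[, 2]]
          dq <- e^2 * sum(dxe^2) - 2 * e * sum(dve * dxe)
          isl <- which(cg$degree == 0L)
          if (length(isl)) {
            dq <- dq + sum((p$v[isl] - e * xk[isl])^2 - p$v[isl]^2)
          }
          dl2 <- p$delta[, k] + p$lambda * e
          lpr <- sum(stats::dnorm(dl2, 0, prior_sd, log = TRUE)) -
            sum(stats::dnorm(p$delta[, k], 0, prior_sd, log = TRUE))
          a <- -dq / (2 * p$sigma2_v) + lpr
          ok <- is.finite(a) && log(stats::runif(1)) < a
          if (ok) {
            p$v <- p$v - e * xk
            p$delta[, k] <- dl2
            Xd <- Xd_fun(p)
          }
          try_n[["swap"]] <- try_n[["swap"]] + 1
          acc[["swap"]] <- acc[["swap"]] + ok
          bump(key, ok)
        }
      }

      # -- conditional variances, sampled on the log scale --
      # target in z = log sigma2: ICAR kernel + half-Normal(0,1) on sigma
      # + log-Jacobian log(sigma / 2)
      lp_sig <- function(x, graph, sigma2) {
        icar_logpdf_kernel(x, graph, sigma2) +
          stats::dnorm(sqrt(sigma2), 0, 1, log = TRUE) + log(2) +
          log(sqrt(sigma2) / 2)
      }
      z <- log(p$sigma2_v)
      z2 <- z + stats::rnorm(1, 0, exp(ls[["sv"]]))
      a <- lp_sig(p$v, cg, exp(z2)) - lp_sig(p$v, cg, exp(z))
      ok <- is.finite(a) && log(stats::runif(1)) < a
      if (ok) p$sigma2_v <- exp(z2)
      try_n[["sigma"]] <- try_n[["sigma"]] + 1
      acc[["sigma"]] <- acc[["sigma"]] + ok
      bump("sv", ok)

      # sigma2_u is moved only jointly with u (the interweaving rescale
      # above): with few states the centered kernel-only update would be
      # drawn into the degenerate sigma2 -> 0 corner and trap the chain

      # -- re-center latent fields, compensating through the intercepts --
      mv <- mean(p$v)
      p$v <- p$v - mv
      p$alpha <- p$alpha + p$lambda * mv
      mu_ <- mean(p$u)
      p$u <- p$u - mu_
      p$alpha <- p$alpha + p$kappa * mu_
    }

    # -- re-center age effects, compensating through the intercepts --
    me <- rowMeans(p$eta)
    p$eta <- p$eta - me
    p$alpha <- p$alpha + me

    # -- windowed scale adaptation --
    if (adapting && it %% mcmc$adapt_window == 0L) {
      have <- wtry > 0
      rate <- wacc[have] / wtry[have]
      tgt <- targets[scale_group[have]]
      ls[have] <- ls[have] + pmax(-0.6, pmin(0.6, 0.7 * (rate - tgt)))
      wacc[] <- 0
      wtry[] <- 0
    }

    if (it > n_burn) {
      k <- it - n_burn
      draws[k, ] <- .pack_params(p, spec, latent)
      deviance[[k]] <- -2 * ll
    }
  }
  list(draws = draws, deviance = deviance,
       accept = acc / pmax(1, try_n))
}
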