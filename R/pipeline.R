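#' Run configuration for the full pipeline
#'
#' Bundles the file paths, model selectors and sampler settings consumed by
#' \code{\link{run_pipeline}}. Flat key-value serialisation is provided by
#' \code{\link{read_run_config}} / \code{\link{write_run_config}}.
#'
#' @param respondent_file,county_file,county_adj_file,state_adj_file input
#'   paths (delimited tables and GAL neighbour lists)
#' @param models integer vector of model selectors (subset of 1:3)
#' @param out_dir output directory (created if absent)
#' @param n_chains,n_iter,burn_frac,seed sampler settings
#' @param normalize_weights rescale survey weights to mean 1
#' @return list of class \code{jp_run_config}
#' @export
run_config <- function(respondent_file, county_file, county_adj_file,
                       state_adj_file, models = 1:3, out_dir = "results",
                       n_chains = 2L, n_iter = 2000L, burn_frac = 0.5,
                       seed = 1L, normalize_weights = TRUE) {
  models <- as.integer(models)
  if (!all(models %in% 1:3)) stop("model selectors must be in 1..3")
  structure(list(respondent_file = respondent_file,
                 county_file = county_file,
                 county_adj_file = county_adj_file,
                 state_adj_file = state_adj_file,
                 models = models, out_dir = out_dir,
                 n_chains = as.integer(n_chains),
                 n_iter = as.integer(n_iter), burn_frac = burn_frac,
                 seed = as.integer(seed),
                 normalize_weights = isTRUE(normalize_weights)),
            class = "jp_run_config")
}

#' @rdname run_config
#' @param path path of a flat \code{key = value} config file
#' @export
read_run_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) stop("malformed config line: ", lines[which(bad)[1L]])
  vals <- stats::setNames(vapply(kv, `[[`, "", 2L),
                          vapply(kv, `[[`, "", 1L))
  need <- c("respondent_file", "county_file", "county_adj_file",
            "state_adj_file")
  miss <- setdiff(need, names(vals))
  if (length(miss)) stop("config missing key(s): ",
                         paste(miss, collapse = ", "))
  # environment-variable overrides, for paths only
  for (k in need) {
    ev <- Sys.getenv(paste0("JOINTPREV_", toupper(k)), "")
    if (nzchar(ev)) vals[[k]] <- ev
  }
  gv <- function(k, default) if (k %in% names(vals)) vals[[k]] else default
  run_config(vals[["respondent_file"]], vals[["county_file"]],
             vals[["county_adj_file"]], vals[["state_adj_file"]],
             models = as.integer(strsplit(gv("models", "1 2 3"),
                                          "[ ,]+")[[1]]),
             out_dir = gv("out_dir", "results"),
             n_chains = as.integer(gv("n_chains", "2")),
             n_iter = as.integer(gv("n_iter", "2000")),
             burn_frac = as.numeric(gv("burn_frac", "0.5")),
             seed = as.integer(gv("seed", "1")),
             normalize_weights = gv("normalize_weights", "true") %in%
               c("true", "TRUE", "1", "yes"))
}

#' @rdname run_config
#' @param config a \code{jp_run_config} to serialise
#' @export
write_run_config <- function(config, path) {
  stopifnot(inherits(config, "jp_run_config"))
  fmt <- function(v) {
    if (is.logical(v)) tolower(as.character(v)) else
      paste(as.character(v), collapse = " ")
  }
  writeLines(paste(names(config), vapply(config, fmt, ""), sep = " = "),
             path)
  invisible(path)
}

.log_msg <- function(...) {
  message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

#' Fit and post-process the incremental model sequence
#'
#' Orchestrates the full analysis: reads the respondent and county tables
#' and the two GAL adjacency files, fits each requested model by MCMC,
#' and writes per-model posterior summary tables, convergence reports,
#' age-standardised county prevalence tables, and a model comparison table
#' in the reference layout (Average Deviance | Effective Parameters | DIC |
#' Variance Spatial Effects). Seeds and the package version are logged to a
#' manifest so a run can be reproduced bit for bit.
#'
#' @param config a \code{jp_run_config} (or the path of its key-value file)
#' @return invisibly, a list with the fits, DIC table and output paths
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "jp_run_config"))
  for (f in c(config$respondent_file, config$county_file,
              config$county_adj_file, config$state_adj_file)) {
    if (!file.exists(f)) stop("input file does not exist: ", f)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  .log_msg("reading inputs")
  counties <- read_counties(config$county_file)
  respondents <- read_respondents(config$respondent_file, counties)
  geography <- list(county_graph = read_adjacency_gal(config$county_adj_file),
                    state_graph = read_adjacency_gal(config$state_adj_file))
  fits <- list()
  comp <- NULL
  outputs <- character(0)
  for (m in config$models) {
    spec <- model_spec(m)
    .log_msg("fitting model ", m, " (", config$n_chains, " chains x ",
             config$n_iter, " iterations)")
    fit <- run_mcmc(respondents, counties, geography, spec,
                    mcmc_config(n_chains = config$n_chains,
                                n_iter = config$n_iter,
                                burn_frac = config$burn_frac,
                                seed = config$seed + m,
                                normalize_weights =
                                  config$normalize_weights))
    fits[[paste0("model", m)]] <- fit
    sm <- fit_summary(fit)
    f_sum <- file.path(config$out_dir, paste0("summary_model", m, ".csv"))
    utils::write.csv(sm, f_sum, row.names = FALSE)
    dic <- compute_dic(fit, respondents, counties)
    mv <- marginal_latent_variance(fit, respondents, counties)
    comp <- rbind(comp, data.frame(
      model = m, avg_deviance = dic$Dbar, effective_parameters = dic$pD,
      DIC = dic$DIC, variance_spatial_effects = mv))
    prev <- standardized_prevalence(fit, counties)
    f_prev <- file.path(config$out_dir, paste0("prevalence_model", m,
                                               ".csv"))
    utils::write.csv(
      data.frame(county = seq_len(nrow(counties)),
                 stats::setNames(as.data.frame(prev$p),
                                 paste0("p", seq_len(ncol(prev$p))))),
      f_prev, row.names = FALSE)
    psrf <- if (config$n_chains >= 2L) {
      gelman_rubin(fit)[reported_parameters(fit)]
    } else NA_real_
    f_diag <- file.path(config$out_dir, paste0("diagnostics_model", m,
                                               ".txt"))
    writeLines(c(
      paste0("model ", m, ": ", config$n_chains, " chains x ",
             config$n_iter, " iterations, burn-in fraction ",
             config$burn_frac),
      paste0("max PSRF (reported parameters): ",
             format(max(psrf), digits = 4)),
      paste0("acceptance rates: ",
             paste(names(fit$accept[[1]]),
                   round(colMeans(do.call(rbind, fit$accept)), 3),
                   sep = "=", collapse = " "))), f_diag)
    outputs <- c(outputs, f_sum, f_prev, f_diag)
  }
  f_comp <- file.path(config$out_dir, "dic_comparison.csv")
  utils::write.csv(comp, f_comp, row.names = FALSE)
  f_man <- file.path(config$out_dir, "manifest.txt")
  writeLines(c(
    paste0("jointprev version: ",
           as.character(utils::packageVersion("jointprev"))),
    paste0("seed: ", config$seed),
    paste0("models: ", paste(config$models, collapse = " ")),
    paste0("inputs: ", paste(c(config$respondent_file, config$county_file,
                               config$county_adj_file,
                               config$state_adj_file), collapse = " ")),
    paste0("outputs: ", paste(basename(c(outputs, f_comp)),
                              collapse = " "))), f_man)
  .log_msg("pipeline complete: ", config$out_dir)
  invisible(list(fits = fits, comparison = comp,
                 outputs = c(outputs, f_comp, f_man)))
}
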