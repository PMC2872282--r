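#' Model specification for the incremental modelling strategy
#'
#' The three nested models share the multinomial logit core and the shared
#' latent county/state factors, and differ in which predictor blocks enter
#' the linear predictor:
#' \describe{
#'   \item{model 1}{age effects + latent county/state factors only (the
#'     baseline, age-adjusted model)}
#'   \item{model 2}{model 1 + the five known county covariates}
#'   \item{model 3}{model 2 + subject-level race and education}
#' }
#'
#' @param model integer 1, 2 or 3
#' @param J number of non-reference outcome categories (default 5; the
#'   reference is the non-morbid category J + 1 = 6)
#' @param A number of age groups (default 12)
#' @return an object of class \code{jp_spec}
#' @export
model_spec <- function(model = 3L, J = 5L, A = 12L) {
  model <- as.integer(model)
  if (!model %in% 1:3) stop("'model' must be 1, 2 or 3")
  structure(list(model = model,
                 include_race_education = model == 3L,
                 include_county_covariates = model >= 2L,
                 J = as.integer(J), A = as.integer(A),
                 n_race = 4L, n_edu = 4L, n_x = 5L),
            class = "jp_spec")
}

#' @export
print.jp_spec <- function(x, ...) {
  cat("jp_spec: model", x$model,
      "(race/education:", x$include_race_education,
      "| county covariates:", x$include_county_covariates, ")",
      "J =", x$J, "A =", x$A, "\n")
  invisible(x)
}

.resp_cols <- c("id", "age_group", "race", "education", "county",
                "weight", "category")
.county_cols <- c("county", "state", "poverty", "log_density",
                  "top_black", "top_hisp", "top_other")

#' Validate a respondent table
#'
#' Checks the schema and code ranges of a survey respondent table: age group
#' in 1..A, race and education in 1..4, outcome category in 1..J+1 (the last
#' category being the non-morbid reference), positive survey weights, and
#' county indices resolving to the county table when one is supplied.
#' Errors name the offending row.
#'
#' @param respondents data.frame with columns
#'   \code{id, age_group, race, education, county, weight, category}
#' @param counties optional county table used to check county resolution
#' @param spec a \code{jp_spec} giving the valid code ranges
#' @return the validated data.frame, invisibly coerced to integer codes
#' @export
validate_respondents <- function(respondents, counties = NULL,
                                 spec = model_spec(3L)) {
  miss <- setdiff(.resp_cols, names(respondents))
  if (length(miss)) stop("respondent table missing column(s): ",
                         paste(miss, collapse = ", "))
  r <- respondents
  .check_codes <- function(x, lo, hi, col) {
    x <- as.integer(x)
    bad <- which(is.na(x) | x < lo | x > hi)
    if (length(bad)) {
      stop("respondent row ", bad[[1L]], ": '", col, "' = ",
           respondents[[col]][bad[[1L]]], " outside ", lo, "..", hi)
    }
    x
  }
  r$age_group <- .check_codes(r$age_group, 1L, spec$A, "age_group")
  r$race <- .check_codes(r$race, 1L, spec$n_race, "race")
  r$education <- .check_codes(r$education, 1L, spec$n_edu, "education")
  r$category <- .check_codes(r$category, 1L, spec$J + 1L, "category")
  nc <- if (is.null(counties)) max(r$county) else nrow(counties)
  r$county <- .check_codes(r$county, 1L, nc, "county")
  bad_w <- which(!is.finite(r$weight) | r$weight <= 0)
  if (length(bad_w)) {
    stop("respondent row ", bad_w[[1L]], ": 'weight' must be positive")
  }
  invisible(r)
}

#' Validate a county table
#'
#' Checks that counties are listed once in index order, each belongs to one
#' state, the poverty rate is a proportion in [0, 1] and the three top-decile
#' race-composition indicators are binary.
#'
#' @param counties data.frame with columns
#'   \code{county, state, poverty, log_density, top_black, top_hisp, top_other}
#' @return the validated data.frame, invisibly
#' @export
validate_counties <- function(counties) {
  miss <- setdiff(.county_cols, names(counties))
  if (length(miss)) stop("county table missing column(s): ",
                         paste(miss, collapse = ", "))
  x <- counties
  if (!identical(as.integer(x$county), seq_len(nrow(x)))) {
    stop("county table must list counties 1..n in order")
  }
  if (any(!is.finite(x$state) | x$state < 1)) stop("invalid state index")
  bad <- which(!is.finite(x$poverty) | x$poverty < 0 | x$poverty > 1)
  if (length(bad)) stop("county row ", bad[[1L]],
                        ": poverty must be a proportion in [0, 1]")
  if (any(!is.finite(x$log_density))) stop("non-finite log_density")
  for (col in c("top_black", "top_hisp", "top_other")) {
    if (!all(x[[col]] %in% c(0, 1))) stop("'", col, "' must be binary 0/1")
  }
  invisible(x)
}

#' Read / write respondent and county tables
#'
#' Plain comma-delimited text with a fixed header; the writers and readers
#' round-trip exactly for integer codes and at full double precision for
#' weights and covariates.
#'
#' @param path file path
#' @param counties,spec passed to the validators
#' @return a validated data.frame
#' @export
read_respondents <- function(path, counties = NULL, spec = model_spec(3L)) {
  r <- utils::read.csv(path, colClasses = c(
    id = "integer", age_group = "integer", race = "integer",
    education = "integer", county = "integer", weight = "numeric",
    category = "integer"))
  validate_respondents(r, counties, spec)
  r
}

#' @rdname read_respondents
#' @param respondents respondent table to write
#' @export
write_respondents <- function(respondents, path) {
  utils::write.csv(respondents[, .resp_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname read_respondents
#' @export
read_counties <- function(path) {
  x <- utils::read.csv(path)
  validate_counties(x)
  x
}

#' @rdname read_respondents
#' @export
write_counties <- function(counties, path) {
  utils::write.csv(counties[, .county_cols], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Flag counties in the top decile of a composition measure
#'
#' Codes 1 exactly for the counties whose value strictly exceeds the
#' empirical 90th percentile, defined as the order statistic at position
#' \code{ceiling(0.9 n)}. With n distinct values exactly \code{floor(n/10)}
#' counties are flagged (311 of the 3,110 continental US counties); ties at
#' the threshold are coded 0, so a constant vector yields all zeros.
#'
#' @param values numeric vector, one proportion per county
#' @return integer 0/1 vector of the same length
#' @export
top_decile_indicator <- function(values) {
  if (length(values) == 0L) stop("empty input to top_decile_indicator")
  if (any(!is.finite(values))) stop("non-finite values")
  thr <- sort(values)[ceiling(0.9 * length(values))]
  as.integer(values > thr)
}
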