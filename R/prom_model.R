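#' Post-operative PROM score regression
#'
#' The post-operative patient-reported outcome measure (PROM) score is
#' modelled as a linear function of the pre-operative score, age, age
#' squared, and any further covariates:
#' \deqn{PROM_{post} = \beta_0 PROM_{pre} + \beta_1 Age + \beta_2 Age^2
#'   + \sum_k \beta_k x_k (+ intercept),}
#' fitted by ordinary least squares (minimum mean squared error). The
#' predicted score is reported as an integer, rounded half-up and clamped
#' to the instrument's range (default 0-48, the Oxford Hip/Knee Score
#' scale). An intercept is included by default; set `intercept = FALSE`
#' for the strictly interceptless reading of the regression.
#'
#' @name prom_model
NULL

#' Construct a PROM model from known coefficients
#'
#' @param coefficients named numeric vector; names must match the design
#'   columns produced by [prom_design()]: `prom_pre`, `age`, `age2`, any
#'   extra covariates, and `(Intercept)` when `intercept = TRUE`.
#' @param covariates character vector of extra covariate names beyond
#'   pre-op PROM and age (default none).
#' @param intercept logical; whether the model carries an intercept term.
#' @param score_range inclusive integer bounds of the PROM instrument.
#' @return An object of class `prom_model`.
#' @export
prom_model <- function(coefficients, covariates = character(0),
                       intercept = TRUE, score_range = c(0L, 48L)) {
  covariates <- as.character(covariates)
  expected <- prom_term_names(covariates, intercept)
  coefficients <- as.numeric(coefficients) |>
    stats::setNames(names(coefficients) %||% expected)
  if (!identical(sort(names(coefficients)), sort(expected)))
    stop("coefficient names must be exactly {",
         paste(expected, collapse = ", "), "}", call. = FALSE)
  if (any(!is.finite(coefficients)))
    stop("PROM coefficients must be finite", call. = FALSE)
  score_range <- as.integer(score_range)
  if (length(score_range) != 2L || score_range[1L] >= score_range[2L])
    stop("`score_range` must be two increasing integers", call. = FALSE)
  structure(list(coefficients = coefficients[expected],
                 covariates = covariates, intercept = intercept,
                 score_range = score_range),
            class = "prom_model")
}

prom_term_names <- function(covariates, intercept) {
  c(if (intercept) "(Intercept)", "prom_pre", "age", "age2", covariates)
}

#' @export
print.prom_model <- function(x, ...) {
  cat(sprintf("<prom_model> score range [%d, %d]%s\n",
              x$score_range[1L], x$score_range[2L],
              if (x$intercept) "" else ", no intercept"))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' Build the PROM design row(s) for patient records
#'
#' Produces the ordered design matrix (intercept, pre-op PROM, age, age^2,
#' extra covariates) matching the model's coefficient order.
#'
#' @param records data frame with columns `prom_pre`, `age`, and every
#'   extra covariate the model names.
#' @param model a [prom_model()] (or a list with `covariates` and
#'   `intercept` fields).
#' @return Numeric matrix with one row per record.
#' @export
prom_design <- function(records, model) {
  stopifnot(is.data.frame(records))
  needed <- c("prom_pre", "age", model$covariates)
  missing <- setdiff(needed, names(records))
  if (length(missing))
    stop("record is missing required field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  cols <- lapply(needed, function(nm) as.numeric(records[[nm]]))
  names(cols) <- needed
  bad <- names(cols)[vapply(cols, function(v) any(!is.finite(v)), logical(1))]
  if (length(bad))
    stop("non-finite value in field(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  X <- cbind(prom_pre = cols$prom_pre, age = cols$age, age2 = cols$age^2)
  for (nm in model$covariates) X <- cbind(X, cols[[nm]])
  colnames(X) <- c("prom_pre", "age", "age2", model$covariates)
  if (isTRUE(model$intercept)) X <- cbind(`(Intercept)` = 1, X)
  X
}

#' Fit the PROM regression by ordinary least squares
#'
#' @param data data frame with the observed post-operative score in
#'   `prom_post` plus the design fields (`prom_pre`, `age`, extras).
#' @param covariates extra covariate column names beyond pre-op PROM/age.
#' @param intercept include an intercept (default `TRUE`).
#' @param score_range PROM instrument bounds for prediction clamping.
#' @return A fitted [prom_model()] with `sigma` (residual SD) and `n`
#'   attached in a `fit` element.
#' @export
fit_prom <- function(data, covariates = character(0), intercept = TRUE,
                     score_range = c(0L, 48L)) {
  stopifnot(is.data.frame(data))
  if (!"prom_post" %in% names(data))
    stop("`data` must contain the observed post-operative score `prom_post`",
         call. = FALSE)
  skeleton <- list(covariates = as.character(covariates), intercept = intercept)
  X <- prom_design(data, skeleton)
  y <- as.numeric(data$prom_post)
  if (nrow(X) < ncol(X) + 1L)
    stop("too few rows to fit: need at least ", ncol(X) + 1L, call. = FALSE)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1L):ncol(X)]]
    stop("rank-deficient PROM design; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  fit <- stats::lm.fit(X, y)
  model <- prom_model(stats::setNames(fit$coefficients, colnames(X)),
                      covariates = covariates, intercept = intercept,
                      score_range = score_range)
  rss <- sum(fit$residuals^2)
  model$fit <- list(n = length(y),
                    sigma = sqrt(rss / (length(y) - ncol(X))),
                    r_squared = 1 - rss / sum((y - mean(y))^2))
  model
}

round_half_up <- function(x) floor(x + 0.5)

#' Predict the post-operative PROM score
#'
#' Linear prediction, rounded half-up to the nearest integer and clamped
#' to the model's score range.
#'
#' @param model a [prom_model()].
#' @param records data frame of patient records (see [prom_design()]).
#' @param raw if `TRUE`, return the unrounded linear prediction.
#' @return Integer score(s), or numeric when `raw = TRUE`.
#' @export
predict_prom <- function(model, records, raw = FALSE) {
  stopifnot(inherits(model, "prom_model"))
  X <- prom_design(records, model)
  pred <- drop(X %*% model$coefficients[colnames(X)])
  if (raw) return(pred)
  as.integer(pmin(pmax(round_half_up(pred), model$score_range[1L]),
                  model$score_range[2L]))
}
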