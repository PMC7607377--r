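#' Repeated k-fold cross-validation and performance metrics
#'
#' Models are validated with repeated k-fold cross-validation (default 50
#' repetitions of 5 folds): in each repetition the data are randomly
#' partitioned into k subsets, the model is fitted on each combination of
#' k-1 subsets and scored on the held-out subset, and the repetition's
#' value for each metric is the average over the k folds. The overall
#' estimate is the mean across repetitions with a 95% confidence interval
#' from the normal approximation across repetition means (a percentile
#' bootstrap is available as an option).
#'
#' @name validation
NULL

# Run code under a seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Random k-fold partition of record indices
#'
#' Disjoint, exhaustive folds with sizes differing by at most one;
#' reproducible under `seed`.
#'
#' @param n number of records (>= k).
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return List of k integer index vectors.
#' @export
kfold_partition <- function(n, k = 5L, seed = 1L) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) stop("`k` must be at least 2", call. = FALSE)
  if (n < k) stop(sprintf("cannot split %d record(s) into %d folds", n, k),
                  call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold_of <- rep_len(seq_len(k), n)
  unname(split(perm, fold_of))
}

#' Repeated k-fold cross-validation
#'
#' @param data data frame of records.
#' @param fit_fn function(train_data) -> fitted model.
#' @param metric_fns named list of functions(model, test_data) -> scalar.
#' @param repetitions number of repetitions (default 50).
#' @param k folds per repetition (default 5).
#' @param seed integer seed; repetition r uses derived seed `seed + r`.
#' @return List of `cv_result` objects, one per metric: each has
#'   `metric_name`, `per_repetition_values`, `overall_mean`, `ci_low`,
#'   `ci_high`, `ci_method`, and `failed_repetitions`.
#' @export
repeated_cv <- function(data, fit_fn, metric_fns, repetitions = 50L, k = 5L,
                        seed = 1L, ci_method = c("normal", "bootstrap")) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.data.frame(data), is.function(fit_fn),
            is.list(metric_fns), length(metric_fns) > 0,
            !is.null(names(metric_fns)))
  n <- nrow(data)
  rep_values <- matrix(NA_real_, nrow = repetitions, ncol = length(metric_fns),
                       dimnames = list(NULL, names(metric_fns)))
  failed <- 0L
  for (r in seq_len(repetitions)) {
    folds <- kfold_partition(n, k, seed = seed + r)
    fold_vals <- matrix(NA_real_, nrow = k, ncol = length(metric_fns))
    ok <- TRUE
    for (f in seq_len(k)) {
      test_idx <- folds[[f]]
      res <- tryCatch({
        model <- fit_fn(data[-test_idx, , drop = FALSE])
        vapply(metric_fns, function(mf)
          mf(model, data[test_idx, , drop = FALSE]), numeric(1))
      }, error = function(e) e)
      if (inherits(res, "error")) { ok <- FALSE; break }
      fold_vals[f, ] <- res
    }
    if (ok) rep_values[r, ] <- colMeans(fold_vals) else failed <- failed + 1L
  }
  if (failed > 0.2 * repetitions)
    stop(sprintf("repeated_cv aborted: %d of %d repetitions failed",
                 failed, repetitions), call. = FALSE)

  lapply(stats::setNames(names(metric_fns), names(metric_fns)), function(nm) {
    vals <- rep_values[, nm]
    vals <- vals[!is.na(vals)]
    mu <- mean(vals)
    if (ci_method == "normal") {
      se <- stats::sd(vals) / sqrt(length(vals))
      if (!is.finite(se)) se <- 0
      ci <- mu + c(-1, 1) * 1.96 * se
    } else {
      boots <- with_seed(seed, vapply(seq_len(2000L), function(i)
        mean(sample(vals, replace = TRUE)), numeric(1)))
      ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
    }
    structure(list(metric_name = nm, per_repetition_values = vals,
                   overall_mean = mu,
                   ci_low = min(ci[1], mu), ci_high = max(ci[2], mu),
                   ci_method = ci_method, failed_repetitions = failed),
              class = "cv_result")
  })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s: %.5g (95%% CI %.5g to %.5g; %d repetition(s)%s)\n",
              x$metric_name, x$overall_mean, x$ci_low, x$ci_high,
              length(x$per_repetition_values),
              if (x$failed_repetitions)
                sprintf(", %d failed", x$failed_repetitions) else ""))
  invisible(x)
}

# ---- metric suite ---------------------------------------------------------

#' Root-mean-square error for PROM predictions
#'
#' @param predictions,truths numeric vectors of equal length.
#' @return Scalar RMSE.
#' @export
prom_rmse <- function(predictions, truths) {
  stopifnot(length(predictions) == length(truths))
  sqrt(mean((as.numeric(predictions) - as.numeric(truths))^2))
}

#' Harrell concordance index
#'
#' Probability that a randomly chosen usable pair is correctly
#' risk-ordered. A pair (i, j) is usable when the earlier time is an event
#' and the times differ; concordant when the earlier-event subject has the
#' higher risk score; ties in score count 0.5.
#'
#' @param risk_scores numeric vector (higher = higher predicted risk).
#' @param times event/censoring times.
#' @param events 0/1 event indicators.
#' @return Concordance in \[0, 1\].
#' @export
concordance_index <- function(risk_scores, times, events) {
  risk_scores <- as.numeric(risk_scores)
  times <- as.numeric(times)
  events <- as.numeric(events)
  n <- length(times)
  stopifnot(length(risk_scores) == n, length(events) == n)
  num <- 0; den <- 0
  for (i in which(events == 1)) {
    usable <- times > times[i]
    den <- den + sum(usable)
    num <- num + sum(risk_scores[i] > risk_scores[usable]) +
      0.5 * sum(risk_scores[i] == risk_scores[usable])
  }
  if (den == 0)
    stop("concordance undefined: no usable pairs", call. = FALSE)
  num / den
}

#' Fixed-time Brier score
#'
#' Mean squared difference between the predicted event risk by a horizon
#' and the observed outcome at that horizon. Records censored before the
#' horizon without an event have unknown status and are excluded.
#'
#' @param predicted_risk predicted event probabilities by `horizon`.
#' @param times follow-up times.
#' @param events 0/1 event indicators.
#' @param horizon evaluation time.
#' @return Scalar Brier score.
#' @export
brier_score <- function(predicted_risk, times, events, horizon) {
  predicted_risk <- as.numeric(predicted_risk)
  had_event <- events == 1 & times <= horizon
  known <- had_event | times >= horizon
  if (!any(known))
    stop("brier score undefined: no record with known status at the horizon",
         call. = FALSE)
  mean((predicted_risk[known] - as.numeric(had_event[known]))^2)
}

#' Cross-validate a survival model specification
#'
#' Convenience wrapper around [repeated_cv()] for [fit_flexph()]: fits on
#' the training folds (knots re-derived per fold, so no information leaks
#' from held-out events) and scores held-out concordance and fixed-time
#' Brier score.
#'
#' @param data survival data frame (`time`, `event`, covariates).
#' @param covariates covariate column names for the fit.
#' @param m internal knot count.
#' @param horizon Brier-score horizon in years (default 5).
#' @inheritParams repeated_cv
#' @return List of `cv_result` objects (`concordance`, `brier`).
#' @export
cv_flexph <- function(data, covariates, m = 0L, repetitions = 50L, k = 5L,
                      seed = 1L, horizon = 5) {
  repeated_cv(
    data,
    fit_fn = function(train) fit_flexph(train, covariates, m = m),
    metric_fns = list(
      concordance = function(model, test) {
        lp <- linear_predictor(model, as.matrix(test[covariates]))
        concordance_index(lp, test$time, test$event)
      },
      brier = function(model, test) {
        risk <- event_probability(model, as.matrix(test[covariates]), horizon)
        brier_score(risk, test$time, test$event, horizon)
      }),
    repetitions = repetitions, k = k, seed = seed)
}

#' Cross-validate the PROM regression
#'
#' Held-out RMSE of the integer score prediction under [repeated_cv()].
#'
#' @inheritParams cv_flexph
#' @param covariates extra PROM covariates (see [fit_prom()]).
#' @param intercept,score_range passed to [fit_prom()].
#' @return List with the `rmse` `cv_result`.
#' @export
cv_prom <- function(data, covariates = character(0), intercept = TRUE,
                    score_range = c(0L, 48L), repetitions = 50L, k = 5L,
                    seed = 1L) {
  repeated_cv(
    data,
    fit_fn = function(train) fit_prom(train, covariates, intercept,
                                      score_range),
    metric_fns = list(
      rmse = function(model, test)
        prom_rmse(predict_prom(model, test, raw = TRUE), test$prom_post)),
    repetitions = repetitions, k = k, seed = seed)
}

#' Export cross-validation results as JSON
#'
#' @param results list of `cv_result` objects (as returned by
#'   [repeated_cv()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_cv_report <- function(results, path) {
  payload <- lapply(results, function(r)
    list(metric = r$metric_name, overall_mean = r$overall_mean,
         ci_low = r$ci_low, ci_high = r$ci_high, ci_method = r$ci_method,
         repetitions = length(r$per_repetition_values),
         failed_repetitions = r$failed_repetitions,
         per_repetition_values = r$per_repetition_values))
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}
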