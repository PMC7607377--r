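#' Model registry and personalised calculation pipeline
#'
#' A model bundle packages the three fitted models used for one surgery
#' group: the PROM regression, the mortality survival model, and the
#' revision survival model, keyed by (surgery_group, model_type,
#' dataset_version). `model_type` distinguishes "community" bundles, whose
#' covariates a patient can supply alone, from "clinic" bundles that
#' additionally require surgical-choice inputs entered with professional
#' assistance. Bundles are serialised as human-auditable JSON so every
#' coefficient in a clinical tool can be inspected.
#'
#' [calculate()] runs the end-to-end personalised calculation: select the
#' bundle, validate the request against the same rules as the cohort
#' filters, predict the post-operative PROM score, and evaluate the
#' mortality and revision cumulative hazards year by year, converting each
#' to a probability via 1 - exp(-Lambda). Headline figures are mortality
#' risk within one year and revision risk within ten years.
#'
#' @name calculator
NULL

surgery_groups <- c("hip", "total_knee", "patellofemoral", "unicompartmental")
model_types <- c("community", "clinic")
BUNDLE_FORMAT_VERSION <- 1L

#' Assemble a model bundle
#'
#' @param surgery_group one of hip, total_knee, patellofemoral,
#'   unicompartmental.
#' @param model_type `"community"` or `"clinic"`.
#' @param dataset_version identifier string; versions are ordered by
#'   natural sort so the registry can resolve "latest".
#' @param prom a [prom_model()].
#' @param mortality,revision [flexph_model()] objects.
#' @param required_fields fields a request must supply (defaults to the
#'   union of the three models' covariates plus the core biometrics).
#' @return An object of class `model_bundle`.
#' @export
model_bundle <- function(surgery_group, model_type, dataset_version,
                         prom, mortality, revision, required_fields = NULL) {
  surgery_group <- match.arg(surgery_group, surgery_groups)
  model_type <- match.arg(model_type, model_types)
  stopifnot(inherits(prom, "prom_model"), inherits(mortality, "flexph"),
            inherits(revision, "flexph"))
  surv_covs <- union(mortality$covariate_names %||% character(0),
                     revision$covariate_names %||% character(0))
  schema <- union(c("prom_pre", "age", prom$covariates), surv_covs)
  if (is.null(required_fields))
    required_fields <- union(c("age", "sex", "bmi", "asa"),
                             setdiff(schema, c("age2")))
  structure(list(surgery_group = surgery_group, model_type = model_type,
                 dataset_version = as.character(dataset_version),
                 prom = prom, mortality = mortality, revision = revision,
                 covariate_schema = schema,
                 required_fields = required_fields,
                 format_version = BUNDLE_FORMAT_VERSION),
            class = "model_bundle")
}

#' @export
print.model_bundle <- function(x, ...) {
  cat(sprintf("<model_bundle> %s / %s / %s\n",
              x$surgery_group, x$model_type, x$dataset_version))
  cat("  covariate schema:", paste(x$covariate_schema, collapse = ", "), "\n")
  invisible(x)
}

bundle_key <- function(b)
  paste(b$surgery_group, b$model_type, b$dataset_version, sep = "/")

#' Build a registry from a list of bundles
#'
#' @param bundles list of [model_bundle()] objects.
#' @return An object of class `bundle_registry`.
#' @export
bundle_registry <- function(bundles = list()) {
  stopifnot(all(vapply(bundles, inherits, logical(1), "model_bundle")))
  keys <- vapply(bundles, bundle_key, character(1))
  if (anyDuplicated(keys))
    stop("registry integrity error: duplicate bundle key(s): ",
         paste(unique(keys[duplicated(keys)]), collapse = ", "), call. = FALSE)
  structure(list(bundles = stats::setNames(bundles, keys)),
            class = "bundle_registry")
}

#' @export
print.bundle_registry <- function(x, ...) {
  cat(sprintf("<bundle_registry> %d bundle(s)\n", length(x$bundles)))
  for (k in names(x$bundles)) cat(" ", k, "\n")
  invisible(x)
}

#' Select a model bundle from the registry
#'
#' @param registry a [bundle_registry()].
#' @param surgery_group,model_type bundle key components.
#' @param dataset_version version string; when `NULL`, the latest version
#'   (by natural sort order) among matching bundles is used.
#' @return The matching [model_bundle()].
#' @export
select_models <- function(registry, surgery_group, model_type,
                          dataset_version = NULL) {
  stopifnot(inherits(registry, "bundle_registry"))
  hits <- Filter(function(b)
    b$surgery_group == surgery_group && b$model_type == model_type &&
      (is.null(dataset_version) || b$dataset_version == dataset_version),
    registry$bundles)
  if (!length(hits))
    stop(sprintf(
      "no bundle for (%s, %s%s); available: %s", surgery_group, model_type,
      if (is.null(dataset_version)) "" else paste0(", ", dataset_version),
      paste(names(registry$bundles), collapse = "; ")), call. = FALSE)
  if (is.null(dataset_version) && length(hits) > 1L) {
    vers <- vapply(hits, function(b) b$dataset_version, character(1))
    hits <- hits[order(vers)]
  }
  hits[[length(hits)]]
}

validate_request <- function(request, bundle) {
  problems <- character(0)
  req <- bundle$required_fields
  missing <- req[!vapply(req, function(f)
    !is.null(request[[f]]) && !is.na(request[[f]]) &&
      !(is.character(request[[f]]) && request[[f]] == ""), logical(1))]
  if (length(missing))
    problems <- c(problems, paste0("missing field: ", missing))
  num <- function(f) suppressWarnings(as.numeric(request[[f]]))
  if (!is.null(request$asa) && !is.na(request$asa) && !num("asa") %in% c(1, 2, 3))
    problems <- c(problems, "asa: must be 1, 2 or 3")
  if (!is.null(request$age) && !is.na(request$age) &&
      (num("age") < 30 || num("age") > 100))
    problems <- c(problems, "age: must be within [30, 100] years")
  if (!is.null(request$bmi) && !is.na(request$bmi) &&
      (num("bmi") < 15 || num("bmi") > 55))
    problems <- c(problems, "bmi: must be within [15, 55] kg/m^2")
  problems
}

risk_curve <- function(model, x, years) {
  risks <- vapply(years, function(t) event_probability(model, x, t), numeric(1))
  data.frame(year = years, cumulative_risk = risks)
}

#' Personalised PROM and risk calculation
#'
#' Runs the full pipeline for one patient request: bundle selection,
#' request validation, PROM prediction, and yearly mortality and revision
#' risk curves. Deterministic: identical requests give identical results.
#'
#' @param request named list (or one-row data frame) of survey answers;
#'   must contain `surgery_group`, and the fields the bundle requires
#'   (`age`, `sex`, `bmi`, `asa`, `prom_pre`, plus any model covariates).
#' @param registry a [bundle_registry()].
#' @param model_type `"community"` or `"clinic"`.
#' @param dataset_version version string, or `NULL` for latest.
#' @param horizon_years number of years for both risk curves (default 10).
#' @return An object of class `result_set`: list with `prom_score`
#'   (integer), `mortality` and `revision` risk-curve data frames
#'   (`year`, `cumulative_risk`), and `headline` (1-year mortality,
#'   10-year revision).
#' @export
calculate <- function(request, registry, model_type = "community",
                      dataset_version = NULL, horizon_years = 10L) {
  if (is.data.frame(request)) request <- as.list(request[1L, , drop = FALSE])
  sg <- request$surgery_group
  if (is.null(sg) || !sg %in% surgery_groups)
    stop("request validation failed: surgery_group must be one of ",
         paste(surgery_groups, collapse = ", "), call. = FALSE)
  bundle <- select_models(registry, sg, model_type, dataset_version)
  problems <- validate_request(request, bundle)
  if (length(problems))
    stop("request validation failed:\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)

  rec <- as.data.frame(request[setdiff(names(request), "surgery_group")],
                       stringsAsFactors = FALSE)
  prom_score <- predict_prom(bundle$prom, rec)

  surv_x <- function(model) {
    nms <- model$covariate_names %||% character(0)
    if (!length(nms)) return(NULL)
    vals <- vapply(nms, function(nm) as.numeric(request[[nm]]), numeric(1))
    matrix(vals, nrow = 1L, dimnames = list(NULL, nms))
  }
  years <- seq_len(horizon_years)
  mortality <- risk_curve(bundle$mortality, surv_x(bundle$mortality), years)
  revision <- risk_curve(bundle$revision, surv_x(bundle$revision), years)

  headline <- list(
    mortality_1yr = mortality$cumulative_risk[mortality$year == 1L],
    revision_10yr = if (10L %in% revision$year)
      revision$cumulative_risk[revision$year == 10L]
    else revision$cumulative_risk[nrow(revision)]
  )
  structure(list(prom_score = prom_score, mortality = mortality,
                 revision = revision, headline = headline,
                 bundle_key = bundle_key(bundle)),
            class = "result_set")
}

#' @export
print.result_set <- function(x, ...) {
  cat(sprintf("<result_set> bundle %s\n", x$bundle_key))
  cat(sprintf("  predicted post-operative PROM score: %d\n", x$prom_score))
  cat(sprintf("  mortality risk within 1 year:  %.2f%%\n",
              100 * x$headline$mortality_1yr))
  cat(sprintf("  revision risk within 10 years: %.2f%%\n",
              100 * x$headline$revision_10yr))
  invisible(x)
}

# ---- bundle serialisation (JSON) ------------------------------------------

flexph_to_list <- function(m) {
  list(gamma = m$gamma, beta = as.list(m$beta), scale = m$scale,
       knots = list(boundary = m$knots$boundary, internal = m$knots$internal))
}

flexph_from_list <- function(l, what) {
  for (f in c("gamma", "scale", "knots"))
    if (is.null(l[[f]]))
      stop(sprintf("malformed bundle: %s model missing \"%s\"", what, f),
           call. = FALSE)
  if (is.null(l$knots$boundary))
    stop(sprintf("malformed bundle: %s model missing \"knots.boundary\"", what),
         call. = FALSE)
  beta <- unlist(l$beta) %||% numeric(0)
  flexph_model(unlist(l$gamma),
               knot_set(unlist(l$knots$boundary),
                        unlist(l$knots$internal) %||% numeric(0)),
               beta = beta, scale = l$scale)
}

#' Save a model bundle to a JSON file
#'
#' @param bundle a [model_bundle()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  payload <- list(
    format_version = bundle$format_version,
    surgery_group = bundle$surgery_group,
    model_type = bundle$model_type,
    dataset_version = bundle$dataset_version,
    covariate_schema = bundle$covariate_schema,
    required_fields = bundle$required_fields,
    prom = list(coefficients = as.list(bundle$prom$coefficients),
                covariates = bundle$prom$covariates,
                intercept = bundle$prom$intercept,
                score_range = bundle$prom$score_range),
    mortality = flexph_to_list(bundle$mortality),
    revision = flexph_to_list(bundle$revision))
  jsonlite::write_json(payload, path, auto_unbox = TRUE,
                       digits = I(17), pretty = TRUE)
  invisible(path)
}

#' Load a model bundle from a JSON file
#'
#' Fails loudly on unknown format versions or missing components.
#'
#' @param path bundle file path.
#' @return A [model_bundle()].
#' @export
load_bundle <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e)
                        stop("malformed bundle file ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  fv <- payload$format_version
  if (is.null(fv) || fv != BUNDLE_FORMAT_VERSION)
    stop(sprintf("unsupported bundle format version %s (expected %d)",
                 fv %||% "<missing>", BUNDLE_FORMAT_VERSION), call. = FALSE)
  for (f in c("surgery_group", "model_type", "dataset_version",
              "prom", "mortality", "revision"))
    if (is.null(payload[[f]]))
      stop(sprintf("malformed bundle: missing \"%s\"", f), call. = FALSE)
  pm <- payload$prom
  if (is.null(pm$coefficients))
    stop("malformed bundle: prom model missing \"coefficients\"", call. = FALSE)
  prom <- prom_model(unlist(pm$coefficients),
                     covariates = unlist(pm$covariates) %||% character(0),
                     intercept = isTRUE(pm$intercept),
                     score_range = unlist(pm$score_range))
  b <- model_bundle(payload$surgery_group, payload$model_type,
                    payload$dataset_version, prom,
                    flexph_from_list(payload$mortality, "mortality"),
                    flexph_from_list(payload$revision, "revision"),
                    required_fields = unlist(payload$required_fields))
  stored <- unlist(payload$covariate_schema)
  if (!is.null(stored) && !setequal(stored, b$covariate_schema))
    stop("bundle integrity error: stored covariate schema does not match the models",
         call. = FALSE)
  b
}
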