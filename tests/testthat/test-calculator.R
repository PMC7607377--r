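test_that("registry lookup matches keys exactly and resolves the latest version", {
  reg <- bundle_registry(list(
    toy_bundle(dataset_version = "v1"),
    toy_bundle(dataset_version = "v2"),
    toy_bundle(dataset_version = "v1", model_type = "clinic")))
  hit <- select_models(reg, "hip", "community", "v1")
  expect_equal(hit$dataset_version, "v1")
  latest <- select_models(reg, "hip", "community")
  expect_equal(latest$dataset_version, "v2")
  expect_error(select_models(reg, "hip", "community", "v9"), "available")
  expect_error(select_models(reg, "total_knee", "community"), "available")
  expect_error(bundle_registry(list(toy_bundle(), toy_bundle())), "duplicate")
})

test_that("the personalised calculation reproduces closed-form risks", {
  # unit-exponential mortality baseline, revision Lambda0(t) = 0.01 t,
  # no covariate effects on either hazard
  reg <- bundle_registry(list(toy_bundle(mort_gamma = c(0, 1),
                                         rev_gamma = c(log(0.01), 1))))
  res <- calculate(base_request(), reg)
  expect_equal(res$headline$mortality_1yr, 1 - exp(-1), tolerance = 1e-12)
  expect_equal(res$headline$revision_10yr, 1 - exp(-0.1), tolerance = 1e-12)
  # prom coefficients (0.5, 0.1, 0) at PROM_pre 20, age 60 give raw 16
  expect_identical(res$prom_score, 16L)
  expect_equal(res$mortality$year, 1:10)
  expect_true(all(diff(res$mortality$cumulative_risk) >= 0))
  expect_true(all(diff(res$revision$cumulative_risk) >= 0))
})

test_that("calculate is deterministic and validates requests before computing", {
  reg <- bundle_registry(list(toy_bundle()))
  r1 <- calculate(base_request(), reg)
  r2 <- calculate(base_request(), reg)
  expect_identical(r1, r2)

  expect_error(calculate(base_request(age = 101), reg), "age")
  expect_error(calculate(base_request(asa = 4), reg), "asa")
  expect_error(calculate(base_request(bmi = 14), reg), "bmi")
  expect_error(calculate(base_request(prom_pre = NULL), reg), "prom_pre")
  expect_error(calculate(base_request(surgery_group = "ankle"), reg),
               "surgery_group")
})

test_that("a community bundle never requires clinic-only fields", {
  reg <- bundle_registry(list(toy_bundle()))
  clinic_request <- base_request(implant_type = "cemented")
  stripped <- clinic_request[setdiff(names(clinic_request), "implant_type")]
  expect_s3_class(calculate(stripped, reg), "result_set")
})

test_that("bundles round-trip through JSON bit-exactly", {
  sim <- simulate_cohort(generator_config(n = 600), seed = 9)
  dat <- sim$cohort
  bundle <- model_bundle(
    "total_knee", "community", "2024-01",
    prom = fit_prom(dat, covariates = "male"),
    mortality = fit_flexph(recode_competing_event(dat, "death"),
                           covariates = c("age_c", "male"), m = 1),
    revision = fit_flexph(recode_competing_event(dat, "revision"),
                          covariates = c("age_c", "male"), m = 0))
  path <- withr::local_tempfile(fileext = ".json")
  save_bundle(bundle, path)
  back <- load_bundle(path)
  expect_identical(back$prom$coefficients, bundle$prom$coefficients)
  expect_identical(back$mortality$gamma, bundle$mortality$gamma)
  expect_identical(back$mortality$beta, bundle$mortality$beta)
  expect_identical(back$revision$knots, bundle$revision$knots)
  expect_identical(back$covariate_schema, bundle$covariate_schema)
})

test_that("malformed bundle files fail loudly naming the missing piece", {
  path <- withr::local_tempfile(fileext = ".json")
  save_bundle(toy_bundle(), path)
  payload <- jsonlite::read_json(path)

  broken <- payload; broken$mortality$gamma <- NULL
  jsonlite::write_json(broken, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_bundle(path), "gamma")

  broken <- payload; broken$format_version <- 99
  jsonlite::write_json(broken, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_bundle(path), "version")

  broken <- payload; broken$covariate_schema <- list("nonexistent_field")
  jsonlite::write_json(broken, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_bundle(path), "integrity")

  writeLines("{not json", path)
  expect_error(load_bundle(path), "malformed")
})
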