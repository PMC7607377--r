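test_that("k-fold partitions are disjoint, exhaustive, balanced, and reproducible", {
  p <- kfold_partition(100, 5, seed = 1)
  expect_length(p, 5)
  expect_equal(lengths(p), rep(20L, 5))
  expect_setequal(unlist(p), 1:100)

  p2 <- kfold_partition(101, 5, seed = 1)
  expect_equal(sort(lengths(p2), decreasing = TRUE), c(21L, 20L, 20L, 20L, 20L))
  expect_setequal(unlist(p2), 1:101)

  expect_identical(kfold_partition(57, 4, seed = 7),
                   kfold_partition(57, 4, seed = 7))
  expect_error(kfold_partition(3, 5), "folds")
})

test_that("every record is held out exactly once per repetition", {
  for (r in 1:5) {
    folds <- kfold_partition(83, 5, seed = 100 + r)
    expect_equal(sort(unlist(folds)), 1:83)
    expect_equal(sum(lengths(folds)), 83L)
  }
})

test_that("a constant metric yields a zero-width confidence interval", {
  dat <- data.frame(x = 1:40)
  res <- repeated_cv(dat, fit_fn = function(train) NULL,
                     metric_fns = list(const = function(model, test) 1),
                     repetitions = 10, k = 5, seed = 1)
  expect_equal(res$const$overall_mean, 1)
  expect_equal(res$const$ci_low, 1)
  expect_equal(res$const$ci_high, 1)
  expect_equal(mean(res$const$per_repetition_values),
               res$const$overall_mean, tolerance = 1e-12)
})

test_that("held-out RMSE is at interpolation level on noiseless linear data", {
  set.seed(51)
  n <- 300
  dat <- data.frame(prom_pre = sample(0:48, n, TRUE), age = runif(n, 30, 100))
  dat$prom_post <- 0.4 * dat$prom_pre + 0.2 * dat$age - 0.001 * dat$age^2 + 8
  res <- cv_prom(dat, repetitions = 10, k = 5, seed = 2)
  expect_lt(max(res$rmse$per_repetition_values), 1e-6)
})

test_that("cross-validation aborts when too many repetitions fail", {
  dat <- data.frame(x = 1:30)
  expect_error(
    repeated_cv(dat, fit_fn = function(train) stop("boom"),
                metric_fns = list(m = function(model, test) 1),
                repetitions = 5, k = 5, seed = 1),
    "failed")
})

test_that("concordance matches a brute-force all-pairs oracle exactly", {
  expect_equal(concordance_index(c(3, 2, 1), times = c(1, 2, 3),
                                 events = c(1, 1, 1)), 1)
  expect_equal(concordance_index(c(1, 1, 1), times = c(1, 2, 3),
                                 events = c(1, 1, 1)), 0.5)
  expect_error(concordance_index(1, times = 1, events = 0), "usable")

  set.seed(52)
  n <- 50
  risk <- sample(1:8, n, TRUE)          # ties on purpose
  times <- round(rexp(n, 0.3), 1)        # tied times on purpose
  events <- rbinom(n, 1, 0.7)
  num <- 0; den <- 0
  for (i in 1:n) for (j in 1:n) {
    if (i == j || times[i] >= times[j] || events[i] != 1) next
    den <- den + 1
    if (risk[i] > risk[j]) num <- num + 1
    else if (risk[i] == risk[j]) num <- num + 0.5
  }
  expect_identical(concordance_index(risk, times, events), num / den)
})

test_that("brier score handles censoring by excluding unknown status", {
  # events at 1 and 3, censored at 2 and 6; horizon 5
  risk <- c(0.9, 0.2, 0.8, 0.1)
  times <- c(1, 2, 3, 6)
  events <- c(1, 0, 1, 0)
  # record 2 (censored before 5) is excluded; outcomes are 1, 1, 0
  expect_equal(brier_score(risk, times, events, horizon = 5),
               mean(c((0.9 - 1)^2, (0.8 - 1)^2, (0.1 - 0)^2)))
  expect_error(brier_score(0.5, times = 1, events = 0, horizon = 5),
               "undefined")
})

test_that("cross-validated concordance recovers the generating model's true concordance", {
  cfg <- generator_config(n = 2000,
                          mortality = list(gamma = c(log(0.08), 1),
                                           beta = c(age_c = 0.7, male = 0.3)))
  sim <- simulate_cohort(cfg, seed = 53)
  dat <- recode_competing_event(sim$cohort, "death")
  res <- cv_flexph(dat, c("age_c", "male"), m = 0, repetitions = 3, k = 5,
                   seed = 54)

  # Monte-Carlo oracle: true concordance of the generating model from 1e6
  # independent uncensored pairs
  truth <- sim$truth$mortality
  set.seed(55)
  npairs <- 1e6
  draw <- function(seed_shift) {
    covs <- simulate_covariates(generator_config(n = npairs), seed = 55 + seed_shift)
    lp <- drop(as.matrix(covs[c("age_c", "male")]) %*% truth$beta)
    u <- runif(npairs)
    list(lp = lp, t = exp((log(-log(u)) - lp - truth$gamma[1]) / truth$gamma[2]))
  }
  a <- draw(1); b <- draw(2)
  earlier_a <- a$t < b$t
  concordant <- (earlier_a & a$lp > b$lp) | (!earlier_a & b$lp > a$lp)
  true_c <- mean(concordant + 0.5 * (a$lp == b$lp))
  expect_equal(res$concordance$overall_mean, true_c, tolerance = 0.03)
  expect_lt(res$brier$overall_mean, 0.25)
})

test_that("cross-validation reports round-trip through JSON", {
  dat <- data.frame(x = 1:40)
  res <- repeated_cv(dat, function(train) NULL,
                     list(const = function(model, test) 2.5),
                     repetitions = 4, k = 4, seed = 3)
  path <- withr::local_tempfile(fileext = ".json")
  write_cv_report(res, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$const$overall_mean, 2.5)
})
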