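# Small simulation helpers, deliberately independent of the package's own
# generator so parameter-recovery checks have an outside oracle.

# Weibull PH times: Lambda0(t) = (t/scale)^shape, multiplied by exp(X beta).
rweibull_ph <- function(n, shape, scale, beta = NULL, X = NULL,
                        censor = Inf, seed = 1L) {
  set.seed(seed)
  bx <- if (is.null(beta)) rep(0, n) else drop(X %*% beta)
  u <- runif(n)
  t <- scale * (-log(u) / exp(bx))^(1 / shape)
  data.frame(time = pmin(t, censor), event = as.numeric(t <= censor))
}

# A tiny valid patient record for calculator tests.
base_request <- function(...) {
  utils::modifyList(
    list(surgery_group = "hip", age = 60, sex = "female", bmi = 28,
         asa = 2, prom_pre = 20L),
    list(...))
}

# A bundle whose three models have hand-chosen coefficients (no covariates
# on the survival side), for closed-form pipeline checks.
toy_bundle <- function(mort_gamma = c(0, 1), rev_gamma = c(log(0.01), 1),
                       dataset_version = "v1", model_type = "community") {
  kn <- knot_set(c(log(0.01), log(50)))
  model_bundle(
    surgery_group = "hip", model_type = model_type,
    dataset_version = dataset_version,
    prom = prom_model(c(prom_pre = 0.5, age = 0.1, age2 = 0),
                      intercept = FALSE),
    mortality = flexph_model(mort_gamma, kn),
    revision = flexph_model(rev_gamma, kn))
}
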