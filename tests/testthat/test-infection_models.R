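test_that("intercept-only logistic fit equals the logit of the proportion", {
  hosts <- survey_loads(toy_survey(23, 27))
  fit <- fit_glm(hosts, design_spec(response = "infected",
                                    predictors = character(0),
                                    reference_levels = list()))
  expect_equal(unname(fit$coefficients["(Intercept)"]),
               qlogis(23 / 27), tolerance = 1e-6)
  expect_equal(fit$family, "binomial-logit")
  expect_equal(fit$n_obs, 27)
})

test_that("gaussian fit is exact when the response is a predictor", {
  hosts <- survey_loads(toy_survey(20, 20))
  set.seed(3)
  hosts$length_um <- runif(20, 3000, 8000)
  hosts$load_copies_ng <- exp(hosts$length_um / 1000)
  fit <- fit_glm(hosts, design_spec(response = "log_load",
                                    predictors = "length_um",
                                    reference_levels = list()))
  expect_equal(unname(fit$coefficients["length_um"]), 1 / 1000)
  expect_lt(sum(residuals(fit$fit)^2), 1e-16)
})

test_that("duplicating every row shrinks gaussian SEs by sqrt(2) exactly", {
  set.seed(4)
  hosts <- survey_loads(toy_survey(30, 30))
  hosts$length_um <- runif(30, 3000, 8000)
  hosts$load_copies_ng <- exp(0.5 + hosts$length_um / 5000 + rnorm(30, 0, 0.3))
  spec <- design_spec(response = "log_load", predictors = "length_um",
                      reference_levels = list())
  f1 <- fit_glm(hosts, spec)
  doubled <- rbind(hosts, hosts)
  doubled$host_id <- sprintf("h%03d", seq_len(nrow(doubled)))
  f2 <- fit_glm(doubled, spec)
  expect_equal(f2$coefficients, f1$coefficients)
  # sqrt(2) shrink, corrected exactly for the residual-df change:
  # SE2 = SE1 * sqrt((n - p) / (2n - p)) -> SE1 / sqrt(2) as n grows
  n <- 30; p <- 2
  expect_equal(f2$standard_errors,
               f1$standard_errors * sqrt((n - p) / (2 * n - p)),
               tolerance = 1e-8)
  expect_equal(unname(f2$standard_errors / f1$standard_errors),
               rep(1 / sqrt(2), p), tolerance = 0.02)
})

test_that("rank-deficient designs error with the collinear term named", {
  hosts <- survey_loads(toy_survey(10, 12))
  hosts$density_ind_m2 <- hosts$length_um  # collinear copy
  expect_error(
    fit_glm(hosts, design_spec(predictors = c("length_um", "density_ind_m2"),
                               reference_levels = list())),
    "density_ind_m2")
})

test_that("pmm imputation: identity on complete data, PMM property, reproducibility", {
  hosts <- simulate_survey(hosts_per_cell = 10, seed = 31)
  comp <- pmm_impute(hosts, m = 3, iters = 2, seed = 5)
  expect_length(comp, 3)
  expect_identical(comp[[1]], comp[[2]])
  expect_identical(as.data.frame(comp[[1]])$length_um, hosts$length_um)

  sm <- survey_model(missing_length = 0.2, missing_organic = 0.15)
  holey <- simulate_survey(sm, hosts_per_cell = 10, seed = 32)
  imp <- pmm_impute(holey, m = 2, iters = 5, seed = 6)
  miss <- is.na(holey$length_um)
  expect_false(anyNA(imp[[1]]$length_um))
  # every imputed value occurs among the observed values of that variable
  expect_true(all(imp[[1]]$length_um[miss] %in% holey$length_um[!miss]))
  expect_true(all(imp[[1]]$organic_content_pct[is.na(holey$organic_content_pct)]
                  %in% holey$organic_content_pct[!is.na(holey$organic_content_pct)]))
  # bit-reproducible from the seed; different seeds diverge
  imp2 <- pmm_impute(holey, m = 2, iters = 5, seed = 6)
  expect_identical(imp, imp2)
  imp3 <- pmm_impute(holey, m = 2, iters = 5, seed = 7)
  expect_false(identical(imp[[1]]$length_um, imp3[[1]]$length_um))

  allna <- holey
  allna$length_um <- NA_real_
  expect_error(pmm_impute(allna), "every row")
})

test_that("density interpolation fills interior gaps on month indices", {
  d <- c(March = 120, May = 80, August = 100, October = NA, November = 50)
  filled <- interpolate_density(d)
  expect_equal(unname(filled["October"]), 100 + (50 - 100) * (10 - 8) / (11 - 8))
  expect_equal(unname(interpolate_density(
    c(August = 80, October = NA, November = 80))["October"]), 80)
  expect_error(interpolate_density(c(March = NA, May = 10, August = 12)),
               "boundary")
})

test_that("Rubin pooling arithmetic matches the hand-computed oracle", {
  fake_fit <- function(est, se, n = 100) {
    structure(list(coefficients = est, standard_errors = se,
                   vcov = diag(se^2), n_obs = n, family = "gaussian",
                   n_params = length(est), separation = FALSE),
              class = "fitted_model")
  }
  ests <- list(c(a = 1.0, b = -2.0), c(a = 1.4, b = -2.2),
               c(a = 0.8, b = -1.9), c(a = 1.1, b = -2.1),
               c(a = 1.2, b = -1.8))
  ses <- list(c(a = 0.5, b = 0.3), c(a = 0.55, b = 0.25),
              c(a = 0.45, b = 0.35), c(a = 0.5, b = 0.3),
              c(a = 0.6, b = 0.28))
  fits <- Map(fake_fit, ests, ses)
  pl <- rubin_pool(fits)
  est_mat <- do.call(cbind, ests); se_mat <- do.call(cbind, ses)
  W <- rowMeans(se_mat^2)
  B <- apply(est_mat, 1, var)
  expect_equal(unname(pl$estimates), unname(rowMeans(est_mat)))
  expect_equal(unname(pl$within_var), unname(W))
  expect_equal(unname(pl$between_var), unname(B))
  expect_equal(unname(pl$total_var), unname(W + (1 + 1 / 5) * B))
  expect_true(all(pl$total_var >= pl$within_var))

  one <- rubin_pool(fits[1])
  expect_equal(one$estimates, ests[[1]])
  expect_equal(unname(one$within_var), unname(ses[[1]]^2))
  expect_equal(unname(one$between_var), c(0, 0))

  same <- rubin_pool(Map(fake_fit, rep(ests[1], 4), rep(ses[1], 4)))
  expect_equal(unname(same$between_var), c(0, 0))
  expect_equal(same$total_var, same$within_var)

  mismatched <- Map(fake_fit, list(c(a = 1), c(b = 1)),
                    list(c(a = 1), c(b = 1)))
  expect_error(rubin_pool(mismatched), "same terms")
})

test_that("odds ratios exponentiate pooled logistic estimates", {
  hosts <- survey_loads(toy_survey(15, 27))
  fit <- fit_glm(hosts, design_spec(response = "infected",
                                    predictors = character(0),
                                    reference_levels = list()))
  pl <- rubin_pool(list(fit))
  ors <- odds_ratios(pl)
  expect_equal(ors$or, exp(pl$estimates), ignore_attr = TRUE)
  expect_true(ors$ci_low < ors$or & ors$or < ors$ci_high)

  gfit <- structure(list(coefficients = c(a = 0), standard_errors = c(a = 1e-8),
                         vcov = diag(1e-16, 1), n_obs = 10,
                         family = "binomial-logit", n_params = 1,
                         separation = FALSE), class = "fitted_model")
  o <- odds_ratios(rubin_pool(list(gfit)))
  expect_equal(o$or, 1)
  gfit$family <- "gaussian"
  expect_error(odds_ratios(rubin_pool(list(gfit))), "logistic")
})

test_that("between-imputation variance is positive when data are missing", {
  sm <- survey_model(missing_length = 0.25)
  hosts <- simulate_survey(sm, hosts_per_cell = 15, seed = 41)
  imps <- pmm_impute(hosts, m = 3, iters = 5, seed = 42)
  spec <- design_spec(predictors = c("population", "month", "length_um",
                                     "density_ind_m2"))
  pl <- rubin_pool(lapply(imps, fit_glm, spec = spec))
  expect_gt(pl$between_var[["length_um"]], 0)
  expect_true(all(pl$total_var >= pl$within_var))
})
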