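#' Model design specification
#'
#' Declares the response, the predictor set, and the reference level of
#' each categorical predictor for the survey regressions: a binomial-logit
#' model of infection status, or a gaussian model of log infection load
#' (natural log; only infected hosts, load > 0, enter that model).
#'
#' @param response `"infected"` or `"log_load"`.
#' @param predictors Subset of `population`, `month`, `length_um`,
#'   `density_ind_m2`, `organic_content_pct`.
#' @param reference_levels Named list of reference levels for the
#'   categorical predictors; defaults `population = "Herslev"`,
#'   `month = "March"` (ignored when absent from the data).
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(response = c("infected", "log_load"),
                        predictors = c("population", "month", "length_um",
                                       "density_ind_m2"),
                        reference_levels = list(population = "Herslev",
                                                month = "March")) {
  response <- match.arg(response)
  allowed <- c("population", "month", "length_um", "density_ind_m2",
               "organic_content_pct")
  bad <- setdiff(predictors, allowed)
  if (length(bad))
    stop("design_spec: unknown predictor(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(response = response, predictors = predictors,
                 reference_levels = reference_levels),
            class = "design_spec")
}

model_frame_for <- function(hosts, spec) {
  df <- as.data.frame(hosts)
  if (!"load_copies_ng" %in% names(df))
    stop("fit_glm: hosts need a 'load_copies_ng' column (see survey_loads())",
         call. = FALSE)
  df$infected <- as.integer(infected_flag(df$load_copies_ng))
  if (spec$response == "log_load") {
    df <- df[!is.na(df$load_copies_ng) & df$load_copies_ng > 0, , drop = FALSE]
    df$log_load <- log(df$load_copies_ng)
  }
  for (v in intersect(c("population", "month"), spec$predictors)) {
    ref <- spec$reference_levels[[v]]
    df[[v]] <- factor(df[[v]])
    if (!is.null(ref) && ref %in% levels(df[[v]]))
      df[[v]] <- stats::relevel(df[[v]], ref = ref)
    else if (!is.null(ref))
      stop(sprintf("fit_glm: reference level '%s' absent from '%s'", ref, v),
           call. = FALSE)
  }
  keep <- c(spec$response, spec$predictors)
  df <- df[stats::complete.cases(df[keep]), , drop = FALSE]
  df
}

#' Fit the survey regression on one (complete) dataset
#'
#' Binomial-logit (infection status) or gaussian (log load) regression via
#' iteratively reweighted least squares, with categorical predictors
#' dummy-coded against the declared reference levels. Complete cases only;
#' rows with a missing predictor are dropped (impute first with
#' [pmm_impute()] if that is not acceptable).
#'
#' @param hosts A `host_survey` data.frame with `load_copies_ng` (see
#'   [survey_loads()]).
#' @param spec A [design_spec()].
#' @return A list of class `fitted_model`: `coefficients`,
#'   `standard_errors`, `vcov`, `n_obs`, `family`, `separation` (perfect
#'   separation flag) and the underlying `glm` fit.
#' @export
fit_glm <- function(hosts, spec = design_spec()) {
  stopifnot(inherits(spec, "design_spec"))
  df <- model_frame_for(hosts, spec)
  if (nrow(df) == 0L)
    stop("fit_glm: no complete cases", call. = FALSE)
  fam <- if (spec$response == "infected") stats::binomial("logit")
  else stats::gaussian()
  fml <- stats::as.formula(paste(
    spec$response, "~",
    if (length(spec$predictors)) paste(spec$predictors, collapse = " + ")
    else "1"))
  fit <- suppressWarnings(
    stats::glm(fml, family = fam, data = df,
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)))
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("fit_glm: rank-deficient design; collinear term(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  separation <- spec$response == "infected" &&
    (!fit$converged || any(abs(stats::coef(fit)) > 15))
  if (separation)
    warning("fit_glm: possible perfect separation; coefficients unreliable")
  V <- stats::vcov(fit)
  structure(
    list(coefficients = stats::coef(fit),
         standard_errors = sqrt(diag(V)),
         vcov = V, n_obs = nrow(df),
         family = if (spec$response == "infected") "binomial-logit"
         else "gaussian",
         n_params = length(stats::coef(fit)),
         separation = separation, fit = fit),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> %s, n = %d\n", x$family, x$n_obs))
  print(round(cbind(estimate = x$coefficients, se = x$standard_errors), 4))
  invisible(x)
}

# One chained-equations sweep target: linear regression of `target` on the
# other covariates over rows where `target` is observed, then PMM draws for
# the missing rows.
pmm_draw <- function(data, target, predictors, donors) {
  obs <- !is.na(data[[paste0(".obs_", target)]]) &
    data[[paste0(".obs_", target)]]
  fml <- stats::as.formula(paste(
    target, "~", if (length(predictors)) paste(predictors, collapse = " + ")
    else "1"))
  fit <- stats::lm(fml, data = data[obs, , drop = FALSE])
  pred_all <- stats::predict(fit, newdata = data)
  miss_idx <- which(!obs)
  obs_idx <- which(obs)
  for (i in miss_idx) {
    d <- abs(pred_all[obs_idx] - pred_all[i])
    pool <- obs_idx[order(d, stats::runif(length(d)))][
      seq_len(min(donors, length(obs_idx)))]
    data[[target]][i] <- data[[target]][sample(pool, 1L)]
  }
  data
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Fills missing numeric covariates by fully conditional specification:
#' each incomplete variable is regressed on the other covariates over the
#' currently completed data, missing cells are predicted, and each is
#' replaced by the observed value of a donor drawn at random from the
#' `donors` observed rows with the nearest predictions. Sweeps repeat
#' `iters` times per imputation; `m` independent imputations are returned.
#' Every imputed value is, by construction, an observed value of its
#' variable.
#'
#' @param hosts Data frame with missing cells confined to numeric
#'   covariates.
#' @param vars Variables to impute (default `c("length_um",
#'   "organic_content_pct")`); variables with no missing cells are skipped.
#' @param predictors Covariates used in the chained regressions; categorical
#'   columns are allowed. Defaults to population, month and the numeric
#'   covariates. When a `load_copies_ng` column is present, infection status
#'   and log1p(load) are added automatically: an imputation model must
#'   condition on the analysis outcome or it attenuates the
#'   covariate–outcome association in the pooled fit.
#' @param m Number of imputations (default 5).
#' @param iters Chained-equation sweeps per imputation (default 50).
#' @param donors Donor-pool size (default 5).
#' @param seed Integer seed; the result is bit-reproducible given
#'   `(data, parameters, seed)`.
#' @return A list of `m` completed data frames.
#' @export
pmm_impute <- function(hosts, vars = c("length_um", "organic_content_pct"),
                       predictors = c("population", "month", "length_um",
                                      "density_ind_m2",
                                      "organic_content_pct"),
                       m = 5L, iters = 50L, donors = 5L, seed = 1L) {
  df <- as.data.frame(hosts)
  vars <- intersect(vars, names(df))
  vars <- vars[vapply(vars, function(v) anyNA(df[[v]]), logical(1))]
  if (length(vars) == 0L) return(replicate(m, df, simplify = FALSE))
  for (v in vars) {
    if (all(is.na(df[[v]])))
      stop(sprintf("pmm_impute: '%s' is missing for every row", v),
           call. = FALSE)
    if (!is.numeric(df[[v]]))
      stop(sprintf("pmm_impute: '%s' is not numeric", v), call. = FALSE)
  }
  predictors <- intersect(predictors, names(df))
  if ("load_copies_ng" %in% names(df) && !anyNA(df$load_copies_ng)) {
    df$.infected <- as.integer(df$load_copies_ng > 0)
    df$.log1p_load <- log1p(df$load_copies_ng)
    predictors <- union(predictors, c(".infected", ".log1p_load"))
  }
  other_miss <- setdiff(predictors, vars)
  other_miss <- other_miss[vapply(other_miss, function(v) anyNA(df[[v]]),
                                  logical(1))]
  if (length(other_miss))
    stop("pmm_impute: predictor(s) with unhandled missing cells: ",
         paste(other_miss, collapse = ", "),
         " (interpolate or add them to 'vars')", call. = FALSE)
  for (v in vars) df[[paste0(".obs_", v)]] <- !is.na(df[[v]])
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  out <- vector("list", m)
  for (imp in seq_len(m)) {
    cur <- df
    # initialise missing cells with random observed draws
    for (v in vars) {
      miss <- !cur[[paste0(".obs_", v)]]
      cur[[v]][miss] <- sample(cur[[v]][!miss], sum(miss), replace = TRUE)
    }
    for (it in seq_len(iters)) {
      for (v in vars)
        cur <- pmm_draw(cur, v, setdiff(predictors, v), donors)
    }
    cur <- cur[, !startsWith(names(cur), "."), drop = FALSE]
    out[[imp]] <- cur
  }
  out
}

#' Linear interpolation of a density gap
#'
#' Completes a per-population density series with one interior gap by
#' linear interpolation on calendar month index (March = 3, May = 5,
#' August = 8, October = 10, November = 11). Gaps at a series boundary are
#' an error: no extrapolation.
#'
#' @param density Named numeric vector (or 1-column series) of densities,
#'   names being month names or indices; `NA` marks the gap(s).
#' @param month_index Optional numeric month indices; defaults to mapping
#'   the names through the standard calendar.
#' @return The completed numeric vector.
#' @export
interpolate_density <- function(density, month_index = NULL) {
  month_map <- c(January = 1, February = 2, March = 3, April = 4, May = 5,
                 June = 6, July = 7, August = 8, September = 9,
                 October = 10, November = 11, December = 12)
  if (is.null(month_index)) {
    if (is.null(names(density)))
      stop("interpolate_density: need month names or explicit month_index",
           call. = FALSE)
    month_index <- month_map[names(density)]
    if (anyNA(month_index))
      month_index <- suppressWarnings(as.numeric(names(density)))
    if (anyNA(month_index))
      stop("interpolate_density: unrecognised month names", call. = FALSE)
  }
  stopifnot(length(month_index) == length(density))
  o <- order(month_index)
  x <- month_index[o]; y <- as.numeric(density)[o]
  miss <- which(is.na(y))
  if (!length(miss)) return(density)
  if (1L %in% miss || length(y) %in% miss)
    stop("interpolate_density: gap at series boundary; no extrapolation",
         call. = FALSE)
  filled <- stats::approx(x[!is.na(y)], y[!is.na(y)], xout = x,
                          method = "linear")$y
  y[miss] <- filled[miss]
  out <- density
  out[o] <- y
  out
}

#' Pool fitted models over imputations with Rubin's rules
#'
#' Pooled estimate = mean of the per-imputation estimates; within-imputation
#' variance W = mean squared SE; between-imputation variance B = sample
#' variance of the estimates; total variance T = W + (1 + 1/m) B. Per-term
#' degrees of freedom follow the Barnard–Rubin small-sample formula, and
#' the per-term Wald statistic is estimate / sqrt(T) with a two-sided
#' t-distribution p-value.
#'
#' @param fits List of `m >= 1` [fit_glm()] results sharing the same terms.
#' @return A list of class `pooled_model` with `estimates`, `total_se`,
#'   `within_var`, `between_var`, `df`, `statistic`, `p_value`, `m`,
#'   `family`, `n_obs`.
#' @export
rubin_pool <- function(fits) {
  if (inherits(fits, "fitted_model")) fits <- list(fits)
  stopifnot(length(fits) >= 1L,
            all(vapply(fits, inherits, logical(1), "fitted_model")))
  terms <- names(fits[[1]]$coefficients)
  for (f in fits)
    if (!identical(names(f$coefficients), terms))
      stop("rubin_pool: fits do not share the same terms", call. = FALSE)
  m <- length(fits)
  est <- matrix(unlist(lapply(fits, `[[`, "coefficients")),
                nrow = length(terms), dimnames = list(terms, NULL))
  ses <- matrix(unlist(lapply(fits, `[[`, "standard_errors")),
                nrow = length(terms), dimnames = list(terms, NULL))
  qbar <- rowMeans(est)
  W <- rowMeans(ses^2)
  B <- if (m > 1L) apply(est, 1, stats::var) else rep(0, length(qbar))
  Tv <- W + (1 + 1 / m) * B
  n <- fits[[1]]$n_obs; kpar <- fits[[1]]$n_params
  dfcom <- max(n - kpar, 1L)
  lam <- pmin(pmax((1 + 1 / m) * B / Tv, 0), 1 - 1e-12)
  df_old <- ifelse(lam > 0 & m > 1, (m - 1) / lam^2, Inf)
  df_obs <- dfcom * (dfcom + 1) / (dfcom + 3) * (1 - lam)
  dfs <- 1 / (1 / df_old + 1 / df_obs)
  stat <- qbar / sqrt(Tv)
  structure(
    list(estimates = qbar, total_se = sqrt(Tv), within_var = W,
         between_var = B, total_var = Tv, df = dfs, statistic = stat,
         p_value = 2 * stats::pt(-abs(stat), dfs), m = m,
         family = fits[[1]]$family, n_obs = n, terms = terms),
    class = "pooled_model"
  )
}

#' @export
print.pooled_model <- function(x, ...) {
  cat(sprintf("<pooled_model> %s pooled over m = %d imputation(s), n = %d\n",
              x$family, x$m, x$n_obs))
  print(round(data.frame(estimate = x$estimates, se = x$total_se,
                         df = x$df, t = x$statistic, p = x$p_value), 4))
  invisible(x)
}

#' Odds ratios from a pooled logistic model
#'
#' `OR = exp(estimate)` with a t-based confidence interval
#' `exp(estimate ± t(df) * sqrt(T))` per term.
#'
#' @param model A `pooled_model` with binomial-logit family.
#' @param level Confidence level (default 0.95).
#' @return A data.frame with columns `term`, `or`, `ci_low`, `ci_high`,
#'   `p_value`.
#' @export
odds_ratios <- function(model, level = 0.95) {
  stopifnot(inherits(model, "pooled_model"))
  if (model$family != "binomial-logit")
    stop("odds_ratios: model is not a logistic fit", call. = FALSE)
  tq <- stats::qt(1 - (1 - level) / 2, model$df)
  data.frame(
    term = model$terms,
    or = exp(model$estimates),
    ci_low = exp(model$estimates - tq * model$total_se),
    ci_high = exp(model$estimates + tq * model$total_se),
    p_value = model$p_value,
    row.names = NULL
  )
}
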