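#' Replicate reproducibility summary
#'
#' Mean, standard deviation, standard error and percent coefficient of
#' variation (`%CV = 100 * sd / mean`) for a set of replicate
#' concentrations. Instrument reports mix two SD conventions: group tables
#' typically use the population divisor (m) while in-text pairwise CVs use
#' the sample divisor (m - 1); both are exposed via `sd_mode`.
#'
#' @param values Replicate concentrations (copies/µl), length >= 1.
#' @param sd_mode `"population"` (divisor m) or `"sample"` (divisor m - 1).
#' @return A list of class `replicate_summary` with `mean`, `sd`, `se`,
#'   `cv_pct`, `m` and `sd_mode`.
#' @export
replicate_summary <- function(values, sd_mode = c("population", "sample")) {
  sd_mode <- match.arg(sd_mode)
  values <- as.numeric(values)
  if (length(values) == 0L || anyNA(values))
    stop("replicate_summary: need at least one non-missing value",
         call. = FALSE)
  m <- length(values)
  mu <- mean(values)
  s <- if (m == 1L) 0 else stats::sd(values)
  if (sd_mode == "population") s <- s * sqrt((m - 1) / m)
  structure(
    list(mean = mu, sd = s, se = s / sqrt(m),
         cv_pct = if (mu > 0) 100 * s / mu else NA_real_,
         m = m, sd_mode = sd_mode),
    class = "replicate_summary"
  )
}

#' @export
print.replicate_summary <- function(x, ...) {
  cat(sprintf("<replicate_summary> m=%d mean=%.4g sd=%.4g (%s) se=%.4g CV=%.1f%%\n",
              x$m, x$mean, x$sd, x$sd_mode, x$se, x$cv_pct))
  invisible(x)
}

# W statistic with tie-splitting: number of (x_i, y_j) pairs with x_i > y_j,
# plus 1/2 per exact tie. Identical to the Mann-Whitney U of x over y.
rank_sum_w <- function(x, y) {
  d <- outer(x, y, "-")
  sum(d > 0) + 0.5 * sum(d == 0)
}

#' Exact Wilcoxon rank-sum comparison of two replicate groups
#'
#' `w` counts pairs with `x_i > y_j` (half per tie). The two-sided p-value
#' is exact — by complete enumeration of rank assignments — whenever the
#' combined sample size is at most 20 and there are no ties; otherwise a
#' normal approximation with continuity and tie correction is used.
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A list of class `cartridge_comparison` with `w`, `p_value`,
#'   `method`, and the Hodges–Lehmann `shift` (median pairwise difference).
#' @export
rank_sum_test <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) > 0L, length(y) > 0L)
  m1 <- length(x); m2 <- length(y)
  w <- rank_sum_w(x, y)
  ties <- anyDuplicated(c(x, y)) > 0L
  if (m1 + m2 <= 20 && !ties) {
    # enumerate every assignment of m1 ranks out of m1+m2 to group x
    combos <- utils::combn(m1 + m2, m1)
    r <- rank(c(x, y))
    w_null <- colSums(matrix(combos, nrow = m1)) - m1 * (m1 + 1) / 2
    w_obs <- sum(r[seq_len(m1)]) - m1 * (m1 + 1) / 2
    centre <- m1 * m2 / 2
    p <- mean(abs(w_null - centre) >= abs(w_obs - centre) - 1e-12)
    method <- "exact"
  } else {
    r <- rank(c(x, y))
    w_obs <- sum(r[seq_len(m1)]) - m1 * (m1 + 1) / 2
    nt <- table(c(x, y))
    tie_term <- sum(nt^3 - nt) / ((m1 + m2) * (m1 + m2 - 1))
    sigma2 <- m1 * m2 / 12 * (m1 + m2 + 1 - tie_term)
    z <- (w_obs - m1 * m2 / 2 - sign(w_obs - m1 * m2 / 2) * 0.5) /
      sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal_approx"
  }
  structure(
    list(w = w, p_value = p, method = method,
         shift = hodges_lehmann_shift(x, y), m1 = m1, m2 = m2),
    class = "cartridge_comparison"
  )
}

#' @export
print.cartridge_comparison <- function(x, ...) {
  cat(sprintf("<rank-sum comparison> W = %g, p = %.4g (%s), HL shift = %g\n",
              x$w, x$p_value, x$method, x$shift))
  invisible(x)
}

#' Hodges–Lehmann location shift between two groups
#'
#' The median of all `m1 * m2` pairwise differences `x_i - y_j`; the
#' location-shift estimate attached to a rank-sum comparison ("median
#' shift" between droplet-generation events).
#'
#' @param x,y Numeric vectors, both non-empty.
#' @return A single number in the units of the inputs.
#' @export
hodges_lehmann_shift <- function(x, y) {
  stopifnot(length(x) > 0L, length(y) > 0L)
  stats::median(as.vector(outer(as.numeric(x), as.numeric(y), "-")))
}

#' Dynamic-range linearity of a dilution series
#'
#' Ordinary least squares of measured concentration on relative template
#' quantity over the QC-passing wells of a dilution series. `scale =
#' "log10"` regresses log10(concentration) on log10(fold) — a perfect
#' geometric series then has slope 1 — and must drop zero-concentration
#' wells; `scale = "linear"` regresses copies/µl on fold directly, which is
#' how dynamic-range r² is conventionally reported for these assays.
#'
#' @param quant A `well_quant` data.frame carrying a `dilution_fold` column
#'   (see [quantify_wells()]).
#' @param scale `"log10"` or `"linear"`.
#' @param qc_only Drop wells failing droplet QC first (default `TRUE`).
#' @return A list of class `linearity_result` with `slope`, `intercept`,
#'   `r2`, `p_value`, `n_points` and `scale`.
#' @export
dilution_linearity <- function(quant, scale = c("log10", "linear"),
                               qc_only = TRUE) {
  scale <- match.arg(scale)
  df <- as.data.frame(quant)
  if (!all(c("dilution_fold", "conc_copies_ul") %in% names(df)))
    stop("dilution_linearity: need 'dilution_fold' and 'conc_copies_ul' columns",
         call. = FALSE)
  if (qc_only && "qc_pass" %in% names(df)) df <- df[df$qc_pass, ]
  df <- df[!is.na(df$dilution_fold) & !is.na(df$conc_copies_ul), ]
  if (scale == "log10") df <- df[df$conc_copies_ul > 0, ]
  if (length(unique(df$dilution_fold)) < 2L || nrow(df) < 3L)
    stop("dilution_linearity: need >= 2 distinct dilution levels and >= 3 usable wells",
         call. = FALSE)
  xy <- if (scale == "log10")
    data.frame(x = log10(df$dilution_fold), y = log10(df$conc_copies_ul))
  else data.frame(x = df$dilution_fold, y = df$conc_copies_ul)
  fit <- stats::lm(y ~ x, data = xy)
  sm <- summary(fit)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r2 = sm$r.squared,
         p_value = unname(sm$coefficients[2, 4]),
         n_points = nrow(xy), scale = scale),
    class = "linearity_result"
  )
}

#' Limit of detection of a dilution series
#'
#' A dilution level is detected when every QC-passing replicate at that
#' level has at least `min_positive_droplets_lod` positive droplets
#' (default 3). The LOD is the most dilute detected level; the reported LOD
#' concentration is the mean of that level's per-replicate concentrations.
#' When no level is detected the result carries `lod_reached = FALSE`
#' rather than raising.
#'
#' @param quant A `well_quant` data.frame with a `dilution_fold` column.
#' @param cfg A [quant_config()].
#' @return A list of class `lod_result` with `lod_reached`, `lod_level`
#'   (dilution fold), `lod_conc` (copies/µl) and `per_level_pass` (named
#'   logical, folds descending).
#' @export
limit_of_detection <- function(quant, cfg = quant_config()) {
  df <- as.data.frame(quant)
  stopifnot(all(c("dilution_fold", "k", "conc_copies_ul") %in% names(df)))
  if ("qc_pass" %in% names(df)) df <- df[df$qc_pass, ]
  df <- df[!is.na(df$dilution_fold), ]
  if (nrow(df) == 0L)
    stop("limit_of_detection: no QC-passing wells", call. = FALSE)
  folds <- sort(unique(df$dilution_fold), decreasing = TRUE)
  pass <- vapply(folds, function(f) {
    all(df$k[df$dilution_fold == f] >= cfg$min_positive_droplets_lod)
  }, logical(1))
  names(pass) <- format(folds, trim = TRUE)
  if (!any(pass)) {
    res <- list(lod_reached = FALSE, lod_level = NA_real_,
                lod_conc = NA_real_, per_level_pass = pass)
  } else {
    lod_level <- min(folds[pass])
    res <- list(
      lod_reached = TRUE, lod_level = lod_level,
      lod_conc = mean(df$conc_copies_ul[df$dilution_fold == lod_level]),
      per_level_pass = pass)
  }
  structure(res, class = "lod_result")
}

#' @export
print.lod_result <- function(x, ...) {
  if (x$lod_reached)
    cat(sprintf("<lod_result> LOD %.3g copies/ul at dilution fold %g\n",
                x$lod_conc, x$lod_level))
  else cat("<lod_result> LOD not reached at any level\n")
  invisible(x)
}

#' Amplification efficiency from a standard-curve slope
#'
#' For a qPCR standard curve of Cq against log10(quantity) with slope `s`
#' (< 0), per-cycle efficiency is `(10^(-1/s) - 1) * 100` percent; a slope
#' of -3.3219 is perfect doubling (100%).
#'
#' @param slope Standard-curve slope, must be negative.
#' @return Efficiency in percent.
#' @examples
#' qpcr_efficiency(-3.465)   # 94.4
#' @export
qpcr_efficiency <- function(slope) {
  if (!is.numeric(slope) || any(slope >= 0))
    stop("qpcr_efficiency: slope must be negative", call. = FALSE)
  (10^(-1 / slope) - 1) * 100
}
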